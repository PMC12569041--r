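---
title: "Methods: conformational states, ligand bias and spectral analysis for KOR signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational states, ligand bias and spectral analysis for KOR signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(korbias)
```

korbias packages the quantitative analyses used in biased-signaling
studies of the kappa opioid receptor (KOR): classifying molecular
dynamics (MD) frames into intracellular conformational states, measuring
ligand-residue contact fingerprints, quantifying pathway bias from
NanoBiT luminescence dose-response data, analysing radioligand binding,
and extracting band shifts from ATR-FTIR ligand-exchange difference
spectra. This vignette records the models, the parameter choices, the
numerical conventions, and what the synthetic-data generators do and do
not emulate.

## The six-state conformational scheme

The intracellular face of an activated class-A GPCR is summarized here
by three observables per MD frame:

* **d** - the distance (Angstrom) between the Calpha of the TM3 residue
  at Ballesteros-Weinstein position 3.47 (S153 in KOR author numbering)
  and the Czeta of the NPxxY tyrosine 7.53 (Y330). It reports how far
  the TM7 tyrosine has dropped toward TM3.
* **chi** - the C-Calpha-Cgamma-Czeta dihedral of Y330 (degrees,
  IUPAC sign, range (-180, 180]). It distinguishes the tyrosine rotamer
  families.
* **r_down** - whether the side chain of the DRY arginine 3.50 (R156)
  points toward the intracellular side. Operationally: the projection of
  the Calpha-to-Czeta unit vector on the membrane normal is negative,
  with +z declared extracellular and a configurable angular threshold
  (default 90 degrees). This is the simplest testable reading of
  "facing downward"; softer definitions (e.g. a 60-degree cone) can be
  set via the `threshold` argument of `featurize()`.

Four base regions in the (d, chi) plane define states 1-4; states 2 and
3 split into A (r_down) and B (not) substates, giving six labels
`S1 S2A S2B S3A S3B S4`. State 1 is the canonical active conformation,
S2A carries an intracellular R3.50 with the canonical tyrosine rotamer,
S3A is the "alternative" conformation (both R3.50 and Y7.53 facing in -
the state associated with beta-arrestin recruitment), and S4 has the
tyrosine toward TM1.

**Boundaries ship as configuration, not constants.** Published state
maps of this kind show the clusters as heatmap density without numeric
interval edges. The packaged default
(`inst/extdata/state_boundaries.yaml`) is a qualitative reading of such
a map: d splits at 11 Angstrom (6-11 for states 1/2, 11-17 for 3/4) and
chi splits around the -60-degree and +60-degree rotamer wells. Every
population table records the MD5 hash of the boundary file used, so a
re-analysis with recalibrated boundaries is traceable. Regions use
half-open intervals `[lo, hi)` and must be pairwise disjoint - overlap
is rejected at configuration time, so no runtime tie-break is ever
needed. chi intervals may wrap across +/-180. Frames falling outside
every region are labelled `UNASSIGNED`, a first-class label, so
population fractions always sum to one exactly.

Whether published percentages pooled frames across replicates or
averaged per-replicate fractions is typically unstated;
`state_populations()` emits both (the pooled value equals the
frame-weighted mean of the per-replicate values).

## Contact fingerprints

`contact_fingerprint()` marks a residue as contacting the ligand in a
frame when any of its heavy atoms is within 6.0 Angstrom (inclusive) of
any ligand heavy atom - the distance-only convention of standard
interaction-fingerprint tools at their default cutoff. Frequencies are
contact frames over total frames. `delta_fingerprint()` reports
wild-type minus mutant over the union of residues, so positive values
mean the mutation weakened the interaction. Interaction-type
subclassification (hydrogen bonds, pi-stacking) is deliberately out of
scope; fingerprints computed at different cutoffs refuse to subtract.

## Dose-response pharmacology and ligand bias

Concentration-response data follow the four-parameter logistic

$$y = \mathrm{Bottom} + \frac{\mathrm{Top} - \mathrm{Bottom}}
  {1 + 10^{(\log_{10}\mathrm{EC_{50}} - \log_{10} c)\,h}}$$

with the Hill slope box-bounded to |h| <= 2 (the closed bound is the
optimizable reading of "absolute values less than 2"). `fit_4pl()`
multi-starts the Levenberg-Marquardt optimizer across a grid of
log10 EC50 values spanning the tested range and both Hill signs, and
keeps the best converged start. Two numerical conventions matter:

* the 4PL has an exact symmetry - swapping Top/Bottom while negating the
  Hill slope reproduces the identical curve at the same EC50 - so fits
  are canonicalized to Span = Top - Bottom >= 0, keeping
  log10(Span/EC50) defined for activating curves;
* flat data (zero response variance) are flagged `span_zero` rather than
  failed, and non-convergence from every start is a flagged failure, not
  a silent one.

Kinetic luminescence reads are reduced to responses by averaging the
5-10 minute post-addition window, dividing by the pre-addition baseline,
and normalizing that fold-change by the vehicle wells of the same
construct and replicate.

Relative activity parameters normalize a test construct to the
wild-type run in parallel, replicate by replicate: Emax = Span ratio,
delta-pEC50, and RAi = (Span/EC50) ratio. Ligand bias is

$$\Delta\Delta\log(E_{max}/EC_{50}) =
  \Delta\log_{10}(\mathrm{Span}/EC_{50})_{\mathrm{pathway A}} -
  \Delta\log_{10}(\mathrm{Span}/EC_{50})_{\mathrm{pathway B}}$$

where each Delta-log is test ligand minus reference ligand within a
pathway. Replicates are matched by experiment index (the
parallel-experiment pairing); mismatched replicate counts are an error,
never silently broadcast. The per-replicate Delta-Delta-log values are
tested against zero with a two-sided one-sample t-test, starred at
0.05/0.01/0.001. The statistic is antisymmetric under pathway swap and
identically zero for the reference ligand against itself. Whether to
run the t-test on per-replicate values or on means of per-pathway
Delta-logs is ambiguous in most reports; per-replicate values are the
default here and both ingredients are returned.

## Radioligand binding

Saturation data are reduced to specific binding (total minus
replicate-matched nonspecific; negative values from counting noise are
retained, not clipped, and counted in the report) and fit to the
one-site model B = Bmax L/(Kd + L). Confidence intervals are asymptotic
(covariance-based) 95% intervals - the unnamed default of common
fitting software. Competition curves are descending sigmoids in
log10(inhibitor); the fitted IC50 converts to Ki by the Cheng-Prusoff
equation Ki = IC50/(1 + L/Kd), which holds bit-exactly by construction.

## ATR-FTIR difference spectra

Spectra live on a strictly ascending uniform wavenumber grid, default
step 2 cm-1 (the acquisition resolution this pipeline assumes).
Corrections are declared, least-squares scalar fits recorded in
provenance, applied additive-first:

1. **Reference subtraction** (water vapor, CO2, buffer): subtract
   alpha x reference with alpha minimizing the summed squared first
   differences of the corrected spectrum in 1700-1900 cm-1, a window
   dominated by sharp vapor lines and free of protein bands.
2. **Scale** (film swelling/shrinkage): multiply by the scalar
   minimizing the squared residual against the reference spectrum in the
   protein-dominated 1500-1700 cm-1 amide window.

The order matters: scaling against a vapor-free reference inside a
vapor-dominated window would collapse the fit, so additive contamination
is removed first. The exact windows the original instrument operators
used are never published; these defaults are declared choices, not
inferences.

The difference spectrum is pointwise active minus inactive on the
common grid: agonist-state bands appear positive, antagonist-state
bands negative. `find_band()` locates the extremum of the requested
sign in a diagnostic window (defaults: S-H 2500-2600, His C-N
1100-1200, amide-I 1600-1700 cm-1) and refines it by parabolic
interpolation through the three surrounding points. On a 2 cm-1 grid
this gives sub-0.5 cm-1 accuracy for bands of FWHM >= 8 cm-1 (verified
against a dense-grid oracle), supporting the 1 cm-1 reporting
precision. A window with no extremum of the requested sign reports
absence instead of fabricating a peak. Band shifts are positive
position minus negative position, so hydrogen-bond-weakening upshifts
are positive.

## Structure comparison

`superpose()` matches residues by chain and author number (insertion
codes included), takes backbone atoms N/CA/C/O, drops unpaired atoms
pairwise with a logged count, and solves the least-squares rigid
transform by the Kabsch/SVD method with determinant correction (the
rotation is always proper). The atom set behind a published
"receptor-region backbone RMSD" is rarely stated; the selection used
here is always recorded in the output, and chain and residue-range
restrictions are explicit arguments. Distances use heavy atoms only;
summaries round to 0.1 Angstrom while machine output keeps full
precision. Ligand identity is read from HETATM residue names, never
assumed from a deposition-ID mapping.

## The synthetic-data generators

Every stage is testable offline because its inputs can be generated
with known ground truth, seeded and byte-reproducible:

* `gen_trajectory()` constructs marker-atom frames **analytically**:
  the four dihedral atoms of Y330 are placed with fixed internal
  geometry and the prescribed torsion (natural-extension construction),
  S153-Calpha sits on the sphere of the prescribed distance about
  Y330-Czeta, and R156-Czeta is placed above/below its Calpha along the
  membrane normal (with a random tilt up to 60 degrees) per the
  orientation draw. Features are therefore exactly invertible, and the
  classifier must recover the generated labels whenever targets sit
  strictly inside the state regions - the oracle-equivalence property
  the test suite enforces on configurations from 100 to 10,000 frames.
  For split substates the orientation probability is forced to the
  substate's identity (1 for A, 0 for B), since anything else would
  contradict the ground-truth label; unsplit states take a free
  probability in [0, 1], checked against binomial bounds.
* `gen_dose_response()`, `gen_binding()` and `gen_spectrum()` add
  independent Gaussian noise to exact model values (4PL; one-site or
  competition isotherms; additive Gaussian bands plus baseline).
  Band width defaults to 10 cm-1 FWHM so that for a 15 cm-1 amide-I
  separation the interference displacement of the difference-spectrum
  extremum stays below 0.5 cm-1, keeping worked examples on-grid.
* `gen_helix_model()`/`perturb_model()`/`gen_pocket_model()` build
  idealized receptor stand-ins for superposition and pocket-distance
  exercises; they are labelled synthetic and are not deposited
  coordinates.

What the generators do **not** emulate: physical MD (no force field,
no solvent or lipid atoms, no kinetics - state sequences are shuffled,
not time-correlated), realistic plate-reader drift or heteroscedastic
counting noise (binding noise is Gaussian by default), instrument
baselines beyond a constant or supplied function, and real protein
geometry beyond the marker atoms. Green tests therefore certify the
*analysis* chain - featurization, classification, fitting, peak
detection - under controlled truth; they do not certify robustness to
every artifact of real data.

## Study conditions and problem sizes

The bundled analysis workflow (`analysis/01...07`) runs the full chain
at desk scale as the package's declared study conditions: five systems
(wild type and the K227A/Y312A/C286A/H291A pocket mutants) with three
replicates of 600 frames each and state mixtures in which every mutant
depletes the alternative S3A state; three-replicate dose-response
curves over 8 concentrations spanning five decades with 5%-of-span
noise; saturation binding on the 0.5-12 nM working range at the
reported Kd values (7.79/12.1/6.29 nM) and competition over six
decades; spectra on a 1000-3000 cm-1 grid with component bands at the
reported positions (amide-I 1651 to 1666/1663; S-H 2550 to 2570/2565;
His C-N 1130). Statistical calibration uses 200 seeded fits for pEC50
error (median absolute error below 0.1 log units) and 500 null
simulations for the bias t-test (type-I rate required to land in
2-8% at alpha = 0.05).

## Known limitations

* State boundaries are a declared configuration; conclusions about real
  trajectories are conditional on that calibration.
* The R3.50 orientation criterion (sign of the projection on a declared
  membrane normal) requires the trajectory frames to be aligned to a
  membrane frame; no internal alignment is performed.
* The operational-model (Black-Leff) bias factor, Schild analysis,
  Markov state models, clustering-based state discovery and
  per-interaction-type fingerprints are out of scope.
* The structure-comparison stage demonstrates its measurements on
  synthetic stand-ins; pointing `read_structure()` at locally available
  deposited models runs the identical code path.
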