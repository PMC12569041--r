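#' Read a typed assay table
#'
#' Reads delimited text with a header matching one of the pipeline's
#' schemas and returns a typed data frame with canonical units attached:
#' concentrations in molar, wavenumbers in cm-1. Unit variants are
#' declared in the header (`conc_M`, `conc_nM`, `conc_uM`,
#' `wavenumber_cm-1`); an unknown unit suffix is an error, never a guess.
#'
#' Schemas (required columns):
#' \describe{
#'   \item{dose_response}{ligand, pathway, construct, conc_*, response, replicate}
#'   \item{kinetic_luminescence}{well, time_s, counts, construct, ligand, conc_*, replicate}
#'   \item{binding}{mode, conc_*, counts_total, counts_nonspecific, replicate}
#'   \item{spectrum}{wavenumber_cm-1, absorbance}
#' }
#'
#' @param path CSV path.
#' @param schema one of `"dose_response"`, `"kinetic_luminescence"`,
#'   `"binding"`, `"spectrum"`.
#' @return data frame with canonical column names; spectra are re-ordered
#'   to ascending wavenumber.
#' @export
read_assay_table <- function(path,
                             schema = c("dose_response", "kinetic_luminescence",
                                        "binding", "spectrum")) {
  schema <- match.arg(schema)
  assert_that(file.exists(path), "file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

  conc_scale <- c(conc_M = 1, conc_mM = 1e-3, conc_uM = 1e-6,
                  conc_nM = 1e-9, conc_pM = 1e-12)
  find_conc <- function(df) {
    hit <- intersect(names(conc_scale), names(df))
    other <- grep("^conc_", names(df), value = TRUE)
    bad <- setdiff(other, names(conc_scale))
    assert_that(length(bad) == 0L, "unknown concentration unit suffix: %s", paste(bad, collapse = ", "))
    assert_that(length(hit) == 1L, "schema needs exactly one conc_<unit> column; found: %s",
                if (length(hit)) paste(hit, collapse = ", ") else "none")
    hit
  }
  need <- function(cols) {
    missing <- setdiff(cols, names(df))
    assert_that(
      length(missing) == 0L,
      "'%s' is missing required column(s) for schema %s: %s",
      path, schema, paste(missing, collapse = ", ")
    )
  }
  numericize <- function(df, cols) {
    for (cl in cols) {
      v <- suppressWarnings(as.numeric(df[[cl]]))
      bad <- which(is.na(v) & !is.na(df[[cl]]))
      assert_that(
        length(bad) == 0L,
        "non-numeric value in column %s, row %s of '%s'",
        cl, if (length(bad)) bad[1] else 0L, path
      )
      df[[cl]] <- v
    }
    df
  }

  if (schema == "spectrum") {
    need(c("wavenumber_cm-1", "absorbance"))
    df <- numericize(df, c("wavenumber_cm-1", "absorbance"))
    names(df)[names(df) == "wavenumber_cm-1"] <- "wavenumber"
    df <- df[order(df$wavenumber), , drop = FALSE]
    rownames(df) <- NULL
    return(df)
  }

  conc_col <- find_conc(df)
  if (schema == "dose_response") {
    need(c("ligand", "pathway", "construct", conc_col, "response", "replicate"))
    df <- numericize(df, c(conc_col, "response"))
  } else if (schema == "kinetic_luminescence") {
    need(c("well", "time_s", "counts", "construct", "ligand", conc_col, "replicate"))
    df <- numericize(df, c("time_s", "counts", conc_col))
  } else {
    need(c("mode", conc_col, "counts_total", "counts_nonspecific", "replicate"))
    df <- numericize(df, c(conc_col, "counts_total", "counts_nonspecific"))
    assert_that(
      all(df$mode %in% c("saturation", "competition")),
      "binding 'mode' must be saturation or competition"
    )
  }
  df$conc_M <- df[[conc_col]] * conc_scale[[conc_col]]
  if (conc_col != "conc_M") df[[conc_col]] <- NULL
  rownames(df) <- NULL
  df
}
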