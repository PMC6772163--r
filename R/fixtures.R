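# Packaged plain-text fixtures.

#' Path to a packaged data file
#'
#' @param name File name under `extdata/`; with no argument, lists the
#'   available files.
#' @return File path (errors if the file does not exist).
#' @export
mf_example <- function(name = NULL) {
  if (is.null(name))
    return(dir(system.file("extdata", package = "mfclass")))
  path <- system.file("extdata", name, package = "mfclass")
  if (!nzchar(path)) stop("no packaged file '", name, "'", call. = FALSE)
  path
}

#' Reference set of classified BRCA1/2 variants
#'
#' The 94 variants classified (Likely) Pathogenic by published large-scale
#' multifactorial likelihood analysis, with their priors, per-component LRs
#' (blank when the component was unavailable), combined LRs, posteriors and
#' IARC classes as publicly reported. Used as a reproduction fixture:
#' component LRs are printed rounded to two decimals, so recombined products
#' match the reported combined LRs only to within print precision.
#'
#' @return Data frame with columns `gene`, `hgvs_c`, `hgvs_p`, `prior`,
#'   `segregation_lr`, `pathology_lr`, `cooccurrence_lr`,
#'   `family_history_lr`, `combined_lr`, `posterior`, `iarc_class`.
#' @export
load_reference_variants <- function() {
  df <- read.delim(mf_example("classified_variants_reference.tsv"),
                   stringsAsFactors = FALSE, na.strings = "")
  stopifnot(nrow(df) == 94L)
  df
}

#' Reference calibration cross-tabs
#'
#' Published counts of (Likely) Benign vs (Likely) Pathogenic reference
#' variants per evidence category for three evidence types: allele-specific
#' splicing assays, all splicing assays, protein functional assays, and
#' reference-population frequency categories.
#'
#' @return Named list of [crosstab()] objects (`splicing_allele_specific`,
#'   `splicing_all`, `functional`, `frequency`).
#' @export
load_reference_crosstabs <- function() {
  read_crosstab(mf_example("calibration_crosstabs.tsv"))
}

#' Convert the reference variant table to evidence records
#'
#' @param df Output of [load_reference_variants()] (default).
#' @return List of [variant_evidence()] objects using the printed
#'   per-component LRs.
#' @export
reference_evidence <- function(df = load_reference_variants()) {
  cols <- c(segregation = "segregation_lr", pathology = "pathology_lr",
            cooccurrence = "cooccurrence_lr",
            family_history = "family_history_lr")
  lapply(seq_len(nrow(df)), function(i) {
    comps <- list()
    for (nm in names(cols)) {
      v <- df[[cols[[nm]]]][i]
      if (!is.na(v)) comps[[nm]] <- v
    }
    variant_evidence(df$gene[i], df$hgvs_c[i], prior = df$prior[i],
                     components = comps)
  })
}
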