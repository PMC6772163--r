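# Core data model: priors, LR combination, informativeness gate, Bayes
# posterior and IARC five-tier classification.

#' Evidence component names recognised by the model
#'
#' The multifactorial model combines at most five independent clinical
#' evidence types per variant.
#'
#' @return Character vector of valid component names.
#' @export
component_names <- function() {
  c("segregation", "pathology", "cooccurrence", "family_history",
    "case_control")
}

#' Construct a per-variant evidence record
#'
#' Bundles a variant's prior probability of pathogenicity with the observed
#' likelihood-ratio data points per evidence component. Multiple data points
#' for one component (e.g. several segregation families) are kept as a list
#' and combined multiplicatively by [combine_lrs()].
#'
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @param hgvs_c HGVS cDNA description (treated as an opaque label).
#' @param prior Prior probability of pathogenicity in `[0, 1]`.
#' @param components Named list; names from [component_names()], each element
#'   a numeric vector of positive LRs.
#' @param hgvs_p Optional HGVS protein description.
#' @param variant_kind One of `"missense"`, `"intronic"`, `"synonymous"`,
#'   `"inframe_indel"`, `"large_rearrangement"`, `"other"`.
#' @param provenance Optional named list of free-text provenance strings per
#'   component.
#' @return An object of class `mf_variant_evidence`.
#' @examples
#' variant_evidence("BRCA1", "c.131G>T", prior = 0.81,
#'                  components = list(segregation = 156.17, pathology = 41.24))
#' @export
variant_evidence <- function(gene, hgvs_c, prior, components = list(),
                             hgvs_p = NULL, variant_kind = "other",
                             provenance = list()) {
  gene <- match.arg(gene, c("BRCA1", "BRCA2"))
  variant_kind <- match.arg(variant_kind,
                            c("missense", "intronic", "synonymous",
                              "inframe_indel", "large_rearrangement", "other"))
  stopifnot(is.character(hgvs_c), length(hgvs_c) == 1L, nzchar(hgvs_c))
  if (!is.numeric(prior) || length(prior) != 1L || is.na(prior) ||
      prior < 0 || prior > 1)
    stop("'prior' must be a single probability in [0, 1]", call. = FALSE)
  if (length(components)) {
    if (is.null(names(components)) || any(!nzchar(names(components))))
      stop("'components' must be a named list", call. = FALSE)
    bad <- setdiff(names(components), component_names())
    if (length(bad))
      stop("unknown evidence component(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(components)) {
      lrs <- components[[nm]]
      if (!is.numeric(lrs) || any(!is.finite(lrs)) || any(lrs <= 0))
        stop("component '", nm, "' contains a non-positive or non-finite LR",
             call. = FALSE)
    }
  }
  structure(
    list(gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
         variant_kind = variant_kind, prior = prior,
         components = components, provenance = provenance),
    class = "mf_variant_evidence")
}

#' @export
print.mf_variant_evidence <- function(x, ...) {
  cat(sprintf("<%s %s> prior = %g\n", x$gene, x$hgvs_c, x$prior))
  for (nm in names(x$components))
    cat(sprintf("  %-15s LR(s): %s\n", nm,
                paste(signif(x$components[[nm]], 6), collapse = ", ")))
  invisible(x)
}

#' Candidate priors for one variant
#'
#' A variant may carry a missense (protein-level) prior, a splicing prior,
#' and -- for in-frame deletions -- one protein-level prior per deleted base.
#'
#' @param missense,splicing Optional probabilities in `[0, 1]`.
#' @param per_base Optional numeric vector of per-deleted-base priors.
#' @return An object of class `mf_prior_spec`.
#' @export
prior_spec <- function(missense = NULL, splicing = NULL, per_base = NULL) {
  chk <- function(p, what) {
    if (!is.null(p) &&
        (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)))
      stop("'", what, "' must be probabilities in [0, 1]", call. = FALSE)
  }
  chk(missense, "missense"); chk(splicing, "splicing"); chk(per_base, "per_base")
  if (is.null(missense) && is.null(splicing) &&
      (is.null(per_base) || !length(per_base)))
    stop("no prior available", call. = FALSE)
  structure(list(missense = missense, splicing = splicing,
                 per_base = per_base), class = "mf_prior_spec")
}

#' Assign the prior probability of pathogenicity
#'
#' The working prior is the larger of the protein-level (missense) and
#' splicing priors. In-frame deletions, which protein-level predictors do
#' not score directly, take the highest per-deleted-base prior in place of a
#' missense prior.
#'
#' @param spec An [prior_spec()] object.
#' @return A single probability.
#' @examples
#' assign_prior(prior_spec(missense = 0.03, splicing = 0.97))  # 0.97
#' assign_prior(prior_spec(per_base = c(0.02, 0.29, 0.81)))    # 0.81
#' @export
assign_prior <- function(spec) {
  stopifnot(inherits(spec, "mf_prior_spec"))
  cand <- c(spec$missense, spec$splicing, spec$per_base)
  if (!length(cand)) stop("no prior available", call. = FALSE)
  max(cand)
}

#' Combine component likelihood ratios multiplicatively
#'
#' Evidence types are assumed independent given pathogenicity status, so all
#' LR data points across all components multiply. The empty product is 1.
#'
#' @param components Named list of numeric LR vectors (as in
#'   [variant_evidence()]), or a bare numeric vector.
#' @return The combined LR (positive scalar).
#' @examples
#' combine_lrs(list(segregation = 13545, pathology = 60.31))
#' @export
combine_lrs <- function(components) {
  lrs <- unlist(components, use.names = FALSE)
  if (is.null(lrs) || !length(lrs)) return(1)
  if (!is.numeric(lrs) || any(!is.finite(lrs)) || any(lrs <= 0))
    stop("all likelihood ratios must be positive and finite", call. = FALSE)
  prod(lrs)
}

#' Is a combined LR informative enough to classify?
#'
#' Combined LRs strictly between `gate[1]` and `gate[2]` (default 0.5 and 2)
#' are treated as insufficient observational data: no posterior is
#' calculated. The excluded band is open, so an LR of exactly 0.5 or 2 is
#' informative.
#'
#' @param combined_lr Positive combined likelihood ratio.
#' @param gate Length-2 numeric, the open uninformative interval.
#' @return Logical flag.
#' @export
is_informative <- function(combined_lr, gate = c(0.5, 2)) {
  stopifnot(is.numeric(combined_lr), all(combined_lr > 0),
            length(gate) == 2L, gate[1] < gate[2])
  !(combined_lr > gate[1] & combined_lr < gate[2])
}

#' Bayes posterior probability of pathogenicity
#'
#' Odds-form Bayes update: posterior odds are prior odds times the combined
#' LR, so `posterior = prior * LR / (prior * LR + 1 - prior)`.
#'
#' @param prior Prior probability in `[0, 1]`.
#' @param combined_lr Positive combined likelihood ratio.
#' @return Posterior probability (vectorised over the inputs).
#' @examples
#' posterior_probability(0.81, 6440.7)  # 0.99996
#' @export
posterior_probability <- function(prior, combined_lr) {
  stopifnot(is.numeric(prior), all(prior >= 0 & prior <= 1),
            is.numeric(combined_lr), all(combined_lr > 0))
  prior * combined_lr / (prior * combined_lr + (1 - prior))
}

#' IARC five-tier class from a posterior probability
#'
#' Cut-offs: Class 5 Pathogenic `> 0.99`; Class 4 Likely Pathogenic
#' `[0.95, 0.99]`; Class 3 Uncertain `[0.05, 0.95)`; Class 2 Likely Benign
#' `[0.001, 0.05)`; Class 1 Benign `< 0.001`. The published description of
#' Class 3 as "0.05-0.949" leaves the band 0.949-0.95 undefined; this
#' implementation closes it by using `[0.05, 0.95)` for Class 3.
#'
#' @param posterior Posterior probability in `[0, 1]`.
#' @return Factor with levels `C1`..`C5` (vectorised).
#' @examples
#' classify_posterior(c(0.99996, 0.965, 0.0005))
#' @export
classify_posterior <- function(posterior) {
  if (!is.numeric(posterior) || any(is.na(posterior)) ||
      any(posterior < 0 | posterior > 1))
    stop("'posterior' must be probabilities in [0, 1]", call. = FALSE)
  cls <- ifelse(posterior > 0.99, "C5",
         ifelse(posterior >= 0.95, "C4",
         ifelse(posterior >= 0.05, "C3",
         ifelse(posterior >= 0.001, "C2", "C1"))))
  factor(cls, levels = c("C1", "C2", "C3", "C4", "C5"))
}

#' Classify one variant from its evidence record
#'
#' Combines the component LRs, applies the informativeness gate, and -- for
#' informative variants -- computes the posterior probability and IARC class.
#' Gated variants get `informative = FALSE` and no posterior or class.
#'
#' @param evidence An [variant_evidence()] object.
#' @param gate Open uninformative LR interval, see [is_informative()].
#' @return An object of class `mf_classification`: a list with elements
#'   `gene`, `hgvs_c`, `prior`, `component_lrs` (per-component combined LRs),
#'   `combined_lr`, `informative`, `posterior` (NA if gated) and
#'   `iarc_class` (NA if gated).
#' @examples
#' ev <- variant_evidence("BRCA1", "c.131G>T", prior = 0.81,
#'                        components = list(segregation = 156.17,
#'                                          pathology = 41.24))
#' classify_variant(ev)
#' @export
classify_variant <- function(evidence, gate = c(0.5, 2)) {
  stopifnot(inherits(evidence, "mf_variant_evidence"))
  comp_lr <- vapply(evidence$components, combine_lrs, numeric(1))
  combined <- combine_lrs(evidence$components)
  inf <- is_informative(combined, gate)
  post <- if (inf) posterior_probability(evidence$prior, combined) else NA_real_
  cls <- if (inf) classify_posterior(post)
         else factor(NA, levels = c("C1", "C2", "C3", "C4", "C5"))
  structure(
    list(gene = evidence$gene, hgvs_c = evidence$hgvs_c,
         prior = evidence$prior, component_lrs = comp_lr,
         combined_lr = combined, informative = inf,
         posterior = post, iarc_class = cls),
    class = "mf_classification")
}

#' @export
print.mf_classification <- function(x, ...) {
  cat(sprintf("<%s %s> prior %.3f, combined LR %s\n", x$gene, x$hgvs_c,
              x$prior, format(x$combined_lr, big.mark = ",")))
  if (x$informative)
    cat(sprintf("  posterior %.5f -> IARC %s\n", x$posterior,
                as.character(x$iarc_class)))
  else
    cat("  combined LR inside the 0.5-2 gate: no posterior calculated\n")
  invisible(x)
}

#' Baseline common-variant rule (IARC Class 1 at MAF > 1%)
#'
#' A variant observed at minor allele frequency above `maf_cutoff` in at
#' least one outbred reference subpopulation is classified Class 1 Benign
#' outright. The inequality is strict.
#'
#' @param freq An [frequency_table()] object.
#' @param maf_cutoff Frequency cut-off, default 0.01.
#' @return Logical flag.
#' @export
baseline_common_class1 <- function(freq, maf_cutoff = 0.01) {
  stopifnot(inherits(freq, "mf_frequency_table"))
  tab <- pop_totals(freq)
  out <- tab[tab$population %in% outbred_populations(), , drop = FALSE]
  if (all(out$allele_number == 0))
    stop("no frequency data", call. = FALSE)
  out <- out[out$allele_number > 0, , drop = FALSE]
  maf <- pmin(out$allele_count / out$allele_number,
              1 - out$allele_count / out$allele_number)
  any(maf > maf_cutoff)
}
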