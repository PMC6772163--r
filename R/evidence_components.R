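# Non-segregation evidence components: tumour pathology lookup,
# co-occurrence in trans, family-history lookup, case-control
# profile-likelihood LR, and population-frequency categorisation.

#' Reference population labels
#'
#' The five outbred (non-founder) gnomAD-style populations used for
#' frequency categorisation, and the two founder populations used only for
#' the exclusion rule.
#'
#' @return Character vector of population codes.
#' @export
outbred_populations <- function() c("NFE", "AFR", "AMR", "SAS", "EAS")

#' @rdname outbred_populations
#' @export
founder_populations <- function() c("FIN", "ASJ")

#' Per-population allele-count table
#'
#' @param population Population codes (see [outbred_populations()]).
#' @param allele_count,allele_number Non-negative integers, `AC <= AN`.
#' @param cohort Optional tranche label (`"exome"`/`"genome"`); tranches for
#'   the same population are summed before any frequency is computed.
#' @return An object of class `mf_frequency_table` (a data frame).
#' @export
frequency_table <- function(population, allele_count, allele_number,
                            cohort = "exome") {
  population <- as.character(population)
  known <- c(outbred_populations(), founder_populations())
  bad <- setdiff(population, known)
  if (length(bad))
    stop("unknown population(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(allele_count), is.numeric(allele_number),
            all(allele_count >= 0), all(allele_number >= 0),
            all(allele_count <= allele_number | allele_number == 0))
  if (any(allele_number == 0 & allele_count > 0))
    stop("allele_number is 0 for a population with allele_count > 0",
         call. = FALSE)
  df <- data.frame(population = population,
                   allele_count = as.numeric(allele_count),
                   allele_number = as.numeric(allele_number),
                   cohort = rep_len(as.character(cohort), length(population)),
                   stringsAsFactors = FALSE)
  class(df) <- c("mf_frequency_table", "data.frame")
  df
}

# Sum exome/genome tranches per population; absent populations count as 0/0.
pop_totals <- function(freq) {
  all_pops <- c(outbred_populations(), founder_populations())
  ac <- setNames(numeric(length(all_pops)), all_pops)
  an <- ac
  agg_ac <- tapply(freq$allele_count, freq$population, sum)
  agg_an <- tapply(freq$allele_number, freq$population, sum)
  ac[names(agg_ac)] <- agg_ac
  an[names(agg_an)] <- agg_an
  data.frame(population = all_pops, allele_count = as.numeric(ac),
             allele_number = as.numeric(an), stringsAsFactors = FALSE)
}

#' Categorise a rare variant by reference-population frequency
#'
#' The category is driven by the highest minor allele frequency across the
#' five outbred populations (exome and genome tranches combined):
#' * `not_observed` -- absent from all outbred and founder sets;
#' * `single_observation` -- exactly one allele across the outbred sets;
#' * `low` -- maximum MAF in `(0, 1e-4)`;
#' * `mid` -- maximum MAF in `[1e-4, 0.01)` (the boundary 1e-4 falls in
#'   `mid`);
#' * `excluded_na` -- absent from the outbred sets but present in the
#'   Finnish or Ashkenazi Jewish founder sets (excluded from frequency-LR
#'   derivation).
#'
#' Allele counts (not carrier counts) are used throughout. A maximum MAF at
#' or above 0.01 is outside the rare-variant range handled here and is an
#' error; see [baseline_common_class1()] for the common-variant rule.
#'
#' @param freq An [frequency_table()] object.
#' @return One of `"not_observed"`, `"single_observation"`, `"low"`,
#'   `"mid"`, `"excluded_na"`.
#' @export
frequency_category <- function(freq) {
  stopifnot(inherits(freq, "mf_frequency_table"))
  tab <- pop_totals(freq)
  out <- tab[tab$population %in% outbred_populations(), , drop = FALSE]
  fou <- tab[tab$population %in% founder_populations(), , drop = FALSE]
  ac_out <- sum(out$allele_count)
  if (ac_out == 0) {
    if (sum(fou$allele_count) >= 1) return("excluded_na")
    return("not_observed")
  }
  if (ac_out == 1) return("single_observation")
  obs <- out[out$allele_number > 0, , drop = FALSE]
  af <- obs$allele_count / obs$allele_number
  maf <- max(pmin(af, 1 - af))
  if (maf >= 0.01)
    stop("frequency exceeds the rare-variant range (max MAF >= 0.01); ",
         "apply baseline_common_class1() instead", call. = FALSE)
  if (maf >= 1e-4) "mid" else "low"
}

#' Read a per-population frequency table
#'
#' Tab-separated with header columns `population`, `allele_count`,
#' `allele_number` and optional `cohort`.
#'
#' @param path File path.
#' @return An `mf_frequency_table`.
#' @export
read_frequency_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "allele_count", "allele_number")
  if (!all(need %in% names(df)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"cohort" %in% names(df)) df$cohort <- "exome"
  frequency_table(df$population, df$allele_count, df$allele_number, df$cohort)
}

#' Parse VCF-INFO style allele counts
#'
#' Convenience reader for strings such as
#' `"AC_nfe=1;AN_nfe=113000;AC_afr=0;AN_afr=24000"`. Population suffixes are
#' matched case-insensitively against `nfe`, `afr`, `amr`, `sas`, `eas`,
#' `fin`, `asj`.
#'
#' @param info Single INFO string.
#' @return An `mf_frequency_table`.
#' @export
parse_vcf_info_frequencies <- function(info) {
  stopifnot(is.character(info), length(info) == 1L)
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  pops <- c(nfe = "NFE", afr = "AFR", amr = "AMR", sas = "SAS", eas = "EAS",
            fin = "FIN", asj = "ASJ")
  rows <- list()
  for (p in names(pops)) {
    ac <- vals[keys == paste0("ac_", p)]
    an <- vals[keys == paste0("an_", p)]
    if (length(ac) && length(an))
      rows[[p]] <- data.frame(population = pops[[p]], allele_count = ac[1],
                              allele_number = an[1])
  }
  if (!length(rows)) stop("no AC_*/AN_* fields found", call. = FALSE)
  df <- do.call(rbind, rows)
  frequency_table(df$population, df$allele_count, df$allele_number)
}

#' Likelihood ratio for co-occurrence in trans with a pathogenic variant
#'
#' Carrying the assessed variant together with a known pathogenic variant on
#' the other allele is very rare if the assessed variant is itself
#' pathogenic (biallelic loss is embryonically lethal for BRCA1 and causes
#' Fanconi anaemia for BRCA2), so absence of co-occurrence among tested
#' carriers mildly supports pathogenicity. Modelled as a binomial likelihood
#' ratio: each of `n_tested` carriers co-occurs with probability
#' `theta_path` under the pathogenic hypothesis and `theta_neutral`
#' (approximately the population pathogenic-carrier frequency) under the
#' neutral hypothesis.
#'
#' @param n_tested Number of carriers tested for an in-trans pathogenic
#'   variant.
#' @param k_trans Number observed in trans, `k_trans <= n_tested`.
#' @param theta_path,theta_neutral Co-occurrence probabilities in `(0, 1)`
#'   under the two hypotheses.
#' @return The likelihood ratio
#'   `((1 - theta_path)/(1 - theta_neutral))^(n-k) *
#'    (theta_path/theta_neutral)^k`.
#' @export
cooccurrence_lr <- function(n_tested, k_trans, theta_path = 1e-4,
                            theta_neutral = 0.01) {
  stopifnot(n_tested >= 0, k_trans >= 0, k_trans <= n_tested)
  if (theta_path <= 0 || theta_path >= 1 ||
      theta_neutral <= 0 || theta_neutral >= 1)
    stop("theta parameters must lie in (0, 1)", call. = FALSE)
  if (n_tested == 0) return(1)
  ((1 - theta_path) / (1 - theta_neutral))^(n_tested - k_trans) *
    (theta_path / theta_neutral)^k_trans
}

#' Family-history likelihood ratio lookup
#'
#' Family-history LRs are externally calibrated per profile category and
#' passed through from a lookup table. The reserved category
#' `"none_supplied"` means the component is omitted (returns `NULL`).
#'
#' @param category Category identifier.
#' @param table Named numeric vector or list mapping category to LR.
#' @return The LR, or `NULL` for `"none_supplied"`.
#' @export
family_history_lr <- function(category, table) {
  stopifnot(is.character(category), length(category) == 1L)
  if (identical(category, "none_supplied")) return(NULL)
  tab <- unlist(table)
  if (is.null(tab) || !length(tab))
    stop("empty family-history LR table", call. = FALSE)
  if (!category %in% names(tab))
    stop("unknown family-history category: ", category, call. = FALSE)
  unname(tab[[category]])
}

# Case frequency implied by a carrier relative risk rr at population carrier
# frequency q (rare-disease enrichment of carriers among cases).
case_freq_from_rr <- function(q, rr) rr * q / (rr * q + (1 - q))

# Maximised log-likelihood of the two-arm carrier counts over the nuisance
# population carrier frequency q, for a fixed relative risk.
profile_loglik <- function(case_k, case_n, control_k, control_n, rr,
                           q_max = 0.5) {
  ll <- function(q) {
    dbinom(case_k, case_n, case_freq_from_rr(q, rr), log = TRUE) +
      dbinom(control_k, control_n, q, log = TRUE)
  }
  if (case_k == 0 && control_k == 0) return(0)  # supremum at q -> 0
  opt <- optimize(ll, interval = c(1e-12, q_max), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  # optimize can miss a boundary supremum; check the crude MLE too
  q0 <- min(max((case_k + control_k) / (case_n + control_n), 1e-12), q_max)
  max(opt$objective, ll(q0))
}

#' Case-control likelihood ratio by profile likelihood
#'
#' Compares carrier counts in cases and controls under two hypotheses: the
#' variant confers a gene-specific relative risk `assumed_rr` (the average
#' risk of a classical pathogenic variant), or no risk (`rr = 1`). The
#' population carrier frequency is a nuisance parameter profiled out by
#' maximisation under each hypothesis; the LR is the ratio of the two
#' maximised binomial likelihoods. The construction returns a finite LR for
#' degenerate counts (e.g. no carriers anywhere gives exactly 1).
#'
#' @param case_carriers,n_cases Carrier count and sample size in cases.
#' @param control_carriers,n_controls Carrier count and sample size in
#'   controls.
#' @param assumed_rr Relative risk of the pathogenic hypothesis, `> 0`.
#' @return Positive likelihood ratio.
#' @export
case_control_lr <- function(case_carriers, n_cases, control_carriers,
                            n_controls, assumed_rr) {
  stopifnot(case_carriers >= 0, case_carriers <= n_cases,
            control_carriers >= 0, control_carriers <= n_controls,
            assumed_rr > 0)
  l1 <- profile_loglik(case_carriers, n_cases, control_carriers, n_controls,
                       rr = assumed_rr)
  l0 <- profile_loglik(case_carriers, n_cases, control_carriers, n_controls,
                       rr = 1)
  exp(l1 - l0)
}

#' Tumour pathology LR lookup table
#'
#' Entries are keyed by gene, information level (`"receptors_grade"` when
#' both ER status and grade are known, `"receptors"` for ER without grade,
#' `"grade"` for grade only -- richer levels take precedence), a category
#' pattern built from the available markers, and an age band (`"<50"`,
#' `">=50"` or `"any"`).
#'
#' @param df Data frame with columns `gene`, `level`, `pattern`, `age_band`,
#'   `lr`.
#' @return An object of class `mf_pathology_table`.
#' @export
pathology_table <- function(df) {
  need <- c("gene", "level", "pattern", "age_band", "lr")
  if (!all(need %in% names(df)))
    stop("pathology table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$lr <= 0)) stop("pathology LRs must be positive", call. = FALSE)
  stopifnot(all(df$level %in% c("receptors_grade", "receptors", "grade")),
            all(df$age_band %in% c("<50", ">=50", "any")))
  if (anyDuplicated(df[c("gene", "level", "pattern", "age_band")]))
    stop("duplicate pathology table keys", call. = FALSE)
  structure(df, class = c("mf_pathology_table", "data.frame"))
}

#' Read a pathology LR table
#' @param path Tab-separated file with the [pathology_table()] columns.
#' @return An `mf_pathology_table`.
#' @export
read_pathology_table <- function(path) {
  pathology_table(read.delim(path, stringsAsFactors = FALSE))
}

# Build the canonical category pattern for one tumour at one information
# level, e.g. "ER-:G3" or "ER+" or "G2".
tumor_pattern <- function(tumor, level) {
  er <- if (!is.na(tumor$er)) paste0("ER", if (tumor$er == "positive") "+" else "-")
  gr <- if (!is.na(tumor$grade)) paste0("G", tumor$grade)
  switch(level,
         receptors_grade = paste(er, gr, sep = ":"),
         receptors = er,
         grade = gr)
}

tumor_level <- function(tumor) {
  has_er <- !is.na(tumor$er)
  has_gr <- !is.na(tumor$grade)
  if (has_er && has_gr) "receptors_grade"
  else if (has_er) "receptors"
  else if (has_gr) "grade"
  else NA_character_
}

#' Tumour pathology likelihood ratio for one individual
#'
#' Takes the earliest-diagnosed tumour that carries any informative marker
#' (grade, ER, PR or HER2), determines the richest information level
#' available for which the table has entries, and assigns exactly one LR for
#' the matching pattern and age band. Individuals with several tumours never
#' receive more than one pathology LR.
#'
#' @param tumors Data frame with columns `diagnosis_order`, `age_diagnosis`,
#'   and optional `grade` (1-3), `er`, `pr`, `her2`
#'   (`"positive"`/`"negative"`/NA).
#' @param table An [pathology_table()].
#' @param gene `"BRCA1"` or `"BRCA2"`.
#' @return A positive LR, or `NULL` when no tumour is informative.
#' @export
pathology_lr <- function(tumors, table, gene) {
  stopifnot(inherits(table, "mf_pathology_table"))
  gene <- match.arg(gene, c("BRCA1", "BRCA2"))
  if (is.null(tumors) || !nrow(tumors)) return(NULL)
  for (col in c("grade", "er", "pr", "her2"))
    if (!col %in% names(tumors)) tumors[[col]] <- NA
  tumors <- tumors[order(tumors$diagnosis_order), , drop = FALSE]
  informative <- !is.na(tumors$grade) | !is.na(tumors$er) |
    !is.na(tumors$pr) | !is.na(tumors$her2)
  if (!any(informative)) return(NULL)
  tumor <- tumors[which(informative)[1L], , drop = FALSE]
  lev <- tumor_level(tumor)
  if (is.na(lev)) return(NULL)  # PR/HER2 alone carry no table entry
  levels_try <- switch(lev,
                       receptors_grade = c("receptors_grade", "receptors", "grade"),
                       receptors = "receptors",
                       grade = "grade")
  band <- if (!is.na(tumor$age_diagnosis) && tumor$age_diagnosis < 50)
    "<50" else ">=50"
  for (lv in levels_try) {
    sub <- table[table$gene == gene & table$level == lv, , drop = FALSE]
    if (!nrow(sub)) next
    pat <- tumor_pattern(tumor, lv)
    hit <- sub[sub$pattern == pat & sub$age_band %in% c(band, "any"), ,
               drop = FALSE]
    if (nrow(hit)) {
      exact <- hit[hit$age_band == band, , drop = FALSE]
      return(if (nrow(exact)) exact$lr[1L] else hit$lr[1L])
    }
    stop("no pathology table entry for pattern '", pat, "' (", gene,
         ", level ", lv, ", age band ", band, ")", call. = FALSE)
  }
  stop("pathology table has no entries for gene ", gene, call. = FALSE)
}
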