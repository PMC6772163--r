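# Evidence-type calibration: likelihood ratios from cross-tabulations of
# classified variants, log-scale Wald confidence intervals with a
# conservative zero-cell convention, ACMG/AMP strength mapping, and
# concordance tabulation against external assertions.

#' Cross-tabulation of an evidence type over classified variants
#'
#' Counts of (Likely) Benign and (Likely) Pathogenic reference variants per
#' evidence category (e.g. splicing effect none/partial/complete).
#'
#' @param categories Character vector of category labels (ordered).
#' @param benign_counts,pathogenic_counts Non-negative integer counts per
#'   category.
#' @param evidence_type Optional label.
#' @return An object of class `mf_crosstab`.
#' @export
crosstab <- function(categories, benign_counts, pathogenic_counts,
                     evidence_type = "evidence") {
  stopifnot(length(categories) == length(benign_counts),
            length(categories) == length(pathogenic_counts),
            all(benign_counts >= 0), all(pathogenic_counts >= 0))
  if (anyDuplicated(categories)) stop("duplicate categories", call. = FALSE)
  structure(list(evidence_type = evidence_type,
                 categories = as.character(categories),
                 benign_counts = as.numeric(benign_counts),
                 pathogenic_counts = as.numeric(pathogenic_counts),
                 benign_total = sum(benign_counts),
                 pathogenic_total = sum(pathogenic_counts)),
            class = "mf_crosstab")
}

#' Likelihood ratio towards pathogenicity for one cross-tab category
#'
#' Point estimate `LR = (a/n1) / (c/n2)` where `a`/`n1` are the pathogenic
#' count in the category and the pathogenic total, and `c`/`n2` the benign
#' ones. A zero cell is conservatively replaced by a single observation
#' (flagged), in both the proportion and the standard error. In a
#' two-category table the borrowed observation is taken from the other
#' category of the same arm so the within-arm proportions still sum to one;
#' that complementary cell keeps its raw count in the standard error. The
#' 95% interval is the log-scale Wald CI
#' `exp(log LR +/- 1.96 * sqrt(1/a - 1/n1 + 1/c - 1/n2))`.
#'
#' @param tab An [crosstab()].
#' @param category Category label present in `tab`.
#' @param conf_z Normal quantile for the interval (default 1.96).
#' @return An object of class `mf_lr_estimate`: list with `lr`, `ci_low`,
#'   `ci_high`, `zero_cell_adjusted`, `adjusted_counts` (a, n1, c, n2 used
#'   for the point estimate) and the proportions.
#' @export
crosstab_lr <- function(tab, category, conf_z = 1.96) {
  stopifnot(inherits(tab, "mf_crosstab"))
  i <- match(category, tab$categories)
  if (is.na(i)) stop("unknown category: ", category, call. = FALSE)
  n1 <- tab$pathogenic_total
  n2 <- tab$benign_total
  if (n1 <= 0 || n2 <= 0)
    stop("both arms of the cross-tab must have observations", call. = FALSE)
  a_raw <- tab$pathogenic_counts[i]
  c_raw <- tab$benign_counts[i]
  if (a_raw == 0 && c_raw == 0)
    stop("category unobserved in both arms: ", category, call. = FALSE)
  two_cat <- length(tab$categories) == 2L
  a <- max(a_raw, 1)
  cc <- max(c_raw, 1)
  # complementary-cell handling in two-category tables: estimate only
  a_est <- a
  c_est <- cc
  if (two_cat) {
    j <- 3L - i
    if (tab$pathogenic_counts[j] == 0) a_est <- a_raw - 1
    if (tab$benign_counts[j] == 0) c_est <- c_raw - 1
  }
  lr <- (a_est / n1) / (c_est / n2)
  # SE: zero cells use the substituted single observation; complementary
  # cells keep their raw counts
  se <- sqrt(1 / a - 1 / n1 + 1 / cc - 1 / n2)
  f <- exp(conf_z * se)
  structure(list(lr = lr, ci_low = lr / f, ci_high = lr * f,
                 zero_cell_adjusted = (a_raw == 0 || c_raw == 0 ||
                                         a_est != a || c_est != cc),
                 adjusted_counts = c(a = a_est, n1 = n1, c = c_est, n2 = n2),
                 p_pathogenic = a_est / n1, p_benign = c_est / n2,
                 category = category, se_log = se),
            class = "mf_lr_estimate")
}

#' @export
print.mf_lr_estimate <- function(x, ...) {
  cat(sprintf("LR %s%.2f (95%% CI %.2f-%.2f)%s\n",
              if (!is.null(x$category)) paste0("[", x$category, "] ") else "",
              x$lr, x$ci_low, x$ci_high,
              if (isTRUE(x$zero_cell_adjusted)) "  [zero cell adjusted]" else ""))
  invisible(x)
}

#' Invert an LR estimate (evidence against pathogenicity)
#'
#' Reciprocal of the point estimate with swapped, reciprocal CI bounds.
#'
#' @param est An `mf_lr_estimate` (or a plain list with `lr`, `ci_low`,
#'   `ci_high`).
#' @return An `mf_lr_estimate` in the opposite direction.
#' @export
inverse_lr <- function(est) {
  stopifnot(est$lr > 0, est$ci_low > 0, est$ci_high > 0,
            est$ci_low <= est$lr, est$lr <= est$ci_high)
  out <- est
  out$lr <- 1 / est$lr
  out$ci_low <- 1 / est$ci_high
  out$ci_high <- 1 / est$ci_low
  out$p_pathogenic <- est$p_benign
  out$p_benign <- est$p_pathogenic
  out
}

#' Map a likelihood ratio to an ACMG/AMP evidence strength
#'
#' Pathogenic-direction bins (half-open on the right): supporting
#' `[2.08, 4.3)`, moderate `[4.3, 18.7)`, strong `[18.7, 350)`, very strong
#' `>= 350`. Benign-direction bins are the reciprocals, mirrored so that
#' `acmg_strength(1/x)` flips the direction and preserves the strength.
#' LRs in `(1/2.08, 2.08)` are uninformative.
#'
#' @param lr Positive likelihood ratio.
#' @return List with `direction` (`"pathogenic"`, `"benign"`,
#'   `"uninformative"`) and `strength` (`"supporting"`, `"moderate"`,
#'   `"strong"`, `"very_strong"`, or `NA` when uninformative).
#' @examples
#' acmg_strength(12.24)  # moderate pathogenic
#' acmg_strength(0.02)   # strong benign
#' @export
acmg_strength <- function(lr) {
  stopifnot(is.numeric(lr), length(lr) == 1L, lr > 0)
  bins <- c(supporting = 2.08, moderate = 4.3, strong = 18.7,
            very_strong = 350)
  strength_of <- function(x) {
    names(bins)[findInterval(x, bins)]
  }
  if (lr >= bins[["supporting"]])
    list(direction = "pathogenic", strength = strength_of(lr))
  else if (lr <= 1 / bins[["supporting"]])
    list(direction = "benign", strength = strength_of(1 / lr))
  else
    list(direction = "uninformative", strength = NA_character_)
}

#' Concordance of internal classes with external assertions
#'
#' Internal IARC classes are grouped as LB = C1 u C2, VUS = C3,
#' LP = C4 u C5. Each variant's external record is a vector of assertions
#' from `{"LB", "VUS", "LP"}`; a variant counts as externally (Likely)
#' Pathogenic / (Likely) Benign if *at least one* assertion says so
#' (pathogenic takes precedence when both occur), as Uncertain if all
#' assertions are VUS, and as absent when it has no external record.
#'
#' @param internal Named vector/list mapping variant id to IARC class
#'   (`"C1"`..`"C5"`).
#' @param external Named list mapping variant id to a character vector of
#'   assertions among `"LB"`, `"VUS"`, `"LP"`.
#' @return A contingency table (matrix) of internal group x external status
#'   (`LB`, `VUS`, `LP`, `not_in_external`).
#' @export
concordance_table <- function(internal, external) {
  grp <- function(cls) switch(cls, C1 = , C2 = "LB", C3 = "VUS",
                              C4 = , C5 = "LP",
                              stop("bad class: ", cls, call. = FALSE))
  ext_status <- function(id) {
    as_ <- external[[id]]
    if (is.null(as_) || !length(as_)) return("not_in_external")
    if (any(as_ == "LP")) "LP"
    else if (any(as_ == "LB")) "LB"
    else "VUS"
  }
  rows <- c("LB", "VUS", "LP")
  cols <- c("LB", "VUS", "LP", "not_in_external")
  out <- matrix(0L, length(rows), length(cols),
                dimnames = list(internal = rows, external = cols))
  for (id in names(internal)) {
    g <- grp(as.character(internal[[id]]))
    e <- ext_status(id)
    out[g, e] <- out[g, e] + 1L
  }
  out
}

#' Read an evidence cross-tab file
#'
#' Tab-separated with columns `evidence_type`, `category`, `benign_count`,
#' `pathogenic_count`; one [crosstab()] is built per `evidence_type`,
#' preserving row order.
#'
#' @param path File path.
#' @return Named list of `mf_crosstab` objects.
#' @export
read_crosstab <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("evidence_type", "category", "benign_count", "pathogenic_count")
  if (!all(need %in% names(df)))
    stop("cross-tab file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(split(df, df$evidence_type), function(d)
    crosstab(d$category, d$benign_count, d$pathogenic_count,
             evidence_type = d$evidence_type[1]))
  out[unique(df$evidence_type)]
}

# Report formatting: two decimals; a strictly positive value that would
# display as 0.00 is shown as 0.01 (no true zero can occur in these
# ratios).
format_lr <- function(x) {
  s <- sprintf("%.2f", x)
  s[x > 0 & s == "0.00"] <- "0.01"
  s
}

#' Calibrate every category of a cross-tab
#'
#' Runs [crosstab_lr()] per category (skipping categories empty in both
#' arms) and attaches the [acmg_strength()] label. Display columns follow
#' the reporting convention of [format_lr()].
#'
#' @param tab An [crosstab()].
#' @param conf_z Normal quantile for the CIs.
#' @return Data frame with counts, percentages, LR, CI, strength and the
#'   formatted display columns.
#' @export
calibrate_crosstab <- function(tab, conf_z = 1.96) {
  stopifnot(inherits(tab, "mf_crosstab"))
  rows <- lapply(seq_along(tab$categories), function(i) {
    cat_i <- tab$categories[i]
    if (tab$benign_counts[i] == 0 && tab$pathogenic_counts[i] == 0)
      return(NULL)
    est <- crosstab_lr(tab, cat_i, conf_z = conf_z)
    st <- acmg_strength(est$lr)
    data.frame(
      evidence_type = tab$evidence_type, category = cat_i,
      benign_count = tab$benign_counts[i],
      benign_pct = 100 * est$p_benign,
      pathogenic_count = tab$pathogenic_counts[i],
      pathogenic_pct = 100 * est$p_pathogenic,
      lr = est$lr, ci_low = est$ci_low, ci_high = est$ci_high,
      zero_cell_adjusted = est$zero_cell_adjusted,
      direction = st$direction,
      strength = if (is.na(st$strength)) "" else st$strength,
      lr_display = format_lr(est$lr),
      ci_display = sprintf("(%s-%s)", format_lr(est$ci_low),
                           format_lr(est$ci_high)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
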