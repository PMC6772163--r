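# Age-bracket penetrance model: piecewise-constant baseline hazards per
# cancer type with carrier hazard ratios per bracket.

# Fixed age brackets: <30, 30-39, 40-49, 50-59, 60-69, 70-79, 80+.
bracket_starts <- function() c(0, 30, 40, 50, 60, 70, 80)
# The open-ended 80+ bracket is capped at 105 years for event probabilities.
bracket_ends <- function() c(30, 40, 50, 60, 70, 80, 105)
bracket_labels <- function() {
  c("<30", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}
n_brackets <- function() 7L
cancer_types <- function() c("breast_female", "ovarian", "breast_male")

bracket_of_age <- function(age) {
  findInterval(age, bracket_starts())
}

#' Age-bracket penetrance model
#'
#' Piecewise-constant per-year baseline hazards for breast cancer (female),
#' ovarian cancer and optionally male breast cancer over the seven age
#' brackets `<30, 30-39, ..., 70-79, 80+`, together with per-bracket hazard
#' ratios for variant carriers and the population carrier frequency of the
#' assessed variant. Carrier hazards are `hazard * hazard_ratio`.
#'
#' The package ships a clearly labelled placeholder configuration (see
#' [default_penetrance_model()]); users performing real classification must
#' substitute published penetrance estimates.
#'
#' @param hazard Numeric matrix `7 x 3` (brackets x cancer types
#'   `breast_female`, `ovarian`, `breast_male`) of non-negative per-year
#'   hazards.
#' @param hazard_ratio Numeric matrix of the same shape with positive hazard
#'   ratios (carrier vs population).
#' @param allele_frequency Population allele frequency of the variant; the
#'   heterozygous carrier frequency used for founder genotype priors is
#'   `2 * allele_frequency`.
#' @return An object of class `mf_penetrance`.
#' @export
penetrance_model <- function(hazard, hazard_ratio, allele_frequency = 5e-4) {
  shape_ok <- function(m) is.matrix(m) && nrow(m) == n_brackets() &&
    ncol(m) == length(cancer_types())
  if (!shape_ok(hazard) || !shape_ok(hazard_ratio))
    stop("hazard and hazard_ratio must be 7 x 3 matrices ",
         "(brackets x cancer types)", call. = FALSE)
  colnames(hazard) <- colnames(hazard_ratio) <- cancer_types()
  rownames(hazard) <- rownames(hazard_ratio) <- bracket_labels()
  stopifnot(all(hazard >= 0), all(hazard_ratio > 0),
            allele_frequency > 0, allele_frequency < 0.5)
  structure(list(hazard = hazard, hazard_ratio = hazard_ratio,
                 allele_frequency = allele_frequency),
            class = "mf_penetrance")
}

#' @export
print.mf_penetrance <- function(x, ...) {
  cat("<penetrance model> per-year baseline hazards:\n")
  print(signif(x$hazard, 3))
  cat("carrier hazard ratios:\n")
  print(signif(x$hazard_ratio, 3))
  cat(sprintf("variant allele frequency: %g\n", x$allele_frequency))
  invisible(x)
}

# Per-bracket hazards for one cancer type / carrier status.
type_hazard <- function(model, type, carrier) {
  h <- model$hazard[, type]
  if (carrier) h <- h * model$hazard_ratio[, type]
  h
}

# Cancer types applicable to a sex (male breast hazard is usually 0 and
# then contributes nothing).
sex_types <- function(sex) {
  if (sex == "female") c("breast_female", "ovarian") else "breast_male"
}

# Total cumulative hazard (all applicable types) from age 0 to `age`.
cumulative_hazard <- function(model, sex, carrier, age) {
  if (age <= 0) return(0)
  widths <- pmax(0, pmin(age, bracket_ends()) - bracket_starts())
  h_tot <- rowSums(vapply(sex_types(sex),
                          function(t) type_hazard(model, t, carrier),
                          numeric(n_brackets())))
  sum(h_tot * widths)
}

#' Read / write a penetrance configuration
#'
#' Tab-separated key-value format with columns `field`
#' (`hazard`, `hazard_ratio` or `allele_frequency`), `cancer_type`,
#' `bracket` (one of `<30`, `30-39`, ..., `80+`) and `value`. The
#' `allele_frequency` row leaves `cancer_type` and `bracket` empty.
#'
#' @param path File path.
#' @return `read_penetrance_config()` returns an [penetrance_model()];
#'   `write_penetrance_config()` returns `path` invisibly.
#' @export
read_penetrance_config <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("field", "cancer_type", "bracket", "value")
  if (!all(need %in% names(df)))
    stop("penetrance config needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  hz <- matrix(0, n_brackets(), length(cancer_types()),
               dimnames = list(bracket_labels(), cancer_types()))
  hr <- matrix(1, n_brackets(), length(cancer_types()),
               dimnames = list(bracket_labels(), cancer_types()))
  af <- NA_real_
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (row$field == "allele_frequency") { af <- row$value; next }
    if (!row$field %in% c("hazard", "hazard_ratio"))
      stop("unknown penetrance field: ", row$field, call. = FALSE)
    if (!row$cancer_type %in% cancer_types() ||
        !row$bracket %in% bracket_labels())
      stop("bad penetrance key at line ", i + 1L, call. = FALSE)
    if (row$field == "hazard") hz[row$bracket, row$cancer_type] <- row$value
    else hr[row$bracket, row$cancer_type] <- row$value
  }
  if (is.na(af)) stop("penetrance config lacks allele_frequency", call. = FALSE)
  penetrance_model(hz, hr, af)
}

#' @rdname read_penetrance_config
#' @param model An [penetrance_model()].
#' @export
write_penetrance_config <- function(model, path) {
  stopifnot(inherits(model, "mf_penetrance"))
  rows <- expand.grid(bracket = bracket_labels(), cancer_type = cancer_types(),
                      stringsAsFactors = FALSE)
  df <- rbind(
    data.frame(field = "hazard", cancer_type = rows$cancer_type,
               bracket = rows$bracket,
               value = model$hazard[cbind(rows$bracket, rows$cancer_type)]),
    data.frame(field = "hazard_ratio", cancer_type = rows$cancer_type,
               bracket = rows$bracket,
               value = model$hazard_ratio[cbind(rows$bracket, rows$cancer_type)]),
    data.frame(field = "allele_frequency", cancer_type = "", bracket = "",
               value = model$allele_frequency))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Placeholder penetrance model shipped with the package
#'
#' Loads `inst/extdata/penetrance_placeholder.tsv`: order-of-magnitude
#' baseline incidences and carrier hazard ratios chosen to resemble a
#' high-risk breast/ovarian predisposition gene. These are placeholders for
#' published penetrance estimates, which are not redistributed here; all
#' tests and simulations are relative to this configuration.
#'
#' @return An [penetrance_model()].
#' @export
default_penetrance_model <- function() {
  read_penetrance_config(mf_example("penetrance_placeholder.tsv"))
}
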