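# Co-segregation Bayes factor: pedigree likelihood under the causal vs
# neutral hypothesis, marginalising untyped genotypes by Elston-Stewart
# style peeling (variable elimination in reverse topological order, which
# peels nuclear-family cliques on loop-free pedigrees).
#
# Genotype model: rare autosomal dominant with two states per member,
# noncarrier / heterozygous carrier (homozygotes are ignored for rare
# variants). Founder carrier probability is 2 * allele frequency; a carrier
# parent transmits the variant with probability 1/2.

#' Effective censoring age of an unaffected member
#'
#' Unaffected members are censored at the earliest of their last-observed
#' age and any prophylactic surgery age; when no last-observed age was
#' supplied, the age inferred from the genotyping test date is used in its
#' place. Returns `NA` (with a warning) when no usable age exists -- such
#' members contribute likelihood 1.
#'
#' @param member One-row data frame (or list) with fields `age_last`,
#'   `surgery_age`, `test_age`, `phenotype`.
#' @return Censoring age in years, or `NA_real_`.
#' @export
effective_censoring_age <- function(member) {
  if (!identical(member$phenotype, "unaffected"))
    stop("effective_censoring_age() applies to unaffected members",
         call. = FALSE)
  base <- member$age_last
  if (is.null(base) || is.na(base)) base <- member$test_age
  cand <- c(base, member$surgery_age)
  cand <- cand[!is.na(cand)]
  if (!length(cand)) {
    warning("unaffected member without usable age contributes likelihood 1",
            call. = FALSE)
    return(NA_real_)
  }
  min(cand)
}

#' Phenotype likelihood of one member given carrier status
#'
#' Piecewise-constant hazard model over the seven age brackets. An
#' unaffected member censored at age `c` contributes the probability of no
#' diagnosis of any modelled cancer through `c`. A member affected at age
#' `a` contributes the probability that the first diagnosis falls in `a`'s
#' bracket and is of the observed type: survive all causes through the
#' earlier brackets, then event in the bracket
#' (`S(start) * h_type/h_total * (1 - exp(-h_total * width))`; when only one
#' cancer type has positive hazard this reduces to
#' `S(start) * (1 - exp(-h * width))`).
#'
#' Conventions: ovarian cancers diagnosed before age 30 use the 30-39
#' bracket hazard for the event term (the youngest ovarian penetrance class
#' is unreliable); affected members without a diagnosis age fall back to age
#' 45; cancers other than breast/ovarian censor the member at their
#' diagnosis age; a male breast cancer with no modelled male hazard (the
#' default configuration) is likewise treated as censored at diagnosis.
#'
#' @param member One-row data frame/list with `sex`, `phenotype`, `age_dx`,
#'   `age_last`, `surgery_age`, `test_age`.
#' @param carrier Logical; apply carrier hazard ratios?
#' @param model An [penetrance_model()].
#' @return Non-negative likelihood.
#' @export
phenotype_likelihood <- function(member, carrier, model) {
  stopifnot(inherits(model, "mf_penetrance"))
  ph <- member$phenotype
  if (ph %in% c("breast_cancer", "ovarian_cancer")) {
    age <- member$age_dx
    if (is.null(age) || is.na(age)) age <- 45  # documented fallback
    if (age < 0) stop("negative ages", call. = FALSE)
    type <- if (ph == "ovarian_cancer") "ovarian"
            else if (member$sex == "female") "breast_female" else "breast_male"
    # male phenotypes are outside the likelihood unless configured: a male
    # breast cancer with no modelled hazard censors at diagnosis
    if (type == "breast_male" &&
        all(type_hazard(model, type, carrier = FALSE) == 0))
      return(censored_likelihood(member, carrier, model, age))
    b <- bracket_of_age(age)
    if (type == "ovarian" && age < 30) b <- 2L  # youngest ovarian class rule
    types <- sex_types(member$sex)
    h <- vapply(types, function(t) type_hazard(model, t, carrier)[b],
                numeric(1))
    h_tot <- sum(h)
    if (h_tot == 0) return(0)
    width <- bracket_ends()[b] - bracket_starts()[b]
    surv <- exp(-cumulative_hazard(model, member$sex, carrier,
                                   bracket_starts()[b]))
    surv * (h[[type]] / h_tot) * (1 - exp(-h_tot * width))
  } else if (identical(ph, "other")) {
    age <- member$age_dx
    if (is.null(age) || is.na(age)) age <- member$age_last
    if (is.null(age) || is.na(age)) return(1)
    censored_likelihood(member, carrier, model, age)
  } else {
    cens <- effective_censoring_age(member)
    if (is.na(cens)) return(1)
    censored_likelihood(member, carrier, model, cens)
  }
}

censored_likelihood <- function(member, carrier, model, age) {
  if (age < 0) stop("negative ages", call. = FALSE)
  exp(-cumulative_hazard(model, member$sex, carrier, age))
}

## ---- factor machinery ----------------------------------------------------
## A factor is list(vars = character(), tab = numeric vector over the
## genotype grid of vars, state order noncarrier (1), carrier (2), var 1
## fastest).

factor_unary <- function(var, values) list(vars = var, tab = values)

# P(child | father, mother), dims ordered (child, father, mother).
transmission_factor <- function(child, father, mother) {
  p_c <- function(gf, gm) 1 - (1 - 0.5 * (gf == 2)) * (1 - 0.5 * (gm == 2))
  tab <- numeric(8)
  k <- 1L
  for (gm in 1:2) for (gf in 1:2) for (gc in 1:2) {
    pc <- p_c(gf, gm)
    tab[k] <- if (gc == 2) pc else 1 - pc
    k <- k + 1L
  }
  list(vars = c(child, father, mother), tab = tab)
}

# 0/1 state grids over k binary variables, cached (column j is bit j of the
# row index; variable 1 varies fastest, matching the factor table layout).
bit_grid <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      g <- matrix(0L, 2L^k, k)
      for (j in seq_len(k))
        g[, j] <- rep(rep(0:1, each = 2L^(j - 1L)), length.out = 2L^k)
      cache[[key]] <<- g
    }
    cache[[key]]
  }
})

# Multiply a set of factors and sum out `var`. Grid built over the union of
# variables; pedigree cliques are small so the 2^k grid stays tiny.
eliminate_var <- function(factors, var) {
  touch <- vapply(factors, function(f) var %in% f$vars, logical(1))
  fs <- factors[touch]
  keep_factors <- factors[!touch]
  u <- unique(unlist(lapply(fs, `[[`, "vars")))
  grid <- bit_grid(length(u))
  val <- rep(1, nrow(grid))
  for (f in fs) {
    pos <- match(f$vars, u)
    lin <- as.vector(grid[, pos, drop = FALSE] %*%
                       2L^(seq_along(pos) - 1L)) + 1L
    val <- val * f$tab[lin]
  }
  rest_pos <- which(u != var)
  if (!length(rest_pos))
    return(c(keep_factors, list(factor_unary("..const..", c(sum(val), 0)))))
  lin_rest <- as.vector(grid[, rest_pos, drop = FALSE] %*%
                          2L^(seq_along(rest_pos) - 1L)) + 1L
  tab <- as.vector(rowsum(val, lin_rest))
  c(keep_factors, list(list(vars = u[rest_pos], tab = tab)))
}

# Full elimination; returns the scalar likelihood.
peel_likelihood <- function(factors, vars_order) {
  for (v in vars_order) factors <- eliminate_var(factors, v)
  prod(vapply(factors, function(f) {
    if (identical(f$vars, "..const..")) f$tab[1] else sum(f$tab)
  }, numeric(1)))
}

# Build the genotype-model factors (founder priors, transmissions) plus
# clamps and phenotype factors for a subset of members.
build_factors <- function(ped, model, hypothesis, clamp_ids, pheno_ids,
                          member_ids = ped$members$member_id) {
  m <- ped$members[ped$members$member_id %in% member_ids, , drop = FALSE]
  q <- 2 * model$allele_frequency  # heterozygous carrier frequency
  factors <- list()
  for (i in seq_len(nrow(m))) {
    id <- m$member_id[i]
    if (is.na(m$father_id[i]))
      factors <- c(factors, list(factor_unary(id, c(1 - q, q))))
    else
      factors <- c(factors, list(transmission_factor(id, m$father_id[i],
                                                     m$mother_id[i])))
    if (id %in% clamp_ids && m$genotype[i] != "untyped") {
      obs <- if (m$genotype[i] == "carrier") c(0, 1) else c(1, 0)
      factors <- c(factors, list(factor_unary(id, obs)))
    }
    if (id %in% pheno_ids) {
      row <- m[i, ]
      # under the neutral hypothesis carriers have population penetrance
      l_non <- phenotype_likelihood(row, carrier = FALSE, model = model)
      l_car <- if (identical(hypothesis, "causal"))
        phenotype_likelihood(row, carrier = TRUE, model = model) else l_non
      factors <- c(factors, list(factor_unary(id, c(l_non, l_car))))
    }
  }
  factors
}

# Joint probability of the observed data under one hypothesis, conditioned
# on the proband's genotype and phenotype (single-ascertainment correction:
# divide by the marginal probability of the proband's own data).
hypothesis_likelihood <- function(ped, model, hypothesis) {
  m <- ped$members
  order_all <- topological_order(m)
  pro <- m$member_id[m$proband]
  typed <- m$member_id[m$genotype != "untyped"]
  full <- peel_likelihood(
    build_factors(ped, model, hypothesis, clamp_ids = typed,
                  pheno_ids = m$member_id), rev(order_all))
  # the proband's marginal only involves the proband's ancestor closure:
  # genotype probabilities of everyone else sum to 1
  anc <- c(pro, ancestor_ids(m, pro))
  pro_only <- peel_likelihood(
    build_factors(ped, model, hypothesis, clamp_ids = pro, pheno_ids = pro,
                  member_ids = anc),
    rev(order_all[order_all %in% anc]))
  full / pro_only
}

#' Co-segregation likelihood ratio for one family
#'
#' Bayes factor `P(data | variant pathogenic) / P(data | variant neutral)`
#' for a pedigree with partial genotyping. Untyped genotypes are summed out
#' by pedigree peeling; founder genotype priors come from the variant
#' allele frequency in the penetrance model and non-founders follow
#' Mendelian transmission. Phenotypes use carrier penetrance for carriers
#' under the causal hypothesis and population penetrance for everyone under
#' the neutral hypothesis. Both hypotheses are conditioned on the proband's
#' genotype-and-phenotype data (the proband's own factors cancel), the
#' single-ascertainment correction for families collected through an
#' affected carrier index case.
#'
#' Eligibility: at least two genotyped members including the proband, and
#' the proband must be a carrier; otherwise the family is not eligible and
#' an error is raised (callers typically record the family as excluded).
#'
#' @param ped An [pedigree()].
#' @param model An [penetrance_model()].
#' @return Positive likelihood ratio.
#' @examples
#' # a genotyped affected relative who is NOT a carrier is evidence against:
#' ped <- pedigree(data.frame(
#'   member_id = c("F", "M", "P", "S"),
#'   father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"),
#'   sex = c("male", "female", "female", "female"),
#'   genotype = c("untyped", "untyped", "carrier", "noncarrier"),
#'   proband = c(FALSE, FALSE, TRUE, FALSE),
#'   phenotype = c("unaffected", "unaffected", "breast_cancer",
#'                 "breast_cancer"),
#'   age_dx = c(NA, NA, 42, 45), age_last = c(80, 78, NA, NA)))
#' family_segregation_lr(ped, default_penetrance_model()) < 1
#' @export
family_segregation_lr <- function(ped, model) {
  stopifnot(inherits(ped, "mf_pedigree"), inherits(model, "mf_penetrance"))
  m <- ped$members
  typed <- m$genotype != "untyped"
  if (sum(typed) < 2L || !typed[m$proband])
    stop("family not eligible: fewer than two genotyped members ",
         "(including the proband)", call. = FALSE)
  if (m$genotype[m$proband] != "carrier")
    stop("family not eligible: proband is not a carrier", call. = FALSE)
  check_no_loops(ped)
  l1 <- hypothesis_likelihood(ped, model, "causal")
  l0 <- hypothesis_likelihood(ped, model, "neutral")
  l1 / l0
}

#' Combined co-segregation LR across families
#'
#' Per-family Bayes factors multiply across independent families carrying
#' the same variant. Families failing the eligibility rule are skipped and
#' reported in the `excluded` attribute.
#'
#' @param families List of [pedigree()] objects.
#' @param model An [penetrance_model()].
#' @return The product LR with attribute `excluded` (family ids skipped);
#'   errors if no family is eligible.
#' @export
variant_segregation_lr <- function(families, model) {
  if (inherits(families, "mf_pedigree")) families <- list(families)
  lrs <- numeric(0)
  excluded <- character(0)
  for (ped in families) {
    lr <- tryCatch(family_segregation_lr(ped, model),
                   error = function(e) {
                     if (grepl("not eligible", conditionMessage(e))) NULL
                     else stop(e)
                   })
    if (is.null(lr)) excluded <- c(excluded, ped$family_id)
    else lrs <- c(lrs, lr)
  }
  if (!length(lrs))
    stop("no eligible family for segregation analysis", call. = FALSE)
  structure(prod(lrs), excluded = excluded, family_lrs = lrs)
}
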