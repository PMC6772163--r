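# Seed-deterministic generators for pedigrees, evidence cohorts and
# population frequency tables with the statistical structure the analysis
# assumes. Each generator runs in its own RNG scope (the caller's RNG state
# is saved and restored), so simulations never leak global RNG state.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators. Defaults
#' describe a typical clinic pedigree: three generations, sibship sizes
#' `1 + Poisson(2)`, ascertainment through an affected carrier proband,
#' relatives genotyped with probability 0.5, and the placeholder penetrance
#' model.
#'
#' @param seed Integer seed (mandatory: all generators are deterministic
#'   given the config).
#' @param n_families Number of families for [simulate_pedigrees()].
#' @param hypothesis `"causal"` or `"neutral"`: do carriers get the carrier
#'   hazard ratios?
#' @param penetrance An [penetrance_model()].
#' @param genotyping_probability Probability each non-proband member is
#'   genotyped.
#' @param sibship_lambda Poisson mean of `sibship size - 1`.
#' @param generations Number of generations (2 or 3).
#' @param n_variants,pathogenic_fraction Evidence-cohort size and true
#'   pathogenic fraction.
#' @param category_probs Data frame with columns `category`, `p_benign`,
#'   `p_path` (each probability column sums to 1): the class-conditional
#'   evidence-category distributions.
#' @param accuracy Probability that a cohort variant's component LR is drawn
#'   from its own class's LR distribution (else from the other class's).
#' @param population_an Named vector of allele numbers per population for
#'   [simulate_population_frequencies()].
#' @param frequency_mix Named probabilities over the five frequency
#'   categories.
#' @return An object of class `mf_sim_config`.
#' @export
simulation_config <- function(seed,
                              n_families = 100L,
                              hypothesis = c("neutral", "causal"),
                              penetrance = default_penetrance_model(),
                              genotyping_probability = 0.5,
                              sibship_lambda = 2,
                              generations = 3L,
                              n_variants = 400L,
                              pathogenic_fraction = 0.5,
                              category_probs = data.frame(
                                category = c("effect", "no_effect"),
                                p_benign = c(0.2, 0.8),
                                p_path = c(0.8, 0.2)),
                              accuracy = 0.9,
                              population_an = c(NFE = 118000, AFR = 23000,
                                                AMR = 35000, SAS = 30000,
                                                EAS = 19000, FIN = 25000,
                                                ASJ = 10000),
                              frequency_mix = c(not_observed = 0.40,
                                                single_observation = 0.20,
                                                low = 0.20, mid = 0.15,
                                                excluded_na = 0.05)) {
  hypothesis <- match.arg(hypothesis)
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed),
            inherits(penetrance, "mf_penetrance"),
            genotyping_probability >= 0, genotyping_probability <= 1,
            generations %in% 2:3,
            pathogenic_fraction >= 0, pathogenic_fraction <= 1,
            accuracy >= 0, accuracy <= 1,
            all(c("category", "p_benign", "p_path") %in% names(category_probs)))
  if (abs(sum(category_probs$p_benign) - 1) > 1e-8 ||
      abs(sum(category_probs$p_path) - 1) > 1e-8)
    stop("category_probs columns must each sum to 1", call. = FALSE)
  stopifnot(abs(sum(frequency_mix) - 1) < 1e-8)
  structure(
    list(seed = as.integer(seed), n_families = as.integer(n_families),
         hypothesis = hypothesis, penetrance = penetrance,
         genotyping_probability = genotyping_probability,
         sibship_lambda = sibship_lambda, generations = as.integer(generations),
         n_variants = as.integer(n_variants),
         pathogenic_fraction = pathogenic_fraction,
         category_probs = category_probs, accuracy = accuracy,
         population_an = population_an, frequency_mix = frequency_mix),
    class = "mf_sim_config")
}

# Run expr with the RNG seeded from (config$seed, offset), restoring the
# caller's RNG state afterwards.
with_sim_rng <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((config$seed + offset) %% .Machine$integer.max)
  force(expr)
}

# Draw an event age from per-bracket hazards; Inf if no event by 105.
sample_event_age <- function(hazards) {
  e <- rexp(1)
  for (b in seq_len(n_brackets())) {
    w <- bracket_ends()[b] - bracket_starts()[b]
    h <- hazards[b]
    if (h <= 0) next
    if (e < h * w) return(bracket_starts()[b] + e / h)
    e <- e - h * w
  }
  Inf
}

# Family skeleton: ids, parents, sexes, current ages; independent of
# genotypes and phenotypes so the ascertainment rejection loop can keep it
# fixed.
sim_structure <- function(config) {
  id <- function(k) sprintf("I%02d", k)
  k <- 0L
  new_id <- function() { k <<- k + 1L; id(k) }
  m <- data.frame(member_id = character(0), father_id = character(0),
                  mother_id = character(0), sex = character(0),
                  generation = integer(0), age_now = numeric(0),
                  stringsAsFactors = FALSE)
  add <- function(father, mother, sex, gen, age) {
    m[nrow(m) + 1L, ] <<- list(new_id(), father, mother, sex, gen, age)
    m$member_id[nrow(m)]
  }
  gp_f <- add(NA, NA, "male", 1L, runif(1, 65, 85))
  gp_m <- add(NA, NA, "female", 1L, runif(1, 65, 85))
  n_sib <- 1L + rpois(1, config$sibship_lambda)
  for (s in seq_len(n_sib)) {
    sex <- if (runif(1) < 0.5) "female" else "male"
    child <- add(gp_f, gp_m, sex, 2L, runif(1, 40, 60))
    if (config$generations >= 3L && runif(1) < 0.8) {
      spouse <- add(NA, NA, if (sex == "female") "male" else "female", 2L,
                    runif(1, 40, 60))
      n_kid <- 1L + rpois(1, config$sibship_lambda)
      fa <- if (sex == "male") child else spouse
      mo <- if (sex == "female") child else spouse
      for (kk in seq_len(n_kid))
        add(fa, mo, if (runif(1) < 0.5) "female" else "male", 3L,
            runif(1, 18, 40))
    }
  }
  m
}

# Ancestor closure (indices) of a member, including the member.
closure_idx <- function(m, i) {
  out <- i
  frontier <- i
  while (length(frontier)) {
    ps <- match(stats::na.omit(c(m$father_id[frontier], m$mother_id[frontier])),
                m$member_id)
    ps <- setdiff(ps, out)
    out <- c(out, ps)
    frontier <- ps
  }
  sort(out)
}

# Exact conditional genotype draw given the proband is a carrier: enumerate
# the proband's ancestor closure (small), weight each configuration by
# founder priors and Mendelian transmission with the proband clamped to
# carrier, sample one, then forward-fill everyone else by transmission.
# Sampling the rest of the family from the model conditional on the
# proband's data is what makes E[LR] = 1 exact under the neutral hypothesis.
sim_genotypes_conditional <- function(m, q, pro) {
  n <- nrow(m)
  anc <- closure_idx(m, pro)
  free <- setdiff(anc, pro)
  k <- length(free)
  configs <- if (k) as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
             else matrix(logical(0), nrow = 1)
  w <- apply(configs, 1, function(g) {
    carrier <- rep(NA, n)
    carrier[free] <- as.logical(g)
    carrier[pro] <- TRUE
    p <- 1
    for (i in anc) {
      if (is.na(m$father_id[i])) p <- p * (if (carrier[i]) q else 1 - q)
      else {
        gf <- carrier[match(m$father_id[i], m$member_id)]
        gm <- carrier[match(m$mother_id[i], m$member_id)]
        pc <- 1 - (1 - 0.5 * gf) * (1 - 0.5 * gm)
        p <- p * (if (carrier[i]) pc else 1 - pc)
      }
    }
    p
  })
  pick <- sample.int(nrow(configs), 1L, prob = w)
  carrier <- rep(NA, n)
  if (k) carrier[free] <- as.logical(configs[pick, ])
  carrier[pro] <- TRUE
  for (i in order(match(m$member_id, topological_order(m)))) {
    if (!is.na(carrier[i])) next
    if (is.na(m$father_id[i])) carrier[i] <- runif(1) < q
    else {
      gf <- carrier[match(m$father_id[i], m$member_id)]
      gm <- carrier[match(m$mother_id[i], m$member_id)]
      carrier[i] <- runif(1) < 1 - (1 - 0.5 * gf) * (1 - 0.5 * gm)
    }
  }
  carrier
}

# Phenotype draw for non-proband members: independent piecewise-exponential
# event ages per applicable cancer type, competing by minimum.
sim_phenotypes <- function(m, carrier, config, skip) {
  model <- config$penetrance
  n <- nrow(m)
  phenotype <- rep("unaffected", n)
  age_dx <- rep(NA_real_, n)
  for (i in setdiff(seq_len(n), skip)) {
    risk <- carrier[i] && identical(config$hypothesis, "causal")
    types <- sex_types(m$sex[i])
    t_ev <- vapply(types, function(t)
      sample_event_age(type_hazard(model, t, carrier = risk)), numeric(1))
    b <- which.min(t_ev)
    if (is.finite(t_ev[b]) && t_ev[b] < m$age_now[i]) {
      phenotype[i] <- if (types[b] == "ovarian") "ovarian_cancer"
                      else "breast_cancer"
      age_dx[i] <- t_ev[b]
    }
  }
  list(phenotype = phenotype, age_dx = age_dx)
}

# Draw the proband's (cancer type, diagnosis age) conditional on being
# affected before the current age, under the proband's own hazards.
sim_proband_event <- function(member, carrier_risk, model) {
  c_now <- member$age_now
  types <- sex_types(member$sex)
  rows <- list()
  for (b in seq_len(n_brackets())) {
    s <- bracket_starts()[b]
    if (s >= c_now) break
    w <- min(bracket_ends()[b], c_now) - s
    h <- vapply(types, function(t) type_hazard(model, t, carrier_risk)[b],
                numeric(1))
    h_tot <- sum(h)
    if (h_tot <= 0) next
    surv <- exp(-cumulative_hazard(model, member$sex, carrier_risk, s))
    for (t in types)
      rows[[length(rows) + 1L]] <- list(
        b = b, type = t,
        p = surv * (h[[t]] / h_tot) * (1 - exp(-h_tot * w)))
  }
  mass <- vapply(rows, `[[`, numeric(1), "p")
  if (!length(mass) || sum(mass) <= 0)
    stop("cannot ascertain an affected carrier proband: the penetrance ",
         "configuration gives the proband zero cancer probability",
         call. = FALSE)
  pick <- rows[[sample.int(length(rows), 1L, prob = mass)]]
  s <- bracket_starts()[pick$b]
  list(type = pick$type,
       age = runif(1, s, min(bracket_ends()[pick$b], c_now)))
}

simulate_pedigree_impl <- function(config, fam_id) {
  model <- config$penetrance
  m <- sim_structure(config)
  females <- which(m$sex == "female")
  pro <- if (length(females) == 1L) females else sample(females, 1L)
  carrier <- sim_genotypes_conditional(m, 2 * model$allele_frequency, pro)
  draw <- sim_phenotypes(m, carrier, config, skip = pro)
  ev <- sim_proband_event(m[pro, ],
                          carrier_risk = identical(config$hypothesis,
                                                   "causal"), model)
  draw$phenotype[pro] <- if (ev$type == "ovarian") "ovarian_cancer"
                         else "breast_cancer"
  draw$age_dx[pro] <- ev$age
  draw$carrier <- carrier
  typed <- runif(nrow(m)) < config$genotyping_probability
  typed[pro] <- TRUE
  genotype <- ifelse(typed, ifelse(draw$carrier, "carrier", "noncarrier"),
                     "untyped")
  members <- data.frame(
    member_id = m$member_id, father_id = m$father_id,
    mother_id = m$mother_id, sex = m$sex, genotype = genotype,
    proband = seq_len(nrow(m)) == pro, phenotype = draw$phenotype,
    age_dx = round(draw$age_dx, 1),
    age_last = ifelse(draw$phenotype == "unaffected", round(m$age_now, 1),
                      NA_real_),
    surgery_type = NA_character_, surgery_age = NA_real_,
    test_age = NA_real_, stringsAsFactors = FALSE)
  pedigree(members, family_id = fam_id)
}

#' Simulate one ascertained pedigree
#'
#' Builds a family skeleton (structure, sexes, current ages), then draws
#' founder genotypes at the carrier frequency of the penetrance model,
#' transmits Mendelianly, and draws cancer phenotypes from the age-bracket
#' hazard model -- with carrier hazard ratios applied only when the config's
#' hypothesis is `"causal"` and the member carries the variant. Single
#' ascertainment through an affected carrier proband is exact-conditional:
#' a proband position is chosen among the females up front, her genotype is
#' clamped to carrier with the ancestor genotypes drawn from their exact
#' Bayes conditional, and her diagnosis is drawn conditional on occurring
#' before her current age. This is equivalent to resampling the family
#' until the chosen member is an affected carrier, but needs no rejection
#' loop even for rare variants, and it makes the rest of the family exactly
#' model-conditional given the proband's data (so the neutral-hypothesis
#' mean family LR is exactly 1). Relatives are genotyped independently with
#' the configured probability; the proband is always genotyped.
#'
#' @param config An [simulation_config()].
#' @param family_id Label for the resulting pedigree.
#' @return An [pedigree()].
#' @export
simulate_pedigree <- function(config, family_id = "SIM1") {
  stopifnot(inherits(config, "mf_sim_config"))
  with_sim_rng(config, 0L, simulate_pedigree_impl(config, family_id))
}

#' Simulate a cohort of ascertained pedigrees
#'
#' @param config An [simulation_config()]; `config$n_families` pedigrees are
#'   generated from one RNG stream.
#' @return List of [pedigree()] objects.
#' @export
simulate_pedigrees <- function(config) {
  stopifnot(inherits(config, "mf_sim_config"))
  with_sim_rng(config, 0L, lapply(seq_len(config$n_families), function(i)
    simulate_pedigree_impl(config, sprintf("SIM%04d", i))))
}

#' Simulate an evidence cohort for calibration
#'
#' Draws `n_variants` variants with true class pathogenic at the configured
#' fraction, assigns each an evidence category from its class-conditional
#' distribution (`category_probs`), and draws a single segregation-style
#' component LR per variant such that classification matches truth at
#' roughly the configured accuracy (LRs are drawn log-normally around a high
#' median for pathogenic and a low median for benign variants; with
#' probability `1 - accuracy` the wrong class's distribution is used).
#'
#' @param config An [simulation_config()].
#' @return List with `variants` (data frame: `variant_id`, `truth`,
#'   `category`, `prior`, `component_lr`), `crosstab` (an [crosstab()] of
#'   category counts by truth) and `config`.
#' @export
simulate_evidence_cohort <- function(config) {
  stopifnot(inherits(config, "mf_sim_config"))
  with_sim_rng(config, 1L, {
    n <- config$n_variants
    cp <- config$category_probs
    truth <- ifelse(runif(n) < config$pathogenic_fraction, "pathogenic",
                    "benign")
    category <- character(n)
    is_p <- truth == "pathogenic"
    if (any(is_p))
      category[is_p] <- sample(cp$category, sum(is_p), replace = TRUE,
                               prob = cp$p_path)
    if (any(!is_p))
      category[!is_p] <- sample(cp$category, sum(!is_p), replace = TRUE,
                                prob = cp$p_benign)
    own <- runif(n) < config$accuracy
    eff <- ifelse(own, truth,
                  ifelse(truth == "pathogenic", "benign", "pathogenic"))
    component_lr <- ifelse(eff == "pathogenic",
                           rlnorm(n, log(500), 1.5),
                           rlnorm(n, log(0.02), 1.5))
    prior <- ifelse(truth == "pathogenic", 0.81, 0.03)
    variants <- data.frame(
      variant_id = sprintf("V%05d", seq_len(n)), truth = truth,
      category = category, prior = prior, component_lr = component_lr,
      stringsAsFactors = FALSE)
    tab <- crosstab(
      cp$category,
      benign_counts = vapply(cp$category, function(ct)
        sum(truth == "benign" & category == ct), numeric(1)),
      pathogenic_counts = vapply(cp$category, function(ct)
        sum(truth == "pathogenic" & category == ct), numeric(1)),
      evidence_type = "synthetic")
    list(variants = variants, crosstab = tab, config = config)
  })
}

#' Simulate per-population allele-frequency tables
#'
#' Each variant is assigned a frequency category from `frequency_mix` and
#' allele counts are drawn to realise it: `single_observation` places one
#' allele in a random outbred population; `low` (max MAF < 1e-4) and `mid`
#' (1e-4 <= max MAF < 0.01) draw the defining allele count in a random
#' outbred population; `excluded_na` places a single allele in a founder
#' population. At the default mix all five categories are represented for
#' moderate `n_variants`.
#'
#' @param config An [simulation_config()].
#' @param n_variants Number of tables to generate (default from config).
#' @return List with `tables` (list of [frequency_table()]) and `truth`
#'   (the generating categories).
#' @export
simulate_population_frequencies <- function(config,
                                            n_variants = config$n_variants) {
  stopifnot(inherits(config, "mf_sim_config"))
  with_sim_rng(config, 2L, {
    an <- config$population_an
    pops <- names(an)
    out_pops <- intersect(pops, outbred_populations())
    fou_pops <- intersect(pops, founder_populations())
    cats <- sample(names(config$frequency_mix), n_variants, replace = TRUE,
                   prob = config$frequency_mix)
    tables <- lapply(cats, function(ct) {
      ac <- setNames(numeric(length(pops)), pops)
      if (ct == "single_observation") {
        ac[sample(out_pops, 1L)] <- 1
      } else if (ct == "low") {
        # need AC >= 2 (not a single observation) with AC/AN < 1e-4
        big <- out_pops[an[out_pops] > 2e4]
        p <- if (length(big) > 1L) sample(big, 1L) else big
        hi <- ceiling(an[[p]] * 1e-4) - 1L
        ac[p] <- if (hi > 2L) sample(2:hi, 1L) else 2L
      } else if (ct == "mid") {
        p <- sample(out_pops, 1L)
        lo <- max(2L, ceiling(an[[p]] * 1e-4))
        hi <- floor(an[[p]] * 0.009)
        ac[p] <- sample(lo:hi, 1L)
      } else if (ct == "excluded_na") {
        ac[sample(fou_pops, 1L)] <- 1
      }
      frequency_table(pops, ac, an)
    })
    list(tables = tables, truth = cats)
  })
}
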