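# Independent oracles used by the test-suite. These deliberately avoid the
# package's peeling machinery: likelihoods are computed by brute-force
# enumeration of genotype configurations.

# Joint probability of one full genotype configuration times the phenotype
# factors of `pheno_idx`, under one hypothesis.
oracle_joint <- function(m, carrier, hyp, model, pheno_idx) {
  q <- 2 * model$allele_frequency
  p <- 1
  for (i in seq_len(nrow(m))) {
    # members left NA are fully marginalised (their genotype probabilities
    # sum to 1 and no phenotype factor touches them)
    if (is.na(carrier[i])) next
    if (is.na(m$father_id[i])) {
      p <- p * (if (carrier[i]) q else 1 - q)
    } else {
      gf <- carrier[match(m$father_id[i], m$member_id)]
      gm <- carrier[match(m$mother_id[i], m$member_id)]
      pc <- 1 - (1 - 0.5 * gf) * (1 - 0.5 * gm)
      p <- p * (if (carrier[i]) pc else 1 - pc)
    }
    if (i %in% pheno_idx) {
      risk <- carrier[i] && hyp == "causal"
      p <- p * phenotype_likelihood(m[i, ], risk, model)
    }
  }
  p
}

# Sum oracle_joint over all configurations of `free_idx` (others clamped).
oracle_sum <- function(m, base_carrier, free_idx, hyp, model, pheno_idx) {
  k <- length(free_idx)
  tot <- 0
  for (code in 0:(2^k - 1)) {
    carrier <- base_carrier
    if (k)
      carrier[free_idx] <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    tot <- tot + oracle_joint(m, carrier, hyp, model, pheno_idx)
  }
  tot
}

# Ancestor closure indices of a member (including the member).
oracle_closure <- function(m, i) {
  out <- i
  frontier <- i
  while (length(frontier)) {
    ps <- match(stats::na.omit(c(m$father_id[frontier],
                                 m$mother_id[frontier])), m$member_id)
    ps <- setdiff(ps, out)
    out <- c(out, ps)
    frontier <- ps
  }
  sort(out)
}

# Exhaustive-enumeration co-segregation LR. The proband marginal only needs
# the proband's ancestor closure: genotype probabilities of everyone else
# marginalise to 1 when no phenotype factor touches them.
oracle_family_lr <- function(ped, model) {
  m <- ped$members
  pro <- which(m$proband)
  untyped <- which(m$genotype == "untyped")
  base <- ifelse(m$genotype == "carrier", TRUE,
                 ifelse(m$genotype == "noncarrier", FALSE, NA))
  anc <- oracle_closure(m, pro)
  lik <- function(hyp) {
    full <- oracle_sum(m, base, untyped, hyp, model, seq_len(nrow(m)))
    base_pro <- rep(NA, nrow(m))
    base_pro[pro] <- base[pro]
    pro_marg <- oracle_sum(m, base_pro, setdiff(anc, pro), hyp, model, pro)
    full / pro_marg
  }
  lik("causal") / lik("neutral")
}

# Small random pedigree generator for property tests: independent of the
# synthetic_data module so structural edge cases (unaffected probands aside)
# are exercised directly.
random_test_pedigree <- function(max_untyped = 10L) {
  repeat {
    n_kids <- sample(2:4, 1)
    ids <- c("F", "M", paste0("K", seq_len(n_kids)))
    n <- length(ids)
    fa <- c(NA, NA, rep("F", n_kids))
    mo <- c(NA, NA, rep("M", n_kids))
    sex <- c("male", "female",
             sample(c("female", "male"), n_kids, replace = TRUE))
    # maybe extend one generation
    if (runif(1) < 0.5) {
      gk <- sample(1:3, 1)
      sp_sex <- if (sex[3] == "female") "male" else "female"
      ids <- c(ids, "SP", paste0("G", seq_len(gk)))
      fa <- c(fa, NA, rep(if (sex[3] == "male") "K1" else "SP", gk))
      mo <- c(mo, NA, rep(if (sex[3] == "female") "K1" else "SP", gk))
      sex <- c(sex, sp_sex, sample(c("female", "male"), gk, replace = TRUE))
      n <- length(ids)
    }
    # simulate true genotypes (high carrier frequency so carriers are
    # common), then mask: guarantees Mendelian-consistent observed clamps
    carrier <- logical(n)
    for (i in seq_len(n)) {
      if (is.na(fa[i])) carrier[i] <- runif(1) < 0.4
      else {
        pc <- 1 - (1 - 0.5 * carrier[match(fa[i], ids)]) *
          (1 - 0.5 * carrier[match(mo[i], ids)])
        carrier[i] <- runif(1) < pc
      }
    }
    genotype <- ifelse(runif(n) < 0.5, "untyped",
                       ifelse(carrier, "carrier", "noncarrier"))
    phenotype <- ifelse(
      sex == "female",
      sample(c("unaffected", "breast_cancer", "ovarian_cancer", "other"), n,
             replace = TRUE, prob = c(0.55, 0.3, 0.1, 0.05)),
      "unaffected")
    age_dx <- ifelse(phenotype %in% c("breast_cancer", "ovarian_cancer",
                                      "other"),
                     round(runif(n, 25, 75)), NA)
    age_last <- ifelse(is.na(age_dx), round(runif(n, 30, 85)), NA)
    pro_cand <- which(sex == "female" & carrier &
                        phenotype %in% c("breast_cancer", "ovarian_cancer"))
    if (!length(pro_cand)) next
    pro <- pro_cand[sample.int(length(pro_cand), 1)]
    genotype[pro] <- "carrier"
    if (sum(genotype != "untyped") < 2 ||
        sum(genotype == "untyped") > max_untyped) next
    members <- data.frame(member_id = ids, father_id = fa, mother_id = mo,
                          sex = sex, genotype = genotype,
                          proband = seq_len(n) == pro,
                          phenotype = phenotype, age_dx = age_dx,
                          age_last = age_last, stringsAsFactors = FALSE)
    return(pedigree(members, family_id = "RND"))
  }
}

test_penetrance <- function() default_penetrance_model()

# penetrance model with every hazard ratio forced to 1
null_hr_model <- function(model = test_penetrance()) {
  penetrance_model(model$hazard,
                   matrix(1, 7, 3), model$allele_frequency)
}
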