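# segregation: censoring, penetrance likelihoods, pedigree Bayes factor.

member_row <- function(...) {
  defaults <- list(member_id = "X", father_id = NA, mother_id = NA,
                   sex = "female", genotype = "untyped", proband = FALSE,
                   phenotype = "unaffected", age_dx = NA_real_,
                   age_last = NA_real_, surgery_type = NA_character_,
                   surgery_age = NA_real_, test_age = NA_real_)
  as.data.frame(modifyList(defaults, list(...)), stringsAsFactors = FALSE)
}

# constant breast hazard h, no ovarian/male hazard, flat hazard ratio
flat_model <- function(h, hr = 3, af = 0.0005) {
  hz <- matrix(0, 7, 3)
  hz[, 1] <- h
  penetrance_model(hz, matrix(hr, 7, 3), af)
}

test_that("effective censoring age: min(last observed, earliest surgery)", {
  expect_equal(effective_censoring_age(
    member_row(age_last = 60, surgery_type = "oophorectomy",
               surgery_age = 42)), 42)
  expect_equal(effective_censoring_age(member_row(age_last = 55)), 55)
  expect_equal(effective_censoring_age(member_row(test_age = 48)), 48)
  expect_warning(age <- effective_censoring_age(member_row()),
                 "likelihood 1")
  expect_true(is.na(age))
  expect_error(effective_censoring_age(member_row(phenotype = "breast_cancer",
                                                  age_dx = 50)), "unaffected")
})

test_that("phenotype likelihood degenerate and null cases", {
  zero <- flat_model(0)
  expect_equal(phenotype_likelihood(member_row(age_last = 70), TRUE, zero), 1)
  expect_equal(phenotype_likelihood(
    member_row(phenotype = "breast_cancer", age_dx = 45), TRUE, zero), 0)
  # hazard ratio 1 makes carrier and noncarrier likelihoods identical
  null_m <- null_hr_model()
  for (mem in list(member_row(age_last = 62),
                   member_row(phenotype = "breast_cancer", age_dx = 45),
                   member_row(phenotype = "ovarian_cancer", age_dx = 55)))
    expect_equal(phenotype_likelihood(mem, TRUE, null_m),
                 phenotype_likelihood(mem, FALSE, null_m))
})

test_that("unaffected survival matches the closed-form exponential", {
  m <- flat_model(0.01)
  expect_equal(phenotype_likelihood(member_row(age_last = 50), FALSE, m),
               exp(-0.5), tolerance = 1e-12)
  # carrier multiplies the hazard by the bracket hazard ratio
  expect_equal(phenotype_likelihood(member_row(age_last = 50), TRUE, m),
               exp(-0.5 * 3), tolerance = 1e-12)
})

test_that("affected likelihood is survive-then-event in the age bracket", {
  m <- flat_model(0.01)
  # breast cancer at 45: survive to 40 at h=0.01, event in the 10y bracket
  expect_equal(phenotype_likelihood(
    member_row(phenotype = "breast_cancer", age_dx = 45), FALSE, m),
    exp(-0.4) * (1 - exp(-0.1)), tolerance = 1e-12)
  # ovarian cancer at 20-29 uses the 30-39 bracket
  full <- test_penetrance()
  expect_equal(phenotype_likelihood(
    member_row(phenotype = "ovarian_cancer", age_dx = 25), TRUE, full),
    phenotype_likelihood(
      member_row(phenotype = "ovarian_cancer", age_dx = 35), TRUE, full))
  # other cancers censor at diagnosis age
  expect_equal(phenotype_likelihood(
    member_row(phenotype = "other", age_dx = 50), FALSE, m),
    exp(-0.5), tolerance = 1e-12)
  expect_error(phenotype_likelihood(
    member_row(phenotype = "breast_cancer", age_dx = -5), FALSE, m),
    "negative")
})

test_that("family eligibility rules are enforced", {
  model <- test_penetrance()
  only_pro <- pedigree(data.frame(
    member_id = c("F", "M", "P"), father_id = c(NA, NA, "F"),
    mother_id = c(NA, NA, "M"), sex = c("male", "female", "female"),
    genotype = c("untyped", "untyped", "carrier"),
    proband = c(FALSE, FALSE, TRUE),
    phenotype = c("unaffected", "unaffected", "breast_cancer"),
    age_dx = c(NA, NA, 40), age_last = c(70, 70, NA)))
  expect_error(family_segregation_lr(only_pro, model), "not eligible")
  noncar <- only_pro
  noncar$members$genotype <- c("carrier", "untyped", "noncarrier")
  noncar <- pedigree(noncar$members)
  expect_error(family_segregation_lr(noncar, model), "not a carrier")
})

test_that("an affected genotyped noncarrier relative is evidence against", {
  ped <- pedigree(data.frame(
    member_id = c("F", "M", "P", "S"),
    father_id = c(NA, NA, "F", "F"), mother_id = c(NA, NA, "M", "M"),
    sex = c("male", "female", "female", "female"),
    genotype = c("untyped", "untyped", "carrier", "noncarrier"),
    proband = c(FALSE, FALSE, TRUE, FALSE),
    phenotype = c("unaffected", "unaffected", "breast_cancer",
                  "breast_cancer"),
    age_dx = c(NA, NA, 42, 45), age_last = c(80, 78, NA, NA)))
  expect_lt(family_segregation_lr(ped, test_penetrance()), 1)
  # and an affected carrier relative is evidence for
  ped2 <- ped
  ped2$members$genotype[4] <- "carrier"
  ped2 <- pedigree(ped2$members)
  expect_gt(family_segregation_lr(ped2, test_penetrance()), 1)
})

test_that("peeling equals exhaustive enumeration on random pedigrees", {
  model <- test_penetrance()
  set.seed(421)
  for (i in 1:40) {
    ped <- random_test_pedigree()
    a <- family_segregation_lr(ped, model)
    b <- oracle_family_lr(ped, model)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("hazard ratio 1 forces every family LR to exactly 1", {
  null_m <- null_hr_model()
  for (seed in 1:8) {
    ped <- simulate_pedigree(simulation_config(
      seed = seed, hypothesis = if (seed %% 2) "causal" else "neutral"))
    if (sum(ped$members$genotype != "untyped") < 2) next
    expect_equal(family_segregation_lr(ped, null_m), 1, tolerance = 1e-12)
  }
})

test_that("consanguineous pedigrees are rejected", {
  # first cousins mating: K1's child with K2's child
  ped <- data.frame(
    member_id = c("F", "M", "K1", "K2", "S1", "S2", "C1", "C2", "G"),
    father_id = c(NA, NA, "F", "F", NA, NA, "K1", "K2", "C1"),
    mother_id = c(NA, NA, "M", "M", NA, NA, "S1", "S2", "C2"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "female", "female"),
    genotype = c(rep("untyped", 6), "carrier", "noncarrier", "carrier"),
    proband = c(rep(FALSE, 8), TRUE),
    phenotype = c(rep("unaffected", 8), "breast_cancer"),
    age_dx = c(rep(NA, 8), 35),
    age_last = c(90, 90, 70, 70, 70, 70, 50, 50, NA))
  ped <- pedigree(ped)
  expect_error(family_segregation_lr(ped, test_penetrance()),
               "consanguineous")
})

test_that("variant-level LR is the product over eligible families", {
  model <- test_penetrance()
  peds <- read_pedigree_file(mf_example("example_family.ped"))
  single <- variant_segregation_lr(peds[1], model)
  expect_equal(as.numeric(single), family_segregation_lr(peds[[1]], model))
  both <- variant_segregation_lr(peds, model)
  expect_equal(as.numeric(both),
               family_segregation_lr(peds[[1]], model) *
                 family_segregation_lr(peds[[2]], model))
  # ineligible families are excluded, not fatal
  lone <- pedigree(data.frame(
    member_id = "P", father_id = NA, mother_id = NA, sex = "female",
    genotype = "carrier", proband = TRUE, phenotype = "breast_cancer",
    age_dx = 40), family_id = "LONE")
  mixed <- variant_segregation_lr(c(peds, list(lone)), model)
  expect_equal(as.numeric(mixed), as.numeric(both))
  expect_equal(attr(mixed, "excluded"), "LONE")
  expect_error(variant_segregation_lr(list(lone), model), "no eligible")
})
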