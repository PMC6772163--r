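# calibration: cross-tab LRs, Wald CIs, ACMG strengths, concordance.

test_that("reproduction suite: published calibration tables", {
  tabs <- load_reference_crosstabs()
  rep <- do.call(rbind, lapply(tabs, calibrate_crosstab))
  key <- paste(rep$evidence_type, rep$category)
  row <- function(k) rep[key == k, ]
  # all twelve published LRs at two decimals (11 table rows + the inverse)
  expect_equal(row("splicing_allele_specific None")$lr_display, "0.12")
  expect_equal(row("splicing_allele_specific Partial")$lr_display, "3.82")
  expect_equal(row("splicing_allele_specific Complete")$lr_display, "6.36")
  expect_equal(row("splicing_all None")$lr_display, "0.02")
  expect_equal(row("splicing_all Any impact")$lr_display, "12.24")
  expect_equal(row("functional None")$lr_display, "0.07")
  expect_equal(row("functional Complete")$lr_display, "57.19")
  expect_equal(row("frequency Single observation")$lr_display, "0.67")
  expect_equal(row("frequency >= 0.0001 & < 0.01")$lr_display, "0.05")
  expect_equal(row("frequency > 0 & < 0.0001")$lr_display, "0.13")
  expect_equal(row("frequency Not observed")$lr_display, "2.50")
  # confidence intervals as printed
  expect_equal(row("splicing_allele_specific None")$ci_display, "(0.02-0.76)")
  expect_equal(row("splicing_allele_specific Partial")$ci_display,
               "(0.95-15.36)")
  expect_equal(row("splicing_allele_specific Complete")$ci_display,
               "(0.86-46.86)")
  expect_equal(row("splicing_all None")$ci_display, "(0.01-0.15)")
  expect_equal(row("splicing_all Any impact")$ci_display, "(4.78-31.35)")
  expect_equal(row("functional None")$ci_display, "(0.01-0.45)")
  expect_equal(row("functional Complete")$ci_display, "(8.15-401.14)")
  expect_equal(row("frequency Single observation")$ci_display, "(0.33-1.36)")
  expect_equal(row("frequency >= 0.0001 & < 0.01")$ci_display, "(0.01-0.32)")
  expect_equal(row("frequency > 0 & < 0.0001")$ci_display, "(0.04-0.39)")
  expect_equal(row("frequency Not observed")$ci_display, "(2.16-2.91)")
  # percentages carry the zero-cell convention
  expect_equal(round(row("splicing_all Any impact")$pathogenic_pct, 2), 97.96)
  expect_equal(round(row("functional None")$pathogenic_pct, 2), 6.25)
})

test_that("zero-cell convention flags and adjusted counts", {
  tabs <- load_reference_crosstabs()
  est <- crosstab_lr(tabs$functional, "None")
  expect_true(est$zero_cell_adjusted)
  expect_equal(unname(est$adjusted_counts),
               c(1, 16, 56, 61))
  expect_equal(round(est$lr, 4), round((1 / 16) / (56 / 61), 4))
  # unadjusted category
  est2 <- crosstab_lr(tabs$frequency, "Not observed")
  expect_false(est2$zero_cell_adjusted)
  expect_error(crosstab_lr(crosstab(c("a", "b"), c(0, 5), c(0, 5)), "a"),
               "unobserved")
  # equal proportions give LR exactly 1
  eq <- crosstab_lr(crosstab(c("a", "b"), c(10, 30), c(5, 15)), "a")
  expect_equal(eq$lr, 1)
})

test_that("benign-direction inverse of the mid-frequency bin", {
  tabs <- load_reference_crosstabs()
  est <- crosstab_lr(tabs$frequency, ">= 0.0001 & < 0.01")
  inv <- inverse_lr(est)
  expect_equal(round(inv$lr, 2), 22.10)
  expect_equal(round(inv$ci_high, 2), 156.21)
  # full-precision inversion gives 3.13; the published 3.12 is the
  # reciprocal of the bound after rounding (1/0.32 = 3.125)
  expect_equal(round(inv$ci_low, 2), 3.13)
  expect_equal(round(1 / round(est$ci_high, 2), 2), 3.12)
  expect_true(inv$ci_low <= inv$lr && inv$lr <= inv$ci_high)
  # involution and unity
  back <- inverse_lr(inv)
  expect_equal(back$lr, est$lr)
  expect_equal(back$ci_low, est$ci_low)
  one <- list(lr = 1, ci_low = 0.5, ci_high = 2, p_pathogenic = 0.1,
              p_benign = 0.1)
  expect_equal(inverse_lr(one)$lr, 1)
})

test_that("doubling all counts keeps the LR and narrows the CI", {
  set.seed(3)
  for (i in 1:20) {
    b <- rpois(3, 20) + 1
    p <- rpois(3, 20) + 1
    t1 <- crosstab(c("x", "y", "z"), b, p)
    t2 <- crosstab(c("x", "y", "z"), 2 * b, 2 * p)
    e1 <- crosstab_lr(t1, "x")
    e2 <- crosstab_lr(t2, "x")
    expect_equal(e2$lr, e1$lr, tolerance = 1e-12)
    expect_gt(e2$ci_low, e1$ci_low)
    expect_lt(e2$ci_high, e1$ci_high)
  }
})

test_that("ACMG/AMP strength mapping", {
  expect_equal(acmg_strength(12.24),
               list(direction = "pathogenic", strength = "moderate"))
  expect_equal(acmg_strength(57.19),
               list(direction = "pathogenic", strength = "strong"))
  expect_equal(acmg_strength(2.50),
               list(direction = "pathogenic", strength = "supporting"))
  expect_equal(acmg_strength(0.07),
               list(direction = "benign", strength = "moderate"))
  expect_equal(acmg_strength(0.02),
               list(direction = "benign", strength = "strong"))
  expect_equal(acmg_strength(0.67)$direction, "uninformative")
  # boundary policy: half-open [low, high) on the pathogenic side
  expect_equal(acmg_strength(4.3)$strength, "moderate")
  expect_equal(acmg_strength(18.7)$strength, "strong")
  expect_equal(acmg_strength(350)$strength, "very_strong")
  expect_equal(acmg_strength(2.08)$strength, "supporting")
})

test_that("strength is preserved and direction flipped under x -> 1/x", {
  set.seed(4)
  for (x in exp(runif(60, log(1 / 1000), log(1000)))) {
    a <- acmg_strength(x)
    b <- acmg_strength(1 / x)
    if (a$direction == "uninformative") {
      expect_equal(b$direction, "uninformative")
    } else {
      expect_equal(sort(c(a$direction, b$direction)),
                   c("benign", "pathogenic"))
      expect_equal(a$strength, b$strength)
    }
  }
})

test_that("concordance table counts agreement with external assertions", {
  t1 <- concordance_table(list(v1 = "C5"), list(v1 = c("LP")))
  expect_equal(t1["LP", "LP"], 1L)
  t2 <- concordance_table(list(v1 = "C5"), list())
  expect_equal(t2["LP", "not_in_external"], 1L)
  t3 <- concordance_table(list(v1 = "C2", v2 = "C2"),
                          list(v1 = c("VUS"), v2 = c("LP")))
  expect_equal(t3["LB", "LP"], 1L)
  expect_equal(t3["LB", "VUS"], 1L)
  # at-least-one semantics: LP dominates mixed assertions
  t4 <- concordance_table(list(v1 = "C4"), list(v1 = c("VUS", "LP", "LB")))
  expect_equal(t4["LP", "LP"], 1L)
  expect_equal(sum(t4), 1L)
})

test_that("synthetic cohort recovers a generating LR within its CI", {
  cfg <- simulation_config(seed = 99, n_variants = 10000,
                           category_probs = data.frame(
                             category = c("hit", "miss"),
                             p_benign = c(0.1, 0.9),
                             p_path = c(0.6, 0.4)))
  coh <- simulate_evidence_cohort(cfg)
  est <- crosstab_lr(coh$crosstab, "hit")
  expect_true(est$ci_low <= 6 && 6 <= est$ci_high)
  expect_equal(est$lr, 6, tolerance = 0.15)
  # no-signal design: equal conditional distributions give LR ~ 1
  cfg0 <- simulation_config(seed = 100, n_variants = 10000,
                            category_probs = data.frame(
                              category = c("hit", "miss"),
                              p_benign = c(0.3, 0.7),
                              p_path = c(0.3, 0.7)))
  est0 <- crosstab_lr(simulate_evidence_cohort(cfg0)$crosstab, "hit")
  expect_equal(est0$lr, 1, tolerance = 0.15)
})
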