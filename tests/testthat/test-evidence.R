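# evidence_components: pathology, co-occurrence, family history,
# case-control, frequency categorisation.

path_table <- function() read_pathology_table(mf_example("pathology_lr_placeholder.tsv"))

test_that("pathology LR uses the first informative tumour only", {
  tab <- path_table()
  tumors <- data.frame(diagnosis_order = c(1, 2), age_diagnosis = c(41, 45),
                       grade = c(NA, 3), er = c(NA, "negative"))
  # dx-41 tumour has no data; the dx-45 ER-/G3 entry (<50 band) applies
  expect_equal(pathology_lr(tumors, tab, "BRCA1"), 3.73)
  # no informative tumour -> no LR
  expect_null(pathology_lr(data.frame(diagnosis_order = 1,
                                      age_diagnosis = 50), tab, "BRCA1"))
  expect_null(pathology_lr(NULL, tab, "BRCA1"))
  # lookup identity at a specific entry
  one <- data.frame(diagnosis_order = 1, age_diagnosis = 44, grade = 3,
                    er = "negative")
  expect_equal(pathology_lr(one, tab, "BRCA1"), 3.73)
  expect_equal(pathology_lr(transform(one, age_diagnosis = 61), tab,
                            "BRCA1"), 3.16)
})

test_that("pathology LR emits one value regardless of tumour count and
           falls back through information levels", {
  tab <- path_table()
  many <- data.frame(diagnosis_order = 1:4,
                     age_diagnosis = c(40, 45, 50, 55),
                     grade = c(2, 3, 3, 1),
                     er = c("negative", "negative", "positive", "positive"))
  expect_length(pathology_lr(many, tab, "BRCA1"), 1L)
  # grade-only tumour uses the grade level
  g_only <- data.frame(diagnosis_order = 1, age_diagnosis = 45, grade = 3)
  expect_equal(pathology_lr(g_only, tab, "BRCA1"), 1.69)
  # missing pattern errors and names the pattern
  small <- pathology_table(data.frame(gene = "BRCA1", level = "grade",
                                      pattern = "G3", age_band = "any",
                                      lr = 1.69))
  expect_error(pathology_lr(data.frame(diagnosis_order = 1,
                                       age_diagnosis = 45, grade = 2),
                            small, "BRCA1"), "G2")
  expect_error(pathology_lr(g_only, small, "BRCA2"), "no entries")
})

test_that("co-occurrence LR follows the binomial form", {
  expect_equal(cooccurrence_lr(0, 0), 1)
  expect_equal(cooccurrence_lr(25, 3, theta_path = 0.007,
                               theta_neutral = 0.007), 1)
  expect_equal(cooccurrence_lr(10, 0, theta_path = 1e-4,
                               theta_neutral = 0.01),
               (0.9999 / 0.99)^10)
  # k = 0 with theta_path < theta_neutral supports pathogenicity
  expect_gt(cooccurrence_lr(10, 0, 1e-4, 0.01), 1)
  # strictly decreasing in the number of in-trans observations
  lrs <- vapply(0:5, function(k) cooccurrence_lr(12, k, 1e-4, 0.01),
                numeric(1))
  expect_true(all(diff(lrs) < 0))
  expect_error(cooccurrence_lr(10, 0, theta_path = 0), "0, 1")
  expect_error(cooccurrence_lr(3, 5), "k_trans")
})

test_that("family history LR is a table lookup with an omission category", {
  tab <- read.delim(mf_example("family_history_placeholder.tsv"))
  lut <- setNames(tab$lr, tab$category)
  expect_equal(family_history_lr("strong_bc_oc_history", lut), 8.13)
  expect_null(family_history_lr("none_supplied", lut))
  expect_error(family_history_lr("strong_bc_oc_history", list()), "empty")
  expect_error(family_history_lr("mystery", lut), "unknown")
})

test_that("case-control profile LR identities", {
  # assumed_rr = 1 makes both hypotheses identical
  set.seed(2)
  for (i in 1:10) {
    n1 <- sample(1000:20000, 1); n2 <- sample(1000:20000, 1)
    k1 <- rbinom(1, n1, 0.002); k2 <- rbinom(1, n2, 0.002)
    expect_equal(case_control_lr(k1, n1, k2, n2, assumed_rr = 1), 1)
  }
  expect_equal(case_control_lr(0, 10000, 0, 10000, assumed_rr = 10), 1)
})

test_that("case-control LR matches a brute-force profile grid", {
  grid_lr <- function(k1, n1, k2, n2, rr) {
    qs <- seq(1e-6, 0.01, length.out = 20000)
    ll <- function(rr_) {
      qp <- rr_ * qs / (rr_ * qs + 1 - qs)
      max(dbinom(k1, n1, qp, log = TRUE) + dbinom(k2, n2, qs, log = TRUE))
    }
    exp(ll(rr) - ll(1))
  }
  got <- case_control_lr(5, 10000, 0, 10000, assumed_rr = 10)
  expect_equal(got, grid_lr(5, 10000, 0, 10000, 10), tolerance = 1e-3)
  expect_gt(got, 1)  # carriers only in cases support pathogenicity
  got2 <- case_control_lr(2, 5000, 8, 5000, assumed_rr = 10)
  expect_equal(got2, grid_lr(2, 5000, 8, 5000, 10), tolerance = 1e-3)
  expect_lt(got2, 1)
})

test_that("frequency categories follow the outbred-max-MAF rules", {
  pops <- c(outbred_populations(), founder_populations())
  an <- c(118000, 23000, 35000, 30000, 19000, 25000, 10000)
  tab <- function(ac) frequency_table(pops, ac, an)
  expect_equal(frequency_category(tab(rep(0, 7))), "not_observed")
  expect_equal(frequency_category(tab(c(0, 1, 0, 0, 0, 0, 0))),
               "single_observation")
  expect_equal(frequency_category(tab(c(0, 0, 0, 0, 0, 1, 0))),
               "excluded_na")
  expect_equal(frequency_category(tab(c(0, 0, 0, 0, 0, 0, 3))),
               "excluded_na")
  expect_equal(frequency_category(tab(c(2, 0, 0, 0, 0, 0, 0))), "low")
  expect_equal(frequency_category(tab(c(500, 0, 0, 0, 0, 0, 0))), "mid")
  # boundary: MAF exactly 1e-4 belongs to the mid bin
  b <- frequency_table(c("NFE", "AFR"), c(2, 0), c(20000, 20000))
  expect_equal(frequency_category(b), "mid")
  expect_error(frequency_category(tab(c(5000, 0, 0, 0, 0, 0, 0))),
               "rare-variant range")
  expect_error(frequency_table("NFE", 3, 0), "allele_number is 0")
})

test_that("frequency category is invariant to row order and tranche splits", {
  f1 <- frequency_table(c("NFE", "NFE", "AFR"), c(1, 2, 0),
                        c(60000, 58000, 23000),
                        cohort = c("exome", "genome", "exome"))
  f2 <- frequency_table(c("AFR", "NFE"), c(0, 3), c(23000, 118000))
  expect_equal(frequency_category(f1), frequency_category(f2))
  # single observation split across tranches is still counted by alleles
  s1 <- frequency_table(c("NFE", "NFE"), c(1, 0), c(60000, 58000),
                        cohort = c("exome", "genome"))
  expect_equal(frequency_category(s1), "single_observation")
})

test_that("VCF-INFO frequency parsing matches the table reader", {
  f <- parse_vcf_info_frequencies(
    "AC_nfe=1;AN_nfe=113000;AC_afr=0;AN_afr=24000;AC_fin=2;AN_fin=25000")
  expect_s3_class(f, "mf_frequency_table")
  expect_equal(frequency_category(f), "single_observation")
  expect_error(parse_vcf_info_frequencies("DP=4"), "no AC_")
})
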