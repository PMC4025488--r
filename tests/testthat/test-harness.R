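test_that("relative bias is the signed percent difference", {
  expect_equal(relative_bias(0.223, 0.334), 100 * (0.223 - 0.334) / 0.334)
  expect_equal(relative_bias(0.116, 0.200), -42)
  expect_equal(relative_bias(5, 5), 0)
  expect_lt(relative_bias(0.215, 0.353), 0)     # downward bias is negative
  expect_warning(b0 <- relative_bias(1, 0), "zero reference")
  expect_true(is.na(b0))
})

test_that("accuracy breakdown matches a hand-counted example", {
  # marker freqs make code 1 the major homozygote everywhere
  orig <- genotype_matrix(rbind(c(1L, 1L, 1L, 1L),
                                c(1L, 1L, 2L, 3L),
                                c(1L, 1L, 1L, 1L),
                                c(1L, 3L, 1L, 1L),
                                c(1L, 1L, 1L, 1L)))
  # mask: (1,1) maj, (3,2) maj, (2,3) het, (2,4) min
  mask <- rbind(c(1L, 1L), c(3L, 2L), c(2L, 3L), c(2L, 4L))
  imputed <- orig
  imputed[3, 2] <- 3L       # maj imputed as min: mismatch
  acc <- imputation_accuracy(orig, mask, imputed)
  expect_equal(acc$m_pct, 75)
  expect_equal(acc$maj_pct, 25)
  expect_equal(acc$het_pct, 25)
  expect_equal(acc$aa_pct, 25)
  expect_equal(acc$denominator, 4L)

  perfect <- imputation_accuracy(orig, mask, orig)
  expect_equal(perfect$m_pct, 100)
  wrong <- orig
  wrong[1, 1] <- 2L; wrong[3, 2] <- 2L; wrong[2, 3] <- 1L; wrong[2, 4] <- 1L
  none <- imputation_accuracy(orig, mask, wrong)
  expect_equal(none$m_pct, 0)
  expect_equal(none$aa_pct + none$het_pct + none$maj_pct, 0)
})

test_that("accuracy classes always sum to the match percentage", {
  withr::with_seed(51, {
    for (rep in 1:10) {
      g <- rand_geno(15, 12)
      masked <- apply_random_missing(g, 0.3)
      imp <- impute_nipals(masked$genotypes, n_pcs = 1)
      acc <- imputation_accuracy(g, masked$mask, imp$imputed)
      expect_equal(acc$aa_pct + acc$het_pct + acc$maj_pct, acc$m_pct,
                   tolerance = 1e-9)
    }
  })
})

test_that("masked cells whose original is itself missing are excluded", {
  g <- genotype_matrix(rbind(c(1L, NA), c(3L, 2L)))
  mask <- rbind(c(1L, 1L), c(1L, 2L))
  acc <- imputation_accuracy(g, mask, genotype_matrix(rbind(c(1L, 2L),
                                                            c(3L, 2L))))
  expect_equal(acc$denominator, 1L)
  expect_equal(acc$m_pct, 100)
})

test_that("a zero missing level reproduces the original statistics exactly", {
  pop <- generate_population(synthetic_config(
    n_groups = 4, lines_per_group = 15, n_markers = 300, seed = 52))
  at <- run_assessment(pop$genotypes, pop$groups, assessment_config(
    missing_levels = 0, n_runs = 3, n_lines = 20, n_markers = 100,
    methods = "NONE", seed = 53))
  s <- at$summary
  none <- s[s$method == "NONE", ]
  orig <- s[s$method == "ORIGINAL", ]
  expect_equal(none$ho_mean, orig$ho_mean)
  expect_equal(none$he_mean, orig$he_mean)
  expect_equal(none$phi_st_mean, orig$phi_st_mean)
  expect_equal(none$topology_accuracy, 100)
  expect_equal(none$he_bias_mean, 0)
})

test_that("the assessment loop is deterministic in its master seed", {
  pop <- generate_population(synthetic_config(
    n_groups = 2, lines_per_group = 10, n_markers = 120, seed = 54))
  cfg <- assessment_config(missing_levels = c(0.2, 0.6), n_runs = 2,
                           n_lines = 12, n_markers = 60,
                           methods = c("NONE", "NI"), seed = 55)
  a1 <- run_assessment(pop$genotypes, pop$groups, cfg)
  a2 <- run_assessment(pop$genotypes, pop$groups, cfg)
  expect_identical(a1$per_run, a2$per_run)
  expect_equal(nrow(a1$failures), 0L)
})

test_that("expected heterozygosity declines with missing level while Phi-ST is stable", {
  pop <- generate_population(synthetic_config(
    n_groups = 4, lines_per_group = 40, n_markers = 1500, fst_target = 0.05,
    f_is = 0.98, seed = 56))
  cfg <- assessment_config(missing_levels = c(0.1, 0.5, 0.9), n_runs = 40,
                           n_lines = 60, n_markers = 300, methods = "NONE",
                           seed = 57)
  at <- run_assessment(pop$genotypes, pop$groups, cfg)
  s <- at$summary[at$summary$method == "NONE", ]
  s <- s[order(s$missing_level), ]
  expect_true(all(diff(s$he_mean) < 0))
  # Phi-ST level-invariance: ends differ by < 2 pooled standard errors
  se_pool <- sqrt(s$phi_st_sd[1]^2 / s$n_runs[1] +
                  s$phi_st_sd[3]^2 / s$n_runs[3])
  expect_lt(abs(s$phi_st_mean[3] - s$phi_st_mean[1]), 2 * se_pool)
  # topology accuracy non-increasing up to Monte-Carlo slack
  expect_lte(s$topology_accuracy[2], s$topology_accuracy[1] + 5)
  expect_lte(s$topology_accuracy[3], s$topology_accuracy[2] + 5)
})

test_that("imputation inflates observed heterozygosity in inbred data", {
  pop <- generate_population(crop_preset("rice", lines_per_group = 40,
                                         n_markers = 1000, seed = 58))
  cfg <- assessment_config(missing_levels = 0.5, n_runs = 4, n_lines = 40,
                           n_markers = 200, methods = c("NONE", "PP", "NI"),
                           seed = 59)
  at <- run_assessment(pop$genotypes, pop$groups, cfg)
  s <- at$summary
  ho <- function(m) s$ho_mean[s$method == m]
  f <- function(m) s$f_mean[s$method == m]
  expect_gt(ho("PP"), ho("NONE"))
  expect_gt(ho("NI"), ho("NONE"))
  expect_lt(f("PP"), f("NONE"))    # inbreeding biased downward by imputation
  expect_lt(f("NI"), f("NONE"))
})
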