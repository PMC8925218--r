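# Summary tables, correlation matrices, paired Wilcoxon comparisons.

make_records <- function(n_subjects = 6, seed = 101,
                         eta_mult = 20.37 / 43.9, noise = 0.05) {
  # lightweight cohort records straight from sampled parameters (no
  # simulation), for statistics-layer tests
  set.seed(seed)
  coh <- sample_cohort(cohort_config(n_subjects = n_subjects), seed = seed)
  data.frame(subject_id = coh$subject_id, side = coh$side,
             condition = coh$condition, age = coh$age, bmi = coh$bmi,
             primary_thickness = coh$h0_true,
             peak_strain = coh$peak_strain_true,
             peak_stress = coh$E_true * coh$peak_strain_true,
             elastic_modulus = coh$E_true,
             viscous_modulus = coh$eta_true,
             edr = 100 * coh$eta_true / (coh$eta_true + coh$E_true),
             stringsAsFactors = FALSE)
}

test_that("summary cells hold median and min-max range", {
  rec <- make_records(2)
  rec3 <- rec[rec$condition == "time_zero", ][1:3, ]
  rec3$primary_thickness <- c(9.60, 15.40, 16.73)
  s <- summarize_cohort(rec3)
  cell <- s[s$property == "primary_thickness" & s$side == "combined" &
              s$condition == "time_zero", ]
  expect_equal(cell$median, 15.40)
  expect_equal(cell$min, 9.60)
  expect_equal(cell$max, 16.73)
  # single record: median = min = max
  s1 <- summarize_cohort(rec3[1, ])
  c1 <- s1[s1$property == "edr" & s1$side == "combined" &
             s1$condition == "time_zero", ]
  expect_equal(c1$median, c1$min)
  expect_equal(c1$median, c1$max)
  # even count: mean of the middle two
  rec4 <- rec[rec$condition == "time_zero", ][1:4, ]
  rec4$edr <- c(1, 2, 3, 4)
  s4 <- summarize_cohort(rec4)
  expect_equal(s4[s4$property == "edr" & s4$side == "combined" &
                    s4$condition == "time_zero", "median"], 2.5)
  # absent cells are flagged by n = 0 with NA statistics, not zeros
  post <- s4[s4$property == "edr" & s4$side == "combined" &
               s4$condition == "post_loading", ]
  expect_identical(post$n, 0L)
  expect_true(is.na(post$median))
  expect_error(summarize_cohort(rec[0, ]), class = "empty_input_error")
})

test_that("summary medians are invariant to record order", {
  rec <- make_records(5)
  s1 <- summarize_cohort(rec)
  s2 <- summarize_cohort(rec[rev(seq_len(nrow(rec))), ])
  expect_equal(s1, s2)
})

test_that("pearson matrix matches hand computations and is symmetric", {
  rec <- make_records(4)
  tz <- rec[rec$condition == "time_zero", ]
  # exact linear relation
  tz$edr <- 2 * tz$age + 3
  pm <- pearson_matrix(tz, variables = c("age", "edr", "elastic_modulus"))
  expect_equal(pm$r["age", "edr"], 1)
  # hand oracle: x = (1,2,3), y = (6,4,5) -> r = -0.5
  small <- tz[1:3, ]
  small$age <- c(1, 2, 3); small$bmi <- c(6, 4, 5)
  pm2 <- pearson_matrix(small, variables = c("age", "bmi"))
  expect_equal(pm2$r["age", "bmi"], -0.5)
  # symmetry, unit diagonal, bounded entries
  pm3 <- pearson_matrix(rec, condition = "time_zero")
  expect_equal(pm3$r, t(pm3$r))
  expect_equal(unname(diag(pm3$r)), rep(1, ncol(pm3$r)))
  expect_true(all(abs(pm3$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(pm3$p, t(pm3$p))
})

test_that("constant variables are flagged, small cohorts are rejected", {
  rec <- make_records(3)
  tz <- rec[rec$condition == "time_zero", ]
  tz$bmi <- 25
  pm <- pearson_matrix(tz, variables = c("age", "bmi", "edr"))
  expect_identical(pm$flagged_constant, "bmi")
  expect_true(is.na(pm$r["age", "bmi"]))
  expect_false(is.na(pm$r["age", "edr"]))
  expect_error(pearson_matrix(rec[1:2, ], condition = "time_zero"),
               class = "insufficient_data_error")
})

test_that("pearson r transforms correctly under affine maps", {
  rec <- make_records(8)
  tz <- rec[rec$condition == "time_zero", ]
  r0 <- pearson_matrix(tz)$r["age", "viscous_modulus"]
  tz2 <- tz; tz2$viscous_modulus <- 3 * tz2$viscous_modulus + 7
  expect_equal(pearson_matrix(tz2)$r["age", "viscous_modulus"], r0,
               tolerance = 1e-12)
  tz3 <- tz; tz3$viscous_modulus <- -2 * tz3$viscous_modulus + 1
  expect_equal(pearson_matrix(tz3)$r["age", "viscous_modulus"], -r0,
               tolerance = 1e-12)
})

test_that("paired Wilcoxon exact p-values match known enumerations", {
  # n = 5, all differences positive, distinct magnitudes: p = 2/32
  res5 <- paired_wilcoxon(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(res5$p_value, 0.0625)
  expect_true(res5$exact)
  expect_identical(res5$n_effective, 5L)
  # n = 6: p = 2/64
  res6 <- paired_wilcoxon(rep(0, 6), c(1, 2.5, 3, 4.2, 5, 6))
  expect_equal(res6$p_value, 0.03125)
  # all ties
  expect_error(paired_wilcoxon(1:4, 1:4), class = "all_ties_error")
  # zero differences are dropped from n_effective
  res <- paired_wilcoxon(c(1, 2, 3, 4, 5, 9), c(2, 4, 6, 8, 10, 9))
  expect_identical(res$n_effective, 5L)
  expect_equal(res$p_value, 0.0625)
})

test_that("exact Wilcoxon equals full 2^n enumeration for n <= 12", {
  set.seed(77)
  for (n in 3:12) {
    for (rep in 1:3) {
      pre <- rnorm(n)
      post <- pre + rnorm(n, 0.3, 1)
      d <- post - pre
      if (any(d == 0) || anyDuplicated(abs(d))) next
      res <- paired_wilcoxon(pre, post)
      expect_true(res$exact)
      expect_equal(res$p_value, oracle_wilcoxon_enumeration(d),
                   tolerance = 1e-12, label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("pairing by ids aligns records before differencing", {
  pre <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  post_shuffled <- c(9, 2, 7, 4, 5) # e, a(+1), d, b(+2), c(+2) order
  res <- paired_wilcoxon(pre, post_shuffled,
                         ids = list(pre = c("a", "b", "c", "d", "e"),
                                    post = c("e", "a", "d", "b", "c")))
  expect_equal(res$p_value,
               paired_wilcoxon(unname(pre), c(2, 4, 5, 7, 9))$p_value)
})

test_that("condition comparison finds the viscous drop and spares the elastic modulus", {
  rec <- analyzed_cohort(cohort_config(), gait_config(), seed = 1)
  cmp <- compare_conditions(rec)
  expect_lt(cmp$p_value[cmp$property == "viscous_modulus"], 0.001)
  expect_gt(cmp$p_value[cmp$property == "elastic_modulus"], 0.05)
  expect_lt(cmp$median_post_loading[cmp$property == "viscous_modulus"],
            0.6 * cmp$median_time_zero[cmp$property == "viscous_modulus"])
  std <- attr(cmp, "standardized")
  expect_true(all(abs(tapply(std$z, std$property, mean)) < 1e-10))
})

test_that("degenerate comparisons: identical conditions and single heels", {
  rec <- make_records(3)
  tz <- rec[rec$condition == "time_zero", ]
  dup <- tz; dup$condition <- "post_loading"
  cmp <- compare_conditions(rbind(tz, dup))
  expect_true(all(cmp$p_value == 1))
  one <- rec[rec$subject_id == "S01" & rec$side == "left", ]
  expect_error(compare_conditions(one), class = "insufficient_data_error")
})
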