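test_that("to_rra averages replicates then normalises", {
  cnt <- rbind(A = c(S1_r1 = 30, S1_r2 = 50, B1 = 5),
               B = c(70, 50, 0))
  sheet <- data.frame(occurrence_id = c("S1_r1", "S1_r2", "B1"),
                      sample_id = c("S1", "S1", "B1"),
                      replicate = c(1L, 2L, 1L),
                      role = c("sample", "sample", "extraction_blank"))
  rra <- to_rra(occurrence_table(cnt, sheet))
  expect_equal(unname(rra["S1", ]), c(0.4, 0.6)) # means (40, 60) / 100
  expect_equal(unname(rowSums(rra)), 1)

  # single-taxon sample
  rra1 <- to_rra(occurrence_table(cnt[1, , drop = FALSE], sheet))
  expect_equal(unname(rra1[1, 1]), 1)

  # zero-total sample dropped with a warning
  cnt0 <- cnt; cnt0[, 1:2] <- 0
  expect_warning(r0 <- to_rra(occurrence_table(cnt0, sheet)), "zero reads")
  expect_equal(nrow(r0), 0)
})

test_that("morphotype mapping sums columns and preserves row sums", {
  rra <- matrix(c(0.6, 0.1, 0.3,
                  0.2, 0.5, 0.3), 2, 3, byrow = TRUE,
                dimnames = list(c("S1", "S2"),
                                c("Taxus baccata", "Chamaecyparis",
                                  "Urtica dioica")))
  map <- data.frame(taxon = c("Taxus baccata", "Chamaecyparis", "Urtica dioica"),
                    morphotype = c("Cupressaceae-type", "Cupressaceae-type",
                                   "Urticaceae"))
  out <- map_to_morphotypes(rra, map)
  expect_equal(out["S1", "Cupressaceae-type"], 0.7)
  expect_equal(rowSums(out), rowSums(rra))

  # identity map leaves values unchanged
  idm <- data.frame(taxon = colnames(rra), morphotype = colnames(rra))
  out_id <- map_to_morphotypes(rra, idm)
  expect_equal(out_id[, colnames(rra)], rra)

  # non-total map is rejected
  expect_error(map_to_morphotypes(rra, map[1:2, ]), "not total")
})

test_that("least_squares_fit matches the closed-form normal equations", {
  x <- c(0.1, 0.2, 0.4); y <- c(0.15, 0.22, 0.41)
  f <- least_squares_fit(x, y)
  # hand-computed normal equations
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  expect_equal(f$slope, sl, tolerance = 1e-12)
  expect_equal(f$intercept, ic, tolerance = 1e-12)
  r2 <- 1 - sum((y - ic - sl * x)^2) / sum((y - mean(y))^2)
  expect_equal(f$r_squared, r2, tolerance = 1e-12)

  ident <- least_squares_fit(seq(0, 1, length.out = 10),
                             seq(0, 1, length.out = 10))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r_squared, 1)

  const <- least_squares_fit(1:10, rep(2, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)

  expect_error(least_squares_fit(rep(1, 5), 1:5), "zero variance")
  expect_error(least_squares_fit(1:2, 1:2), "3 points")

  # property: agreement with normal equations on random inputs
  with_seed_helper(61, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      x <- runif(n); y <- 0.7 * x + rnorm(n, sd = 0.1)
      f <- least_squares_fit(x, y)
      sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
      expect_equal(f$slope, sl, tolerance = 1e-10)
    }
  })
})

test_that("slope recovery is calibrated at the 95% CI level", {
  with_seed_helper(71, {
    hits <- vapply(1:300, function(i) {
      x <- runif(20, 0, 0.5)
      beta <- 0.8
      y <- beta * x + rnorm(20, sd = 0.05)
      fit <- lm(y ~ x)
      ci <- confint(fit, "x", level = 0.95)
      ci[1] <= beta && beta <= ci[2]
    }, logical(1))
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("the combined regression applies the >5% microscope filter", {
  # two samples, two morphotypes; mt2 sits below 5% in sample S2
  rra <- matrix(c(0.90, 0.10,
                  0.97, 0.03), 2, 2, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("mt1", "mt2")))
  micro <- data.frame(sample_id = rep(c("S1", "S2"), each = 2),
                      morphotype = rep(c("mt1", "mt2"), 2),
                      concentration = c(450, 50, 480, 20)) # 10% and 4%
  map <- data.frame(taxon = c("mt1", "mt2"), morphotype = c("mt1", "mt2"))
  rep_ <- quantification_report(list(m = rra), micro, map,
                                targets = c("mt1", "mt2"))
  comb <- rep_[rep_$target == "combined", ]
  # points: mt1 in S1+S2, mt2 only in S1 (S2 microscope share 4% < 5%)
  expect_equal(comb$n, 3)
})

test_that("quantification recovers truth in the unbiased limit", {
  qs <- quick_sim(seed = 9, depth_mean = 5e4, error_rate = 0,
                  leakage_rate = 0, contam_prob = 0, nontarget_prob = 0,
                  grains_counted = 5000, theta_sample = 30,
                  markers = list(m0 = marker_params(
                    "m0", "GGGCAATCCTGAGCCAA", "CCATTGAGTCTCTGCACCTATC",
                    8, 100, bias_sd = 0, seq_length = 80)))
  tab <- sim_occ_table(qs, "m0")
  rra <- to_rra(tab)
  rep_ <- quantification_report(list(m0 = rra), qs$sim$microscope,
                                qs$sim$morphotype_map)
  comb <- rep_[rep_$target == "combined", ]
  expect_lt(abs(comb$slope - 1), 0.05)
  expect_gt(comb$r_squared, 0.98)
})
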