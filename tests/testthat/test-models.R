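test_that("GM volume normalization is the TIV ratio with guarded domain", {
  expect_equal(normalize_gm_volume(600000, 1500000), 0.4)
  x <- c(1e5, 7e5, 1.2e6)
  expect_equal(normalize_gm_volume(x, 2 * x), rep(0.5, 3))
  expect_error(normalize_gm_volume(10, 10), "smaller")
  expect_error(normalize_gm_volume(-1, 10), "positive")
})

test_that("motion exclusion removes only subjects strictly above threshold", {
  set.seed(2)
  subj <- data.frame(subject_id = sprintf("s%03d", 1:301),
                     max_displacement = runif(301, 0.1, 2.0))
  subj$max_displacement[sample(301, 7)] <- runif(7, 2.6, 5)
  expect_equal(nrow(exclude_by_motion(subj)), 294L)

  at_threshold <- data.frame(max_displacement = c(2.5, 2.5000001, 1))
  kept <- exclude_by_motion(at_threshold)
  expect_equal(kept$max_displacement, c(2.5, 1))

  all_low <- data.frame(max_displacement = rep(1, 10))
  expect_equal(nrow(exclude_by_motion(all_low)), 10L)
  expect_error(exclude_by_motion(data.frame(x = 1)), "max_displacement")
  expect_error(exclude_by_motion(data.frame(max_displacement = c(1, NA))),
               "missing")
})

make_records <- function(n, betas, noise_sd, seed, bfr = NULL, age = NULL) {
  set.seed(seed)
  if (is.null(age)) age <- runif(n, 18, 89)
  bc <- 2.9 - 0.008 * (age - 18) + rnorm(n, sd = 0.08)
  if (is.null(bfr)) bfr <- runif(n, 0.05, 0.95)
  site <- rbinom(n, 1, .5); sex <- rbinom(n, 1, .5)
  y <- gen_moderated_outcome(bc, bfr, site, sex, betas, noise_sd,
                             seed = seed + 1)
  data.frame(cortical_thickness = bc, bfr = bfr, site = site, sex = sex,
             age = age, PC1 = y)
}

test_that("moderation fit recovers exact coefficients without noise", {
  betas <- c(14.39, -0.03, -0.15, -0.74, 1.02, 0)
  rec <- make_records(60, betas, noise_sd = 0, seed = 4)
  fit <- fit_moderation(rec, "thickness")
  ct <- fit$coefficients$PC1
  got <- setNames(ct$beta, ct$predictor)
  expect_equal(unname(got["cortical_thickness"]), betas[1], tolerance = 1e-8)
  expect_equal(unname(got["bfr"]), betas[2], tolerance = 1e-8)
  expect_equal(unname(got["cortical_thickness:bfr"]), betas[3],
               tolerance = 1e-8)
  expect_equal(unname(got["site"]), betas[4], tolerance = 1e-8)
  expect_equal(unname(got["sex"]), betas[5], tolerance = 1e-8)
  expect_false(fit$include_chron_age)
})

test_that("residuals are orthogonal to every design column", {
  rec <- make_records(120, c(2, -1, -0.5, 0.3, 0.4, 1), noise_sd = 1.2,
                      seed = 6)
  fit <- fit_moderation(rec, "thickness")
  mm <- model.matrix(fit$lm_fit)
  mm_std <- scale(mm[, -1])
  res <- residuals(fit)
  expect_lt(max(abs(crossprod(mm_std, scale(res, scale = FALSE)))) /
              nrow(mm), 1e-8)
})

test_that("coefficients are unbiased across synthetic replicates", {
  betas <- c(14.39, -0.03, -0.15, -0.74, 1.02, 0)
  ests <- vapply(1:120, function(r) {
    rec <- make_records(260, betas, noise_sd = 1.71, seed = 1000 + r)
    ct <- fit_moderation(rec, "thickness")$coefficients$PC1
    ct$beta[ct$predictor == "cortical_thickness:bfr"]
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - betas[3]), 3.5 * mc_se)
})

test_that("adding chronological age attenuates an age-confounded BFR effect", {
  # age drives both BFR and the outcome directly; with age omitted the BFR
  # coefficient absorbs the shared age signal, with age included it shrinks
  set.seed(77)
  n <- 400
  age <- runif(n, 18, 89)
  bfr <- pmin(pmax(0.9 - 0.008 * age + rnorm(n, sd = 0.05), 0), 1)
  rec <- make_records(n, c(1, -0.5, 0, 0.2, 0.1, 0), noise_sd = 0.5,
                      seed = 78, bfr = bfr, age = age)
  rec$PC1 <- rec$PC1 - 0.05 * age
  fit_no_age <- fit_moderation(rec, "thickness", include_chron_age = FALSE)
  fit_age <- fit_moderation(rec, "thickness", include_chron_age = TRUE)
  b_no <- with(fit_no_age$coefficients$PC1, beta[predictor == "bfr"])
  b_yes <- with(fit_age$coefficients$PC1, beta[predictor == "bfr"])
  expect_lt(abs(b_yes), abs(b_no))
  expect_true(fit_age$include_chron_age)
})

test_that("degenerate designs are rejected", {
  rec <- make_records(40, rep(0, 6), noise_sd = 1, seed = 10)
  rec$bfr <- rec$cortical_thickness   # collinear with the brain change
  expect_error(fit_moderation(rec, "thickness"), "collinear")
  small <- make_records(12, rep(0, 6), noise_sd = 1, seed = 11)
  expect_error(fit_moderation(small, "thickness"), "insufficient")
  expect_error(fit_moderation(make_records(40, rep(0, 6), 1, 12),
                              "gm_volume"), "missing column")
})

test_that("multi-outcome fits match per-outcome OLS", {
  rec <- make_records(100, c(2, -1, -0.5, 0.3, 0.4, 1), noise_sd = 1,
                      seed = 13)
  set.seed(14)
  rec$PC2 <- rnorm(100)
  fit <- fit_moderation(rec, "thickness")
  expect_equal(fit$outcomes, c("PC1", "PC2"))
  single <- lm(PC2 ~ cortical_thickness + bfr + cortical_thickness:bfr +
                 site + sex, data = rec)
  expect_equal(fit$coefficients$PC2$beta, unname(coef(single)),
               tolerance = 1e-10)
  expect_equal(dim(fit$residual_covariance), c(2L, 2L))
})

test_that("mean split assigns the boundary to the high group and partitions", {
  g <- mean_split(c(1, 2, 3))
  expect_equal(as.character(g), c("low", "high", "high"))
  expect_equal(as.character(mean_split(rep(4, 5))), rep("high", 5))
  set.seed(15)
  v <- rnorm(50)
  g2 <- mean_split(v)
  expect_equal(sum(g2 == "low") + sum(g2 == "high"), 50L)
  expect_lt(mean(v[g2 == "low"]), mean(v))
  expect_gt(mean(v[g2 == "high"]), mean(v))
})

test_that("threshold split reports groups and per-group slopes", {
  sp <- threshold_split(c(0.1, 0.29, 0.30, 0.9), cut = 0.30)
  expect_equal(sp$n_low, 2L)
  expect_equal(sp$n_high, 2L)
  expect_error(threshold_split(c(0.1, 0.5), cut = 0), "strictly between")
  expect_error(threshold_split(c(-0.1, 0.5)), "\\[0, 1\\]")

  # negative interaction -> steeper brain-change slope in the low-BFR group
  set.seed(16)
  n <- 300
  bc <- rnorm(n, 2.5, 0.4)
  bfr <- runif(n)
  y <- gen_moderated_outcome(bc, bfr, rep(0, n), rep(0, n),
                             betas = c(3, 0, -2.5, 0, 0, 0), noise_sd = 0.3)
  sp2 <- threshold_split(bfr, 0.5, outcome = y, bc = bc)
  expect_gt(sp2$slope_low, sp2$slope_high)
  expect_equal(sp2$n_low + sp2$n_high, n)
})
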