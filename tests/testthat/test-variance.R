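# Balanced nested ANOVA method-of-moments oracle for a single-organ,
# single-angle table: pigs / images-within-pigs / repetitions.
nested_anova_oracle <- function(df) {
  a <- length(unique(df$pig_id))
  b <- length(unique(df$position_id)) / a
  n <- nrow(df) / (a * b)
  gm <- mean(df$value)
  pig_means <- tapply(df$value, df$pig_id, mean)
  img_means <- tapply(df$value, df$position_id, mean)
  img_pig <- tapply(df$pig_id, df$position_id, function(p) unique(p))
  ms_pig <- b * n * sum((pig_means - gm)^2) / (a - 1)
  ms_img <- n * sum((img_means - pig_means[img_pig])^2) / (a * (b - 1))
  ss_rep <- sum((df$value - img_means[df$position_id])^2)
  ms_rep <- ss_rep / (a * b * (n - 1))
  c(pig = (ms_pig - ms_img) / (b * n), image = (ms_img - ms_rep) / n,
    repetition = ms_rep)
}

test_that("REML variance components match the balanced-ANOVA closed form", {
  grid <- coarse_grid(2)
  lib <- make_fingerprint_library(porcine_organs()[1:2], seed = 21, grid = grid)
  design <- make_standardized_design(6, "stomach", 4)
  design <- design[design$angle == "perpendicular", ] # pure nested layout
  comps <- generative_components(4e-4, 2e-4, 1e-4)
  sp <- simulate_spectra(design, lib, comps, seed = 22)
  df <- data.frame(value = sp$b500, pig_id = sp$pig_id,
                   position_id = sp$position_id, organ = sp$organ,
                   angle = sp$angle, repetition = sp$repetition)
  oracle <- nested_anova_oracle(df)
  skip_if(any(oracle < 0)) # oracle only valid in the interior
  lmm <- fit_reflectance_lmm(df, include_organ = FALSE)
  vc <- as.data.frame(lme4::VarCorr(lmm$fit))
  got <- c(pig = vc$vcov[vc$grp == "pig_id"],
           image = vc$vcov[vc$grp == "position_id"],
           repetition = vc$vcov[vc$grp == "Residual"])
  expect_equal(got, oracle, tolerance = 1e-5)
})

test_that("pure-residual data yields near-zero fixed effects and sigma ~ 1", {
  grid <- coarse_grid(2)
  lib0 <- make_fingerprint_library(porcine_organs()[1:3], seed = 23, grid = grid)
  # erase organ differences: every organ gets the same flat fingerprint
  cols <- spectra_band_columns(lib0)
  for (cc in cols) lib0[[cc]] <- 1 / length(cols)
  design <- make_standardized_design(8, porcine_organs()[1:3], 2)
  comps <- generative_components(0, 0, 1)
  sp <- simulate_spectra(design, lib0, comps, seed = 24)
  df <- data.frame(value = sp$b500, pig_id = sp$pig_id,
                   position_id = sp$position_id, organ = sp$organ,
                   angle = sp$angle, repetition = sp$repetition)
  lmm <- fit_reflectance_lmm(df)
  fe <- lme4::fixef(lmm$fit)
  n_per_level <- nrow(df) / 3
  se3 <- 3 * sqrt(2 / n_per_level) # ~3 SE of a mean difference at sigma = 1
  expect_true(all(abs(fe[-1]) < se3))
  vc <- as.data.frame(lme4::VarCorr(lmm$fit))
  sigma_rep <- vc$vcov[vc$grp == "Residual"]
  expect_lt(abs(sigma_rep - 1), 3 * sqrt(2 / nrow(df)))
})

test_that("decomposition recovers analytic proportions of the generative model", {
  # organ-term variance 3x each noise component -> (0.5, 0, 1/6, 1/6, 1/6)
  grid <- coarse_grid(6)
  lib <- make_fingerprint_library(porcine_organs()[1:10], seed = 25, grid = grid)
  design <- make_standardized_design(10, porcine_organs()[1:10], 2)
  v_org <- organspectra:::analytic_organ_term_variance(lib, design)
  s <- mean(v_org) / 3
  comps <- generative_components(s, s, s)
  sp <- simulate_spectra(design, lib, comps, seed = 26)
  dec <- decompose_variance(sp)
  med <- attr(dec, "medians")
  truth_tbl <- analytic_variance_proportions(lib, design, comps)
  truth <- tapply(truth_tbl$proportion, truth_tbl$factor, median)
  for (f in med$factor) {
    expect_lt(abs(med$median[med$factor == f] - truth[[f]]), 0.05)
  }
  # proportions lie in [0,1] and sum to 1 per wavelength
  expect_true(all(dec$estimate >= 0 & dec$estimate <= 1))
  sums <- tapply(dec$estimate, dec$wavelength, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("single-source and orthogonality limits behave as expected", {
  grid <- coarse_grid(2)
  lib <- make_fingerprint_library(porcine_organs()[1:4], seed = 27, grid = grid)
  design <- make_standardized_design(4, porcine_organs()[1:4], 2)
  # organ-only variation (tiny numerical floor for the residual)
  comps <- generative_components(0, 0, 1e-12)
  sp <- simulate_spectra(design, lib, comps, seed = 28)
  dec <- decompose_variance(sp)
  organ_share <- dec$estimate[dec$factor == "organ"]
  expect_true(all(organ_share > 0.999))
  # balanced design: organ/angle fixed terms are orthogonal, so the
  # cross-covariance term the decomposition splits is essentially zero
  comps2 <- generative_components(1e-5, 1e-5, 1e-5,
                                  theta = c(side_a_25deg = 0.01, side_b_25deg = -0.01))
  sp2 <- simulate_spectra(design, lib, comps2, seed = 29)
  df <- data.frame(value = sp2$b500, pig_id = sp2$pig_id,
                   position_id = sp2$position_id, organ = sp2$organ,
                   angle = sp2$angle, repetition = sp2$repetition)
  lmm <- fit_reflectance_lmm(df)
  X <- model.matrix(lmm$fit)
  beta <- lme4::fixef(lmm$fit)
  o <- X[, grepl("^organ", colnames(X))] %*% beta[grepl("^organ", names(beta))]
  a <- X[, grepl("^angle", colnames(X))] %*% beta[grepl("^angle", names(beta))]
  expect_lt(abs(mean((o - mean(o)) * (a - mean(a)))), 1e-12)
})

test_that("stratified decomposition returns the component SDs", {
  grid <- coarse_grid(2)
  lib <- make_fingerprint_library(porcine_organs()[1:2], seed = 30, grid = grid)
  design <- make_standardized_design(25, "jejunum", 3)
  # sigma_pig^2 = 0.04 -> explained pig SD ~ 0.2
  comps <- generative_components(0.04, 1e-4, 1e-4)
  sp <- simulate_spectra(design, lib, comps, seed = 31)
  dec <- decompose_variance_stratified(sp, wavelengths = 500)
  get <- function(f) dec$estimate[dec$factor == f]
  expect_lt(abs(get("pig") - 0.2), 0.06)
  expect_lt(get("angle"), 0.005) # theta = 0 generative
  # all components zero except repetition: only the residual SD is material
  comps2 <- generative_components(0, 0, 2.5e-5)
  sp2 <- simulate_spectra(design, lib, comps2, seed = 32)
  dec2 <- decompose_variance_stratified(sp2, wavelengths = 500)
  get2 <- function(f) dec2$estimate[dec2$factor == f]
  expect_equal(get2("repetition"), 0.005, tolerance = 0.2)
  expect_lt(get2("pig"), 0.002)
  expect_lt(get2("image"), 0.002)
  expect_error(decompose_variance_stratified(sp[sp$pig_id == "P01", ]),
               "fewer than 2 pigs")
})

test_that("median across wavelengths equals a sort-based oracle", {
  dec <- tibble::tibble(
    wavelength = rep(c(500, 505, 510), 2),
    factor = rep(c("organ", "pig"), each = 3),
    estimate = c(0.8, 0.8, 0.8, 0.1, 0.3, 0.9)
  )
  class(dec) <- c("variance_decomposition", class(dec))
  med <- median_across_wavelengths(dec)
  expect_equal(med$median[med$factor == "organ"], 0.8)
  expect_equal(med$median[med$factor == "pig"], 0.3)
  set.seed(33)
  vals <- runif(11)
  dec2 <- tibble::tibble(wavelength = seq_along(vals), factor = "organ",
                         estimate = vals)
  class(dec2) <- c("variance_decomposition", class(dec2))
  expect_equal(median_across_wavelengths(dec2)$median,
               sort(vals)[6]) # brute-force middle element
})

test_that("bootstrap bands are seeded, contain the estimate, and smoke at B=2", {
  grid <- coarse_grid(2)
  lib <- make_fingerprint_library(porcine_organs()[1:3], seed = 34, grid = grid)
  design <- make_standardized_design(4, porcine_organs()[1:3], 2)
  comps <- calibrate_components(lib, design, organ_share = 0.6)
  sp <- simulate_spectra(design, lib, comps, seed = 35)
  b2 <- decompose_variance(sp, wavelengths = 500, bootstrap = 2, seed = 9)
  expect_true(all(b2$ci_lo <= b2$estimate & b2$estimate <= b2$ci_hi))
  a <- decompose_variance(sp, wavelengths = 500, bootstrap = 25, seed = 9)
  b <- decompose_variance(sp, wavelengths = 500, bootstrap = 25, seed = 9)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_error(decompose_variance(sp, bootstrap = 10), "seed")
})

test_that("pig share is monotone in sigma_pig and invariant to scaling", {
  grid <- coarse_grid(2)
  lib <- make_fingerprint_library(porcine_organs()[1:4], seed = 36, grid = grid)
  design <- make_standardized_design(8, porcine_organs()[1:4], 2)
  base_v <- mean(organspectra:::analytic_organ_term_variance(lib, design))
  shares <- vapply(c(0.25, 1, 4), function(mult) {
    comps <- generative_components(base_v * mult, base_v / 4, base_v / 4)
    sp <- simulate_spectra(design, lib, comps, seed = 37)
    med <- attr(decompose_variance(sp), "medians")
    med$median[med$factor == "pig"]
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  # scale equivariance: multiplying all responses by c > 0 changes nothing
  comps <- generative_components(base_v, base_v / 4, base_v / 4)
  sp <- simulate_spectra(design, lib, comps, seed = 38)
  sp_scaled <- sp
  cols <- spectra_band_columns(sp)
  sp_scaled[cols] <- sp_scaled[cols] * 532.1
  d1 <- decompose_variance(sp)
  d2 <- decompose_variance(sp_scaled)
  expect_equal(d1$estimate, d2$estimate, tolerance = 1e-6)
})

test_that("single-organ tables drop the organ term instead of failing", {
  grid <- coarse_grid(2)
  lib <- make_fingerprint_library(porcine_organs()[1:2], seed = 39, grid = grid)
  design <- make_standardized_design(3, "stomach", 2)
  sp <- simulate_spectra(design, lib, generative_components(1e-5, 1e-5, 1e-5),
                         seed = 40)
  df <- data.frame(value = sp$b500, pig_id = sp$pig_id,
                   position_id = sp$position_id, organ = sp$organ,
                   angle = sp$angle, repetition = sp$repetition)
  lmm <- fit_reflectance_lmm(df, include_organ = TRUE)
  expect_false(any(grepl("^organ", names(lme4::fixef(lmm$fit)))))
  # non-nested grouping rejected
  df_bad <- df
  df_bad$position_id <- rep_len(c("shared1", "shared2"), nrow(df_bad))
  expect_error(fit_reflectance_lmm(df_bad), "nested")
})
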