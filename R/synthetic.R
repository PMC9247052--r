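#' Synthetic organ fingerprint library
#'
#' Draws one smooth spectral fingerprint per organ: a smooth quadratic
#' baseline, one to three negative Gaussian "absorption" dips with centres
#' between 520 and 600 nm (haemoglobin-like), and a logistic rise across
#' 600-750 nm (the near-infrared rise seen in tissue reflectance). Each
#' fingerprint is l1-normalized. Parameters are drawn per organ from seeded
#' distributions, so distinct organs differ and the same seed reproduces the
#' same library.
#'
#' @param organs Character vector of organ labels (default the 20-class
#'   vocabulary), or a single integer number of organs.
#' @param seed Integer seed.
#' @param grid Wavelength grid to evaluate fingerprints on.
#' @param min_separation Minimum required mean pairwise l1 distance between
#'   fingerprints; generation errors if the drawn library falls below it.
#' @param max_step Maximum allowed absolute first difference of a
#'   fingerprint (smoothness bound). The default `1 / n_bands` scales with
#'   the band count: unit-l1 fingerprints have mean level `1 / n_bands`, so
#'   the bound caps the change per step at that level.
#' @return A tibble of class `fingerprint_library` with columns `organ` and
#'   one `b<wavelength>` column per band; attributes `grid` and `seed`.
#' @export
make_fingerprint_library <- function(organs = porcine_organs(), seed = 1L,
                                     grid = make_wavelength_grid(),
                                     min_separation = 0.02, max_step = NULL) {
  if (is.null(max_step)) max_step <- 1 / grid$n_bands
  if (is.numeric(organs) && length(organs) == 1L) {
    if (organs > length(porcine_organs())) {
      organs <- sprintf("organ_%02d", seq_len(organs))
    } else {
      organs <- porcine_organs()[seq_len(max(0, organs))]
    }
  }
  if (length(organs) < 2L) abort("Need at least 2 organs.")
  wl <- grid$wavelengths_nm
  set.seed(seed)
  spectra <- t(vapply(seq_along(organs), function(i) {
    x <- (wl - 500) / 495
    baseline <- runif(1, 0.3, 0.7) + runif(1, -0.2, 0.6) * x +
      runif(1, -0.3, 0.3) * x^2
    n_dips <- sample(1:3, 1)
    dips <- rep(0, length(wl))
    for (d in seq_len(n_dips)) {
      centre <- runif(1, 520, 600)
      width <- runif(1, 10, 25)
      depth <- runif(1, 0.1, 0.4)
      dips <- dips + depth * exp(-(wl - centre)^2 / (2 * width^2))
    }
    rise_amp <- runif(1, 0.5, 2)
    rise_centre <- runif(1, 620, 720)
    rise_width <- runif(1, 25, 60)
    raw <- baseline * (1 - dips) + rise_amp / (1 + exp(-(wl - rise_centre) / rise_width))
    raw <- pmax(raw, 0.02 * max(raw))
    raw / sum(raw)
  }, numeric(length(wl))))
  mean_l1 <- mean(as.vector(stats::dist(spectra, method = "manhattan")))
  if (mean_l1 <= min_separation) {
    abort(sprintf("Fingerprints insufficiently separated (mean l1 %.4g <= %.4g).",
                  mean_l1, min_separation))
  }
  if (max(abs(t(apply(spectra, 1, diff)))) > max_step) {
    abort("Fingerprint smoothness bound violated.")
  }
  out <- tibble::tibble(organ = organs)
  out[band_columns(grid)] <- as.data.frame(spectra)
  structure(out, grid = grid, seed = seed,
            class = c("fingerprint_library", class(out)))
}

#' Standardized acquisition design
#'
#' The standardized protocol records, for every organ of every pig, 3
#' repetitions of the same surgical scene from 3 camera angles at
#' `n_positions` organ positions: `n_positions * 9` recordings per organ per
#' pig (36 with the default 4 positions).
#'
#' @param n_pigs Number of pigs.
#' @param organs Organ labels.
#' @param n_positions Organ positions per (pig, organ); the "image" factor.
#' @return A tibble of class `study_design` with columns `pig_id`, `organ`,
#'   `position_id` (globally unique image identifier), `angle`, `repetition`.
#' @export
make_standardized_design <- function(n_pigs, organs = porcine_organs(),
                                     n_positions = 4L) {
  if (n_pigs < 1L || n_positions < 1L || length(organs) < 1L) {
    abort("`n_pigs`, `n_positions` and `organs` must be positive/non-empty.")
  }
  design <- tidyr::expand_grid(
    pig_id = sprintf("P%02d", seq_len(n_pigs)),
    organ = organs,
    position = seq_len(n_positions),
    angle = hsi_angles(),
    repetition = 1:3
  )
  design <- dplyr::mutate(
    design,
    position_id = sprintf("%s_%s_pos%d", .data$pig_id, .data$organ, .data$position),
    position = NULL, .after = "organ"
  )
  structure(design, class = c("study_design", class(design)))
}

#' Generative variance components
#'
#' Container for the components of the per-wavelength generative model
#' `value = m_organ(lambda) * organ_effect_scale + theta_angle + pig + image
#' + residual`, with pig, image and residual effects drawn independently
#' normal with the given variances.
#'
#' @param sigma_pig_sq Variance of the pig-level random effect.
#' @param sigma_image_sq Variance of the image-level (position) random effect.
#' @param sigma_rep_sq Residual (repetition-level) variance.
#' @param theta Named length-2 vector of fixed angle effects for the two
#'   non-reference angles (`side_a_25deg`, `side_b_25deg`); the perpendicular
#'   angle is the reference with effect 0.
#' @param organ_effect_scale Multiplier applied to the fingerprints, scaling
#'   the between-organ spread.
#' @return A list of class `generative_components`.
#' @export
generative_components <- function(sigma_pig_sq = 0, sigma_image_sq = 0,
                                  sigma_rep_sq = 0,
                                  theta = c(side_a_25deg = 0, side_b_25deg = 0),
                                  organ_effect_scale = 1) {
  if (any(c(sigma_pig_sq, sigma_image_sq, sigma_rep_sq) < 0)) {
    abort("Variances must be non-negative.")
  }
  if (length(theta) != 2L || any(!is.finite(theta))) {
    abort("`theta` must be two finite angle effects.")
  }
  names(theta) <- c("side_a_25deg", "side_b_25deg")
  structure(
    list(sigma_pig_sq = sigma_pig_sq, sigma_image_sq = sigma_image_sq,
         sigma_rep_sq = sigma_rep_sq, theta = theta,
         organ_effect_scale = organ_effect_scale),
    class = "generative_components"
  )
}

#' Simulate spectra under the standardized generative model
#'
#' For each design row and wavelength, generates
#' `m_organ(lambda) * organ_effect_scale + theta_angle + delta_pig(lambda) +
#' gamma_image(lambda) + eps(lambda)`, with the random effects drawn
#' independently per wavelength (default) so the per-wavelength mixed model
#' is exactly correctly specified, or smoothed across wavelengths
#' (`smooth_effects = TRUE`, variance-preserving Gaussian kernel) for
#' realism checks.
#'
#' With `normalize = TRUE` negative values are clipped to zero and rows are
#' re-normalized to unit l1 mass (the classifier path); with the default
#' `normalize = FALSE` the raw table retains exactly the specified variance
#' components (the variance-recovery path).
#'
#' @param design A [make_standardized_design()] tibble (columns `pig_id`,
#'   `organ`, `position_id`, `angle`, `repetition`).
#' @param lib A [make_fingerprint_library()]; must cover all design organs.
#' @param comps A [generative_components()].
#' @param seed Integer seed; identical inputs and seed give identical tables.
#' @param normalize Clip and re-normalize rows to unit sum.
#' @param smooth_effects Draw wavelength-correlated random effects.
#' @param smooth_bandwidth Gaussian kernel SD in bands for `smooth_effects`.
#' @return A spectra tibble: design columns plus `n_pixels` (NA; no pixels
#'   were simulated) and one `b<wavelength>` column per band.
#' @export
simulate_spectra <- function(design, lib, comps, seed = 1L, normalize = FALSE,
                             smooth_effects = FALSE, smooth_bandwidth = 2) {
  stopifnot(inherits(comps, "generative_components"))
  bands <- spectra_band_columns(lib)
  B <- length(bands)
  unknown <- setdiff(unique(design$organ), lib$organ)
  if (length(unknown)) {
    abort(sprintf("Design organs missing from library: %s.",
                  paste(unknown, collapse = ", ")))
  }
  set.seed(seed)
  n <- nrow(design)
  fp <- spectra_matrix(lib) * comps$organ_effect_scale
  rownames(fp) <- lib$organ
  values <- fp[design$organ, , drop = FALSE]
  theta_full <- c(perpendicular = 0, comps$theta)
  values <- values + theta_full[design$angle]

  draw <- function(n_levels, var) {
    e <- matrix(rnorm(n_levels * B, sd = sqrt(var)), n_levels, B)
    if (smooth_effects && var > 0) {
      k <- stats::dnorm(seq(-3 * smooth_bandwidth, 3 * smooth_bandwidth),
                        sd = smooth_bandwidth)
      k <- k / sqrt(sum(k^2)) # preserves the marginal variance
      e <- t(apply(e, 1, function(row) {
        stats::convolve(row, rev(k), type = "open")[
          (length(k) - 1) / 2 + seq_len(B)]
      }))
    }
    e
  }
  pigs <- sort(unique(design$pig_id))
  images <- sort(unique(design$position_id))
  delta <- draw(length(pigs), comps$sigma_pig_sq)
  gamma <- draw(length(images), comps$sigma_image_sq)
  eps <- draw(n, comps$sigma_rep_sq)
  values <- values + delta[match(design$pig_id, pigs), , drop = FALSE] +
    gamma[match(design$position_id, images), , drop = FALSE] + eps

  if (normalize) {
    values <- pmax(values, 0)
    rs <- rowSums(values)
    rs[rs <= 0] <- 1
    values <- values / rs
  }
  out <- tibble::as_tibble(design)
  out$n_pixels <- NA_integer_
  out[bands] <- as.data.frame(values)
  out
}

#' Calibrate noise components to a target organ share of variance
#'
#' Computes, from a fingerprint library and a design, the population
#' variance of the organ term (averaged over wavelengths) and returns
#' [generative_components()] whose total random variation makes the organ
#' term account for `organ_share` of the total at the wavelength-averaged
#' organ variance (per-wavelength proportions scatter around the target as
#' the organ variance varies across bands), with the remaining variance
#' split between pig, image and repetition in `noise_split` ratios. The
#' default split mirrors the relative sizes reported for porcine organ
#' reflectance (image dominating pig, repetition negligible).
#'
#' @param lib Fingerprint library.
#' @param design Study design.
#' @param organ_share Target average proportion of variance explained by
#'   organ (0 < share < 1).
#' @param noise_split Named non-negative ratios for `pig`, `image`,
#'   `repetition` (normalized internally).
#' @param organ_effect_scale Passed through to the components.
#' @return A [generative_components()] object.
#' @export
calibrate_components <- function(lib, design, organ_share = 0.8,
                                 noise_split = c(pig = 2.3, image = 13.8,
                                                 repetition = 0.2),
                                 organ_effect_scale = 1) {
  stopifnot(organ_share > 0, organ_share < 1)
  v_org <- mean(analytic_organ_term_variance(lib, design) * organ_effect_scale^2)
  total_noise <- v_org * (1 - organ_share) / organ_share
  split <- noise_split / sum(noise_split)
  generative_components(
    sigma_pig_sq = total_noise * split[["pig"]],
    sigma_image_sq = total_noise * split[["image"]],
    sigma_rep_sq = total_noise * split[["repetition"]],
    organ_effect_scale = organ_effect_scale
  )
}

#' Analytic variance decomposition of the generative model
#'
#' For simulated data the true decomposition is available in closed form:
#' per wavelength, the organ term's population variance over design rows,
#' the angle term's population variance, and the three generative variance
#' components. `analytic_variance_proportions()` returns the true
#' per-wavelength proportions the estimator should recover.
#'
#' @param lib Fingerprint library.
#' @param design Study design.
#' @param comps Generative components.
#' @return A tibble with columns `wavelength`, `factor`, `proportion`.
#' @export
analytic_variance_proportions <- function(lib, design, comps) {
  v_org <- analytic_organ_term_variance(lib, design) * comps$organ_effect_scale^2
  theta_full <- c(perpendicular = 0, comps$theta)
  a <- theta_full[design$angle]
  v_angle <- mean((a - mean(a))^2)
  wl <- spectra_wavelengths(lib)
  total <- v_org + v_angle + comps$sigma_pig_sq + comps$sigma_image_sq +
    comps$sigma_rep_sq
  tibble::tibble(
    wavelength = rep(wl, times = 5L),
    factor = rep(c("organ", "angle", "pig", "image", "repetition"), each = length(wl)),
    proportion = c(v_org / total, rep(v_angle, length(wl)) / total,
                   rep(comps$sigma_pig_sq, length(wl)) / total,
                   rep(comps$sigma_image_sq, length(wl)) / total,
                   rep(comps$sigma_rep_sq, length(wl)) / total)
  )
}

# per-wavelength population variance over design rows of the organ fingerprint
analytic_organ_term_variance <- function(lib, design) {
  fp <- spectra_matrix(lib)
  rownames(fp) <- lib$organ
  m <- fp[design$organ, , drop = FALSE]
  colMeans(m^2) - colMeans(m)^2
}

#' Render a synthetic datacube around a median spectrum
#'
#' Builds a cube whose masked pixels carry the given spectrum plus seeded
#' pixel noise and whose background is a distinct constant spectrum, so that
#' the preprocessing chain (`l1_normalize_pixels()` +
#' `extract_median_spectrum()`) can be tested end-to-end: extraction on the
#' rendered cube recovers the input spectrum up to noise.
#'
#' @param med One-row spectra tibble (as returned by
#'   [extract_median_spectrum()] or one row of [simulate_spectra()] output).
#' @param shape `c(width, height)` of the cube; must fit the mask.
#' @param n_mask_pixels Number of annotated pixels (a centred block) if
#'   `mask` is not given.
#' @param mask Optional logical matrix of shape `shape`.
#' @param pixel_noise_sd SD of additive pixel noise per band.
#' @param seed Integer seed.
#' @param grid Wavelength grid (defaults to the grid implied by `med`).
#' @return A list with elements `cube` ([datacube()], unnormalized) and
#'   `annotation` ([annotation_record()]).
#' @export
render_cube <- function(med, shape = c(32L, 32L), n_mask_pixels = 64L,
                        mask = NULL, pixel_noise_sd = 0, seed = 1L,
                        grid = NULL) {
  if (any(shape < 1L)) abort("`shape` must be positive.")
  bands <- spectra_band_columns(med)
  values <- as.numeric(med[1, bands])
  if (is.null(grid)) {
    wl <- as.numeric(sub("^b", "", bands))
    grid <- make_wavelength_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  }
  if (is.null(mask)) {
    if (n_mask_pixels > prod(shape)) abort("`shape` too small for the mask.")
    mask <- matrix(FALSE, shape[1], shape[2])
    side <- ceiling(sqrt(n_mask_pixels))
    x0 <- max(1L, (shape[1] - side) %/% 2L)
    y0 <- max(1L, (shape[2] - side) %/% 2L)
    cells <- as.matrix(expand.grid(
      x = x0 + seq_len(min(side, shape[1] - x0 + 1L)) - 1L,
      y = y0 + seq_len(min(side, shape[2] - y0 + 1L)) - 1L
    ))[seq_len(n_mask_pixels), , drop = FALSE]
    mask[cells] <- TRUE
  }
  stopifnot(identical(dim(mask), as.integer(shape)))
  set.seed(seed)
  B <- length(values)
  # background: distinct smooth ramp, same l1 mass as the foreground spectrum
  background <- rev(seq_len(B))
  background <- background / sum(background) * sum(values)
  refl <- array(rep(background, each = prod(shape)), dim = c(shape, B))
  idx <- which(mask)
  noise <- matrix(rnorm(length(idx) * B, sd = pixel_noise_sd), length(idx), B)
  px <- pmax(matrix(values, length(idx), B, byrow = TRUE) + noise, 0)
  for (b in seq_len(B)) {
    plane <- refl[, , b]
    plane[idx] <- px[, b]
    refl[, , b] <- plane
  }
  meta <- function(col, default) {
    if (col %in% names(med)) med[[col]][1] else default
  }
  image_id <- as.character(meta("image_id", "synthetic_img"))
  ann <- annotation_record(
    pig_id = meta("pig_id", "P01"), organ = meta("organ", "stomach"),
    image_id = image_id,
    position_id = meta("position_id", "P01_pos1"),
    angle = meta("angle", "perpendicular"), repetition = meta("repetition", 1L),
    mask = mask
  )
  list(cube = datacube(refl, grid, image_id = image_id), annotation = ann)
}
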