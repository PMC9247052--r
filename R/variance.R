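# Per-wavelength linear mixed models and the explained-variation
# decomposition. At each wavelength the model is
#
#   value_ijk = alpha + organ'beta + angle'theta + delta_i + gamma_ij + eps_ijk
#
# with fixed effects for organ (treatment contrasts, reference "stomach")
# and angle (reference "perpendicular"), a random pig intercept delta_i, a
# random image-within-pig intercept gamma_ij (image identifiers are globally
# unique, so plain intercepts encode the nesting) and residual eps_ijk
# capturing repetition-to-repetition variability. Estimation is REML.

popvar <- function(x) mean((x - mean(x))^2) # population (1/n) variance

#' Fit the per-wavelength reflectance mixed model
#'
#' @param df Data frame with columns `value`, `organ`, `angle`, `pig_id`,
#'   `position_id` (the image factor; globally unique levels).
#' @param include_organ Include the organ fixed effect (`FALSE` for the
#'   organ-stratified analysis). Single-level factors are dropped
#'   automatically.
#' @return A list of class `reflectance_lmm`: `fit` (a `merMod`),
#'   `converged`, `n_obs` and `data`.
#' @export
fit_reflectance_lmm <- function(df, include_organ = TRUE) {
  required <- c("value", "organ", "angle", "pig_id", "position_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (dplyr::n_distinct(df$pig_id) < 2L) {
    abort("Need at least 2 pigs to separate pig from image variation.")
  }
  df <- as.data.frame(df)
  # image must be nested in pig: each image level belongs to exactly one pig
  if (any(tapply(df$pig_id, df$position_id,
                 function(p) length(unique(p))) > 1L)) {
    abort("`position_id` levels must be nested within pigs.")
  }
  organ_levels <- unique(as.character(df$organ))
  ref <- if ("stomach" %in% organ_levels) "stomach" else sort(organ_levels)[1]
  df$organ <- stats::relevel(factor(df$organ), ref = ref)
  df$angle <- factor(df$angle, levels = intersect(hsi_angles(),
                                                  unique(as.character(df$angle))))
  fixed <- c(
    if (include_organ && nlevels(df$organ) > 1L) "organ",
    if (nlevels(df$angle) > 1L) "angle"
  )
  form <- stats::as.formula(paste(
    "value ~", paste(c("1", fixed), collapse = " + "),
    "+ (1 | pig_id) + (1 | position_id)"
  ))
  fit <- suppressMessages(lme4::lmer(
    form, data = df, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  ))
  structure(
    list(fit = fit, converged = lmm_converged(fit), n_obs = nrow(df), data = df),
    class = "reflectance_lmm"
  )
}

lmm_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  isTRUE(fit@optinfo$conv$opt == 0) &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
}

# Variance components by group name; singular fits give exact zeros
# (the fitter's non-negativity constraint), counted via attr "truncated".
lmm_varcomps <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v else 0
  }
  out <- c(pig = get("pig_id"), image = get("position_id"), repetition = get("Residual"))
  attr(out, "truncated") <- sum(out[c("pig", "image")] == 0)
  out
}

#' Decompose a fitted mixed model into explained-variation shares
#'
#' Operationalizes the empirical decomposition of explained variation: the
#' organ and angle contributions are the population variances, over the
#' observations used in the fit, of the fitted fixed-effect terms
#' `organ'beta_hat` and `angle'theta_hat`; their cross-covariance is split
#' equally between the two terms (it is near zero in balanced designs and a
#' warning is raised if it exceeds 1% of the total). The pig, image and
#' repetition contributions are the REML variance components. Proportions
#' are each contribution divided by the total.
#'
#' @param lmm A [fit_reflectance_lmm()] result.
#' @return A tibble with columns `factor`, `variance`, `proportion` (rows
#'   organ, angle, pig, image, repetition).
#' @export
decompose_fit <- function(lmm) {
  stopifnot(inherits(lmm, "reflectance_lmm"))
  fit <- lmm$fit
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  term_values <- function(prefix) {
    cols <- grepl(paste0("^", prefix), colnames(X))
    if (!any(cols)) return(rep(0, nrow(X)))
    as.vector(X[, cols, drop = FALSE] %*% beta[cols])
  }
  o <- term_values("organ")
  a <- term_values("angle")
  v_organ <- popvar(o)
  v_angle <- popvar(a)
  cross <- mean((o - mean(o)) * (a - mean(a)))
  vc <- lmm_varcomps(fit)
  v <- c(organ = v_organ + cross, angle = v_angle + cross,
         pig = unname(vc["pig"]), image = unname(vc["image"]),
         repetition = unname(vc["repetition"]))
  total <- sum(v)
  if (total <= 0) abort("No variation to decompose.")
  if (abs(2 * cross) > 0.01 * total) {
    warn(sprintf("Fixed-term cross-covariance is %.2f%% of total variance; the equal split is material.",
                 200 * cross / total))
  }
  tibble::tibble(factor = names(v), variance = unname(v),
                 proportion = unname(v) / total)
}

# Explained SDs for the organ-stratified model (no organ fixed effect):
# angle = population SD of the fitted angle term, the rest are the
# square roots of the variance components.
decompose_fit_sd <- function(lmm) {
  fit <- lmm$fit
  X <- stats::model.matrix(fit)
  beta <- lme4::fixef(fit)
  cols <- grepl("^angle", colnames(X))
  a <- if (any(cols)) as.vector(X[, cols, drop = FALSE] %*% beta[cols]) else rep(0, nrow(X))
  vc <- lmm_varcomps(fit)
  tibble::tibble(
    factor = c("angle", "pig", "image", "repetition"),
    estimate = c(sqrt(popvar(a)), sqrt(unname(vc[c("pig", "image", "repetition")])))
  )
}

# Parametric bootstrap around a fitted model: simulate new responses from
# the fitted model (fresh pig/image/residual draws at the REML estimates),
# refit, re-decompose, and take pointwise percentile intervals.
bootstrap_decomposition <- function(lmm, statistic, B, level, seed,
                                    max_fail = 0.2) {
  sims <- stats::simulate(lmm$fit, nsim = B, seed = seed)
  draws <- lapply(sims, function(y) {
    tryCatch({
      refit <- suppressMessages(lme4::refit(lmm$fit, newresp = y))
      boot_lmm <- list(fit = refit, converged = lmm_converged(refit),
                       n_obs = lmm$n_obs, data = lmm$data)
      class(boot_lmm) <- "reflectance_lmm"
      if (!boot_lmm$converged) NULL else statistic(boot_lmm)
    }, error = function(e) NULL)
  })
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > max_fail) {
    abort(sprintf("Bootstrap non-convergence rate %.1f%% exceeds %.0f%%.",
                  100 * mean(!ok), 100 * max_fail))
  }
  mat <- vapply(draws[ok], function(d) d[[ncol(d)]], numeric(nrow(draws[ok][[1]])))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(mat, 1L, stats::quantile, probs = probs, names = FALSE)
  list(ci_lo = qs[1, ], ci_hi = qs[2, ], n_failed = sum(!ok))
}

#' Per-wavelength variance decomposition of a spectra table
#'
#' Fits an independent mixed model at every wavelength and decomposes the
#' reflectance variance into organ, angle, pig, image and repetition
#' shares. With `bootstrap > 0`, pointwise percentile confidence intervals
#' from a parametric bootstrap (new random-effect and residual draws from
#' the fitted model, refit and re-decomposition per replicate) are
#' attached.
#'
#' @param spectra Spectra tibble (`pig_id`, `organ`, `position_id`, `angle`,
#'   `repetition`, `b<wavelength>` columns).
#' @param wavelengths Wavelengths to analyse (default: all bands).
#' @param bootstrap Number of parametric bootstrap replications (0 = none;
#'   the study protocol uses 500).
#' @param level Confidence level for the bootstrap intervals.
#' @param seed Integer seed; required when `bootstrap > 0`.
#' @return A tibble of class `variance_decomposition` with columns
#'   `wavelength`, `factor`, `estimate` (the proportion) and, with
#'   bootstrap, `ci_lo`/`ci_hi`. Non-convergent wavelengths are omitted
#'   (reported as gaps) with a warning. Attributes: `medians` (per-factor
#'   median across wavelengths), `diagnostics`.
#' @export
decompose_variance <- function(spectra, wavelengths = NULL, bootstrap = 0L,
                               level = 0.95, seed = NULL) {
  if (bootstrap > 0L && is.null(seed)) {
    abort("`seed` is required when `bootstrap > 0`.")
  }
  wl_all <- spectra_wavelengths(spectra)
  wavelengths <- if (is.null(wavelengths)) wl_all else wavelengths
  stopifnot(all(wavelengths %in% wl_all))
  base <- spectra[c("pig_id", "organ", "position_id", "angle", "repetition")]
  failed <- character()
  truncated <- 0L
  rows <- purrr::map(seq_along(wavelengths), function(i) {
    wl <- wavelengths[i]
    df <- base
    df$value <- spectra[[sprintf("b%g", wl)]]
    lmm <- fit_reflectance_lmm(df, include_organ = TRUE)
    if (!lmm$converged) {
      failed <<- c(failed, sprintf("%g", wl))
      return(NULL)
    }
    dec <- decompose_fit(lmm)
    truncated <<- truncated + attr(lmm_varcomps(lmm$fit), "truncated")
    out <- tibble::tibble(wavelength = wl, factor = dec$factor,
                          estimate = dec$proportion)
    if (bootstrap > 0L) {
      ci <- bootstrap_decomposition(
        lmm, statistic = decompose_fit, B = bootstrap, level = level,
        seed = (seed + i) %% .Machine$integer.max
      )
      out$ci_lo <- pmin(ci$ci_lo, out$estimate)
      out$ci_hi <- pmax(ci$ci_hi, out$estimate)
    }
    out
  })
  if (length(failed)) {
    warn(sprintf("Mixed model did not converge at wavelength(s) %s; reported as gaps.",
                 paste(failed, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) abort("No wavelength converged.")
  medians <- dplyr::summarise(dplyr::group_by(out, .data$factor),
                              median = median(.data$estimate), .groups = "drop")
  structure(out,
            medians = medians,
            measure = "proportion",
            diagnostics = list(n_nonconverged = length(failed),
                               n_truncated_components = truncated),
            class = c("variance_decomposition", class(out)))
}

#' Organ-stratified variance decomposition
#'
#' For each organ (and wavelength), fits the mixed model without the organ
#' covariate and reports the explained standard deviation of each remaining
#' factor: the population SD of the fitted angle term, the pig and image
#' random-effect SDs, and the residual (repetition) SD.
#'
#' @inheritParams decompose_variance
#' @param organs Organs to analyse (default: all in `spectra`); each needs
#'   at least 2 pigs.
#' @return A tibble of class `variance_decomposition` (`measure = "sd"`)
#'   with columns `organ`, `wavelength`, `factor`, `estimate` and optional
#'   CI columns; attribute `medians` holds per-(organ, factor) medians
#'   across wavelengths.
#' @export
decompose_variance_stratified <- function(spectra, organs = NULL,
                                          wavelengths = NULL, bootstrap = 0L,
                                          level = 0.95, seed = NULL) {
  if (bootstrap > 0L && is.null(seed)) {
    abort("`seed` is required when `bootstrap > 0`.")
  }
  organs <- if (is.null(organs)) sort(unique(spectra$organ)) else organs
  wl_all <- spectra_wavelengths(spectra)
  wavelengths <- if (is.null(wavelengths)) wl_all else wavelengths
  out <- purrr::map_dfr(seq_along(organs), function(oi) {
    org <- organs[oi]
    sub <- spectra[spectra$organ == org, ]
    if (dplyr::n_distinct(sub$pig_id) < 2L) {
      abort(sprintf("Organ '%s' has fewer than 2 pigs.", org))
    }
    base <- sub[c("pig_id", "organ", "position_id", "angle", "repetition")]
    purrr::map_dfr(seq_along(wavelengths), function(i) {
      wl <- wavelengths[i]
      df <- base
      df$value <- sub[[sprintf("b%g", wl)]]
      lmm <- fit_reflectance_lmm(df, include_organ = FALSE)
      if (!lmm$converged) {
        warn(sprintf("No convergence for organ %s at %g nm; gap.", org, wl))
        return(NULL)
      }
      dec <- decompose_fit_sd(lmm)
      res <- tibble::tibble(organ = org, wavelength = wl,
                            factor = dec$factor, estimate = dec$estimate)
      if (bootstrap > 0L) {
        ci <- bootstrap_decomposition(
          lmm, statistic = decompose_fit_sd, B = bootstrap, level = level,
          seed = (seed + 1000L * oi + i) %% .Machine$integer.max
        )
        res$ci_lo <- pmin(ci$ci_lo, res$estimate)
        res$ci_hi <- pmax(ci$ci_hi, res$estimate)
      }
      res
    })
  })
  medians <- dplyr::summarise(dplyr::group_by(out, .data$organ, .data$factor),
                              median = median(.data$estimate), .groups = "drop")
  structure(out, medians = medians, measure = "sd",
            class = c("variance_decomposition", class(out)))
}

#' Median of per-wavelength estimates per factor
#'
#' The headline numbers of the decomposition figures: for each factor (and
#' organ in the stratified analysis), the median across wavelengths.
#'
#' @param decomp A [decompose_variance()] or
#'   [decompose_variance_stratified()] result.
#' @return A tibble with the grouping columns and `median`.
#' @export
median_across_wavelengths <- function(decomp) {
  groups <- intersect(c("organ", "factor"), names(decomp))
  dplyr::summarise(
    dplyr::group_by(decomp, dplyr::across(dplyr::all_of(groups))),
    median = median(.data$estimate), .groups = "drop"
  )
}

#' @export
tidy.variance_decomposition <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.variance_decomposition <- function(x, ...) {
  med <- attr(x, "medians")
  tidyr::pivot_wider(
    med, names_from = dplyr::any_of("factor"), values_from = "median",
    names_prefix = "median_"
  )
}

#' Plot a variance decomposition
#'
#' Per-wavelength stacked estimates per factor, with confidence bands if
#' present; stratified results are facetted by organ.
#'
#' @param object A `variance_decomposition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variance_decomposition <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$wavelength, y = .data$estimate, colour = .data$factor
  ))
  if ("ci_lo" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi, fill = .data$factor),
      alpha = 0.2, colour = NA
    )
  }
  p <- p + ggplot2::geom_line()
  if ("organ" %in% names(object)) p <- p + ggplot2::facet_wrap(~organ)
  p + ggplot2::labs(
    x = "wavelength [nm]",
    y = if (identical(attr(object, "measure"), "sd")) {
      "explained standard deviation"
    } else {
      "proportion of explained variation"
    }
  )
}
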