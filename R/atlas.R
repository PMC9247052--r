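#' Compute the per-organ spectral fingerprint atlas
#'
#' For every organ present in the spectra table, computes the overall mean
#' spectrum and its per-band standard deviation across all annotation rows
#' (sample SD, n-1 denominator), the per-pig mean curves, the number of
#' contributing animals (A) and the number of measurements (n). Statistics
#' are taken across annotation rows, not across per-pig means; the per-pig
#' curves are reported separately.
#'
#' @param spectra A spectra tibble (columns `pig_id`, `organ`,
#'   `b<wavelength>`...). Factor levels of `organ` with zero rows are
#'   omitted with a warning.
#' @return An object of class `fingerprint_atlas`: a list with tibbles
#'   `summary` (organ, wavelength, overall_mean, sd), `per_pig` (organ,
#'   pig_id, wavelength, mean) and `counts` (organ, n_animals,
#'   n_measurements).
#' @export
compute_atlas <- function(spectra) {
  if (nrow(spectra) == 0L) abort("`spectra` is empty.")
  if (is.factor(spectra$organ)) {
    empty <- setdiff(levels(spectra$organ), unique(as.character(spectra$organ)))
    if (length(empty)) {
      warn(sprintf("Omitting organ(s) with zero rows: %s.",
                   paste(empty, collapse = ", ")))
    }
    spectra$organ <- as.character(spectra$organ)
  }
  long <- tidyr::pivot_longer(
    spectra[c("pig_id", "organ", spectra_band_columns(spectra))],
    cols = -c("pig_id", "organ"),
    names_to = "wavelength", values_to = "value"
  )
  long$wavelength <- as.numeric(sub("^b", "", long$wavelength))
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$organ, .data$wavelength),
    overall_mean = mean(.data$value),
    sd = if (dplyr::n() > 1L) stats::sd(.data$value) else 0,
    .groups = "drop"
  )
  per_pig <- dplyr::summarise(
    dplyr::group_by(long, .data$organ, .data$pig_id, .data$wavelength),
    mean = mean(.data$value), .groups = "drop"
  )
  counts <- dplyr::summarise(
    dplyr::group_by(spectra, .data$organ),
    n_animals = dplyr::n_distinct(.data$pig_id),
    n_measurements = dplyr::n(), .groups = "drop"
  )
  structure(list(summary = summary, per_pig = per_pig, counts = counts),
            class = "fingerprint_atlas")
}

#' @export
print.fingerprint_atlas <- function(x, ...) {
  cat(sprintf("<fingerprint_atlas> %d organs, %d measurements, %d wavelengths\n",
              nrow(x$counts), sum(x$counts$n_measurements),
              dplyr::n_distinct(x$summary$wavelength)))
  invisible(x)
}

#' @export
tidy.fingerprint_atlas <- function(x, ...) x$summary

#' @export
glance.fingerprint_atlas <- function(x, ...) x$counts

#' Export a fingerprint atlas to disk
#'
#' Writes one CSV per organ (columns `wavelength`, `overall_mean`, `sd` and
#' one `pig_<id>` column per contributing pig) plus an `index.json` listing
#' each organ with its A (animals) and n (measurements) counts. An empty
#' atlas produces an empty index and a warning.
#'
#' @param atlas A [compute_atlas()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "fingerprint_atlas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(atlas$counts) == 0L) {
    warn("Empty atlas: writing empty index only.")
    jsonlite::write_json(list(), file.path(dir, "index.json"), auto_unbox = TRUE)
    return(invisible(file.path(dir, "index.json")))
  }
  paths <- purrr::map_chr(atlas$counts$organ, function(org) {
    wide <- tidyr::pivot_wider(
      dplyr::filter(atlas$per_pig, .data$organ == org),
      id_cols = "wavelength", names_from = "pig_id", values_from = "mean",
      names_prefix = "pig_"
    )
    out <- dplyr::left_join(
      dplyr::select(dplyr::filter(atlas$summary, .data$organ == org),
                    "wavelength", "overall_mean", "sd"),
      wide, by = "wavelength"
    )
    path <- file.path(dir, paste0(org, ".csv"))
    readr::write_csv(out, path)
    path
  })
  index <- purrr::pmap(atlas$counts, function(organ, n_animals, n_measurements) {
    list(organ = organ, n_animals = n_animals, n_measurements = n_measurements,
         file = paste0(organ, ".csv"))
  })
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "index.json")))
}

#' Plot a fingerprint atlas
#'
#' One panel per organ: per-pig mean curves in grey, overall mean in blue,
#' +/- 1 SD band shaded.
#'
#' @param object A `fingerprint_atlas`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fingerprint_atlas <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$wavelength)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$overall_mean - .data$sd,
                   ymax = .data$overall_mean + .data$sd),
      fill = "grey80"
    ) +
    ggplot2::geom_line(
      data = object$per_pig,
      ggplot2::aes(y = .data$mean, group = .data$pig_id),
      colour = "grey50", linewidth = 0.2
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$overall_mean), colour = "#2166ac") +
    ggplot2::facet_wrap(~organ, scales = "free_y") +
    ggplot2::labs(x = "wavelength [nm]", y = "reflectance (l1-normalized, a.u.)")
}
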