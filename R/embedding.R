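#' t-SNE embedding configuration
#'
#' Default values are the triple selected by the study's staged random
#' search: early exaggeration 34, learning rate 92, perplexity 30.
#'
#' @param early_exaggeration Integer in \[5, 100\].
#' @param learning_rate Integer in \[10, 1000\].
#' @param perplexity Integer in \[2, 100\].
#' @param seed Integer seed for the embedding initialization.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(early_exaggeration = 34L, learning_rate = 92L,
                             perplexity = 30L, seed = 0L) {
  if (early_exaggeration < 5 || early_exaggeration > 100) {
    abort("`early_exaggeration` must be in [5, 100].")
  }
  if (learning_rate < 10 || learning_rate > 1000) {
    abort("`learning_rate` must be in [10, 1000].")
  }
  if (perplexity < 2 || perplexity > 100) {
    abort("`perplexity` must be in [2, 100].")
  }
  structure(
    list(early_exaggeration = as.integer(early_exaggeration),
         learning_rate = as.integer(learning_rate),
         perplexity = as.integer(perplexity), seed = as.integer(seed)),
    class = "embedding_config"
  )
}

#' Mean same-label k-nearest-neighbour purity
#'
#' Quality score for 2-D embeddings: for every point, the fraction of its k
#' nearest neighbours (Euclidean, excluding itself) sharing its label,
#' averaged over points.
#'
#' @param coords Numeric matrix or data frame of coordinates (n x 2).
#' @param labels Vector of length n.
#' @param k Number of neighbours.
#' @return A scalar in \[0, 1\].
#' @export
knn_purity <- function(coords, labels, k = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(labels) == n, n > k)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[seq_len(k)]
    mean(labels[nn] == labels[i])
  }, numeric(1)))
}

#' Embed annotation spectra in two dimensions
#'
#' Runs t-SNE (exact gradient, single-threaded, seeded: identical calls
#' give identical coordinates) on the band columns of a spectra table. One
#' output point represents the median spectrum of one annotation. The
#' quality score attached to the result is the mean same-organ
#' nearest-neighbour purity ([knn_purity()]).
#'
#' @param spectra Spectra tibble; needs more than `3 * perplexity` rows.
#' @param config An [embedding_config()].
#' @param n_iter Number of gradient iterations.
#' @param score_k Neighbourhood size of the purity score.
#' @return An object of class `spectra_embedding`: list with `coordinates`
#'   (tibble: metadata + `tsne1`, `tsne2`), `config`, `score`.
#' @export
embed_spectra <- function(spectra, config = embedding_config(), n_iter = 1000L,
                          score_k = 10L) {
  stopifnot(inherits(config, "embedding_config"))
  X <- spectra_matrix(spectra)
  if (nrow(X) - 1L < 3L * config$perplexity) {
    abort(sprintf("Too few rows (%d) for perplexity %d (need > %d).",
                  nrow(X), config$perplexity, 3L * config$perplexity + 1L))
  }
  set.seed(config$seed)
  fit <- Rtsne::Rtsne(
    X, dims = 2L, perplexity = config$perplexity,
    eta = config$learning_rate, exaggeration_factor = config$early_exaggeration,
    max_iter = n_iter, theta = 0, pca = FALSE, check_duplicates = FALSE,
    num_threads = 1L, verbose = FALSE
  )
  meta <- spectra[setdiff(names(spectra), spectra_band_columns(spectra))]
  coords <- dplyr::bind_cols(
    meta, tibble::tibble(tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  )
  score <- if ("organ" %in% names(spectra) && nrow(X) > score_k) {
    knn_purity(fit$Y, spectra$organ, k = score_k)
  } else {
    NA_real_
  }
  structure(list(coordinates = coords, config = config, score = score),
            class = "spectra_embedding")
}

#' @export
print.spectra_embedding <- function(x, ...) {
  cat(sprintf(
    "<spectra_embedding> %d points (EE %d, eta %d, perplexity %d); purity %.3f\n",
    nrow(x$coordinates), x$config$early_exaggeration, x$config$learning_rate,
    x$config$perplexity, x$score
  ))
  invisible(x)
}

#' @export
tidy.spectra_embedding <- function(x, ...) x$coordinates

#' @export
glance.spectra_embedding <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coordinates), score = x$score,
    early_exaggeration = x$config$early_exaggeration,
    learning_rate = x$config$learning_rate, perplexity = x$config$perplexity
  )
}

#' @export
autoplot.spectra_embedding <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$tsne1, y = .data$tsne2,
                               colour = .data$organ)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2")
}

#' Equidistant integer perplexity grid
#'
#' The third search stage scans 50 equidistant integer perplexity values
#' spanning \[2, 100\].
#'
#' @param n Number of grid points.
#' @param range Length-2 integer range.
#' @return An integer vector.
#' @export
perplexity_grid <- function(n = 50L, range = c(2L, 100L)) {
  as.integer(round(seq(range[1], range[2], length.out = n)))
}

#' Staged random search for t-SNE hyperparameters
#'
#' Reproduces the study's three-stage tuning protocol with a quantitative
#' score in place of visual inspection: stage 1 draws `n` random integer
#' early-exaggeration values in \[5, 100\] (the other parameters held at
#' `defaults`); stage 2 draws random integer learning rates in \[10, 1000\]
#' at the stage-1 winner; stage 3 scans equidistant integer perplexities in
#' \[2, 100\] at the previous winners. Each candidate embedding is scored by
#' `score_fn`; ties are broken by the first-drawn candidate, non-finite
#' scores are skipped with a warning.
#'
#' @param spectra Spectra tibble; needs more than `3 * max(perplexity)` rows
#'   for the perplexities the search can visit.
#' @param score_fn Function(embedding) -> scalar score (higher is better).
#'   Default: the embedding's same-organ purity score.
#' @param seed Integer seed driving the random draws.
#' @param n_draws Draws per stage, `c(early_exaggeration, learning_rate,
#'   perplexity)`; protocol default `c(50, 100, 50)`.
#' @param defaults Parameter values used before a stage has tuned them
#'   (conventional t-SNE defaults; recorded in the search log).
#' @param perplexity_range Range scanned by the third stage.
#' @param n_iter Gradient iterations per candidate embedding.
#' @return The winning [embedding_config()] with attribute `search_log`
#'   (tibble: stage, parameter, value, score).
#' @export
staged_search <- function(spectra, score_fn = NULL, seed = 0L,
                          n_draws = c(50L, 100L, 50L),
                          defaults = list(early_exaggeration = 12L,
                                          learning_rate = 200L,
                                          perplexity = 30L),
                          perplexity_range = c(2L, 100L), n_iter = 500L) {
  if (is.null(score_fn)) score_fn <- function(emb) emb$score
  perp_grid <- perplexity_grid(n_draws[3], perplexity_range)
  max_perp <- max(defaults$perplexity, perp_grid)
  if (nrow(spectra) - 1L < 3L * max_perp) {
    abort(sprintf("Too few rows (%d) for a search visiting perplexity %d.",
                  nrow(spectra), max_perp))
  }
  set.seed(seed)
  log <- list()
  score_candidates <- function(param, values, current) {
    scores <- vapply(values, function(v) {
      cfg <- current
      cfg[[param]] <- v
      cfg <- embedding_config(cfg$early_exaggeration, cfg$learning_rate,
                              cfg$perplexity, seed = seed)
      s <- tryCatch(score_fn(embed_spectra(spectra, cfg, n_iter = n_iter)),
                    error = function(e) NA_real_)
      if (!is.finite(s)) {
        warn(sprintf("Candidate %s = %d skipped (non-finite score).", param, v))
        s <- -Inf
      }
      s
    }, numeric(1))
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = length(log) + 1L, parameter = param,
      value = values, score = scores
    )
    values[which.max(scores)] # which.max: first-drawn candidate wins ties
  }
  current <- defaults
  current$early_exaggeration <- score_candidates(
    "early_exaggeration", sample(5:100, n_draws[1]), current
  )
  current$learning_rate <- score_candidates(
    "learning_rate", sample(10:1000, n_draws[2]), current
  )
  current$perplexity <- score_candidates("perplexity", perp_grid, current)
  out <- embedding_config(current$early_exaggeration, current$learning_rate,
                          current$perplexity, seed = seed)
  attr(out, "search_log") <- dplyr::bind_rows(log)
  out
}
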