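#' Pig-level train/test split with organ-coverage constraint
#'
#' Randomly selects `n_test` test pigs from the standardized subset,
#' rejecting draws until every organ observed among standardized pigs is
#' represented by at least one standardized pig on each side of the split
#' (the study's selection criterion). Organs held by a single standardized
#' pig can only ever sit on one side; they are exempted from the two-sided
#' requirement and reported in `degenerate_organs`. The rejection log is
#' attached.
#'
#' @param pig_ids All pig identifiers.
#' @param standardized_ids Identifiers of the standardized-protocol pigs
#'   (test pigs are drawn from these).
#' @param organs_per_pig Data frame with columns `pig_id`, `organ` listing
#'   which organs were recorded for which pig.
#' @param n_test Number of test pigs.
#' @param seed Integer seed.
#' @param max_attempts Attempt cap before declaring the constraint
#'   unsatisfiable.
#' @return A list of class `pig_split`: `train_pigs`, `test_pigs`, `log`
#'   (tibble: attempt, accepted, reason).
#' @export
split_train_test <- function(pig_ids, standardized_ids, organs_per_pig,
                             n_test = 8L, seed = 1L, max_attempts = 1000L) {
  standardized_ids <- intersect(standardized_ids, pig_ids)
  if (length(standardized_ids) < n_test) {
    abort(sprintf("Cannot draw %d test pigs from %d standardized pigs.",
                  n_test, length(standardized_ids)))
  }
  opp <- organs_per_pig[organs_per_pig$pig_id %in% standardized_ids, ]
  holders <- tapply(opp$pig_id, opp$organ, function(p) length(unique(p)))
  # an organ held by a single standardized pig can only ever sit on one side;
  # the two-sided requirement applies to organs with at least two holders
  degenerate <- names(holders)[holders < 2L]
  organs <- setdiff(unique(opp$organ), degenerate)
  set.seed(seed)
  log <- list()
  for (attempt in seq_len(max_attempts)) {
    test <- sort(standardized_ids[sample.int(length(standardized_ids), n_test)])
    std_train <- setdiff(standardized_ids, test)
    covered_test <- unique(opp$organ[opp$pig_id %in% test])
    covered_train <- unique(opp$organ[opp$pig_id %in% std_train])
    miss_test <- setdiff(organs, covered_test)
    miss_train <- setdiff(organs, covered_train)
    ok <- !length(miss_test) && !length(miss_train)
    log[[attempt]] <- tibble::tibble(
      attempt = attempt, accepted = ok,
      reason = if (ok) {
        NA_character_
      } else if (length(miss_test)) {
        sprintf("organ(s) %s missing from test", paste(miss_test, collapse = ","))
      } else {
        sprintf("organ(s) %s missing from standardized training pigs",
                paste(miss_train, collapse = ","))
      }
    )
    if (ok) {
      return(structure(
        list(train_pigs = sort(setdiff(pig_ids, test)), test_pigs = test,
             log = dplyr::bind_rows(log),
             degenerate_organs = degenerate),
        class = "pig_split"
      ))
    }
  }
  abort(sprintf("Organ-coverage constraint unsatisfiable within %d attempts.",
                max_attempts))
}

#' Train one leave-one-pig-out fold
#'
#' Trains the CNN on all training annotations except those of
#' `held_out_pig` and returns the model together with its logits on the
#' held-out pig.
#'
#' @param train_table Spectra tibble of the training pigs (columns `pig_id`,
#'   `organ`, band columns).
#' @param held_out_pig Pig to leave out; must occur in `train_table`.
#' @param arch A [cnn_architecture()].
#' @param config A [training_config()].
#' @param classes Class-label ordering (default [porcine_organs()]).
#' @return A list: `model`, `predictions` (tibble of held-out metadata,
#'   `truth`, `pred` and `logit_<class>` columns).
#' @export
train_fold <- function(train_table, held_out_pig, arch, config,
                       classes = porcine_organs()) {
  if (!held_out_pig %in% train_table$pig_id) {
    abort(sprintf("Held-out pig '%s' is not in the training set.", held_out_pig))
  }
  fit_rows <- train_table$pig_id != held_out_pig
  X <- spectra_matrix(train_table)
  y <- factor(train_table$organ, levels = classes)
  model <- build_model(arch, seed = config$seed)
  model <- train_model(model, X[fit_rows, , drop = FALSE], y[fit_rows], config)
  held <- !fit_rows
  logits <- predict_logits(model, X[held, , drop = FALSE])
  preds <- tibble::tibble(
    pig_id = train_table$pig_id[held],
    truth = as.character(train_table$organ[held]),
    pred = classes[max.col(logits, ties.method = "first")]
  )
  colnames(logits) <- paste0("logit_", classes)
  list(model = model, predictions = dplyr::bind_cols(preds, tibble::as_tibble(logits)))
}

#' Leave-one-pig-out cross-validation
#'
#' Trains one fold per training pig (per-fold seed derived from the config
#' seed) and aggregates the held-out predictions into a validation
#' accuracy.
#'
#' @inheritParams train_fold
#' @return An object of class `classifier_bundle`: `models` (one per fold,
#'   named by held-out pig), `val_predictions`, `val_accuracy`, `arch`,
#'   `config`.
#' @export
train_lopo <- function(train_table, arch, config, classes = porcine_organs()) {
  pigs <- sort(unique(train_table$pig_id))
  folds <- purrr::map(seq_along(pigs), function(i) {
    fold_config <- config
    fold_config$seed <- (config$seed + i) %% .Machine$integer.max
    train_fold(train_table, pigs[i], arch, fold_config, classes = classes)
  })
  preds <- purrr::map_dfr(folds, "predictions")
  structure(
    list(models = setNames(purrr::map(folds, "model"), pigs),
         val_predictions = preds,
         val_accuracy = mean(preds$pred == preds$truth),
         arch = arch, config = config, classes = classes),
    class = "classifier_bundle"
  )
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle> %d LOPO folds, validation accuracy %.3f\n",
              length(x$models), x$val_accuracy))
  invisible(x)
}

#' Hyperparameter grids of the training protocol
#'
#' The study's grid: dropout {0.1, 0.2} x initial learning rate
#' {0.001, 0.0001} x decay {0.75, 0.9, 1.0} x batch size {20000, 40000} x
#' class weighting {on, off} x oversampling {on, off} - 96 combinations.
#'
#' @return A named list of grid values.
#' @export
default_grids <- function() {
  list(
    dropout_p = c(0.1, 0.2),
    initial_lr = c(0.001, 0.0001),
    lr_decay = c(0.75, 0.9, 1.0),
    batch_size = c(20000L, 40000L),
    class_weighting = c(TRUE, FALSE),
    oversampling = c(TRUE, FALSE)
  )
}

#' @rdname grid_search
#' @export
grid_combinations <- function(grids = default_grids()) {
  if (!length(grids) || any(!lengths(grids))) abort("`grids` must be non-empty.")
  tibble::as_tibble(expand.grid(grids, KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the grids by leave-one-pig-out
#' validation accuracy on the training pigs and returns the best
#' combination (ties: first row). The full result table is kept.
#'
#' @inheritParams train_lopo
#' @param grids Named list of candidate values; names matching
#'   [training_config()] fields override the base config, `dropout_p`
#'   overrides the architecture.
#' @param base_config A [training_config()] supplying all non-grid values.
#' @return A list of class `grid_search_result`: `results` (tibble with
#'   `val_accuracy` per combination), `best` (one-row tibble),
#'   `best_config`, `best_arch`.
#' @export
grid_search <- function(train_table, grids = default_grids(), base_config,
                        arch = cnn_architecture(), classes = porcine_organs()) {
  combos <- grid_combinations(grids)
  accs <- purrr::map_dbl(seq_len(nrow(combos)), function(i) {
    row <- as.list(combos[i, ])
    cfg <- base_config
    for (nm in intersect(names(row), names(cfg))) cfg[[nm]] <- row[[nm]]
    this_arch <- arch
    if ("dropout_p" %in% names(row)) {
      this_arch <- cnn_architecture(
        conv_filters = arch$conv_filters, conv_kernel = arch$conv_kernel,
        pool_kernel = arch$pool_kernel, fc_sizes = arch$fc_sizes,
        n_classes = arch$n_classes, dropout_p = row$dropout_p,
        input_bands = arch$input_bands
      )
    }
    train_lopo(train_table, this_arch, cfg, classes = classes)$val_accuracy
  })
  results <- dplyr::mutate(combos, val_accuracy = accs)
  best_i <- which.max(accs)
  row <- as.list(combos[best_i, ])
  best_config <- base_config
  for (nm in intersect(names(row), names(best_config))) {
    best_config[[nm]] <- row[[nm]]
  }
  best_arch <- arch
  if ("dropout_p" %in% names(row)) best_arch$dropout_p <- row$dropout_p
  structure(
    list(results = results, best = results[best_i, ],
         best_config = best_config, best_arch = best_arch),
    class = "grid_search_result"
  )
}

#' Mean-logit ensemble prediction
#'
#' Averages the logits of the fold models per spectrum and takes the
#' argmax; ties are broken by the lowest class index. Probabilities are the
#' softmax of the mean logits.
#'
#' @param models List of trained `spectral_cnn` fold models (or a
#'   `classifier_bundle`) sharing one architecture and class ordering.
#' @param spectra Spectra tibble.
#' @return A tibble: metadata columns of `spectra` (band columns dropped)
#'   plus `pred` and `prob_<class>` columns.
#' @export
ensemble_predict <- function(models, spectra) {
  if (inherits(models, "classifier_bundle")) models <- models$models
  if (!length(models)) abort("Need at least one model.")
  X <- spectra_matrix(spectra)
  logits_sum <- Reduce(`+`, lapply(models, function(m) predict_logits(m, X)))
  mean_logits <- logits_sum / length(models)
  classes <- models[[1]]$classes
  pred <- classes[max.col(mean_logits, ties.method = "first")]
  ex <- exp(mean_logits - apply(mean_logits, 1L, max))
  probs <- ex / rowSums(ex)
  colnames(probs) <- paste0("prob_", classes)
  meta <- spectra[setdiff(names(spectra), spectra_band_columns(spectra))]
  dplyr::bind_cols(meta, tibble::tibble(pred = pred), tibble::as_tibble(probs))
}

#' Evaluate organ classification per pig
#'
#' Computes the evaluation suite of the study: micro accuracy over all
#' annotations; per-class one-vs-rest sensitivity, specificity and F1,
#' computed per pig, averaged per class across the pigs possessing that
#' class, and macro-averaged with the SD taken across per-pig macro means;
#' per-pig confusion matrices column-normalized by true-class counts and
#' averaged entrywise across pigs, ignoring non-existent entries (classes
#' absent from a pig's ground truth).
#'
#' @param truth,pred Character/factor vectors of true and predicted labels.
#' @param pig_id Pig identifier per annotation.
#' @param classes Class vocabulary (fixes the matrix ordering).
#' @return An object of class `evaluation_report`: list with
#'   `micro_accuracy`, `n_misclassified`, `n_total`, `per_class` (tibble),
#'   `macro` (one-row tibble), `confusion_mean`, `confusion_sd` (matrices,
#'   predicted x true), `per_pig_confusion` (list of matrices).
#' @export
evaluate_predictions <- function(truth, pred, pig_id,
                                 classes = porcine_organs()) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) == length(pig_id))
  pigs <- sort(unique(pig_id))
  K <- length(classes)

  per_pig_conf <- lapply(pigs, function(p) {
    sel <- pig_id == p
    tab <- table(factor(pred[sel], levels = classes),
                 factor(truth[sel], levels = classes))
    m <- unclass(tab)
    csum <- colSums(m)
    norm <- sweep(m, 2L, pmax(csum, 1L), "/")
    norm[, csum == 0] <- NA_real_ # class absent for this pig: entry missing
    norm
  })
  names(per_pig_conf) <- pigs
  conf_arr <- array(unlist(per_pig_conf), dim = c(K, K, length(pigs)))
  confusion_mean <- apply(conf_arr, 1:2, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  confusion_sd <- apply(conf_arr, 1:2, function(v) {
    if (sum(!is.na(v)) < 2L) NA_real_ else stats::sd(v, na.rm = TRUE)
  })
  dimnames(confusion_mean) <- dimnames(confusion_sd) <-
    list(predicted = classes, true = classes)

  one_vs_rest <- function(tr, pr, cls) {
    tp <- sum(tr == cls & pr == cls)
    fn <- sum(tr == cls & pr != cls)
    fp <- sum(tr != cls & pr == cls)
    tn <- sum(tr != cls & pr != cls)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    c(sensitivity = sens, specificity = spec, f1 = f1)
  }
  per_pig_class <- purrr::map_dfr(pigs, function(p) {
    sel <- pig_id == p
    present <- intersect(classes, unique(truth[sel]))
    purrr::map_dfr(present, function(cls) {
      tibble::tibble(pig_id = p, class = cls,
                     !!!one_vs_rest(truth[sel], pred[sel], cls))
    })
  })
  per_class <- dplyr::summarise(
    dplyr::group_by(per_pig_class, .data$class),
    dplyr::across(c("sensitivity", "specificity", "f1"),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~stats::sd(.x, na.rm = TRUE))),
    n_pigs = dplyr::n(), .groups = "drop"
  )
  per_class <- per_class[match(intersect(classes, per_class$class),
                               per_class$class), ]
  per_pig_macro <- dplyr::summarise(
    dplyr::group_by(per_pig_class, .data$pig_id),
    dplyr::across(c("sensitivity", "specificity", "f1"),
                  ~mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )
  macro <- tibble::tibble(
    sensitivity = mean(per_class$sensitivity_mean, na.rm = TRUE),
    sensitivity_sd = stats::sd(per_pig_macro$sensitivity),
    specificity = mean(per_class$specificity_mean, na.rm = TRUE),
    specificity_sd = stats::sd(per_pig_macro$specificity),
    f1 = mean(per_class$f1_mean, na.rm = TRUE),
    f1_sd = stats::sd(per_pig_macro$f1)
  )
  structure(
    list(micro_accuracy = mean(pred == truth),
         n_misclassified = sum(pred != truth), n_total = length(truth),
         per_class = per_class, macro = macro,
         confusion_mean = confusion_mean, confusion_sd = confusion_sd,
         per_pig_confusion = per_pig_conf),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> micro accuracy %.3f (%d/%d misclassified); macro sensitivity %.3f, specificity %.3f, F1 %.3f\n",
    x$micro_accuracy, x$n_misclassified, x$n_total,
    x$macro$sensitivity, x$macro$specificity, x$macro$f1
  ))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_class

#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(micro_accuracy = x$micro_accuracy,
                   n_misclassified = x$n_misclassified, n_total = x$n_total),
    x$macro
  )
}

#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion_mean))
  names(df) <- c("predicted", "true", "fraction")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 na.value = "grey90", limits = c(0, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1)) +
    ggplot2::labs(x = "true class", y = "predicted class",
                  fill = "mean fraction")
}
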