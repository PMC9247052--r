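# Config-driven end-to-end runs: simulate -> preprocess -> atlas ->
# variance -> embed -> train -> evaluate. One global seed; every stochastic
# stage derives its own seed from it (seed + a stable hash of the stage
# name), and all stage outputs are files whose MD5 hashes land in the run
# manifest, so identical configs give identical manifests.

stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(global_seed) + h) %% 2147483647L
}

#' Default pipeline configuration
#'
#' Desk-scale settings for a full synthetic run: the standardized design at
#' reduced size, a reduced bootstrap, and a small training schedule. Any
#' element can be overridden via `...` (nested lists are merged), or the
#' whole configuration read from a YAML file with [read_pipeline_config()].
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @param ... Overrides merged into the defaults.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("hsi_run_"), ...) {
  config <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "preprocess", "atlas", "variance", "embed",
               "train", "evaluate"),
    spectra_csv = NULL, # external input; NULL = produced by the simulate stage
    simulate = list(n_pigs = 6L, n_organs = 8L, n_positions = 2L,
                    organ_share = 0.8, grid_step = 11),
    variance = list(bootstrap = 50L, wavelengths = NULL),
    embed = list(n_iter = 300L, perplexity = 15L),
    train = list(n_test = 2L, epochs = 2L, samples_per_epoch = 4096L,
                 batch_size = 128L, initial_lr = 0.001, lr_decay = 0.9,
                 dropout_p = 0.2, paper_scale = FALSE)
  )
  overrides <- list(...)
  utils::modifyList(structure(config, class = "pipeline_config"), overrides)
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the configuration fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = raw$seed %||% 1L,
                                  out_dir = raw$out_dir %||% tempfile("hsi_run_")),
                             raw[setdiff(names(raw), c("seed", "out_dir"))]))
}

#' Run the end-to-end pipeline
#'
#' Validates the configuration (referenced input files must exist), then
#' executes the enabled stages in order. A stage failure halts the run with
#' the stage name; outputs of completed stages persist. The returned
#' manifest records per-stage seeds, output files and their MD5 hashes, and
#' the architecture/training values in effect.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @return The run manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  # fail fast, before any stage runs
  if (!is.null(config$spectra_csv) && !file.exists(config$spectra_csv)) {
    abort(sprintf("Configured spectra file does not exist: %s", config$spectra_csv))
  }
  if (is.null(config$spectra_csv) && !"simulate" %in% config$stages) {
    abort("No input spectra: enable the simulate stage or set `spectra_csv`.")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("organspectra")),
    seed = config$seed,
    design_decisions = list(
      convolution_padding = "valid", bn_position = "before ELU",
      lr_decay_unit = "per epoch", argmax_tie_break = "lowest class index",
      class_weights = "1/n_c normalized to mean 1",
      atlas_sd = "sample SD (n-1) across annotation rows",
      median_renormalized = TRUE
    ),
    stages = list()
  )
  state <- new.env(parent = emptyenv())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    seed <- stage_seed(config$seed, name)
    outputs <- tryCatch(fun(seed), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest()
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seed = seed,
      outputs = lapply(outputs, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      })
    )
  }
  out <- function(...) file.path(config$out_dir, ...)

  run_stage("simulate", function(seed) {
    cfg <- config$simulate
    grid <- make_wavelength_grid(step_nm = cfg$grid_step)
    organs <- porcine_organs()[seq_len(cfg$n_organs)]
    lib <- make_fingerprint_library(organs, seed = seed, grid = grid)
    design <- make_standardized_design(cfg$n_pigs, organs, cfg$n_positions)
    comps <- calibrate_components(lib, design, organ_share = cfg$organ_share)
    state$spectra <- simulate_spectra(design, lib, comps, seed = seed,
                                      normalize = TRUE)
    write_spectra_csv(state$spectra, out("spectra.csv"))
    out("spectra.csv")
  })
  run_stage("preprocess", function(seed) {
    # with an external dataset this stage extracts median spectra from cubes;
    # on the simulated path it validates and canonicalizes the spectra table
    path <- config$spectra_csv %||% out("spectra.csv")
    spectra <- read_spectra_csv(path)
    required <- c("pig_id", "organ", "position_id", "angle", "repetition")
    missing <- setdiff(required, names(spectra))
    if (length(missing)) {
      abort(sprintf("Spectra table lacks column(s) %s.",
                    paste(missing, collapse = ", ")))
    }
    state$spectra <- dplyr::arrange(spectra, .data$pig_id, .data$position_id,
                                    .data$angle, .data$repetition)
    write_spectra_csv(state$spectra, out("spectra_preprocessed.csv"))
    out("spectra_preprocessed.csv")
  })
  run_stage("atlas", function(seed) {
    atlas <- compute_atlas(state$spectra)
    export_atlas(atlas, out("atlas"))
  })
  run_stage("variance", function(seed) {
    decomp <- decompose_variance(state$spectra,
                                 wavelengths = config$variance$wavelengths,
                                 bootstrap = config$variance$bootstrap,
                                 seed = seed)
    readr::write_csv(tibble::as_tibble(decomp), out("variance_decomposition.csv"))
    readr::write_csv(median_across_wavelengths(decomp), out("variance_medians.csv"))
    c(out("variance_decomposition.csv"), out("variance_medians.csv"))
  })
  run_stage("embed", function(seed) {
    cfg <- embedding_config(perplexity = config$embed$perplexity, seed = seed)
    emb <- embed_spectra(state$spectra, cfg, n_iter = config$embed$n_iter)
    readr::write_csv(emb$coordinates, out("embedding.csv"))
    out("embedding.csv")
  })
  run_stage("train", function(seed) {
    cfg <- config$train
    spectra <- state$spectra
    pigs <- sort(unique(spectra$pig_id))
    split <- split_train_test(
      pigs, pigs, dplyr::distinct(spectra, .data$pig_id, .data$organ),
      n_test = cfg$n_test, seed = seed
    )
    classes <- sort(unique(spectra$organ))
    arch <- cnn_architecture(n_classes = length(classes),
                             dropout_p = cfg$dropout_p,
                             input_bands = length(spectra_band_columns(spectra)))
    tc <- if (isTRUE(cfg$paper_scale)) {
      training_config(initial_lr = 0.0001, lr_decay = 0.9, batch_size = 20000L,
                      samples_per_epoch = 10000000L, epochs = 10L,
                      class_weighting = TRUE, oversampling = FALSE, seed = seed)
    } else {
      training_config(initial_lr = cfg$initial_lr, lr_decay = cfg$lr_decay,
                      batch_size = cfg$batch_size,
                      samples_per_epoch = cfg$samples_per_epoch,
                      epochs = cfg$epochs, seed = seed)
    }
    train_tbl <- spectra[spectra$pig_id %in% split$train_pigs, ]
    state$bundle <- train_lopo(train_tbl, arch, tc, classes = classes)
    state$split <- split
    jsonlite::write_json(
      list(train_pigs = split$train_pigs, test_pigs = split$test_pigs,
           val_accuracy = state$bundle$val_accuracy),
      out("training.json"), auto_unbox = TRUE, digits = NA
    )
    out("training.json")
  })
  run_stage("evaluate", function(seed) {
    spectra <- state$spectra
    test_tbl <- spectra[spectra$pig_id %in% state$split$test_pigs, ]
    preds <- ensemble_predict(state$bundle, test_tbl)
    report <- evaluate_predictions(test_tbl$organ, preds$pred, test_tbl$pig_id,
                                   classes = state$bundle$classes)
    jsonlite::write_json(
      c(glance(report), list(per_class = tidy(report))),
      out("evaluation.json"), auto_unbox = TRUE, digits = NA, force = TRUE
    )
    readr::write_csv(
      tibble::as_tibble(report$confusion_mean, rownames = "predicted"),
      out("confusion_mean.csv")
    )
    c(out("evaluation.json"), out("confusion_mean.csv"))
  })
  write_manifest()
  invisible(manifest)
}
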