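test_that("parameter count matches the per-layer closed form", {
  arch <- cnn_architecture()
  model <- build_model(arch, seed = 1)
  # independent oracle: conv out*(in*k+1); BN 2*channels; FC out*(in+1)
  len <- 100
  for (i in 1:3) len <- (len - 5 + 1) %/% 2 # valid conv + avg pool
  flat <- 16 * len # 16 channels remain after the third block
  conv_in <- c(1, 64, 32)
  conv_out <- c(64, 32, 16)
  oracle <- sum(conv_out * (conv_in * 5 + 1)) + # conv weights + biases
    sum(2 * conv_out) + # conv-block BN
    100 * (flat + 1) + 2 * 100 + # fc1 + BN
    50 * (100 + 1) + 2 * 50 + # fc2 + BN
    20 * (50 + 1) # final linear
  expect_equal(n_parameters(model), oracle)
  # within 1% of the published 34,300-weight figure
  expect_lt(abs(n_parameters(model) - 34300) / 34300, 0.01)
})

test_that("forward pass yields finite logits of the right shape", {
  arch <- cnn_architecture()
  model <- build_model(arch, seed = 2)
  set.seed(3)
  X <- matrix(runif(7 * 100), 7)
  X <- X / rowSums(X)
  model$classes <- porcine_organs()
  logits <- predict_logits(model, X)
  expect_equal(dim(logits), c(7L, 20L))
  expect_true(all(is.finite(logits)))
  probs <- predict(model, X, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, 7))
  # input too short for three conv/pool stages reports the minimal length
  expect_error(cnn_architecture(input_bands = 30), "minimal admissible length")
})

test_that("class weights follow the inverse-count rule normalized to mean one", {
  w <- class_weights(c(a = 100, b = 50))
  expect_equal(unname(w), c(2 / 3, 4 / 3))
  expect_equal(mean(class_weights(c(10, 20, 30, 40))), 1)
})

test_that("training is deterministic and solves a separable toy problem", {
  grid <- coarse_grid(10)
  organs <- porcine_organs()[1:2]
  lib <- make_fingerprint_library(organs, seed = 70, grid = grid)
  design <- make_standardized_design(4, organs, 2)
  sp <- simulate_spectra(design, lib, generative_components(0, 0, 1e-10),
                         seed = 71, normalize = TRUE)
  arch <- cnn_architecture(conv_filters = c(8L, 8L), conv_kernel = 3L,
                           fc_sizes = c(16L), n_classes = 2L, dropout_p = 0.1,
                           input_bands = grid$n_bands)
  tc <- training_config(batch_size = 32L, samples_per_epoch = 512L,
                        epochs = 2L, seed = 72L)
  fold <- train_fold(sp, "P01", arch, tc, classes = organs)
  expect_equal(mean(fold$predictions$pred == fold$predictions$truth), 1.0)
  # identical seeds give identical loss trajectories
  fold2 <- train_fold(sp, "P01", arch, tc, classes = organs)
  expect_identical(fold$model$history, fold2$model$history)
  expect_error(train_fold(sp, "P99", arch, tc, classes = organs), "not in")
})

test_that("classes absent from a fold drop their weight term with a warning", {
  grid <- coarse_grid(10)
  organs <- porcine_organs()[1:3]
  lib <- make_fingerprint_library(organs, seed = 73, grid = grid)
  design <- make_standardized_design(2, organs, 1)
  sp <- simulate_spectra(design, lib, generative_components(0, 0, 1e-8),
                         seed = 74, normalize = TRUE)
  sp <- sp[sp$organ != "colon", ]
  arch <- cnn_architecture(conv_filters = c(4L, 4L), conv_kernel = 3L,
                           fc_sizes = c(8L), n_classes = 3L, dropout_p = 0,
                           input_bands = grid$n_bands)
  tc <- training_config(batch_size = 16L, samples_per_epoch = 64L, epochs = 1L,
                        class_weighting = TRUE, seed = 75L)
  model <- build_model(arch, seed = 75)
  X <- spectra_matrix(sp)
  y <- factor(sp$organ, levels = organs)
  expect_warning(train_model(model, X, y, tc), "absent")
})

test_that("oversampling balances the classes drawn into batches", {
  # indirectly: heavily imbalanced two-class data still trains to separate
  grid <- coarse_grid(10)
  organs <- porcine_organs()[1:2]
  lib <- make_fingerprint_library(organs, seed = 76, grid = grid)
  design <- make_standardized_design(4, organs, 2)
  sp <- simulate_spectra(design, lib, generative_components(0, 0, 1e-8),
                         seed = 77, normalize = TRUE)
  sp <- sp[c(which(sp$organ == organs[1]), which(sp$organ == organs[2])[1:6]), ]
  arch <- cnn_architecture(conv_filters = c(6L, 6L), conv_kernel = 3L,
                           fc_sizes = c(12L), n_classes = 2L, dropout_p = 0,
                           input_bands = grid$n_bands)
  tc <- training_config(batch_size = 32L, samples_per_epoch = 512L, epochs = 2L,
                        class_weighting = FALSE, oversampling = TRUE, seed = 78L)
  model <- train_model(build_model(arch, seed = 78), spectra_matrix(sp),
                       factor(sp$organ, levels = organs), tc)
  pred <- predict(model, spectra_matrix(sp))
  expect_gt(mean(pred == sp$organ), 0.95)
})

test_that("uninformative labels drive accuracy to chance level", {
  # organ_effect_scale = 0 erases all class signal: held-out accuracy ~ 1/20
  design <- make_standardized_design(4, porcine_organs(), 1)
  lib <- make_fingerprint_library(porcine_organs(), seed = 85,
                                  grid = coarse_grid(20))
  comps <- generative_components(1e-6, 1e-6, 1e-6, organ_effect_scale = 0)
  sp <- simulate_spectra(design, lib, comps, seed = 86, normalize = TRUE)
  arch <- cnn_architecture(conv_filters = c(8L, 8L), conv_kernel = 3L,
                           fc_sizes = c(16L), n_classes = 20L, dropout_p = 0.1,
                           input_bands = 20L)
  tc <- training_config(batch_size = 128L, samples_per_epoch = 2048L,
                        epochs = 1L, seed = 87L)
  fold <- train_fold(sp, "P01", arch, tc)
  acc <- mean(fold$predictions$pred == fold$predictions$truth)
  expect_lt(abs(acc - 1 / 20), 0.05)
})

test_that("grid search is exhaustive and penalizes harmful dropout", {
  expect_equal(nrow(grid_combinations(default_grids())), 96L)
  expect_error(grid_combinations(list()), "non-empty")
  grid <- coarse_grid(10)
  organs <- porcine_organs()[1:3]
  lib <- make_fingerprint_library(organs, seed = 88, grid = grid)
  design <- make_standardized_design(3, organs, 1)
  sp <- simulate_spectra(design, lib, generative_components(1e-8, 1e-8, 1e-8),
                         seed = 89, normalize = TRUE)
  arch <- cnn_architecture(conv_filters = c(6L, 6L), conv_kernel = 3L,
                           fc_sizes = c(12L), n_classes = 3L, dropout_p = 0,
                           input_bands = grid$n_bands)
  base <- training_config(batch_size = 32L, samples_per_epoch = 512L,
                          epochs = 2L, seed = 90L)
  # single-point grid returns that point
  single <- grid_search(sp, grids = list(initial_lr = 0.001), base,
                        arch = arch, classes = organs)
  expect_equal(nrow(single$results), 1L)
  expect_equal(single$best$initial_lr, 0.001)
  # near-total dropout wrecks the fit; the search must pick the small p
  gs <- grid_search(sp, grids = list(dropout_p = c(0.05, 0.95)), base,
                    arch = arch, classes = organs)
  expect_equal(nrow(gs$results), 2L)
  expect_equal(gs$best$dropout_p, 0.05)
  expect_equal(gs$best_arch$dropout_p, 0.05)
})

test_that("train/test split honours the organ-coverage constraint", {
  pigs <- sprintf("P%02d", 1:12)
  std <- sprintf("P%02d", 1:6)
  everywhere <- tidyr::expand_grid(pig_id = pigs, organ = porcine_organs()[1:5])
  s <- split_train_test(pigs, std, everywhere, n_test = 3, seed = 1)
  expect_length(s$test_pigs, 3L)
  expect_length(s$train_pigs, 9L)
  expect_true(all(s$log$accepted[nrow(s$log)]))
  expect_equal(nrow(s$log), 1L) # trivially satisfied on the first draw
  # an organ held by one standardized pig is exempt from the two-sided
  # requirement and reported; the requirement still binds the other organs
  rare <- everywhere[!(everywhere$organ == "colon" & everywhere$pig_id != "P03"), ]
  found <- split_train_test(pigs, std, rare, n_test = 3, seed = 2,
                            max_attempts = 500)
  expect_equal(found$degenerate_organs, "colon")
  # oracle: enumerate all 3-subsets of the standardized pigs; with every
  # non-degenerate organ held by all pigs, every subset satisfies the
  # constraint, so the first seeded draw must be accepted
  subsets <- combn(std, 3, simplify = FALSE)
  admissible <- Filter(function(s) {
    others <- setdiff(std, s)
    all(vapply(porcine_organs()[1:5][-3], function(org) {
      any(rare$pig_id[rare$organ == org] %in% s) &&
        any(rare$pig_id[rare$organ == org] %in% others)
    }, logical(1)))
  }, subsets)
  expect_length(admissible, length(subsets))
  expect_equal(nrow(found$log), 1L)
  # taking every standardized pig into the test set leaves no standardized
  # training pig: the coverage constraint becomes unsatisfiable
  expect_error(split_train_test(std, std, everywhere[everywhere$pig_id %in% std, ],
                                n_test = 6, seed = 3, max_attempts = 50),
               "unsatisfiable")
})

test_that("mean-logit ensembling reduces to argmax rules", {
  arch <- cnn_architecture(conv_filters = c(4L, 4L), conv_kernel = 3L,
                           fc_sizes = c(8L), n_classes = 3L, dropout_p = 0,
                           input_bands = 20L)
  grid <- coarse_grid(20)
  organs <- porcine_organs()[1:3]
  lib <- make_fingerprint_library(organs, seed = 80, grid = grid)
  design <- make_standardized_design(2, organs, 1)
  sp <- simulate_spectra(design, lib, generative_components(0, 0, 1e-8),
                         seed = 81, normalize = TRUE)
  tc <- training_config(batch_size = 16L, samples_per_epoch = 128L, epochs = 1L,
                        seed = 82L)
  m <- train_model(build_model(arch, seed = 82), spectra_matrix(sp),
                   factor(sp$organ, levels = organs), tc)
  # singleton ensemble equals the model's own argmax
  single <- ensemble_predict(list(m), sp)
  own <- as.character(predict(m, spectra_matrix(sp)))
  expect_equal(single$pred, own)
  expect_error(ensemble_predict(list(), sp), "at least one")
})

test_that("logit ties break toward the lowest class index", {
  # two constant-output models built in the engine itself: logits (1,0,0)
  # and (0,1,0); the mean (0.5, 0.5, 0) must resolve to the first class
  constant_model <- function(logits) {
    structure(
      list(layers = list(
        list(kind = "flatten"),
        list(kind = "dense", W = matrix(0, 4, length(logits)), b = logits)
      ),
      arch = NULL, classes = c("stomach", "jejunum", "colon")),
      class = "spectral_cnn"
    )
  }
  sp <- tibble::tibble(pig_id = "P01", organ = "colon",
                       b500 = 0.3, b525 = 0.3, b550 = 0.2, b575 = 0.2)
  out <- ensemble_predict(list(constant_model(c(1, 0, 0)),
                               constant_model(c(0, 1, 0))), sp)
  expect_equal(out$pred, "stomach")
  expect_equal(unname(as.numeric(out[1, c("prob_stomach", "prob_jejunum")])),
               rep(exp(0.5) / (2 * exp(0.5) + 1), 2))
})
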