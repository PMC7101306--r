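# The training protocol: fresh stratified 80/20 splits, fixed learning
# settings, five independent trials, prediction on a held-out test set and
# best-test-accuracy selection. Selecting on the test set replicates the
# published protocol faithfully; it is a methodological caveat of that
# protocol (the test set participates in model selection) and is flagged
# here and in the returned objects.

#' Training configuration
#'
#' @param backbone `"small_cnn"` (default: the in-package convolutional
#'   network trained from scratch) or `"pretrained_transfer"` (train only a
#'   new final classification layer over features from `feature_fn`,
#'   replicating the transfer-learning final-layer-replacement recipe).
#' @param learning_rate default 0.001.
#' @param epochs maximum epochs, default 10.
#' @param validation_fraction fraction of the learning set held out for
#'   validation in each trial, default 0.20; validation accuracy is logged
#'   once per epoch.
#' @param trials number of independent trials, default 5.
#' @param batch_size minibatch size, default 32 (optimizer and batch size
#'   are package defaults: Adam, recorded here).
#' @param resolution input resolution (images are nearest-neighbour
#'   downscaled squares), default 40: the default layout's blocks are all
#'   at least 26 px in their narrow dimension, so 40x40 sampling of the
#'   871x494 canvas (spacing ~22 x ~12 px) still hits every block.
#' @param n_filters convolution filters in the small CNN, default 8.
#' @param base_seed seed from which per-trial seeds are derived.
#' @param feature_fn for `pretrained_transfer`: function mapping an image
#'   matrix (rows = flattened rasters in \[0,1\]) to a feature matrix.
#' @return A list of class `tda_config`.
#' @export
training_config <- function(backbone = c("small_cnn", "pretrained_transfer"),
                            learning_rate = 0.001, epochs = 10,
                            validation_fraction = 0.20, trials = 5,
                            batch_size = 32, resolution = 40, n_filters = 8,
                            base_seed = 1, feature_fn = NULL) {
  backbone <- match.arg(backbone)
  stopifnot(validation_fraction > 0, validation_fraction < 1, trials >= 1,
            epochs >= 1, learning_rate > 0, resolution %% 2 == 0)
  if (backbone == "pretrained_transfer" && is.null(feature_fn)) {
    stop("pretrained_transfer needs a feature_fn (locally available ",
         "pretrained weights wrapped as a feature extractor)")
  }
  structure(list(backbone = backbone, learning_rate = learning_rate,
                 epochs = epochs,
                 validation_fraction = validation_fraction, trials = trials,
                 batch_size = batch_size, resolution = resolution,
                 n_filters = n_filters, base_seed = base_seed,
                 optimizer = "adam", feature_fn = feature_fn),
            class = "tda_config")
}

#' Encode records as a classifier-ready image dataset
#'
#' Renders each record at full canvas size, optionally masks it to an
#' ablation variant, and nearest-neighbour downscales to
#' `resolution` x `resolution`.
#'
#' @param records list of validated records.
#' @param resolution square input resolution.
#' @param ablation `NULL` (full image), `"cruciform_only"`, or
#'   `"clinical_only"`.
#' @param rules,palette,layout encoder configuration.
#' @return A list of class `tda_dataset`: `x` (n x resolution^2*3 matrix in
#'   \[0,1\], rows = flattened rasters), `y` (factor RA/nonRA, `NA` where
#'   unlabelled), `ids`, `resolution`.
#' @export
encode_cohort <- function(records, resolution = 40, ablation = NULL,
                          rules = default_rules(),
                          palette = default_palette(),
                          layout = default_layout()) {
  n <- length(records)
  x <- matrix(0, n, resolution * resolution * 3)
  ids <- character(n)
  labs <- character(n)
  for (i in seq_len(n)) {
    img <- render_tda(records[[i]], rules, palette, layout)
    if (!is.null(ablation)) {
      img <- split_ablation(img, ablation, rules, palette, layout)
    }
    small <- downscale_tda(img, resolution, resolution)
    x[i, ] <- as.vector(small) / 255
    ids[i] <- records[[i]]$patient_id
    labs[i] <- records[[i]]$label
  }
  structure(list(x = x, y = factor(labs, levels = c("RA", "nonRA")),
                 ids = ids, resolution = resolution),
            class = "tda_dataset")
}

#' Stratified train/validation split
#'
#' Validation size is `round(fraction * n)`, allocated across the two
#' classes by largest remainder so the split is stratified by label;
#' reproducible from the seed.
#'
#' @param labels factor/character vector of RA/nonRA labels.
#' @param fraction validation fraction in (0, 1).
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
make_split <- function(labels, fraction = 0.2, seed = 1) {
  n <- length(labels)
  if (n < 2) stop("need at least 2 examples to split")
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop("both classes must be present to split")
  target <- round(fraction * n)
  per <- fraction * table(labels)
  base <- floor(per)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- names(sort(per - base, decreasing = TRUE))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  with_seed(seed, {
    val <- integer(0)
    for (cl in names(base)) {
      idx <- which(labels == cl)
      k <- min(base[[cl]], length(idx))
      val <- c(val, sort(sample(idx, k)))
    }
    val <- sort(val)
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}

subset_dataset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
                 ids = ds$ids[idx], resolution = ds$resolution),
            class = "tda_dataset")
}

#' Train one classifier
#'
#' Fits the configured backbone on the training images, logging training
#' loss and validation accuracy once per epoch; training stops at the
#' epoch cap. Seeded runs on identical data reproduce identical logs.
#'
#' @param train,validation `tda_dataset`s (validation may have 0 rows).
#' @param config a [training_config()].
#' @param seed integer seed for initialization and shuffling.
#' @return A model of class `tda_model` with the per-epoch `log`.
#' @export
train_once <- function(train, validation, config = training_config(),
                       seed = 1) {
  yidx <- as.integer(train$y)          # 1 = RA, 2 = nonRA
  if (anyNA(yidx)) stop("training set contains unlabelled records")
  if (length(unique(yidx)) < 2) {
    stop("training set must contain both classes")
  }
  if (config$backbone == "small_cnn") {
    res <- train$resolution
    fitted <- cnn_train(train$x, yidx, validation$x, as.integer(validation$y),
                        res = res, n_filters = config$n_filters,
                        lr = config$learning_rate, epochs = config$epochs,
                        batch_size = config$batch_size, seed = seed)
  } else {
    feats <- config$feature_fn(train$x)
    fitted <- head_train(feats, yidx, lr = config$learning_rate,
                         epochs = config$epochs,
                         batch_size = config$batch_size, seed = seed)
    if (!is.null(validation$x) && nrow(validation$x) > 0) {
      pv <- head_predict_probs(fitted$net,
                               config$feature_fn(validation$x))
      fitted$log$val_accuracy[nrow(fitted$log)] <-
        mean((pv[, 1] >= 0.5) == (as.integer(validation$y) == 1))
    }
  }
  structure(list(backbone = config$backbone, net = fitted$net,
                 log = fitted$log, config = config, seed = seed,
                 levels = c("RA", "nonRA"),
                 resolution = train$resolution),
            class = "tda_model")
}

#' Predict labels and scores for images
#'
#' @param object a `tda_model`.
#' @param newdata a `tda_dataset` or an image matrix (rows = flattened
#'   rasters in \[0,1\]) at the model's training resolution.
#' @param ... unused.
#' @return data.frame with `label` (RA/nonRA) and `score` (probability of
#'   RA); deterministic for a fixed model.
#' @export
predict.tda_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "tda_dataset")) newdata$x else newdata
  if (!is.matrix(x)) stop("newdata must be a tda_dataset or a matrix")
  if (nrow(x) == 0) {
    return(data.frame(label = character(0), score = numeric(0)))
  }
  expected <- object$resolution^2 * 3
  if (object$backbone == "small_cnn" && ncol(x) != expected) {
    stop(sprintf("images have %d values per row; model expects %d",
                 ncol(x), expected))
  }
  probs <- if (object$backbone == "small_cnn") {
    cnn_predict_probs(object$net, x)
  } else {
    head_predict_probs(object$net, object$config$feature_fn(x))
  }
  data.frame(label = ifelse(probs[, 1] >= 0.5, "RA", "nonRA"),
             score = probs[, 1])
}

#' Run the five-trial protocol and select the best model
#'
#' Each trial draws a fresh seeded stratified split of the learning set,
#' trains from a fresh initialization, and scores the held-out test set;
#' the trial with the highest test accuracy is selected (ties: lowest
#' index), exactly as in the published protocol. The learning and test
#' sets must be disjoint by patient id, which is enforced, never assumed.
#'
#' @param learning,test `tda_dataset`s with labels.
#' @param config a [training_config()].
#' @return A list of class `tda_trials`: per-trial results (seed, split,
#'   per-epoch log, per-test-image predictions, test accuracy), the
#'   selected index, the selected model, and the config.
#' @export
run_trials <- function(learning, test, config = training_config()) {
  overlap <- intersect(learning$ids, test$ids)
  if (length(overlap) > 0) {
    stop("learning and test sets share patient ids: ",
         paste(utils::head(overlap, 3), collapse = ", "))
  }
  trials <- vector("list", config$trials)
  for (i in seq_len(config$trials)) {
    seed_i <- config$base_seed + 7919L * i
    split <- make_split(learning$y, config$validation_fraction, seed_i)
    model <- train_once(subset_dataset(learning, split$train),
                        subset_dataset(learning, split$validation),
                        config, seed = seed_i)
    preds <- predict(model, test)
    acc <- mean(preds$label == as.character(test$y))
    trials[[i]] <- list(trial = i, seed = seed_i, split = split,
                        log = model$log,
                        predictions = data.frame(id = test$ids,
                                                 truth = as.character(test$y),
                                                 label = preds$label,
                                                 score = preds$score),
                        accuracy = acc, model = model)
  }
  accs <- vapply(trials, `[[`, numeric(1), "accuracy")
  selected <- which.max(accs)   # ties resolve to the lowest index
  structure(list(trials = trials, accuracies = accs, selected = selected,
                 model = trials[[selected]]$model, config = config,
                 note = paste("selection uses the held-out test set,",
                              "replicating the published protocol")),
            class = "tda_trials")
}

#' @export
print.tda_trials <- function(x, ...) {
  cat(sprintf("<tda_trials> %d trials, accuracies: %s; selected trial %d\n",
              length(x$trials),
              paste(sprintf("%.0f%%", 100 * x$accuracies), collapse = ", "),
              x$selected))
  invisible(x)
}
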