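# U-Net ventricle segmentation: model construction, dice loss, training
# with Adam, grouped cross-validation over patient groups, and mask
# prediction.

#' U-Net architecture configuration
#'
#' Encoder levels halve the resolution (2x2 max pooling) while feature-map
#' widths grow; the decoder mirrors the encoder with stride-2 transpose
#' convolutions and concatenating skip connections. Every convolution is
#' 3x3 stride 1 followed by batch normalization and ReLU except the final
#' 1x1 layer, which produces one channel through a sigmoid. The default
#' widths are the clinical-scale network; `scale_widths()` produces
#' desk-scale variants with the same topology.
#'
#' @param widths strictly increasing feature-map widths, one per level.
#' @param input_size `c(height, width)` of input slices; each must be
#'   divisible by `2^(levels - 1)`.
#' @return A `unet_config`.
#' @export
unet_config <- function(widths = c(32L, 64L, 128L, 256L, 320L),
                        input_size = c(256L, 256L)) {
  widths <- as.integer(widths)
  input_size <- as.integer(input_size)
  if (length(widths) < 2L) stop("need at least two resolution levels")
  if (any(diff(widths) <= 0L)) stop("feature-map widths must strictly increase")
  if (any(widths < 1L)) stop("feature-map widths must be positive")
  down <- 2L^(length(widths) - 1L)
  if (length(input_size) != 2L || any(input_size < down) ||
      any(input_size %% down != 0L)) {
    stop(sprintf(
      "incompatible input size: each dimension must be a multiple of %d",
      down))
  }
  structure(list(widths = widths, input_size = input_size,
                 levels = length(widths)),
            class = "unet_config")
}

#' @rdname unet_config
#' @param cfg a `unet_config` to rescale.
#' @param factor divisor applied to every width (e.g. 8 for desk-scale).
#' @export
scale_widths <- function(cfg, factor) {
  stopifnot(inherits(cfg, "unet_config"), factor >= 1)
  unet_config(pmax(1L, as.integer(cfg$widths / factor)), cfg$input_size)
}

#' Training regime configuration
#'
#' Defaults are the regime used throughout: dice loss, Adam, learning rate
#' 0.003, batch size 20, 30 epochs.
#'
#' @param learning_rate Adam step size, > 0.
#' @param batch_size slices per minibatch, >= 1.
#' @param epochs full passes over the training set, >= 1.
#' @param seed integer seed fixing shuffling (weight initialization is
#'   seeded separately in [build_unet()]).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 0.003, batch_size = 20L,
                         epochs = 30L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

#' Build an (untrained) U-Net model
#'
#' Weights use He initialization from a dedicated deterministic generator.
#'
#' @param cfg a [unet_config()].
#' @param seed integer weight-initialization seed.
#' @return A `unet_model` with fields `config`, `params`, `seed`.
#' @export
build_unet <- function(cfg = unet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "unet_config"))
  params <- unet_init_cpp(cfg$widths, as.integer(seed))
  structure(list(config = cfg, params = params, seed = as.integer(seed),
                 loss_history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> levels %d, widths %s, input %dx%d, %s\n",
              x$config$levels, paste(x$config$widths, collapse = "/"),
              x$config$input_size[1], x$config$input_size[2],
              if (is.null(x$loss_history)) "untrained"
              else sprintf("trained (%d epochs, best %.4f)",
                           length(x$loss_history), min(x$loss_history))))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Counts weights, biases and batch-norm scale/shift; running batch-norm
#' statistics are not trainable and are excluded.
#'
#' @param model a `unet_model`.
#' @return Integer parameter count.
#' @export
unet_n_params <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  nm <- names(model$params)
  keep <- !grepl("_(rmean|rvar)$", nm)
  sum(vapply(model$params[keep], length, 0L))
}

#' Dice loss between a predicted map and a reference mask
#'
#' `1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)`. The smoothing
#' term `eps = 1` keeps the loss defined (and 0) when both masks are empty.
#'
#' @param pred predicted map, values in `[0, 1]`.
#' @param label binary reference mask, same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in `[0, 1]`; 0 for perfect binary agreement.
#' @export
dice_loss <- function(pred, label, eps = 1) {
  if (!identical(dim2(pred), dim2(label))) {
    stop("incompatible shapes: prediction and label differ")
  }
  p <- as.numeric(pred); g <- as.numeric(label)
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("prediction values must lie in [0, 1]")
  }
  1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' @rdname dice_loss
#' @details `dice_coefficient()` is the overlap itself (no smoothing),
#'   computed on binarized inputs; conventionally 1 when both are empty.
#' @export
dice_coefficient <- function(pred, label) {
  if (!identical(dim2(pred), dim2(label))) {
    stop("incompatible shapes: prediction and label differ")
  }
  p <- as.numeric(pred) > 0.5; g <- as.numeric(label) > 0.5
  denom <- sum(p) + sum(g)
  if (denom == 0) return(1)
  2 * sum(p & g) / denom
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Bundle labeled slices with patient-group ids
#'
#' @param images numeric array `(H, W, N)` of normalized slices in `[0, 1]`.
#' @param masks 0/1 array of the same shape.
#' @param groups length-N patient-group id per slice.
#' @return A `labeled_slice_set`.
#' @export
labeled_slice_set <- function(images, masks, groups) {
  stopifnot(length(dim(images)) == 3L)
  if (!identical(dim(images), dim(masks))) {
    stop("incompatible shapes: images and masks differ")
  }
  if (length(groups) != dim(images)[3]) {
    stop("one group id per slice is required")
  }
  if (!all(masks %in% c(0, 1))) stop("labels must be binary 0/1")
  structure(list(images = images, masks = masks, groups = groups),
            class = "labeled_slice_set")
}

#' Train a U-Net with dice loss and Adam
#'
#' Deterministic given the model seed, `cfg$seed` and a fixed thread count.
#' The returned model carries the weights of the best epoch (lowest
#' training dice loss) and the per-epoch loss history.
#'
#' @param model a [build_unet()] model.
#' @param data a [labeled_slice_set()] (group ids unused here), or a plain
#'   list with `images` and `masks` arrays.
#' @param cfg a [train_config()].
#' @return The trained `unet_model` with `loss_history` and `best_epoch`.
#' @export
train_unet <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  images <- data$images; masks <- data$masks
  if (is.null(images) || length(dim(images)) != 3L || dim(images)[3] < 1L) {
    stop("nothing to train on")
  }
  insz <- model$config$input_size
  if (!identical(as.integer(dim(images)[1:2]), insz)) {
    stop(sprintf("incompatible input size: model expects %dx%d slices",
                 insz[1], insz[2]))
  }
  fit <- unet_train_cpp(model$params, model$config$widths, images, masks,
                        cfg$learning_rate, cfg$batch_size, cfg$epochs,
                        cfg$seed, dice_eps = 1)
  model$params <- fit$params
  model$loss_history <- as.numeric(fit$loss_history)
  model$best_epoch <- fit$best_epoch
  model
}

#' Predict a binary ventricle mask for one or more slices
#'
#' Runs the network in inference mode (running batch-norm statistics) and
#' thresholds the sigmoid output.
#'
#' @param model a trained `unet_model`.
#' @param slices matrix `(H, W)` or array `(H, W, N)`, normalized to
#'   `[0, 1]`.
#' @param threshold sigmoid cutoff, default 0.5.
#' @return 0/1 integer array matching the input shape.
#' @export
predict_mask <- function(model, slices, threshold = 0.5) {
  prob <- predict_prob(model, slices)
  array(as.integer(prob >= threshold), dim(prob))
}

#' @rdname predict_mask
#' @export
predict_prob <- function(model, slices) {
  stopifnot(inherits(model, "unet_model"))
  x <- slices
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("slices must be (H, W) or (H, W, N)")
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9) {
    stop("normalize first: slice intensities must lie in [0, 1]")
  }
  insz <- model$config$input_size
  if (!identical(as.integer(dim(x)[1:2]), insz)) {
    stop(sprintf("incompatible input size: model expects %dx%d slices",
                 insz[1], insz[2]))
  }
  n <- dim(x)[3]
  out <- array(0, dim(x))
  # chunked inference keeps im2col buffers small
  for (start in seq(1L, n, by = 16L)) {
    idx <- start:min(start + 15L, n)
    out[, , idx] <- unet_forward_cpp(model$params, model$config$widths,
                                     x[, , idx, drop = FALSE], train = FALSE)
  }
  if (is.matrix(slices)) out <- array(out, dim(slices)) else out
  out
}

#' Grouped k-fold assignment at the patient level
#'
#' Distinct group ids are sorted and split into `n_folds` consecutive,
#' equally sized test sets, so no patient contributes slices to both the
#' train and test side of any fold. With 10 groups and 5 folds each test
#' fold holds exactly 2 groups and the remaining 8 train.
#'
#' @param groups vector of group ids (one per slice), or a
#'   [labeled_slice_set()].
#' @param n_folds number of folds.
#' @param fold_groups optional explicit list of group-id vectors, one per
#'   fold, overriding the sorted-consecutive default.
#' @return A `grouped_cv` list: `folds` (list of test-group vectors),
#'   `assignment` (data.frame `slice`, `group`, `fold`) and `n_folds`.
#' @export
grouped_cross_validation <- function(groups, n_folds = 5L,
                                     fold_groups = NULL) {
  if (inherits(groups, "labeled_slice_set")) groups <- groups$groups
  ids <- sort(unique(groups))
  if (length(ids) < n_folds) {
    stop("insufficient groups: need at least one group per fold")
  }
  if (is.null(fold_groups)) {
    if (length(ids) %% n_folds != 0L) {
      stop("insufficient groups: group count must divide evenly into folds")
    }
    per <- length(ids) %/% n_folds
    fold_groups <- split(ids, rep(seq_len(n_folds), each = per))
  } else {
    if (!setequal(unlist(fold_groups), ids) ||
        anyDuplicated(unlist(fold_groups)) > 0L) {
      stop("fold_groups must partition the group ids")
    }
  }
  fold_of <- integer(length(groups))
  for (f in seq_along(fold_groups)) {
    fold_of[groups %in% fold_groups[[f]]] <- f
  }
  structure(
    list(folds = unname(fold_groups),
         assignment = data.frame(slice = seq_along(groups), group = groups,
                                 fold = fold_of),
         n_folds = as.integer(n_folds)),
    class = "grouped_cv"
  )
}

#' Run grouped cross-validation training and evaluation
#'
#' For each fold, trains a fresh model on the training groups and computes
#' the dice coefficient, pixel sensitivity, specificity and accuracy on the
#' held-out groups.
#'
#' @param data a [labeled_slice_set()].
#' @param unet_cfg a [unet_config()].
#' @param train_cfg a [train_config()].
#' @param cv a [grouped_cross_validation()] assignment (defaults to 5
#'   folds over `data$groups`).
#' @param folds which folds to run (default all).
#' @param threshold sigmoid cutoff for the predicted masks.
#' @return data.frame with one row per fold: `fold`, `test_groups`,
#'   `train_dice`, `test_dice`, `sensitivity`, `specificity`, `accuracy`.
#' @export
run_grouped_cv <- function(data, unet_cfg, train_cfg = train_config(),
                           cv = grouped_cross_validation(data),
                           folds = seq_len(cv$n_folds), threshold = 0.5) {
  stopifnot(inherits(data, "labeled_slice_set"))
  out <- lapply(folds, function(f) {
    test_idx <- cv$assignment$fold == f
    train_idx <- !test_idx
    model <- build_unet(unet_cfg, seed = train_cfg$seed + f)
    model <- train_unet(
      model,
      list(images = data$images[, , train_idx, drop = FALSE],
           masks = data$masks[, , train_idx, drop = FALSE]),
      train_cfg)
    pred_tr <- predict_mask(model, data$images[, , train_idx, drop = FALSE],
                            threshold)
    pred_te <- predict_mask(model, data$images[, , test_idx, drop = FALSE],
                            threshold)
    cc <- confusion_counts(pred_te, data$masks[, , test_idx, drop = FALSE])
    pm <- pixel_metrics(cc)
    data.frame(
      fold = f,
      test_groups = paste(cv$folds[[f]], collapse = "+"),
      train_dice = dice_coefficient(pred_tr,
                                    data$masks[, , train_idx, drop = FALSE]),
      test_dice = dice_coefficient(pred_te,
                                   data$masks[, , test_idx, drop = FALSE]),
      sensitivity = pm[["sensitivity"]],
      specificity = pm[["specificity"]],
      accuracy = pm[["accuracy"]])
  })
  do.call(rbind, out)
}
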