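# Patient-aware splitting, the Adam training loop with patience-based early
# stopping and best-weight restoration, fine-tuning, and per-image evaluation.

#' Training configuration
#'
#' Defaults follow the training protocol of the segmentation study: Adam with
#' learning rate 1e-5, batch size 2, early stopping after 10 epochs without
#' validation-loss improvement.
#'
#' @param learning_rate Adam step size (default 1e-5).
#' @param batch_size Images per gradient step (default 2).
#' @param patience Consecutive epochs without validation-loss improvement
#'   before stopping (default 10).
#' @param max_epochs Hard epoch cap.
#' @param class_weights A [class_weights()] object, or `NULL` to derive
#'   inverse-frequency weights from the training masks.
#' @param seed Seed for shuffling and any stochastic component.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 2L, patience = 10L,
                         max_epochs = 100L, class_weights = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, patience >= 1, max_epochs >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 class_weights = class_weights,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Write / read a training configuration as YAML
#'
#' The YAML mirrors the [train_config()] keys one-to-one.
#'
#' @param cfg A `train_config`.
#' @param path YAML file path.
#' @export
save_train_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "train_config"))
  x <- unclass(cfg)
  if (!is.null(x$class_weights)) x$class_weights <- unclass(x$class_weights)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_train_config
#' @export
load_train_config <- function(path) {
  x <- yaml::read_yaml(path)
  cw <- if (!is.null(x$class_weights)) {
    class_weights(x$class_weights$w_background, x$class_weights$w_wound)
  }
  train_config(learning_rate = x$learning_rate, batch_size = x$batch_size,
               patience = x$patience, max_epochs = x$max_epochs,
               class_weights = cw, seed = x$seed)
}

#' Split records into train/validation/test by patient
#'
#' Patients (not images) are shuffled by the seed and apportioned to the
#' three subsets by largest-remainder rounding of the ratios, so all images
#' of a patient always travel together and no patient leaks across subsets.
#'
#' @param records Data frame with columns `image_id` and `patient_id`.
#' @param ratios Train/validation/test proportions; must sum to 1.
#' @param seed Shuffling seed.
#' @return List of class `split_plan`: `train_ids`, `val_ids`, `test_ids`
#'   (image ids), the patient assignment, and the ratios.
#' @export
split_by_patient <- function(records, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (!all(c("image_id", "patient_id") %in% names(records)) || nrow(records) == 0) {
    stop("records must be a non-empty data frame with image_id and patient_id")
  }
  if (abs(sum(ratios) - 1) > 1e-9 || length(ratios) != 3L || any(ratios < 0)) {
    stop("ratios must be three non-negative numbers summing to 1")
  }
  patients <- unique(records$patient_id)
  perm <- .with_seed(as.integer(seed), sample.int(length(patients)))
  patients <- patients[perm]
  P <- length(patients)
  quota <- ratios * P
  base <- floor(quota)
  rem <- P - sum(base)
  # distribute the remainder by largest fractional part; ties favour the
  # earlier subset (train, then validation, then test)
  ord <- order(-(quota - base), seq_along(ratios))
  extra <- integer(3)
  if (rem > 0) extra[ord[seq_len(rem)]] <- 1L
  sizes <- base + extra
  assign_subset <- rep(c("train", "val", "test"), times = sizes)
  pat_subset <- stats::setNames(assign_subset, patients)
  subset_of <- pat_subset[as.character(records$patient_id)]
  plan <- structure(list(train_ids = records$image_id[subset_of == "train"],
                         val_ids = records$image_id[subset_of == "val"],
                         test_ids = records$image_id[subset_of == "test"],
                         patients = pat_subset, ratios = ratios,
                         seed = as.integer(seed)),
                    class = "split_plan")
  plan
}

#' Per-subset wound-pixel balance report
#'
#' Post-hoc check of the wound-pixel distribution across the subsets of a
#' split plan (count of images, total and mean foreground pixels per image).
#'
#' @param plan A [split_by_patient()] plan.
#' @param scenes List of `wound_scene` objects covering the plan's image ids.
#' @return Data frame with one row per subset.
#' @export
split_balance <- function(plan, scenes) {
  stopifnot(inherits(plan, "split_plan"))
  ids <- vapply(scenes, function(s) s$image_id, character(1))
  fg <- vapply(scenes, function(s) sum(s$mask), numeric(1))
  one <- function(subset, sel) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop("scenes are missing ids from the plan")
    data.frame(subset = subset, n_images = length(idx),
               total_wound_pixels = sum(fg[idx]),
               mean_wound_pixels = if (length(idx)) mean(fg[idx]) else 0)
  }
  rbind(one("train", plan$train_ids), one("val", plan$val_ids),
        one("test", plan$test_ids))
}

# ---- internal batching and optimisation ------------------------------------

.scenes_x4 <- function(scenes) {
  d <- dim(scenes[[1]]$image)
  x <- array(0, c(length(scenes), d))
  for (b in seq_along(scenes)) x[b, , , ] <- scenes[[b]]$image / 255
  x
}

.scenes_t4 <- function(scenes) {
  d <- dim(scenes[[1]]$mask)
  t4 <- array(0, c(length(scenes), d, 1L))
  for (b in seq_along(scenes)) t4[b, , , 1] <- scenes[[b]]$mask
  t4
}

.adam_init <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0
  e$m <- list()
  e$v <- list()
  e
}

.adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (!(nm %in% net$trainable)) next
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- as.numeric(g) * 0
      state$v[[nm]] <- as.numeric(g) * 0
    }
    net$params[[nm]] <- .adam_update(net$params[[nm]], g, state$m[[nm]],
                                     state$v[[nm]], lr, beta1, beta2, eps,
                                     c1, c2)
  }
  net
}

.val_metrics <- function(net, scenes, w, threshold = 0.5) {
  losses <- numeric(length(scenes))
  dices <- numeric(length(scenes))
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    x4 <- .scenes_x4(scenes[i])
    p <- .forward_net(net, x4, train = FALSE)$prob
    losses[i] <- weighted_cross_entropy(p, .scenes_t4(scenes[i]), w)
    dices[i] <- dice_coefficient(matrix(as.integer(p[1, , , 1] > threshold),
                                        nrow(sc$mask), ncol(sc$mask)), sc$mask)
  }
  list(loss = mean(losses), dice = mean(dices))
}

# patience-based early stopping with best-state restoration. epoch_fn(e)
# runs one epoch and returns the training loss; val_fn(e) returns the
# validation loss; snapshot_fn() captures the current best state.
.early_stop_loop <- function(max_epochs, patience, epoch_fn, val_fn,
                             snapshot_fn = function() NULL,
                             min_delta = 1e-8) {
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  stopped <- 0L
  for (e in seq_len(max_epochs)) {
    tl <- epoch_fn(e)
    vl <- val_fn(e)
    history <- rbind(history, data.frame(epoch = e, train_loss = tl, val_loss = vl))
    stopped <- e
    if (best - vl >= min_delta) {
      best <- vl
      best_epoch <- e
      wait <- 0L
      snapshot_fn()
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(history = history, best_epoch = best_epoch, stopped_epoch = stopped,
       best_val = best)
}

#' Train a segmentation network
#'
#' Adam optimisation of the weighted cross-entropy over seeded shuffled
#' mini-batches. Training stops when the validation loss has not strictly
#' decreased (by at least 1e-8) for `patience` consecutive epochs, or at
#' `max_epochs`; the weights of the best-validation epoch are restored.
#'
#' @param net A `wound_network`.
#' @param train_set,val_set Non-empty lists of `wound_scene` objects with
#'   identical extents (multiples of 16).
#' @param cfg A [train_config()].
#' @param val_loss_fn Optional override `function(net, epoch) -> numeric`
#'   used as the validation loss (for protocol testing); when supplied the
#'   real validation pass is skipped.
#' @param verbose Emit a per-epoch progress message.
#' @return List with the trained `net` and a `training_history` (per-epoch
#'   train/validation loss, validation Dice, `best_epoch`, `stopped_epoch`).
#' @export
train <- function(net, train_set, val_set, cfg = train_config(),
                  val_loss_fn = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "wound_network"), inherits(cfg, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0) {
    stop("training and validation sets must be non-empty")
  }
  w <- cfg$class_weights
  if (is.null(w)) w <- derive_class_weights(lapply(train_set, `[[`, "mask"))
  state <- .adam_init()
  n <- length(train_set)
  best_params <- NULL
  val_dices <- numeric(0)
  rng <- .rng_stream(cfg$seed)

  epoch_fn <- function(e) {
    ord <- rng(function() sample.int(n))
    losses <- c()
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      x4 <- .scenes_x4(train_set[idx])
      t4 <- .scenes_t4(train_set[idx])
      fw <- .forward_net(net, x4, train = TRUE)
      for (nm in names(fw$bn_updates)) net$params[[nm]] <<- fw$bn_updates[[nm]]
      losses <- c(losses, weighted_cross_entropy(fw$prob, t4, w))
      du <- .wce_logit_grad(fw$prob, t4, w)
      grads <- .backward_net(net, fw$cache, du)
      rm(fw, du, x4, t4)
      net <<- .adam_step(net, grads, state, cfg$learning_rate)
      rm(grads)
    }
    mean(losses)
  }
  val_fn <- function(e) {
    if (!is.null(val_loss_fn)) {
      val_dices <<- c(val_dices, NA_real_)
      vl <- val_loss_fn(net, e)
    } else {
      vm <- .val_metrics(net, val_set, w)
      val_dices <<- c(val_dices, vm$dice)
      vl <- vm$loss
    }
    if (verbose) {
      message(sprintf("epoch %d: val loss %.5f, val dice %s", e, vl,
                      if (length(val_dices) && !is.na(val_dices[e]))
                        sprintf("%.4f", val_dices[e]) else "-"))
    }
    vl
  }
  snapshot_fn <- function() best_params <<- net$params

  res <- .early_stop_loop(cfg$max_epochs, cfg$patience, epoch_fn, val_fn,
                          snapshot_fn)
  if (!is.null(best_params)) net$params <- best_params
  history <- structure(list(epochs = cbind(res$history,
                                           val_dice = val_dices[seq_len(nrow(res$history))]),
                            best_epoch = res$best_epoch,
                            stopped_epoch = res$stopped_epoch,
                            class_weights = w),
                       class = "training_history")
  list(net = net, history = history)
}

# deterministic RNG stream isolated from the global RNG
.rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- .with_seed(as.integer(seed), get(".Random.seed", globalenv()))
  function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", e$state, globalenv())
    on.exit({
      e$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    f()
  }
}

#' Fine-tune a previously trained network on a new distribution
#'
#' Runs the identical training loop starting from the incoming weights, with
#' all layers trainable at the same learning rate and a fresh optimiser
#' state. `max_epochs = 0` returns the network unchanged.
#'
#' @inheritParams train
#' @param new_train_set,new_val_set Scene lists from the new distribution.
#' @return As [train()].
#' @export
fine_tune <- function(net, new_train_set, new_val_set, cfg = train_config()) {
  if (cfg$max_epochs == 0L) {
    history <- structure(list(epochs = data.frame(epoch = integer(),
                                                  train_loss = numeric(),
                                                  val_loss = numeric(),
                                                  val_dice = numeric()),
                              best_epoch = 0L, stopped_epoch = 0L,
                              class_weights = cfg$class_weights),
                         class = "training_history")
    return(list(net = net, history = history))
  }
  train(net, new_train_set, new_val_set, cfg)
}

#' Write a training history as CSV
#'
#' @param history A `training_history`.
#' @param path Output CSV.
#' @export
save_history <- function(history, path) {
  stopifnot(inherits(history, "training_history"))
  write.csv(history$epochs, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate a network on a scene set
#'
#' Per-image Dice and IoU on binarised predictions, plus their arithmetic
#' mean and population standard deviation across images (metrics are computed
#' per image and then averaged, never pooled over the corpus).
#'
#' @param net A `wound_network` (ignored when `predictor` is given).
#' @param test_set Non-empty list of `wound_scene` objects.
#' @param threshold Binarisation threshold (strict `>`), default 0.5.
#' @param predictor Optional override `function(scene) -> binary mask` used
#'   in place of network inference.
#' @return List with `samples` (data frame `image_id`, `dice`, `iou`) and
#'   `summary` (`mean_dice`, `sd_dice`, `mean_iou`, `sd_iou`).
#' @export
evaluate_network <- function(net, test_set, threshold = 0.5, predictor = NULL) {
  if (length(test_set) == 0) stop("test set must be non-empty")
  rows <- lapply(test_set, function(sc) {
    pred <- if (is.null(predictor)) {
      predict_mask(net, sc$image, threshold)
    } else {
      predictor(sc)
    }
    metric_sample(pred, sc$mask, sc$image_id)
  })
  samples <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  list(samples = samples,
       summary = list(mean_dice = mean(samples$dice), sd_dice = pop_sd(samples$dice),
                      mean_iou = mean(samples$iou), sd_iou = pop_sd(samples$iou)))
}

#' Write per-image metric samples as CSV
#'
#' @param samples Data frame from [evaluate_network()].
#' @param path Output CSV.
#' @param variant,dataset Labels added as columns.
#' @export
save_metrics <- function(samples, path, variant = "", dataset = "") {
  out <- cbind(samples, variant = variant, dataset = dataset)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
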