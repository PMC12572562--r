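# Patient-aware splitting, early-stopping semantics, fine-tuning and
# evaluation conventions.

test_that("ten single-image patients split 7/2/1", {
  rec <- data.frame(image_id = sprintf("i%02d", 1:10),
                    patient_id = sprintf("p%02d", 1:10))
  plan <- split_by_patient(rec, c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(length(plan$train_ids), 7L)
  expect_equal(length(plan$val_ids), 2L)
  expect_equal(length(plan$test_ids), 1L)
  expect_equal(sort(c(plan$train_ids, plan$val_ids, plan$test_ids)),
               sort(rec$image_id))
})

test_that("all images of a patient travel together", {
  rec <- data.frame(image_id = sprintf("i%02d", 1:12),
                    patient_id = c(rep("pA", 3), sprintf("p%02d", 4:12)))
  for (seed in 1:10) {
    plan <- split_by_patient(rec, seed = seed)
    sets <- list(plan$train_ids, plan$val_ids, plan$test_ids)
    hitting <- vapply(sets, function(s) any(c("i01", "i02", "i03") %in% s),
                      logical(1))
    expect_equal(sum(hitting), 1L)
    expect_equal(length(intersect(plan$train_ids, plan$val_ids)), 0L)
    expect_equal(length(intersect(plan$train_ids, plan$test_ids)), 0L)
    expect_equal(length(intersect(plan$val_ids, plan$test_ids)), 0L)
  }
})

test_that("splitting is deterministic and validates ratios", {
  rec <- data.frame(image_id = sprintf("i%02d", 1:9),
                    patient_id = sprintf("p%02d", 1:9))
  expect_identical(split_by_patient(rec, seed = 4), split_by_patient(rec, seed = 4))
  expect_error(split_by_patient(rec, c(0.7, 0.2, 0.2)), "summing to 1")
})

test_that("largest-remainder apportionment favours the larger remainder", {
  # 5 patients at (0.7, 0.2, 0.1): quotas 3.5/1.0/0.5, one leftover seat goes
  # to the larger fractional remainder with ties to the earlier subset
  rec <- data.frame(image_id = sprintf("i%d", 1:5), patient_id = sprintf("p%d", 1:5))
  plan <- split_by_patient(rec, c(0.7, 0.2, 0.1), seed = 2)
  expect_equal(vapply(list(plan$train_ids, plan$val_ids, plan$test_ids),
                      length, integer(1)), c(4L, 1L, 0L))
})

test_that("never-improving validation stops at best + patience exactly", {
  sched <- c(1, rep(2, 50))  # improves at epoch 1, never again
  res <- woundseg:::.early_stop_loop(50, 10,
                                     epoch_fn = function(e) 0,
                                     val_fn = function(e) sched[e])
  expect_equal(res$best_epoch, 1L)
  expect_equal(res$stopped_epoch, 11L)
  expect_equal(nrow(res$history), 11L)
})

test_that("a strictly improving schedule runs to max_epochs", {
  res <- woundseg:::.early_stop_loop(17, 10,
                                     epoch_fn = function(e) 0,
                                     val_fn = function(e) 1 / e)
  expect_equal(res$stopped_epoch, 17L)
  expect_equal(res$best_epoch, 17L)
})

test_that("sub-tolerance improvements do not reset the patience counter", {
  sched <- function(e) if (e == 1) 1 else 1 - e * 1e-12
  res <- woundseg:::.early_stop_loop(40, 5,
                                     epoch_fn = function(e) 0,
                                     val_fn = sched)
  expect_equal(res$best_epoch, 1L)
  expect_equal(res$stopped_epoch, 6L)
})

test_that("late improvements reset the counter and snapshots fire", {
  sched <- c(5, 4, 4.5, 4.6, 3, 3.1, 3.2, 3.3, 3.4)
  snaps <- 0
  res <- woundseg:::.early_stop_loop(9, 4,
                                     epoch_fn = function(e) 0,
                                     val_fn = function(e) sched[e],
                                     snapshot_fn = function() snaps <<- snaps + 1)
  expect_equal(res$best_epoch, 5L)
  expect_equal(res$stopped_epoch, 9L)
  expect_equal(snaps, 3)  # epochs 1, 2 and 5
})

test_that("train wires the injected validation schedule into early stopping", {
  scenes <- small_scenes(2, 16, 16, seed = 21)
  net <- build_network("vgg16_unet", 16, 16, seed = 1)
  cfg <- train_config(learning_rate = 1e-5, batch_size = 2, patience = 3,
                      max_epochs = 30, seed = 1)
  res <- train(net, scenes, scenes, cfg,
               val_loss_fn = function(net, e) c(1, rep(2, 29))[e])
  expect_equal(res$history$best_epoch, 1L)
  expect_equal(res$history$stopped_epoch, 4L)
  expect_equal(nrow(res$history$epochs), 4L)
})

test_that("training restores the weights of the best epoch", {
  scenes <- small_scenes(2, 16, 16, seed = 22)
  net <- build_network("vgg16_unet", 16, 16, seed = 2)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 2, patience = 2,
                      max_epochs = 10, seed = 1)
  seen <- list()
  res <- train(net, scenes, scenes, cfg,
               val_loss_fn = function(net, e) {
                 seen[[e]] <<- net$params$head1_b
                 c(1, rep(2, 9))[e]
               })
  # best epoch is 1; restored head bias must equal the epoch-1 state, which
  # differs from the final (epoch 3) state
  expect_equal(res$net$params$head1_b, seen[[1]])
  expect_false(identical(seen[[1]], seen[[3]]))
})

test_that("fine-tuning with a zero epoch budget returns the network unchanged", {
  scenes <- small_scenes(2, 16, 16, seed = 23)
  net <- build_network("vgg16_unet", 16, 16, seed = 5)
  res <- fine_tune(net, scenes, scenes, train_config(max_epochs = 0))
  expect_identical(res$net$params, net$params)
  expect_equal(res$history$stopped_epoch, 0L)
})

test_that("evaluation follows the per-image averaging conventions", {
  scenes <- small_scenes(4, 32, 32, seed = 24)
  perfect <- evaluate_network(NULL, scenes, predictor = function(sc) sc$mask)
  expect_equal(perfect$summary$mean_dice, 1)
  expect_equal(perfect$summary$sd_dice, 0)
  # all-zero predictor on one empty and one non-empty mask: samples 1 and 0
  two <- scenes[1:2]
  two[[1]]$mask <- matrix(0L, 32, 32)
  two[[2]]$mask[1:4, 1:4] <- 1L
  ev <- evaluate_network(NULL, two, predictor = function(sc) matrix(0L, 32, 32))
  expect_equal(sort(ev$samples$dice), c(0, 1))
  expect_equal(ev$summary$mean_dice, 0.5)
  expect_equal(ev$summary$sd_dice, 0.5)  # population sd
  expect_error(evaluate_network(NULL, list()), "non-empty")
})

test_that("the CSV report reproduces the returned summary", {
  scenes <- small_scenes(5, 32, 32, seed = 25)
  ev <- evaluate_network(NULL, scenes,
                         predictor = function(sc) {
                           m <- sc$mask
                           m[1, 1] <- 1L - m[1, 1]
                           m
                         })
  f <- tempfile(fileext = ".csv")
  save_metrics(ev$samples, f, variant = "x", dataset = "synth")
  back <- read.csv(f)
  expect_equal(mean(back$dice), ev$summary$mean_dice, tolerance = 1e-12)
  expect_equal(sqrt(mean((back$iou - mean(back$iou))^2)), ev$summary$sd_iou,
               tolerance = 1e-12)
})

test_that("training configurations round-trip through YAML unchanged", {
  cfg <- train_config(learning_rate = 1e-5, batch_size = 2, patience = 10,
                      max_epochs = 37,
                      class_weights = class_weights(0.25, 1.75), seed = 99)
  f <- tempfile(fileext = ".yaml")
  save_train_config(cfg, f)
  back <- load_train_config(f)
  expect_identical(back$learning_rate, cfg$learning_rate)
  expect_identical(back$batch_size, cfg$batch_size)
  expect_identical(back$patience, cfg$patience)
  expect_identical(back$max_epochs, cfg$max_epochs)
  expect_identical(back$seed, cfg$seed)
  expect_equal(back$class_weights$w_wound, 1.75)
})

test_that("split balance reports per-subset wound pixels", {
  scenes <- small_scenes(6, 32, 32, seed = 26)
  rec <- data.frame(image_id = vapply(scenes, `[[`, character(1), "image_id"),
                    patient_id = vapply(scenes, `[[`, character(1), "patient_id"))
  plan <- split_by_patient(rec, c(0.5, 0.25, 0.25), seed = 1)
  bal <- split_balance(plan, scenes)
  expect_equal(bal$subset, c("train", "val", "test"))
  expect_equal(sum(bal$n_images), 6L)
  expect_equal(sum(bal$total_wound_pixels),
               sum(vapply(scenes, function(s) sum(s$mask), numeric(1))))
})
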