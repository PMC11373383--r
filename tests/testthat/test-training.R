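test_that("a separable toy problem is learned to perfect validation accuracy", {
  toy <- toy_dataset(20L, seed = 1L)
  spec <- model_spec(2L, 8L, 2L, 1L, input_width = 8L)
  fit <- fit_sweep_model(spec, toy$train, toy$val,
                         train_control(epochs = 40L, seed = 7L))
  expect_equal(fit$best_val_accuracy, 1)
  expect_identical(fit$best_val_accuracy, max(fit$report$val_acc))
  expect_identical(fit$report$val_acc[fit$best_epoch],
                   fit$best_val_accuracy)
  ev <- evaluate(fit, toy$test)
  expect_equal(ev$accuracy, 1)
  expect_identical(sum(ev$confusion), as.integer(ev$n))
})

test_that("training is bitwise deterministic under a fixed seed", {
  toy <- toy_dataset(8L, seed = 3L)
  spec <- model_spec(2L, 4L, 2L, 1L, input_width = 8L)
  ctl <- train_control(epochs = 5L, seed = 11L)
  f1 <- fit_sweep_model(spec, toy$train, toy$val, ctl)
  f2 <- fit_sweep_model(spec, toy$train, toy$val, ctl)
  expect_identical(f1$report, f2$report)
  expect_identical(coef(f1), coef(f2))
})

test_that("checkpoints reload to identical predictions and accuracy", {
  toy <- toy_dataset(10L, seed = 5L)
  fit <- fit_sweep_model(model_spec(2L, 6L, 2L, 1L, input_width = 8L),
                         toy$train, toy$val,
                         train_control(epochs = 10L, seed = 2L))
  acc <- evaluate(fit, toy$test)$accuracy
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  write_checkpoint(fit, tf)
  back <- read_checkpoint(tf)
  expect_identical(evaluate(back, toy$test)$accuracy, acc)
  expect_identical(predict(back, toy$test), predict(fit, toy$test))
  saveRDS(1:3, tf)
  expect_error(read_checkpoint(tf), "not a sweep_nn")
})

test_that("row-shuffle augmentation permutes rows without touching features", {
  m <- random_window(12L, 9L, seed = 8L)
  m$label <- "sweep"
  s1 <- augment_row_shuffle(m, seed = 4L)
  expect_identical(s1, augment_row_shuffle(m, seed = 4L))
  expect_false(identical(s1$alleles, augment_row_shuffle(m, seed = 5L)$alleles))
  expect_identical(sort(as.vector(s1$alleles)), sort(as.vector(m$alleles)))
  expect_identical(s1$positions, m$positions)
  expect_identical(s1$label, "sweep")
  expect_identical(compute_daf(s1), compute_daf(m))
})

test_that("a constant classifier scores one half on a balanced set", {
  toy <- toy_dataset(8L, seed = 9L)
  model <- untrained_model(model_spec(2L, 4L, 2L, 1L, input_width = 8L))
  p <- dafsweep:::nn_params(model$net)
  model$net <- dafsweep:::nn_set_params(model$net,
                                        lapply(p, function(x) x * 0))
  ev <- evaluate(model, toy$test)
  expect_equal(ev$accuracy, 0.5)
  cm <- ev$confusion
  expect_equal((cm["neutral", "neutral"] + cm["sweep", "sweep"]) / sum(cm),
               ev$accuracy)
})

test_that("repeated runs aggregate over derived seeds and retain reports", {
  toy <- toy_dataset(8L, seed = 13L)
  spec <- model_spec(2L, 4L, 2L, 1L, input_width = 8L)
  one <- repeat_runs(spec, toy, train_control(epochs = 4L, seed = 20L),
                     n_runs = 1L)
  expect_identical(one$mean, one$min)
  expect_identical(one$mean, one$max)
  three <- repeat_runs(spec, toy, train_control(epochs = 4L, seed = 20L),
                       n_runs = 3L)
  expect_identical(three$table$seed, 21:23)
  expect_length(three$fits, 3L)
  expect_identical(three$table$test_acc[1L], one$table$test_acc[1L])
  expect_equal(three$mean, mean(three$table$test_acc))
})

test_that("training aborts informatively when the loss turns non-finite", {
  toy <- toy_dataset(6L, seed = 17L)
  tr <- prepare_input(toy$train, "daf")
  va <- prepare_input(toy$val, "daf")
  tr$x[1L, 1L, 1L] <- NaN  # corrupt activation poisons its batch's loss
  expect_error(
    fit_sweep_model(model_spec(2L, 4L, 2L, 1L, input_width = 8L), tr, va,
                    train_control(epochs = 2L, seed = 1L)),
    "non-finite loss at epoch")
})

test_that("a reduced mild-bottleneck dataset is learned well above chance", {
  ds <- desk_dataset("D1")
  tr <- balanced_subset(ds$train, 100L)   # 200-window training set
  va <- balanced_subset(ds$val, 25L)
  te <- balanced_subset(ds$test, 50L)
  fit <- fit_sweep_model(model_spec(3L, 80L, 2L, 1L), tr, va,
                         train_control(epochs = 20L, seed = 33L))
  acc <- evaluate(fit, te)$accuracy
  expect_gt(acc, 0.9)
})
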