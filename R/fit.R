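# Model fitting: the training protocol is mini-batch Adam (batch 8,
# learning rate 5e-4, 100 epochs by default), with the parameter state of
# the epoch with the highest validation accuracy kept as the checkpoint.

#' Training protocol configuration
#'
#' @param batch_size mini-batch size.
#' @param epochs full epoch budget (no early stopping).
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization, batch order and
#'   augmentation.
#' @param shuffle_rows per-epoch random permutation of the sample rows of
#'   each raw training image (raw 2D pipelines only; the fused 1D
#'   representation is already permutation-invariant).
#' @param verbose print per-epoch progress.
#' @return a `train_control` list.
#' @export
train_control <- function(batch_size = 8L, epochs = 100L,
                          learning_rate = 5e-4, seed = 1L,
                          shuffle_rows = FALSE, verbose = FALSE) {
  stopifnot(batch_size >= 1L, epochs >= 1L, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 shuffle_rows = isTRUE(shuffle_rows),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

input_kind_for <- function(spec) {
  if (inherits(spec, "model_spec")) return("daf")
  switch(spec$fusion, none = "raw", early_conv = "raw_early",
         late_fc = "raw_late")
}

#' Assemble network inputs from labeled windows
#'
#' @param windows list of [snp_matrix] (any type) or [feature_matrix]
#'   (`"daf"` type only) objects.
#' @param type `"daf"` (2 x W fused features), `"raw"` (allele image),
#'   `"raw_early"` (image + broadcast distance channel) or `"raw_late"`
#'   (image plus separate distance vector).
#' @param labels class labels; defaults to the labels carried by the
#'   windows.
#' @param scale distance divisor passed to [featurize()].
#' @return a `model_input` holding arrays ready for training/prediction.
#' @export
prepare_input <- function(windows, type = c("daf", "raw", "raw_early",
                                            "raw_late"),
                          labels = NULL, scale = 1) {
  type <- match.arg(type)
  if (inherits(windows, c("snp_matrix", "feature_matrix")))
    windows <- list(windows)
  n <- length(windows)
  if (n == 0L) stop_fmt("no windows")
  labels <- labels %||% window_labels(windows)
  y <- if (all(is.na(labels))) rep(NA_integer_, n)
       else as.integer(labels == "sweep")

  if (type == "daf") {
    feats <- lapply(windows, function(w)
      if (inherits(w, "feature_matrix")) w else featurize(w, scale = scale))
    W <- ncol(feats[[1L]])
    x <- array(unlist(feats, use.names = FALSE), c(2L, W, n))
    return(structure(list(kind = type, x = x, y = y, n = n, W = W,
                          N = NA_integer_, scale = scale),
                     class = "model_input"))
  }

  ok <- vapply(windows, inherits, TRUE, what = "snp_matrix")
  if (!all(ok)) stop_fmt("raw input types require snp_matrix windows")
  N <- nrow(windows[[1L]]$alleles); W <- ncol(windows[[1L]]$alleles)
  img_c <- if (type == "raw_early") 2L else 1L
  img <- array(0, c(img_c, N, W, n))
  dist <- matrix(0, W, n)
  for (i in seq_len(n)) {
    ai <- windows[[i]]$alleles
    ai[is.na(ai)] <- 0.5  # missing as half-intensity, image convention
    img[1L, , , i] <- ai
    dist[, i] <- compute_distances(windows[[i]]$positions) / scale
    if (type == "raw_early")
      img[2L, , , i] <- matrix(dist[, i], N, W, byrow = TRUE)
  }
  x <- if (type == "raw_late") list(img = img, dist = dist) else img
  structure(list(kind = type, x = x, y = y, n = n, W = W, N = N,
                 scale = scale),
            class = "model_input")
}

slice_input <- function(inp, idx) {
  if (inp$kind == "raw_late")
    list(img = inp$x$img[, , , idx, drop = FALSE],
         dist = inp$x$dist[, idx, drop = FALSE])
  else if (inp$kind == "daf") inp$x[, , idx, drop = FALSE]
  else inp$x[, , , idx, drop = FALSE]
}

# per-epoch, per-sample row shuffle of the raw image channel(s); the
# distance channel has constant rows so a row permutation leaves it fixed.
shuffle_input_rows <- function(inp, seed, epoch) {
  img <- if (inp$kind == "raw_late") inp$x$img else inp$x
  N <- dim(img)[2L]
  for (i in seq_len(dim(img)[4L])) {
    perm <- with_seed(derive_seed(seed, 7700L + epoch, i), sample.int(N))
    img[1L, , , i] <- img[1L, perm, , i]
  }
  if (inp$kind == "raw_late") inp$x$img <- img else inp$x <- img
  inp
}

#' Shuffle the sample rows of a SNP window
#'
#' Training-time augmentation for raw-genotype models: a uniformly random
#' permutation of the haplotype rows.  Positions and label are untouched,
#' and the fused DAF/distance representation is invariant to it.
#'
#' @param x an [snp_matrix].
#' @param seed optional seed; by default the current RNG stream is used.
#' @return the row-shuffled [snp_matrix].
#' @export
augment_row_shuffle <- function(x, seed = NULL) {
  stopifnot(inherits(x, "snp_matrix"))
  N <- nrow(x$alleles)
  perm <- if (is.null(seed)) sample.int(N)
          else with_seed(seed, sample.int(N))
  x$alleles <- x$alleles[perm, , drop = FALSE]
  x
}

predict_logits <- function(net, inp, batch = 256L) {
  out <- matrix(0, 2L, inp$n)
  for (lo in seq(1L, inp$n, by = batch)) {
    idx <- lo:min(lo + batch - 1L, inp$n)
    out[, idx] <- nn_forward(net, slice_input(inp, idx))$out
  }
  out
}

accuracy_of <- function(logits, y) mean((logits[2L, ] > logits[1L, ]) == y)

#' Fit a sweep classifier
#'
#' Trains a network for the given architecture on labeled windows using
#' mini-batch Adam and cross-entropy, evaluating validation accuracy after
#' every epoch and returning the parameter state of the best epoch (ties
#' resolved toward the earlier, less overfit epoch).  Test data are never
#' touched here; use [evaluate()] on the returned model exactly once.
#'
#' @param spec a [model_spec()] (1D, fused DAF/distance input) or
#'   [fusion2d_spec()] (2D raw-genotype baseline).
#' @param train,val labeled [prepare_input()] objects (lists of labeled
#'   windows are accepted and prepared automatically).
#' @param control a [train_control()].
#' @return an object of class `sweep_nn`: the checkpointed network, its
#'   spec, the control, and a per-epoch `report` data frame.
#' @export
fit_sweep_model <- function(spec, train, val, control = train_control()) {
  kind <- input_kind_for(spec)
  if (!inherits(train, "model_input")) {
    sc <- distance_scale(train)
    train <- prepare_input(train, kind, scale = sc)
    if (!inherits(val, "model_input"))
      val <- prepare_input(val, kind, scale = sc)
  }
  if (!inherits(val, "model_input")) val <- prepare_input(val, kind,
                                                          scale = train$scale)
  if (train$kind != kind || val$kind != kind)
    stop_fmt("input kind '%s' does not match the spec's '%s' pipeline",
             train$kind, kind)
  if (anyNA(train$y) || anyNA(val$y))
    stop_fmt("training and validation windows must be labeled")

  with_seed(control$seed, {
    net <- if (inherits(spec, "model_spec")) build_1d_model(spec)
           else build_reference_2d(spec)
    params <- nn_params(net)
    opt <- adam_new(params)
    report <- data.frame(epoch = seq_len(control$epochs), train_loss = NA_real_,
                         train_acc = NA_real_, val_loss = NA_real_,
                         val_acc = NA_real_)
    best <- list(acc = -Inf, epoch = NA_integer_, params = params)

    for (ep in seq_len(control$epochs)) {
      ep_train <- if (control$shuffle_rows && kind != "daf")
        shuffle_input_rows(train, control$seed, ep) else train
      ord <- sample.int(train$n)
      tot_loss <- 0; tot_correct <- 0
      for (lo in seq(1L, train$n, by = control$batch_size)) {
        idx <- ord[lo:min(lo + control$batch_size - 1L, train$n)]
        xb <- slice_input(ep_train, idx)
        yb <- train$y[idx]
        fw <- nn_forward(net, xb)
        ls <- softmax_xent(fw$out, yb)
        if (!is.finite(ls$loss))
          stop_fmt("non-finite loss at epoch %d, batch starting %d", ep, lo)
        tot_loss <- tot_loss + ls$loss * length(idx)
        tot_correct <- tot_correct +
          sum((fw$out[2L, ] > fw$out[1L, ]) == yb)
        gr <- grads_flat(net, nn_backward(net, fw$caches, ls$dlogits))
        st <- adam_step(params, gr, opt, control$learning_rate)
        params <- st$params
        opt <- st$state
        net <- nn_set_params(net, params)
      }
      vlog <- predict_logits(net, val)
      vls <- softmax_xent(vlog, val$y)
      report$train_loss[ep] <- tot_loss / train$n
      report$train_acc[ep] <- tot_correct / train$n
      report$val_loss[ep] <- vls$loss
      report$val_acc[ep] <- accuracy_of(vlog, val$y)
      if (report$val_acc[ep] > best$acc) {
        best <- list(acc = report$val_acc[ep], epoch = ep, params = params)
      }
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.4f  train %.3f  val %.3f",
                        ep, report$train_loss[ep], report$train_acc[ep],
                        report$val_acc[ep]))
    }

    structure(list(net = nn_set_params(net, best$params), spec = spec,
                   control = control, report = report,
                   best_epoch = best$epoch, best_val_accuracy = best$acc,
                   input_kind = kind, scale = train$scale,
                   classes = c("neutral", "sweep")),
              class = "sweep_nn")
  })
}

#' @export
print.sweep_nn <- function(x, ...) {
  cat("Sweep classifier (", x$input_kind, " input)\n", sep = "")
  print(x$spec)
  cat(sprintf("  %d parameters; best validation accuracy %.4f at epoch %d/%d\n",
              n_params(x$net), x$best_val_accuracy, x$best_epoch,
              nrow(x$report)))
  invisible(x)
}

#' @export
summary.sweep_nn <- function(object, ...) {
  r <- object$report
  cat("Training report (checkpoint at best validation accuracy)\n")
  print(object)
  cat(sprintf("  final epoch: train acc %.4f, val acc %.4f\n",
              r$train_acc[nrow(r)], r$val_acc[nrow(r)]))
  cat(sprintf("  train-val gap at final epoch: %.4f\n",
              r$train_acc[nrow(r)] - r$val_acc[nrow(r)]))
  invisible(object)
}

#' @export
coef.sweep_nn <- function(object, ...) nn_params(object$net)

#' Training/validation curves
#' @param x a fitted `sweep_nn`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sweep_nn <- function(x, ...) {
  r <- x$report
  graphics::matplot(r$epoch, cbind(r$train_acc, r$val_acc), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Class probabilities / calls for new windows
#'
#' @param object a fitted `sweep_nn`.
#' @param newdata a `model_input`, a list of windows, or a single window;
#'   converted with the model's own input pipeline and distance scale.
#' @param type `"prob"` (n x 2 matrix of class probabilities) or `"class"`.
#' @param ... unused.
#' @export
predict.sweep_nn <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "model_input"))
    newdata <- prepare_input(newdata, object$input_kind,
                             scale = object$scale)
  if (newdata$kind != object$input_kind)
    stop_fmt("input kind '%s' does not match model '%s'", newdata$kind,
             object$input_kind)
  p <- t(softmax_prob(predict_logits(object$net, newdata)))
  colnames(p) <- object$classes
  if (type == "prob") p
  else factor(object$classes[max.col(p, ties.method = "first")],
              levels = object$classes)
}

#' Accuracy and confusion counts on a labeled set
#'
#' @param object a fitted `sweep_nn`.
#' @param test labeled windows or `model_input`.
#' @return list with `accuracy`, the 2 x 2 `confusion` matrix
#'   (rows = truth, columns = call) and `n`.
#' @export
evaluate <- function(object, test) {
  if (!inherits(test, "model_input"))
    test <- prepare_input(test, object$input_kind, scale = object$scale)
  if (test$n == 0L || anyNA(test$y)) stop_fmt("need a labeled test set")
  cls <- predict(object, test, type = "class")
  truth <- factor(object$classes[test$y + 1L], levels = object$classes)
  cm <- table(truth = truth, call = cls)
  list(accuracy = mean(cls == truth), confusion = cm, n = test$n)
}

#' Repeat the train/evaluate protocol
#'
#' Trains the same architecture `n_runs` times with derived seeds
#' (`seed + run index`) on one dataset, reporting mean/min/max test
#' accuracy in the style used for architecture comparisons.
#'
#' @param spec architecture specification.
#' @param data list with `train`, `val`, `test` inputs (window lists or
#'   `model_input`s).
#' @param control base [train_control()]; each run uses
#'   `control$seed + run`.
#' @param n_runs number of repetitions.
#' @return a `sweep_runs` object: per-run table, all fitted reports, and
#'   aggregate statistics.
#' @export
repeat_runs <- function(spec, data, control = train_control(),
                        n_runs = 10L) {
  stopifnot(n_runs >= 1L)
  kind <- input_kind_for(spec)
  sc <- if (inherits(data$train, "model_input")) data$train$scale
        else distance_scale(data$train)
  tr <- if (inherits(data$train, "model_input")) data$train
        else prepare_input(data$train, kind, scale = sc)
  va <- if (inherits(data$val, "model_input")) data$val
        else prepare_input(data$val, kind, scale = sc)
  te <- if (inherits(data$test, "model_input")) data$test
        else prepare_input(data$test, kind, scale = sc)
  runs <- vector("list", n_runs)
  tab <- data.frame(run = seq_len(n_runs), seed = NA_integer_,
                    best_val_acc = NA_real_, best_epoch = NA_integer_,
                    test_acc = NA_real_)
  for (r in seq_len(n_runs)) {
    ctl <- control
    ctl$seed <- control$seed + r
    fit <- fit_sweep_model(spec, tr, va, ctl)
    ev <- evaluate(fit, te)
    tab$seed[r] <- ctl$seed
    tab$best_val_acc[r] <- fit$best_val_accuracy
    tab$best_epoch[r] <- fit$best_epoch
    tab$test_acc[r] <- ev$accuracy
    runs[[r]] <- fit
  }
  structure(list(table = tab, fits = runs,
                 mean = mean(tab$test_acc), min = min(tab$test_acc),
                 max = max(tab$test_acc)),
            class = "sweep_runs")
}

#' @export
print.sweep_runs <- function(x, ...) {
  cat(sprintf("<sweep_runs> %d runs: test accuracy mean %.4f (min %.4f, max %.4f)\n",
              nrow(x$table), x$mean, x$min, x$max))
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' Checkpoints carry the full model state: parameters, architecture spec,
#' input pipeline kind and distance scale, so a reloaded model reproduces
#' its predictions exactly and a scan can verify compatibility.
#'
#' @param object a `sweep_nn`.
#' @param path file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   the restored `sweep_nn`.
#' @export
write_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "sweep_nn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "sweep_nn"))
    stop_fmt("%s is not a sweep_nn checkpoint", path)
  obj
}
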