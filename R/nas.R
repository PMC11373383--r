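# Exhaustive grid architecture search: every candidate of the
# hyperparameter grid is trained once on the same dataset with the same
# seed policy and ranked by its best validation accuracy.

#' Grid architecture search
#'
#' Trains every feasible candidate of the grid with [fit_sweep_model()] on
#' identical data and master seed, recording each candidate's best
#' validation accuracy.  Infeasible cells (width collapse) and failed runs
#' are kept in the table with `NA` accuracy and are never ranked.
#'
#' @param grid data.frame from [enumerate_grid()] (or a subset of its rows).
#' @param data list with `train` and `val` window lists or `model_input`s.
#' @param control base [train_control()]; the same seed is used for every
#'   candidate so data order is identical across candidates.
#' @param keep_reports retain every candidate's full fit object (needed for
#'   [overfitting_report()]).
#' @param progress print per-candidate progress.
#' @return a `nas_result`: the annotated grid table, the winning spec, and
#'   (optionally) all fits.
#' @export
run_grid_search <- function(grid, data, control = train_control(),
                            keep_reports = TRUE, progress = FALSE) {
  sc <- if (inherits(data$train, "model_input")) data$train$scale
        else distance_scale(data$train)
  tr <- if (inherits(data$train, "model_input")) data$train
        else prepare_input(data$train, "daf", scale = sc)
  va <- if (inherits(data$val, "model_input")) data$val
        else prepare_input(data$val, "daf", scale = sc)
  tab <- grid
  tab$best_val_acc <- NA_real_
  tab$best_epoch <- NA_integer_
  tab$n_params <- NA_integer_
  tab$status <- "ok"
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- grid_spec(grid, i)
    if (!spec_feasible(spec)) {
      tab$status[i] <- "infeasible"
      next
    }
    fit <- tryCatch(fit_sweep_model(spec, tr, va, control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tab$status[i] <- paste("failed:", conditionMessage(fit))
      next
    }
    tab$best_val_acc[i] <- fit$best_val_accuracy
    tab$best_epoch[i] <- fit$best_epoch
    tab$n_params[i] <- n_params(fit$net)
    if (keep_reports) fits[[i]] <- fit
    if (progress)
      message(sprintf("[%3d/%d] L%d c%d k%d s%d  val %.4f", i, nrow(grid),
                      spec$n_layers, spec$channels, spec$kernel_width,
                      spec$stride, fit$best_val_accuracy))
  }
  res <- structure(list(table = tab, fits = fits, control = control),
                   class = "nas_result")
  res$winner <- tryCatch(select_best(res), error = function(e) NULL)
  res
}

#' @export
print.nas_result <- function(x, ...) {
  ok <- sum(x$table$status == "ok")
  cat(sprintf("<nas_result> %d candidates (%d trained, %d infeasible/failed)\n",
              nrow(x$table), ok, nrow(x$table) - ok))
  w <- x$winner
  if (!is.null(w))
    cat(sprintf("  winner: %d layers, %d channels, kernel %d, stride %d\n",
                w$n_layers, w$channels, w$kernel_width, w$stride))
  invisible(x)
}

#' Winning architecture of a grid search
#'
#' The feasible candidate with the highest best-validation accuracy; exact
#' ties go to the smaller parameter count, then fewer layers, then grid
#' order.
#'
#' @param result a `nas_result`.
#' @return the winning [model_spec()].
#' @export
select_best <- function(result) {
  tab <- result$table
  ok <- which(!is.na(tab$best_val_acc))
  if (length(ok) == 0L) stop_fmt("no feasible candidates in grid search")
  o <- ok[order(-tab$best_val_acc[ok], tab$n_params[ok], tab$n_layers[ok],
                ok)]
  grid_spec(tab, o[1L])
}

#' Overfitting comparison across layer counts
#'
#' For each layer count in the searched grid, extracts the best candidate's
#' training and validation accuracy curves, and flags the candidate as
#' overfit when its final-epoch train-validation gap exceeds a threshold.
#'
#' @param result a `nas_result` built with `keep_reports = TRUE`.
#' @param gap_threshold train-minus-validation accuracy gap at the final
#'   epoch above which a model is called overfit.
#' @return list with one entry per layer count: the spec row, the per-epoch
#'   curves, the final gap and the overfit flag.
#' @export
overfitting_report <- function(result, gap_threshold = 0.05) {
  tab <- result$table
  out <- list()
  for (L in sort(unique(tab$n_layers))) {
    cand <- which(tab$n_layers == L & !is.na(tab$best_val_acc))
    if (length(cand) == 0L) next
    best <- cand[which.max(tab$best_val_acc[cand])]
    fit <- result$fits[[best]]
    if (is.null(fit)) stop_fmt("run_grid_search was called without reports")
    r <- fit$report
    gap <- r$train_acc[nrow(r)] - r$val_acc[nrow(r)]
    out[[as.character(L)]] <- list(
      spec = tab[best, , drop = FALSE],
      curves = r[, c("epoch", "train_acc", "val_acc")],
      final_gap = gap, overfit = gap > gap_threshold)
  }
  out
}
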