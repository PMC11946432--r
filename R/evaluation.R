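# Regression metrics and the grouped K-fold cross-validation protocol.

#' Six regression metrics for a prediction series
#'
#' MSE, RMSE, MAE, maximum absolute error, coefficient of determination R^2
#' and explained variance `EV = 1 - Var(y - yhat) / Var(y)` (population
#' variances). When `Var(y) = 0`, R^2 and EV are reported as `NA` with
#' `r2_defined = FALSE` rather than an error.
#'
#' @param truth True values.
#' @param estimate Predicted values, same length (>= 2).
#' @return A one-row tibble `mse`, `rmse`, `mae`, `max_error`, `r2`, `ev`,
#'   `r2_defined`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))
regression_metrics <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 2)
  err <- truth - estimate
  mse <- mean(err^2)
  pop_var <- function(x) mean((x - mean(x))^2)
  vy <- pop_var(truth)
  defined <- vy > 0
  tibble(
    mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
    max_error = max(abs(err)),
    r2 = if (defined) 1 - sum(err^2) / sum((truth - mean(truth))^2) else
      NA_real_,
    ev = if (defined) 1 - pop_var(err) / vy else NA_real_,
    r2_defined = defined)
}

#' Assign groups to K near-equal cross-validation folds
#'
#' Whole recordings (sessions) are the fold unit, never individual rows, so
#' the decoder is always validated on time spans it never trained on.
#'
#' @param n_groups Number of recordings.
#' @param k Number of folds (`k <= n_groups`).
#' @param seed Shuffle seed; the same seed yields the same folds.
#' @return Integer fold id per group.
#' @export
cv_folds <- function(n_groups, k = 5, seed = 1) {
  if (k > n_groups) {
    abort(sprintf("k = %d exceeds the number of recordings (%d).", k,
                  n_groups))
  }
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n_groups))
}

#' Grouped K-fold cross-validation of the hybrid HMM
#'
#' Splits the recordings into `k` near-equal folds, fits the model on
#' `k - 1` folds and decodes the held-out fold, so every recording is
#' validated exactly once. Reports the per-fold row accuracy (fraction of
#' fused grid rows whose Viterbi state equals the label), their mean, a
#' segment-level accuracy (fraction of labeled intervals whose majority
#' decoded state matches), and the six regression metrics of the hypnosis
#' posterior against the 0/1 state indicator pooled over all held-out rows.
#'
#' @param recordings List of labeled [multimodal_recording()]s or fused
#'   feature tibbles.
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment seed.
#' @param config,kappa,params,fit_seed Passed to [hhmm_fit()].
#' @return An object of class `eval_report`: tibble of folds, mean
#'   accuracy, pooled metrics.
#' @export
evaluate_cv <- function(recordings, k = 5, seed = 1, config = NULL,
                        kappa = 1, params = list(), fit_seed = 1) {
  fused <- fuse_inputs(recordings, config)
  n <- length(fused)
  fold <- cv_folds(n, k, seed)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- fused[fold != f]
    test <- fused[fold == f]
    model <- hhmm_fit(train, config = config, kappa = kappa,
                      params = params, seed = fit_seed)
    dec <- lapply(test, function(ft) predict(model, ft))
    rows <- bind_rows(dec)
    seg_acc <- segment_accuracy(dec)
    fold_rows[[f]] <- tibble(
      fold = f, n_rows = nrow(rows),
      accuracy = mean(rows$viterbi_state == rows$label),
      segment_accuracy = seg_acc,
      posterior = list(rows$posterior_hypnosis),
      indicator = list(as.numeric(rows$label == "hypnosis")))
  }
  folds <- bind_rows(fold_rows)
  pooled_post <- unlist(folds$posterior)
  pooled_ind <- unlist(folds$indicator)
  metrics <- regression_metrics(pooled_ind, pooled_post)
  folds <- folds[, c("fold", "n_rows", "accuracy", "segment_accuracy")]
  structure(
    list(folds = folds, mean_accuracy = mean(folds$accuracy),
         mean_segment_accuracy = mean(folds$segment_accuracy, na.rm = TRUE),
         metrics = metrics, k = k, seed = seed),
    class = "eval_report")
}

# majority-vote accuracy over maximal ground-truth label runs
segment_accuracy <- function(decoded) {
  hits <- unlist(lapply(decoded, function(d) {
    runs <- rle(d$label)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    vapply(seq_along(runs$values), function(i) {
      seg <- d$viterbi_state[starts[i]:ends[i]]
      names(which.max(table(seg))) == runs$values[i]
    }, logical(1))
  }))
  if (!length(hits)) NA_real_ else mean(hits)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold grouped CV (seed %d)\n", x$k, x$seed))
  print(as.data.frame(x$folds), row.names = FALSE)
  cat(sprintf("mean row accuracy: %.4f  mean segment accuracy: %.4f\n",
              x$mean_accuracy, x$mean_segment_accuracy))
  cat(sprintf("pooled posterior vs indicator: MSE %.4f RMSE %.4f MAE %.4f\n",
              x$metrics$mse, x$metrics$rmse, x$metrics$mae))
  cat(sprintf("  R2 %.4f EV %.4f max error %.4f\n", x$metrics$r2,
              x$metrics$ev, x$metrics$max_error))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$folds

#' @export
glance.eval_report <- function(x, ...) {
  bind_cols(tibble(k = x$k, mean_accuracy = x$mean_accuracy,
                   mean_segment_accuracy = x$mean_segment_accuracy,
                   accuracy_spread = max(x$folds$accuracy) -
                     min(x$folds$accuracy)),
            x$metrics)
}
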