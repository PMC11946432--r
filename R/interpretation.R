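# Feature-importance and feature-selection analyses: split-based
# importance, additive attribution, local surrogate explanation,
# L1-penalized selection, recursive elimination.

get_boosters <- function(object) {
  if (inherits(object, "hybrid_hmm")) object <- object$emissions
  if (inherits(object, "emission_model")) {
    return(list(boosters = object$boosters,
                features = object$feature_names))
  }
  if (inherits(object, "xgb.Booster")) {
    return(list(boosters = list(object),
                features = stats::variable.names(object)))
  }
  abort("Expected a hybrid_hmm, emission_model, or xgb.Booster.")
}

#' Split-based feature importance (gain / cover / frequency)
#'
#' Aggregates, over every tree of every per-state scorer, the total split
#' gain, the total cover (training rows routed through the split), and the
#' split frequency (an integer count) per feature. Features never split on
#' appear with zeros, so the table covers exactly the model's feature set.
#'
#' @param object A fitted [hhmm_fit()] model, an [train_emissions()]
#'   emission model, or a single booster.
#' @return An `importance_table` tibble: `feature`, `gain`, `cover`,
#'   `frequency`, sorted by gain.
#' @export
split_importance <- function(object) {
  parts <- get_boosters(object)
  acc <- tibble(feature = parts$features, gain = 0, cover = 0,
                frequency = 0)
  for (bst in parts$boosters) {
    tr <- xgboost::xgb.model.dt.tree(bst)
    splits <- tr[tr$Feature != "Leaf", ]
    if (!nrow(splits)) next
    agg <- stats::aggregate(
      cbind(gain = splits$Gain, cover = splits$Cover,
            frequency = rep(1, nrow(splits))),
      by = list(feature = splits$Feature), FUN = sum)
    i <- match(agg$feature, acc$feature)
    acc$gain[i] <- acc$gain[i] + agg$gain
    acc$cover[i] <- acc$cover[i] + agg$cover
    acc$frequency[i] <- acc$frequency[i] + agg$frequency
  }
  out <- arrange(acc, dplyr::desc(gain))
  class(out) <- c("importance_table", class(out))
  out
}

#' Additive (Shapley-style) per-feature attribution
#'
#' Tree-path additive contributions: for every row, `base +` the sum of the
#' per-feature contributions equals the model's raw score (the defining
#' additivity property).
#'
#' @param object A fitted model (see [split_importance()]); for a
#'   `hybrid_hmm`/`emission_model` the scorer of `state` is explained.
#' @param x Feature rows (matrix or data frame).
#' @param state State whose scorer is explained (default `"hypnosis"`).
#' @return A list: `contributions` (tibble, one column per feature),
#'   `base` (scalar), `prediction` (raw scores).
#' @export
additive_attribution <- function(x, object, state = "hypnosis") {
  bst <- pick_booster(object, state)
  xm <- as_feature_matrix(x, object)
  contrib <- predict(bst, xm, predcontrib = TRUE)
  pred <- predict(bst, xm)
  base <- unname(contrib[1, "(Intercept)"])
  keep <- setdiff(colnames(contrib), "(Intercept)")
  list(contributions = as_tibble(contrib[, keep, drop = FALSE]),
       base = base, prediction = pred)
}

pick_booster <- function(object, state) {
  if (inherits(object, "hybrid_hmm")) object <- object$emissions
  if (inherits(object, "emission_model")) {
    return(object$boosters[[state]])
  }
  object
}

as_feature_matrix <- function(x, object) {
  feats <- tryCatch(get_boosters(object)$features, error = function(e) NULL)
  if (is.data.frame(x)) {
    if (!is.null(feats)) x <- x[, feats, drop = FALSE]
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x
}

#' Local surrogate explanation of one prediction
#'
#' Draws Gaussian perturbations around the row, scores them with the model,
#' weights them by an RBF distance kernel, and fits a weighted linear model
#' in the perturbation space. The coefficients are the local feature
#' weights; `r2` reports how faithful the surrogate is in the
#' neighborhood.
#'
#' @param row A single named feature row (standardized scale).
#' @param object A fitted model, or a plain `function(matrix) -> numeric`
#'   scoring function.
#' @param n_perturbations Neighborhood size (default 1000).
#' @param sigma Perturbation standard deviation per feature (default 0.5,
#'   on the standardized scale).
#' @param kernel_width RBF kernel width (default `0.75 * sqrt(p)`).
#' @param state Scorer to explain for emission models.
#' @param seed RNG seed; the same seed yields identical output.
#' @return A list: `weights` (tibble `feature`, `weight`), `intercept`,
#'   `r2`.
#' @export
local_surrogate <- function(row, object, n_perturbations = 1000,
                            sigma = 0.5, kernel_width = NULL,
                            state = "hypnosis", seed = 1) {
  if (is.data.frame(row)) row <- unlist(row[1, , drop = TRUE])
  row <- unlist(row)
  p <- length(row)
  score_fn <- if (is.function(object)) {
    object
  } else {
    bst <- pick_booster(object, state)
    function(m) predict(bst, m)
  }
  set.seed(seed)
  Z <- matrix(rnorm(n_perturbations * p, sd = sigma), n_perturbations, p)
  X <- sweep(Z, 2, row, "+")
  colnames(X) <- names(row)
  y <- score_fn(X)
  if (sd(y) == 0 && all(Z == 0)) abort("Degenerate perturbation set.")
  kw <- kernel_width %||% (0.75 * sqrt(p))
  w <- exp(-rowSums(Z^2) / kw^2)
  fit <- stats::lm.wfit(cbind(1, Z), y, w)
  yhat <- cbind(1, Z) %*% fit$coefficients
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar)^2)
  if (!is.finite(r2)) r2 <- 1  # constant model: surrogate is exact
  list(weights = tibble(feature = names(row) %||% paste0("x", seq_len(p)),
                        weight = unname(fit$coefficients[-1])),
       intercept = unname(fit$coefficients[1]), r2 = r2)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' L1-penalized (lasso) coefficient path and selection
#'
#' Cyclic coordinate descent on
#' `(1/2n) * ||y - b0 - X b||^2 + lambda * ||b||_1` (intercept
#' unpenalized), solved over a decreasing penalty grid with warm starts. At
#' `lambda = 0` the solution coincides with ordinary least squares. The
#' selected set holds the non-zero coefficients at the penalty minimizing
#' K-fold cross-validated error.
#'
#' @param x Feature matrix or data frame. Inputs whose columns are not
#'   standardized are standardized internally with a warning.
#' @param y Numeric target (e.g. the 0/1 state indicator).
#' @param lambda Optional penalty grid; defaults to a log-spaced grid from
#'   `lambda_max` (all-zero solution) down to `lambda_max / 1000` plus 0.
#' @param nlambda Grid size (default 50).
#' @param cv_folds Folds for penalty selection (default 5).
#' @param seed Fold shuffle seed.
#' @param tol,max_iter Coordinate-descent convergence controls.
#' @return A list of class `l1_path`: `path` (tibble `lambda`, `feature`,
#'   `beta`), `intercepts`, `lambda_min`, `selected` (feature names),
#'   `coefficients` (at `lambda_min`).
#' @export
l1_select <- function(x, y, lambda = NULL, nlambda = 50, cv_folds = 5,
                      seed = 1, tol = 1e-10, max_iter = 100000) {
  if (is.data.frame(x)) x <- as.matrix(x)
  feats <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (max(abs(mu)) > 1e-6 || max(abs(sdev - 1)) > 1e-6) {
    warn("Features are not standardized; standardizing internally.")
    if (any(sdev == 0)) abort("Zero-variance feature column.")
    x <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  }
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(lambda)) {
    lmax <- max(abs(crossprod(x, y - mean(y)))) / n
    lambda <- c(exp(seq(log(lmax), log(lmax / 1000),
                        length.out = nlambda - 1)), 0)
  }
  lambda <- sort(unique(lambda), decreasing = TRUE)
  fit_path <- function(xx, yy, lams) {
    nn <- nrow(xx)
    xs2 <- colMeans(xx^2)
    b <- rep(0, p)
    b0 <- mean(yy)
    r <- yy - b0
    out_b <- matrix(0, length(lams), p)
    out_b0 <- numeric(length(lams))
    for (li in seq_along(lams)) {
      lam <- lams[li]
      for (it in seq_len(max_iter)) {
        delta_max <- 0
        for (j in seq_len(p)) {
          bj_old <- b[j]
          z <- mean(xx[, j] * r) + xs2[j] * bj_old
          bj <- soft_threshold(z, lam) / xs2[j]
          if (bj != bj_old) {
            r <- r - xx[, j] * (bj - bj_old)
            b[j] <- bj
            delta_max <- max(delta_max, abs(bj - bj_old))
          }
        }
        b0_new <- b0 + mean(r)
        r <- r - (b0_new - b0)
        delta_max <- max(delta_max, abs(b0_new - b0))
        b0 <- b0_new
        if (delta_max < tol) break
      }
      out_b[li, ] <- b
      out_b0[li] <- b0
    }
    list(beta = out_b, b0 = out_b0)
  }
  full <- fit_path(x, y, lambda)
  set.seed(seed)
  fold <- sample(rep(seq_len(cv_folds), length.out = n))
  cv_err <- matrix(NA_real_, cv_folds, length(lambda))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    pf <- fit_path(x[tr, , drop = FALSE], y[tr], lambda)
    pred <- x[!tr, , drop = FALSE] %*% t(pf$beta)
    pred <- sweep(pred, 2, pf$b0, "+")
    cv_err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  mean_err <- colMeans(cv_err)
  best <- which.min(mean_err)
  lam_col <- rep(lambda, each = p)
  feat_col <- rep(feats, times = length(lambda))
  path <- tibble(lambda = lam_col, feature = feat_col,
                 beta = as.numeric(t(full$beta)))
  structure(
    list(path = path, intercepts = full$b0, lambda = lambda,
         cv_error = mean_err, lambda_min = lambda[best],
         coefficients = setNames(full$beta[best, ], feats),
         intercept = full$b0[best],
         selected = feats[full$beta[best, ] != 0]),
    class = "l1_path")
}

#' @export
print.l1_path <- function(x, ...) {
  cat(sprintf("<l1_path> %d penalties, lambda_min = %.5g\n",
              length(x$lambda), x$lambda_min))
  cat("selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Recursive feature elimination with a boosted-tree scorer
#'
#' Repeatedly fits a boosted-tree model and drops the `step`
#' lowest-total-gain features until one remains. Rank 1 is the most
#' important (last surviving) feature.
#'
#' @param x Feature matrix or data frame.
#' @param y Numeric 0/1 target.
#' @param step Features removed per iteration (default 1; must be smaller
#'   than the feature count).
#' @param nrounds,max_depth,learning_rate Boosting controls for the
#'   internal scorer (kept small: ranking, not prediction, is the goal).
#' @param seed Unused by the deterministic scorer but kept for interface
#'   stability.
#' @return A tibble `feature`, `rank`, `eliminated_at` (iteration; `NA`
#'   for the survivor).
#' @export
recursive_elimination <- function(x, y, step = 1, nrounds = 50,
                                  max_depth = 3, learning_rate = 0.2,
                                  seed = 1) {
  if (is.data.frame(x)) x <- as.matrix(x)
  feats <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  colnames(x) <- feats
  if (length(feats) < 2) abort("Need at least 2 features.")
  if (step >= length(feats)) {
    abort("`step` must be smaller than the number of features.")
  }
  remaining <- feats
  order_out <- character(0)
  iter <- 0
  while (length(remaining) > 1) {
    iter <- iter + 1
    bst <- fit_booster(x[, remaining, drop = FALSE], y,
                       list(max_depth = max_depth,
                            learning_rate = learning_rate, reg_lambda = 1),
                       nrounds)
    imp <- split_importance(bst)
    drop_n <- min(step, length(remaining) - 1)
    worst <- tail(imp$feature, drop_n)
    order_out <- c(order_out, worst)
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(rev(order_out), character(0))
  tibble(feature = c(remaining, rev(order_out)),
         rank = seq_len(length(feats)),
         eliminated_at = c(NA_integer_,
                           rev(rep(seq_len(iter),
                                   each = step,
                                   length.out = length(order_out)))))
}
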