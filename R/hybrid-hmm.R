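# Hybrid hidden Markov model: supervised transition estimation, calibrated
# boosted-tree emission scorers, scaled forward filtering, Viterbi decoding
# and the linear hypnosis-degree readout.

#' Construct an HMM specification
#'
#' @param pi Initial state distribution (sums to 1).
#' @param A Transition matrix, rows summing to 1; `A[i, j]` is the
#'   probability of moving from state `i` to state `j`.
#' @param states State names (default `c("normal", "hypnosis")`).
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(pi, A, states = c("normal", "hypnosis")) {
  A <- as.matrix(A)
  n <- length(states)
  stopifnot(length(pi) == n, all(dim(A) == n))
  if (any(A < 0) || any(pi < 0)) abort("Probabilities must be non-negative.")
  if (abs(sum(pi) - 1) > 1e-10 || any(abs(rowSums(A) - 1) > 1e-10)) {
    abort("`pi` and each row of `A` must sum to 1.")
  }
  dimnames(A) <- list(states, states)
  structure(list(pi = setNames(as.numeric(pi), states), A = A,
                 states = states),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat(sprintf("<hmm_spec> %d states: %s\n", length(x$states),
              paste(x$states, collapse = ", ")))
  cat("pi:", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  print(round(x$A, 4))
  invisible(x)
}

#' Estimate transition probabilities from labeled state sequences
#'
#' Counts observed transitions across one or more label sequences and
#' normalizes rows with additive (pseudo-count) smoothing:
#' `a_ij = (count(i -> j) + kappa) / (sum_k count(i -> k) + N * kappa)`.
#' The initial distribution uses first-step frequencies with the same
#' smoothing.
#'
#' @param sequences A character vector of state labels, or a list of such
#'   vectors (one per recording).
#' @param states State universe; defaults to the sorted unique labels with
#'   `"normal"` first when present.
#' @param kappa Smoothing pseudo-count (default 1; avoids zero rows when
#'   the minority state never self-transitions in a short sequence).
#' @return An [hmm_spec()].
#' @export
estimate_transitions <- function(sequences, states = NULL, kappa = 1) {
  if (!is.list(sequences)) sequences <- list(sequences)
  labs <- unique(unlist(sequences))
  if (is.null(states)) {
    states <- sort(labs)
    if ("normal" %in% states) {
      states <- c("normal", setdiff(states, "normal"))
    }
  }
  unknown <- setdiff(labs, states)
  if (length(unknown)) {
    abort(paste0("Unknown label(s): ", paste(unknown, collapse = ", ")))
  }
  if (!any(vapply(sequences, length, integer(1)) >= 2)) {
    abort("Need at least one sequence with two or more steps.")
  }
  n <- length(states)
  counts <- matrix(0, n, n, dimnames = list(states, states))
  first <- setNames(rep(0, n), states)
  for (s in sequences) {
    s <- as.character(s)
    if (!length(s)) next
    first[s[1]] <- first[s[1]] + 1
    if (length(s) > 1) {
      from <- s[-length(s)]
      to <- s[-1]
      for (i in seq_along(from)) counts[from[i], to[i]] <-
          counts[from[i], to[i]] + 1
    }
  }
  A <- (counts + kappa) / (rowSums(counts) + n * kappa)
  pi <- (first + kappa) / (sum(first) + n * kappa)
  if (kappa == 0) {
    # guard divisions by zero on never-visited rows
    zero <- rowSums(counts) == 0
    A[zero, ] <- 1 / n
    if (sum(first) == 0) pi[] <- 1 / n
  }
  hmm_spec(pi, A, states)
}

xgb_defaults <- function() {
  list(nrounds = 200, max_depth = 4, learning_rate = 0.1, reg_lambda = 1)
}

fit_booster <- function(x, y, pars, nrounds) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "reg:squarederror", max_depth = pars$max_depth,
      learning_rate = pars$learning_rate, reg_lambda = pars$reg_lambda,
      nthread = 1, seed = 0),
    data = dm, nrounds = nrounds, verbose = 0)
}

#' Train calibrated per-state emission scorers
#'
#' For each hidden state a gradient-boosted tree ensemble is fit one-vs-rest
#' with a squared-error objective against the 0/1 state indicator (plus L2
#' regularization of the leaf weights). Raw scores are then calibrated by
#' Platt scaling - a sigmoid fitted by logistic regression on *out-of-fold*
#' scores so the calibrator never sees in-sample (overfit) scores. The
#' calibrated per-state probabilities are renormalized across states, and
#' the training state priors are recorded for the scaled-likelihood
#' conversion.
#'
#' @param x Numeric feature matrix (standardized), rows are time steps.
#' @param labels State label per row; every state needs at least 2 rows.
#' @param states State universe/order (default from the labels).
#' @param params Boosting hyperparameters overriding `nrounds = 200`,
#'   `max_depth = 4`, `learning_rate = 0.1`, `reg_lambda = 1`.
#' @param calib_folds Folds used to produce held-out scores for the Platt
#'   fit (default 3).
#' @param seed Seed for the fold shuffle (training itself is
#'   deterministic).
#' @return An object of class `emission_model`.
#' @export
train_emissions <- function(x, labels, states = NULL, params = list(),
                            calib_folds = 3, seed = 1) {
  if (is.data.frame(x)) x <- as.matrix(x)
  labels <- as.character(labels)
  if (is.null(states)) {
    states <- sort(unique(labels))
    if ("normal" %in% states) states <- c("normal",
                                          setdiff(states, "normal"))
  }
  if (length(states) < 2) {
    abort("Training labels contain a single state; fewer than 2 examples per remaining state.")
  }
  tab <- table(factor(labels, levels = states))
  if (any(tab < 2)) {
    abort(sprintf("State '%s' has fewer than 2 examples.",
                  states[which.min(tab)]))
  }
  pars <- modifyList(xgb_defaults(), params)
  n <- nrow(x)
  set.seed(seed)
  fold <- sample(rep(seq_len(calib_folds), length.out = n))
  boosters <- list()
  platt <- list()
  priors <- as.numeric(tab) / n
  names(priors) <- states
  for (st in states) {
    y <- as.numeric(labels == st)
    boosters[[st]] <- fit_booster(x, y, pars, pars$nrounds)
    oof <- numeric(n)
    for (f in seq_len(calib_folds)) {
      tr <- fold != f
      bst_f <- fit_booster(x[tr, , drop = FALSE], y[tr], pars, pars$nrounds)
      oof[!tr] <- predict(bst_f, x[!tr, , drop = FALSE])
    }
    fit <- suppressWarnings(
      glm(y ~ oof, family = binomial(), data = data.frame(y = y, oof = oof)))
    platt[[st]] <- coef(fit)
  }
  structure(list(boosters = boosters, platt = platt, priors = priors,
                 states = states, feature_names = colnames(x),
                 params = pars),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf(
    "<emission_model> %d states (%s), %d features, %d trees/state\n",
    length(x$states), paste(x$states, collapse = ", "),
    length(x$feature_names), x$params$nrounds))
  invisible(x)
}

check_feature_matrix <- function(model, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, model$feature_names,
                                          drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$feature_names)) {
    abort(sprintf("Expected %d features, got %d.",
                  length(model$feature_names), ncol(x)))
  }
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), model$feature_names)) {
    x <- x[, model$feature_names, drop = FALSE]
  }
  x
}

#' Calibrated state posteriors for feature rows
#'
#' @param model An [train_emissions()] model.
#' @param x Feature rows (matrix or data frame with the model's features).
#' @return Matrix `n x n_states` of calibrated posteriors summing to 1 per
#'   row.
#' @export
emission_posterior <- function(model, x) {
  x <- check_feature_matrix(model, x)
  p <- vapply(model$states, function(st) {
    raw <- predict(model$boosters[[st]], x)
    ab <- model$platt[[st]]
    plogis(ab[1] + ab[2] * raw)
  }, numeric(nrow(x)))
  if (is.null(dim(p))) p <- matrix(p, nrow = 1,
                                   dimnames = list(NULL, model$states))
  p / rowSums(p)
}

#' Scaled emission likelihoods
#'
#' Converts discriminative posteriors to HMM emission terms by the scaled
#' likelihood `b_j(o) = p(S_j | o) / p(S_j)` (posterior over training
#' prior), floored at `1e-12` so no emission is exactly zero. Constant
#' factors per time step cancel in the scaled forward recursion, so these
#' can replace true class-conditional likelihoods in decoding.
#'
#' @inheritParams emission_posterior
#' @return Matrix `n x n_states` of strictly positive scaled likelihoods.
#' @export
emission_likelihood <- function(model, x) {
  post <- emission_posterior(model, x)
  b <- sweep(post, 2, model$priors, "/")
  pmax(b, 1e-12)
}

#' Scaled forward filtering
#'
#' The forward recursion `alpha_t(j) = sum_i alpha_{t-1}(i) a_ij b_j(o_t)`
#' with per-step normalization; the log-likelihood is the sum of the log
#' scaling factors. Filtered posteriors are the normalized `alpha` rows.
#'
#' @param spec An [hmm_spec()].
#' @param b Emission matrix `T x N` (e.g. from [emission_likelihood()]), or
#'   an [emission_model()] together with `x`.
#' @param x Feature rows when `b` is an emission model.
#' @return A list: `posterior` (`T x N`, rows sum to 1), `scaling` (length
#'   `T`), `log_likelihood`.
#' @export
forward_filter <- function(spec, b, x = NULL) {
  if (inherits(b, "emission_model")) b <- emission_likelihood(b, x)
  b <- as.matrix(b)
  n <- length(spec$states)
  stopifnot(ncol(b) == n, nrow(b) >= 1)
  Tn <- nrow(b)
  alpha <- matrix(0, Tn, n, dimnames = list(NULL, spec$states))
  scaling <- numeric(Tn)
  a <- spec$pi * b[1, ]
  scaling[1] <- sum(a)
  if (scaling[1] <= 0) abort("All-zero emission row at t = 1.")
  alpha[1, ] <- a / scaling[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- as.numeric(alpha[t - 1, ] %*% spec$A) * b[t, ]
      scaling[t] <- sum(a)
      if (scaling[t] <= 0) abort(sprintf("All-zero emission row at t = %d.",
                                         t))
      alpha[t, ] <- a / scaling[t]
    }
  }
  list(posterior = alpha, scaling = scaling,
       log_likelihood = sum(log(scaling)))
}

#' Viterbi decoding
#'
#' Max-product recursion in log space with backpointers. Ties are broken
#' toward the lower state index, deterministically.
#'
#' @inheritParams forward_filter
#' @return A list: `path` (state names, length `T`), `log_score` (log
#'   probability of the best path).
#' @export
viterbi_path <- function(spec, b, x = NULL) {
  if (inherits(b, "emission_model")) b <- emission_likelihood(b, x)
  b <- as.matrix(b)
  n <- length(spec$states)
  Tn <- nrow(b)
  stopifnot(ncol(b) == n, Tn >= 1)
  logb <- log(pmax(b, .Machine$double.xmin))
  logA <- log(pmax(spec$A, .Machine$double.xmin))
  delta <- log(pmax(spec$pi, .Machine$double.xmin)) + logb[1, ]
  back <- matrix(0L, Tn, n)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + logA  # cand[i, j] = delta[i] + log a_ij
      best <- apply(cand, 2, which.max)  # first max = lowest index
      delta <- cand[cbind(best, seq_len(n))] + logb[t, ]
      back[t, ] <- best
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) {
    for (t in (Tn - 1):1) path[t] <- back[t + 1, path[t + 1]]
  }
  list(path = spec$states[path], log_score = max(delta))
}

#' Regression coefficients of the hypnosis-degree readout
#'
#' The shipped defaults are the published coefficient set for the 14-slot
#' standardized observation vector: the 10 named features carry the listed
#' weights, and slots 2, 3, 11 and 13 are reserved padding fixed at 0 (their
#' feature identity is not published). The intercept is 0.471.
#'
#' @return A tibble `slot`, `feature` (NA for the reserved slots), `beta`,
#'   with the intercept in attribute `"intercept"`.
#' @export
degree_coefficients <- function() {
  out <- tibble(
    slot = 1:14,
    feature = c("speed", NA, NA, "delta", "theta", "alpha", "beta", "gamma",
                "gaze_velocity", "pupil_diameter_left", NA,
                "pupil_diameter_right", NA, "ipd"),
    beta = c(0.231, 0, 0, 0.078, 0.113, 0.004, -0.112, 0.074, -0.007,
             0.083, 0, -0.179, 0, 0.071))
  attr(out, "intercept") <- 0.471
  out
}

#' Linear hypnosis-degree readout
#'
#' `degree = sum_i x_i * beta_i + beta_0` over the 14-slot standardized
#' feature vector. Input rows may be bare 14-vectors in slot order, or
#' named rows (vector, matrix or data frame) whose features are mapped to
#' their slots; unnamed slots contribute 0.
#'
#' @param x A numeric vector of length 14, or named feature row(s).
#' @param coefficients Coefficient table as from [degree_coefficients()].
#' @param intercept Intercept (defaults to the table's attribute).
#' @return Numeric vector of degrees, one per input row.
#' @export
#' @examples
#' hypnosis_degree(rep(0, 14))  # returns the intercept
hypnosis_degree <- function(x, coefficients = degree_coefficients(),
                            intercept = attr(coefficients, "intercept")) {
  beta <- coefficients$beta
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric,
                                                logical(1))])
  if (is.null(dim(x))) {
    if (!is.null(names(x))) {
      x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
    } else {
      if (length(x) != 14) {
        abort(sprintf("Unnamed input must have length 14, got %d.",
                      length(x)))
      }
      x <- matrix(x, nrow = 1)
    }
  }
  named <- coefficients[!is.na(coefficients$feature), ]
  if (!is.null(colnames(x)) && any(colnames(x) %in% named$feature)) {
    missing_feats <- setdiff(named$feature, colnames(x))
    if (length(missing_feats)) {
      abort(paste0("Input lacks feature(s): ",
                   paste(missing_feats, collapse = ", ")))
    }
    full <- matrix(0, nrow(x), 14)
    full[, named$slot] <- x[, named$feature, drop = FALSE]
    x <- full
  }
  if (ncol(x) != 14) {
    abort(sprintf("Expected 14 slots, got %d columns.", ncol(x)))
  }
  as.numeric(x %*% beta) + intercept
}

#' Refit the hypnosis-degree coefficients on training data
#'
#' Ordinary least squares of the 0/1 hypnosis indicator on the named
#' feature slots (reserved padding slots stay 0), as an alternative to the
#' shipped published coefficients.
#'
#' @param x Standardized named feature rows.
#' @param labels State label per row.
#' @param hypnosis_label Label counted as 1.
#' @return A coefficient table in the [degree_coefficients()] layout with
#'   the refit intercept attribute.
#' @export
refit_degree <- function(x, labels, hypnosis_label = "hypnosis") {
  coefs <- degree_coefficients()
  named <- coefs[!is.na(coefs$feature), ]
  if (is.data.frame(x)) x <- as.matrix(x[, named$feature, drop = FALSE])
  x <- x[, named$feature, drop = FALSE]
  y <- as.numeric(labels == hypnosis_label)
  fit <- lm.fit(cbind(1, x), y)
  coefs$beta[match(named$slot, coefs$slot)] <- unname(fit$coefficients[-1])
  attr(coefs, "intercept") <- unname(fit$coefficients[1])
  coefs
}
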