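# End-to-end model: fit the hybrid HMM on labeled recordings, decode new
# ones, serialize the bundle.

#' Fit the hybrid boosted-tree HMM on labeled recordings
#'
#' Fuses every recording ([fuse_recording()]), estimates the transition
#' matrix and initial distribution from the label sequences
#' ([estimate_transitions()]), standardizes the pooled features with
#' population moments, and trains the calibrated per-state emission
#' scorers ([train_emissions()]). The scaling moments and feature order are
#' stored with the model so decoding is reproducible.
#'
#' @param recordings A list of [multimodal_recording()] objects (or a
#'   single one), or a list of already fused feature tibbles.
#' @param config Pipeline overrides, see [pipeline_config()].
#' @param kappa Transition smoothing pseudo-count.
#' @param params Boosting hyperparameter overrides.
#' @param seed Seed for emission calibration folds.
#' @return An object of class `hybrid_hmm`.
#' @export
hhmm_fit <- function(recordings, config = NULL, kappa = 1, params = list(),
                     seed = 1) {
  fused <- fuse_inputs(recordings, config)
  states <- c("normal", setdiff(sort(unique(unlist(
    lapply(fused, function(f) unique(f$label))))), "normal"))
  if (length(states) < 2) {
    abort("Training data contain a single state; cannot fit a 2-state model.")
  }
  spec <- estimate_transitions(lapply(fused, function(f) f$label),
                               states = states, kappa = kappa)
  pooled <- bind_rows(fused)
  std <- standardize(pooled)
  scaling <- attr(std, "scaling")
  x <- as.matrix(std[, fused_feature_names()])
  emissions <- train_emissions(x, std$label, states = states,
                               params = params, seed = seed)
  structure(
    list(spec = spec, emissions = emissions, scaling = scaling,
         config = merge_config(pipeline_config(), config),
         feature_names = fused_feature_names(),
         degree = degree_coefficients(), n_train_rows = nrow(std)),
    class = "hybrid_hmm")
}

fuse_inputs <- function(recordings, config = NULL) {
  if (inherits(recordings, "multimodal_recording")) {
    recordings <- list(recordings)
  }
  lapply(recordings, function(r) {
    if (inherits(r, "multimodal_recording")) {
      fuse_recording(r, config)
    } else {
      as_tibble(r)
    }
  })
}

#' @export
print.hybrid_hmm <- function(x, ...) {
  cat("<hybrid_hmm>\n")
  print(x$spec)
  cat(sprintf("emissions: %d trees/state, priors %s\n",
              x$emissions$params$nrounds,
              paste(sprintf("%s=%.3f", names(x$emissions$priors),
                            x$emissions$priors), collapse = " ")))
  cat(sprintf("trained on %d fused rows, %d features\n", x$n_train_rows,
              length(x$feature_names)))
  invisible(x)
}

#' Decode a recording with a fitted hybrid HMM
#'
#' Runs fusion with the training configuration, applies the stored
#' standardization moments, computes scaled emission likelihoods, and
#' returns filtered posteriors, the Viterbi path and the hypnosis-degree
#' series.
#'
#' @param object A fitted [hhmm_fit()] model.
#' @param newdata A [multimodal_recording()] or an already fused feature
#'   tibble (as from [fuse_recording()]).
#' @param ... Unused.
#' @return A tibble of class `hhmm_decode`: `time_s`, `label` (if known),
#'   `posterior_<state>` columns, `viterbi_state`, `hypnosis_degree`;
#'   attributes `log_likelihood` and `viterbi_log_score`.
#' @export
predict.hybrid_hmm <- function(object, newdata, ...) {
  fused <- if (inherits(newdata, "multimodal_recording")) {
    fuse_recording(newdata, object$config)
  } else {
    as_tibble(newdata)
  }
  missing_cols <- setdiff(object$feature_names, names(fused))
  if (length(missing_cols)) {
    abort(paste0("Fused input lacks feature(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  std <- standardize(fused, params = object$scaling)
  x <- as.matrix(std[, object$feature_names])
  b <- emission_likelihood(object$emissions, x)
  fwd <- forward_filter(object$spec, b)
  vit <- viterbi_path(object$spec, b)
  out <- tibble(time_s = fused$time_s)
  if ("label" %in% names(fused)) out$label <- fused$label
  for (st in object$spec$states) {
    out[[paste0("posterior_", st)]] <- fwd$posterior[, st]
  }
  out$viterbi_state <- vit$path
  out$hypnosis_degree <- hypnosis_degree(x, object$degree)
  attr(out, "log_likelihood") <- fwd$log_likelihood
  attr(out, "viterbi_log_score") <- vit$log_score
  class(out) <- c("hhmm_decode", class(out))
  out
}

#' @export
tidy.hybrid_hmm <- function(x, ...) {
  A <- x$spec$A
  tibble(from = rep(rownames(A), each = ncol(A)),
         to = rep(colnames(A), times = nrow(A)),
         probability = as.numeric(t(A)))
}

#' @export
glance.hybrid_hmm <- function(x, ...) {
  tibble(n_states = length(x$spec$states),
         n_features = length(x$feature_names),
         n_train_rows = x$n_train_rows,
         prior_hypnosis = unname(x$emissions$priors["hypnosis"]),
         trees_per_state = x$emissions$params$nrounds)
}

#' Save a fitted model bundle to a directory
#'
#' Writes `hmm.json` (states, pi, A), `fusion_params.json` (scaling moments
#' + pipeline config), `platt.json` (per-state calibrators and priors),
#' `coefficients.json` (degree readout) and one `emission_<state>.json`
#' booster file per state.
#'
#' @param model A fitted [hhmm_fit()] model.
#' @param dir Bundle directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_hhmm <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(states = model$spec$states, pi = unname(model$spec$pi),
         A = unname(model$spec$A)),
    file.path(dir, "hmm.json"), digits = NA)
  jsonlite::write_json(
    list(scaling = model$scaling, config = model$config,
         feature_names = model$feature_names,
         n_train_rows = model$n_train_rows),
    file.path(dir, "fusion_params.json"), digits = NA)
  jsonlite::write_json(
    list(platt = lapply(model$emissions$platt, unname),
         priors = as.list(model$emissions$priors),
         params = model$emissions$params),
    file.path(dir, "platt.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(slot = model$degree$slot, feature = model$degree$feature,
         beta = model$degree$beta,
         intercept = attr(model$degree, "intercept")),
    file.path(dir, "coefficients.json"), digits = NA)
  for (st in model$spec$states) {
    xgboost::xgb.save(model$emissions$boosters[[st]],
                      file.path(dir, paste0("emission_", st, ".json")))
  }
  invisible(dir)
}

#' Load a model bundle saved by [save_hhmm()]
#'
#' @param dir Bundle directory.
#' @return A `hybrid_hmm` model.
#' @export
load_hhmm <- function(dir) {
  hmm <- jsonlite::read_json(file.path(dir, "hmm.json"),
                             simplifyVector = TRUE)
  fus <- jsonlite::read_json(file.path(dir, "fusion_params.json"),
                             simplifyVector = TRUE)
  pl <- jsonlite::read_json(file.path(dir, "platt.json"),
                            simplifyVector = TRUE)
  co <- jsonlite::read_json(file.path(dir, "coefficients.json"),
                            simplifyVector = TRUE)
  states <- hmm$states
  boosters <- lapply(states, function(st) {
    xgboost::xgb.load(file.path(dir, paste0("emission_", st, ".json")))
  })
  names(boosters) <- states
  emissions <- structure(
    list(boosters = boosters,
         platt = lapply(pl$platt, function(v) setNames(v, c("(Intercept)",
                                                            "oof"))),
         priors = unlist(pl$priors), states = states,
         feature_names = fus$feature_names, params = pl$params),
    class = "emission_model")
  degree <- tibble(slot = co$slot, feature = co$feature, beta = co$beta)
  attr(degree, "intercept") <- co$intercept
  cfg <- fus$config
  cfg <- rapply(cfg, function(v) v, how = "replace")
  structure(
    list(spec = hmm_spec(hmm$pi, hmm$A, states),
         emissions = emissions,
         scaling = as_tibble(fus$scaling),
         config = cfg, feature_names = fus$feature_names,
         degree = degree, n_train_rows = fus$n_train_rows),
    class = "hybrid_hmm")
}
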