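# Lazily built shared fixtures (cached for the whole test session).

.fixture_env <- new.env(parent = emptyenv())

# a compact simulated dataset + fitted model shared by model-level tests
fixture_dataset <- function() {
  if (is.null(.fixture_env$recs)) {
    cfg <- sim_config(duration_s = 200, n_recordings = 6)
    .fixture_env$cfg <- cfg
    .fixture_env$recs <- generate_dataset(cfg, k = 6, seed = 7)
    .fixture_env$fused <- lapply(.fixture_env$recs, fuse_recording)
  }
  list(cfg = .fixture_env$cfg, recs = .fixture_env$recs,
       fused = .fixture_env$fused)
}

fixture_model <- function() {
  if (is.null(.fixture_env$model)) {
    ds <- fixture_dataset()
    .fixture_env$model <- hhmm_fit(ds$fused[1:4], seed = 1)
  }
  .fixture_env$model
}

# brute-force HMM oracles: enumerate all N^T paths
enum_likelihood <- function(pi, A, b) {
  Tn <- nrow(b); n <- ncol(b)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- pi[s[1]] * b[1, s[1]]
    if (Tn > 1) for (t in 2:Tn) p <- p * A[s[t - 1], s[t]] * b[t, s[t]]
    total <- total + p
  }
  total
}

enum_best_path <- function(pi, A, b) {
  Tn <- nrow(b); n <- ncol(b)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tn)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- log(pi[s[1]]) + log(b[1, s[1]])
    if (Tn > 1) for (t in 2:Tn) p <- p + log(A[s[t - 1], s[t]]) +
        log(b[t, s[t]])
    if (p > best + 1e-12) { best <- p; best_path <- s }
  }
  list(path = best_path, log_score = best)
}

random_hmm_case <- function(n_states, Tn) {
  pi <- runif(n_states); pi <- pi / sum(pi)
  A <- matrix(runif(n_states^2), n_states)
  A <- A / rowSums(A)
  b <- matrix(runif(Tn * n_states, 0.05, 1), Tn, n_states)
  list(pi = pi, A = A, b = b)
}
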