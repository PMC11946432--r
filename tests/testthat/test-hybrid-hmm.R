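test_that("estimate_transitions counts and smooths correctly", {
  a <- estimate_transitions(list(c("n", "n", "h", "h")),
                            states = c("n", "h"), kappa = 0)
  expect_equal(unname(a$A), matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE))

  b <- estimate_transitions(list(c("n", "n", "n")), states = c("n"),
                            kappa = 0)
  expect_equal(unname(b$A[1, 1]), 1)

  # a state never left: pure smoothing gives a uniform row
  c2 <- estimate_transitions(list(c("n", "n")), states = c("n", "h"),
                             kappa = 1)
  expect_equal(unname(c2$A["h", ]), c(0.5, 0.5))
  expect_error(estimate_transitions(list(c("n", "z")), states = c("n",
                                                                  "h")),
               "Unknown label")
  expect_error(estimate_transitions(list("n"), states = c("n", "h")),
               "two or more steps")
})

test_that("transition rows and pi always sum to 1", {
  set.seed(20)
  for (i in 1:20) {
    seqs <- lapply(1:3, function(j) {
      sample(c("normal", "hypnosis"), 30, replace = TRUE)
    })
    sp <- estimate_transitions(seqs, kappa = sample(0:2, 1))
    expect_lt(max(abs(rowSums(sp$A) - 1)), 1e-10)
    expect_lt(abs(sum(sp$pi) - 1), 1e-10)
  }
})

test_that("emission scorers separate separable classes and stay calibrated", {
  sep <- make_fused_pair(n = 400, shift = 4)
  em <- train_emissions(sep$x, sep$labels, states = c("normal",
                                                      "hypnosis"),
                        seed = 1)
  post <- emission_posterior(em, sep$x)
  true_post <- post[cbind(seq_len(400),
                          match(sep$labels, c("normal", "hypnosis")))]
  expect_gte(mean(true_post > 0.9), 0.95)
  expect_lt(max(abs(rowSums(post) - 1)), 1e-8)

  # labels independent of features: calibrated posteriors ~ class priors
  set.seed(33)
  n <- 2000
  xr <- matrix(rnorm(n * 3), n, 3,
               dimnames = list(NULL, c("f1", "f2", "f3")))
  yr <- sample(c("normal", "hypnosis"), n, replace = TRUE,
               prob = c(0.7, 0.3))
  emr <- train_emissions(xr, yr, states = c("normal", "hypnosis"),
                         seed = 2)
  pr <- emission_posterior(emr, xr)
  prior_h <- mean(yr == "hypnosis")
  expect_lt(mean(abs(pr[, "hypnosis"] - prior_h)), 0.05)

  expect_error(train_emissions(sep$x, rep("normal", 400)),
               "fewer than 2")
})

test_that("emission training is deterministic under a fixed seed", {
  sep <- make_fused_pair(n = 200, shift = 2)
  e1 <- train_emissions(sep$x, sep$labels, seed = 5)
  e2 <- train_emissions(sep$x, sep$labels, seed = 5)
  expect_identical(emission_posterior(e1, sep$x),
                   emission_posterior(e2, sep$x))
})

test_that("emission_likelihood is the prior-scaled posterior with a floor", {
  sep <- make_fused_pair(n = 200, shift = 6)
  em <- train_emissions(sep$x, sep$labels, seed = 1)
  post <- emission_posterior(em, sep$x)
  b <- emission_likelihood(em, sep$x)
  expect_equal(b, pmax(sweep(post, 2, em$priors, "/"), 1e-12))
  expect_true(all(b > 0))
  expect_error(emission_likelihood(em, matrix(0, 1, 7)), "features")
  # posterior equal to priors -> all scaled likelihoods are 1
  manual <- sweep(matrix(em$priors, 1, 2,
                         dimnames = list(NULL, em$states)), 2,
                  em$priors, "/")
  expect_equal(as.numeric(manual), c(1, 1))
})

test_that("forward filtering matches its closed-form reductions", {
  # N = 1: posterior 1 everywhere, log-likelihood = sum(log b)
  s1 <- hmm_spec(1, matrix(1), states = "only")
  b1 <- matrix(c(0.2, 0.5, 0.9), 3, 1)
  f1 <- forward_filter(s1, b1)
  expect_equal(as.numeric(f1$posterior), rep(1, 3))
  expect_equal(f1$log_likelihood, sum(log(b1)))

  # uniform emissions: filtered posteriors are the chain marginals pi A^t
  pi0 <- c(0.9, 0.1)
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, byrow = TRUE)
  sp <- hmm_spec(pi0, A)
  Tn <- 6
  f <- forward_filter(sp, matrix(1, Tn, 2))
  marg <- pi0
  for (t in seq_len(Tn)) {
    expect_lt(max(abs(f$posterior[t, ] - marg)), 1e-10)
    marg <- as.numeric(marg %*% A)
  }
})

test_that("forward likelihood equals brute-force path enumeration", {
  set.seed(77)
  pi0 <- c(0.6, 0.4)
  A <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, byrow = TRUE)
  b <- matrix(runif(6, 0.1, 1), 3, 2)
  f <- forward_filter(hmm_spec(pi0, A), b)
  expect_equal(f$log_likelihood, log(enum_likelihood(pi0, A, b)),
               tolerance = 1e-12)
})

test_that("posterior rows sum to 1 and likelihood is scale invariant", {
  set.seed(41)
  for (rep_i in 1:5) {
    cs <- random_hmm_case(2, 10)
    sp <- hmm_spec(cs$pi, cs$A, states = c("s1", "s2"))
    f <- forward_filter(sp, cs$b)
    expect_lt(max(abs(rowSums(f$posterior) - 1)), 1e-10)
    # multiply all emissions at one step by a constant: log-lik shifts by
    # log(c), posteriors unchanged
    b2 <- cs$b
    b2[4, ] <- b2[4, ] * 13
    f2 <- forward_filter(sp, b2)
    expect_lt(abs(f2$log_likelihood - f$log_likelihood - log(13)), 1e-9)
    expect_lt(max(abs(f2$posterior - f$posterior)), 1e-12)
    # Viterbi log-score never exceeds the total log-likelihood
    v <- viterbi_path(sp, cs$b)
    expect_lte(v$log_score, f$log_likelihood + 1e-12)
  }
})

test_that("viterbi matches exhaustive search and breaks ties low", {
  set.seed(55)
  for (rep_i in 1:10) {
    n_states <- sample(2:3, 1)
    Tn <- sample(3:7, 1)
    cs <- random_hmm_case(n_states, Tn)
    sp <- hmm_spec(cs$pi, cs$A, states = paste0("s", seq_len(n_states)))
    v <- viterbi_path(sp, cs$b)
    oracle <- enum_best_path(cs$pi, cs$A, cs$b)
    expect_equal(match(v$path, sp$states), unname(oracle$path))
    expect_equal(v$log_score, oracle$log_score, tolerance = 1e-10)
  }

  # near-deterministic emissions recover the generating path
  sp <- hmm_spec(c(0.5, 0.5), matrix(0.5, 2, 2), c("a", "b"))
  truth <- c(1, 2, 2, 1)
  b <- matrix(1, 4, 2)
  b[cbind(1:4, truth)] <- 1e6
  expect_equal(match(viterbi_path(sp, b)$path, c("a", "b")), truth)

  # exact symmetric tie: the lower state index wins everywhere
  tie <- viterbi_path(sp, matrix(1, 5, 2))
  expect_true(all(tie$path == "a"))
})

test_that("hypnosis_degree reproduces the published readout", {
  expect_equal(hypnosis_degree(rep(0, 14)), 0.471)
  unit_speed <- c(1, rep(0, 13))
  expect_equal(hypnosis_degree(unit_speed), 0.702)
  co <- degree_coefficients()
  ones_named <- setNames(rep(1, 10), co$feature[!is.na(co$feature)])
  expect_equal(hypnosis_degree(ones_named), 0.827)
  expect_error(hypnosis_degree(rep(0, 10)), "length 14")
})

test_that("transition matrix and path are recovered from simulated data", {
  set.seed(99)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE,
              dimnames = list(c("normal", "hypnosis"),
                              c("normal", "hypnosis")))
  n <- 5000
  lat <- simulate_latent_path(c(normal = 0.5, hypnosis = 0.5), A, n,
                              seed = 123)
  # Gaussian-shifted 2-D features per state
  shift <- ifelse(lat$states == "hypnosis", 2.5, 0)
  x <- cbind(f1 = rnorm(n) + shift, f2 = rnorm(n))
  spec <- estimate_transitions(list(lat$states),
                               states = c("normal", "hypnosis"))
  expect_lte(max(abs(spec$A - A)), 0.05)
  em <- train_emissions(scale(x), lat$states, seed = 1)
  v <- viterbi_path(spec, em, scale(x))
  expect_gte(mean(v$path == lat$states), 0.9)
})

test_that("predict decodes recordings deterministically", {
  ds <- fixture_dataset()
  model <- fixture_model()
  d1 <- predict(model, ds$fused[[5]])
  d2 <- predict(model, ds$fused[[5]])
  expect_identical(d1, d2)
  expect_equal(nrow(d1), nrow(ds$fused[[5]]))
  expect_true(all(abs(rowSums(cbind(d1$posterior_normal,
                                    d1$posterior_hypnosis)) - 1) < 1e-10))
  expect_gte(mean(d1$viterbi_state == d1$label), 0.85)
  expect_lte(attr(d1, "viterbi_log_score"), attr(d1, "log_likelihood"))

  # recording without hypnosis: mean hypnosis posterior stays low
  no_hyp <- ds$fused[[6]]
  no_hyp <- no_hyp[no_hyp$label == "normal", ]
  dn <- predict(model, no_hyp)
  expect_lt(mean(dn$posterior_hypnosis), 0.5)

  # missing modality reported by name
  broken <- ds$fused[[5]]
  broken$beta <- NULL
  expect_error(predict(model, broken), "beta")
})

test_that("model bundles survive a save/load round trip", {
  ds <- fixture_dataset()
  model <- fixture_model()
  dir <- withr::local_tempdir()
  save_hhmm(model, dir)
  back <- load_hhmm(dir)
  expect_equal(back$spec$A, model$spec$A)
  expect_equal(back$scaling, model$scaling)
  d1 <- predict(model, ds$fused[[5]])
  d2 <- predict(back, ds$fused[[5]])
  expect_equal(d2$posterior_hypnosis, d1$posterior_hypnosis,
               tolerance = 1e-6)
  expect_identical(d2$viterbi_state, d1$viterbi_state)
})

test_that("tidy and glance summarize a fitted model", {
  model <- fixture_model()
  td <- tidy(model)
  expect_named(td, c("from", "to", "probability"))
  expect_equal(sum(td$probability), 2)
  gl <- glance(model)
  expect_equal(gl$n_states, 2)
  expect_equal(gl$n_features, 11)
})
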