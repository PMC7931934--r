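test_that("default HMM matrices are well-formed", {
  for (sc in list(three_scheme, nine_scheme, nineteen_scheme)) {
    spec <- default_hmm(sc)
    expect_equal(rowSums(spec$transition), rep(1, length(spec$initial)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(rowSums(spec$emission), rep(1, length(spec$initial)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(sum(spec$initial), 1, tolerance = 1e-12)
    # emission concentrated on the latent class's own aggregated label
    for (i in seq_along(spec$initial)) {
      own <- spec$to_three[[names(spec$initial)[i]]]
      expect_gte(spec$emission[i, own], 0.9)
    }
    # the U column is identical across latent classes (uninformative)
    expect_equal(length(unique(spec$emission[, "U"])), 1)
  }
})

test_that("plantation-to-forest transitions are capped at delta", {
  spec <- default_hmm(nineteen_scheme, delta = 1e-6)
  p_lat <- names(spec$to_three)[spec$to_three == "P"]
  f_lat <- names(spec$to_three)[spec$to_three == "F"]
  expect_true(all(spec$transition[p_lat, f_lat] <= 1e-6 / 0.9))
  # rho = 1 gives the identity transition matrix
  spec_id <- default_hmm(three_scheme, rho = 1)
  expect_equal(spec_id$transition, diag(3), ignore_attr = TRUE)
})

test_that("deterministic emissions leave conflict-free sequences unchanged", {
  spec <- default_hmm(three_scheme, q = 1, delta = 0)
  for (obs in list(c("F", "F", "F"), c("O", "P", "P"), c("F", "O", "P"))) {
    expect_equal(viterbi_smooth(spec, obs), obs)
  }
})

test_that("the worked sequence is corrected to a persistent plantation", {
  obs <- c("F", "F", "P", "P", "F", "P")
  want <- c("F", "F", "P", "P", "P", "P")
  for (sc in list(nineteen_scheme, nine_scheme, three_scheme)) {
    spec <- default_hmm(sc, rho = 0.9, q = 0.9, delta = 1e-6)
    expect_equal(viterbi_smooth(spec, obs), want, label = sc$name)
  }
})

test_that("Viterbi equals exhaustive path enumeration", {
  # all observation sequences of length <= 4 over {P,F,O}, three latent
  # schemes: identical best-path score, identical smoothed labels
  for (sc in list(three_scheme, nine_scheme, nineteen_scheme)) {
    spec <- default_hmm(sc)
    for (len in 1:4) {
      for (obs in all_sequences(c("P", "F", "O"), len)) {
        bf <- brute_force_smooth(spec, obs)
        path <- plantmapr:::viterbi_batch(spec, matrix(obs, nrow = 1))[1, ]
        expect_equal(path_logp(spec, path, obs), bf$logp,
                     tolerance = 1e-10,
                     label = paste(sc$name, paste(obs, collapse = "")))
        expect_equal(viterbi_smooth(spec, obs), bf$labels,
                     label = paste(sc$name, paste(obs, collapse = "")))
      }
    }
  }
})

test_that("the worked sequence matches brute-force enumeration end to end", {
  obs <- c("F", "F", "P", "P", "F", "P")
  for (sc in list(three_scheme, nine_scheme)) {
    spec <- default_hmm(sc, rho = 0.9, q = 0.9, delta = 1e-6)
    expect_equal(viterbi_smooth(spec, obs), brute_force_smooth(spec, obs)$labels)
  }
})

test_that("U observations are uninformative", {
  spec <- default_hmm(nineteen_scheme)
  # replacing an observation consistent with its neighbours by U does not
  # change the decoded labels elsewhere
  expect_equal(viterbi_smooth(spec, c("P", "U", "P", "P")),
               c("P", "P", "P", "P"))
  expect_equal(viterbi_smooth(spec, c("F", "U", "F")), c("F", "F", "F"))
  # a single U decodes deterministically (lowest-index tie-break applies)
  expect_length(viterbi_smooth(spec, "U"), 1)
})

test_that("anti-reversion: with delta = 0 no P is later followed by F", {
  spec <- default_hmm(nineteen_scheme, delta = 0)
  set.seed(42)
  for (i in 1:50) {
    obs <- sample(c("P", "F", "O", "U"), 8, replace = TRUE)
    sm <- viterbi_smooth(spec, obs)
    p_pos <- which(sm == "P")
    if (length(p_pos) > 0) {
      expect_false(any(sm[seq_along(sm) > min(p_pos)] == "F"),
                   label = paste(obs, collapse = ""))
    }
  }
})

test_that("length-1 sequences are returned unchanged", {
  spec <- default_hmm(nineteen_scheme)
  for (obs in c("P", "F", "O")) {
    expect_equal(viterbi_smooth(spec, obs), obs)
  }
})

test_that("invalid observations are rejected", {
  spec <- default_hmm(three_scheme)
  expect_error(viterbi_smooth(spec, c("P", "X")), "outside")
})

test_that("transition estimation recovers the generator", {
  # constant sequences, no smoothing -> identity
  truth <- matrix(rep(c("OPL", "DIF", "SCH"), each = 5), 3, 5, byrow = TRUE)
  est <- estimate_transitions(truth, three_scheme, alpha = 0)
  expect_equal(est, diag(3), ignore_attr = TRUE)
  # two-state toy with known generator, multinomial 3-sigma bound
  set.seed(9)
  p_stay <- 0.8
  n_seq <- 500; len <- 21  # 10,000 transitions
  seqs <- replicate(n_seq, {
    s <- character(len); s[1] <- "UDF"
    for (t in 2:len) {
      cur <- s[t - 1]
      s[t] <- if (stats::runif(1) < p_stay) cur else setdiff(c("UDF", "OPL"), cur)
    }
    s
  }, simplify = FALSE)
  est2 <- estimate_transitions(seqs, nineteen_scheme, alpha = 0)
  n_from_udf <- sum(unlist(lapply(seqs, function(s) sum(s[-len] == "UDF"))))
  sigma <- sqrt(p_stay * (1 - p_stay) / n_from_udf)
  expect_lt(abs(est2["UDF", "UDF"] - p_stay), 3 * sigma)
  # pseudocounts make every entry positive
  est3 <- estimate_transitions(truth, three_scheme, alpha = 1)
  expect_true(all(est3 > 0))
  expect_equal(rowSums(est3), rep(1, 3), ignore_attr = TRUE)
  expect_error(estimate_transitions(list(), three_scheme), "length >= 2")
})

test_that("smoothing reduces symmetric label noise on truth sequences", {
  spec <- default_hmm(nineteen_scheme)
  cfg <- scene_config(n_rows = 20, n_cols = 10, seed = 31)
  truth <- simulate_truth(cfg)
  t3 <- matrix(aggregate_code(as.vector(truth), three_scheme), nrow(truth),
               dimnames = dimnames(truth))
  set.seed(31)
  obs <- t3
  flip <- stats::runif(length(obs)) < 0.10
  obs[flip] <- vapply(obs[flip],
                      function(l) sample(setdiff(c("P", "F", "O"), l), 1), "")
  sm <- smooth_map(spec, obs)
  expect_lt(mean(sm != t3), mean(obs != t3))
})

test_that("smooth_map agrees with per-sequence viterbi_smooth", {
  spec <- default_hmm(nine_scheme)
  set.seed(5)
  pred <- matrix(sample(c("P", "F", "O", "U"), 60, replace = TRUE), 10, 6,
                 dimnames = list(1:10, 2000:2005))
  sm <- smooth_map(spec, pred)
  for (i in 1:10) {
    expect_equal(unname(sm[i, ]), viterbi_smooth(spec, pred[i, ]))
  }
})

test_that("posterior decoding is available and sane", {
  spec <- default_hmm(nineteen_scheme)
  set.seed(12)
  pred <- matrix(sample(c("P", "F", "O", "U"), 80, replace = TRUE), 10, 8,
                 dimnames = list(1:10, 2000:2007))
  sm <- smooth_map(spec, pred, method = "posterior")
  expect_true(all(sm %in% c("P", "F", "O")))
  expect_equal(dim(sm), dim(pred))
  # on clean consistent sequences both decoders agree with the input
  clean <- matrix(rep(c("F", "F", "O", "O", "P", "P", "P", "P"), 3), 3, 8,
                  byrow = TRUE, dimnames = list(1:3, 2000:2007))
  expect_equal(smooth_map(spec, clean, method = "viterbi"), clean)
  expect_equal(smooth_map(spec, clean, method = "posterior"), clean)
  # posterior marginals from a single sequence work too (no dim dropping)
  one <- clean[1, , drop = FALSE]
  expect_equal(smooth_map(spec, one, method = "posterior"), one)
})

test_that("HMM specifications round-trip through YAML", {
  spec <- default_hmm(nine_scheme, rho = 0.85, q = 0.92, delta = 1e-5)
  tmp <- tempfile(fileext = ".yaml")
  write_hmm_spec(spec, tmp)
  back <- read_hmm_spec(tmp)
  expect_equal(back$initial, spec$initial)
  expect_equal(back$transition, spec$transition, tolerance = 1e-12)
  expect_equal(back$emission, spec$emission, tolerance = 1e-12)
  obs <- c("F", "P", "F", "P")
  expect_equal(viterbi_smooth(back, obs), viterbi_smooth(spec, obs))
  t2 <- tempfile(); yaml::write_yaml(list(latent_scheme = "nine"), t2)
  expect_error(read_hmm_spec(t2), "missing field")
})
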