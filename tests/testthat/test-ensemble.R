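test_that("feature assembly is composite-major and invertible", {
  m <- matrix(0, 46, 7)
  expect_equal(assemble_features(m), rep(0, 322))
  m[1, ] <- 1:7
  expect_equal(assemble_features(m)[1:7], 1:7)
  set.seed(1)
  m2 <- matrix(stats::runif(322), 46, 7)
  expect_equal(unflatten_features(assemble_features(m2)), m2)
  expect_error(assemble_features(matrix(0, 40, 7)), "46")
  m3 <- m2; m3[5, 3] <- NA
  expect_error(assemble_features(m3), "missing")
})

# The full three-classifier aggregation table: every combination of the
# P-F, F-O and O-P votes and its published aggregated label.
vote_table <- data.frame(
  pf = c("P", "P", "F", "F", "P", "F", "P", "F"),
  fo = c("F", "O", "F", "F", "O", "O", "F", "O"),
  op = c("P", "P", "O", "P", "O", "O", "O", "P"),
  agg = c("P", "P", "F", "F", "O", "O", "U", "U")
)

test_that("vote aggregation reproduces the three-class table exactly", {
  for (i in seq_len(nrow(vote_table))) {
    votes <- c("P-F" = vote_table$pf[i], "F-O" = vote_table$fo[i],
               "O-P" = vote_table$op[i])
    expect_equal(aggregate_votes(votes, three_scheme), vote_table$agg[i],
                 label = paste(votes, collapse = ","))
  }
})

test_that("the three-classifier joint outcome space has exactly 8 rows", {
  combos <- expand.grid(pf = c("P", "F"), fo = c("F", "O"), op = c("O", "P"),
                        stringsAsFactors = FALSE)
  expect_equal(nrow(combos), 8)
  expect_equal(nrow(unique(combos)), 8)
  # and every one of them aggregates without error
  labs <- apply(combos, 1, function(r) {
    aggregate_votes(c("P-F" = r[["pf"]], "F-O" = r[["fo"]], "O-P" = r[["op"]]),
                    three_scheme)
  })
  expect_setequal(unique(labs), c("P", "F", "O", "U"))
})

test_that("vote aggregation is invariant to pair order and orientation", {
  votes <- c("P-F" = "P", "F-O" = "F", "O-P" = "P")
  reordered <- votes[c(3, 1, 2)]
  flipped <- c("F-P" = "P", "O-F" = "F", "P-O" = "P")
  expect_equal(aggregate_votes(reordered, three_scheme),
               aggregate_votes(votes, three_scheme))
  expect_equal(aggregate_votes(flipped, three_scheme),
               aggregate_votes(votes, three_scheme))
})

test_that("two agreeing classifiers decide regardless of the third", {
  for (third in c("F", "O")) {
    votes <- c("P-F" = "P", "O-P" = "P",
               "F-O" = third)
    expect_equal(aggregate_votes(votes, three_scheme), "P")
  }
})

test_that("malformed votes are rejected", {
  expect_error(aggregate_votes(c("P-F" = "O", "F-O" = "F", "O-P" = "P"),
                               three_scheme), "not a member")
  expect_error(aggregate_votes(c("P-F" = "P", "F-O" = "F"), three_scheme),
               "one vote per unordered pair")
  expect_error(aggregate_votes(c("P-F" = "P", "F-O" = "F", "O-P" = "P",
                                 "P-F" = "F"), three_scheme),
               "one vote per unordered pair")
  expect_error(aggregate_votes(c("P-X" = "P", "F-O" = "F", "O-P" = "P"),
                               three_scheme), "malformed pair")
})

test_that("four-class majority returns a label winning all its pairs", {
  # exhaustive: whenever one label wins every pair it appears in (3 of 3),
  # the aggregation returns it
  labels <- four_scheme$labels
  pairs <- utils::combn(labels, 2)
  pair_names <- apply(pairs, 2, paste, collapse = "-")
  grid <- expand.grid(lapply(seq_len(ncol(pairs)), function(j) pairs[, j]),
                      stringsAsFactors = FALSE)
  names(grid) <- pair_names
  for (i in seq_len(nrow(grid))) {
    votes <- unlist(grid[i, ])
    counts <- table(factor(votes, levels = labels))
    out <- aggregate_votes(votes, four_scheme)
    if (max(counts) == 3) {
      expect_equal(out, names(counts)[which.max(counts)])
    } else if (sum(counts == max(counts)) > 1) {
      expect_equal(out, "U")
    }
  }
})

test_that("ensembles hold one classifier per unordered label pair", {
  sc <- noiseless_scene()
  pool <- scene_pool(sc)
  train <- suppressWarnings(balanced_sample(pool, three_scheme, 15, seed = 2))
  model <- train_ensemble(train, three_scheme, backend_spec("logistic"),
                          seed = 2)
  expect_setequal(names(model$classifiers), c("P-F", "P-O", "F-O"))
  train4 <- suppressWarnings(balanced_sample(pool, four_scheme, 15, seed = 2))
  model4 <- train_ensemble(train4, four_scheme, backend_spec("logistic"),
                           seed = 2)
  expect_length(model4$classifiers, 6)
})

test_that("pairwise classifiers are perfect on noiseless separable data", {
  sc <- noiseless_scene()
  pool <- scene_pool(sc)
  train <- suppressWarnings(balanced_sample(pool, three_scheme, 15, seed = 3))
  model <- train_ensemble(train, three_scheme, backend_spec("logistic"),
                          seed = 3)
  agg <- aggregate_code(train$meta$code, three_scheme)
  x <- plantmapr:::apply_band_scaler(model$scaler, train$features)
  for (nm in names(model$classifiers)) {
    pr <- strsplit(nm, "-")[[1]]
    idx <- agg %in% pr
    pred <- predict_backend(model$classifiers[[nm]], x[idx, , drop = FALSE])
    expect_equal(mean(pred == agg[idx]), 1.0, label = nm)
  }
  # and the aggregated map matches the truth almost everywhere
  pred_map <- predict_map(model, sc)
  expect_gte(mean(pred_map == truth_three(sc)), 0.99)
})

test_that("binary scheme never emits Unknown", {
  sc <- tiny_scene()
  pool <- scene_pool(sc)
  train <- suppressWarnings(balanced_sample(pool, binary_scheme, 15, seed = 4))
  model <- train_ensemble(train, binary_scheme, backend_spec("logistic"),
                          seed = 4)
  pred <- predict_map(model, sc)
  expect_true(all(pred %in% c("P", "nonP")))
})

test_that("training validates label coverage and dimensionality", {
  sc <- tiny_scene()
  pool <- scene_pool(sc)
  # a pool with no plantation samples cannot train the ensemble
  keep <- aggregate_code(pool$meta$code, three_scheme) != "P"
  pool_np <- plantmapr:::subset_samples(pool, which(keep))
  train_np <- suppressWarnings(balanced_sample(pool_np, three_scheme, 10,
                                               seed = 1))
  expect_error(train_ensemble(train_np, three_scheme,
                              backend_spec("logistic"), seed = 1),
               "unrepresented")
  # dimensionality mismatch at prediction time
  train <- suppressWarnings(balanced_sample(pool, three_scheme, 10, seed = 1))
  model <- train_ensemble(train, three_scheme, backend_spec("logistic"),
                          seed = 1)
  expect_error(predict_ensemble(model, matrix(0, 2, 100)), "mismatch")
})

test_that("training is reproducible from the seed (mlp backend)", {
  sc <- tiny_scene()
  pool <- scene_pool(sc)
  train <- suppressWarnings(balanced_sample(pool, three_scheme, 10, seed = 5))
  be <- backend_spec("mlp", epochs = 10)
  m1 <- train_ensemble(train, three_scheme, be, seed = 5)
  m2 <- train_ensemble(train, three_scheme, be, seed = 5)
  p1 <- predict_ensemble(m1, pool$features[1:50, ])
  p2 <- predict_ensemble(m2, pool$features[1:50, ])
  expect_identical(p1, p2)
})

test_that("plantation scores are vote shares in {0, 1/2, 1}", {
  sc <- tiny_scene()
  pool <- scene_pool(sc)
  train <- suppressWarnings(balanced_sample(pool, three_scheme, 10, seed = 6))
  model <- train_ensemble(train, three_scheme, backend_spec("logistic"),
                          seed = 6)
  s <- plantation_score(model, pool$features[1:100, ])
  expect_true(all(s %in% c(0, 0.5, 1)))
})
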