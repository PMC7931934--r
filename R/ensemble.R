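# One-vs-one pairwise ensemble with Unknown-tie vote aggregation.
#
# For a k-class scheme, k(k-1)/2 binary classifiers are trained, one per
# unordered label pair, each on the training samples of its two classes
# only. At prediction time every classifier casts one vote; the unique
# majority label wins and ties yield the Unknown label "U".

#' Flatten a 46 x 7 reflectance record to a feature vector
#'
#' Produces the composite-major feature layout used everywhere in the
#' package: composite 1 bands 1--7, composite 2 bands 1--7, ..., composite
#' 46 bands 1--7 — 322 values.
#'
#' @param series Numeric 46 x 7 matrix (rows = composites, cols = bands).
#' @return Numeric vector of length 322.
#' @export
#' @examples
#' m <- matrix(0, 46, 7); m[1, ] <- 1:7
#' assemble_features(m)[1:7]  # 1 2 3 4 5 6 7
assemble_features <- function(series) {
  if (!is.matrix(series) || nrow(series) != N_COMPOSITES ||
      ncol(series) != N_BANDS) {
    stop("series must be a ", N_COMPOSITES, " x ", N_BANDS, " matrix")
  }
  if (anyNA(series)) stop("series has missing entries; imputation is not supported")
  as.vector(t(series))
}

#' Inverse of [assemble_features()]
#'
#' @param features Numeric vector of length 322.
#' @return 46 x 7 matrix.
#' @export
unflatten_features <- function(features) {
  if (length(features) != N_FEATURES) {
    stop("features must have length ", N_FEATURES)
  }
  t(matrix(features, N_BANDS, N_COMPOSITES))
}

# Per-band standardization fitted on training features only: one mean and
# one sd per spectral band, pooled over the 46 composites.
fit_band_scaler <- function(features) {
  band_of <- rep(seq_len(N_BANDS), times = N_COMPOSITES)
  mu <- vapply(seq_len(N_BANDS), function(b) {
    mean(features[, band_of == b])
  }, numeric(1))
  sd_ <- vapply(seq_len(N_BANDS), function(b) {
    stats::sd(as.vector(features[, band_of == b]))
  }, numeric(1))
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  list(mu = mu, sd = sd_, band_of = band_of)
}

apply_band_scaler <- function(scaler, features) {
  mu_full <- scaler$mu[scaler$band_of]
  sd_full <- scaler$sd[scaler$band_of]
  sweep(sweep(features, 2, mu_full, "-"), 2, sd_full, "/")
}

pair_name <- function(a, b) paste(a, b, sep = "-")

# Unordered label pairs in scheme order: for three -> P-F, P-O, F-O.
scheme_pairs <- function(scheme) {
  labels <- scheme$labels
  if (length(labels) < 2) stop("scheme needs at least 2 labels")
  pairs <- utils::combn(labels, 2)
  stats::setNames(
    lapply(seq_len(ncol(pairs)), function(j) pairs[, j]),
    apply(pairs, 2, function(p) pair_name(p[1], p[2]))
  )
}

#' Train the pairwise ensemble
#'
#' Fits one binary backend per unordered pair of the scheme's labels, each
#' restricted to the training samples whose aggregated label is one of the
#' pair. Feature standardization (per spectral band) is fitted on the
#' training set only and stored with the model.
#'
#' @param train A [labeled_samples()] training set.
#' @param scheme The active [class_scheme()].
#' @param backend A [backend_spec()]; default the 158-64-20 network.
#' @param seed Integer seed threaded into every backend fit.
#' @return Object of class `ensemble_model`.
#' @export
train_ensemble <- function(train, scheme, backend = backend_spec(), seed = 1L) {
  stopifnot(inherits(train, "labeled_samples"),
            inherits(scheme, "class_scheme"),
            inherits(backend, "backend_spec"))
  agg <- aggregate_code(train$meta$code, scheme)
  missing_labels <- setdiff(scheme$labels, unique(agg))
  if (length(missing_labels) > 0) {
    stop("scheme label(s) unrepresented in training set: ",
         paste(missing_labels, collapse = ", "))
  }
  scaler <- fit_band_scaler(train$features)
  x <- apply_band_scaler(scaler, train$features)
  pairs <- scheme_pairs(scheme)
  classifiers <- vector("list", length(pairs))
  names(classifiers) <- names(pairs)
  for (j in seq_along(pairs)) {
    pr <- pairs[[j]]
    idx <- which(agg %in% pr)
    sides <- table(factor(agg[idx], levels = pr))
    if (any(sides == 0)) {
      stop("pair ", names(pairs)[j], " has an empty side: ",
           pr[which(sides == 0)[1]])
    }
    classifiers[[j]] <- fit_backend(backend, x[idx, , drop = FALSE], agg[idx],
                                    seed = seed + j)
  }
  structure(list(scheme = scheme, backend = backend, scaler = scaler,
                 classifiers = classifiers,
                 meta = list(n_train = n_samples(train),
                             per_label = table(agg), seed = seed)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model>", x$scheme$name, "scheme,",
      length(x$classifiers), "pairwise", x$backend$type, "classifier(s):",
      paste(names(x$classifiers), collapse = ", "), "\n")
  cat("  trained on ", x$meta$n_train, " samples (seed ", x$meta$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Aggregate pairwise votes into a final label
#'
#' Counts the votes cast by the pairwise classifiers and returns the
#' unique majority label; if the maximal vote count is shared (the
#' classifiers mutually disagree), the Unknown label `"U"` is returned.
#' For the three-class scheme this reproduces the full 8-row aggregation
#' table of the P-F / F-O / O-P classifiers, including both U rows.
#'
#' @param votes Named character vector: names are pair names (`"P-F"`,
#'   `"F-O"`, `"O-P"` in any order/orientation), values the winning label
#'   of each pair.
#' @param scheme The active [class_scheme()].
#' @return A single scheme label or `"U"`.
#' @export
#' @examples
#' sc <- class_scheme("three")
#' aggregate_votes(c("P-F" = "P", "F-O" = "F", "O-P" = "P"), sc)  # "P"
#' aggregate_votes(c("P-F" = "P", "F-O" = "F", "O-P" = "O"), sc)  # "U"
aggregate_votes <- function(votes, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  if (is.null(names(votes)) || any(!nzchar(names(votes)))) {
    stop("votes must be named by label pair, e.g. 'P-F'")
  }
  pair_labels <- strsplit(names(votes), "-", fixed = TRUE)
  n_pairs <- choose(length(scheme$labels), 2)
  seen <- character(0)
  for (j in seq_along(votes)) {
    pr <- pair_labels[[j]]
    if (length(pr) != 2 || !all(pr %in% scheme$labels)) {
      stop("malformed pair name: ", names(votes)[j])
    }
    if (!votes[[j]] %in% pr) {
      stop("vote '", votes[[j]], "' is not a member of pair ", names(votes)[j])
    }
    seen <- c(seen, pair_name(sort(pr)[1], sort(pr)[2]))
  }
  if (anyDuplicated(seen) || length(votes) != n_pairs) {
    stop("expected exactly one vote per unordered pair (", n_pairs, " votes)")
  }
  counts <- table(factor(unlist(votes), levels = scheme$labels))
  top <- which(counts == max(counts))
  if (length(top) == 1) names(counts)[top] else "U"
}

# Vectorized vote aggregation over a feature matrix. Returns a list with
# hard labels and the per-label vote count matrix.
ensemble_votes <- function(model, features) {
  stopifnot(inherits(model, "ensemble_model"), is.matrix(features))
  if (ncol(features) != N_FEATURES) {
    stop("feature dimensionality mismatch: expected ", N_FEATURES,
         ", got ", ncol(features))
  }
  x <- apply_band_scaler(model$scaler, features)
  labels <- model$scheme$labels
  counts <- matrix(0L, nrow(x), length(labels),
                   dimnames = list(NULL, labels))
  for (nm in names(model$classifiers)) {
    pred <- predict_backend(model$classifiers[[nm]], x)
    for (lab in unique(pred)) {
      counts[pred == lab, lab] <- counts[pred == lab, lab] + 1L
    }
  }
  row_max <- do.call(pmax, as.data.frame(counts))
  n_at_max <- rowSums(counts == row_max)
  hard <- labels[max.col(counts, ties.method = "first")]
  hard[n_at_max > 1] <- "U"
  list(labels = hard, counts = counts)
}

#' Predict labels for a feature matrix
#'
#' @param model A trained [train_ensemble()] model.
#' @param features Numeric matrix with 322 columns.
#' @return Character vector of labels in `scheme labels + "U"`. A binary
#'   scheme has a single classifier and can never tie, so never emits `U`.
#' @export
predict_ensemble <- function(model, features) {
  ensemble_votes(model, features)$labels
}

#' Plantation score for ranking (AUC)
#'
#' The fraction of the pairwise classifiers involving the plantation label
#' that vote `P`: 0, 1/2 or 1 for the three-class scheme. Used as the
#' rankable statistic behind the learning-curve AUC.
#'
#' @param model A trained [train_ensemble()] model.
#' @param features Numeric matrix with 322 columns.
#' @return Numeric vector in \[0, 1\].
#' @export
plantation_score <- function(model, features) {
  counts <- ensemble_votes(model, features)$counts
  if (!"P" %in% colnames(counts)) stop("scheme has no plantation label 'P'")
  n_p_pairs <- sum(vapply(scheme_pairs(model$scheme),
                          function(pr) "P" %in% pr, logical(1)))
  counts[, "P"] / n_p_pairs
}

#' Predict a label map for a whole scene
#'
#' Runs every pairwise classifier on every pixel-year of the scene and
#' aggregates the votes.
#'
#' @param model A trained [train_ensemble()] model.
#' @param scene A `plant_scene` with a reflectance stack.
#' @param pixels Optional pixel subset (default all).
#' @return Character matrix (pixels x years) over the scheme's labels plus
#'   `"U"`, with years as column names and pixel ids as row names.
#' @export
predict_map <- function(model, scene, pixels = NULL) {
  stopifnot(inherits(model, "ensemble_model"), inherits(scene, "plant_scene"))
  if (is.null(scene$reflectance)) stop("scene has no reflectance stack")
  if (is.null(pixels)) pixels <- seq_len(nrow(scene$truth))
  years <- colnames(scene$truth)
  out <- matrix(NA_character_, length(pixels), length(years),
                dimnames = list(pixels, years))
  for (j in seq_along(years)) {
    out[, j] <- predict_ensemble(model, scene$reflectance[pixels, j, ])
  }
  out
}
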