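# Training-set construction: subclass-balanced sampling (the default) and
# the uniform-within-aggregated-class baseline.

#' Labeled sample pool
#'
#' A pool is a set of labeled pixel-years: metadata (pixel id, year,
#' land-cover code) plus the 322-length reflectance feature vector of each
#' pixel-year.
#'
#' @param meta data.frame with columns `pixel_id`, `year`, `code`.
#' @param features Numeric matrix, one row per row of `meta`, 322 columns
#'   in composite-major order.
#' @param replaced Optional named logical: subclass -> drawn with
#'   replacement (set by the samplers).
#' @return Object of class `labeled_samples`.
#' @export
labeled_samples <- function(meta, features, replaced = NULL) {
  stopifnot(is.data.frame(meta),
            all(c("pixel_id", "year", "code") %in% names(meta)),
            is.matrix(features), nrow(features) == nrow(meta))
  if (ncol(features) != N_FEATURES) {
    stop("feature vectors must have length ", N_FEATURES,
         " (46 composites x 7 bands), got ", ncol(features))
  }
  if (any(!is.finite(features))) stop("features must be finite")
  structure(list(meta = meta, features = features, replaced = replaced),
            class = "labeled_samples")
}

#' @export
print.labeled_samples <- function(x, ...) {
  cat("<labeled_samples>", nrow(x$meta), "pixel-years,",
      length(unique(x$meta$code)), "subclasses,",
      length(unique(x$meta$year)), "years\n")
  if (!is.null(x$replaced) && any(x$replaced)) {
    cat("  drawn with replacement:",
        paste(names(x$replaced)[x$replaced], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples
#' @param pool A `labeled_samples`.
#' @return Integer count.
#' @export
n_samples <- function(pool) nrow(pool$meta)

# sample() treats a length-1 numeric x as 1:x; index explicitly instead.
safe_sample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

# Row subset preserving the class.
subset_samples <- function(pool, idx) {
  labeled_samples(pool$meta[idx, , drop = FALSE],
                  pool$features[idx, , drop = FALSE],
                  replaced = pool$replaced)
}

#' Build the labeled pool of a simulated scene
#'
#' Pairs every pixel-year's true land-cover code with its reflectance
#' feature vector. Restrict with `pixels` / `years` (e.g. to keep a
#' held-out pixel set out of the training pool).
#'
#' @param scene A `plant_scene` with a reflectance stack.
#' @param pixels Integer pixel ids to include (default all).
#' @param years Years to include (default all).
#' @return A [labeled_samples()] pool.
#' @export
scene_pool <- function(scene, pixels = NULL, years = NULL) {
  stopifnot(inherits(scene, "plant_scene"))
  if (is.null(scene$reflectance)) stop("scene has no reflectance stack")
  all_years <- as.integer(colnames(scene$truth))
  if (is.null(pixels)) pixels <- seq_len(nrow(scene$truth))
  if (is.null(years)) years <- all_years
  stopifnot(all(years %in% all_years))
  yr_idx <- match(years, all_years)
  n_px <- length(pixels); n_yr <- length(years)
  meta <- data.frame(
    pixel_id = rep(pixels, times = n_yr),
    year = rep(as.integer(years), each = n_px),
    code = as.vector(scene$truth[pixels, yr_idx, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  feats <- matrix(NA_real_, n_px * n_yr, N_FEATURES)
  for (j in seq_len(n_yr)) {
    feats[((j - 1) * n_px + 1):(j * n_px), ] <- scene$reflectance[pixels, yr_idx[j], ]
  }
  labeled_samples(meta, feats)
}

#' Split a scene's pixels into disjoint train / test sets
#'
#' The split is by pixel, so all years of a pixel fall on the same side —
#' this avoids temporal leakage between training and evaluation.
#'
#' @param scene A `plant_scene`.
#' @param test_frac Fraction of pixels held out.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test` (pixel ids).
#' @export
split_pixels <- function(scene, test_frac = 0.3, seed = 1L) {
  stopifnot(inherits(scene, "plant_scene"), test_frac > 0, test_frac < 1)
  n_px <- nrow(scene$truth)
  with_seed(seed, {
    test <- sort(sample.int(n_px, round(test_frac * n_px)))
    list(train = setdiff(seq_len(n_px), test), test = test)
  })
}

#' Subclass-balanced training sample
#'
#' Draws exactly `n_per_subclass` pixel-years for every land-cover subclass
#' (19-code level) present in the pool, so that no aggregated class is
#' dominated by its most common subclass. Subclasses with fewer than
#' `n_per_subclass` members are drawn with replacement (recorded in the
#' result's `replaced` field); subclasses absent from the pool are skipped
#' with a warning. Draws span all years present in the pool.
#'
#' @param pool A [labeled_samples()] pool.
#' @param scheme The active [class_scheme()] (determines which subclasses
#'   are in scope; all of the scheme's codes are sampled).
#' @param n_per_subclass Samples per subclass.
#' @param seed Integer seed.
#' @return A [labeled_samples()] training set.
#' @export
balanced_sample <- function(pool, scheme, n_per_subclass, seed = 1L) {
  stopifnot(inherits(pool, "labeled_samples"), inherits(scheme, "class_scheme"),
            n_per_subclass >= 1)
  if (n_samples(pool) == 0) stop("pool is empty")
  codes <- names(scheme$mapping)
  absent <- setdiff(codes, unique(pool$meta$code))
  if (length(absent) > 0) {
    warning("subclass(es) absent from pool, skipped: ",
            paste(absent, collapse = ", "))
  }
  present <- intersect(codes, unique(pool$meta$code))
  with_seed(seed, {
    idx_list <- lapply(present, function(code) {
      members <- which(pool$meta$code == code)
      replace <- length(members) < n_per_subclass
      list(idx = safe_sample(members, n_per_subclass, replace = replace),
           replaced = replace)
    })
    idx <- unlist(lapply(idx_list, `[[`, "idx"))
    replaced <- stats::setNames(vapply(idx_list, `[[`, logical(1), "replaced"),
                                present)
    out <- subset_samples(pool, idx)
    out$replaced <- replaced
    out
  })
}

#' Uniform training sample (baseline)
#'
#' Splits `n_total` equally across the scheme's aggregated classes and
#' draws simple random samples within each class, ignoring subclass
#' structure — the strategy against which subclass balancing is compared.
#' Rare subclasses receive draws roughly in proportion to their prevalence.
#'
#' @param pool A [labeled_samples()] pool.
#' @param scheme The active [class_scheme()].
#' @param n_total Total sample count, split equally over aggregated classes.
#' @param seed Integer seed.
#' @return A [labeled_samples()] training set.
#' @export
uniform_sample <- function(pool, scheme, n_total, seed = 1L) {
  stopifnot(inherits(pool, "labeled_samples"), inherits(scheme, "class_scheme"))
  labels <- scheme$labels
  if (n_total < length(labels)) {
    stop("n_total must be at least the number of aggregated classes (",
         length(labels), ")")
  }
  agg <- aggregate_code(pool$meta$code, scheme)
  absent <- setdiff(labels, unique(agg))
  if (length(absent) > 0) {
    warning("aggregated class(es) absent from pool, skipped: ",
            paste(absent, collapse = ", "))
  }
  present <- intersect(labels, unique(agg))
  per_class <- floor(n_total / length(present))
  extra <- n_total - per_class * length(present)
  with_seed(seed, {
    idx_list <- lapply(seq_along(present), function(i) {
      members <- which(agg == present[i])
      n_i <- per_class + as.integer(i <= extra)
      replace <- length(members) < n_i
      list(idx = safe_sample(members, n_i, replace = replace),
           replaced = replace)
    })
    idx <- unlist(lapply(idx_list, `[[`, "idx"))
    replaced <- stats::setNames(vapply(idx_list, `[[`, logical(1), "replaced"),
                                present)
    out <- subset_samples(pool, idx)
    out$replaced <- replaced
    out
  })
}

#' Labeled samples as a flat data.frame
#'
#' One row per sample with columns `pixel_id`, `year`, `code`,
#' `f001`..`f322` — the CSV interchange layout.
#'
#' @param x A `labeled_samples`.
#' @param ... Unused.
#' @return data.frame.
#' @export
as.data.frame.labeled_samples <- function(x, ...) {
  feats <- as.data.frame(x$features)
  names(feats) <- sprintf("f%03d", seq_len(N_FEATURES))
  cbind(x$meta[c("pixel_id", "year", "code")], feats)
}
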