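# Evaluation protocol against the two asymmetric reference products:
# yearly recall on confident plantation locations (anchor-year maps),
# overall precision vs the high-recall single-epoch mask, overall recall
# vs the last anchor-year map, and pixel <-> area accounting.

#' Reference products for evaluation
#'
#' @param rspo_like Named list: anchor year (as name) -> character vector
#'   over `P`/`F`/`O`, one entry per pixel (high precision, low recall).
#' @param tp_like Integer vector of pixel ids flagged plantation by the
#'   single-epoch mask (high recall, low precision).
#' @param tp_epoch Year of the mask.
#' @return Object of class `reference_set`.
#' @export
reference_set <- function(rspo_like, tp_like, tp_epoch) {
  stopifnot(is.list(rspo_like), length(rspo_like) >= 1,
            !is.null(names(rspo_like)))
  anchor_years <- as.integer(names(rspo_like))
  if (anyNA(anchor_years)) stop("rspo_like must be named by anchor year")
  if (is.unsorted(anchor_years)) {
    rspo_like <- rspo_like[order(anchor_years)]
    anchor_years <- sort(anchor_years)
  }
  structure(list(rspo_like = rspo_like, tp_like = as.integer(tp_like),
                 anchor_years = anchor_years, tp_epoch = as.integer(tp_epoch)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("<reference_set> anchor years:", paste(x$anchor_years, collapse = ", "),
      "| mask:", length(x$tp_like), "pixels at", x$tp_epoch, "\n")
  invisible(x)
}

#' Confident plantation locations
#'
#' A pixel-year is a confident plantation location if the pixel is labeled
#' plantation by the anchor-year maps at both ends of a consecutive
#' anchor-year pair; it is then confident for every year of that interval,
#' inclusive (a pixel plantation at 2000 and 2005 is confident for
#' 2000--2005).
#'
#' @param refs A [reference_set()] (needs >= 2 anchor years).
#' @return data.frame with columns `pixel_id`, `year`, one row per
#'   confident pixel-year.
#' @export
confident_plantation_locations <- function(refs) {
  stopifnot(inherits(refs, "reference_set"))
  if (length(refs$anchor_years) < 2) stop("need at least 2 anchor years")
  out <- list()
  for (i in seq_len(length(refs$anchor_years) - 1)) {
    y1 <- refs$anchor_years[i]; y2 <- refs$anchor_years[i + 1]
    p1 <- which(refs$rspo_like[[as.character(y1)]] == "P")
    p2 <- which(refs$rspo_like[[as.character(y2)]] == "P")
    both <- intersect(p1, p2)
    if (length(both) > 0) {
      yrs <- y1:y2
      out[[i]] <- data.frame(pixel_id = rep(both, times = length(yrs)),
                             year = rep(yrs, each = length(both)))
    }
  }
  if (length(out) == 0) {
    return(data.frame(pixel_id = integer(0), year = integer(0)))
  }
  res <- do.call(rbind, out)
  unique(res[order(res$year, res$pixel_id), ])
}

#' Yearly recall on confident plantation locations
#'
#' Fraction of the year's confident plantation locations predicted `P`;
#' `F`, `O` and `U` all count as not detected.
#'
#' @param pred Character label matrix (pixels x years; column names years).
#' @param confident Output of [confident_plantation_locations()].
#' @param year Year to evaluate.
#' @return Fraction in \[0, 1\], or `NA` if the year has no confident
#'   locations.
#' @export
yearly_recall <- function(pred, confident, year) {
  px <- confident$pixel_id[confident$year == year]
  if (length(px) == 0) return(NA_real_)
  if (!as.character(year) %in% colnames(pred)) return(NA_real_)
  mean(pred[px, as.character(year)] == "P")
}

# Pixels predicted P in any year of the window.
detected_plantations <- function(pred, window = NULL) {
  years <- as.integer(colnames(pred))
  if (is.null(window)) window <- years
  cols <- as.character(intersect(years, window))
  if (length(cols) == 0) stop("detection window contains no predicted years")
  which(rowSums(pred[, cols, drop = FALSE] == "P") > 0)
}

#' Overall precision against the single-epoch mask
#'
#' `|D intersect tp_like| / |D|` where `D` is the set of pixels predicted
#' plantation in any year of the window. The mask's high recall makes
#' pixels outside it unlikely to be plantations, which is what justifies
#' using it as the precision reference.
#'
#' @param pred Character label matrix (pixels x years).
#' @param refs A [reference_set()].
#' @param window Years forming the detection union (default: all predicted
#'   years).
#' @return Fraction in \[0, 1\], or `NA` if nothing is detected.
#' @export
overall_precision <- function(pred, refs, window = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  d <- detected_plantations(pred, window)
  if (length(d) == 0) return(NA_real_)
  length(intersect(d, refs$tp_like)) / length(d)
}

#' Overall recall against the last anchor-year map
#'
#' `|D intersect R| / |R|` where `R` is the set of pixels labeled
#' plantation by the anchor-year map at the last anchor year and `D` the
#' detection union as in [overall_precision()].
#'
#' @inheritParams overall_precision
#' @return Fraction in \[0, 1\], or `NA` if the reference has no
#'   plantations.
#' @export
overall_recall <- function(pred, refs, window = NULL) {
  stopifnot(inherits(refs, "reference_set"))
  last <- as.character(max(refs$anchor_years))
  r <- which(refs$rspo_like[[last]] == "P")
  if (length(r) == 0) return(NA_real_)
  d <- detected_plantations(pred, window)
  length(intersect(d, r)) / length(r)
}

#' Convert a pixel count to area
#'
#' @param n Pixel count (>= 0).
#' @param pixel_size_m Pixel edge length in metres (default 500, i.e.
#'   0.25 km^2 per pixel).
#' @return Area in km^2.
#' @export
#' @examples
#' pixels_to_area(1312112)  # 328028 km^2
pixels_to_area <- function(n, pixel_size_m = 500) {
  if (any(n < 0)) stop("pixel count must be non-negative")
  n * (pixel_size_m / 1000)^2
}

#' Area in thousands of km^2 at reporting precision
#'
#' Rounds half-up to two decimals in units of 10^3 km^2, the convention of
#' the regional land-cover area tables.
#'
#' @inheritParams pixels_to_area
#' @return Area in 10^3 km^2, rounded to 2 decimals.
#' @export
#' @examples
#' area_1e3_km2(101806)  # 25.45
area_1e3_km2 <- function(n, pixel_size_m = 500) {
  x <- pixels_to_area(n, pixel_size_m) / 1000
  floor(x * 100 + 0.5) / 100
}

#' Annual plantation area series and mean growth rate
#'
#' Converts per-year plantation pixel counts to km^2 and summarizes growth
#' as the geometric mean of year-over-year area ratios minus one. Steps
#' from a zero-area year are skipped (and counted in the result).
#'
#' @param pred Character label matrix (pixels x years).
#' @param pixel_size_m Pixel edge length in metres.
#' @return List with `area_km2` (named by year), `growth_rate`, and
#'   `n_skipped_steps`.
#' @export
annual_area_series <- function(pred, pixel_size_m = 500) {
  counts <- colSums(pred == "P")
  area <- pixels_to_area(counts, pixel_size_m)
  ratios <- area[-1] / area[-length(area)]
  ok <- is.finite(ratios) & ratios > 0
  growth <- if (any(ok)) exp(mean(log(ratios[ok]))) - 1 else NA_real_
  list(area_km2 = area, growth_rate = growth,
       n_skipped_steps = sum(!ok))
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' @param scores Numeric scores (higher = more plantation-like).
#' @param positive Logical vector, `TRUE` for true plantations.
#' @return AUC in \[0, 1\] (ties handled by midranks).
#' @export
auc_score <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("need both positive and negative cases")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Learning curve: AUC vs training-set size
#'
#' For each requested total training size, draws a subclass-balanced
#' training set of (approximately) that size from the training-pixel pool,
#' trains the pairwise ensemble, scores a fixed held-out test set of
#' plantation and non-plantation pixel-years with [plantation_score()],
#' and records the AUC; repeated over seeds.
#'
#' @param scene A `plant_scene` with reflectance.
#' @param sizes Ascending total training-set sizes.
#' @param n_test Held-out pixel-years per side (plantation / rest).
#' @param seeds Integer vector of replicate seeds.
#' @param scheme Scheme for the ensemble (default three-class).
#' @param backend A [backend_spec()].
#' @param test_frac Fraction of pixels held out for testing.
#' @return data.frame with columns `size`, `seed`, `auc`.
#' @export
auc_learning_curve <- function(scene, sizes = c(60, 300, 1500, 6000),
                               n_test = 1000, seeds = 1:3,
                               scheme = class_scheme("three"),
                               backend = backend_spec(),
                               test_frac = 0.3) {
  stopifnot(inherits(scene, "plant_scene"), !is.unsorted(sizes))
  n_codes <- length(scheme$mapping)
  if (min(sizes) < n_codes) {
    stop("smallest size (", min(sizes), ") is below the number of subclasses (",
         n_codes, ")")
  }
  split <- split_pixels(scene, test_frac = test_frac, seed = min(seeds))
  train_pool <- scene_pool(scene, pixels = split$train)
  test_pool <- scene_pool(scene, pixels = split$test)
  three <- class_scheme("three")
  test_is_p <- aggregate_code(test_pool$meta$code, three) == "P"
  res <- list()
  for (seed in seeds) {
    test_idx <- with_seed(seed + 7L, {
      p_idx <- which(test_is_p); n_idx <- which(!test_is_p)
      c(sample(p_idx, min(n_test, length(p_idx))),
        sample(n_idx, min(n_test, length(n_idx))))
    })
    test_x <- test_pool$features[test_idx, , drop = FALSE]
    test_pos <- test_is_p[test_idx]
    for (size in sizes) {
      n_sub <- max(1L, round(size / n_codes))
      train <- suppressWarnings(
        balanced_sample(train_pool, scheme, n_sub, seed = seed)
      )
      model <- train_ensemble(train, scheme, backend, seed = seed)
      scores <- plantation_score(model, test_x)
      res[[length(res) + 1]] <- data.frame(size = size, seed = seed,
                                           auc = auc_score(scores, test_pos))
    }
  }
  do.call(rbind, res)
}

#' Full metrics report
#'
#' Bundles the yearly recalls (over the anchor-year span), the overall
#' precision and recall, and the annual area series, with the counts
#' behind every fraction.
#'
#' @param pred Character label matrix (pixels x years).
#' @param refs A [reference_set()].
#' @param window Detection-union window (default: all predicted years).
#' @param pixel_size_m Pixel edge length in metres.
#' @return Object of class `metrics_report`.
#' @export
metrics_report <- function(pred, refs, window = NULL, pixel_size_m = 500) {
  stopifnot(inherits(refs, "reference_set"))
  confident <- confident_plantation_locations(refs)
  span <- min(refs$anchor_years):max(refs$anchor_years)
  years <- intersect(span, as.integer(colnames(pred)))
  yr <- vapply(years, function(y) yearly_recall(pred, confident, y), numeric(1))
  names(yr) <- years
  denom <- vapply(years, function(y) sum(confident$year == y), numeric(1))
  d <- detected_plantations(pred, window)
  area <- annual_area_series(pred, pixel_size_m)
  structure(list(
    yearly_recall = yr,
    overall_precision = overall_precision(pred, refs, window),
    overall_recall = overall_recall(pred, refs, window),
    annual_area = area$area_km2,
    growth_rate = area$growth_rate,
    counts = list(confident_per_year = stats::setNames(denom, years),
                  n_detected = length(d),
                  n_mask = length(refs$tp_like),
                  n_reference_last_anchor =
                    sum(refs$rspo_like[[as.character(max(refs$anchor_years))]] == "P"))
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat("  yearly recall:",
      paste(sprintf("%s=%.3f", names(x$yearly_recall), x$yearly_recall),
            collapse = " "), "\n")
  cat(sprintf("  overall precision: %.4f  overall recall: %.4f\n",
              x$overall_precision, x$overall_recall))
  cat(sprintf("  mean annual area growth: %.1f%%\n", 100 * x$growth_rate))
  invisible(x)
}

#' Metrics report as a data.frame
#'
#' One row per year plus an `overall` row — the CSV layout of the report.
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return data.frame with columns `year`, `recall`, `precision`,
#'   `area_km2`.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  years <- names(x$yearly_recall)
  rbind(
    data.frame(year = years, recall = unname(x$yearly_recall),
               precision = NA_real_,
               area_km2 = unname(x$annual_area[years])),
    data.frame(year = "overall", recall = x$overall_recall,
               precision = x$overall_precision, area_km2 = NA_real_)
  )
}
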