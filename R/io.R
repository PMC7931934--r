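# Format adapters (CSV label maps, CSV sample tables, YAML configs) and
# the end-to-end pipeline: simulate -> sample -> train -> predict ->
# smooth -> evaluate.

#' Write / read a label map as CSV
#'
#' Long format: `pixel_id`, `year`, `label`. Round-trips losslessly to the
#' pixels x years character matrix used throughout the package.
#'
#' @param map Character matrix (pixels x years, column names years).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(is.matrix(map), !is.null(colnames(map)))
  df <- data.frame(
    pixel_id = rep(seq_len(nrow(map)), times = ncol(map)),
    year = rep(as.integer(colnames(map)), each = nrow(map)),
    label = as.vector(map)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_label_map
#' @return For `read_label_map`: the pixels x years character matrix.
#' @export
read_label_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pixel_id", "year", "label")
  if (!all(need %in% names(df))) {
    stop("malformed label map ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  years <- sort(unique(df$year))
  n_px <- max(df$pixel_id)
  if (nrow(df) != n_px * length(years)) {
    stop("malformed label map ", path, ": not a complete pixel x year grid")
  }
  map <- matrix(NA_character_, n_px, length(years),
                dimnames = list(seq_len(n_px), years))
  map[cbind(df$pixel_id, match(df$year, years))] <- df$label
  map
}

#' Write / read a labeled sample table as CSV
#'
#' Columns `pixel_id`, `year`, `code`, `f001`..`f322`.
#'
#' @param samples A [labeled_samples()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(samples, path) {
  stopifnot(inherits(samples, "labeled_samples"))
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_samples_csv
#' @return For `read_samples_csv`: a [labeled_samples()] object.
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- sprintf("f%03d", seq_len(N_FEATURES))
  need <- c("pixel_id", "year", "code", fcols)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("malformed sample table ", path, ": missing column(s) ",
         miss[1], if (length(miss) > 1) paste0(" (+", length(miss) - 1, " more)"))
  }
  feats <- as.matrix(df[fcols])
  if (any(!is.finite(feats))) {
    stop("malformed sample table ", path, ": non-finite feature values")
  }
  labeled_samples(df[c("pixel_id", "year", "code")], unname(feats))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param scene A [scene_config()].
#' @param scheme Scheme name for the ensemble (`"three"`, `"binary"`,
#'   `"four"`).
#' @param sampling `"balanced"` or `"uniform"`.
#' @param n_per_subclass Balanced draws per subclass.
#' @param n_total Uniform-baseline total size (default keeps parity with
#'   the balanced draw: `n_per_subclass * 19`).
#' @param backend A [backend_spec()].
#' @param smoothing `"none"`, `"hmm3"`, `"hmm9"` or `"hmm19"`.
#' @param rho,q,delta Smoothing HMM parameters (see [default_hmm()]).
#' @param window Detection-union year window for the overall metrics
#'   (default: second predicted year through the last, so the first year
#'   only seeds the temporal model).
#' @param out_dir Artifact directory, or `NULL` for no files.
#' @param seed Integer master seed for sampling and training.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scene = scene_config(),
                       scheme = c("three", "binary", "four"),
                       sampling = c("balanced", "uniform"),
                       n_per_subclass = 30, n_total = NULL,
                       backend = backend_spec(),
                       smoothing = c("hmm19", "none", "hmm3", "hmm9"),
                       rho = 0.9, q = 0.9, delta = 1e-6,
                       window = NULL, out_dir = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  sampling <- match.arg(sampling)
  smoothing <- match.arg(smoothing)
  if (is.null(n_total)) n_total <- n_per_subclass * 19L
  structure(list(scene = scene, scheme = scheme, sampling = sampling,
                 n_per_subclass = n_per_subclass, n_total = n_total,
                 backend = backend, smoothing = smoothing,
                 rho = rho, q = q, delta = delta,
                 window = window, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

smoothing_scheme <- function(smoothing) {
  switch(smoothing,
         none = NULL,
         hmm3 = class_scheme("three"),
         hmm9 = class_scheme("nine"),
         hmm19 = class_scheme("nineteen"),
         stop("unknown smoothing variant: ", smoothing))
}

#' Run the full pipeline
#'
#' Stages: simulate the scene, build the training pool from a pixel-level
#' train split, draw the training set (balanced or uniform), train the
#' pairwise ensemble, predict the full yearly label map, smooth it with
#' the configured HMM variant, and evaluate against the scene's reference
#' products. Identical configurations give identical outputs.
#'
#' If `out_dir` is set, writes `truth.csv`, `predictions.csv`,
#' `smoothed.csv`, `metrics.csv`, a `metrics.json` summary and a
#' `manifest.yaml` recording the configuration digest, seeds and package
#' version.
#'
#' @param config A [run_config()].
#' @return List with `metrics` (a [metrics_report()]), `pred`, `smoothed`,
#'   `model`, `scene`, and `paths` (written artifacts, if any).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  scene <- stage("simulate", simulate_scene(config$scene))
  scheme <- class_scheme(config$scheme)
  split <- split_pixels(scene, test_frac = 0.3, seed = config$seed)
  pool <- stage("pool", scene_pool(scene, pixels = split$train))
  train <- stage("sample", suppressWarnings(switch(config$sampling,
    balanced = balanced_sample(pool, scheme, config$n_per_subclass,
                               seed = config$seed),
    uniform = uniform_sample(pool, scheme, config$n_total,
                             seed = config$seed))))
  model <- stage("train", train_ensemble(train, scheme, config$backend,
                                         seed = config$seed))
  pred <- stage("predict", predict_map(model, scene))
  smoothed <- if (config$smoothing == "none") {
    pred
  } else {
    stage("smooth", {
      spec <- default_hmm(smoothing_scheme(config$smoothing),
                          rho = config$rho, q = config$q, delta = config$delta)
      sm <- smooth_map(spec, pred)
      # a binary-scheme run stays on the binary alphabet
      if (config$scheme == "binary") sm[sm != "P"] <- "nonP"
      sm
    })
  }
  window <- config$window
  if (is.null(window)) {
    yrs <- as.integer(colnames(pred))
    window <- if (length(yrs) > 1) yrs[-1] else yrs
  }
  refs <- scene_references(scene)
  metrics <- stage("evaluate", metrics_report(smoothed, refs, window = window,
                                              pixel_size_m = scene$config$pixel_size_m))
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_label_map(scene$truth, p("truth.csv"))
    write_label_map(pred, p("predictions.csv"))
    write_label_map(smoothed, p("smoothed.csv"))
    utils::write.csv(as.data.frame(metrics), p("metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(
      yearly_recall = as.list(metrics$yearly_recall),
      overall_precision = metrics$overall_precision,
      overall_recall = metrics$overall_recall,
      annual_area_km2 = as.list(metrics$annual_area),
      growth_rate = metrics$growth_rate,
      counts = metrics$counts
    ), p("metrics.json"), auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package = "plantmapr",
      version = as.character(utils::packageVersion("plantmapr")),
      seed = config$seed,
      scene_seed = config$scene$seed,
      scheme = config$scheme, sampling = config$sampling,
      smoothing = config$smoothing,
      backend = config$backend$type,
      config_digest = config_digest(config)
    )
    yaml::write_yaml(manifest, p("manifest.yaml"))
    paths <- vapply(c("truth.csv", "predictions.csv", "smoothed.csv",
                      "metrics.csv", "metrics.json", "manifest.yaml"),
                    p, character(1))
  }
  list(metrics = metrics, pred = pred, smoothed = smoothed, model = model,
       scene = scene, paths = paths)
}

# md5 of the deparsed configuration (reproducibility manifest).
config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read a scene configuration as YAML
#'
#' @param config A [scene_config()].
#' @param path YAML path.
#' @return `path` invisibly; `read_scene_config` returns a
#'   [scene_config()].
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  lst <- unclass(config)
  lst$annual_transitions <- list(
    codes = rownames(config$annual_transitions),
    values = as.vector(config$annual_transitions)
  )
  lst$initial_mix <- as.list(config$initial_mix)
  lst$signatures <- lapply(config$signatures, function(s) {
    lapply(s, as.numeric)
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  lst <- yaml::read_yaml(path)
  need <- c("n_rows", "n_cols", "years", "signatures", "noise_sd",
            "initial_mix", "annual_transitions", "tp_fpr", "tp_fnr",
            "rspo_fnr", "rspo_fpr", "anchor_years", "tp_epoch", "seed")
  miss <- setdiff(need, names(lst))
  if (length(miss) > 0) {
    stop("malformed scene config ", path, ": missing field(s) ",
         paste(miss, collapse = ", "))
  }
  codes <- lst$annual_transitions$codes
  k <- length(codes)
  tr <- matrix(as.numeric(lst$annual_transitions$values), k, k,
               dimnames = list(codes, codes))
  scene_config(
    n_rows = lst$n_rows, n_cols = lst$n_cols, years = lst$years,
    signatures = lapply(lst$signatures, function(s) lapply(s, as.numeric)),
    noise_sd = lst$noise_sd,
    initial_mix = unlist(lst$initial_mix),
    annual_transitions = tr,
    tp_fpr = lst$tp_fpr, tp_fnr = lst$tp_fnr,
    rspo_fnr = lst$rspo_fnr, rspo_fpr = lst$rspo_fpr,
    anchor_years = lst$anchor_years, tp_epoch = lst$tp_epoch,
    pixel_size_m = if (is.null(lst$pixel_size_m)) 500 else lst$pixel_size_m,
    seed = lst$seed
  )
}
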