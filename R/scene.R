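# Synthetic scene simulation: Markov land-use change, harmonic seasonal
# reflectance, and the two asymmetric noisy reference products.

N_COMPOSITES <- 46L
N_BANDS <- 7L
N_FEATURES <- N_COMPOSITES * N_BANDS  # 322

#' Default per-class spectral signatures
#'
#' One harmonic signature per land-cover code and band: an annual mean
#' `mu`, a seasonal amplitude `amp` and a phase `phase` (radians), all on
#' the unitless reflectance scale in \[0, 1\]. The composite at step t of
#' 46 is drawn around `mu + amp * sin(2*pi*t/46 + phase)`.
#'
#' The defaults encode the qualitative structure of the mapped landscape:
#' closed forest is dark in the visible, bright in the NIR and nearly
#' aseasonal; mature plantations sit between forest and cropland in both
#' greenness and seasonality (oil palm canopies approach forest greenness);
#' cultivated classes are strongly seasonal; water is dark everywhere;
#' built-up and mining are bright across the SWIR. Upland grassland (`GRS`)
#' is deliberately given a signature close to plantation so that rare
#' plantation-mimicking "other" subclasses are present, which is the regime
#' where subclass-balanced sampling matters.
#'
#' Band order follows the 7 MOD09A1-style bands:
#' red, NIR, blue, green, NIR-1240, SWIR-1640, SWIR-2130.
#'
#' @return Named list: code -> list(mu, amp, phase), each a length-7 vector.
#' @export
default_signatures <- function() {
  b <- function(...) c(...)
  # archetype mean profiles (red, nir, blue, green, nir2, swir1, swir2)
  forest  <- b(0.030, 0.450, 0.020, 0.060, 0.400, 0.150, 0.070)
  palm    <- b(0.045, 0.400, 0.030, 0.070, 0.360, 0.185, 0.095)
  crop    <- b(0.100, 0.300, 0.060, 0.100, 0.280, 0.250, 0.180)
  shrub   <- b(0.080, 0.310, 0.050, 0.090, 0.290, 0.255, 0.160)
  water   <- b(0.020, 0.030, 0.030, 0.040, 0.020, 0.010, 0.010)
  urban   <- b(0.180, 0.220, 0.120, 0.150, 0.220, 0.300, 0.280)
  flat <- rep(0.010, 7)
  seas <- rep(0.080, 7)
  mild <- rep(0.030, 7)
  sig <- function(mu, amp, phase = rep(0, 7)) list(mu = mu, amp = amp, phase = phase)
  list(
    CFP = sig(water + 0.030, mild, rep(pi / 3, 7)),
    CPL = sig(palm + c(0.010, -0.030, 0.005, 0.005, -0.020, 0.015, 0.010), mild),
    DCL = sig(crop, seas, rep(0, 7)),
    DIF = sig(forest + c(0.010, -0.040, 0.005, 0.008, -0.030, 0.020, 0.012), flat),
    DIM = sig(forest + c(0.015, -0.120, 0.010, 0.010, -0.100, 0.030, 0.020), mild),
    DSF = sig(forest + c(0.012, -0.080, 0.008, 0.008, -0.070, 0.010, 0.005), mild),
    # plantation-mimicking rare subclass: close to young plantation
    GRS = sig(palm + c(0.012, -0.015, 0.006, 0.006, -0.012, 0.010, 0.008),
              mild + 0.010),
    MIN = sig(urban + c(0.040, -0.020, 0.030, 0.020, 0.000, 0.030, 0.030), flat),
    MTC = sig(crop + c(-0.030, 0.050, -0.015, -0.010, 0.040, -0.040, -0.040),
              rep(0.050, 7)),
    OPL = sig(palm, mild),
    RCF = sig(crop + c(-0.020, -0.050, 0.000, 0.000, -0.060, -0.060, -0.050),
              rep(0.100, 7), rep(pi / 2, 7)),
    SCH = sig(shrub, rep(0.050, 7)),
    SET = sig(urban, flat),
    SGR = sig(shrub + c(-0.010, -0.040, 0.000, 0.000, -0.040, -0.030, -0.030),
              rep(0.060, 7), rep(pi / 4, 7)),
    SSH = sig(shrub + c(-0.015, 0.030, -0.010, -0.005, 0.020, -0.050, -0.040),
              rep(0.040, 7)),
    TPL = sig(palm + c(-0.008, 0.035, -0.005, -0.005, 0.030, -0.025, -0.020), mild),
    UDF = sig(forest, flat),
    USF = sig(forest + c(0.000, -0.020, 0.002, 0.000, -0.020, -0.020, -0.010), flat),
    WAB = sig(water, rep(0.005, 7))
  )
}

#' Default initial land-cover proportions
#'
#' Mirrors the relative land-cover frequencies reported for the mapped
#' region in 2000 (dominated by disturbed upland forest and upland shrub
#' land; plantations around 4--5% of pixels).
#'
#' @return Named numeric vector over the 19 codes, summing to 1.
#' @export
default_initial_mix <- function() {
  mix <- c(CFP = 0.004, CPL = 0.014, DCL = 0.034, DIF = 0.310, DIM = 0.005,
           DSF = 0.062, GRS = 0.011, MIN = 0.001, MTC = 0.005, OPL = 0.021,
           RCF = 0.022, SCH = 0.218, SET = 0.002, SGR = 0.013, SSH = 0.075,
           TPL = 0.009, UDF = 0.102, USF = 0.067, WAB = 0.025)
  mix / sum(mix)
}

#' Default annual land-use transition matrix
#'
#' A sparse, mostly-diagonal stochastic matrix encoding the dominant
#' dynamics of a plantation frontier: logging converts undisturbed to
#' disturbed forest, disturbed forest / shrub land / cropland convert to
#' plantation, and plantations do not revert. From the default initial
#' mix these rates grow total plantation area by roughly 8% per year over
#' 2000--2009 (decelerating as the base grows), the same order as the
#' region's published trajectory of about 10% per year.
#'
#' @param codes Character vector of codes (default taxonomy order).
#' @return 19x19 row-stochastic matrix with dimnames `codes`.
#' @export
default_transitions <- function(codes = taxonomy()$code) {
  k <- length(codes)
  tr <- diag(k)
  dimnames(tr) <- list(codes, codes)
  bump <- function(from, to, p) {
    tr[from, to] <<- tr[from, to] + p
    tr[from, from] <<- tr[from, from] - p
  }
  bump("UDF", "DIF", 0.020); bump("UDF", "OPL", 0.002)
  bump("USF", "DSF", 0.015)
  bump("DIF", "OPL", 0.008); bump("DIF", "TPL", 0.0015)
  bump("DIF", "DCL", 0.003); bump("DIF", "SCH", 0.003)
  bump("DSF", "OPL", 0.004)
  bump("SCH", "OPL", 0.006); bump("SCH", "DCL", 0.004)
  bump("GRS", "OPL", 0.004)
  bump("DCL", "OPL", 0.004)
  tr
}

#' Scene configuration
#'
#' Bundles every knob of the synthetic scene: grid size, simulated years,
#' spectral signatures, reflectance noise, initial land-cover mix, annual
#' land-use transition matrix, and the error rates of the two emulated
#' reference products. The two products have opposite error structure:
#' the single-epoch plantation mask (TP-like) has high recall and low
#' precision (`tp_fnr` small, `tp_fpr` appreciable), while the anchor-year
#' land-cover maps (RSPO-like) have high precision and low recall
#' (`rspo_fpr` small, `rspo_fnr` appreciable).
#'
#' @param n_rows,n_cols Grid dimensions in pixels.
#' @param years Ordered calendar years simulated.
#' @param signatures Named list code -> list(mu, amp, phase); see
#'   [default_signatures()].
#' @param noise_sd Gaussian reflectance noise SD (unitless reflectance).
#'   Default 0.03, a typical composite-to-composite residual scatter for
#'   500 m surface reflectance.
#' @param initial_mix Named probabilities over codes for the first year.
#' @param annual_transitions Row-stochastic code x code matrix.
#' @param tp_fpr,tp_fnr Commission / omission rates of the TP-like mask.
#' @param rspo_fnr,rspo_fpr Omission / commission rates of the RSPO-like maps.
#' @param anchor_years Years at which RSPO-like maps exist. Default: the
#'   conventional anchors (2000, 2005, 2009) where simulated, else the
#'   first simulated year.
#' @param tp_epoch Year of the TP-like mask (default: last simulated year).
#' @param pixel_size_m Pixel edge length in metres (default 500).
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(n_rows = 30, n_cols = 30, years = 2000:2014,
                         signatures = default_signatures(),
                         noise_sd = 0.03,
                         initial_mix = default_initial_mix(),
                         annual_transitions = default_transitions(),
                         tp_fpr = 0.10, tp_fnr = 0.05,
                         rspo_fnr = 0.30, rspo_fpr = 0.01,
                         anchor_years = NULL,
                         tp_epoch = NULL,
                         pixel_size_m = 500,
                         seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, length(years) >= 1)
  rates <- c(tp_fpr = tp_fpr, tp_fnr = tp_fnr,
             rspo_fnr = rspo_fnr, rspo_fpr = rspo_fpr)
  if (any(rates < 0 | rates > 1)) stop("reference-product rates must be in [0,1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (abs(sum(initial_mix) - 1) > 1e-9) stop("initial_mix must sum to 1")
  if (any(initial_mix < 0)) stop("initial_mix must be non-negative")
  rs <- rowSums(annual_transitions)
  if (any(abs(rs - 1) > 1e-9) || any(annual_transitions < 0)) {
    stop("annual_transitions rows must be non-negative and sum to 1")
  }
  if (is.null(anchor_years)) {
    # reference-map years: the conventional anchors where simulated,
    # otherwise the first simulated year
    anchor_years <- intersect(c(2000, 2005, 2009), years)
    if (length(anchor_years) == 0) anchor_years <- min(years)
  }
  if (is.null(tp_epoch)) tp_epoch <- max(years)
  if (!all(anchor_years %in% years)) stop("anchor_years must be simulated years")
  if (!tp_epoch %in% years) stop("tp_epoch must be a simulated year")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    years = as.integer(years), signatures = signatures, noise_sd = noise_sd,
    initial_mix = initial_mix, annual_transitions = annual_transitions,
    tp_fpr = tp_fpr, tp_fnr = tp_fnr, rspo_fnr = rspo_fnr, rspo_fpr = rspo_fpr,
    anchor_years = as.integer(sort(anchor_years)), tp_epoch = as.integer(tp_epoch),
    pixel_size_m = pixel_size_m, seed = as.integer(seed)
  ), class = "scene_config")
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate ground-truth land-cover trajectories
#'
#' Draws the first year's labels from `initial_mix`, then evolves every
#' pixel independently through the annual transition matrix.
#'
#' @param config A [scene_config()].
#' @return Character matrix (pixels x years) of land-cover codes, with
#'   column names the years. Pixels are indexed row-major from the
#'   top-left of the grid.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  codes <- rownames(config$annual_transitions)
  miss <- setdiff(names(config$initial_mix)[config$initial_mix > 0], codes)
  if (length(miss) > 0) stop("initial_mix codes missing from transitions: ",
                             paste(miss, collapse = ", "))
  n_px <- config$n_rows * config$n_cols
  n_yr <- length(config$years)
  truth <- matrix(NA_character_, n_px, n_yr,
                  dimnames = list(NULL, as.character(config$years)))
  with_seed(config$seed, {
    truth[, 1] <- sample(names(config$initial_mix), n_px, replace = TRUE,
                         prob = config$initial_mix)
    if (n_yr > 1) {
      for (j in 2:n_yr) {
        prev <- truth[, j - 1]
        cur <- prev
        for (code in unique(prev)) {
          idx <- which(prev == code)
          cur[idx] <- sample(codes, length(idx), replace = TRUE,
                             prob = config$annual_transitions[code, ])
        }
        truth[, j] <- cur
      }
    }
  })
  truth
}

# 322-length composite-major noiseless curve for one code.
signature_curve <- function(sig) {
  t_seq <- seq_len(N_COMPOSITES)
  # rows = composites, cols = bands
  curve <- vapply(seq_len(N_BANDS), function(b) {
    sig$mu[b] + sig$amp[b] * sin(2 * pi * t_seq / N_COMPOSITES + sig$phase[b])
  }, numeric(N_COMPOSITES))
  as.vector(t(curve))
}

#' Simulate the reflectance stack
#'
#' For a pixel-year with code c, composite t and band b the simulated value
#' is `mu[c,b] + amp[c,b] * sin(2*pi*t/46 + phase[c,b]) + N(0, noise_sd)`,
#' clipped to \[0, 1\]. Noise is independent across pixels, years,
#' composites and bands.
#'
#' @param truth Pixel x year code matrix from [simulate_truth()].
#' @param config A [scene_config()].
#' @return Numeric array `[pixel, year, feature]` with 322 features in
#'   composite-major order (composite 1 bands 1--7, ..., composite 46
#'   bands 1--7).
#' @export
simulate_reflectance <- function(truth, config) {
  stopifnot(inherits(config, "scene_config"))
  if (anyNA(truth)) stop("truth must be defined for all pixel-years")
  present <- unique(as.vector(truth))
  miss <- setdiff(present, names(config$signatures))
  if (length(miss) > 0) stop("no spectral signature for code(s): ",
                             paste(miss, collapse = ", "))
  n_px <- nrow(truth); n_yr <- ncol(truth)
  curves <- vapply(config$signatures, signature_curve, numeric(N_FEATURES))
  refl <- array(NA_real_, c(n_px, n_yr, N_FEATURES),
                dimnames = list(NULL, colnames(truth), NULL))
  for (j in seq_len(n_yr)) {
    refl[, j, ] <- t(curves[, truth[, j]])
  }
  with_seed(config$seed + 1L, {
    if (config$noise_sd > 0) {
      refl <- refl + stats::rnorm(length(refl), sd = config$noise_sd)
    }
  })
  refl[refl < 0] <- 0
  refl[refl > 1] <- 1
  refl
}

#' Simulate the two noisy reference products
#'
#' The TP-like mask keeps each true plantation pixel at `tp_epoch` with
#' probability `1 - tp_fnr` and adds each non-plantation pixel with
#' probability `tp_fpr` (high recall, low precision). The RSPO-like maps
#' at each anchor year start from the three-class truth, drop plantation
#' pixels to `O` with probability `rspo_fnr` and flip non-plantation
#' pixels to `P` with probability `rspo_fpr` (high precision, low recall).
#'
#' @param truth Pixel x year code matrix.
#' @param config A [scene_config()].
#' @param tax Taxonomy table used for the three-class aggregation.
#' @return List with `tp_mask` (integer pixel ids) and `rspo_maps`
#'   (named list: anchor year -> character vector over P/F/O per pixel).
#' @export
simulate_reference_products <- function(truth, config, tax = taxonomy()) {
  stopifnot(inherits(config, "scene_config"))
  years <- colnames(truth)
  need <- as.character(c(config$anchor_years, config$tp_epoch))
  if (!all(need %in% years)) stop("truth must cover anchor_years and tp_epoch")
  three <- class_scheme("three", tax)
  with_seed(config$seed + 2L, {
    truth_tp <- aggregate_code(truth[, as.character(config$tp_epoch)], three)
    is_p <- truth_tp == "P"
    keep <- which(is_p)[stats::runif(sum(is_p)) >= config$tp_fnr]
    add <- which(!is_p)[stats::runif(sum(!is_p)) < config$tp_fpr]
    tp_mask <- sort(c(keep, add))
    rspo_maps <- lapply(as.character(config$anchor_years), function(y) {
      lab <- aggregate_code(truth[, y], three)
      p_idx <- which(lab == "P")
      np_idx <- which(lab != "P")
      drop <- p_idx[stats::runif(length(p_idx)) < config$rspo_fnr]
      flip <- np_idx[stats::runif(length(np_idx)) < config$rspo_fpr]
      lab[drop] <- "O"
      lab[flip] <- "P"
      lab
    })
    names(rspo_maps) <- as.character(config$anchor_years)
    list(tp_mask = tp_mask, rspo_maps = rspo_maps)
  })
}

#' Simulate a full scene
#'
#' Convenience wrapper running [simulate_truth()], [simulate_reflectance()]
#' and [simulate_reference_products()] with the config's seed; identical
#' configs give bit-identical scenes.
#'
#' @param config A [scene_config()].
#' @param reflectance If `FALSE`, skip the reflectance stack (labels and
#'   reference products only).
#' @return Object of class `plant_scene`: list with `truth`, `reflectance`,
#'   `tp_mask`, `rspo_maps`, `config`.
#' @export
simulate_scene <- function(config = scene_config(), reflectance = TRUE) {
  truth <- simulate_truth(config)
  refl <- if (reflectance) simulate_reflectance(truth, config) else NULL
  refs <- simulate_reference_products(truth, config)
  structure(list(truth = truth, reflectance = refl,
                 tp_mask = refs$tp_mask, rspo_maps = refs$rspo_maps,
                 config = config),
            class = "plant_scene")
}

#' @export
print.plant_scene <- function(x, ...) {
  cat("<plant_scene>", x$config$n_rows, "x", x$config$n_cols, "pixels,",
      length(x$config$years), "years",
      sprintf("(%d-%d)", min(x$config$years), max(x$config$years)), "\n")
  cat("  reflectance:", if (is.null(x$reflectance)) "absent" else "46x7 per pixel-year", "\n")
  cat("  TP-like mask:", length(x$tp_mask), "pixels at", x$config$tp_epoch, "\n")
  cat("  RSPO-like maps at:", paste(names(x$rspo_maps), collapse = ", "), "\n")
  invisible(x)
}

#' Reference products of a scene as a `reference_set`
#'
#' @param scene A `plant_scene`.
#' @return A [reference_set()] for the evaluation functions.
#' @export
scene_references <- function(scene) {
  stopifnot(inherits(scene, "plant_scene"))
  reference_set(rspo_like = scene$rspo_maps, tp_like = scene$tp_mask,
                tp_epoch = scene$config$tp_epoch)
}
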