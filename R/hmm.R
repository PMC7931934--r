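# HMM post-processing of yearly label sequences.
#
# Latent states are land-cover classes (19 codes, the 9 high-level classes,
# or the 3 aggregated classes); observations are the ensemble's yearly
# P/F/O/U labels. Viterbi decoding returns the most probable latent path,
# mapped back to P/F/O. The transition prior makes plantation -> forest
# reversion (nearly) forbidden, which is what corrects isolated "forest"
# errors inside an established plantation sequence.

OBS_LABELS <- c("P", "F", "O", "U")

# Three-class label of each latent class. For the nineteen- and
# three-class latent spaces this is the taxonomy aggregation (identity for
# three). A high-level (nine) class can mix three-class labels among its
# subclasses, so it is assigned the label holding the majority of its
# published 2000 pixel count (e.g. Disturbed forest -> F because disturbed
# upland forest dominates its area).
latent_to_three <- function(scheme, tax = taxonomy()) {
  three <- class_scheme("three", tax)
  switch(scheme$name,
    nineteen = stats::setNames(aggregate_code(scheme$labels, three),
                               scheme$labels),
    three = stats::setNames(scheme$labels, scheme$labels),
    nine = {
      counts_path <- system.file("extdata", "rspo_pixel_counts.csv",
                                 package = "plantmapr")
      counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
      counts$three <- aggregate_code(counts$code, three)
      counts$high <- aggregate_code(counts$code, class_scheme("nine", tax))
      vapply(scheme$labels, function(h) {
        sub <- counts[counts$high == h, ]
        agg <- tapply(sub$pixels_2000, sub$three, sum)
        names(agg)[which.max(agg)]
      }, character(1))
    },
    stop("latent scheme must be nineteen, nine or three, got: ", scheme$name)
  )
}

#' HMM specification for yearly label smoothing
#'
#' @param latent_scheme A [class_scheme()] (`nineteen`, `nine` or `three`).
#' @param initial Probability vector over latent classes.
#' @param transition Latent x latent annual stochastic matrix.
#' @param emission Latent x {P,F,O,U} stochastic matrix.
#' @param tax Taxonomy used to map latent classes to P/F/O.
#' @return Object of class `hmm_spec`.
#' @export
hmm_spec <- function(latent_scheme, initial, transition, emission,
                     tax = taxonomy()) {
  stopifnot(inherits(latent_scheme, "class_scheme"))
  k <- length(latent_scheme$labels)
  stopifnot(length(initial) == k, nrow(transition) == k, ncol(transition) == k,
            nrow(emission) == k, ncol(emission) == length(OBS_LABELS))
  if (abs(sum(initial) - 1) > 1e-9 || any(initial < 0)) {
    stop("initial must be a probability vector")
  }
  if (any(abs(rowSums(transition) - 1) > 1e-9) || any(transition < 0)) {
    stop("transition rows must sum to 1")
  }
  if (any(abs(rowSums(emission) - 1) > 1e-9) || any(emission < 0)) {
    stop("emission rows must sum to 1")
  }
  dimnames(transition) <- list(latent_scheme$labels, latent_scheme$labels)
  dimnames(emission) <- list(latent_scheme$labels, OBS_LABELS)
  structure(list(latent_scheme = latent_scheme,
                 initial = stats::setNames(initial, latent_scheme$labels),
                 transition = transition, emission = emission,
                 to_three = latent_to_three(latent_scheme, tax)),
            class = "hmm_spec")
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("<hmm_spec>", length(x$initial), "latent classes (",
      x$latent_scheme$name, "), observations P/F/O/U\n")
  invisible(x)
}

#' Default smoothing HMM
#'
#' Builds the package's parametric smoothing model:
#'
#' * transition: self-transition probability `rho` on the diagonal, the
#'   remaining `1 - rho` spread uniformly over the other latent classes;
#'   every plantation -> forest entry is then capped at `delta` (default
#'   1e-6, i.e. reversion nearly forbidden) and rows renormalized;
#' * emission: probability `q` on the latent class's own three-class
#'   label, a small constant mass `u_mass` (capped at `1 - q`) on the
#'   Unknown observation identical across latent classes — so a `U`
#'   observation is uninformative about the latent state — and the
#'   remainder split equally over the other two labels;
#' * initial: uniform over latent classes.
#'
#' @param latent_scheme A [class_scheme()] (`nineteen`, `nine` or `three`).
#' @param tax Taxonomy table.
#' @param rho Self-transition probability, in (0, 1\].
#' @param q Emission correctness, in (0.5, 1\].
#' @param delta Plantation -> forest transition cap, small and >= 0.
#' @param u_mass Emission mass on the Unknown observation.
#' @return An [hmm_spec()].
#' @export
#' @examples
#' spec <- default_hmm(class_scheme("nineteen"))
#' viterbi_smooth(spec, c("F", "F", "P", "P", "F", "P"))
default_hmm <- function(latent_scheme, tax = taxonomy(),
                        rho = 0.9, q = 0.9, delta = 1e-6, u_mass = 0.02) {
  stopifnot(inherits(latent_scheme, "class_scheme"))
  if (rho <= 0 || rho > 1) stop("rho must be in (0, 1]")
  if (q <= 0.5 || q > 1) stop("q must be in (0.5, 1]")
  if (delta < 0 || delta > 0.1) stop("delta must be in [0, 0.1]")
  if (u_mass < 0 || u_mass >= 0.5) stop("u_mass must be in [0, 0.5)")
  labels <- latent_scheme$labels
  k <- length(labels)
  to3 <- latent_to_three(latent_scheme, tax)
  transition <- matrix(if (k > 1) (1 - rho) / (k - 1) else 0, k, k,
                       dimnames = list(labels, labels))
  diag(transition) <- if (k > 1) rho else 1
  p_lat <- labels[to3 == "P"]
  f_lat <- labels[to3 == "F"]
  if (length(p_lat) > 0 && length(f_lat) > 0) {
    transition[p_lat, f_lat] <- pmin(transition[p_lat, f_lat], delta)
  }
  transition <- transition / rowSums(transition)
  u_eff <- min(u_mass, 1 - q)
  emission <- matrix(0, k, length(OBS_LABELS),
                     dimnames = list(labels, OBS_LABELS))
  for (i in seq_len(k)) {
    own <- to3[i]
    others <- setdiff(c("P", "F", "O"), own)
    emission[i, own] <- q
    emission[i, others] <- (1 - q - u_eff) / 2
    emission[i, "U"] <- u_eff
  }
  hmm_spec(latent_scheme, rep(1 / k, k), transition, emission, tax)
}

#' Estimate an annual transition matrix from labeled sequences
#'
#' Maximum-likelihood year-to-year transition frequencies over the latent
#' scheme's classes, with additive (pseudocount) smoothing.
#'
#' @param truth Character matrix (pixels x years) of land-cover codes, or
#'   a list of code sequences.
#' @param latent_scheme A [class_scheme()].
#' @param alpha Pseudocount added to every cell before normalization.
#' @return Row-stochastic latent x latent matrix.
#' @export
estimate_transitions <- function(truth, latent_scheme, alpha = 0) {
  stopifnot(inherits(latent_scheme, "class_scheme"), alpha >= 0)
  if (is.matrix(truth)) {
    truth <- lapply(seq_len(nrow(truth)), function(i) truth[i, ])
  }
  if (length(truth) == 0 || all(lengths(truth) < 2)) {
    stop("need at least one sequence of length >= 2")
  }
  labels <- latent_scheme$labels
  counts <- matrix(alpha, length(labels), length(labels),
                   dimnames = list(labels, labels))
  for (s in truth) {
    if (length(s) < 2) next
    lat <- aggregate_code(s, latent_scheme)
    from <- factor(lat[-length(lat)], levels = labels)
    to <- factor(lat[-1], levels = labels)
    counts <- counts + table(from, to)
  }
  rs <- rowSums(counts)
  zero <- rs == 0
  if (any(zero)) {
    # classes never observed as a source: keep them where they are
    counts[zero, ] <- 0
    diag(counts)[zero] <- 1
    rs[zero] <- 1
  }
  counts / rs
}

# Vectorized Viterbi over many sequences of equal length.
# obs: character matrix (sequences x years) over P/F/O/U, plus "nonP"
# (the union event F or O, as emitted by the binary scheme) whose
# likelihood is the summed emission mass of F and O.
# Returns integer matrix of latent indices; ties broken toward the lowest
# latent index at every argmax.
viterbi_batch <- function(spec, obs) {
  labels <- names(spec$initial)
  k <- length(labels)
  n <- nrow(obs); T_len <- ncol(obs)
  bad <- setdiff(unique(as.vector(obs)), c(OBS_LABELS, "nonP"))
  if (length(bad) > 0) {
    stop("observation(s) outside {P,F,O,U}: ", paste(bad, collapse = ", "))
  }
  log_e <- log(cbind(spec$emission,
                     nonP = spec$emission[, "F"] + spec$emission[, "O"]))
  log_a <- log(spec$transition)
  log_pi <- log(spec$initial)
  # delta: n x k accumulated log-probabilities
  delta <- matrix(log_pi, n, k, byrow = TRUE) + t(log_e[, obs[, 1], drop = FALSE])
  psi <- array(NA_integer_, c(n, k, T_len))
  if (T_len > 1) {
    for (t_i in 2:T_len) {
      new_delta <- matrix(NA_real_, n, k)
      for (j in seq_len(k)) {
        scores <- sweep(delta, 2, log_a[, j], "+")
        best <- max.col(scores, ties.method = "first")
        psi[, j, t_i] <- best
        new_delta[, j] <- scores[cbind(seq_len(n), best)]
      }
      delta <- new_delta + t(log_e[, obs[, t_i], drop = FALSE])
    }
  }
  path <- matrix(NA_integer_, n, T_len)
  path[, T_len] <- max.col(delta, ties.method = "first")
  if (T_len > 1) {
    for (t_i in (T_len - 1):1) {
      path[, t_i] <- psi[cbind(seq_len(n), path[, t_i + 1], t_i + 1)]
    }
  }
  path
}

#' Viterbi smoothing of one yearly label sequence
#'
#' Decodes the most probable latent land-cover path for the observed
#' P/F/O/U sequence and returns it mapped to the three aggregated classes.
#' Ties in the path score are broken toward the lowest latent-class index,
#' so the result is deterministic.
#'
#' @param spec An [hmm_spec()].
#' @param observed Character vector over `P`, `F`, `O`, `U` (length >= 1).
#'   The binary-scheme label `nonP` is also accepted and treated as the
#'   union event "F or O" (summed emission likelihood).
#' @return Character vector over `P`, `F`, `O` of the same length.
#' @export
#' @examples
#' spec <- default_hmm(class_scheme("nineteen"))
#' viterbi_smooth(spec, c("F", "F", "P", "P", "F", "P"))
#' # F F P P P P : the isolated forest dip is corrected
viterbi_smooth <- function(spec, observed) {
  stopifnot(inherits(spec, "hmm_spec"), length(observed) >= 1)
  path <- viterbi_batch(spec, matrix(observed, nrow = 1))
  unname(spec$to_three[names(spec$initial)[path[1, ]]])
}

# Scaled forward-backward posterior marginals over many sequences.
# Returns integer matrix (sequences x years) of per-year argmax latent
# indices, ties toward the lowest index.
posterior_batch <- function(spec, obs) {
  labels <- names(spec$initial)
  k <- length(labels)
  n <- nrow(obs); T_len <- ncol(obs)
  bad <- setdiff(unique(as.vector(obs)), c(OBS_LABELS, "nonP"))
  if (length(bad) > 0) {
    stop("observation(s) outside {P,F,O,U}: ", paste(bad, collapse = ", "))
  }
  e <- cbind(spec$emission, nonP = spec$emission[, "F"] + spec$emission[, "O"])
  a <- spec$transition
  alpha <- array(NA_real_, c(n, k, T_len))
  beta <- array(NA_real_, c(n, k, T_len))
  slab <- function(arr, t_i) matrix(arr[, , t_i], n, k)
  a1 <- matrix(spec$initial, n, k, byrow = TRUE) * t(e[, obs[, 1], drop = FALSE])
  alpha[, , 1] <- a1 / rowSums(a1)
  if (T_len > 1) {
    for (t_i in 2:T_len) {
      al <- (slab(alpha, t_i - 1) %*% a) * t(e[, obs[, t_i], drop = FALSE])
      alpha[, , t_i] <- al / rowSums(al)
    }
  }
  beta[, , T_len] <- 1
  if (T_len > 1) {
    for (t_i in (T_len - 1):1) {
      bt <- (slab(beta, t_i + 1) * t(e[, obs[, t_i + 1], drop = FALSE])) %*% t(a)
      beta[, , t_i] <- bt / rowSums(bt)
    }
  }
  out <- matrix(NA_integer_, n, T_len)
  for (t_i in seq_len(T_len)) {
    out[, t_i] <- max.col(slab(alpha, t_i) * slab(beta, t_i),
                          ties.method = "first")
  }
  out
}

#' Smooth a predicted label map
#'
#' Applies [viterbi_smooth()] (joint most-probable path, the default) or
#' per-year posterior-marginal decoding to every pixel's yearly sequence.
#'
#' @param spec An [hmm_spec()].
#' @param pred Character matrix (pixels x years) over `P`, `F`, `O`, `U`
#'   (plus `nonP` for binary-scheme maps).
#' @param method `"viterbi"` (joint MAP path) or `"posterior"` (per-year
#'   marginal argmax).
#' @return Character matrix (pixels x years) over `P`, `F`, `O` with the
#'   same dimnames.
#' @export
smooth_map <- function(spec, pred, method = c("viterbi", "posterior")) {
  stopifnot(inherits(spec, "hmm_spec"), is.matrix(pred))
  method <- match.arg(method)
  path <- switch(method,
                 viterbi = viterbi_batch(spec, pred),
                 posterior = posterior_batch(spec, pred))
  matrix(unname(spec$to_three[names(spec$initial)[path]]),
         nrow(pred), ncol(pred), dimnames = dimnames(pred))
}

#' Write / read an HMM specification as YAML
#'
#' Serializes the latent scheme name and the full initial, transition and
#' emission matrices as structured text.
#'
#' @param spec An [hmm_spec()].
#' @param path YAML path.
#' @param tax Taxonomy used to rebuild the latent scheme on read.
#' @return `path` invisibly; `read_hmm_spec` returns an [hmm_spec()].
#' @export
write_hmm_spec <- function(spec, path) {
  stopifnot(inherits(spec, "hmm_spec"))
  yaml::write_yaml(list(
    latent_scheme = spec$latent_scheme$name,
    latent_labels = names(spec$initial),
    initial = as.numeric(spec$initial),
    transition = as.numeric(spec$transition),
    emission = as.numeric(spec$emission)
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_hmm_spec
#' @export
read_hmm_spec <- function(path, tax = taxonomy()) {
  lst <- yaml::read_yaml(path)
  need <- c("latent_scheme", "latent_labels", "initial", "transition",
            "emission")
  miss <- setdiff(need, names(lst))
  if (length(miss) > 0) {
    stop("malformed HMM spec ", path, ": missing field(s) ",
         paste(miss, collapse = ", "))
  }
  scheme <- class_scheme(lst$latent_scheme, tax)
  k <- length(lst$latent_labels)
  if (!identical(scheme$labels, lst$latent_labels)) {
    stop("malformed HMM spec ", path, ": latent labels do not match the '",
         lst$latent_scheme, "' scheme")
  }
  # absorb serialization round-off (at most ~1e-6) by renormalizing
  renorm <- function(x, what) {
    if (abs(sum(x) - 1) > 1e-6) {
      stop("malformed HMM spec ", path, ": ", what, " does not sum to 1")
    }
    x / sum(x)
  }
  initial <- renorm(as.numeric(lst$initial), "initial")
  transition <- matrix(as.numeric(lst$transition), k, k)
  transition <- t(apply(transition, 1, renorm, what = "a transition row"))
  emission <- matrix(as.numeric(lst$emission), k, length(OBS_LABELS))
  emission <- t(apply(emission, 1, renorm, what = "an emission row"))
  hmm_spec(scheme, initial, transition, emission, tax)
}
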