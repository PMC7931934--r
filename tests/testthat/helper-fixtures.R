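# Shared fixtures: tiny scenes and a brute-force Viterbi oracle.

three_scheme <- class_scheme("three")
binary_scheme <- class_scheme("binary")
four_scheme <- class_scheme("four")
nine_scheme <- class_scheme("nine")
nineteen_scheme <- class_scheme("nineteen")

# Small default scene, simulated once per test run.
tiny_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scene(scene_config(n_rows = 12, n_cols = 12, seed = 7))
    }
    cache
  }
})

# A noiseless, perfectly separable scene (for separability oracles).
noiseless_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scene(scene_config(n_rows = 10, n_cols = 10,
                                            noise_sd = 0, seed = 21))
    }
    cache
  }
})

# Exhaustive all-paths decoder: enumerates every latent path, scores it,
# and returns the three-class mapping of the best path (first in
# enumeration order on exact ties). Independent of the DP implementation.
brute_force_smooth <- function(spec, obs) {
  k <- length(spec$initial)
  T_len <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), T_len)))
  obs_idx <- match(obs, colnames(spec$emission))
  lp <- log(spec$initial)[paths[, 1]] +
    log(spec$emission)[cbind(paths[, 1], obs_idx[1])]
  if (T_len > 1) {
    for (t_i in 2:T_len) {
      lp <- lp + log(spec$transition)[cbind(paths[, t_i - 1], paths[, t_i])] +
        log(spec$emission)[cbind(paths[, t_i], obs_idx[t_i])]
    }
  }
  best <- which.max(lp)
  list(labels = unname(spec$to_three[names(spec$initial)[paths[best, ]]]),
       logp = max(lp))
}

# Log-probability of one latent path given observations (for score checks).
path_logp <- function(spec, latent_idx, obs) {
  obs_idx <- match(obs, colnames(spec$emission))
  lp <- log(spec$initial)[latent_idx[1]] +
    log(spec$emission)[cbind(latent_idx[1], obs_idx[1])]
  if (length(obs) > 1) {
    for (t_i in 2:length(obs)) {
      lp <- lp + log(spec$transition)[latent_idx[t_i - 1], latent_idx[t_i]] +
        log(spec$emission)[latent_idx[t_i], obs_idx[t_i]]
    }
  }
  unname(lp)
}

# All observation sequences of a given length over an alphabet.
all_sequences <- function(alphabet, len) {
  g <- expand.grid(rep(list(alphabet), len), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) unname(unlist(g[i, ])))
}

# Three-class truth map of a scene.
truth_three <- function(scene) {
  matrix(aggregate_code(as.vector(scene$truth), three_scheme),
         nrow(scene$truth), dimnames = dimnames(scene$truth))
}
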