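# Pluggable binary classifier backends for the pairwise ensemble.
#
# The default is a feed-forward network with hidden layers of 158, 64 and
# 20 units (322 -> 158 -> 64 -> 20 -> 1 logit), trained by full-batch Adam
# on the logistic loss; an RBF-kernel SVM (via e1071) covers the
# margin-based baseline, and a plain logistic regression is provided as a
# fast linear reference.

#' Classifier backend specification
#'
#' Describes how each pairwise binary classifier is fitted. The contract
#' is `fit_backend(spec, x, y, seed)` then `predict_backend(model, x)`,
#' with `y` a two-level factor/character vector; predictions are hard
#' labels and deterministic given the seed.
#'
#' @param type `"mlp"` (default), `"svm"` or `"logistic"`.
#' @param hidden Hidden layer sizes for the network backend.
#' @param epochs Training epochs (full-batch Adam) for the network.
#' @param learning_rate Adam step size.
#' @param l2 L2 weight penalty for the network.
#' @param cost,gamma RBF-SVM hyperparameters (`gamma = NULL` uses the
#'   e1071 default `1/ncol(x)`).
#' @return Object of class `backend_spec`.
#' @export
#' @examples
#' backend_spec("mlp")
#' backend_spec("svm", cost = 10)
backend_spec <- function(type = c("mlp", "svm", "logistic"),
                         hidden = c(158L, 64L, 20L),
                         epochs = 150L, learning_rate = 5e-3, l2 = 1e-4,
                         cost = 1, gamma = NULL) {
  type <- match.arg(type)
  stopifnot(length(hidden) >= 1, all(hidden >= 1), epochs >= 1,
            learning_rate > 0, l2 >= 0, cost > 0)
  structure(list(type = type, hidden = as.integer(hidden),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 l2 = l2, cost = cost, gamma = gamma),
            class = "backend_spec")
}

#' @export
print.backend_spec <- function(x, ...) {
  cat("<backend_spec>", x$type,
      if (x$type == "mlp") paste0("(hidden ", paste(x$hidden, collapse = "-"),
                                  ", ", x$epochs, " epochs)"),
      "\n")
  invisible(x)
}

#' Fit a binary classifier backend
#'
#' @param spec A [backend_spec()].
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary labels (character/factor with exactly 2 levels present).
#' @param seed Integer seed for weight initialization.
#' @return A trained backend model (class `backend_model`).
#' @export
fit_backend <- function(spec, x, y, seed = 1L) {
  stopifnot(inherits(spec, "backend_spec"), is.matrix(x))
  y <- as.character(y)
  levels <- sort(unique(y))
  if (length(levels) != 2) {
    stop("backend needs exactly 2 classes in y, got: ",
         paste(levels, collapse = ", "))
  }
  yy <- as.integer(y == levels[2])  # 0/1 target
  fit <- switch(spec$type,
    mlp = with_seed(seed, mlp_fit(x, yy, spec)),
    svm = with_seed(seed, e1071::svm(
      x, factor(y, levels = levels), type = "C-classification",
      kernel = "radial", cost = spec$cost,
      gamma = if (is.null(spec$gamma)) 1 / ncol(x) else spec$gamma,
      scale = FALSE)),
    logistic = with_seed(seed, logistic_fit(x, yy, spec))
  )
  structure(list(spec = spec, fit = fit, levels = levels, p = ncol(x)),
            class = "backend_model")
}

#' Predict hard binary labels
#'
#' @param model A fitted `backend_model`.
#' @param x Feature matrix with the training dimensionality.
#' @return Character vector of predicted labels.
#' @export
predict_backend <- function(model, x) {
  stopifnot(inherits(model, "backend_model"), is.matrix(x))
  if (ncol(x) != model$p) {
    stop("feature dimensionality mismatch: model expects ", model$p,
         ", got ", ncol(x))
  }
  switch(model$spec$type,
    mlp = model$levels[1 + as.integer(mlp_forward(model$fit, x) > 0.5)],
    svm = as.character(stats::predict(model$fit, x)),
    logistic = {
      eta <- drop(cbind(1, x) %*% model$fit$coef)
      model$levels[1 + as.integer(eta > 0)]
    })
}

# ---- feed-forward network (full-batch Adam, logistic loss) ----

mlp_init <- function(sizes) {
  # He-style initialization per layer
  lapply(seq_len(length(sizes) - 1), function(i) {
    n_in <- sizes[i]; n_out <- sizes[i + 1]
    list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
         b = rep(0, n_out))
  })
}

mlp_fit <- function(x, y01, spec) {
  sizes <- c(ncol(x), spec$hidden, 1L)
  layers <- mlp_init(sizes)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(x)
  for (epoch in seq_len(spec$epochs)) {
    # forward
    acts <- vector("list", length(layers) + 1)
    acts[[1]] <- x
    for (i in seq_along(layers)) {
      z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
      acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else z
    }
    p <- 1 / (1 + exp(-acts[[length(acts)]]))
    # backward
    delta <- (p - y01) / n           # d loss / d logit
    for (i in rev(seq_along(layers))) {
      gW <- crossprod(acts[[i]], delta) + spec$l2 * layers[[i]]$W
      gb <- colSums(delta)
      if (i > 1) {
        delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
      }
      t_adam <- epoch
      m[[i]]$W <- b1 * m[[i]]$W + (1 - b1) * gW
      m[[i]]$b <- b1 * m[[i]]$b + (1 - b1) * gb
      v[[i]]$W <- b2 * v[[i]]$W + (1 - b2) * gW^2
      v[[i]]$b <- b2 * v[[i]]$b + (1 - b2) * gb^2
      mhW <- m[[i]]$W / (1 - b1^t_adam); mhb <- m[[i]]$b / (1 - b1^t_adam)
      vhW <- v[[i]]$W / (1 - b2^t_adam); vhb <- v[[i]]$b / (1 - b2^t_adam)
      layers[[i]]$W <- layers[[i]]$W - spec$learning_rate * mhW / (sqrt(vhW) + eps)
      layers[[i]]$b <- layers[[i]]$b - spec$learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }
  list(layers = layers)
}

mlp_forward <- function(fit, x) {
  a <- x
  layers <- fit$layers
  for (i in seq_along(layers)) {
    z <- sweep(a %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    a <- if (i < length(layers)) pmax(z, 0) else z
  }
  drop(1 / (1 + exp(-a)))
}

# ---- logistic regression (IRLS with ridge guard) ----

logistic_fit <- function(x, y01, spec) {
  xd <- cbind(1, x)
  coef <- rep(0, ncol(xd))
  lambda <- max(spec$l2, 1e-6)
  for (iter in 1:25) {
    eta <- drop(xd %*% coef)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-6)
    z <- eta + (y01 - p) / w
    xtw <- t(xd * w)
    h <- xtw %*% xd + diag(lambda, ncol(xd))
    new_coef <- drop(solve(h, xtw %*% z))
    if (max(abs(new_coef - coef)) < 1e-8) { coef <- new_coef; break }
    coef <- new_coef
  }
  list(coef = coef)
}
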