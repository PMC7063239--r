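#' Partial least squares regression between score spaces (SIMPLS)
#'
#' Deterministic SIMPLS fit: components sequentially maximise the covariance
#' between predictor and response scores, with deflation of the
#' cross-product matrix. Columns are mean-centred but, by default, not
#' variance-scaled — PC scores carry meaningful eigenvalue-weighted scale.
#' SIMPLS components are nested, so a model fitted with `k` components
#' also provides the fit at every smaller component count (see
#' [pls_coefficients()]), which the error-evolution analysis exploits.
#'
#' @param X Numeric n-by-p predictor matrix (e.g. decoupled PC scores).
#' @param Y Numeric n-by-q response matrix (e.g. articulated PC scores).
#' @param k Number of latent components (at most `rank(X)`).
#' @param scale Standardise predictor and response columns (default
#'   `FALSE`).
#' @return A `limb_pls` object with centering vectors, coefficient matrix
#'   `B` (p-by-q, at the stored `k`), and per-component weights/loadings.
#' @export
fit_pls <- function(X, Y, k, scale = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have the same number of rows.")
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  x_scale <- rep(1, p); y_scale <- rep(1, q)
  X0 <- sweep(X, 2L, x_mean); Y0 <- sweep(Y, 2L, y_mean)
  if (scale) {
    x_scale <- apply(X0, 2L, sd); x_scale[x_scale == 0] <- 1
    y_scale <- apply(Y0, 2L, sd); y_scale[y_scale == 0] <- 1
    X0 <- sweep(X0, 2L, x_scale, "/"); Y0 <- sweep(Y0, 2L, y_scale, "/")
  }
  dx <- svd(X0, nu = 0, nv = 0)$d
  rk <- sum(dx > max(1, dx[1]) * 1e-10)
  if (k < 1L) abort("`k` must be at least 1.")
  if (k > rk) abort(sprintf("`k` (%d) exceeds the predictor rank (%d).", k, rk))
  R <- matrix(0, p, k); TT <- matrix(0, n, k)
  P <- matrix(0, p, k); Q <- matrix(0, q, k); V <- matrix(0, p, k)
  S <- crossprod(X0, Y0)
  for (a in seq_len(k)) {
    qa <- svd(S, nu = 0)$v[, 1L]
    ra <- S %*% qa
    ta <- X0 %*% ra
    ta <- ta - mean(ta)
    nt <- sqrt(sum(ta^2))
    if (nt < 1e-300) abort("Predictor matrix is rank deficient for the requested k.")
    ta <- ta / nt; ra <- ra / nt
    pa <- crossprod(X0, ta)
    qa <- crossprod(Y0, ta)
    va <- pa
    if (a > 1L) {
      va <- va - V[, 1:(a - 1L), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1L), drop = FALSE], pa)
    }
    va <- va / sqrt(sum(va^2))
    S <- S - va %*% crossprod(va, S)
    R[, a] <- ra; TT[, a] <- ta; P[, a] <- pa; Q[, a] <- qa; V[, a] <- va
  }
  structure(list(k = k, x_mean = x_mean, y_mean = y_mean,
                 x_scale = x_scale, y_scale = y_scale, scaled = scale,
                 weights = R, x_scores = TT, x_loadings = P, y_loadings = Q,
                 B = R %*% t(Q), n = n),
            class = "limb_pls")
}

#' @export
print.limb_pls <- function(x, ...) {
  cat(sprintf("<limb_pls: %d components, %d -> %d variables, n = %d>\n",
              x$k, nrow(x$B), ncol(x$B), x$n))
  invisible(x)
}

#' Coefficient matrix of a PLS fit truncated at `k` components
#'
#' @param object A `limb_pls`.
#' @param k Component count (defaults to the stored `k`).
#' @return The p-by-q coefficient matrix mapping centred predictors to
#'   centred responses.
#' @export
pls_coefficients <- function(object, k = object$k) {
  if (k < 1L || k > object$k) abort("`k` outside the fitted component range.")
  object$weights[, 1:k, drop = FALSE] %*% t(object$y_loadings[, 1:k, drop = FALSE])
}

#' Predict responses from a PLS model
#'
#' Applies centering (and scaling if fitted), the coefficient matrix, and
#' un-centering. The map is affine in the predictors.
#'
#' @param object A `limb_pls`.
#' @param newdata Numeric matrix (or vector) of predictors.
#' @param k Use the fit truncated at `k` components.
#' @param ... Unused.
#' @return Matrix of predicted responses.
#' @export
predict.limb_pls <- function(object, newdata, k = object$k, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  X0 <- sweep(X, 2L, object$x_mean)
  if (object$scaled) X0 <- sweep(X0, 2L, object$x_scale, "/")
  Yh <- X0 %*% pls_coefficients(object, k)
  if (object$scaled) Yh <- sweep(Yh, 2L, object$y_scale, "*")
  sweep(Yh, 2L, -object$y_mean)
}

#' Canonical correlation between shape scores and a binary label
#'
#' With a one-dimensional label there is a single canonical pair; the
#' canonical correlation equals the multiple correlation of the label on
#' the score columns, computed here through the regression identity and
#' invariant to any invertible affine re-coding of the label. The result
#' carries two score-space directions: `weights` (canonical coefficients,
#' the combination maximising correlation) and `loadings` (covariance of
#' the scores with the canonical variate, the direction used to render
#' effect shapes).
#'
#' @param X Numeric n-by-p score matrix.
#' @param y Labels: +1 (male) / -1 (female), any two-level coding, or a
#'   factor with two levels.
#' @return A `limb_cca` object with `r`, `weights`, `loadings`,
#'   `scores` (canonical variate values, unit variance) and the recoded
#'   labels.
#' @export
fit_cca <- function(X, y) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L) abort("`y` must have exactly two classes.")
    y <- ifelse(as.character(y) == lev[2L], 1, -1)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) abort("Both classes must be present in `y`.")
  if (length(y) != nrow(X)) abort("Length of `y` must match rows of `X`.")
  yc <- y - mean(y)
  fit <- lm.fit(cbind(1, X), y)
  coefs <- fit$coefficients[-1L]
  coefs[is.na(coefs)] <- 0
  u <- as.vector(sweep(X, 2L, colMeans(X)) %*% coefs)
  r <- if (sd(u) == 0) 0 else abs(cor(u, yc))
  if (sd(u) > 0 && cor(u, yc) < 0) { coefs <- -coefs; u <- -u }
  a <- coefs / sqrt(sum(coefs^2))
  us <- if (sd(u) > 0) u / sd(u) else u
  cov_xu <- as.vector(crossprod(sweep(X, 2L, colMeans(X)), us)) / (length(y) - 1)
  nl <- sqrt(sum(cov_xu^2))
  loadings <- if (nl > 0) cov_xu / nl else cov_xu
  structure(list(r = r, weights = unname(a), loadings = unname(loadings),
                 cov_xu = unname(cov_xu), x_mean = unname(colMeans(X)),
                 scores = us, y = y, n = length(y)),
            class = "limb_cca")
}

#' @export
print.limb_cca <- function(x, ...) {
  cat(sprintf("<limb_cca: r = %.3f, n = %d, %d score dimensions>\n",
              x$r, x$n, length(x$weights)))
  invisible(x)
}

#' Percent of shape variance explained by a binary factor (one-component PLSR)
#'
#' Reconstructs the score matrix from the label through a one-component
#' PLS regression (equivalently, per-column least-squares on the centred
#' label) and reports `100 * sum(w_j var(Xhat_j)) / sum(w_j var(X_j))`.
#' When `X` holds raw (unstandardised) PC scores their variances already
#' equal the model eigenvalues, so the default unit weights measure the
#' fraction of shape-space variance; pass `weights = eigenvalues` if the
#' scores were standardised.
#'
#' @param X Numeric n-by-p score matrix.
#' @param y Binary labels as in [fit_cca()].
#' @param weights Per-column variance weights (default 1).
#' @return Percent (0-100).
#' @export
plsr_explained_variance <- function(X, y, weights = NULL) {
  X <- as.matrix(X)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L) abort("`y` must have exactly two classes.")
    y <- ifelse(as.character(y) == lev[2L], 1, -1)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) abort("Both classes must be present in `y`.")
  if (is.null(weights)) weights <- rep(1, ncol(X))
  yc <- y - mean(y)
  Xc <- sweep(X, 2L, colMeans(X))
  b <- as.vector(crossprod(Xc, yc)) / sum(yc^2)
  Xhat <- outer(yc, b)
  100 * sum(weights * apply(Xhat, 2L, var)) / sum(weights * apply(Xc, 2L, var))
}
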