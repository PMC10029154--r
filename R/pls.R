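#' Fit a partial least squares regression by SIMPLS
#'
#' Multi-response PLSR via the SIMPLS algorithm (de Jong 1993): components
#' are extracted from the successively deflated cross-product matrix
#' `S = X'Y`, with scores computed directly from the centred predictor
#' matrix. Predictors and responses are mean-centred and not scaled. The
#' algorithm is deterministic; for a one-column response it coincides with
#' univariate PLS1.
#'
#' @param x numeric predictor matrix (n x p), e.g. genotype dosages.
#' @param y numeric response matrix (n x q), e.g. one-hot breed indicators.
#' @param ncomp number of latent components; capped at
#'   `min(ncomp, n - 1, p)`.
#' @return an object of class `breedid_pls` with elements `coefficients`
#'   (p x q, on the original scale), `x_means`, `y_means`, `ncomp`.
#' @export
plsr_fit <- function(x, y, ncomp) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  p <- ncol(x)
  q <- ncol(y)
  if (nrow(y) != n) stop_breedid("plsr_fit: x and y row counts differ")
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1) stop_breedid("plsr_fit: fewer than one usable component")
  x_means <- colMeans(x)
  y_means <- colMeans(y)
  xc <- sweep(x, 2L, x_means)
  yc <- sweep(y, 2L, y_means)

  s <- crossprod(xc, yc)                 # p x q
  r_mat <- matrix(0, p, ncomp)           # weights: scores T = Xc %*% R
  q_mat <- matrix(0, q, ncomp)           # y loadings
  v_mat <- matrix(0, p, ncomp)           # orthonormal basis for x-loadings
  used <- 0L
  for (a in seq_len(ncomp)) {
    # dominant singular pair of S via the small q x q eigenproblem
    sts <- crossprod(s)                  # q x q
    eig <- eigen(sts, symmetric = TRUE)
    if (eig$values[1] < .Machine$double.eps * max(1, eig$values[1], na.rm = TRUE) ||
        eig$values[1] <= 1e-30) break
    w <- s %*% eig$vectors[, 1, drop = FALSE]   # p x 1
    t_score <- xc %*% w
    tt <- drop(crossprod(t_score))
    if (tt <= 1e-30) break
    normt <- sqrt(tt)
    t_score <- t_score / normt
    w <- w / normt
    p_load <- crossprod(xc, t_score)     # p x 1
    q_load <- crossprod(yc, t_score)     # q x 1
    v <- p_load
    if (used > 0) {
      vv <- v_mat[, seq_len(used), drop = FALSE]
      v <- v - vv %*% crossprod(vv, v)
    }
    vnorm <- sqrt(drop(crossprod(v)))
    if (vnorm <= 1e-30) break
    v <- v / vnorm
    s <- s - v %*% crossprod(v, s)
    used <- used + 1L
    r_mat[, used] <- w
    q_mat[, used] <- q_load
    v_mat[, used] <- v
  }
  if (used == 0L) stop_breedid("plsr_fit: response has no variance")
  r_mat <- r_mat[, seq_len(used), drop = FALSE]
  q_mat <- q_mat[, seq_len(used), drop = FALSE]
  coefficients <- tcrossprod(r_mat, q_mat)     # p x q
  dimnames(coefficients) <- list(colnames(x), colnames(y))
  structure(list(coefficients = coefficients, x_means = x_means,
                 y_means = y_means, ncomp = used),
            class = "breedid_pls")
}

#' Predict responses from a fitted PLSR model
#'
#' @param object a `breedid_pls` fit.
#' @param newdata numeric matrix with the same predictors as training.
#' @param ... unused.
#' @return the n x q matrix of raw predicted responses.
#' @export
predict.breedid_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means)) {
    stop_breedid("predict.breedid_pls: predictor count differs from training")
  }
  sweep(newdata, 2L, object$x_means) %*% object$coefficients +
    matrix(object$y_means, nrow(newdata), length(object$y_means), byrow = TRUE)
}

# One-hot (indicator) coding of breed labels, columns in sorted label order.
one_hot <- function(labels) {
  lev <- sort(unique(labels))
  y <- matrix(0, length(labels), length(lev),
              dimnames = list(names(labels), lev))
  y[cbind(seq_along(labels), match(labels, lev))] <- 1
  y
}
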