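#' NIPALS partial least squares regression
#'
#' Fits a bilinear latent-variable regression of `Y` on `X` by the NIPALS
#' algorithm with mean-centering of both blocks (variance scaling of `X`
#' optional, off by default as usual for spectra). Deflation order is
#' fixed and the inner loop is initialized from the `Y` column with the
#' largest variance, so the fit is deterministic. With as many latent
#' variables as the rank of centered `X`, training predictions coincide
#' with the least-squares solution.
#'
#' @param X Numeric matrix, cases by variables (no missing values).
#' @param Y Numeric response vector or matrix (multi-response PLS2).
#' @param ncomp Number of latent variables to extract; must not exceed
#'   `min(nrow(X) - 1, ncol(X))`. If the residual `X` block runs out of
#'   rank earlier, extraction stops there with a warning.
#' @param scale Autoscale `X` columns to unit variance? Constant columns
#'   keep scale 1 (their centered values, hence weights, are zero).
#' @param tol Inner-loop convergence tolerance on the score vector.
#' @param maxit Maximum inner-loop iterations per latent variable.
#' @return Object of class `nipals_pls` with components `weights` (W),
#'   `x_loadings` (P), `y_loadings` (C), `projection`
#'   (R = W (P'W)^-1, so scores = centered X %*% R), `scores`,
#'   `x_mean`, `x_scale`, `y_mean`, and `ncomp` (latent variables actually
#'   extracted).
#' @seealso [predict.nipals_pls()], [coef.nipals_pls()], [nipals_plsda()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(100), 20, 5)
#' y <- X %*% runif(5) + rnorm(20, sd = 0.1)
#' fit <- nipals_pls(X, y, ncomp = 3)
#' print(fit)
#' @export
nipals_pls <- function(X, Y, ncomp, scale = FALSE, tol = 1e-10, maxit = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y have different numbers of cases")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not supported")
  if (ncomp < 1) stop("at least one latent variable is required")
  if (ncomp > min(n - 1, p)) {
    stop("ncomp = ", ncomp, " exceeds the rank bound min(n - 1, p) = ",
         min(n - 1, p))
  }
  x_mean <- colMeans(X)
  Xd <- sweep(X, 2, x_mean)
  if (scale) {
    x_scale <- apply(Xd, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xd <- sweep(Xd, 2, x_scale, "/")
  } else {
    x_scale <- rep(1, p)
  }
  y_mean <- colMeans(Y)
  Yd <- sweep(Y, 2, y_mean)

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  x_var <- sum(Xd^2)
  x_var_expl <- numeric(ncomp)
  a <- 0
  while (a < ncomp) {
    yvar <- apply(Yd, 2, function(col) sum(col^2))
    if (max(yvar) < 1e-14 * max(1, sum(y_mean^2), x_var)) {
      if (a == 0) warning("response has no variance; 0 latent variables extracted")
      break
    }
    u <- Yd[, which.max(yvar)]
    t_old <- rep(0, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(Xd, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- as.numeric(Xd %*% w)
      cc <- crossprod(Yd, tt) / sum(tt^2)
      if (q == 1) break
      u_new <- as.numeric(Yd %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * max(1, sqrt(sum(tt^2)))) {
        u <- u_new; break
      }
      t_old <- tt
      u <- u_new
    }
    w <- crossprod(Xd, u)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(x_var))) {
      if (a == 0) warning("X has no usable variance; 0 latent variables extracted")
      break
    }
    w <- w / nw
    tt <- as.numeric(Xd %*% w)
    tss <- sum(tt^2)
    if (tss < 1e-24 * max(1, x_var)) break
    pp <- crossprod(Xd, tt) / tss
    cc <- crossprod(Yd, tt) / tss
    a <- a + 1
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
    Xd <- Xd - tcrossprod(tt, pp)
    Yd <- Yd - tcrossprod(tt, cc)
    x_var_expl[a] <- tss * sum(pp^2)
  }
  if (a < ncomp) {
    if (a > 0) {
      warning("rank exhausted after ", a, " latent variables (", ncomp,
              " requested)")
    }
    W <- W[, seq_len(max(a, 1)), drop = FALSE]
    P <- P[, seq_len(max(a, 1)), drop = FALSE]
    C <- C[, seq_len(max(a, 1)), drop = FALSE]
    Tm <- Tm[, seq_len(max(a, 1)), drop = FALSE]
  }
  # projection matrix R with scores = Xc %*% R, built incrementally
  R <- W
  if (a >= 2) {
    for (j in 2:a) {
      prev <- seq_len(j - 1)
      R[, j] <- W[, j] - R[, prev, drop = FALSE] %*%
        crossprod(P[, prev, drop = FALSE], W[, j])
    }
  }
  structure(list(ncomp = a, weights = W, x_loadings = P, y_loadings = C,
                 projection = R, scores = Tm,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 x_var = x_var, x_var_explained = x_var_expl[seq_len(max(a, 1))],
                 dims = c(n = n, p = p, q = q),
                 Y = Y, y_names = colnames(Y)),
            class = "nipals_pls")
}

#' Predict from a NIPALS PLS model
#'
#' Applies the stored centering (and scaling) and the model coefficients;
#' the model object is never modified. Predictions through the regression
#' coefficients and through the score decomposition are algebraically
#' identical.
#'
#' @param object A `nipals_pls` model.
#' @param newdata Matrix with the training variable count.
#' @param ncomp Latent-variable count(s) at which to predict; defaults to
#'   all extracted. A scalar gives a cases x responses matrix, a vector a
#'   3-D array (cases x responses x ncomp).
#' @param ... Unused.
#' @export
predict.nipals_pls <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " variables; model was trained on ",
         length(object$x_mean))
  }
  if (object$ncomp == 0) {
    out <- matrix(object$y_mean, nrow(newdata), length(object$y_mean),
                  byrow = TRUE)
    colnames(out) <- object$y_names
    return(out)
  }
  if (any(ncomp < 1) || any(ncomp > object$ncomp)) {
    stop("ncomp must lie in 1..", object$ncomp)
  }
  Xc <- sweep(sweep(newdata, 2, object$x_mean), 2, object$x_scale, "/")
  Tn <- Xc %*% object$projection
  q <- nrow(object$y_loadings)
  amax <- max(ncomp)
  # cumulative predictions over latent variables
  preds <- array(0, dim = c(nrow(newdata), q, amax))
  acc <- matrix(rep(object$y_mean, each = nrow(newdata)), nrow(newdata), q)
  for (a in seq_len(amax)) {
    acc <- acc + tcrossprod(Tn[, a], object$y_loadings[, a])
    preds[, , a] <- acc
  }
  if (length(ncomp) == 1) {
    out <- preds[, , ncomp, drop = FALSE]
    dim(out) <- c(nrow(newdata), q)
    colnames(out) <- object$y_names
    rownames(out) <- rownames(newdata)
    return(out)
  }
  out <- preds[, , ncomp, drop = FALSE]
  dimnames(out) <- list(rownames(newdata), object$y_names, ncomp)
  out
}

#' Regression coefficients of a NIPALS PLS model
#'
#' @param object A `nipals_pls` model.
#' @param ncomp Latent-variable count (default: all extracted).
#' @param ... Unused.
#' @return Variables x responses coefficient matrix on the original
#'   (unscaled) variable scale; the intercept is
#'   `y_mean - x_mean %*% B`.
#' @export
coef.nipals_pls <- function(object, ncomp = object$ncomp, ...) {
  if (object$ncomp == 0) {
    return(matrix(0, length(object$x_mean), length(object$y_mean)))
  }
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  idx <- seq_len(ncomp)
  B <- object$projection[, idx, drop = FALSE] %*%
    t(object$y_loadings[, idx, drop = FALSE])
  B / object$x_scale
}

#' @export
fitted.nipals_pls <- function(object, ncomp = object$ncomp, ...) {
  if (object$ncomp == 0) {
    return(matrix(object$y_mean, object$dims["n"], object$dims["q"],
                  byrow = TRUE))
  }
  idx <- seq_len(ncomp)
  sweep(object$scores[, idx, drop = FALSE] %*%
          t(object$y_loadings[, idx, drop = FALSE]), 2, object$y_mean, "+")
}

#' @export
residuals.nipals_pls <- function(object, ncomp = object$ncomp, ...) {
  object$Y - fitted(object, ncomp = ncomp)
}

#' @export
print.nipals_pls <- function(x, ...) {
  cat("NIPALS PLS model:", x$dims["p"], "variables ->", x$dims["q"],
      if (x$dims["q"] == 1) "response," else "responses,",
      x$ncomp, "latent variables\n")
  if (x$ncomp > 0) {
    cat("  X variance explained:",
        paste0(round(100 * cumsum(x$x_var_explained) / x$x_var, 1), "%",
               collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.nipals_pls <- function(object, ...) {
  print(object)
  invisible(object)
}

#' NIPALS PLS discriminant analysis
#'
#' One-hot encodes the class labels and fits a multi-response NIPALS PLS
#' model ([nipals_pls]) to the indicator matrix. Classification assigns
#' each case to the class with the largest predicted indicator, ties
#' broken toward the lowest class index, so only class indices (not their
#' name strings) matter.
#'
#' @param X Numeric matrix, cases by variables.
#' @param labels Class labels (character or factor); at least two classes,
#'   each with at least one training case.
#' @param ncomp Latent variables, as in [nipals_pls()].
#' @param ... Passed on to [nipals_pls()].
#' @return Object of class `nipals_plsda` (inherits `nipals_pls`) with a
#'   `levels` component holding the class order (order of first
#'   appearance).
#' @examples
#' set.seed(2)
#' X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, mean = 10), 20, 2))
#' lab <- rep(c("a", "b"), each = 20)
#' fit <- nipals_plsda(X, lab, ncomp = 1)
#' table(predict(fit, X), lab)
#' @export
nipals_plsda <- function(X, labels, ncomp, ...) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2) {
    stop("PLS-DA needs at least two classes; got ", length(lev))
  }
  Y <- sapply(lev, function(cl) as.numeric(labels == cl))
  fit <- nipals_pls(X, Y, ncomp = ncomp, ...)
  fit$levels <- lev
  class(fit) <- c("nipals_plsda", class(fit))
  fit
}

#' @rdname nipals_plsda
#' @param object A `nipals_plsda` model.
#' @param newdata Matrix of cases to classify.
#' @param type `"class"` for labels (argmax of predicted indicators) or
#'   `"response"` for the raw indicator predictions.
#' @export
predict.nipals_plsda <- function(object, newdata,
                                 ncomp = object$ncomp,
                                 type = c("class", "response"), ...) {
  type <- match.arg(type)
  resp <- predict.nipals_pls(object, newdata, ncomp = ncomp)
  if (type == "response") return(resp)
  if (length(dim(resp)) == 3) {
    out <- apply(resp, 3, function(m)
      object$levels[max.col(m, ties.method = "first")])
    if (is.null(dim(out))) out <- matrix(out, nrow = 1)
    colnames(out) <- dimnames(resp)[[3]]
    return(out)
  }
  object$levels[max.col(resp, ties.method = "first")]
}

#' @export
print.nipals_plsda <- function(x, ...) {
  cat("NIPALS PLS-DA model:", length(x$levels), "classes,",
      x$dims["p"], "variables,", x$ncomp, "latent variables\n")
  invisible(x)
}

#' Principal component analysis of a spectral matrix
#'
#' Centered SVD-based PCA for data exploration; explained-variance
#' fractions are non-increasing and sum to 1 over all components.
#'
#' @param X Numeric matrix, cases by variables.
#' @param k Number of components, at most `min(nrow(X) - 1, ncol(X))`.
#' @return Object of class `spectral_pca` with `loadings` (variables x k),
#'   `scores` (cases x k) and `explained` (all variance fractions, of
#'   which the first `k` belong to the returned components).
#' @export
spectral_pca <- function(X, k) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1, ncol(X))
  if (k < 1 || k > kmax) stop("k must lie in 1..", kmax)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  ev <- sv$d^2
  expl <- ev / sum(ev)
  structure(list(loadings = sv$v[, seq_len(k), drop = FALSE],
                 scores = (sv$u %*% diag(sv$d, length(sv$d)))[, seq_len(k),
                                                              drop = FALSE],
                 explained = expl, k = k),
            class = "spectral_pca")
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat("PCA:", x$k, "components;",
      paste0(round(100 * x$explained[seq_len(min(x$k, 5))], 1), "%",
             collapse = " + "), "explained\n")
  invisible(x)
}
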