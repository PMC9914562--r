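#' Reflectance calibration of a raw hypercube
#'
#' `Rc = (I - B) / (W - B)` elementwise, where `I` is the raw cube, `W` the
#' white-reference cube (reflectance ~100%) and `B` the black reference
#' (reflectance 0%). The transform is scale-free: a common positive gain on
#' `I`, `W` and `B` leaves the reflectance unchanged.
#'
#' @param cube A `hypercube` (see [simulate_hypercube()]).
#' @return 3-D reflectance array with the cube's dimensions.
#' @export
calibrate_reflectance <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  denom <- cube$white - cube$black
  bad <- which(denom == 0)
  if (length(bad) > 0) {
    ijk <- arrayInd(bad[1], dim(denom))
    stop("white equals black at voxel (", paste(ijk, collapse = ", "),
         "): reflectance undefined")
  }
  (cube$data - cube$black) / denom
}

#' Mean spectrum over a region of interest
#'
#' Per-band arithmetic mean over the ROI pixels. The default ROI is a
#' 50 x 50 pixel block centered in the image, mirroring selection at the
#' center of the sample dish.
#'
#' @param cube 3-D reflectance array (x, y, band).
#' @param roi List with `x`, `y` (1-based offsets), `width`, `height`;
#'   `NULL` for the centered default.
#' @return Numeric vector, one value per band.
#' @export
roi_mean_spectrum <- function(cube, roi = NULL) {
  d <- dim(cube)
  stopifnot(length(d) == 3)
  if (is.null(roi)) {
    w <- 50; h <- 50
    roi <- list(x = floor((d[1] - w) / 2) + 1, y = floor((d[2] - h) / 2) + 1,
                width = w, height = h)
  }
  x2 <- roi$x + roi$width - 1
  y2 <- roi$y + roi$height - 1
  if (roi$x < 1 || roi$y < 1 || x2 > d[1] || y2 > d[2]) {
    stop("ROI (", roi$x, ":", x2, ", ", roi$y, ":", y2,
         ") outside cube of ", d[1], " x ", d[2], " pixels")
  }
  apply(cube[roi$x:x2, roi$y:y2, , drop = FALSE], 3, mean)
}

#' Standard normal variate normalization
#'
#' Centers and scales each spectrum to mean 0 and (sample) standard
#' deviation 1, removing multiplicative and additive intensity effects;
#' invariant under any affine transform of the input.
#'
#' @param x Numeric vector (one spectrum) or matrix (one spectrum per row).
#' @return Object of the same shape.
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  if (length(x) < 2) stop("SNV needs at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("SNV undefined for a zero-variance spectrum")
  (x - mean(x)) / s
}

#' Asymmetric least-squares baseline correction
#'
#' Estimates a smooth baseline by penalized least squares with asymmetric
#' weights (points above the running baseline, i.e. peaks, get weight `p`;
#' points at or below it weight `1 - p`), and returns the spectrum minus
#' that baseline. For positive-peak spectra the estimate hugs the valleys,
#' so peak shapes survive while smooth drifts are removed.
#'
#' @param y Numeric vector (one spectrum) or matrix (spectra in rows).
#' @param lambda Smoothness penalty on the squared second differences of
#'   the baseline (larger = stiffer); default 1e5.
#' @param p Asymmetry in (0, 1); default 0.01.
#' @param maxit Weight-update iterations.
#' @return Corrected spectrum (same shape as `y`); for a vector input the
#'   estimated baseline is attached as attribute `"baseline"`.
#' @export
baseline_als <- function(y, lambda = 1e5, p = 0.01, maxit = 10) {
  stopifnot(lambda > 0, p > 0, p < 1)
  if (is.matrix(y)) {
    return(t(apply(y, 1, function(r)
      as.numeric(baseline_als(r, lambda, p, maxit)))))
  }
  if (any(!is.finite(y))) stop("baseline correction needs finite input")
  m <- length(y)
  if (m < 4) stop("spectrum too short for baseline estimation")
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  out <- y - z
  attr(out, "baseline") <- z
  out
}

#' Preprocess a spectral dataset
#'
#' Applies, in this fixed order, asymmetric least-squares baseline
#' correction (spectral modalities only) followed by standard normal
#' variate normalization, per spectrum. Both steps are switchable; the
#' settings used are recorded on the result for provenance.
#'
#' @param dataset A `spectral_dataset`.
#' @param baseline Apply baseline correction? (Never applied to `GCMS_FA`,
#'   which has no baseline to drift.)
#' @param normalize Apply SNV?
#' @param lambda,p Baseline parameters, see [baseline_als()].
#' @return The dataset with `X` preprocessed and a `preprocess` record.
#' @export
preprocess_dataset <- function(dataset, baseline = TRUE, normalize = TRUE,
                               lambda = 1e5, p = 0.01) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  X <- dataset$X
  do_base <- baseline && dataset$modality != "GCMS_FA"
  if (do_base) X <- baseline_als(X, lambda = lambda, p = p)
  if (normalize) X <- snv(X)
  dimnames(X) <- dimnames(dataset$X)
  dataset$X <- X
  dataset$preprocess <- list(baseline = do_base, normalize = normalize,
                             lambda = lambda, p = p)
  dataset
}
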