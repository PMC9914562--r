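#' Measurement modalities and their variable axes
#'
#' Five modalities are emulated: NIR hyperspectral imaging (`HSI_NIR`,
#' 900-1700 nm), mid-infrared (`FTIR`, 400-4000 cm-1), Raman shift
#' (`RAMAN`, 500-2000 cm-1), `UVVIS` (200-800 nm) and the GC-MS fatty-acid
#' profile (`GCMS_FA`, seven named fatty acids).
#'
#' @return `modalities()` returns the modality names; `modality_axis()`
#'   the ordered variable grid (numeric positions, or named fatty-acid
#'   slots for `GCMS_FA`).
#' @export
modalities <- function() c("HSI_NIR", "FTIR", "RAMAN", "UVVIS", "GCMS_FA")

#' @rdname modalities
#' @param modality One of [modalities()].
#' @param spacing Optional grid spacing overriding the default
#'   (4 nm HSI, 4 cm-1 FTIR, 1 cm-1 Raman, 5 nm UV-Vis).
#' @export
modality_axis <- function(modality, spacing = NULL) {
  modality <- match.arg(modality, modalities())
  if (modality == "GCMS_FA") {
    ax <- seq_len(7)
    names(ax) <- rownames(fa_reference())
    return(ax)
  }
  rng <- switch(modality,
    HSI_NIR = c(900, 1700), FTIR = c(400, 4000),
    RAMAN = c(500, 2000), UVVIS = c(200, 800))
  dflt <- switch(modality, HSI_NIR = 4, FTIR = 4, RAMAN = 1, UVVIS = 5)
  seq(rng[1], rng[2], by = if (is.null(spacing)) dflt else spacing)
}

#' Noiseless endmember spectrum of a pure oil
#'
#' Each spectral modality carries a fixed set of Gaussian bands at the
#' characteristic positions of edible-oil spectra; a band's intensity is a
#' linear form in the oil's fatty-acid composition (plus an EVOO pigment
#' component for the visible range), so EVOO is strong at the oleic-linked
#' bands and the adulterant oils at the linoleic/linolenic-linked ones.
#' For `GCMS_FA` the "spectrum" is the fatty-acid fraction vector itself.
#' The function is deterministic.
#'
#' @param oil One of [oil_classes()].
#' @param modality One of [modalities()].
#' @param axis Optional axis (defaults to [modality_axis()]).
#' @return Named numeric vector on the modality axis.
#' @export
endmember_spectrum <- function(oil, modality, axis = NULL) {
  oil <- match.arg(oil, oil_classes())
  modality <- match.arg(modality, modalities())
  if (modality == "GCMS_FA") {
    prof <- fa_reference("mean")[, oil] / 100
    return(prof)
  }
  if (is.null(axis)) axis <- modality_axis(modality)
  comp <- .oil_composition(oil)
  shift <- .oil_band_shift(oil, modality)
  s <- numeric(length(axis))
  for (band in c(.endmember_bands(modality), .signature_bands(modality))) {
    h <- band$height * sum(band$loading * comp)
    if (h < 0) stop("negative band intensity for ", oil, " at ", band$center)
    ctr <- band$center + if (isTRUE(band$fixed)) 0 else shift
    s <- s + h * exp(-((axis - ctr)^2) / (2 * band$width^2))
  }
  names(s) <- axis
  s
}

#' Linear gravimetric mixing of two spectra
#'
#' `(1 - mass_fraction) * evoo + mass_fraction * adulterant`, elementwise:
#' the in-silico stand-in for blending the oils by mass. Mixing is affine,
#' so `mix(a, b, f) + mix(a, b, 1 - f) = a + b`.
#'
#' @param evoo,adulterant Spectra on the same axis.
#' @param mass_fraction Adulterant mass fraction in \[0, 1\].
#' @return Mixed spectrum.
#' @export
mix_spectrum <- function(evoo, adulterant, mass_fraction) {
  if (length(evoo) != length(adulterant)) {
    stop("spectra have different axes (", length(evoo), " vs ",
         length(adulterant), " points)")
  }
  stopifnot(mass_fraction >= 0, mass_fraction <= 1)
  (1 - mass_fraction) * evoo + mass_fraction * adulterant
}

#' Simulate a spectral dataset for a design
#'
#' One row per case: the gravimetric mixture of the EVOO and adulterant
#' endmembers at the sample's mass fraction, plus a random smooth quadratic
#' baseline (drift between replicate acquisitions) and i.i.d. additive
#' Gaussian noise. Identical `(design, modality, seed)` give identical
#' datasets.
#'
#' @param design An `oil_design`.
#' @param modality One of [modalities()].
#' @param noise_sd Standard deviation of additive noise, in intensity units
#'   (endmember peaks are of order 1).
#' @param drift_sd Standard deviation of the random quadratic baseline
#'   coefficients.
#' @param seed Integer seed.
#' @return Object of class `spectral_dataset`: list with `modality`,
#'   `axis`, matrix `X` (cases x variables), and per-case vectors
#'   `case_id`, `sample_id`, `class_label`, `category`, `adulterant`,
#'   `mass_fraction`.
#' @export
simulate_dataset <- function(design, modality, noise_sd = 0.01,
                             drift_sd = 0.01, seed = 1) {
  stopifnot(inherits(design, "oil_design"), noise_sd >= 0, drift_sd >= 0)
  modality <- match.arg(modality, modalities())
  axis <- modality_axis(modality)
  ends <- sapply(oil_classes(), endmember_spectrum, modality = modality)
  cases <- design_cases(design)
  n <- nrow(cases)
  p <- length(axis)
  base <- matrix(0, n, p)
  evoo <- ends[, "EVOO"]
  for (i in seq_len(n)) {
    if (cases$category[i] == "pure_evoo") {
      base[i, ] <- evoo
    } else {
      base[i, ] <- mix_spectrum(evoo, ends[, cases$adulterant[i]],
                                cases$mass_fraction[i])
    }
  }
  set.seed(seed)
  if (drift_sd > 0) {
    u <- seq(-1, 1, length.out = p)
    cf <- matrix(stats::rnorm(3 * n, sd = drift_sd), n, 3)
    base <- base + cf %*% rbind(rep(1, p), u, u^2)
  }
  if (noise_sd > 0) {
    base <- base + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  }
  dimnames(base) <- list(cases$case_id, names(axis) %||% axis)
  structure(list(modality = modality, axis = axis, X = base,
                 case_id = cases$case_id, sample_id = cases$sample_id,
                 class_label = cases$class_label,
                 category = cases$category, adulterant = cases$adulterant,
                 mass_fraction = cases$mass_fraction,
                 noise_sd = noise_sd, drift_sd = drift_sd, seed = seed),
            class = "spectral_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("Spectral dataset:", x$modality, "-", nrow(x$X), "cases x",
      ncol(x$X), "variables\n")
  cat("  classes:", length(unique(x$class_label)),
      " noise_sd:", x$noise_sd, " drift_sd:", x$drift_sd, "\n")
  invisible(x)
}

#' Read and write spectra as CSV
#'
#' Header row = axis positions, first column = case id. `read_spectra`
#' re-attaches case metadata from a design when given one.
#'
#' @param dataset A `spectral_dataset`.
#' @param path File path.
#' @param modality Modality name for the file being read.
#' @param design Optional `oil_design` whose case table labels the rows.
#' @export
write_spectra <- function(dataset, path) {
  df <- data.frame(case_id = dataset$case_id, dataset$X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("case_id", as.character(unname(dataset$axis)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, modality, design = NULL) {
  modality <- match.arg(modality, modalities())
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$case_id
  axis <- modality_axis(modality)
  if (ncol(X) != length(axis)) {
    stop("file has ", ncol(X), " variables but the ", modality,
         " axis has ", length(axis))
  }
  out <- list(modality = modality, axis = axis, X = X, case_id = df$case_id)
  if (!is.null(design)) {
    cases <- design_cases(design)
    m <- match(df$case_id, cases$case_id)
    if (anyNA(m)) stop("case ids in file not present in design")
    out$sample_id <- cases$sample_id[m]
    out$class_label <- cases$class_label[m]
    out$category <- cases$category[m]
    out$adulterant <- cases$adulterant[m]
    out$mass_fraction <- cases$mass_fraction[m]
  }
  structure(out, class = "spectral_dataset")
}

#' Simulate a GC-MS fatty-acid profile
#'
#' Draws each fatty acid from a normal truncated at zero with the reference
#' mean and standard deviation for the oil, then rescales to the oil's
#' reference total, so replicate profiles sum like measured ones.
#' "Not detected" fatty acids are exactly zero.
#'
#' @param oil One of [oil_classes()].
#' @param seed Optional integer seed.
#' @param sd_scale Multiplier on the reference SDs (0 gives the reference
#'   means exactly).
#' @return Named vector of fatty-acid percentages of total FA.
#' @export
simulate_fa_profile <- function(oil, seed = NULL, sd_scale = 1) {
  oil <- match.arg(oil, oil_classes())
  stopifnot(sd_scale >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- fa_reference("mean")[, oil]
  sdv <- fa_reference("sd")[, oil] * sd_scale
  draw <- mu
  for (i in seq_along(mu)) {
    if (mu[i] == 0) { draw[i] <- 0; next }   # nd stays nd
    if (sdv[i] == 0) { draw[i] <- mu[i]; next }
    repeat {
      x <- stats::rnorm(1, mu[i], sdv[i])
      if (x >= 0) { draw[i] <- x; break }
    }
  }
  tot <- sum(mu)
  if (sum(draw) > 0) draw <- draw * tot / sum(draw)
  draw
}

#' Simulate a hyperspectral cube with reference frames
#'
#' Every pixel carries the input spectrum scaled into raw counts between a
#' synthetic black (dark-current) and white (calibration-board) reference,
#' plus optional noise, stored as (x, y, wavelength). Calibrating with the
#' returned references and averaging a region of interest recovers the
#' input spectrum exactly when `noise_sd = 0`.
#'
#' @param spectrum Reflectance-scale spectrum (one value per band).
#' @param nx,ny Spatial dimensions in pixels.
#' @param noise_sd Noise SD in raw counts.
#' @param seed Optional integer seed.
#' @param white_level,black_level Raw count levels of the reference frames
#'   (must differ).
#' @return Object of class `hypercube`: list with 3-D arrays `data`,
#'   `white`, `black` and the band count.
#' @export
simulate_hypercube <- function(spectrum, nx = 60, ny = 60, noise_sd = 0,
                               seed = NULL, white_level = 1000,
                               black_level = 100) {
  stopifnot(nx >= 1, ny >= 1, noise_sd >= 0)
  if (white_level <= black_level) {
    stop("white reference must exceed black reference at every voxel")
  }
  if (!is.null(seed)) set.seed(seed)
  nb <- length(spectrum)
  white <- array(white_level, dim = c(nx, ny, nb))
  black <- array(black_level, dim = c(nx, ny, nb))
  raw <- black + aperm(array(rep(spectrum, nx * ny), dim = c(nb, nx, ny)),
                       c(2, 3, 1)) * (white - black)
  if (noise_sd > 0) raw <- raw + array(stats::rnorm(length(raw), sd = noise_sd),
                                       dim = dim(raw))
  structure(list(data = raw, white = white, black = black, bands = nb),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat("Hypercube:", d[1], "x", d[2], "pixels x", d[3], "bands\n")
  invisible(x)
}
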