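#' Fit a FAME calibration curve
#'
#' Least-squares line through (concentration, peak-area ratio) points,
#' where the ratio is the FAME peak area divided by the internal-standard
#' (tridecanoic acid, C13:0) peak area: `ratio = slope * conc + intercept`.
#' The fit is unweighted.
#'
#' @param concentration FAME standard concentrations (ug/mL), at least two
#'   distinct values.
#' @param ratio Peak-area ratios to the internal standard, same length.
#' @param fame Optional FAME name carried on the object.
#' @return Object of class `fame_calibration` with `slope`, `intercept`,
#'   `points`, `fame`.
#' @export
fit_calibration <- function(concentration, ratio, fame = NA_character_) {
  if (length(concentration) != length(ratio)) {
    stop("concentration and ratio differ in length")
  }
  if (length(unique(concentration)) < 2) {
    stop("calibration needs at least 2 distinct concentrations")
  }
  slope <- stats::cov(concentration, ratio) / stats::var(concentration)
  intercept <- mean(ratio) - slope * mean(concentration)
  pts <- data.frame(concentration = concentration, ratio = ratio)
  pts <- pts[order(pts$concentration), ]
  rownames(pts) <- NULL
  structure(list(slope = slope, intercept = intercept, points = pts,
                 fame = fame),
            class = "fame_calibration")
}

#' @export
print.fame_calibration <- function(x, ...) {
  cat("FAME calibration", if (!is.na(x$fame)) paste0("(", x$fame, ")"),
      ": ratio =", signif(x$slope, 6), "* conc",
      sprintf("%+g", signif(x$intercept, 6)),
      "|", nrow(x$points), "points\n")
  invisible(x)
}

#' Quantify a FAME from peak areas and a calibration curve
#'
#' Converts the sample's peak-area ratio to the internal standard into a
#' concentration by inverting the calibration line:
#' `conc = (ratio - intercept) / slope`. Negative results are floored at
#' zero with a warning.
#'
#' @param sample_area FAME peak area in the sample.
#' @param is_area Internal-standard peak area (> 0).
#' @param curve A `fame_calibration`.
#' @return Concentration in the calibration units (ug/mL).
#' @export
quantify_fame <- function(sample_area, is_area, curve) {
  stopifnot(inherits(curve, "fame_calibration"))
  if (any(is_area <= 0)) stop("internal-standard peak area must be positive")
  if (curve$slope == 0) stop("degenerate calibration: slope is zero")
  conc <- (sample_area / is_area - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("negative concentration floored at 0")
    conc <- pmax(conc, 0)
  }
  conc
}

#' Fatty-acid class sums (SFA, MUFA, PUFA)
#'
#' Aggregates a fatty-acid profile into saturated (C16:0 + C18:0),
#' monounsaturated (C16:1 + C18:1 cis-9) and polyunsaturated
#' (C18:2 + C18:3) totals. The trans isomer C18:1 trans-9 is excluded from
#' MUFA: the reference table's own arithmetic demands it (canola MUFA
#' 58.05 = 57.99 + 0.06, leaving out elaidic 2.96).
#'
#' @param profile Named numeric vector with the seven fatty-acid names of
#'   [fa_reference()] (percent of total FA, all non-negative).
#' @return Named vector `c(sfa, mufa, pufa)`.
#' @export
fa_class_sums <- function(profile) {
  need <- rownames(fa_reference())
  if (!all(need %in% names(profile))) {
    stop("profile is missing: ",
         paste(setdiff(need, names(profile)), collapse = ", "))
  }
  if (any(profile[need] < 0)) stop("fatty-acid fractions must be non-negative")
  c(sfa = unname(profile["C16:0"] + profile["C18:0"]),
    mufa = unname(profile["C16:1"] + profile["C18:1 cis-9"]),
    pufa = unname(profile["C18:2"] + profile["C18:3"]))
}
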