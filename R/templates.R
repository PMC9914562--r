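#' Reference fatty-acid composition of the seven oils
#'
#' Mean percentage of total fatty acids (and between-replicate standard
#' deviations) for the seven fatty acids quantified by GC-MS in each oil.
#' "Not detected" entries are exactly zero. These values parameterize the
#' GC-MS simulator and set the band-intensity contrasts of the spectral
#' endmember templates, so all five simulated modalities share one
#' underlying chemistry.
#'
#' @param type `"mean"` or `"sd"`.
#' @return Numeric matrix, 7 fatty acids (rows) by 7 oils (columns), in
#'   percent of total fatty acids.
#' @export
fa_reference <- function(type = c("mean", "sd")) {
  type <- match.arg(type)
  fam <- c("C16:0", "C16:1", "C18:0", "C18:1 cis-9", "C18:1 trans-9",
           "C18:2", "C18:3")
  oils <- oil_classes()
  mean_tab <- matrix(c(
    # EVOO   safflower corn   soybean canola sunflower sesame
    16.49,  8.99, 13.58, 12.53, 11.52,  8.88,  8.27,   # C16:0
     0.11,  0.00,  0.00,  0.00,  0.06,  0.00,  0.00,   # C16:1
     4.17,  3.86,  2.36,  6.71,  2.40,  3.67,  5.51,   # C18:0
    75.69, 10.38, 25.50, 17.76, 57.99, 20.18, 44.82,   # C18:1 cis-9
     0.00,  0.13,  0.05,  0.46,  2.96,  1.01,  0.92,   # C18:1 trans-9
     3.48, 76.50, 58.30, 58.62, 17.57, 66.26, 40.49,   # C18:2
     0.06,  0.14,  0.21,  3.93,  7.49,  0.00,  0.00    # C18:3
  ), nrow = 7, byrow = TRUE, dimnames = list(fam, oils))
  sd_tab <- matrix(c(
     0.49, 0.50, 0.81, 1.10, 0.40, 0.58, 1.22,
     0.00, 0.00, 0.00, 0.00, 0.01, 0.00, 0.00,
     0.31, 0.42, 0.16, 0.41, 0.19, 0.47, 0.67,
     0.73, 1.03, 1.47, 1.87, 0.58, 0.52, 0.65,
     0.00, 0.02, 0.02, 0.10, 0.21, 0.04, 0.26,
     0.46, 1.88, 1.49, 1.56, 0.45, 0.44, 0.26,
     0.02, 0.03, 0.03, 0.48, 0.53, 0.00, 0.00
  ), nrow = 7, byrow = TRUE, dimnames = list(fam, oils))
  if (type == "mean") mean_tab else sd_tab
}

# Composition vector driving endmember band intensities: the seven
# fatty-acid fractions (of total FA), a "pigment" pseudo-component
# (carotenoids/chlorophyll, which is what makes the unrefined EVOO
# visually distinct in the UV-Vis range), and one minor-constituent
# indicator per oil (tocopherols, phenolics, sesamin and the like) that
# carries each oil's fingerprint bands. Fatty acids alone leave canola
# nearly collinear with EVOO, which contradicts the clean class separation
# the instruments actually achieve; the minor constituents are what real
# spectra discriminate on.
.oil_composition <- function(oil) {
  fa <- fa_reference("mean")[, oil] / 100
  pig <- if (oil == "EVOO") 1 else 0.05
  sig <- stats::setNames(as.numeric(oil_classes() == oil),
                         paste0("sig_", oil_classes()))
  c(fa, pigment = pig, sig)
}

# Composition-dependent displacement of the shared band centers: band
# maxima of edible-oil spectra shift by a fraction of the band width with
# the cis/trans and chain-length makeup of the oil. One scalar per oil,
# scaled to each modality's band width (well under the grid tolerance of
# the reported band positions).
.oil_band_shift <- function(oil, modality) {
  base <- c(EVOO = 0, safflower = 0.4, corn = -0.4, soybean = 0.65,
            canola = -0.65, sunflower = 0.9, sesame = -0.9)[oil]
  w <- switch(modality, HSI_NIR = 8, FTIR = 12, RAMAN = 12, UVVIS = 8)
  base * w * 0.8
}

# Fingerprint bands of each oil's minor constituents, placed in otherwise
# quiet regions of each modality.
.signature_bands <- function(modality) {
  pos <- switch(modality,
    HSI_NIR = c(safflower = 952, corn = 996, soybean = 1044, canola = 1088,
                sunflower = 1608, sesame = 1648),
    FTIR = c(safflower = 1033, corn = 913, soybean = 968, canola = 845,
             sunflower = 780, sesame = 1512),
    RAMAN = c(safflower = 560, corn = 620, soybean = 680, canola = 740,
              sunflower = 800, sesame = 1880),
    UVVIS = c(safflower = 305, corn = 325, soybean = 345, canola = 365,
              sunflower = 385, sesame = 315))
  w <- switch(modality, HSI_NIR = 10, FTIR = 12, RAMAN = 12, UVVIS = 8)
  h <- switch(modality, HSI_NIR = 0.55, FTIR = 0.15, RAMAN = 0.15,
              UVVIS = 0.12)
  lapply(names(pos), function(oil) {
    ld <- .band_loading()
    ld[paste0("sig_", oil)] <- 1
    list(center = unname(pos[oil]), width = w, height = h, loading = ld,
         fixed = TRUE)  # fingerprint bands do not shift with composition
  })
}

# Band tables per modality. Each band has a center on the modality axis, a
# Gaussian width (nm or cm^-1), a height scale, and a loading vector over
# the 8-component composition; the realized endmember intensity is
# height * (loading . composition), so every band is linear in the oil's
# chemistry and the seven endmembers span a 7-dimensional space.
.band_loading <- function(...) {
  nm <- c("C16:0", "C16:1", "C18:0", "C18:1 cis-9", "C18:1 trans-9",
          "C18:2", "C18:3", "pigment", paste0("sig_", oil_classes()))
  v <- stats::setNames(rep(0, length(nm)), nm)
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}

.endmember_bands <- function(modality) {
  L <- .band_loading
  switch(modality,
    # NIR absorption bands; EVOO dominates the oleic-linked 1220/1400/1422 nm
    # bands, adulterants the linoleic/linolenic-linked ones.
    HSI_NIR = list(
      list(center = 1156, width = 8, height = 0.6,
           loading = L(`C18:2` = 1.0, `C18:3` = 0.8, `C18:1 trans-9` = 0.5)),
      list(center = 1174, width = 8, height = 0.6,
           loading = L(`C18:2` = 0.9, `C16:0` = 0.3)),
      list(center = 1220, width = 8, height = 1.0,
           loading = L(`C18:1 cis-9` = 1.0, `C16:1` = 1.0)),
      list(center = 1400, width = 8, height = 0.9,
           loading = L(`C18:1 cis-9` = 0.9, `C18:0` = 0.5, pigment = 0.10)),
      list(center = 1422, width = 8, height = 0.8,
           loading = L(`C18:1 cis-9` = 0.8, `C16:0` = 0.4, pigment = 0.08)),
      list(center = 1534, width = 8, height = 0.7,
           loading = L(`C18:2` = 0.8, `C18:3` = 1.0, `C18:1 trans-9` = 0.3)),
      list(center = 1580, width = 8, height = 0.6,
           loading = L(`C18:2` = 0.7, `C18:0` = 0.8))
    ),
    # Mid-IR bands; the =C-H (3010) and cis-olefin (1654) intensities track
    # unsaturation, the rest are shared triglyceride backbone bands.
    FTIR = list(
      list(center = 3010, width = 12, height = 0.7,
           loading = L(`C18:1 cis-9` = 0.4, `C18:2` = 1.0, `C18:3` = 1.2)),
      list(center = 2927, width = 12, height = 1.0,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.0, `C18:1 cis-9` = 1.0,
                       `C18:2` = 1.0, `C18:3` = 1.0, `C18:1 trans-9` = 1.0)),
      list(center = 2857, width = 12, height = 0.8,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.1, `C18:1 cis-9` = 0.9,
                       `C18:2` = 0.9, `C18:3` = 0.9)),
      list(center = 1747, width = 12, height = 0.9,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.0, `C18:1 cis-9` = 1.0,
                       `C18:1 trans-9` = 1.0, `C18:2` = 1.0, `C18:3` = 1.0)),
      list(center = 1654, width = 12, height = 0.15,
           loading = L(`C18:1 cis-9` = 0.5, `C18:2` = 1.0, `C18:3` = 1.3)),
      list(center = 1463, width = 12, height = 0.5,
           loading = L(`C16:0` = 1.0, `C18:0` = 0.8, `C18:1 cis-9` = 0.9,
                       `C18:2` = 0.8)),
      list(center = 1373, width = 12, height = 0.35,
           loading = L(`C16:0` = 0.9, `C18:0` = 1.0, `C18:1 cis-9` = 0.8,
                       `C18:2` = 0.9, `C16:1` = 1.0)),
      list(center = 1241, width = 12, height = 0.35,
           loading = L(`C18:1 cis-9` = 0.7, `C18:2` = 1.0, `C18:0` = 0.5)),
      list(center = 1164, width = 12, height = 0.65,
           loading = L(`C16:0` = 0.8, `C18:1 cis-9` = 0.9, `C18:2` = 1.0,
                       `C18:3` = 0.8)),
      list(center = 1095, width = 12, height = 0.4,
           loading = L(`C18:2` = 1.0, `C18:3` = 0.9, `C18:1 trans-9` = 0.6)),
      list(center = 721, width = 12, height = 0.45,
           loading = L(`C18:1 cis-9` = 0.8, `C18:2` = 1.2, `C18:3` = 1.0,
                       `C16:0` = 0.3))
    ),
    # Raman shifts of the study's band table; C=C-linked bands (968, 1265,
    # 1525, 1650) scale with unsaturation, so PUFA-rich oils are strong at
    # 1265/1650 while EVOO keeps a (weaker) oleic contribution there.
    RAMAN = list(
      list(center = 868, width = 12, height = 0.35,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.0, `C18:1 cis-9` = 0.8,
                       `C18:2` = 0.8)),
      list(center = 968, width = 12, height = 0.4,
           loading = L(`C18:1 trans-9` = 2.0, `C18:2` = 0.3, `C18:3` = 0.4,
                       `C18:1 cis-9` = 0.12)),
      list(center = 1008, width = 12, height = 0.3,
           loading = L(`C16:0` = 0.8, `C18:0` = 1.0, `C18:1 cis-9` = 0.7,
                       `C18:2` = 0.7, `C16:1` = 1.0)),
      list(center = 1150, width = 12, height = 0.35,
           loading = L(`C16:0` = 1.0, `C18:0` = 0.9, `C18:1 cis-9` = 0.8,
                       `C18:2` = 0.7)),
      list(center = 1265, width = 12, height = 0.9,
           loading = L(`C18:1 cis-9` = 0.4, `C18:2` = 1.0, `C18:3` = 1.2)),
      list(center = 1300, width = 12, height = 0.7,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.0, `C18:1 cis-9` = 1.0,
                       `C18:2` = 0.9, `C18:3` = 0.8)),
      list(center = 1440, width = 12, height = 1.0,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.0, `C18:1 cis-9` = 1.0,
                       `C18:2` = 0.85, `C18:3` = 0.8,
                       `C18:1 trans-9` = 1.0)),
      list(center = 1525, width = 12, height = 0.2,
           loading = L(`C18:2` = 0.8, `C18:3` = 1.0, `C18:1 cis-9` = 0.1,
                       pigment = 0.5)),
      list(center = 1650, width = 12, height = 1.0,
           loading = L(`C18:1 cis-9` = 0.4, `C18:2` = 1.0, `C18:3` = 1.2,
                       `C16:1` = 0.4)),
      list(center = 1750, width = 12, height = 0.5,
           loading = L(`C16:0` = 1.0, `C18:0` = 1.0, `C18:1 cis-9` = 1.0,
                       `C18:2` = 1.0, `C18:3` = 1.0))
    ),
    # UV-Vis: conjugated diene band at 232 nm (strong in PUFA-rich oils,
    # but the main feature of every oil), triene band at 270 nm, and the
    # EVOO-only carotenoid (410/460/475 nm) and chlorophyll (670 nm) bands.
    UVVIS = list(
      list(center = 232, width = 8, height = 1.0,
           loading = L(`C18:1 cis-9` = 0.85, `C16:0` = 0.85, `C18:0` = 0.85,
                       `C18:2` = 1.6, `C18:3` = 1.8, `C18:1 trans-9` = 1.2)),
      list(center = 270, width = 8, height = 0.5,
           loading = L(`C18:2` = 1.0, `C18:3` = 1.4, `C18:1 trans-9` = 0.8,
                       `C18:1 cis-9` = 0.05)),
      list(center = 410, width = 8, height = 0.12, loading = L(pigment = 1)),
      list(center = 460, width = 8, height = 0.10, loading = L(pigment = 1)),
      list(center = 475, width = 8, height = 0.09, loading = L(pigment = 1)),
      list(center = 670, width = 8, height = 0.08, loading = L(pigment = 1))
    ),
    stop("no band templates for modality ", modality)
  )
}
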