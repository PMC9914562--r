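test_that("endmember spectra are deterministic and show the reported bands", {
  expect_identical(endmember_spectrum("EVOO", "RAMAN"),
                   endmember_spectrum("EVOO", "RAMAN"))
  # EVOO Raman: a local maximum near every band of the study's band table
  ax <- modality_axis("RAMAN")
  s <- endmember_spectrum("EVOO", "RAMAN")
  peaks <- ax[which(diff(sign(diff(s))) == -2) + 1]
  for (ctr in c(868, 968, 1008, 1150, 1265, 1300, 1440, 1525, 1650, 1750)) {
    # band overlap can displace a maximum by a couple of grid steps
    expect_lte(min(abs(peaks - ctr)), 2 * (ax[2] - ax[1]),
               label = paste("Raman band", ctr))
  }
  # EVOO UV-Vis absorbance peaks at the conjugated-diene band (~232 nm)
  ax <- modality_axis("UVVIS")
  u <- endmember_spectrum("EVOO", "UVVIS")
  expect_lte(abs(ax[which.max(u)] - 232), ax[2] - ax[1])
  # HSI absorption bands: some oil shows a local maximum near each center
  # (neighbouring bands can merge in oils where one of them is weak)
  ax <- modality_axis("HSI_NIR")
  hs <- sapply(oil_classes(), endmember_spectrum, modality = "HSI_NIR")
  all_peaks <- unlist(lapply(oil_classes(), function(oil) {
    s <- hs[, oil]
    ax[which(diff(sign(diff(s))) == -2) + 1]
  }))
  for (ctr in c(1156, 1174, 1220, 1400, 1422, 1534, 1580)) {
    expect_lte(min(abs(all_peaks - ctr)), 2 * (ax[2] - ax[1]),
               label = paste("HSI band", ctr))
  }
  # EVOO dominates the oleic-linked bands, PUFA-rich oils the linoleic ones
  band <- function(m, ctr) m[which.min(abs(ax - ctr)), ]
  expect_equal(names(which.max(band(hs, 1220))), "EVOO")
  expect_equal(names(which.max(band(hs, 1400))), "EVOO")
  expect_gt(band(hs, 1156)["safflower"], band(hs, 1156)["EVOO"])
  expect_error(endmember_spectrum("lard", "RAMAN"))
})

test_that("mixing is the stated affine combination", {
  a <- endmember_spectrum("EVOO", "UVVIS")
  b <- endmember_spectrum("corn", "UVVIS")
  expect_equal(mix_spectrum(a, b, 0), a)
  expect_equal(mix_spectrum(a, b, 1), b)
  expect_equal(mix_spectrum(c(0, 2), c(2, 0), 0.5), c(1, 1))
  for (f in c(0.1, 0.37, 0.8)) {
    expect_equal(mix_spectrum(a, b, f) + mix_spectrum(a, b, 1 - f), a + b)
  }
  expect_error(mix_spectrum(a, b[-1], 0.5), "axes")
})

test_that("simulated datasets are seeded, sized and centered correctly", {
  d <- build_design()
  ds <- simulate_dataset(d, "UVVIS", seed = 7)
  expect_equal(nrow(ds$X), 183)
  expect_identical(ds$X, simulate_dataset(d, "UVVIS", seed = 7)$X)
  expect_false(identical(ds$X, simulate_dataset(d, "UVVIS", seed = 8)$X))
  # noiseless limit: EVOO rows equal the endmember exactly
  ds0 <- small_dataset()
  evoo_rows <- ds0$X[ds0$class_label == "EVOO", ]
  e <- endmember_spectrum("EVOO", "UVVIS")
  for (i in seq_len(nrow(evoo_rows))) {
    expect_equal(unname(evoo_rows[i, ]), unname(e))
  }
  # replicate means converge to the noiseless row (Monte-Carlo)
  dbig <- build_design(n_evoo = 1, n_adulterants = 1, levels = 0.2,
                       replicates = 200)
  dsn <- simulate_dataset(dbig, "UVVIS", noise_sd = 0.01, drift_sd = 0,
                          seed = 3)
  m <- colMeans(dsn$X[dsn$class_label == "EVOO", ])
  se <- 0.01 / sqrt(200)
  expect_lt(sqrt(mean((m - e)^2)), 2 * se)   # RMS deviation ~ one SE
  expect_lt(max(abs(m - e)), 5 * se)
})

test_that("noiseless class separation is perfect for nearest-endmember assignment", {
  ends <- sapply(oil_classes(), endmember_spectrum, modality = "HSI_NIR")
  ds <- small_dataset(small_design(), "HSI_NIR")
  pure <- ds$category != "adulterated"
  nearest <- apply(ds$X[pure, ], 1, function(r)
    oil_classes()[which.min(colSums((ends - r)^2))])
  want <- ifelse(ds$category[pure] == "pure_evoo", "EVOO",
                 ds$adulterant[pure])
  expect_equal(unname(nearest), want)
})

test_that("fatty-acid profiles honour the reference table", {
  # not-detected entries stay exactly zero
  p <- simulate_fa_profile("EVOO", seed = 1)
  expect_identical(unname(p["C18:1 trans-9"]), 0)
  expect_identical(unname(simulate_fa_profile("sunflower", seed = 2)["C18:3"]), 0)
  # degenerate noise returns the reference means exactly
  expect_equal(simulate_fa_profile("canola", sd_scale = 0),
               fa_reference("mean")[, "canola"])
  # Monte-Carlo: mean of oleic over 1000 draws near the reference mean
  set.seed(42)
  draws <- replicate(1000, simulate_fa_profile("EVOO")["C18:1 cis-9"])
  se <- fa_reference("sd")["C18:1 cis-9", "EVOO"] / sqrt(1000)
  expect_lt(abs(mean(draws) - 75.69), 3 * se + 0.05)
})

test_that("hypercubes have the contracted shape and references", {
  s <- endmember_spectrum("EVOO", "UVVIS")[1:20]
  cube <- simulate_hypercube(s, nx = 60, ny = 60)
  expect_equal(dim(cube$data), c(60, 60, 20))
  expect_true(all(cube$white > cube$black))
  expect_error(simulate_hypercube(s, white_level = 5, black_level = 5),
               "white reference")
})

test_that("spectra round-trip through CSV byte-identically", {
  d <- small_design()
  ds <- simulate_dataset(d, "UVVIS", noise_sd = 0.01, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, p1)
  write_spectra(simulate_dataset(d, "UVVIS", noise_sd = 0.01, seed = 5), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_spectra(p1, "UVVIS", design = d)
  expect_equal(unname(back$X), unname(ds$X), tolerance = 1e-12)
  expect_equal(back$class_label, ds$class_label)
})
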