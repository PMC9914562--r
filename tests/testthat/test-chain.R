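test_that("binary collapse counts any adulterated call as adulterated", {
  truth <- c("EVOO", "EVOO+corn", "EVOO+corn", "EVOO", "safflower")
  pred <- c("EVOO", "EVOO+safflower", "EVOO", "EVOO+canola", "corn")
  # pure-adulterant truths are excluded; of the 4 kept:
  # EVOO->EVOO ok; EVOO+corn->EVOO+safflower ok; EVOO+corn->EVOO wrong;
  # EVOO->EVOO+canola wrong
  expect_equal(collapse_to_binary(truth, pred), 50)
  expect_equal(collapse_to_binary(c("EVOO", "EVOO+corn"),
                                  c("EVOO", "EVOO+corn")), 100)
  expect_error(collapse_to_binary("corn", "corn"), "no pure-EVOO")
})

test_that("noiseless mixtures are quantified essentially exactly", {
  # folds small enough that no fold can swallow all mixtures of one
  # adulterant, so every training pool identifies every mixing direction
  d <- build_design(n_evoo = 4, n_adulterants = 3,
                    levels = c(0.05, 0.1, 0.15, 0.2), replicates = 2)
  ds <- small_dataset(d, "HSI_NIR")
  rep1 <- run_chain(ds, d, small_chain_config(folds = 7))
  ov <- rep1$regression[rep1$regression$model == "overall" &
                          rep1$regression$mode == "known_identity", ]
  expect_lt(ov$rmsep, 1e-6)
  expect_gt(ov$r2, 1 - 1e-10)
})

test_that("chain reports are deterministic and internally consistent", {
  d <- small_design()
  ds <- small_dataset(d, "UVVIS", noise_sd = 0.01, drift_sd = 0.01, seed = 3)
  cfg <- small_chain_config(baseline = TRUE, normalize = TRUE)
  r1 <- run_chain(ds, d, cfg)
  r2 <- run_chain(ds, d, cfg)
  expect_identical(r1$regression, r2$regression)
  expect_identical(r1$classification$confusion$counts,
                   r2$classification$confusion$counts)
  # every case classified once per repetition
  cl <- r1$classification
  expect_equal(sum(cl$confusion$counts), nrow(ds$X) * cfg$repetitions)
  expect_equal(cl$total_classified, nrow(ds$X) * cfg$repetitions)
  # confusion row sums = class case counts x repetitions
  cases <- design_cases(d)
  want <- table(cases$class_label)[rownames(cl$confusion$counts)] *
    cfg$repetitions
  expect_equal(unname(rowSums(cl$confusion$counts)), unname(as.numeric(want)))
  # regression pools: every quantifiable case of the blend appears once per
  # repetition and per mode
  pr <- r1$predictions
  n_mix <- sum(cases$category == "adulterated")
  for (md in unique(pr$mode)) {
    sub <- pr[pr$model == "overall" & pr$mode == md, ]
    expect_equal(nrow(sub), n_mix * cfg$repetitions)
    expect_equal(sort(unique(table(sub$case_id))), cfg$repetitions)
  }
})

test_that("misaligned datasets and bad configurations are refused", {
  d <- small_design()
  ds <- small_dataset(d)
  ds2 <- ds
  ds2$case_id <- rev(ds2$case_id)
  expect_error(run_chain(ds2, d, small_chain_config()), "align")
  expect_error(chain_config(modes = "nonsense"))
  expect_error(chain_config(folds = 1), "folds")
})

test_that("classification errors propagate into quantification exactly as routed", {
  d <- small_design(replicates = 3)
  ds <- small_dataset(d, "HSI_NIR", noise_sd = 0.01, drift_sd = 0.01, seed = 6)
  # lv_max_reg = 1 pins every regression to one latent variable, so the two
  # modes differ only through routing
  r <- run_chain(ds, d, small_chain_config(baseline = TRUE, normalize = TRUE,
                                           repetitions = 3, lv_max_reg = 1))
  expect_lt(r$classification$binary_mean, 100)  # misclassifications occur
  cl <- r$classification
  pr <- r$predictions
  for (j in r$adulterants) {
    for (rep_i in seq_along(cl$predicted_labels)) {
      dep <- pr[pr$model == j & pr$mode == "plsda_dependent" & pr$rep == rep_i, ]
      kn <- pr[pr$model == j & pr$mode == "known_identity" & pr$rep == rep_i, ]
      kn <- kn[match(dep$case_id, kn$case_id), ]
      routed_ok <- cl$predicted_labels[[rep_i]][match(dep$case_id, cl$case_id)] ==
        paste0("EVOO+", j)
      # correctly routed cases get the identical prediction in both modes
      expect_equal(dep$predicted[routed_ok], kn$predicted[routed_ok])
      # cases predicted as pure EVOO are forced to zero concentration
      pure_pred <- cl$predicted_labels[[rep_i]][match(dep$case_id, cl$case_id)] ==
        "EVOO"
      expect_true(all(dep$predicted[pure_pred] == 0))
    }
  }
})

test_that("training-set cross-validation metrics are produced on demand", {
  d <- small_design()
  ds <- small_dataset(d, "UVVIS", noise_sd = 0.01, seed = 4)
  r <- run_chain(ds, d, small_chain_config(compute_cv = TRUE,
                                           inner_folds = 3))
  expect_false(is.null(r$cv))
  expect_setequal(r$cv$model, c("overall", adulterant_oils()[1:3]))
  expect_true(all(r$cv$rmsecv > 0))
  expect_true(all(r$cv$n > 0))
})

test_that("chain reports write the tabular exports", {
  d <- small_design()
  ds <- small_dataset(d)
  r <- run_chain(ds, d, small_chain_config())
  dir <- withr::local_tempdir()
  write_chain_report(r, dir)
  expect_true(all(file.exists(file.path(dir, c("confusion.csv", "metrics.csv",
                                               "summary.csv", "report.json")))))
  conf <- utils::read.csv(file.path(dir, "confusion.csv"), check.names = FALSE)
  expect_equal(sum(conf[, -1]), r$classification$total_classified)
  met <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_true(all(c("model", "mode", "lv", "rmsep", "rpd",
                    "fitted_line") %in% names(met)))
})
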