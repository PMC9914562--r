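test_that("partitions are sample-level, even-sized, exhaustive and seeded", {
  d <- build_design()
  ps <- make_partitions(d, folds = 10, repetitions = 10, seed = 9)
  expect_equal(dim(ps$assignment), c(61, 10))
  for (r in 1:10) {
    sizes <- table(ps$assignment[, r])
    expect_length(sizes, 10)
    expect_lte(max(sizes) - min(sizes), 1)   # pigeonhole
    expect_equal(sum(sizes), 61)
  }
  # same seed reproduces; different seed does not
  expect_identical(ps$assignment,
                   make_partitions(d, 10, 10, seed = 9)$assignment)
  expect_false(identical(ps$assignment,
                         make_partitions(d, 10, 10, seed = 10)$assignment))
  # union of test folds covers all 183 cases exactly once per repetition
  cases <- design_cases(d)
  fold_of_case <- ps$assignment[match(cases$sample_id, d$sample_id), 1]
  covered <- unlist(lapply(1:10, function(k) which(fold_of_case == k)))
  expect_equal(sort(unname(covered)), seq_len(183))
  # replicates of one sample always share a fold
  expect_equal(length(unique(tapply(fold_of_case, cases$sample_id, unique))) <=
                 10, TRUE)
  expect_error(make_partitions(small_design(), folds = 99), "folds")
})

test_that("performance curves aggregate repetition values correctly", {
  # identical repetitions have zero SE
  cv <- performance_curve(matrix(5, 4, 3), type = "regression")
  expect_equal(cv$se, rep(0, 3))
  # stated arithmetic: means {90, 92} -> mean 91, SE 1
  cv2 <- performance_curve(matrix(c(90, 92), 2, 1), type = "classification")
  expect_equal(cv2$mean, 91)
  expect_equal(cv2$se, 1)
  # independent recomputation on a random matrix
  set.seed(10)
  m <- matrix(rnorm(50), 10, 5)
  cv3 <- performance_curve(m, type = "regression")
  expect_equal(cv3$mean, unname(colMeans(m)))
  expect_equal(cv3$se, unname(apply(m, 2, sd) / sqrt(10)))
  expect_error(performance_curve(matrix(1, 1, 3)), "2 repetitions")
})

test_that("one-SE selection matches the worked examples", {
  mk <- function(means, ses, type) {
    cv <- performance_curve(matrix(0, 2, length(means)), type = type)
    cv$mean <- means; cv$se <- ses
    cv
  }
  # classification: best 92.5 at LV4; LV3 has 92 + 1 > 92.5, LV2 does not
  expect_equal(select_lv(mk(c(80, 90, 92, 92.5), c(2, 1, 1, 1),
                            "classification")), 3)
  # regression: best 1.75 at LV4; LV3 has 1.8 - 0.1 < 1.75, LV2 does not
  expect_equal(select_lv(mk(c(3, 2, 1.8, 1.75), c(0.2, 0.15, 0.1, 0.1),
                            "regression")), 3)
  # best model already minimal
  expect_equal(select_lv(mk(c(95, 90, 85), c(1, 1, 1), "classification")), 1)
  # all means equal with positive SE: parsimony wins
  expect_equal(select_lv(mk(rep(88, 5), rep(2, 5), "classification")), 1)
  # strictly decreasing RMSEP with zero SE: no slack, best (last) model
  expect_equal(select_lv(mk(c(3, 2.5, 2), c(0, 0, 0), "regression")), 3)
  # single-LV curve
  expect_equal(select_lv(mk(2, 0.1, "regression")), 1)
  # type guards
  expect_error(select_lv_regression(mk(c(1, 2), c(0, 0), "classification")),
               "built for")
  expect_error(select_lv_classification(mk(c(1, 2), c(0, 0), "regression")),
               "built for")
})

test_that("one-SE selection agrees with brute-force search on random curves", {
  set.seed(11)
  for (i in 1:200) {
    k <- sample(2:12, 1)
    means <- runif(k, 50, 100)
    ses <- runif(k, 0, 5)
    cls <- performance_curve(matrix(0, 2, k), type = "classification")
    cls$mean <- means; cls$se <- ses
    expect_equal(select_lv(cls), brute_force_one_se(means, ses, TRUE))
    reg <- performance_curve(matrix(0, 2, k), type = "regression")
    rm_ <- runif(k, 0.5, 5)
    reg$mean <- rm_; reg$se <- ses / 10
    expect_equal(select_lv(reg), brute_force_one_se(rm_, ses / 10, FALSE))
  }
})

test_that("selection is invariant to monotone rescaling of the units", {
  cv <- performance_curve(matrix(runif(40, 60, 95), 5, 8),
                          type = "classification")
  cv_frac <- cv
  cv_frac$mean <- cv$mean / 100
  cv_frac$se <- cv$se / 100
  expect_equal(select_lv(cv), select_lv(cv_frac))
})

test_that("partition schemes serialize to JSON", {
  ps <- make_partitions(small_design(), folds = 3, repetitions = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_partitions(ps, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 4)
  expect_equal(back$folds, 3)
  expect_equal(unname(as.matrix(back$assignment)),
               unname(ps$assignment))
})
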