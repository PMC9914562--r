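test_that("a single predictive column is fitted exactly with one latent variable", {
  set.seed(1)
  y <- rnorm(15)
  X <- matrix(y, ncol = 1)
  fit <- nipals_pls(X, y, ncomp = 1)
  expect_equal(as.numeric(predict(fit, X)), y, tolerance = 1e-10)
  # training-mean row predicts the training mean of y
  expect_equal(as.numeric(predict(fit, matrix(mean(y), 1, 1))), mean(y),
               tolerance = 1e-10)
})

test_that("full-rank NIPALS reproduces the least-squares solution", {
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(rnorm(200), 20, 10)
    beta <- runif(10)
    y <- as.numeric(X %*% beta)            # noiseless linear response
    fit <- nipals_pls(X, y, ncomp = 10)
    expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-6)
    # noisy response: full-rank PLS equals OLS fitted values
    y2 <- y + rnorm(20, sd = 0.3)
    fit2 <- nipals_pls(X, y2, ncomp = 10)
    ols <- stats::lm.fit(cbind(1, X), y2)
    expect_equal(as.numeric(predict(fit2, X)), unname(ols$fitted.values),
                 tolerance = 1e-8)
  }
})

test_that("degenerate inputs behave as documented", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  expect_warning(fit <- nipals_pls(X, rep(2, 20), ncomp = 2), "no variance")
  expect_equal(max(abs(coef(fit))), 0)
  expect_equal(as.numeric(predict(fit, X)), rep(2, 20))
  expect_error(nipals_pls(X, rnorm(20), ncomp = 5), "rank bound")
  # constant X column gets zero weight
  Xc <- cbind(X, 7)
  f2 <- nipals_pls(Xc, rnorm(20), ncomp = 2)
  expect_equal(max(abs(f2$weights[4, ])), 0)
  expect_error(predict(f2, X), "variables")
})

test_that("scores are orthogonal and coefficient/score predictions agree", {
  set.seed(4)
  for (rep in 1:10) {
    n <- sample(10:30, 1); p <- sample(5:15, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * 2), n, 2)
    a <- min(5, n - 1, p)
    fit <- nipals_pls(X, Y, ncomp = a)
    G <- crossprod(fit$scores)
    offdiag <- max(abs(G[upper.tri(G)]))
    expect_lt(offdiag, 1e-8 * max(diag(G)))
    # predictions via coefficients match predictions via scores
    Xnew <- matrix(rnorm(4 * p), 4, p)
    via_coef <- sweep(Xnew %*% coef(fit), 2,
                      as.numeric(fit$y_mean - crossprod(coef(fit), fit$x_mean)),
                      "+")
    expect_equal(unname(predict(fit, Xnew)), unname(via_coef),
                 tolerance = 1e-8)
  }
})

test_that("row permutation permutes predictions identically", {
  set.seed(5)
  X <- matrix(rnorm(100), 20, 5); y <- rnorm(20)
  fit <- nipals_pls(X, y, ncomp = 3)
  Xn <- matrix(rnorm(40), 8, 5)
  perm <- sample(8)
  expect_equal(predict(fit, Xn[perm, ]), predict(fit, Xn)[perm, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("PLS-DA separates well-separated Gaussian classes like nearest-centroid", {
  set.seed(6)
  mu <- 10   # ten sigma apart
  X <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, mean = mu), 30, 2))
  lab <- rep(c("one", "two"), each = 30)
  fit <- nipals_plsda(X, lab, ncomp = 1)
  pred <- predict(fit, X)
  expect_equal(pred, lab)
  cent <- rbind(colMeans(X[1:30, ]), colMeans(X[31:60, ]))
  nc <- c("one", "two")[apply(X, 1, function(r)
    which.min(rowSums(sweep(cent, 2, r)^2)))]
  expect_equal(pred, nc)
  # held-out cases too
  Xt <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, mean = mu), 10, 2))
  expect_equal(predict(fit, Xt), rep(c("one", "two"), each = 10))
})

test_that("classification depends on class indices, not their names", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, mean = 6), 20, 2))
  lab1 <- rep(c("alpha", "beta"), each = 20)
  lab2 <- rep(c("Z9", "A1"), each = 20)   # same partition, other strings
  p1 <- predict(nipals_plsda(X, lab1, ncomp = 2), X)
  p2 <- predict(nipals_plsda(X, lab2, ncomp = 2), X)
  expect_equal(p1 == "alpha", p2 == "Z9")
  expect_error(nipals_plsda(X, rep("only", 40), ncomp = 1), "two classes")
  expect_error(nipals_plsda(X, lab1, ncomp = 0), "at least one")
})

test_that("argmax assignment breaks exact ties toward the lowest class index", {
  # handcrafted model whose indicator predictions are (0.5, 0.5) everywhere
  obj <- structure(list(ncomp = 1, projection = matrix(0, 1, 1),
                        y_loadings = matrix(c(0, 0), 2, 1),
                        x_mean = 0, x_scale = 1, y_mean = c(0.5, 0.5),
                        y_names = c("first", "second"),
                        levels = c("first", "second")),
                   class = c("nipals_plsda", "nipals_pls"))
  expect_equal(predict(obj, matrix(c(1, 2), 2, 1)), c("first", "first"))
  resp <- predict(obj, matrix(1, 1, 1), type = "response")
  expect_equal(as.numeric(resp), c(0.5, 0.5))
})

test_that("PCA explained-variance fractions behave as contracted", {
  set.seed(8)
  v <- rnorm(6)
  X1 <- outer(rnorm(12), v)               # rank one
  p1 <- spectral_pca(X1, 1)
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)
  X <- matrix(rnorm(120), 20, 6)
  pf <- spectral_pca(X, 6)
  expect_equal(sum(pf$explained), 1, tolerance = 1e-10)
  expect_true(all(diff(pf$explained) <= 1e-12))
  # isotropic data spread variance evenly
  Xi <- matrix(rnorm(2500), 500, 5)
  pi_ <- spectral_pca(Xi, 5)
  expect_true(all(abs(pi_$explained - 0.2) < 0.05))
  expect_error(spectral_pca(X, 10), "k must lie")
})
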