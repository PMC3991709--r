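test_that("PCNM axes are orthonormal and reproduce untruncated configurations", {
  # four quadrat centres at the corners of an s-sided square: all pairwise
  # distances are within the truncation, so PCoA must reproduce them
  s <- 10
  cent <- rbind(c(0, 0), c(s, 0), c(0, s), c(s, s))
  b <- pcnm_basis(cent, s)
  expect_equal(crossprod(b$vectors), diag(ncol(b$vectors)),
               ignore_attr = TRUE, tolerance = 1e-10)
  X <- b$vectors %*% diag(sqrt(b$values), ncol(b$vectors))
  expect_equal(as.matrix(dist(X)), as.matrix(dist(cent)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("PCNM agrees with the vegan implementation on a regular grid", {
  skip_if_not_installed("vegan")
  g <- quadrat_grid(c(50, 50), 10)
  cent <- as.matrix(g$quadrats[, c("cx", "cy")])
  b <- pcnm_basis(cent, 10)
  v <- vegan::pcnm(dist(cent), threshold = 10 * sqrt(2) * (1 + 1e-8))
  # same number of positive axes and same eigenvalues
  expect_equal(ncol(b$vectors), ncol(v$vectors))
  expect_equal(b$values, unname(v$values[v$values > max(v$values) * 1e-8]),
               tolerance = 1e-6)
  # same column space: each axis correlates +/-1 with a vegan axis of the
  # same eigenvalue (compare via projection because of eigenvalue ties)
  Q <- qr.Q(qr(v$vectors))
  proj <- crossprod(Q, b$vectors)
  expect_equal(colSums(proj^2), rep(1, ncol(b$vectors)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PCNM basis is invariant to rigid translation", {
  set.seed(83)
  cent <- cbind(runif(30, 0, 100), runif(30, 0, 50))
  b1 <- pcnm_basis(cent, 10)
  b2 <- pcnm_basis(cent + 1000, 10)
  expect_equal(b1$values, b2$values, tolerance = 1e-8)
  expect_equal(abs(diag(crossprod(b1$vectors, b2$vectors))),
               rep(1, ncol(b1$vectors)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("cubic detrending removes exactly a cubic surface", {
  set.seed(89)
  cent <- cbind(runif(60, 0, 10), runif(60, 0, 10))
  x <- cent[, 1]; y <- cent[, 2]
  vals <- 2 + x - 0.5 * y + 0.1 * x * y - 0.02 * x^3 + 0.3 * y^2
  r <- detrend_poly3(vals, cent)
  expect_lt(max(abs(r)), 1e-8)
  # residuals orthogonal to the basis
  vals2 <- vals + rnorm(60)
  r2 <- detrend_poly3(vals2, cent)
  P <- stats::poly(cent, degree = 3)
  expect_lt(max(abs(crossprod(cbind(1, P), r2))), 1e-8)
  expect_error(detrend_poly3(vals[1:8], cent[1:8, ]), "n > 10")
})

test_that("forward selection finds a planted axis and obeys alpha", {
  set.seed(97)
  g <- quadrat_grid(c(100, 50), 10)
  cent <- as.matrix(g$quadrats[, c("cx", "cy")])
  b <- pcnm_basis(cent, 10)
  y <- 3 * b$vectors[, 5] + rnorm(50, 0, 0.3)
  sel <- forward_select(y, b, n_perm = 199, seed = 1)
  expect_equal(sel[1], 5)
  expect_length(forward_select(y, b, alpha = 0, n_perm = 99, seed = 1), 0)
})

test_that("variation partitioning satisfies its algebraic identities", {
  set.seed(101)
  n <- 80
  E <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  x <- rnorm(n)
  y <- x + E %*% c(1, -1, 0.5, 0) + rnorm(n)
  vp <- variation_partition(y, x, E)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-10)
  # [a+b] equals the adjusted R2 of the NRI-only fit, recomputed here
  f <- lm(y ~ x)
  r2a <- 1 - (1 - summary(f)$r.squared) * (n - 1) / (n - 2)
  expect_equal(vp$ab, r2a, tolerance = 1e-12)
  # x collinear with the single spatial axis: all joint, nothing unique
  # noise small relative to the unit-norm axis (variance 1/n)
  y2 <- E[, 1] + rnorm(n, 0, 0.01)
  vp2 <- variation_partition(y2, E[, 1], E[, 1, drop = FALSE])
  expect_lt(abs(vp2$fractions["a"]), 0.02)
  expect_lt(abs(vp2$fractions["c"]), 0.02)
  expect_gt(vp2$fractions["b"], 0.8)
  # no axes selected: everything loads on the predictor side
  vp0 <- variation_partition(y, x, NULL)
  expect_equal(unname(vp0$fractions["c"]), 0)
  expect_equal(vp0$ab, vp0$r2a[["both"]])
})
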