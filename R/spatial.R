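#' Contiguity weights for quadrats on a lattice
#'
#' First-order neighbour weights among (a subset of) the grid's quadrats.
#' Rook contiguity links cells whose centres are exactly one cell side
#' apart — the natural reading of a one-grid-cell lag, since diagonal
#' centres sit at `s * sqrt(2)`; queen contiguity adds the diagonals.
#' Weights are row-standardized by default (each non-isolated row sums
#' to 1).  Isolated quadrats are retained with an empty neighbour set; they
#' are dropped (with a warning) by [morans_i()] and [sar_error_fit()].
#'
#' @param grid a [quadrat_grid()].
#' @param quadrats integer ids of the quadrats to include (default: all).
#' @param scheme `"rook"` or `"queen"`.
#' @param row_standardize logical.
#' @return object of class `lattice_weights` with the sparse weight matrix
#'   `W` (rows/cols ordered as `quadrats`), the binary adjacency `A`, ids,
#'   and an `isolated` flag per quadrat.
#' @export
lattice_weights <- function(grid, quadrats = NULL,
                            scheme = c("rook", "queen"),
                            row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(grid, "quadrat_grid"))
  if (is.null(quadrats)) quadrats <- grid$quadrats$quadrat
  if (length(quadrats) < 2) stop("need at least 2 quadrats")
  qq <- grid$quadrats[match(quadrats, grid$quadrats$quadrat), , drop = FALSE]
  if (anyNA(qq$quadrat)) stop("unknown quadrat id(s)")
  n <- nrow(qq)
  key <- qq$col + qq$row * grid$nx
  lookup <- stats::setNames(seq_len(n), key)
  offs <- if (scheme == "rook") list(c(1, 0), c(0, 1))
          else list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  ii <- integer(0); jj <- integer(0)
  for (off in offs) {
    nb_key <- (qq$col + off[1]) + (qq$row + off[2]) * grid$nx
    valid <- qq$col + off[1] >= 0 & qq$col + off[1] < grid$nx &
             qq$row + off[2] >= 0 & qq$row + off[2] < grid$ny
    j <- lookup[as.character(nb_key)]
    ok <- valid & !is.na(j)
    ii <- c(ii, which(ok), j[ok])
    jj <- c(jj, j[ok], which(ok))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  isolated <- deg == 0
  W <- if (row_standardize) {
    Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0)) %*% A
  } else A
  structure(list(W = W, A = A, ids = qq$quadrat, isolated = isolated,
                 scheme = scheme, row_standardized = row_standardize),
            class = "lattice_weights")
}

# pull the (isolated-free) weight matrix and keep mask out of a
# lattice_weights or plain matrix
.weights_matrix <- function(weights) {
  if (inherits(weights, "lattice_weights")) {
    keep <- !weights$isolated
    if (any(weights$isolated))
      warning(sum(weights$isolated), " isolated quadrat(s) dropped")
    list(W = weights$W[keep, keep, drop = FALSE], keep = keep)
  } else {
    list(W = Matrix::Matrix(weights, sparse = TRUE),
         keep = rep(TRUE, nrow(weights)))
  }
}

#' Moran's I with a permutation test
#'
#' `I = (n/S0) * (z' W z) / (z' z)` with `z` the centred values and `S0`
#' the total weight.  Significance by random permutation of the values over
#' quadrats; the two-sided p-value uses rank position with the add-one
#' rule.
#'
#' @param values numeric vector aligned with the weights.
#' @param weights a [lattice_weights()] or numeric matrix.
#' @param n_perm permutations (default 999).
#' @param seed optional seed.
#' @return list of class `moran_result`: `I`, `p`, `expectation`
#'   (`-1/(n-1)`), `n_perm`.
#' @export
morans_i <- function(values, weights, n_perm = 999, seed = NULL) {
  wm <- .weights_matrix(weights)
  z <- values[wm$keep]
  if (anyNA(z)) stop("values contain NA")
  if (stats::var(z) == 0) stop("values have zero variance")
  .set_seed_if(seed)
  W <- wm$W
  n <- length(z)
  z <- z - mean(z)
  s0 <- sum(W)
  denom <- sum(z^2)
  i_obs <- (n / s0) * as.numeric(z %*% (W %*% z)) / denom
  Z <- vapply(seq_len(n_perm), function(i) z[sample.int(n)],
              numeric(n))
  num <- Matrix::colSums(Z * (W %*% Z))
  i_perm <- (n / s0) * num / denom
  p_hi <- (1 + sum(i_perm >= i_obs)) / (n_perm + 1)
  p_lo <- (1 + sum(i_perm <= i_obs)) / (n_perm + 1)
  structure(list(I = i_obs, p = min(1, 2 * min(p_hi, p_lo)),
                 expectation = -1 / (n - 1), n_perm = n_perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g [%d perms]\n",
              x$I, x$expectation, x$p, x$n_perm))
  invisible(x)
}

#' Simultaneous autoregressive error model by maximum likelihood
#'
#' Fits `y = X b + u`, `u = lambda W u + e`, `e ~ iid N(0, sigma^2)`.  The
#' log-likelihood is concentrated over `lambda` (profiling out `b` and
#' `sigma^2`), with the Jacobian term `log|I - lambda W|` computed from the
#' eigenvalues of `W`; the scalar search uses [stats::optimize()] at
#' tolerance 1e-8 inside the eigenvalue-bounded interval.  Coefficient
#' covariance is the GLS expression at the estimated `lambda`, and
#' p-values are asymptotic z-tests.  Residuals are the innovations
#' `e = (I - lambda W)(y - X b)`.
#'
#' @param y response (e.g. ses.RaoD per quadrat).
#' @param X design matrix *without* intercept column (an intercept is
#'   added), e.g. a one-column matrix of NRI values; or a numeric vector.
#' @param weights a [lattice_weights()] or matrix, row-standardized.
#' @return object of class `sar_fit`: `coefficients` table (estimate, se,
#'   z, p), `lambda`, `loglik`, `residuals`, `fitted`, `n`, `loglik_ols`.
#' @export
sar_error_fit <- function(y, X, weights) {
  wm <- .weights_matrix(weights)
  if (is.null(dim(X))) X <- cbind(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- y[wm$keep]; X <- X[wm$keep, , drop = FALSE]
  if (anyNA(y) || anyNA(X)) stop("NA in y or X; drop flagged quadrats first")
  X <- cbind(`(Intercept)` = 1, X)
  n <- length(y)
  if (qr(X)$rank < ncol(X)) stop("collinear design matrix")
  W <- as.matrix(wm$W)
  ev <- eigen(W, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8)
    ev <- ev[abs(Im(ev)) < 1e-8]
  ev <- Re(ev)
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6

  Wy <- W %*% y; WX <- W %*% X
  conc_ll <- function(lambda) {
    ys <- y - lambda * Wy
    Xs <- X - lambda * WX
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    sum(log(1 - lambda * ev)) - (n / 2) * log(rss / n)
  }
  opt <- stats::optimize(conc_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  lambda <- opt$maximum
  if (min(lambda - lo, hi - lambda) < 1e-4)
    warning("lambda estimate at the edge of the parameter space")
  ys <- y - lambda * Wy
  Xs <- X - lambda * WX
  fit <- stats::lm.fit(Xs, ys)
  beta <- fit$coefficients
  resid <- fit$residuals                 # innovations e
  sigma2 <- sum(resid^2) / n
  XtX <- crossprod(Xs)
  vcov_beta <- sigma2 * solve(XtX)
  se <- sqrt(diag(vcov_beta))
  zstat <- beta / se
  pval <- 2 * stats::pnorm(-abs(zstat))
  ll <- -(n / 2) * (log(2 * pi * sigma2) + 1) + sum(log(1 - lambda * ev))
  ll_ols <- conc_ll(0) - (n / 2) * (log(2 * pi) + 1)

  coefs <- data.frame(estimate = beta, se = se, z = zstat, p = pval)
  structure(list(coefficients = coefs, lambda = lambda, loglik = ll,
                 loglik_ols = ll_ols, sigma2 = sigma2,
                 residuals = as.numeric(resid),
                 fitted = as.numeric(X %*% beta), n = n,
                 vcov = vcov_beta),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR error model (ML): n = %d, lambda = %.4f, logLik = %.2f\n",
              x$n, x$lambda, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}
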