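#' PCNM spatial eigenfunctions for quadrat centroids
#'
#' Principal coordinates of neighbour matrices: the pairwise Euclidean
#' distance matrix among quadrat centroids is truncated at `t = s*sqrt(2)`
#' (the distance between centres of diagonally adjacent quadrats); larger
#' distances are replaced by `4t`, the standard PCNM convention.  Principal
#' coordinate analysis (Gower double-centring and eigendecomposition) of
#' the modified matrix yields orthonormal eigenvectors; only
#' positive-eigenvalue axes are returned, ordered by eigenvalue.  A
#' `"literal"` truncation option multiplies each large distance by 4
#' instead, for sensitivity analysis.
#'
#' @param centroids two-column matrix/data.frame of quadrat centre
#'   coordinates.
#' @param s quadrat side (m), sets the truncation distance.
#' @param truncation `"4t"` (replace by four times the truncation
#'   distance) or `"literal"` (four times each distance).
#' @return object of class `pcnm_basis`: `vectors` (quadrats x axes,
#'   orthonormal), `values`, `threshold`.
#' @export
pcnm_basis <- function(centroids, s, truncation = c("4t", "literal")) {
  truncation <- match.arg(truncation)
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  if (n < 3) stop("need at least 3 quadrats for PCNM")
  d <- as.matrix(stats::dist(centroids))
  t_trunc <- s * sqrt(2) * (1 + 1e-8)
  big <- d > t_trunc
  d[big] <- if (truncation == "4t") 4 * t_trunc else 4 * d[big]
  # Gower double-centring of -d^2/2
  A <- -0.5 * d^2
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rm_, "+") + gm
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eg$values > max(abs(eg$values)) * 1e-8
  vec <- eg$vectors[, pos, drop = FALSE]
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  structure(list(vectors = vec, values = eg$values[pos],
                 threshold = s * sqrt(2), truncation = truncation, n = n),
            class = "pcnm_basis")
}

#' Remove a cubic spatial trend
#'
#' Least-squares fit of the values on a third-degree orthogonal polynomial
#' basis in the centroid coordinates (all monomials `x^p y^q` with
#' `1 <= p+q <= 3`, plus intercept); returns the residuals.  Detrending
#' before eigenfunction selection keeps broad-scale trends out of the
#' spatial fractions.
#'
#' @param values response vector.
#' @param centroids two-column coordinates aligned with `values`.
#' @return residual vector.
#' @export
detrend_poly3 <- function(values, centroids) {
  centroids <- as.matrix(centroids)
  n <- length(values)
  stopifnot(nrow(centroids) == n)
  if (n <= 10) stop("need n > 10 for cubic detrending")
  P <- tryCatch(stats::poly(centroids, degree = 3),
                error = function(e) stop("rank-deficient polynomial basis: ",
                                         conditionMessage(e)))
  fit <- stats::lm.fit(cbind(1, P), values)
  as.numeric(fit$residuals)
}

#' Forward selection of PCNM axes
#'
#' Adds, at each step, the axis giving the largest R-squared increase, and
#' keeps it only if its permutation p-value is at most `alpha`; stops at
#' the first non-significant candidate.  The permutation test is
#' Freedman-Lane style: residuals of the current (reduced) model are
#' permuted and added back to its fitted values before recomputing the
#' candidate's R-squared increase, giving a valid partial test within the
#' sequential procedure.
#'
#' @param y response (typically detrended ses.RaoD).
#' @param basis a [pcnm_basis()].
#' @param alpha significance level for the stopping rule (default 0.05).
#' @param n_perm permutations per step (default 999).
#' @param seed optional seed.
#' @return integer vector of selected axis indices (possibly empty), with
#'   attribute `p_values`.
#' @export
forward_select <- function(y, basis, alpha = 0.05, n_perm = 999,
                           seed = NULL) {
  stopifnot(inherits(basis, "pcnm_basis"))
  .set_seed_if(seed)
  E <- basis$vectors
  n <- length(y)
  stopifnot(nrow(E) == n)
  selected <- integer(0)
  pvals <- numeric(0)
  fit_cur <- rep(mean(y), n)
  r_cur <- y - fit_cur
  candidates <- seq_len(ncol(E))
  while (length(candidates) && length(selected) < n - 2) {
    # axes are orthonormal and centred, so the R2 increase of axis e given
    # the current model is (e' r)^2 / SS_tot
    sc <- as.numeric(crossprod(E[, candidates, drop = FALSE], r_cur))^2
    best <- candidates[which.max(sc)]
    e <- E[, best]
    sst <- sum((y - mean(y))^2)
    stat_obs <- sc[which.max(sc)] / sst
    stat_perm <- vapply(seq_len(n_perm), function(i) {
      rp <- r_cur[sample.int(n)]
      yp <- fit_cur + rp
      sum(e * yp)^2 / sum((yp - mean(yp))^2)
    }, numeric(1))
    p <- (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)
    if (p > alpha) break
    selected <- c(selected, best)
    pvals <- c(pvals, p)
    fit_cur <- fit_cur + e * sum(e * r_cur)
    r_cur <- y - fit_cur
    candidates <- setdiff(candidates, best)
  }
  attr(selected, "p_values") <- pvals
  selected
}

#' Variation partitioning of turnover into relatedness and space
#'
#' Partitions the variance of `y` (detrended ses.RaoD) into the fraction
#' explained only by phylogenetic similarity (`a`), jointly (`b`), only by
#' the selected spatial eigenfunctions (`c`), and residual (`d`), using
#' adjusted R-squared: with `R2a(.)` the adjusted R-squared of a linear
#' fit, `a = R2a(both) - R2a(space)`, `c = R2a(both) - R2a(nri)`,
#' `a + b = R2a(nri)`, and `a+b+c+d = 1` by construction.  Adjusted
#' fractions can be slightly negative.
#'
#' @param y response vector.
#' @param x_nri NRI values (vector or one-column matrix).
#' @param pcnm_axes matrix of selected PCNM axes (possibly zero columns).
#' @return object of class `varpart_result`: `fractions` (a, b, c,
#'   residual), `ab`, the three adjusted R-squared values, `n`.
#' @export
variation_partition <- function(y, x_nri, pcnm_axes) {
  n <- length(y)
  x_nri <- as.matrix(x_nri)
  if (is.null(pcnm_axes)) pcnm_axes <- matrix(numeric(0), n, 0)
  pcnm_axes <- as.matrix(pcnm_axes)
  stopifnot(nrow(x_nri) == n, nrow(pcnm_axes) == n)
  p_both <- ncol(x_nri) + ncol(pcnm_axes)
  if (n - p_both - 1 <= 0) stop("too few observations for the full model")
  r2a <- function(X) {
    if (ncol(X) == 0) return(0)
    fit <- stats::lm.fit(cbind(1, X), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    1 - (1 - r2) * (n - 1) / (n - ncol(X) - 1)
  }
  ab <- r2a(x_nri)
  bc <- r2a(pcnm_axes)
  abc <- r2a(cbind(x_nri, pcnm_axes))
  a <- abc - bc
  c_ <- abc - ab
  b <- ab - a
  d <- 1 - abc
  structure(list(fractions = c(a = a, b = b, c = c_, residual = d),
                 ab = ab, r2a = c(nri = ab, pcnm = bc, both = abc),
                 n = n, n_pcnm = ncol(pcnm_axes)),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("variation partitioning (n = %d, %d PCNM axes)\n",
              x$n, x$n_pcnm))
  f <- x$fractions
  cat(sprintf("  [a] pure NRI      %7.4f\n  [b] shared        %7.4f\n",
              f["a"], f["b"]))
  cat(sprintf("  [c] pure spatial  %7.4f\n  [d] residual      %7.4f\n",
              f["c"], f["residual"]))
  cat(sprintf("  [a+b] total NRI   %7.4f\n", x$ab))
  invisible(x)
}
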