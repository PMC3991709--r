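#' Mean pairwise phylogenetic distance of a presence vector
#'
#' Unweighted mean of `d_ij` over all unordered pairs of species present.
#'
#' @param presence logical or 0/1 vector (or quadrat-by-species matrix)
#'   aligned with `D`.
#' @param D patristic distance matrix.
#' @return scalar (or vector for matrix input); `NA` where richness < 2.
#' @export
mpd_presence <- function(presence, D) {
  if (is.null(dim(presence))) {
    p <- as.numeric(presence > 0)
    k <- sum(p)
    if (k < 2) return(NA_real_)
    return(as.numeric(p %*% D %*% p) / (k * (k - 1)))
  }
  P <- (presence > 0) * 1
  k <- rowSums(P)
  total <- rowSums((P %*% D) * P)   # sums d_ij over ordered present pairs
  ifelse(k >= 2, total / (k * (k - 1)), NA_real_)
}

#' Independent-swap randomization of a binary matrix
#'
#' Runs a chain of 2x2 checkerboard swaps (`[[1,0],[0,1]] <-> [[0,1],[1,0]]`)
#' over the presence matrix.  Row sums (quadrat richness) and column sums
#' (species occurrence frequency) are preserved exactly.  The chain is
#' driven by *trial* swaps: a candidate row pair and column pair is drawn
#' uniformly each step and flipped only if it forms a checkerboard.
#' Counting trials keeps the proposal symmetric, so the long-run
#' distribution is uniform over all matrices with the observed margins
#' (a chain counting only successful flips would oversample matrices with
#' many checkerboards).
#'
#' @param m binary matrix (quadrats x species).
#' @param n_trials trial swaps to attempt; the default, `10 * length(m)`,
#'   is a generous burn-in for matrices of the sizes gridded plots produce.
#' @return randomized matrix with attribute `successes` (realized flips).
#'   A matrix with no checkerboard unit is returned unchanged with a
#'   warning.
#' @export
independent_swap <- function(m, n_trials = 10 * length(m)) {
  stopifnot(is.matrix(m), all(m %in% c(0, 1)))
  storage.mode(m) <- "integer"
  out <- swap_chain_cpp(m, as.integer(n_trials))
  if (attr(out, "successes") == 0L && .has_checkerboard(out))
    warning("no successful swaps in ", n_trials, " trials")
  if (attr(out, "successes") == 0L && !.has_checkerboard(out))
    warning("matrix has no checkerboard unit; returned unchanged")
  dimnames(out) <- dimnames(m)
  out
}

# any 2x2 checkerboard submatrix? (cheap exact scan via column pair counts)
.has_checkerboard <- function(m) {
  nc <- ncol(m)
  if (nc < 2 || nrow(m) < 2) return(FALSE)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      a <- m[, i] == 1 & m[, j] == 0
      b <- m[, i] == 0 & m[, j] == 1
      if (any(a) && any(b)) return(TRUE)
    }
  }
  FALSE
}

#' Net relatedness index per quadrat
#'
#' `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)`, with null MPDs from
#' independent-swap randomizations of the quadrat-by-species presence
#' matrix.  Each of the `n_rand` null matrices is an independent chain
#' started from the observed matrix.  Positive NRI means co-occurring
#' species are phylogenetically closer than expected (clustering).  MPD is
#' presence-based (unweighted), matching the independent-swap null, which
#' preserves occurrences rather than abundances.
#'
#' @param comm abundance or presence matrix (quadrats x species), columns
#'   aligned with `D`.
#' @param D patristic distance matrix.
#' @param n_rand number of null matrices (default 499).
#' @param n_trials trial swaps per null chain (default `10 * length(m)`).
#' @param seed master seed; null chain `r` uses a derived substream.
#' @return data.frame of class `nri_result`: quadrat, richness, `mpd_obs`,
#'   `null_mean`, `null_sd`, `nri`, `flag` (`ok`, `low_richness`,
#'   `degenerate_null`).
#' @export
nri <- function(comm, D, n_rand = 499, n_trials = NULL, seed = 1) {
  stopifnot(ncol(comm) == nrow(D))
  pres <- (comm > 0) * 1L
  if (is.null(n_trials)) n_trials <- 10L * length(pres)
  k <- rowSums(pres)
  mpd_obs <- mpd_presence(pres, D)
  nulls <- matrix(NA_real_, n_rand, nrow(pres))
  for (r in seq_len(n_rand)) {
    set.seed(.substream_seed(seed, r))
    pr <- swap_chain_cpp(pres, as.integer(n_trials))
    nulls[r, ] <- mpd_presence(pr, D)
  }
  null_mean <- colMeans(nulls)
  null_sd <- apply(nulls, 2, stats::sd)
  flag <- rep("ok", nrow(pres))
  flag[k < 2] <- "low_richness"
  degenerate <- k >= 2 & (is.na(null_sd) | null_sd < 1e-12)
  flag[degenerate] <- "degenerate_null"
  nri_v <- ifelse(flag == "ok", -(mpd_obs - null_mean) / null_sd, NA_real_)
  out <- data.frame(quadrat = seq_len(nrow(pres)),
                    richness = k,
                    mpd_obs = mpd_obs,
                    null_mean = ifelse(k >= 2, null_mean, NA_real_),
                    null_sd = ifelse(k >= 2, null_sd, NA_real_),
                    nri = nri_v,
                    flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("nri_result", "data.frame")
  out
}
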