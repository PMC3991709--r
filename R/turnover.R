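#' Rao quadratic-entropy turnover between two censuses of a quadrat
#'
#' Expected phylogenetic distance between one individual drawn from the
#' quadrat at time A and one drawn at time B:
#' `sum_i sum_j pA_i * pB_j * d_ij`.  Conspecific pairs contribute zero
#' (`d_ii = 0`), so identical monocultures give 0 and the value never
#' exceeds the largest pairwise distance.  The statistic is symmetric in
#' time because `D` is symmetric.
#'
#' @param pA,pB relative-abundance vectors over the same species index
#'   (each sums to 1).
#' @param D patristic distance matrix aligned with the vectors.
#' @param normalized subtract the mean within-census Rao diversity
#'   (`(pA'D pA + pB'D pB)/2`) from the cross term.  Off by default: the
#'   plain cross-expectation is the turnover statistic.
#' @return non-negative scalar (the normalized variant can be negative).
#' @export
rao_turnover <- function(pA, pB, D, normalized = FALSE) {
  stopifnot(length(pA) == nrow(D), length(pB) == nrow(D))
  if (sum(pA) == 0 || sum(pB) == 0)
    stop("empty quadrat at one census: RaoD undefined")
  if (abs(sum(pA) - 1) > 1e-8 || abs(sum(pB) - 1) > 1e-8)
    stop("relative abundances must each sum to 1")
  cross <- as.numeric(pA %*% D %*% pB)
  if (!normalized) return(cross)
  cross - 0.5 * (as.numeric(pA %*% D %*% pA) + as.numeric(pB %*% D %*% pB))
}

#' Standardized effect size against a null ensemble
#'
#' `(obs - mean(nulls)) / sd(nulls)` with the usual n-1 denominator in the
#' standard deviation.
#'
#' @param obs observed value.
#' @param nulls numeric vector of null values (>= 2 finite).
#' @return scalar, or `NA` with attribute `flag = "degenerate_null"` when
#'   the null standard deviation is zero.
#' @export
ses_value <- function(obs, nulls) {
  nulls <- nulls[is.finite(nulls)]
  if (length(nulls) < 2) stop("need at least 2 finite null values")
  s <- stats::sd(nulls)
  if (s == 0) {
    out <- NA_real_
    attr(out, "flag") <- "degenerate_null"
    return(out)
  }
  (obs - mean(nulls)) / s
}

#' Temporal phylogenetic turnover analysis over a quadrat grid
#'
#' For every quadrat occupied at both censuses, computes the observed Rao
#' turnover between the two censuses and its standardized effect size
#' (ses.RaoD) against `n_rep` replicate censuses from the chosen null
#' model.  Under NM-I each replicate applies one species-name permutation
#' to both censuses; under NM-II each replicate keeps the observed first
#' census and re-simulates the second via [nm2_replicate()].  Replicate
#' `r` draws from a substream derived from `seed` and `r`, so results are
#' reproducible and independent of evaluation order.
#'
#' @param pair a [census_pair()].
#' @param tree phylogeny covering the species pool.
#' @param grid a [quadrat_grid()].
#' @param null_model `"nm1"` or `"nm2"` (overrides `config$kind`).
#' @param n_rep replicates (default 499).
#' @param seed master seed for the null ensemble.
#' @param species_table required for NM-II (growth forms).
#' @param config a [null_model_config()].
#' @param prune_missing drop stems of species absent from the tree instead
#'   of erroring.
#' @return data.frame of class `turnover_result`: quadrat id and centroid,
#'   scale, `raod_obs`, `null_mean`, `null_sd`, `ses_raod`, `n_null`,
#'   `flag` (`ok`, `empty_at_A`, `empty_at_B`, `degenerate_null`).
#' @export
turnover_analysis <- function(pair, tree, grid,
                              null_model = c("nm2", "nm1"),
                              n_rep = 499, seed = 1,
                              species_table = NULL,
                              config = NULL,
                              prune_missing = FALSE) {
  null_model <- match.arg(null_model)
  if (is.null(config)) config <- null_model_config(kind = null_model)
  pair <- .check_species_coverage(pair, tree, prune = prune_missing)
  species <- species_pool(pair)
  D <- patristic_matrix(tree, species)
  A <- community_matrix(pair$census1, grid, species)
  B <- community_matrix(pair$census2, grid, species)
  PA <- .rel_abund(A)
  PB <- .rel_abund(B)
  nq <- nrow(A)
  raod_obs <- rowSums((PA %*% D) * PB)
  occ_A <- rowSums(A) > 0
  occ_B <- rowSums(B) > 0

  nulls <- matrix(NA_real_, n_rep, nq)
  if (null_model == "nm1") {
    ns <- length(species)
    for (r in seq_len(n_rep)) {
      set.seed(.substream_seed(seed, r))
      perm <- sample.int(ns)
      Dp <- D[perm, perm]
      nulls[r, ] <- rowSums((PA %*% Dp) * PB)
    }
  } else {
    if (is.null(species_table))
      stop("NM-II requires a species_table with a 'growth_form' column")
    model <- nm2_prepare(pair, species_table, config)
    PAD <- PA %*% D
    for (r in seq_len(n_rep)) {
      set.seed(.substream_seed(seed, r))
      sim2 <- nm2_replicate(model)
      Br <- community_matrix(sim2, grid, species)
      PBr <- .rel_abund(Br)
      v <- rowSums(PAD * PBr)
      v[rowSums(Br) == 0] <- NA_real_
      nulls[r, ] <- v
    }
  }

  null_mean <- colMeans(nulls, na.rm = TRUE)
  null_n <- colSums(is.finite(nulls))
  null_sd <- apply(nulls, 2, stats::sd, na.rm = TRUE)
  flag <- rep("ok", nq)
  flag[!occ_B] <- "empty_at_B"
  flag[!occ_A] <- "empty_at_A"
  usable <- occ_A & occ_B
  degenerate <- usable & (is.na(null_sd) | null_sd == 0 | null_n < 2)
  flag[degenerate] <- "degenerate_null"
  ses <- ifelse(usable & !degenerate,
                (raod_obs - null_mean) / null_sd, NA_real_)
  raod_obs[!usable] <- NA_real_

  out <- data.frame(quadrat = grid$quadrats$quadrat,
                    cx = grid$quadrats$cx, cy = grid$quadrats$cy,
                    scale = grid$s,
                    raod_obs = raod_obs,
                    null_mean = ifelse(usable, null_mean, NA_real_),
                    null_sd = ifelse(usable, null_sd, NA_real_),
                    ses_raod = ses,
                    n_null = null_n,
                    flag = flag,
                    null_model = null_model,
                    stringsAsFactors = FALSE)
  class(out) <- c("turnover_result", "data.frame")
  attr(out, "seed") <- seed
  out
}
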