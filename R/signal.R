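#' Blomberg's K phylogenetic signal statistic
#'
#' Ratio of the observed to the Brownian-expected contrast between trait
#' variance ignoring and accounting for phylogeny.  With `C` the
#' shared-path-length (Brownian) covariance among the n tips,
#' phylogenetic mean `a = (1'C^-1 x)/(1'C^-1 1)`,
#' `MSE0 = sum((x - a)^2)/(n-1)` and `MSE = (x - a1)'C^-1(x - a1)/(n-1)`,
#' K = (MSE0/MSE) / ((tr(C) - n/(1'C^-1 1))/(n-1)).
#' K is about 1 under Brownian-motion evolution, near 0 with no signal, and
#' above 1 when relatives resemble each other more than Brownian motion
#' predicts.  K is invariant to affine trait transforms and to rescaling
#' all branch lengths.
#'
#' Species missing from either the tree or the trait vector are dropped
#' (the tree is pruned to the shared set); at least 3 shared species are
#' required.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param trait named numeric vector of tip trait values.
#' @return scalar K.
#' @export
blomberg_k <- function(tree, trait) {
  prep <- .k_prepare(tree, trait)
  .k_stat(prep$x, prep)
}

.k_prepare <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"), !is.null(names(trait)))
  shared <- intersect(tree$tip.label, names(trait)[!is.na(trait)])
  if (length(shared) < 3)
    stop("need at least 3 species shared between tree and trait")
  if (length(shared) < length(tree$tip.label))
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, shared))
  C <- ape::vcv(tree)
  sp <- rownames(C)
  x <- as.numeric(trait[sp])
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance (identical tips?): ",
         conditionMessage(e)))
  n <- length(x)
  sum_cinv <- sum(Cinv)
  list(x = x, n = n, Cinv = Cinv, sum_cinv = sum_cinv,
       colsum_cinv = colSums(Cinv),
       expected = (sum(diag(C)) - n / sum_cinv) / (n - 1),
       species = sp)
}

.k_stat <- function(x, prep) {
  a <- sum(prep$colsum_cinv * x) / prep$sum_cinv
  e <- x - a
  mse0 <- sum(e^2)
  mse <- as.numeric(e %*% prep$Cinv %*% e)
  if (mse0 == 0 || mse <= 0)
    stop("trait is constant across tips: K undefined")
  (mse0 / mse) / prep$expected
}

#' Tip-shuffle significance test for Blomberg's K
#'
#' Null K values are obtained by shuffling trait values across the tips
#' (equivalently, shuffling tips of the phylogeny) `n_shuffles` times; the
#' one-tailed p-value is the proportion of null K at least as large as the
#' observed, with the add-one rule
#' `p = (1 + #(null >= obs)) / (1 + n_shuffles)`.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param trait named numeric vector.
#' @param n_shuffles number of tip shuffles (default 1000).
#' @param seed optional seed.
#' @return list of class `signal_result`: `K`, `p`, `n_shuffles`,
#'   `n_species`.
#' @export
k_significance <- function(tree, trait, n_shuffles = 1000, seed = NULL) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  .set_seed_if(seed)
  prep <- .k_prepare(tree, trait)
  k_obs <- .k_stat(prep$x, prep)
  k_null <- vapply(seq_len(n_shuffles),
                   function(i) .k_stat(sample(prep$x), prep), numeric(1))
  p <- (1 + sum(k_null >= k_obs)) / (1 + n_shuffles)
  structure(list(K = k_obs, p = p, n_shuffles = n_shuffles,
                 n_species = prep$n, k_null = k_null),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.3f (n = %d species), p = %.4g [%d shuffles]\n",
              x$K, x$n_species, x$p, x$n_shuffles))
  invisible(x)
}

#' Phylogenetic signal for every trait in a species table
#'
#' Runs [k_significance()] per numeric trait column; species missing a
#' trait value are pruned for that trait's test.
#'
#' @param tree phylogeny.
#' @param species_table data.frame with `species` and trait columns.
#' @param n_shuffles shuffles per trait.
#' @param seed optional master seed (per-trait substreams).
#' @return data.frame: trait, K, p, n_species.
#' @export
phylo_signal_table <- function(tree, species_table, n_shuffles = 1000,
                               seed = NULL) {
  traits <- names(species_table)[vapply(species_table, is.numeric, logical(1))]
  traits <- setdiff(traits, "species")
  rows <- lapply(seq_along(traits), function(i) {
    tr <- stats::setNames(species_table[[traits[i]]], species_table$species)
    res <- k_significance(tree, tr, n_shuffles,
                          seed = if (is.null(seed)) NULL
                                 else .substream_seed(seed, i))
    data.frame(trait = traits[i], K = res$K, p = res$p,
               n_species = res$n_species, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
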