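# Brute-force oracles and tiny fixtures shared across test files.
# Oracles are deliberately naive and independent of the package's own
# computation paths.

# patristic distance by walking each tip's path to the root and summing the
# branch lengths on the symmetric difference
bf_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    out <- integer(0)
    while (parent[v] != 0) { out <- c(out, v); v <- parent[v] }
    out
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) next
    shared <- intersect(paths[[i]], paths[[j]])
    D[i, j] <- sum(elen[setdiff(paths[[i]], shared)]) +
      sum(elen[setdiff(paths[[j]], shared)])
  }
  D
}

# Rao turnover by exhaustive enumeration of individual pairs
bf_rao <- function(countsA, countsB, D) {
  iA <- rep(seq_along(countsA), countsA)
  iB <- rep(seq_along(countsB), countsB)
  mean(D[cbind(rep(iA, times = length(iB)), rep(iB, each = length(iA)))])
}

# MPD by explicit pair loop
bf_mpd <- function(present, D) {
  idx <- which(present > 0)
  if (length(idx) < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1):length(idx)) {
    tot <- tot + D[idx[i], idx[j]]; np <- np + 1
  }
  tot / np
}

# nearest conspecific mature stem by full scan
bf_nearest_mature <- function(rx, ry, mx, my, radius) {
  if (!length(mx)) return(NA_real_)
  d <- sqrt((mx - rx)^2 + (my - ry)^2)
  dmin <- min(d)
  if (dmin <= radius) dmin else NA_real_
}

# hand-built three-stem censuses used by several files
tiny_pair <- function() {
  c1 <- data.frame(tag = c("A", "B"), species = c("sp1", "sp2"),
                   x = c(1, 2), y = c(1, 2), dbh = c(5, 10),
                   status = "alive", stringsAsFactors = FALSE)
  c2 <- data.frame(tag = c("A", "B", "C"), species = c("sp1", "sp2", "sp1"),
                   x = c(1, 2, 3), y = c(1, 2, 3), dbh = c(5.5, NA, 1.2),
                   status = c("alive", "dead", "alive"),
                   stringsAsFactors = FALSE)
  census_pair(c1, c2, plot_dims = c(10, 10))
}

# small synthetic dataset memoized per session (neutral settings, quick)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(
        synthetic_config(n_species = 20, abundance_meanlog = log(60)),
        seed = 7)
    cache
  }
})
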