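#' Patristic distance matrix of a phylogeny
#'
#' Pairwise tip-to-tip path lengths (sums of branch lengths), the distance
#' d_ij entering Rao quadratic entropy and MPD.  Branch lengths are taken as
#' given (typically Myr after age smoothing).
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param species optional character vector giving the row/column order; must
#'   be a subset of the tip labels.  Default: tips in sorted label order.
#' @return symmetric numeric matrix with zero diagonal, dimnames = species.
#' @export
patristic_matrix <- function(tree, species = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  D <- ape::cophenetic.phylo(tree)
  if (is.null(species)) species <- sort(tree$tip.label)
  miss <- setdiff(species, rownames(D))
  if (length(miss)) stop("species not in tree: ", paste(miss, collapse = ", "))
  D[species, species, drop = FALSE]
}

#' Branch-length smoothing from node-age constraints
#'
#' Fixes named internal nodes at user-supplied ages and positions every
#' unconstrained internal node by even interpolation between its nearest
#' constrained ancestor and its nearest constrained descendant along the
#' path (tips sit at age 0).  When several constrained descendants are
#' reachable through unconstrained nodes, the maximum-age one anchors the
#' interpolation, which keeps the assignment deterministic.  Branch lengths
#' of the returned tree are parent age minus child age, so the output is
#' ultrametric whenever the topology admits it.  Re-running with the same
#' constraints is a no-op.
#'
#' @param tree rooted [ape::phylo]; internal nodes that carry constraints
#'   must be named (`tree$node.label`).
#' @param ages named numeric vector (or two-column data.frame `node`, `age`)
#'   of node ages in time units before present.  The root must be
#'   constrained; ages must decrease root-to-tip.
#' @return the tree with adjusted branch lengths.
#' @export
bladj_smooth <- function(tree, ages) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(ages)) {
    stopifnot(ncol(ages) >= 2)
    ages <- stats::setNames(as.numeric(ages[[2]]), as.character(ages[[1]]))
  }
  if (is.null(names(ages)) || any(names(ages) == ""))
    stop("ages must be named by node label")
  if (is.null(tree$node.label)) stop("tree has no internal node labels")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  node_names <- c(tree$tip.label, tree$node.label)
  unknown <- setdiff(names(ages), node_names)
  if (length(unknown)) stop("age constraints for unknown node(s): ",
                            paste(unknown, collapse = ", "))

  age <- rep(NA_real_, ntip + nnode)
  age[seq_len(ntip)] <- 0
  idx <- match(names(ages), node_names)
  age[idx] <- as.numeric(ages)
  if (is.na(age[root])) stop("root age must be constrained")
  constrained <- !is.na(age)

  # children lists in one pass
  kids <- vector("list", ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], ch)
  }

  # post-order: nearest constrained descendant (max age wins) and its step
  # distance through unconstrained nodes only
  ncd_age <- rep(NA_real_, ntip + nnode)
  ncd_steps <- rep(NA_integer_, ntip + nnode)
  post <- rev(.preorder_nodes(tree, kids))
  for (v in post) {
    if (v <= ntip) next
    best_a <- -Inf; best_s <- NA_integer_
    for (ch in kids[[v]]) {
      if (constrained[ch]) { a <- age[ch]; s <- 1L }
      else { a <- ncd_age[ch]; s <- ncd_steps[ch] + 1L }
      if (a > best_a || (a == best_a && !is.na(best_s) && s < best_s)) {
        best_a <- a; best_s <- s
      }
    }
    ncd_age[v] <- best_a; ncd_steps[v] <- best_s
  }

  parent <- integer(ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # pre-order: interpolate each unconstrained node between its (already
  # dated) parent and its anchor descendant
  for (v in .preorder_nodes(tree, kids)) {
    if (v == root || constrained[v] || v <= ntip) next
    p <- parent[v]
    a_anc <- age[p]
    a_des <- ncd_age[v]; s <- ncd_steps[v]
    if (a_des >= a_anc)
      stop("age constraint conflict below node '", node_names[p],
           "': descendant age ", a_des, " >= ancestor age ", a_anc)
    age[v] <- a_des + (a_anc - a_des) * s / (s + 1)
  }

  bl <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(bl < -1e-12))
    stop("age constraint conflict: child older than parent (e.g. edge to '",
         node_names[tree$edge[which.min(bl), 2]], "')")
  tree$edge.length <- pmax(bl, 0)
  tree
}

# Nodes in preorder (root first), iterative to handle big trees.
.preorder_nodes <- function(tree, kids) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- integer(ntip + tree$Nnode)
  stack <- root; n <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    n <- n + 1L; out[n] <- v
    if (!is.null(kids[[v]])) stack <- c(stack, kids[[v]])
  }
  out[seq_len(n)]
}

#' Read node-age constraints
#'
#' Two-column CSV `node, age`.
#'
#' @param path file path.
#' @return named numeric vector of ages.
#' @export
read_node_ages <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
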