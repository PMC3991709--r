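#' Quadrat grid over a rectangular plot
#'
#' Tiles the plot with non-overlapping square quadrats of side `s`, origin
#' at the lower-left corner.  Cells are half-open `[i*s, (i+1)*s)`; a stem
#' sitting exactly on the plot's upper or right boundary is clamped into the
#' last full cell.  When the plot dimensions are not divisible by `s`, the
#' partial edge strip is not gridded: stems falling there are dropped from
#' quadrat-based analyses (and counted), because unequal quadrat areas bias
#' turnover and relatedness comparisons.
#'
#' @param plot_dims numeric length-2, width and height in metres.
#' @param s quadrat side in metres; one of the analysis scales
#'   (10--50 m in the standard design).
#' @return object of class `quadrat_grid` with cell counts `nx`, `ny` and a
#'   `quadrats` data.frame (id, column, row, centroid).
#' @export
quadrat_grid <- function(plot_dims, s) {
  stopifnot(is.numeric(plot_dims), length(plot_dims) == 2, s > 0,
            s <= min(plot_dims))
  nx <- floor(plot_dims[1] / s + 1e-9)
  ny <- floor(plot_dims[2] / s + 1e-9)
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  q <- data.frame(quadrat = seq_len(nx * ny), col = ix, row = iy,
                  cx = (ix + 0.5) * s, cy = (iy + 0.5) * s)
  structure(list(s = s, nx = nx, ny = ny, plot_dims = as.numeric(plot_dims),
                 quadrats = q),
            class = "quadrat_grid")
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf("quadrat_grid: %d x %d cells of %g m (plot %g x %g m)\n",
              x$nx, x$ny, x$s, x$plot_dims[1], x$plot_dims[2]))
  invisible(x)
}

#' Assign stems to quadrats
#'
#' @param x,y stem coordinates in metres.
#' @param grid a [quadrat_grid()].
#' @return integer vector of quadrat ids (`NA` for stems in a partial edge
#'   strip), with attribute `n_dropped`.
#' @export
assign_quadrats <- function(x, y, grid) {
  stopifnot(inherits(grid, "quadrat_grid"))
  s <- grid$s; dims <- grid$plot_dims
  # clamp points exactly on the plot's maximal boundaries into the plot so
  # that, on divisible dims, they land in the last cell
  xx <- ifelse(x >= dims[1], dims[1] - 1e-9, x)
  yy <- ifelse(y >= dims[2], dims[2] - 1e-9, y)
  ix <- floor(xx / s); iy <- floor(yy / s)
  q <- ifelse(ix >= grid$nx | iy >= grid$ny, NA_integer_,
              as.integer(ix + iy * grid$nx + 1))
  attr(q, "n_dropped") <- sum(is.na(q))
  q
}

#' Quadrat-by-species abundance matrix
#'
#' Counts alive stems per quadrat and species.  Column order follows the
#' supplied species index so the matrix aligns with a patristic distance
#' matrix over the same species.
#'
#' @param census stem table; only rows with `status == "alive"` are counted.
#' @param grid a [quadrat_grid()].
#' @param species character vector fixing the column order.
#' @return integer matrix (quadrats x species) with dimnames.
#' @export
community_matrix <- function(census, grid, species) {
  stopifnot(inherits(grid, "quadrat_grid"))
  alive <- census[census$status == "alive", , drop = FALSE]
  extra <- setdiff(unique(alive$species), species)
  if (length(extra)) stop("census contains species not in the index: ",
                          paste(extra[1:min(3, length(extra))], collapse = ", "))
  q <- assign_quadrats(alive$x, alive$y, grid)
  keep <- !is.na(q)
  nq <- grid$nx * grid$ny
  ns <- length(species)
  sp <- match(alive$species[keep], species)
  counts <- tabulate(q[keep] + (sp - 1L) * nq, nbins = nq * ns)
  m <- matrix(as.integer(counts), nrow = nq, ncol = ns,
              dimnames = list(paste0("q", seq_len(nq)), species))
  attr(m, "n_dropped") <- sum(!keep)
  m
}

# Relative abundances by row; rows with zero total stay all-zero.
.rel_abund <- function(m) {
  tot <- rowSums(m)
  out <- m / ifelse(tot > 0, tot, 1)
  out[tot == 0, ] <- 0
  out
}
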