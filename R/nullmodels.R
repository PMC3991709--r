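#' Null-model configuration
#'
#' Settings shared by the two null models for temporal phylogenetic
#' turnover.  NM-I shuffles species names across the species pool (one
#' permutation per replicate, applied to both censuses).  NM-II re-simulates
#' the demography of the second census: observed deaths are re-assigned at
#' random within each species-by-size-class cell at the observed rate, and
#' each recruit is re-placed at its observed parent distance `Dp` around a
#' randomly chosen conspecific mature stem (uniformly in the plot when no
#' mature conspecific lay within `parent_radius`).
#'
#' @param kind `"nm1"` or `"nm2"`.
#' @param n_rep number of replicate null censuses (default 499).
#' @param mature_dbh named vector, DBH maturity thresholds in cm for
#'   `tree` (15) and `shrub` (5) growth forms, judged at the first census.
#' @param parent_radius search radius in metres for a recruit's nearest
#'   conspecific mature stem (50).
#' @param size_class_edges DBH class edges in cm: 1 cm classes to 20, then
#'   20--25, 25--35, 35--45, 45--55 and >= 55.
#' @param mortality_mode `"exact_count"` re-draws which stems die while
#'   holding each cell's death count at the observed value, so plot-level
#'   abundances are conserved exactly and null variance comes from spatial
#'   rearrangement alone; `"bernoulli"` draws each death independently at
#'   the cell's observed rate.
#' @param placement `"circle"` places a recruit exactly `Dp` metres from its
#'   simulated parent (uniform angle); `"disk"` places it uniformly within
#'   that radius (sensitivity option).
#' @param max_placement_retries angle re-draws per candidate parent before
#'   the parent itself is re-drawn.
#' @param max_parent_redraws candidate parents tried before the recruit
#'   falls back to uniform placement (logged).
#' @return object of class `null_model_config`.
#' @export
null_model_config <- function(kind = c("nm2", "nm1"),
                              n_rep = 499,
                              mature_dbh = c(tree = 15, shrub = 5),
                              parent_radius = 50,
                              size_class_edges = c(1:20, 25, 35, 45, 55, Inf),
                              mortality_mode = c("exact_count", "bernoulli"),
                              placement = c("circle", "disk"),
                              max_placement_retries = 100,
                              max_parent_redraws = 10) {
  kind <- match.arg(kind)
  mortality_mode <- match.arg(mortality_mode)
  placement <- match.arg(placement)
  stopifnot(all(mature_dbh > 0), parent_radius > 0,
            all(diff(size_class_edges) > 0), n_rep >= 1)
  structure(list(kind = kind, n_rep = as.integer(n_rep),
                 mature_dbh = mature_dbh, parent_radius = parent_radius,
                 size_class_edges = size_class_edges,
                 mortality_mode = mortality_mode, placement = placement,
                 max_placement_retries = as.integer(max_placement_retries),
                 max_parent_redraws = as.integer(max_parent_redraws)),
            class = "null_model_config")
}

#' One species-name permutation (NM-I)
#'
#' Draws a uniform random permutation of the species pool.  Within a
#' replicate the same permutation relabels both censuses, preserving
#' abundances, richness, occupancy and species turnover through time while
#' scrambling phylogenetic identities.
#'
#' @param species character vector, the pool (species alive in either
#'   census).
#' @return named character vector: `perm[old_name] = new_name`.
#' @export
nm1_permutation <- function(species) {
  stats::setNames(sample(species), species)
}

#' Species- and size-class-specific survival rates
#'
#' Bins every stem alive at the first census into DBH size classes (by its
#' first-census DBH) and tabulates, per species and class, how many survived
#' to the second census.
#'
#' @param pair a [census_pair()].
#' @param edges DBH class edges in cm (see [null_model_config()]).
#' @return data.frame of class `survival_table`: species, size class,
#'   `n`, `n_surv`, `rate`.
#' @export
estimate_survival_table <- function(pair, edges = c(1:20, 25, 35, 45, 55, Inf)) {
  demo <- classify_demographics(pair)
  c1 <- pair$census1
  alive1 <- c1[c1$status == "alive", , drop = FALSE]
  if (anyNA(alive1$dbh)) stop("alive census-1 stem without DBH")
  cls <- cut(alive1$dbh, breaks = edges, right = FALSE,
             include.lowest = FALSE)
  if (anyNA(cls)) stop("DBH outside the size-class range (must be >= ",
                       edges[1], " cm)")
  surv <- alive1$tag %in% demo$survivors
  agg <- stats::aggregate(cbind(n = rep(1L, nrow(alive1)), n_surv = as.integer(surv)),
                          by = list(species = alive1$species, size_class = cls),
                          FUN = sum)
  agg$rate <- agg$n_surv / agg$n
  agg <- agg[order(agg$species, agg$size_class), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("survival_table", "data.frame")
  agg
}

#' Recruit-to-parent dispersal distances
#'
#' For every recruit, finds the nearest conspecific mature stem of the first
#' census within `parent_radius` metres; that stem is taken as the parent
#' and the Euclidean distance recorded as `Dp`.  Recruits with no mature
#' conspecific within the radius get `Dp = NA` (they are placed uniformly by
#' the demographic null model).
#'
#' @param pair a [census_pair()].
#' @param species_table data.frame with `species` and `growth_form` columns.
#' @param config a [null_model_config()].
#' @return data.frame of class `recruit_records`: tag, species, x, y, `dp`.
#' @export
measure_dispersal <- function(pair, species_table,
                              config = null_model_config()) {
  demo <- classify_demographics(pair)
  c1 <- pair$census1; c2 <- pair$census2
  gf <- stats::setNames(species_table$growth_form, species_table$species)
  rec <- c2[c2$tag %in% demo$recruits, , drop = FALSE]
  need <- unique(c(rec$species, c1$species[c1$status == "alive"]))
  nogf <- need[is.na(gf[need])]
  if (length(nogf)) stop("species without growth form: ",
                         paste(nogf[1:min(3, length(nogf))], collapse = ", "))
  alive1 <- c1[c1$status == "alive", , drop = FALSE]
  thr <- config$mature_dbh[gf[alive1$species]]
  mature <- alive1[!is.na(alive1$dbh) & alive1$dbh >= thr, , drop = FALSE]
  dp <- rep(NA_real_, nrow(rec))
  for (sp in unique(rec$species)) {
    ri <- which(rec$species == sp)
    mi <- which(mature$species == sp)
    if (!length(mi)) next
    dx <- outer(rec$x[ri], mature$x[mi], "-")
    dy <- outer(rec$y[ri], mature$y[mi], "-")
    dmin <- apply(sqrt(dx^2 + dy^2), 1, min)
    dp[ri] <- ifelse(dmin <= config$parent_radius, dmin, NA_real_)
  }
  out <- data.frame(tag = rec$tag, species = rec$species,
                    x = rec$x, y = rec$y, dp = dp,
                    stringsAsFactors = FALSE)
  class(out) <- c("recruit_records", "data.frame")
  out
}

#' Precompute the demographic null model (NM-II)
#'
#' Bundles everything one replicate draw needs: census-1 stems with their
#' species-by-size-class cell and observed fate, per-cell death counts and
#' rates, recruit records with `Dp`, and the positions of mature conspecific
#' candidates per species.
#'
#' @param pair a [census_pair()].
#' @param species_table data.frame with `species` and `growth_form`.
#' @param config a [null_model_config()].
#' @return object of class `nm2_model`.
#' @export
nm2_prepare <- function(pair, species_table, config = null_model_config()) {
  if (!"growth_form" %in% names(species_table))
    stop("NM-II needs a 'growth_form' column in the species table")
  demo <- classify_demographics(pair)
  c1 <- pair$census1
  alive1 <- c1[c1$status == "alive", , drop = FALSE]
  if (anyNA(alive1$dbh)) stop("alive census-1 stem without DBH")
  cls <- cut(alive1$dbh, breaks = config$size_class_edges, right = FALSE)
  cell <- interaction(alive1$species, cls, drop = TRUE)
  died <- !(alive1$tag %in% demo$survivors)
  deaths_per_cell <- tapply(died, cell, sum)
  n_per_cell <- tapply(rep(1L, length(cell)), cell, sum)
  gf <- stats::setNames(species_table$growth_form, species_table$species)
  thr <- config$mature_dbh[gf[alive1$species]]
  mature <- !is.na(thr) & alive1$dbh >= thr
  mature_idx <- split(which(mature), alive1$species[mature])
  recruits <- measure_dispersal(pair, species_table, config)
  rec_dbh <- pair$census2$dbh[match(recruits$tag, pair$census2$tag)]
  structure(list(alive1 = alive1, cell = cell,
                 deaths_per_cell = deaths_per_cell,
                 n_per_cell = n_per_cell,
                 rate_per_cell = 1 - deaths_per_cell / n_per_cell,
                 mature_idx = mature_idx,
                 recruits = recruits, recruit_dbh = rec_dbh,
                 plot_dims = pair$plot_dims, config = config),
            class = "nm2_model")
}

#' Draw one replicate census under NM-II
#'
#' Mortality: in `exact_count` mode each species-by-size-class cell kills
#' exactly its observed number of stems, chosen uniformly without
#' replacement; in `bernoulli` mode each stem dies independently at the
#' cell rate.  Survivors keep their observed positions.  Recruitment: each
#' recruit with a recorded `Dp` gets a parent drawn uniformly from all
#' conspecific mature census-1 stems and is placed at a uniform angle on the
#' circle of radius `Dp` around it; angles falling outside the plot are
#' re-drawn, then the parent re-drawn, and after all retries the recruit is
#' placed uniformly in the plot (counted in the fallback log).  Recruits
#' without a `Dp` are placed uniformly.  Species identities, recruit DBHs
#' and (in `exact_count` mode) per-species abundances are preserved.
#'
#' @param model an [nm2_prepare()] result.
#' @return stem table for the simulated second census, with attribute
#'   `placement_log` (`n_fallback_uniform`, `n_parent_redraws`,
#'   `n_angle_redraws`).
#' @export
nm2_replicate <- function(model) {
  stopifnot(inherits(model, "nm2_model"))
  cfg <- model$config
  alive1 <- model$alive1
  n <- nrow(alive1)
  cell_i <- as.integer(model$cell)

  if (cfg$mortality_mode == "exact_count") {
    # rank a uniform key within each cell; the lowest `deaths` ranks die
    u <- stats::runif(n)
    rk <- stats::ave(u, cell_i, FUN = rank)
    die <- rk <= model$deaths_per_cell[cell_i]
  } else {
    die <- stats::runif(n) >= model$rate_per_cell[cell_i]
  }
  surv <- alive1[!die, , drop = FALSE]
  surv$status <- "alive"

  rec <- model$recruits
  W <- model$plot_dims[1]; H <- model$plot_dims[2]
  nr <- nrow(rec)
  rx <- numeric(nr); ry <- numeric(nr)
  log_angle <- 0L; log_parent <- 0L
  uniform_idx <- which(is.na(rec$dp))
  placed <- is.na(rec$dp)
  rx[uniform_idx] <- stats::runif(length(uniform_idx), 0, W)
  ry[uniform_idx] <- stats::runif(length(uniform_idx), 0, H)
  n_giveup <- 0L

  todo <- which(!placed)
  if (length(todo)) {
    parent_draw <- rep(0L, nr)
    px <- numeric(nr); py <- numeric(nr)
    new_parent <- todo
    angle_tries <- rep(0L, nr)
    while (length(todo)) {
      if (length(new_parent)) {
        for (sp in unique(rec$species[new_parent])) {
          ids <- new_parent[rec$species[new_parent] == sp]
          cand <- model$mature_idx[[sp]]
          pick <- cand[sample.int(length(cand), length(ids), replace = TRUE)]
          px[ids] <- model$alive1$x[pick]
          py[ids] <- model$alive1$y[pick]
        }
        parent_draw[new_parent] <- parent_draw[new_parent] + 1L
        angle_tries[new_parent] <- 0L
        new_parent <- integer(0)
      }
      r <- if (cfg$placement == "circle") rec$dp[todo]
           else rec$dp[todo] * sqrt(stats::runif(length(todo)))
      th <- stats::runif(length(todo), 0, 2 * pi)
      x <- px[todo] + r * cos(th)
      y <- py[todo] + r * sin(th)
      ok <- x >= 0 & x <= W & y >= 0 & y <= H
      rx[todo[ok]] <- x[ok]; ry[todo[ok]] <- y[ok]
      placed[todo[ok]] <- TRUE
      todo <- todo[!ok]
      if (!length(todo)) break
      log_angle <- log_angle + length(todo)
      angle_tries[todo] <- angle_tries[todo] + 1L
      exhausted <- todo[angle_tries[todo] >= cfg$max_placement_retries]
      if (length(exhausted)) {
        redraw <- exhausted[parent_draw[exhausted] < cfg$max_parent_redraws]
        giveup <- setdiff(exhausted, redraw)
        if (length(giveup)) {
          rx[giveup] <- stats::runif(length(giveup), 0, W)
          ry[giveup] <- stats::runif(length(giveup), 0, H)
          placed[giveup] <- TRUE
          n_giveup <- n_giveup + length(giveup)
          todo <- setdiff(todo, giveup)
        }
        if (length(redraw)) {
          new_parent <- redraw
          log_parent <- log_parent + length(redraw)
        }
      }
    }
  }

  out <- surv[c("tag", "species", "x", "y", "dbh", "status")]
  if (nr > 0) {
    rec_out <- data.frame(tag = rec$tag, species = rec$species,
                          x = rx, y = ry, dbh = model$recruit_dbh,
                          status = "alive", stringsAsFactors = FALSE)
    out <- rbind(out, rec_out)
  }
  rownames(out) <- NULL
  attr(out, "placement_log") <-
    list(n_fallback_uniform = n_giveup,
         n_parent_redraws = log_parent, n_angle_redraws = log_angle)
  out
}
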