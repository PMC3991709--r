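#' Configuration for the synthetic census generator
#'
#' Describes a two-census community with known demographic, dispersal and
#' assembly parameters: a pure-birth phylogeny with Brownian (or white
#' noise) traits; lognormal species abundances; Thomas-type clustered stem
#' placement with a per-species scale; species- and size-specific survival
#' on the logit scale; recruitment around surviving mature conspecifics at
#' exponential-kernel distances; and optional habitat-filtering and
#' phylogenetic density-dependence forcing of mortality.
#'
#' Defaults describe a desk-scale plot: 40 species on 200 m x 100 m,
#' around 5--10 thousand stems, five-year-interval-like mortality (~15%)
#' and recruitment (~15%), dispersal scales lognormal around 8 m.
#'
#' @param n_species number of species (>= 3).
#' @param plot_dims plot width and height in metres; keep divisible by the
#'   analysis scales.
#' @param abundance_meanlog,abundance_sdlog lognormal abundance model.
#' @param birth_rate pure-birth speciation rate (tree is rescaled to unit
#'   root depth, so this only shapes topology/branching times).
#' @param trait_model `"brownian"` (signal, K near 1) or `"white"`
#'   (no signal).
#' @param trait_sigma Brownian rate.
#' @param dispersal_meanlog,dispersal_sdlog per-species dispersal scale
#'   (m), lognormal across species; also the Thomas cluster scale.
#' @param shrub_fraction probability a species is a shrub (5 cm maturity
#'   threshold instead of 15 cm).
#' @param dbh_meanlog,dbh_sdlog stem DBH distribution (cm), truncated to
#'   `[1, 90]`.
#' @param survival_base mean five-year survival of a reference-size stem.
#' @param survival_logit_sd among-species spread of baseline survival
#'   (logit scale).
#' @param size_coef logit-survival increase per unit log-DBH above the
#'   median.
#' @param recruit_rate expected recruits per census-1 stem of the species.
#' @param immigrant_fraction recruits placed uniformly (seed rain from
#'   outside parent range), mimicking recruits without a mapped parent.
#' @param filtering habitat-filtering strength `phi >= 0`: logit survival
#'   decreases by `phi * |trait_u - env(x, y)|` with the trait rank-scaled
#'   to `[0, 1]`.
#' @param density_dep phylogenetic density-dependence strength
#'   `delta >= 0`: logit survival decreases with the relatedness-weighted
#'   density of neighbours within `density_radius`.
#' @param density_radius neighbourhood radius in metres.
#' @param env_field `"gradient"` (linear in x) or `"bumps"` (Gaussian
#'   patches).
#' @param n_bumps patches for the `"bumps"` field.
#' @param prefilter also thin census 1 by habitat mismatch, so the first
#'   census is already habitat-sorted (stronger filtering signal).
#' @param prefilter_strength thinning strength on the log scale.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 40,
                             plot_dims = c(200, 100),
                             abundance_meanlog = log(150),
                             abundance_sdlog = 1,
                             birth_rate = 1,
                             trait_model = c("brownian", "white"),
                             trait_sigma = 1,
                             dispersal_meanlog = log(8),
                             dispersal_sdlog = 0.5,
                             shrub_fraction = 0.3,
                             dbh_meanlog = log(3),
                             dbh_sdlog = 0.9,
                             survival_base = 0.85,
                             survival_logit_sd = 0.5,
                             size_coef = 0.5,
                             recruit_rate = 0.15,
                             immigrant_fraction = 0.2,
                             filtering = 0,
                             density_dep = 0,
                             density_radius = 10,
                             env_field = c("gradient", "bumps"),
                             n_bumps = 5,
                             prefilter = FALSE,
                             prefilter_strength = 4) {
  trait_model <- match.arg(trait_model)
  env_field <- match.arg(env_field)
  stopifnot(n_species >= 3, all(plot_dims > 0), filtering >= 0,
            density_dep >= 0, survival_base > 0, survival_base < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a phylogeny and trait values
#'
#' Pure-birth tree rescaled to unit root depth; traits evolve by Brownian
#' motion along the branches (`"brownian"`, phylogenetic signal with K
#' near 1) or are drawn i.i.d. normal at the tips (`"white"`, no signal).
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed.
#' @return list with `tree` ([ape::phylo], tips `sp001`, ...) and `traits`
#'   (named numeric).
#' @export
simulate_phylogeny_traits <- function(config = synthetic_config(),
                                      seed = NULL) {
  .set_seed_if(seed)
  n <- config$n_species
  tree <- ape::rphylo(n, birth = config$birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  traits <- if (config$trait_model == "brownian") {
    ape::rTraitCont(tree, model = "BM", sigma = config$trait_sigma)
  } else {
    stats::setNames(stats::rnorm(n, 0, config$trait_sigma), tree$tip.label)
  }
  list(tree = tree, traits = traits)
}

# environment field on [0,1]
.env_field <- function(config) {
  if (config$env_field == "gradient") {
    W <- config$plot_dims[1]
    function(x, y) x / W
  } else {
    W <- config$plot_dims[1]; H <- config$plot_dims[2]
    cx <- stats::runif(config$n_bumps, 0, W)
    cy <- stats::runif(config$n_bumps, 0, H)
    sdb <- min(W, H) / 4
    function(x, y) {
      v <- rowSums(exp(-(outer(x, cx, "-")^2 + outer(y, cy, "-")^2) /
                         (2 * sdb^2)))
      v / max(v)
    }
  }
}

# relatedness-weighted neighbour density via cell binning; weight of a
# neighbour pair is 1 - d_ij / max(d) (conspecifics weigh 1)
.phylo_neighbor_density <- function(x, y, sp_idx, Wrel, radius) {
  n <- length(x)
  bx <- floor(x / radius); by <- floor(y / radius)
  key <- paste(bx, by, sep = "_")
  bins <- split(seq_len(n), key)
  lookup <- stats::setNames(seq_along(bins), names(bins))
  dens <- numeric(n)
  for (b in seq_along(bins)) {
    me <- bins[[b]]
    b0x <- bx[me[1]]; b0y <- by[me[1]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      j <- lookup[paste(b0x + dx, b0y + dy, sep = "_")]
      if (!is.na(j)) cand <- c(cand, bins[[j]])
    }
    dd <- sqrt(outer(x[me], x[cand], "-")^2 + outer(y[me], y[cand], "-")^2)
    w <- matrix(Wrel[cbind(rep(sp_idx[me], times = length(cand)),
                           rep(sp_idx[cand], each = length(me)))],
                length(me), length(cand))
    w[dd > radius] <- 0
    w[cbind(seq_along(me), match(me, cand))] <- 0  # drop self
    dens[me] <- rowSums(w)
  }
  dens
}

#' Simulate a two-census stem dataset with known truth
#'
#' Census 1: lognormal species abundances; stems placed by a Thomas-type
#' parent-offspring cluster process (per-species cluster scale equal to the
#' species' dispersal scale, torus-wrapped); DBH lognormal; growth forms
#' assigned per species.  Census 2: each stem survives with a logistic
#' probability combining its species baseline, its size, and the optional
#' habitat-filtering and phylogenetic density-dependence penalties;
#' recruits appear around surviving mature conspecifics at
#' exponential-kernel distances (a configurable fraction, plus all recruits
#' of species with no surviving mature stem, arrive uniformly).  All
#' realized survival probabilities, parent assignments and dispersal
#' distances are kept in the attached truth record.  Coordinates and DBH
#' are recorded to 0.1 (m / cm), the usual census precision.
#'
#' @param phylo output of [simulate_phylogeny_traits()].
#' @param config a [synthetic_config()].
#' @param seed optional seed.
#' @return a [census_pair()] with attributes `species_table` (species,
#'   growth_form, trait) and `truth` (per-stem fates and probabilities,
#'   recruit parents and distances, the realized parameters).
#' @export
simulate_census_pair <- function(phylo, config = synthetic_config(),
                                 seed = NULL) {
  .set_seed_if(seed)
  tree <- phylo$tree; traits <- phylo$traits
  nsp <- config$n_species
  W <- config$plot_dims[1]; H <- config$plot_dims[2]
  spp <- tree$tip.label

  abund <- pmax(5L, round(stats::rlnorm(nsp, config$abundance_meanlog,
                                        config$abundance_sdlog)))
  abund <- pmin(abund, 2000L)
  growth_form <- ifelse(stats::runif(nsp) < config$shrub_fraction,
                        "shrub", "tree")
  disp <- stats::rlnorm(nsp, config$dispersal_meanlog, config$dispersal_sdlog)
  s_base <- stats::plogis(stats::rnorm(nsp, stats::qlogis(config$survival_base),
                                       config$survival_logit_sd))
  env <- .env_field(config)
  trait_u <- (rank(traits) - 0.5) / nsp

  # census 1: Thomas clusters, torus wrap
  sp_idx <- rep(seq_len(nsp), abund)
  n1 <- length(sp_idx)
  px <- numeric(n1); py <- numeric(n1)
  for (s in seq_len(nsp)) {
    me <- which(sp_idx == s)
    n_par <- max(1L, round(abund[s] / 15))
    cx <- stats::runif(n_par, 0, W); cy <- stats::runif(n_par, 0, H)
    pick <- sample.int(n_par, length(me), replace = TRUE)
    px[me] <- (cx[pick] + stats::rnorm(length(me), 0, disp[s])) %% W
    py[me] <- (cy[pick] + stats::rnorm(length(me), 0, disp[s])) %% H
  }
  dbh <- pmin(pmax(stats::rlnorm(n1, config$dbh_meanlog, config$dbh_sdlog),
                   1), 90)

  if (config$prefilter) {
    mis1 <- abs(trait_u[sp_idx] - env(px, py))
    keep <- stats::runif(n1) < exp(-config$prefilter_strength * mis1)
    sp_idx <- sp_idx[keep]; px <- px[keep]; py <- py[keep]; dbh <- dbh[keep]
    n1 <- length(sp_idx)
  }
  px <- round(px, 1); py <- round(py, 1)
  px[px >= W] <- W - 0.1; py[py >= H] <- H - 0.1
  dbh <- pmax(1, round(dbh, 1))
  tags1 <- sprintf("t%06d", seq_len(n1))

  # survival probabilities
  eta <- stats::qlogis(s_base[sp_idx]) +
    config$size_coef * (log(dbh) - stats::median(log(dbh)))
  mismatch <- abs(trait_u[sp_idx] - env(px, py))
  if (config$filtering > 0) eta <- eta - config$filtering * mismatch
  dens <- rep(0, n1)
  if (config$density_dep > 0) {
    D <- ape::cophenetic.phylo(tree)[spp, spp]
    Wrel <- 1 - D / max(D)
    dens <- .phylo_neighbor_density(px, py, sp_idx, Wrel,
                                    config$density_radius)
    dscale <- stats::quantile(dens, 0.9)
    if (dscale > 0) eta <- eta - config$density_dep * dens / dscale
  }
  p_surv <- stats::plogis(eta)
  died <- stats::runif(n1) >= p_surv

  census1 <- data.frame(tag = tags1, species = spp[sp_idx], x = px, y = py,
                        dbh = dbh, status = "alive", stringsAsFactors = FALSE)
  surv2 <- data.frame(tag = tags1[!died], species = spp[sp_idx[!died]],
                      x = px[!died], y = py[!died], dbh = dbh[!died],
                      status = "alive", stringsAsFactors = FALSE)
  dead2 <- data.frame(tag = tags1[died], species = spp[sp_idx[died]],
                      x = px[died], y = py[died], dbh = NA_real_,
                      status = "dead", stringsAsFactors = FALSE)

  # recruitment around surviving mature conspecifics
  thr <- ifelse(growth_form == "tree", 15, 5)
  rec_rows <- list(); rec_truth <- list()
  tag_counter <- n1
  for (s in seq_len(nsp)) {
    n_rec <- stats::rpois(1, config$recruit_rate * sum(sp_idx == s))
    if (n_rec == 0) next
    mature <- which(!died & sp_idx == s & dbh >= thr[s])
    uni <- stats::runif(n_rec) < config$immigrant_fraction |
      length(mature) == 0
    rx <- numeric(n_rec); ry <- numeric(n_rec)
    parent <- rep(NA_character_, n_rec); rdist <- rep(NA_real_, n_rec)
    nu <- sum(uni)
    rx[uni] <- stats::runif(nu, 0, W); ry[uni] <- stats::runif(nu, 0, H)
    for (i in which(!uni)) {
      pj <- mature[sample.int(length(mature), 1)]
      for (try in 1:50) {
        dd <- stats::rexp(1, 1 / disp[s])
        th <- stats::runif(1, 0, 2 * pi)
        xx <- px[pj] + dd * cos(th); yy <- py[pj] + dd * sin(th)
        if (xx >= 0 && xx <= W && yy >= 0 && yy <= H) break
      }
      if (xx < 0 || xx > W || yy < 0 || yy > H) {
        xx <- stats::runif(1, 0, W); yy <- stats::runif(1, 0, H)
        dd <- NA_real_; pj <- NA_integer_
      }
      rx[i] <- xx; ry[i] <- yy
      parent[i] <- if (is.na(pj)) NA_character_ else tags1[pj]
      rdist[i] <- dd
    }
    tags_r <- sprintf("t%06d", tag_counter + seq_len(n_rec))
    tag_counter <- tag_counter + n_rec
    rx <- round(rx, 1); ry <- round(ry, 1)
    rx[rx >= W] <- W - 0.1; ry[ry >= H] <- H - 0.1
    rec_rows[[s]] <- data.frame(tag = tags_r, species = spp[s],
                                x = rx, y = ry,
                                dbh = pmax(1, round(stats::rlnorm(n_rec,
                                  log(1.3), 0.2), 1)),
                                status = "alive", stringsAsFactors = FALSE)
    rec_truth[[s]] <- data.frame(tag = tags_r, species = spp[s],
                                 parent = parent, distance = rdist,
                                 uniform = uni, stringsAsFactors = FALSE)
  }
  recruits2 <- do.call(rbind, rec_rows)
  census2 <- rbind(surv2, dead2, recruits2)
  rownames(census2) <- NULL
  if (sum(census2$status == "alive") == 0)
    stop("parameterization produced an empty second census")

  pair <- census_pair(census1, census2, config$plot_dims,
                      dates = c("t1", "t2"))
  attr(pair, "species_table") <-
    data.frame(species = spp, growth_form = growth_form, trait = as.numeric(traits),
               dispersal_scale = disp, base_survival = s_base,
               stringsAsFactors = FALSE)
  attr(pair, "truth") <- list(
    stems = data.frame(tag = tags1, species = spp[sp_idx],
                       p_surv = p_surv, died = died,
                       mismatch = mismatch, neighbor_density = dens,
                       stringsAsFactors = FALSE),
    recruits = do.call(rbind, rec_truth),
    config = config)
  pair
}

#' Simulate a complete dataset
#'
#' Phylogeny + traits + census pair in one call under one seed.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed (substreams for the two stages).
#' @return list: `tree`, `traits`, `pair`, `species_table`, `truth`.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1) {
  phylo <- simulate_phylogeny_traits(config, seed = .substream_seed(seed, 1))
  pair <- simulate_census_pair(phylo, config, seed = .substream_seed(seed, 2))
  list(tree = phylo$tree, traits = phylo$traits, pair = pair,
       species_table = attr(pair, "species_table"),
       truth = attr(pair, "truth"))
}

#' Write a synthetic dataset in the canonical file formats
#'
#' Emits `census1.csv`, `census2.csv`, `species.csv`, `tree.nwk` and the
#' truth tables, so file-based workflows consume synthetic data exactly
#' like real plot exports.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_census_table(dataset$pair$census1, file.path(dir, "census1.csv"))
  write_census_table(dataset$pair$census2, file.path(dir, "census2.csv"))
  utils::write.table(dataset$species_table, file.path(dir, "species.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.table(dataset$truth$stems, file.path(dir, "truth_stems.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$truth$recruits))
    utils::write.table(dataset$truth$recruits,
                       file.path(dir, "truth_recruits.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
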