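test_that("survival table tabulates rates per species and size class", {
  c1 <- data.frame(tag = as.character(1:14),
                   species = c(rep("sp1", 10), rep("sp2", 4)),
                   x = 1, y = 1,
                   dbh = c(rep(1.5, 10), rep(30, 4)),
                   status = "alive", stringsAsFactors = FALSE)
  c2 <- c1
  c2$status[c(1, 2)] <- "dead"; c2$dbh[c(1, 2)] <- NA  # 8/10 sp1 survive
  pair <- census_pair(c1, c2, c(10, 10))
  st <- estimate_survival_table(pair)
  expect_equal(st$rate[st$species == "sp1"], 0.8)
  expect_equal(st$rate[st$species == "sp2"], 1.0)
  expect_equal(st$n[st$species == "sp1"], 10)
  # the 30 cm stems land in the 25-35 class
  expect_match(as.character(st$size_class[st$species == "sp2"]), "25,35")
})

test_that("two-species NM-I permutations are uniform over {identity, swap}", {
  set.seed(17)
  swaps <- replicate(499, nm1_permutation(c("a", "b"))[["a"]] == "b")
  chisq <- stats::chisq.test(table(factor(swaps, c(FALSE, TRUE))))
  expect_gt(chisq$p.value, 0.001)
})

test_that("dispersal measurement finds the nearest conspecific mature stem", {
  c1 <- data.frame(tag = c("m1", "m2", "far"),
                   species = c("sp1", "sp1", "sp2"),
                   x = c(10, 20, 100), y = c(10, 10, 100),
                   dbh = c(20, 20, 20), status = "alive",
                   stringsAsFactors = FALSE)
  c2 <- rbind(c1,
              data.frame(tag = c("r1", "r2"), species = c("sp1", "sp2"),
                         x = c(13, 10), y = c(10, 10), dbh = c(1.5, 1.5),
                         status = "alive", stringsAsFactors = FALSE))
  pair <- census_pair(c1, c2, c(200, 200))
  spt <- data.frame(species = c("sp1", "sp2"), growth_form = "tree",
                    stringsAsFactors = FALSE)
  rec <- measure_dispersal(pair, spt)
  expect_equal(rec$dp[rec$tag == "r1"], 3)          # nearest of two matures
  expect_true(is.na(rec$dp[rec$tag == "r2"]))       # conspecific 127 m away
  # growth-form gate: immature stems are not parents
  c1b <- c1; c1b$dbh <- 10                          # below the 15 cm tree bar
  rec2 <- measure_dispersal(census_pair(c1b, c2, c(200, 200)), spt)
  expect_true(all(is.na(rec2$dp)))
  # missing growth form errors
  expect_error(measure_dispersal(pair, spt[1, ]), "without growth form")
})

test_that("dispersal distances match an exhaustive nearest-neighbour scan", {
  ds <- small_dataset()
  rec <- measure_dispersal(ds$pair, ds$species_table)
  c1 <- ds$pair$census1
  gf <- setNames(ds$species_table$growth_form, ds$species_table$species)
  thr <- ifelse(gf[c1$species] == "tree", 15, 5)
  mature <- c1[c1$status == "alive" & c1$dbh >= thr, ]
  idx <- sample(nrow(rec), 50)
  for (i in idx) {
    m <- mature[mature$species == rec$species[i], ]
    expect_equal(rec$dp[i],
                 bf_nearest_mature(rec$x[i], rec$y[i], m$x, m$y, 50))
  }
})

test_that("NM-II conserves demography and honors recorded distances", {
  ds <- small_dataset()
  model <- nm2_prepare(ds$pair, ds$species_table)
  demo <- classify_demographics(ds$pair)
  c1 <- ds$pair$census1
  obs_deaths <- table(c1$species[c1$tag %in% demo$deaths])
  gf <- setNames(ds$species_table$growth_form, ds$species_table$species)
  thr <- ifelse(gf[c1$species] == "tree", 15, 5)
  mature <- c1[c1$status == "alive" & c1$dbh >= thr, ]
  set.seed(99)
  for (r in 1:5) {
    sim <- nm2_replicate(model)
    # per-species alive counts at census 2 match observation exactly
    obs2 <- table(ds$pair$census2$species[ds$pair$census2$status == "alive"])
    sim2 <- table(sim$species)
    expect_equal(sim2[names(obs2)], obs2, ignore_attr = TRUE)
    # per-species simulated deaths equal observed deaths
    simdead <- table(factor(c1$species[!(c1$tag %in% sim$tag)],
                            names(obs_deaths)))
    expect_equal(unname(simdead), unname(obs_deaths), ignore_attr = TRUE)
    # recruits with a Dp sit exactly Dp from some conspecific mature stem
    log <- attr(sim, "placement_log")
    if (log$n_fallback_uniform == 0) {
      recs <- model$recruits[!is.na(model$recruits$dp), ]
      pos <- sim[match(recs$tag, sim$tag), ]
      for (i in sample(nrow(recs), 25)) {
        m <- mature[mature$species == recs$species[i], ]
        d <- sqrt((m$x - pos$x[i])^2 + (m$y - pos$y[i])^2)
        expect_lt(min(abs(d - recs$dp[i])), 1e-6)
      }
    }
  }
})

test_that("cells with survival rate 1 never lose stems", {
  ds <- small_dataset()
  st <- estimate_survival_table(ds$pair)
  full <- st[st$rate == 1 & st$n >= 3, ][1, ]
  model <- nm2_prepare(ds$pair, ds$species_table)
  c1a <- model$alive1
  cls <- cut(c1a$dbh, model$config$size_class_edges, right = FALSE)
  in_cell <- c1a$species == full$species & cls == full$size_class
  set.seed(12)
  for (r in 1:5) {
    sim <- nm2_replicate(model)
    expect_true(all(c1a$tag[in_cell] %in% sim$tag))
  }
})

test_that("survival estimates recover the generator's rates", {
  # neutral generator: survival depends only on species baseline and size
  ds <- small_dataset()
  truth <- ds$truth$stems
  st <- estimate_survival_table(ds$pair)
  c1 <- ds$pair$census1
  cls <- cut(c1$dbh, c(1:20, 25, 35, 45, 55, Inf), right = FALSE)
  key_stem <- paste(c1$species, cls)
  key_cell <- paste(st$species, st$size_class)
  exp_surv <- tapply(truth$p_surv[match(c1$tag, truth$tag)], key_stem, sum)
  var_surv <- tapply(truth$p_surv * (1 - truth$p_surv), key_stem, sum)
  big <- st$n >= 10
  for (i in which(big)) {
    mu <- exp_surv[[key_cell[i]]]
    sd3 <- 3.5 * sqrt(var_surv[[key_cell[i]]]) + 1
    expect_lt(abs(st$n_surv[i] - mu), sd3)
  }
})
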