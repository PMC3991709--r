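test_that("Rao turnover handles the elementary cases", {
  D <- matrix(c(0, 10, 10, 0), 2, 2)
  expect_equal(rao_turnover(c(1, 0), c(1, 0), D), 0)      # same monoculture
  expect_equal(rao_turnover(c(1, 0), c(0, 1), D), 10)     # single cross pair
  expect_equal(rao_turnover(c(.5, .5), c(.5, .5), D), 5)
  expect_error(rao_turnover(c(0, 0), c(1, 0), D), "empty")
  expect_error(rao_turnover(c(.4, .4), c(1, 0), D), "sum to 1")
})

test_that("Rao turnover equals the exhaustive individual-pair expectation", {
  set.seed(31)
  for (i in 1:50) {
    ns <- sample(2:6, 1)
    D <- matrix(runif(ns^2, 0, 20), ns, ns)
    D <- (D + t(D)) / 2; diag(D) <- 0
    cA <- rpois(ns, 3) + (seq_len(ns) == 1)  # guarantee non-empty
    cB <- rpois(ns, 3) + (seq_len(ns) == ns)
    pA <- cA / sum(cA); pB <- cB / sum(cB)
    expect_equal(rao_turnover(pA, pB, D), bf_rao(cA, cB, D),
                 tolerance = 1e-12)
    # time symmetry
    expect_equal(rao_turnover(pA, pB, D), rao_turnover(pB, pA, D))
    # bounded by the largest pairwise distance
    expect_lte(rao_turnover(pA, pB, D), max(D))
  }
})

test_that("standardized effect size follows the n-1 convention and flags degeneracy", {
  expect_equal(ses_value(5, c(2, 3, 4)), (5 - 3) / sd(c(2, 3, 4)))
  degen <- ses_value(3, rep(3, 10))
  expect_true(is.na(degen))
  expect_equal(attr(degen, "flag"), "degenerate_null")
  expect_error(ses_value(1, c(2)), "at least 2")
  # large-sample behaviour: obs at the null mean gives ses near 0
  set.seed(41)
  expect_lt(abs(ses_value(0, rnorm(1e4))), 0.05)
})

test_that("an identity null model yields degenerate flags everywhere", {
  # no deaths, no recruits: NM-II is the identity on census 2
  c1 <- data.frame(tag = letters[1:6],
                   species = rep(c("sp1", "sp2"), 3),
                   x = c(1, 2, 3, 11, 12, 13), y = rep(2, 6),
                   dbh = rep(c(20, 6), 3), status = "alive",
                   stringsAsFactors = FALSE)
  pair <- census_pair(c1, c1, c(20, 10))
  tree <- ape::read.tree(text = "(sp1:1,sp2:1);")
  spt <- data.frame(species = c("sp1", "sp2"),
                    growth_form = c("tree", "shrub"),
                    stringsAsFactors = FALSE)
  g <- quadrat_grid(c(20, 10), 10)
  res <- turnover_analysis(pair, tree, g, null_model = "nm2", n_rep = 20,
                           seed = 3, species_table = spt)
  expect_true(all(res$flag == "degenerate_null"))
  expect_true(all(is.na(res$ses_raod)))
})

test_that("a single-species plot under NM-I is degenerate with zero RaoD", {
  c1 <- data.frame(tag = c("a", "b"), species = "sp1", x = c(1, 2),
                   y = c(1, 2), dbh = 5, status = "alive",
                   stringsAsFactors = FALSE)
  pair <- census_pair(c1, c1, c(10, 10))
  tree <- ape::read.tree(text = "(sp1:1,sp2:1);")
  g <- quadrat_grid(c(10, 10), 10)
  res <- turnover_analysis(pair, tree, g, null_model = "nm1", n_rep = 10,
                           seed = 1)
  expect_equal(res$raod_obs, 0)
  expect_equal(res$flag, "degenerate_null")
})

test_that("NM-I nulls are equivariant under species relabeling", {
  # relabeling species in the data only permutes which null replicate sees
  # which distance matrix; the multiset of null RaoD values is unchanged
  ds <- small_dataset()
  g <- quadrat_grid(ds$pair$plot_dims, 50)
  res <- turnover_analysis(ds$pair, ds$tree, g, null_model = "nm1",
                           n_rep = 199, seed = 9)
  # relabel: swap two species everywhere (data and tree tips)
  sp <- species_pool(ds$pair)
  swap <- setNames(sp, sp)
  swap[c(sp[1], sp[2])] <- c(sp[2], sp[1])
  pair2 <- ds$pair
  pair2$census1$species <- unname(swap[pair2$census1$species])
  pair2$census2$species <- unname(swap[pair2$census2$species])
  res2 <- turnover_analysis(pair2, ds$tree, g, null_model = "nm1",
                            n_rep = 199, seed = 9)
  ok <- res$flag == "ok" & res2$flag == "ok"
  # the null ensembles estimate the same distribution: means agree within
  # Monte-Carlo error (4 standard errors)
  mc_se <- sqrt(res$null_sd[ok]^2 + res2$null_sd[ok]^2) / sqrt(199)
  expect_true(all(abs(res$null_mean[ok] - res2$null_mean[ok]) < 4 * mc_se))
})

test_that("turnover results are reproducible for a fixed seed", {
  ds <- small_dataset()
  g <- quadrat_grid(ds$pair$plot_dims, 50)
  a <- turnover_analysis(ds$pair, ds$tree, g, null_model = "nm2", n_rep = 19,
                         seed = 5, species_table = ds$species_table)
  b <- turnover_analysis(ds$pair, ds$tree, g, null_model = "nm2", n_rep = 19,
                         seed = 5, species_table = ds$species_table)
  expect_identical(a, b)
})
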