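test_that("census tables round-trip through the canonical dialect", {
  ds <- small_dataset()
  f <- tempfile(fileext = ".csv")
  write_census_table(ds$pair$census1, f)
  back <- read_census_table(f, ds$pair$plot_dims)
  expect_equal(back, ds$pair$census1, ignore_attr = TRUE)
  # byte stability: write the re-read table and compare the files
  f2 <- tempfile(fileext = ".csv")
  write_census_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # gzip round trip
  fz <- tempfile(fileext = ".csv.gz")
  write_census_table(ds$pair$census1, fz)
  expect_equal(read_census_table(fz, ds$pair$plot_dims), ds$pair$census1,
               ignore_attr = TRUE)
})

test_that("reader validates coordinates, tags, status and DBH", {
  f <- tempfile(fileext = ".csv")
  base <- data.frame(tag = c("a", "b", "c"), species = "sp1",
                     x = c(1, 2, 3), y = c(1, 2, 3), dbh = 5,
                     status = "Alive", stringsAsFactors = FALSE)
  write.csv(base, f, row.names = FALSE)
  got <- read_census_table(f, c(10, 10))
  expect_equal(nrow(got), 3)
  expect_equal(got$status, rep("alive", 3))  # case-normalized

  bad <- base; bad$x[2] <- 10.1
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_census_table(f, c(10, 10)), "outside plot")

  bad <- base; bad$tag[2] <- "a"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_census_table(f, c(10, 10)), "duplicate tag")

  bad <- base; bad$status[1] <- "zombie"
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_census_table(f, c(10, 10)), "unrecognized status")

  bad <- base; bad$dbh[1] <- NA
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_census_table(f, c(10, 10)), "without DBH")

  bad <- base; bad$dbh[1] <- 0.5
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_census_table(f, c(10, 10)), "DBH < 1")

  # column mapping for foreign schemas
  foreign <- base
  names(foreign)[names(foreign) == "tag"] <- "TreeID"
  write.csv(foreign, f, row.names = FALSE)
  expect_error(read_census_table(f, c(10, 10)), "missing column")
  got <- read_census_table(f, c(10, 10), col_map = c(tag = "TreeID"))
  expect_equal(got$tag, c("a", "b", "c"))
})

test_that("demographic classification partitions tags correctly", {
  d <- classify_demographics(tiny_pair())
  expect_equal(d$survivors, "A")
  expect_equal(d$deaths, "B")
  expect_equal(d$recruits, "C")

  # identical censuses: no deaths, no recruits
  c1 <- tiny_pair()$census1
  same <- census_pair(c1, c1, c(10, 10))
  d2 <- classify_demographics(same)
  expect_length(d2$deaths, 0)
  expect_length(d2$recruits, 0)
  expect_setequal(d2$survivors, c1$tag)

  # dead stem resurrected -> data-consistency error
  c1z <- data.frame(tag = "Z", species = "sp1", x = 1, y = 1, dbh = NA,
                    status = "dead", stringsAsFactors = FALSE)
  c2z <- data.frame(tag = "Z", species = "sp1", x = 1, y = 1, dbh = 2,
                    status = "alive", stringsAsFactors = FALSE)
  expect_error(classify_demographics(census_pair(c1z, c2z, c(10, 10))),
               "dead in census 1 but alive")
})

test_that("partition counts and generator truth labels agree on synthetic data", {
  ds <- small_dataset()
  d <- classify_demographics(ds$pair)
  alive1 <- sum(ds$pair$census1$status == "alive")
  alive2 <- sum(ds$pair$census2$status == "alive")
  expect_equal(length(d$survivors) + length(d$deaths), alive1)
  expect_equal(length(d$survivors) + length(d$recruits), alive2)
  truth <- ds$truth$stems
  expect_setequal(d$deaths, truth$tag[truth$died])
  expect_setequal(d$survivors, truth$tag[!truth$died])
  expect_setequal(d$recruits, ds$truth$recruits$tag)
})

test_that("species absent from the phylogeny error unless pruned", {
  ds <- small_dataset()
  tree <- ape::drop.tip(ds$tree, ds$tree$tip.label[1])
  g <- quadrat_grid(ds$pair$plot_dims, 20)
  expect_error(turnover_analysis(ds$pair, tree, g, null_model = "nm1",
                                 n_rep = 5),
               "absent from the phylogeny")
  expect_message(
    res <- turnover_analysis(ds$pair, tree, g, null_model = "nm1",
                             n_rep = 5, prune_missing = TRUE),
    "pruning")
  expect_s3_class(res, "turnover_result")
})
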