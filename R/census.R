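#' Read a census table of mapped stems
#'
#' Reads a delimited (comma or tab, optionally gzipped) stem table with
#' columns `tag`, `species`, `x`, `y`, `dbh` and `status`, and validates it
#' against the plot dimensions.  Coordinates are in metres from the plot's
#' lower-left corner; DBH is in centimetres; `status` is one of `alive`,
#' `dead` or `absent` (case-insensitive).  Alive stems must carry a DBH of
#' at least 1 cm, the usual census inclusion threshold; dead or absent
#' records may have missing DBH.
#'
#' @param path path to a CSV/TSV file (may end in `.gz`).
#' @param plot_dims numeric length-2, plot width and height in metres.
#' @param col_map optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(tag = "TreeID", dbh = "DBH_cm")`, for plot networks with other
#'   export schemas.
#' @return a `data.frame` with the canonical columns, one row per stem.
#' @seealso [census_pair()], [write_census_table()]
#' @export
read_census_table <- function(path, plot_dims, col_map = NULL) {
  stopifnot(is.numeric(plot_dims), length(plot_dims) == 2, all(plot_dims > 0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("empty census file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = TRUE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (is.na(j)) stop("mapped column '", col_map[[canon]], "' not found")
      names(df)[j] <- canon
    }
  }
  needed <- c("tag", "species", "x", "y", "dbh", "status")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("census table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[needed]
  df$tag <- as.character(df$tag)
  df$species <- as.character(df$species)
  for (col in c("x", "y", "dbh")) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(v <- as.numeric(df[[col]]))
      bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
      if (length(bad)) stop("malformed '", col, "' at data line ", bad[1])
      df[[col]] <- v
    }
  }
  df$status <- tolower(trimws(df$status))
  bad_status <- setdiff(unique(df$status), c("alive", "dead", "absent"))
  if (length(bad_status))
    stop("unrecognized status code(s): ", paste(bad_status, collapse = ", "))
  dup <- df$tag[duplicated(df$tag)]
  if (length(dup)) stop("duplicate tag(s): ", paste(unique(dup)[1:min(3, length(dup))],
                                                   collapse = ", "))
  bad <- which(is.na(df$x) | is.na(df$y))
  if (length(bad)) stop("missing coordinates at data line ", bad[1])
  out_x <- which(df$x < 0 | df$x > plot_dims[1])
  out_y <- which(df$y < 0 | df$y > plot_dims[2])
  if (length(out_x)) stop("x coordinate outside plot at data line ", out_x[1],
                          " (x = ", df$x[out_x[1]], ")")
  if (length(out_y)) stop("y coordinate outside plot at data line ", out_y[1],
                          " (y = ", df$y[out_y[1]], ")")
  alive <- df$status == "alive"
  if (any(alive & is.na(df$dbh)))
    stop("alive stem without DBH at data line ", which(alive & is.na(df$dbh))[1])
  if (any(alive & df$dbh < 1))
    stop("alive stem with DBH < 1 cm (census threshold) at data line ",
         which(alive & df$dbh < 1)[1])
  df
}

#' Write a census table in the canonical dialect
#'
#' Plain CSV, header, no quoting, no row names.  The canonical dialect is
#' byte-stable under read/write round trips.
#'
#' @param stems data.frame as returned by [read_census_table()].
#' @param path output path (`.gz` suffix writes gzip).
#' @export
write_census_table <- function(stems, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(stems, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Pair two censuses of the same plot
#'
#' @param census1,census2 stem tables (see [read_census_table()]).
#' @param plot_dims numeric length-2 plot dimensions in metres.
#' @param dates labels for the two censuses.
#' @return an object of class `census_pair`.
#' @export
census_pair <- function(census1, census2, plot_dims,
                        dates = c("census1", "census2")) {
  for (cen in list(census1, census2)) {
    stopifnot(all(c("tag", "species", "x", "y", "dbh", "status") %in%
                    names(cen)))
    if (anyDuplicated(cen$tag)) stop("duplicate tags within a census")
  }
  obj <- list(census1 = census1, census2 = census2,
              plot_dims = as.numeric(plot_dims),
              dates = as.character(dates))
  class(obj) <- "census_pair"
  obj
}

#' @export
print.census_pair <- function(x, ...) {
  d <- classify_demographics(x)
  cat(sprintf("census_pair: %g x %g m plot, censuses '%s' -> '%s'\n",
              x$plot_dims[1], x$plot_dims[2], x$dates[1], x$dates[2]))
  cat(sprintf("  alive at %s: %d; alive at %s: %d\n", x$dates[1],
              length(d$survivors) + length(d$deaths), x$dates[2],
              length(d$survivors) + length(d$recruits)))
  cat(sprintf("  survivors %d, deaths %d, recruits %d\n",
              length(d$survivors), length(d$deaths), length(d$recruits)))
  invisible(x)
}

#' Classify stems into survivors, deaths and recruits
#'
#' Survivors are alive in both censuses; deaths are alive in the first and
#' dead or absent in the second; recruits are alive in the second and absent
#' from the first (they crossed the 1 cm DBH threshold during the interval).
#' The partition is exhaustive and disjoint over tags alive in either
#' census.
#'
#' @param pair a [census_pair()].
#' @return list with character vectors `survivors`, `deaths`, `recruits`.
#' @export
classify_demographics <- function(pair) {
  stopifnot(inherits(pair, "census_pair"))
  c1 <- pair$census1; c2 <- pair$census2
  alive1 <- c1$tag[c1$status == "alive"]
  alive2 <- c2$tag[c2$status == "alive"]
  dead1 <- c1$tag[c1$status %in% c("dead")]
  zombie <- intersect(dead1, alive2)
  if (length(zombie))
    stop("stem(s) dead in census 1 but alive in census 2: ",
         paste(zombie[1:min(3, length(zombie))], collapse = ", "))
  survivors <- intersect(alive1, alive2)
  list(survivors = survivors,
       deaths = setdiff(alive1, alive2),
       recruits = setdiff(alive2, alive1))
}

#' Species alive in either census
#'
#' @param pair a [census_pair()].
#' @return sorted character vector of species codes.
#' @export
species_pool <- function(pair) {
  c1 <- pair$census1; c2 <- pair$census2
  sort(unique(c(c1$species[c1$status == "alive"],
                c2$species[c2$status == "alive"])))
}

#' Read a species table (growth forms and traits)
#'
#' CSV with a `species` column, an optional `growth_form` column
#' (`tree` or `shrub`; required by the demographic null model), and any
#' number of numeric trait columns.
#'
#' @param path path to a CSV file (may be gzipped).
#' @return data.frame keyed by `species`.
#' @export
read_species_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE, quote = "\"")
  if (!"species" %in% names(df)) stop("species table needs a 'species' column")
  if (anyDuplicated(df$species)) stop("duplicate species in species table")
  if ("growth_form" %in% names(df)) {
    df$growth_form <- tolower(trimws(df$growth_form))
    bad <- setdiff(unique(df$growth_form), c("tree", "shrub"))
    if (length(bad)) stop("growth_form must be 'tree' or 'shrub'; got: ",
                          paste(bad, collapse = ", "))
  }
  df
}

# Check that every species alive in the pair has a tip in the phylogeny.
# prune = TRUE drops offending stems (with a message); the default errors,
# because silently pruning distorts abundances.
.check_species_coverage <- function(pair, tree, prune = FALSE) {
  pool <- species_pool(pair)
  missing <- setdiff(pool, tree$tip.label)
  if (!length(missing)) return(pair)
  if (!prune)
    stop(length(missing), " species absent from the phylogeny (e.g. ",
         paste(missing[1:min(3, length(missing))], collapse = ", "),
         "); use prune = TRUE to drop them explicitly")
  message("pruning ", length(missing), " species absent from the phylogeny")
  for (nm in c("census1", "census2"))
    pair[[nm]] <- pair[[nm]][!pair[[nm]]$species %in% missing, , drop = FALSE]
  pair
}
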