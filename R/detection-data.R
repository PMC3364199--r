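#' Build a multi-species detection dataset from raw camera-trap records
#'
#' Collapses raw photo records into per-species, per-station detection
#' histories. A station's daily occasions are summarised as a binomial count:
#' `y[i, j]` is the number of distinct calendar days, within station `j`'s
#' deployment window, on which species `i` was photographed, out of `k[j]`
#' trap-days. Collapsing days to a count is likelihood-equivalent to keeping
#' the daily history because all detection covariates are station-level
#' constants.
#'
#' @param detections data frame with columns `station_id`, `species`,
#'   `timestamp` (ISO-8601 date-time or date).
#' @param deployments data frame with columns `station_id`, `x_km`, `y_km`,
#'   `start_date`, `end_date`, and binary design covariates `on_road`,
#'   `paired`, `team`, and optionally `season` (derived from the deployment
#'   window via [assign_season()] when absent).
#' @param species optional character vector declaring the community. Species
#'   present in `detections` but absent from this list are an error: the
#'   model assumes every community member was detected at least once, so an
#'   undeclared species signals a data problem, not a modelling choice.
#' @return an object of class `detection_dataset`: a list with elements
#'   `species` (N names), `sites` (J station ids), `y` (N x J integer matrix
#'   of detection days), `k` (J trap-days), `design` (J x 4 binary matrix:
#'   on_road, paired, team, season) and `coords` (J x 2 matrix, km).
#' @examples
#' dep <- data.frame(station_id = "s1", x_km = 0, y_km = 0,
#'                   start_date = "2007-01-01", end_date = "2007-01-10",
#'                   on_road = 1, paired = 0, team = 1)
#' det <- data.frame(station_id = "s1", species = "genet",
#'                   timestamp = "2007-01-03 21:10:00")
#' d <- build_detection_dataset(det, dep)
#' d$y
#' @export
build_detection_dataset <- function(detections, deployments, species = NULL) {
  req_dep <- c("station_id", "x_km", "y_km", "start_date", "end_date",
               "on_road", "paired", "team")
  missing_cols <- setdiff(req_dep, names(deployments))
  if (length(missing_cols))
    fail("deployments lacks column(s): %s", paste(missing_cols, collapse = ", "))

  dep <- deployments
  dep$start_date <- as.Date(dep$start_date)
  dep$end_date <- as.Date(dep$end_date)
  if (anyNA(dep$start_date) || anyNA(dep$end_date))
    fail("unparseable deployment dates")
  if (any(dep$end_date < dep$start_date))
    fail("deployment with end_date before start_date: %s",
         paste(dep$station_id[dep$end_date < dep$start_date], collapse = ", "))
  if (anyDuplicated(dep$station_id))
    fail("duplicated station_id in deployments")
  if (!all(is.finite(dep$x_km)) || !all(is.finite(dep$y_km)))
    fail("non-finite station coordinates")
  for (v in c("on_road", "paired", "team"))
    if (!is_binary01(dep[[v]])) fail("design covariate '%s' must be 0/1", v)

  if (is.null(dep$season)) {
    dep$season <- vapply(seq_len(nrow(dep)), function(r)
      assign_season(dep$start_date[r], dep$end_date[r]), numeric(1))
  } else if (!is_binary01(dep$season)) fail("design covariate 'season' must be 0/1")

  sites <- as.character(dep$station_id)
  J <- length(sites)
  # trap-day = calendar day; partial first/last days count as full days
  k <- as.integer(dep$end_date - dep$start_date) + 1L

  if (nrow(detections) > 0) {
    det <- detections
    det$station_id <- as.character(det$station_id)
    det$species <- as.character(det$species)
    ts <- as.POSIXct(det$timestamp, tz = "UTC")
    if (anyNA(ts)) fail("unparseable detection timestamp(s)")
    det$day <- as.Date(ts)
    unknown <- setdiff(det$station_id, sites)
    if (length(unknown))
      fail("detection at unknown station_id: %s", paste(unique(unknown), collapse = ", "))
    idx <- match(det$station_id, sites)
    bad <- det$day < dep$start_date[idx] | det$day > dep$end_date[idx]
    if (any(bad)) {
      b <- which(bad)[1]
      fail("detection outside deployment window: station %s, species %s, %s",
           det$station_id[b], det$species[b], format(det$day[b]))
    }
    seen <- sort(unique(det$species))
  } else {
    det <- NULL
    seen <- character(0)
  }

  if (is.null(species)) {
    species <- seen
  } else {
    species <- as.character(species)
    extra <- setdiff(seen, species)
    if (length(extra))
      fail("species detected but not declared in species list: %s",
           paste(extra, collapse = ", "))
  }
  N <- length(species)

  y <- matrix(0L, nrow = N, ncol = J, dimnames = list(species, sites))
  if (!is.null(det) && N > 0) {
    # distinct detection days per species x station
    u <- unique(det[, c("species", "station_id", "day")])
    tab <- table(factor(u$species, levels = species),
                 factor(u$station_id, levels = sites))
    y[] <- as.integer(tab)
  }

  design <- cbind(on_road = dep$on_road, paired = dep$paired,
                  team = dep$team, season = dep$season)
  rownames(design) <- sites
  coords <- cbind(x = dep$x_km, y = dep$y_km)
  rownames(coords) <- sites

  new_detection_dataset(species, sites, y, k, design, coords)
}

# Internal constructor with invariant checks
new_detection_dataset <- function(species, sites, y, k, design, coords) {
  if (any(y < 0) || any(y > rep(k, each = nrow(y))))
    fail("invalid detection counts: need 0 <= y(i,j) <= k_j")
  structure(list(species = species, sites = sites, y = y,
                 k = as.integer(k), design = design, coords = coords),
            class = "detection_dataset")
}

#' @export
print.detection_dataset <- function(x, ...) {
  cat(sprintf("detection_dataset: %d species x %d sites, %d trap-days total\n",
              length(x$species), length(x$sites), sum(x$k)))
  invisible(x)
}

#' Naive occupancy (fraction of sites with at least one detection)
#'
#' The uncorrected occurrence measure: for each species, the proportion of
#' stations at which it was photographed at least once. Biased low whenever
#' per-occasion detection probability is below one.
#'
#' @param data a `detection_dataset`.
#' @return named numeric vector in `[0, 1]`, one entry per species.
#' @export
naive_occupancy <- function(data) {
  stopifnot(inherits(data, "detection_dataset"))
  J <- length(data$sites)
  if (J < 1) fail("need at least one site")
  rowSums(data$y >= 1) / J
}

#' Classify a deployment window as dry or wet season
#'
#' The median calendar date of the deployment window determines the season:
#' dry (1) when it falls in October through April, wet (0) when in May
#' through September.
#'
#' @param start_date,end_date deployment window bounds (coercible to Date).
#' @return 1 (dry) or 0 (wet).
#' @examples
#' assign_season("2007-12-01", "2007-12-20") # dry
#' assign_season("2007-06-01", "2007-06-30") # wet
#' @export
assign_season <- function(start_date, end_date) {
  s <- as.Date(start_date); e <- as.Date(end_date)
  if (is.na(s) || is.na(e) || e < s) fail("invalid deployment window")
  days <- seq(s, e, by = "day")
  med <- stats::median(days)
  m <- as.integer(format(med, "%m"))
  if (m >= 10 || m <= 4) 1 else 0
}

#' Write a detection dataset to its tabular interchange format
#'
#' Two CSV files: a wide species-by-site matrix of detection-day counts, and
#' a site-attribute table carrying effort, design covariates and coordinates.
#'
#' @param data a `detection_dataset`.
#' @param y_file path for the species x site count matrix CSV.
#' @param sites_file path for the site attribute CSV.
#' @export
write_detection_dataset <- function(data, y_file, sites_file) {
  stopifnot(inherits(data, "detection_dataset"))
  ydf <- data.frame(species = data$species, data$y, check.names = FALSE)
  utils::write.csv(ydf, y_file, row.names = FALSE)
  sdf <- data.frame(station_id = data$sites, x_km = data$coords[, 1],
                    y_km = data$coords[, 2], k = data$k,
                    data$design, check.names = FALSE)
  utils::write.csv(sdf, sites_file, row.names = FALSE)
  invisible(data)
}

#' Read a detection dataset from its tabular interchange format
#'
#' @param y_file,sites_file paths written by [write_detection_dataset()].
#' @return a `detection_dataset`.
#' @export
read_detection_dataset <- function(y_file, sites_file) {
  ydf <- utils::read.csv(y_file, check.names = FALSE)
  sdf <- utils::read.csv(sites_file, check.names = FALSE)
  species <- as.character(ydf$species)
  y <- as.matrix(ydf[, -1, drop = FALSE])
  storage.mode(y) <- "integer"
  sites <- as.character(sdf$station_id)
  if (!identical(colnames(y), sites))
    fail("site ids disagree between the count matrix and site table")
  rownames(y) <- species
  design <- as.matrix(sdf[, c("on_road", "paired", "team", "season")])
  rownames(design) <- sites
  coords <- cbind(x = sdf$x_km, y = sdf$y_km)
  rownames(coords) <- sites
  new_detection_dataset(species, sites, y, as.integer(sdf$k), design, coords)
}
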