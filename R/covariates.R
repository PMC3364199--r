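#' Minimum Euclidean distance from sites to a feature geometry
#'
#' Distance from each site to the nearest point of a set of polylines or
#' polygon boundaries, in km. Coordinates are assumed planar (km); projecting
#' geographic coordinates is the caller's responsibility.
#'
#' @param coords two-column matrix/data frame of site coordinates (km).
#' @param feature a geometry: either a list of two-column coordinate
#'   matrices (each a polyline; polygons should be closed rings), or the
#'   result of [read_feature_geojson()].
#' @return numeric vector of distances (>= 0), one per site.
#' @export
distance_to_feature <- function(coords, feature) {
  if (is.matrix(feature) || is.data.frame(feature)) feature <- list(as.matrix(feature))
  if (length(feature) == 0) fail("empty feature geometry")
  coords <- as.matrix(coords)
  apply(coords, 1, function(pt) {
    dmin <- Inf
    for (part in feature) {
      part <- as.matrix(part)
      if (nrow(part) == 0) next
      if (nrow(part) == 1) {
        dmin <- min(dmin, sqrt(sum((pt - part[1, ])^2)))
      } else {
        dmin <- min(dmin, min(point_segments_dist(pt, part)))
      }
    }
    if (!is.finite(dmin)) fail("empty feature geometry")
    dmin
  })
}

# Internal: distances from a point to each segment of a polyline (vectorized)
point_segments_dist <- function(pt, verts) {
  a <- verts[-nrow(verts), , drop = FALSE]
  b <- verts[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  ap <- cbind(pt[1] - a[, 1], pt[2] - a[, 2])
  t <- rowSums(ap * ab) / pmax(len2, .Machine$double.eps)
  t <- pmin(pmax(t, 0), 1)
  proj <- a + ab * t
  sqrt((pt[1] - proj[, 1])^2 + (pt[2] - proj[, 2])^2)
}

#' Read polyline/polygon geometry from a GeoJSON file
#'
#' Supports LineString, MultiLineString, Polygon and MultiPolygon geometries
#' (bare, as Features, or in a FeatureCollection). Polygon rings are returned
#' as closed polylines, so distances computed against them are distances to
#' the boundary.
#'
#' @param path GeoJSON file.
#' @return list of two-column coordinate matrices.
#' @export
read_feature_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  parts <- list()
  add_geom <- function(geom) {
    ring <- function(r) do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    switch(geom$type,
      LineString = parts[[length(parts) + 1]] <<- ring(geom$coordinates),
      MultiLineString = for (l in geom$coordinates)
        parts[[length(parts) + 1]] <<- ring(l),
      Polygon = for (r in geom$coordinates)
        parts[[length(parts) + 1]] <<- ring(r),
      MultiPolygon = for (poly in geom$coordinates) for (r in poly)
        parts[[length(parts) + 1]] <<- ring(r),
      fail("unsupported GeoJSON geometry type: %s", geom$type))
  }
  walk <- function(node) {
    if (is.null(node$type)) return()
    if (node$type == "FeatureCollection") lapply(node$features, walk)
    else if (node$type == "Feature") add_geom(node$geometry)
    else add_geom(node)
  }
  walk(g)
  if (length(parts) == 0) fail("no supported geometries in %s", path)
  parts
}

#' Camera-based prey biomass index
#'
#' Converts prey photo records into a per-station catch-per-unit-effort index
#' of prey biomass, in kg per 100 trap-days. Consecutive photos of the same
#' species at the same station taken less than `dedup_minutes` apart are
#' collapsed into a single detection (a chain rule: each photo within the
#' window of the previous one extends the same event).
#'
#' @param prey_detections data frame with `station_id`, `species`, `timestamp`.
#' @param deployments deployment data frame (same format as
#'   [build_detection_dataset()]); supplies the effort `k_j`.
#' @param body_mass named numeric vector, average adult body mass in kg per
#'   prey species. A species in the records but absent here is an error.
#' @param mass_cutoff optional kg threshold; when given, only species with
#'   mass strictly below it contribute (18 kg separates small prey).
#' @param dedup_minutes deduplication window in minutes (default 5).
#' @return named numeric vector, kg per 100 trap-days per station.
#' @export
camera_prey_biomass <- function(prey_detections, deployments, body_mass,
                                mass_cutoff = NULL, dedup_minutes = 5) {
  sites <- as.character(deployments$station_id)
  k <- as.integer(as.Date(deployments$end_date) - as.Date(deployments$start_date)) + 1L
  out <- stats::setNames(rep(0, length(sites)), sites)
  if (nrow(prey_detections) == 0) return(out)

  det <- prey_detections
  det$station_id <- as.character(det$station_id)
  det$species <- as.character(det$species)
  det$time <- as.POSIXct(det$timestamp, tz = "UTC")
  missing_mass <- setdiff(unique(det$species), names(body_mass))
  if (length(missing_mass))
    fail("no body mass for prey species: %s", paste(missing_mass, collapse = ", "))
  unknown <- setdiff(det$station_id, sites)
  if (length(unknown))
    fail("prey detection at unknown station_id: %s",
         paste(unique(unknown), collapse = ", "))

  if (!is.null(mass_cutoff))
    det <- det[body_mass[det$species] < mass_cutoff, , drop = FALSE]
  if (nrow(det) == 0) return(out)

  det <- det[order(det$station_id, det$species, det$time), ]
  grp <- paste(det$station_id, det$species, sep = "\r")
  gap <- c(Inf, as.numeric(diff(det$time), units = "mins"))
  gap[c(TRUE, grp[-1] != grp[-length(grp)])] <- Inf
  keep <- det[gap >= dedup_minutes, , drop = FALSE]

  mass <- body_mass[keep$species]
  per_site <- tapply(mass, factor(keep$station_id, levels = sites), sum)
  per_site[is.na(per_site)] <- 0
  out[] <- as.numeric(per_site) / k * 100
  out
}

#' Seasonal NDVI for a sampling window
#'
#' Mean of all 16-day composite values whose period overlaps the station's
#' deployment window.
#'
#' @param window_start,window_end deployment window (coercible to Date).
#' @param composite_starts start dates of the composites.
#' @param values composite NDVI values, parallel to `composite_starts`.
#' @param period_days composite length in days (default 16).
#' @return mean NDVI over overlapping composites.
#' @export
ndvi_seasonal <- function(window_start, window_end, composite_starts, values,
                          period_days = 16) {
  ws <- as.Date(window_start); we <- as.Date(window_end)
  cs <- as.Date(composite_starts)
  ce <- cs + period_days - 1
  overlap <- ce >= ws & cs <= we
  if (!any(overlap)) fail("no NDVI composite overlaps the sampling window")
  mean(values[overlap])
}

#' Integrated NDVI over the study period
#'
#' Sum of all 16-day composite values at a location across the whole survey.
#' When composite start dates are supplied, the series is checked for gaps
#' (consecutive starts must be `period_days` apart).
#'
#' @param values composite NDVI values.
#' @param composite_starts optional start dates used for the gap check.
#' @param period_days composite length in days (default 16).
#' @return the sum of composite values.
#' @export
ndvi_integrated <- function(values, composite_starts = NULL, period_days = 16) {
  if (length(values) == 0) fail("no NDVI composites supplied")
  if (!is.null(composite_starts)) {
    cs <- sort(as.Date(composite_starts))
    gaps <- diff(as.integer(cs))
    if (any(gaps != period_days))
      fail("gaps in the NDVI composite series after: %s",
           paste(cs[which(gaps != period_days)], collapse = ", "))
  }
  sum(values)
}

#' Normalize and standardize a covariate column
#'
#' Optionally applies a fourth-root transform (for right-skewed nonnegative
#' indices) and then centres and scales to sample mean 0 and unit variance.
#' The sample standard deviation uses the n-1 denominator.
#'
#' @param x numeric vector (no missing values).
#' @param fourth_root apply `x^(1/4)` before standardizing (requires x >= 0).
#' @return standardized vector with attributes `center` and `scale` (of the
#'   possibly transformed values).
#' @export
transform_standardize <- function(x, fourth_root = FALSE) {
  if (anyNA(x)) fail("missing values in covariate column")
  if (fourth_root) {
    if (any(x < 0)) fail("fourth-root transform requires nonnegative values")
    x <- x^0.25
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) fail("constant column cannot be standardized")
  structure((x - m) / s, center = m, scale = s)
}

#' Collinearity report for a site covariate table
#'
#' Pearson and Spearman correlation matrices plus the variance inflation
#' factor of each covariate (1 / (1 - R^2) from regressing it on all others).
#'
#' @param x numeric matrix or data frame of covariate columns (>= 3 rows).
#' @return list with elements `pearson`, `spearman` (symmetric matrices) and
#'   `vif` (named vector; `Inf` with a warning for singular designs).
#' @export
collinearity_report <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) fail("need at least 3 sites for a collinearity report")
  if (any(apply(x, 2, stats::sd) == 0)) fail("constant covariate column")
  pearson <- stats::cor(x, method = "pearson")
  spearman <- stats::cor(x, method = "spearman")
  p <- ncol(x)
  vif <- stats::setNames(rep(NA_real_, p), colnames(x))
  for (j in seq_len(p)) {
    if (p == 1) { vif[j] <- 1; next }
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12) {
      warning("singular design: VIF infinite for ", colnames(x)[j])
      vif[j] <- Inf
    } else vif[j] <- 1 / (1 - r2)
  }
  list(pearson = pearson, spearman = spearman, vif = vif)
}

#' Assemble a standardized site covariate table
#'
#' Applies [transform_standardize()] column by column and returns a table
#' carrying both raw and standardized versions (suffix `_std`). Binary 0/1
#' columns are passed through untouched.
#'
#' @param raw data frame of raw covariate columns, one row per site.
#' @param fourth_root character vector of column names to fourth-root
#'   transform before standardizing.
#' @return data frame with the raw columns plus `<name>_std` columns.
#' @export
standardize_covariates <- function(raw, fourth_root = character(0)) {
  out <- raw
  for (nm in names(raw)) {
    col <- raw[[nm]]
    if (!is.numeric(col)) next
    if (is_binary01(col)) next
    out[[paste0(nm, "_std")]] <-
      as.numeric(transform_standardize(col, fourth_root = nm %in% fourth_root))
  }
  out
}
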