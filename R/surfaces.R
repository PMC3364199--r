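#' Define a regular raster grid
#'
#' @param xll,yll coordinates (km) of the lower-left corner of the grid.
#' @param cellsize cell edge length in km (default 0.5, i.e. 500 m cells).
#' @param nrow,ncol grid dimensions.
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(xll, yll, nrow, ncol, cellsize = 0.5) {
  stopifnot(cellsize > 0, nrow >= 1, ncol >= 1)
  structure(list(xll = xll, yll = yll, nrow = as.integer(nrow),
                 ncol = as.integer(ncol), cellsize = cellsize),
            class = "grid_spec")
}

# Internal constructor. values: nrow x ncol matrix, row 1 = northernmost row
# (the Esri ASCII convention). NA marks masked / unsampled cells.
new_density_surface <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(values) == grid$nrow, ncol(values) == grid$ncol)
  structure(list(grid = grid, values = values), class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  g <- x$grid
  cat(sprintf("density_surface: %d x %d cells of %.3g km, origin (%.3g, %.3g)\n",
              g$nrow, g$ncol, g$cellsize, g$xll, g$yll))
  cat(sprintf("  values: [%.4g, %.4g], %d masked\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

# Internal: cell-centre coordinates
cell_centers <- function(grid) {
  xs <- grid$xll + (seq_len(grid$ncol) - 0.5) * grid$cellsize
  ys <- grid$yll + (grid$nrow - seq_len(grid$nrow) + 0.5) * grid$cellsize
  list(x = xs, y = ys)
}

#' Quartic kernel density surface from weighted points
#'
#' Each point spreads its weight over a disc of the given search radius with
#' the quartic (biweight) kernel `K(d) = (3/pi) (1 - d^2/r^2)^2` for `d < r`.
#' Cell values are `sum_i w_i K(d_i) / r^2`, a density per square km; the
#' kernel integrates to the point's weight, so the surface conserves total
#' weight up to truncation at the grid edge.
#'
#' @param points data frame with columns `x_km`, `y_km`, `weight`
#'   (weights must be nonnegative; an empty frame yields an all-zero surface).
#' @param grid a [grid_spec()].
#' @param radius kernel search radius in km (default 2).
#' @return a `density_surface`.
#' @export
kernel_density <- function(points, grid, radius = 2) {
  stopifnot(inherits(grid, "grid_spec"), radius > 0)
  vals <- matrix(0, grid$nrow, grid$ncol)
  if (nrow(points) == 0) return(new_density_surface(grid, vals))
  if (any(points$weight < 0)) fail("point weights must be nonnegative")
  if (!all(is.finite(points$x_km)) || !all(is.finite(points$y_km)))
    fail("non-finite point coordinates")
  cc <- cell_centers(grid)
  cs <- grid$cellsize
  r2 <- radius^2
  for (i in seq_len(nrow(points))) {
    px <- points$x_km[i]; py <- points$y_km[i]; w <- points$weight[i]
    if (w == 0) next
    # bounding box of cells possibly within the radius (over-inclusive by
    # design; the kernel is zero beyond the radius anyway)
    jlo <- max(1L, floor((px - radius - grid$xll) / cs))
    jhi <- min(grid$ncol, ceiling((px + radius - grid$xll) / cs) + 1L)
    ilo <- max(1L, grid$nrow - ceiling((py + radius - grid$yll) / cs))
    ihi <- min(grid$nrow, grid$nrow - floor((py - radius - grid$yll) / cs) + 1L)
    if (jlo > jhi || ilo > ihi) next
    dx2 <- (cc$x[jlo:jhi] - px)^2
    dy2 <- (cc$y[ilo:ihi] - py)^2
    d2 <- outer(dy2, dx2, "+")
    kern <- (3 / pi) * (1 - d2 / r2)^2
    kern[d2 >= r2] <- 0
    vals[ilo:ihi, jlo:jhi] <- vals[ilo:ihi, jlo:jhi] + w * kern / r2
  }
  new_density_surface(grid, vals)
}

#' Catch-per-unit-effort surface
#'
#' Cellwise ratio of an observation density surface to an effort density
#' surface. Cells whose effort falls below `effort_floor` carry essentially
#' no sampling information and are masked (`NA`) rather than producing
#' unstable ratios.
#'
#' @param numerator,effort congruent `density_surface` objects.
#' @param effort_floor positive effort threshold; defaults to 1% of the
#'   maximum effort cell.
#' @return a `density_surface` with masked cells where effort is below floor.
#' @export
cpue_surface <- function(numerator, effort, effort_floor = NULL) {
  stopifnot(inherits(numerator, "density_surface"),
            inherits(effort, "density_surface"))
  if (!identical(numerator$grid, effort$grid))
    fail("numerator and effort surfaces are on different grids")
  e <- effort$values
  if (is.null(effort_floor)) {
    emax <- max(e, na.rm = TRUE)
    effort_floor <- 0.01 * emax
  }
  vals <- numerator$values / e
  masked <- is.na(e) | e < effort_floor | effort_floor <= 0
  vals[masked] <- NA_real_
  new_density_surface(numerator$grid, vals)
}

#' Extract surface values at site coordinates
#'
#' Reads the value of the cell containing each site (no interpolation).
#'
#' @param surface a `density_surface`.
#' @param coords two-column matrix or data frame of site x/y in km.
#' @return numeric vector, `NA` for sites in masked cells or off the grid.
#' @export
extract_at_sites <- function(surface, coords) {
  g <- surface$grid
  x <- coords[, 1]; y <- coords[, 2]
  col <- floor((x - g$xll) / g$cellsize) + 1
  row <- g$nrow - floor((y - g$yll) / g$cellsize)
  ok <- col >= 1 & col <= g$ncol & row >= 1 & row <= g$nrow
  out <- rep(NA_real_, length(x))
  out[ok] <- surface$values[cbind(row[ok], col[ok])]
  out
}

#' Write a surface as an Esri ASCII grid
#'
#' @param surface a `density_surface`.
#' @param path output file.
#' @param nodata value used for masked cells (default -9999).
#' @export
write_ascii_grid <- function(surface, path, nodata = -9999) {
  g <- surface$grid
  v <- surface$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
           sprintf("xllcorner %.10g", g$xll), sprintf("yllcorner %.10g", g$yll),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(surface)
}

#' Read an Esri ASCII grid
#'
#' @param path file written in Esri ASCII grid format.
#' @return a `density_surface` (NODATA cells become `NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$nrows, hdr$ncols,
                 hdr$cellsize)
  new_density_surface(g, vals)
}
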