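grid40 <- grid_spec(0, 0, nrow = 40, ncol = 40, cellsize = 0.5)

test_that("kernel density matches the quartic kernel and is linear in weight", {
  empty <- kernel_density(data.frame(x_km = numeric(0), y_km = numeric(0),
                                     weight = numeric(0)), grid40)
  expect_true(all(empty$values == 0))

  # one unit point exactly at a cell centre: peak = (3/pi)/r^2 = 3/(4 pi)
  pt <- data.frame(x_km = 10.25, y_km = 10.25, weight = 1)
  s <- kernel_density(pt, grid40, radius = 2)
  expect_equal(extract_at_sites(s, cbind(10.25, 10.25)), 3 / (4 * pi),
               tolerance = 1e-12)

  s2 <- kernel_density(transform(pt, weight = 2), grid40, radius = 2)
  expect_equal(s2$values, 2 * s$values)
})

test_that("kernel density conserves total weight away from grid edges", {
  set.seed(7)
  pts <- data.frame(x_km = runif(20, 5, 15), y_km = runif(20, 5, 15),
                    weight = runif(20, 0.5, 3))
  s <- kernel_density(pts, grid40, radius = 2)
  total <- sum(s$values) * 0.5^2
  expect_equal(total, sum(pts$weight), tolerance = 0.02)
})

test_that("CPUE surface is a masked cellwise ratio, scale-equivariant", {
  g <- grid_spec(0, 0, 2, 2, 1)
  num <- commoccu:::new_density_surface(g, matrix(c(4, 1, 0, 9), 2, 2))
  eff <- commoccu:::new_density_surface(g, matrix(c(2, 1, 10, 3), 2, 2))
  r <- cpue_surface(num, eff, effort_floor = 0.5)
  expect_equal(r$values, matrix(c(2, 1, 0, 3), 2, 2))

  # masked where effort below floor
  eff2 <- commoccu:::new_density_surface(g, matrix(c(2, 0.1, 10, 3), 2, 2))
  r2 <- cpue_surface(num, eff2, effort_floor = 0.5)
  expect_true(is.na(r2$values[2, 1]))

  # all-zero effort: fully masked
  eff0 <- commoccu:::new_density_surface(g, matrix(0, 2, 2))
  expect_true(all(is.na(cpue_surface(num, eff0)$values)))

  # scaling the numerator scales the unmasked ratio
  num3 <- commoccu:::new_density_surface(g, 3 * num$values)
  expect_equal(cpue_surface(num3, eff, effort_floor = 0.5)$values, 3 * r$values)

  g2 <- grid_spec(0, 0, 3, 3, 1)
  other <- commoccu:::new_density_surface(g2, matrix(1, 3, 3))
  expect_error(cpue_surface(num, other), "different grids")
})

test_that("distance to feature handles vertices, segments and polygons", {
  seg <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(distance_to_feature(cbind(1, 0), list(seg)), 0)   # on feature
  expect_equal(distance_to_feature(cbind(1, 1), list(seg)), 1)   # projection
  expect_equal(distance_to_feature(cbind(3, 4),
                                   list(matrix(c(0, 0), 1, 2))), 5)
  expect_error(distance_to_feature(cbind(0, 0), list()), "empty")

  # brute-force check on a densified ring
  theta <- seq(0, 2 * pi, length.out = 73)
  ring <- cbind(10 + 3 * cos(theta), 10 + 3 * sin(theta))
  sites <- cbind(c(10, 14, 10), c(10, 10, 16))
  d <- distance_to_feature(sites, list(ring))
  brute <- apply(sites, 1, function(pt)
    min(sqrt((pt[1] - ring[, 1])^2 + (pt[2] - ring[, 2])^2)))
  expect_true(all(d <= brute + 1e-12))
  expect_equal(d, brute, tolerance = 0.01)
})

test_that("GeoJSON polylines and polygons are read as coordinate parts", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type":"FeatureCollection","features":[
    {"type":"Feature","geometry":{"type":"LineString",
      "coordinates":[[0,0],[2,0]]},"properties":{}},
    {"type":"Feature","geometry":{"type":"Polygon",
      "coordinates":[[[5,5],[7,5],[7,7],[5,7],[5,5]]]},"properties":{}}
  ]}', path)
  parts <- read_feature_geojson(path)
  expect_length(parts, 2)
  expect_equal(distance_to_feature(cbind(1, 1), parts), 1)
  expect_equal(distance_to_feature(cbind(6, 6), parts[2]), 1) # inside ring
})

test_that("camera prey biomass applies dedup chain, cutoff and effort scaling", {
  dep <- make_deployments(50)
  mass <- c(duiker = 10, kob = 30)
  # two detections well apart: 2 x 10 kg / 50 days x 100 = 40
  det <- data.frame(station_id = "st001", species = "duiker",
                    timestamp = c("2007-01-02 08:00:00", "2007-01-20 09:00:00"))
  expect_equal(unname(camera_prey_biomass(det, dep, mass)), 40)

  # photos 3 minutes apart chain into one detection
  det2 <- data.frame(station_id = "st001", species = "duiker",
                     timestamp = c("2007-01-02 08:00:00", "2007-01-02 08:03:00"))
  expect_equal(unname(camera_prey_biomass(det2, dep, mass)), 10 / 50 * 100)
  # 3 + 3 minutes: still one chained event; 6 minutes alone: two events
  det3 <- data.frame(station_id = "st001", species = "duiker",
                     timestamp = c("2007-01-02 08:00:00", "2007-01-02 08:03:00",
                                   "2007-01-02 08:06:00"))
  expect_equal(unname(camera_prey_biomass(det3, dep, mass)), 10 / 50 * 100)

  # 18-kg cutoff drops the 30-kg species entirely
  det4 <- data.frame(station_id = "st001", species = "kob",
                     timestamp = "2007-01-02 08:00:00")
  expect_equal(unname(camera_prey_biomass(det4, dep, mass, mass_cutoff = 18)), 0)

  expect_error(camera_prey_biomass(
    data.frame(station_id = "st001", species = "oribi",
               timestamp = "2007-01-02 08:00:00"), dep, mass),
    "no body mass.*oribi")
})

test_that("NDVI summaries average overlaps and sum complete series", {
  starts <- as.Date("2007-01-01") + 16 * (0:9)
  vals <- c(3000, 5000, rep(4000, 8))
  # window inside composite 1
  expect_equal(ndvi_seasonal("2007-01-02", "2007-01-10", starts, vals), 3000)
  # window spanning composites 1 and 2
  expect_equal(ndvi_seasonal("2007-01-10", "2007-01-20", starts, vals), 4000)
  expect_equal(ndvi_seasonal("2007-01-01", "2007-02-20", starts[1:3],
                             c(1, 2, 6)), 3)
  expect_error(ndvi_seasonal("2010-01-01", "2010-01-10", starts, vals),
               "no NDVI composite")

  expect_equal(ndvi_integrated(rep(100, 10), starts), 1000)
  expect_equal(ndvi_integrated(4321), 4321)
  expect_equal(ndvi_integrated(sample(vals)), sum(vals))
  expect_error(ndvi_integrated(vals[-3], starts[-3]), "gaps")
})

test_that("transform/standardize uses fourth root and n-1 sd, preserves rank", {
  # fourth root of 16 is 2 before standardizing: (2,1) standardizes to +-1/sqrt(2)
  z <- transform_standardize(c(16, 1), fourth_root = TRUE)
  expect_equal(as.numeric(z), c(1, -1) / sqrt(2))
  expect_equal(attr(z, "center"), 1.5)

  # (-1, 1) under the sample-sd (n-1) convention: sd = sqrt(2)
  z2 <- transform_standardize(c(-1, 1))
  expect_equal(as.numeric(z2), c(-1, 1) / sqrt(2))

  set.seed(3)
  x <- rexp(50)
  z3 <- transform_standardize(x, fourth_root = TRUE)
  expect_lt(abs(mean(z3)), 1e-8)
  expect_equal(var(as.numeric(z3)), 1, tolerance = 1e-8)
  expect_equal(order(as.numeric(z3)), order(x))   # monotone

  expect_error(transform_standardize(rep(2, 5)), "constant")
  expect_error(transform_standardize(c(-1, 2), fourth_root = TRUE),
               "nonnegative")
})

test_that("collinearity report gives correlations and closed-form VIF", {
  e1 <- c(1, -1, 1, -1) / 2
  e2 <- c(1, 1, -1, -1) / 2
  orth <- cbind(a = e1, b = e2)
  rep1 <- collinearity_report(orth)
  expect_equal(rep1$pearson["a", "b"], 0)
  expect_equal(unname(rep1$vif), c(1, 1))

  # exact r = 0.8 pair: VIF = 1/(1 - 0.64)
  pair <- cbind(a = e1, b = 0.8 * e1 + 0.6 * e2)
  rep2 <- collinearity_report(pair)
  expect_equal(rep2$pearson["a", "b"], 0.8)
  expect_equal(unname(rep2$vif), rep(1 / 0.36, 2), tolerance = 1e-9)

  dup <- cbind(a = e1, b = e1, c = e2)
  w <- capture_warnings(rep3 <- collinearity_report(dup))
  expect_true(all(grepl("singular", w)))   # one warning per duplicated column
  expect_true(is.infinite(rep3$vif[["a"]]))
  expect_error(collinearity_report(cbind(a = rep(1, 5))), "constant")
})

test_that("ASCII grid round-trip preserves the surface including mask", {
  set.seed(1)
  g <- grid_spec(2.5, -1, 6, 5, 0.5)
  v <- matrix(round(runif(30), 4), 6, 5)
  v[2, 3] <- NA
  s <- commoccu:::new_density_surface(g, v)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(s, path)
  s2 <- read_ascii_grid(path)
  expect_equal(s2$grid, g)
  expect_equal(s2$values, v)
})

test_that("standardize_covariates keeps binaries and adds _std columns", {
  raw <- data.frame(hunting = c(0, 1, 4, 9), edge = c(-2, 0, 1, 3),
                    road = c(0, 1, 1, 0))
  out <- standardize_covariates(raw, fourth_root = "hunting")
  expect_true(all(c("hunting_std", "edge_std") %in% names(out)))
  expect_false("road_std" %in% names(out))
  expect_lt(abs(mean(out$hunting_std)), 1e-8)
  expect_equal(var(out$edge_std), 1, tolerance = 1e-8)
})
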