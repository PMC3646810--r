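test_that("generate_habitat honours its geometry and range contracts", {
  hab <- generate_habitat(seed = 1, ncols = 64, nrows = 64)
  expect_true(divehab:::same_geometry(hab$depth, hab$sediment))
  expect_true(all(hab$depth$values >= 0))
  expect_gte(max(hab$depth$values), 300)
  expect_equal(min(hab$depth$values), 0)
  expect_true(all(hab$sediment$values %in% 0:3))
  # fixed seed -> bit-identical rasters
  hab2 <- generate_habitat(seed = 1, ncols = 64, nrows = 64)
  expect_identical(hab$depth$values, hab2$depth$values)
  expect_identical(hab$sediment$values, hab2$sediment$values)
  expect_error(generate_habitat(seed = 1, ncols = 8, nrows = 64), "16 x 16")
})

test_that("sim_config validates its probability structure", {
  expect_error(sim_config(p_fix_success = 1.2), "p_fix_success")
  expect_error(sim_config(swim_speed_mps = 3, max_speed_mps = 2),
               "max_speed_mps")
  bad <- default_p_pelagic()[1:3, ]  # drops a sediment class
  expect_error(sim_config(p_pelagic = bad), "p_pelagic")
  bad2 <- default_p_pelagic(); bad2["fine", "day"] <- 1.4
  expect_error(sim_config(p_pelagic = bad2), "probabilities")
})

test_that("deep-water dives are all benthic when p_pelagic is zero", {
  p0 <- default_p_pelagic() * 0
  cfg <- sim_config(n_seals = 1, deployment_days = 0.5, p_pelagic = p0,
                    rng_seed = 5)
  depth <- flat_raster(150, ncols = 64, nrows = 64)
  sed <- flat_raster(1, ncols = 64, nrows = 64)
  sim <- simulate_seal(cfg, depth, sed, "s1")
  deep <- sim$truth[sim$truth$max_depth_m > 0, ]
  expect_gt(nrow(deep), 50)
  expect_true(all(deep$true_type == "benthic"))
})

test_that("an always-surfaced seal yields fixes exactly every 30 minutes", {
  cfg <- sim_config(n_seals = 1, deployment_days = 1,
                    mean_surface_duration_s = 1e7, mean_dive_duration_s = 9.5,
                    p_fix_success = 1, rng_seed = 2)
  depth <- flat_raster(100, ncols = 64, nrows = 64)
  sed <- flat_raster(2, ncols = 64, nrows = 64)
  sim <- simulate_seal(cfg, depth, sed, "s1")
  gaps <- diff(as.numeric(sim$fixes$timestamp))
  expect_gt(length(gaps), 10)
  expect_true(all(gaps == 1800))
})

test_that("dive records respect the detection floor and local depth", {
  hab <- generate_habitat(seed = 4, ncols = 64, nrows = 64)
  cfg <- sim_config(n_seals = 1, deployment_days = 1, rng_seed = 9)
  sim <- simulate_seal(cfg, hab$depth, hab$sediment, "s1")
  tr <- sim$truth
  expect_true(all(tr$max_depth_m > 1.5))
  expect_true(all(tr$duration_s > 8))
  expect_true(all(as.numeric(tr$end_time) - as.numeric(tr$start_time) ==
                    tr$duration_s))
  local_depth <- extract_at(hab$depth, tr$true_lon, tr$true_lat)
  shallow <- tr$true_type == "shallow"
  expect_true(all(tr$max_depth_m[shallow] <= local_depth[shallow]))
  expect_true(all(local_depth[shallow] < 50))
  expect_true(all(local_depth[!shallow] >= 50))
})

test_that("no fix timestamp falls inside any dive", {
  hab <- generate_habitat(seed = 4, ncols = 64, nrows = 64)
  cfg <- sim_config(n_seals = 2, deployment_days = 1, rng_seed = 13)
  sim <- simulate_dataset(cfg, hab$depth, hab$sediment)
  for (id in unique(sim$fixes$seal_id)) {
    ft <- as.numeric(sim$fixes$timestamp[sim$fixes$seal_id == id])
    dv <- sim$truth[sim$truth$seal_id == id, ]
    inside <- vapply(ft, function(t)
      any(t >= as.numeric(dv$start_time) & t < as.numeric(dv$end_time)),
      logical(1))
    expect_false(any(inside))
  }
})

test_that("per-habitat pelagic fractions converge on the configured inputs", {
  # one sediment class at a time over uniform deep water: the dive-type draw
  # reduces to a binomial whose rate must match p_pelagic[sed, diel]
  cfg <- sim_config(n_seals = 1, deployment_days = 4, rng_seed = 21)
  depth <- flat_raster(200, ncols = 64, nrows = 64)
  for (code in c(1, 3)) {
    sed_lab <- divehab:::sediment_from_code(code)
    sim <- simulate_seal(cfg, depth, flat_raster(code, 64, 64), "s1")
    tr <- sim$truth
    tr$diel <- is_daytime(tr$start_time, tr$true_lon, tr$true_lat)
    for (dl in c("day", "night")) {
      sub <- tr[tr$diel == dl, ]
      p_hat <- mean(sub$true_type == "pelagic")
      p_true <- default_p_pelagic()[sed_lab, dl]
      tol <- 3 * sqrt(p_true * (1 - p_true) / nrow(sub)) + 0.005
      expect_gt(nrow(sub), 300)
      expect_lt(abs(p_hat - p_true), tol)
    }
  }
})

test_that("a fixed dataset seed reproduces everything bit-identically", {
  hab <- generate_habitat(seed = 2, ncols = 64, nrows = 64)
  cfg <- sim_config(n_seals = 2, deployment_days = 0.5, rng_seed = 99)
  a <- simulate_dataset(cfg, hab$depth, hab$sediment)
  b <- simulate_dataset(cfg, hab$depth, hab$sediment)
  expect_identical(a, b)
})

test_that("release on a nodata cell is rejected", {
  vals <- matrix(100, 20, 20); vals[10, 10] <- NA
  depth <- habitat_raster(vals, -11, 51, 0.01)
  sed <- flat_raster(1, 20, 20, -11, 51, 0.01)
  cfg <- sim_config(n_seals = 1, deployment_days = 0.1)
  expect_error(
    simulate_seal(cfg, depth, sed, "s1",
                  start_lon = -11 + 9.5 * 0.01, start_lat = 51 + 10.5 * 0.01),
    "nodata")
})

test_that("write_dataset round-trips and never writes partial output", {
  hab <- generate_habitat(seed = 2, ncols = 64, nrows = 64)
  cfg <- sim_config(n_seals = 1, deployment_days = 0.25, rng_seed = 7)
  sim <- simulate_dataset(cfg, hab$depth, hab$sediment)
  dir <- file.path(tempdir(), "ds")
  paths <- write_dataset(sim$fixes, sim$dives, sim$truth, dir)
  expect_equal(nrow(read.csv(paths["truth"])), nrow(sim$truth))
  fx <- read_fixes(paths["fixes"])
  expect_equal(fx$lon, sim$fixes$lon, tolerance = 1e-9)
  expect_equal(fx$lat, sim$fixes$lat, tolerance = 1e-9)
  expect_identical(as.numeric(fx$timestamp), as.numeric(sim$fixes$timestamp))
  dv <- read_dives(paths["dives"])
  expect_equal(dv$max_depth_m, sim$dives$max_depth_m, tolerance = 1e-9)

  dir2 <- file.path(tempdir(), "ds-empty")
  expect_error(write_dataset(sim$fixes, sim$dives[0, ], sim$truth, dir2),
               "no dives")
  expect_false(file.exists(file.path(dir2, "fixes.csv")))
})
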