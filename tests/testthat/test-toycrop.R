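env0 <- list(county = "c1", location = "c1_loc1", base_potential = 10000,
             soil_factor = 1, anomaly = rep(0, 40))

test_that("the yield index is centered, bounded and affine in each parameter", {
  specs <- default_parameter_specs()
  b <- param_bounds(specs)
  w <- toycrop_weights()
  mid <- drop(unit_to_scale(rep(0.5, 9), b))
  expect_equal(yield_index(mid), 1)
  expect_equal(yield_response(mid, env0, 1), 10000)

  # most favorable extremes: u = 1 where w > 0, u = 0 where w < 0
  u_best <- ifelse(w > 0, 1, ifelse(w < 0, 0, 0.5))
  expect_equal(yield_index(drop(unit_to_scale(u_best, b))), 1.5)
  u_worst <- 1 - u_best
  expect_equal(yield_index(drop(unit_to_scale(u_worst, b))), 0.5)

  # single-parameter move: u_rue = 1 adds its full weight / 2
  u <- rep(0.5, 9); names(u) <- colnames(b); u["rue"] <- 1
  expect_equal(yield_response(drop(unit_to_scale(u, b)), env0, 1), 11500)

  # affine: finite-difference slope w.r.t. u_rue equals 0.30 * base * soil
  env1 <- env0; env1$soil_factor <- 0.93; env1$anomaly <- rep(0.05, 40)
  h <- 1e-4
  up <- u; up["rue"] <- 0.5 + h; dn <- u; dn["rue"] <- 0.5 - h
  slope <- (yield_response(drop(unit_to_scale(up, b)), env1, 3) -
              yield_response(drop(unit_to_scale(dn, b)), env1, 3)) / (2 * h)
  expect_equal(slope, 0.30 * 10000 * 0.93 * 1.05, tolerance = 1e-9)

  expect_error(yield_response(rep(0, 9), env0, 1), "bounds")
})

test_that("equifinality: equal yield index implies equal yield", {
  specs <- default_parameter_specs()
  b <- param_bounds(specs)
  # trade rue up against head_grain_no_max down, keeping G fixed
  u1 <- rep(0.5, 9); names(u1) <- colnames(b)
  u2 <- u1
  u1["rue"] <- 0.6
  u2["head_grain_no_max"] <- 0.5 + 0.1 * 0.30 / 0.20
  th1 <- drop(unit_to_scale(u1, b)); th2 <- drop(unit_to_scale(u2, b))
  expect_equal(yield_index(th1), yield_index(th2), tolerance = 1e-12)
  expect_equal(yield_response(th1, env0, 1), yield_response(th2, env0, 1),
               tolerance = 1e-9)
})

test_that("the true trajectory rises linearly from index 0.8 to 1.2 within bounds", {
  tt <- true_trajectory(34)
  g <- apply(tt$theta, 1, yield_index)
  expect_equal(g[1], 0.8, tolerance = 1e-12)
  expect_equal(g[34], 1.2, tolerance = 1e-12)
  expect_equal(g, seq(0.8, 1.2, length.out = 34), tolerance = 1e-12)
  b <- param_bounds(tt$specs)
  expect_true(all(in_bounds(tt$theta, b)))
  # slope direction pattern: breeding-progress parameters up, phenology down
  expect_lt(tt$slopes[["tt_emerg_to_endjuv"]], 0)
  expect_gt(tt$slopes[["tt_flower_to_maturity"]], 0)
  expect_gt(tt$slopes[["rue"]], 0)
  expect_equal(tt$slopes[["transp_eff_cf"]], 0)
  expect_equal(tt$slopes[["n_conc_crit_grain"]], 0)
})

test_that("dataset generation is deterministic and trends upward", {
  d1 <- generate_dataset(counties = 3, soils = 2, years = 20, seed = 77)
  d2 <- generate_dataset(counties = 3, soils = 2, years = 20, seed = 77)
  expect_identical(d1$observed, d2$observed)
  expect_identical(vapply(d1$environments, `[[`, 1, "soil_factor"),
                   vapply(d2$environments, `[[`, 1, "soil_factor"))
  d3 <- generate_dataset(counties = 3, soils = 2, years = 20, seed = 78)
  expect_false(identical(d1$observed$yield_kg_ha, d3$observed$yield_kg_ha))

  expect_true(all(d1$observed$yield_kg_ha > 0))
  for (cty in d1$counties) {
    d <- d1$observed[d1$observed$county == cty, ]
    expect_gt(coef(lm(yield_kg_ha ~ year_index, d))[2], 0)
  }
})

test_that("the noise-free degenerate configuration reproduces base x G exactly", {
  ds <- generate_dataset(counties = 2, soils = 1, years = 12, noise_sd = 0,
                         seed = 5, soil_range = c(1, 1), anomaly_sd = 0)
  g <- apply(ds$truth$theta, 1, yield_index)
  for (cty in ds$counties) {
    base <- ds$environments[[paste0(cty, "_loc1")]]$base_potential
    d <- ds$observed[ds$observed$county == cty, ]
    expect_equal(d$yield_kg_ha[order(d$year_index)], base * g,
                 tolerance = 1e-12)
  }
})

test_that("dataset serialization round-trips through CSV and JSON", {
  ds <- generate_dataset(counties = 2, soils = 2, years = 12, seed = 3,
                         first_year = 2000)
  dir <- withr::local_tempdir()
  write_observed_csv(ds, file.path(dir, "observed.csv"))
  write_environments_json(ds, file.path(dir, "environments.json"))
  write_truth_json(ds, file.path(dir, "truth.json"))

  obs <- read_observed_csv(file.path(dir, "observed.csv"))
  expect_equal(nrow(obs), 2 * 12)
  expect_equal(sort(unique(obs$year)), 2000:2011)
  merged <- merge(obs, ds$observed, by = c("county", "year"))
  expect_equal(merged$yield_kg_ha.x, merged$yield_kg_ha.y, tolerance = 1e-8)

  ej <- read_environments_json(file.path(dir, "environments.json"))
  expect_equal(ej$first_year, 2000L)
  expect_equal(names(ej$environments), names(ds$environments))
  expect_equal(ej$environments[[3]]$soil_factor,
               ds$environments[[3]]$soil_factor)
  expect_equal(ej$environments[[1]]$anomaly,
               as.numeric(ds$environments[[1]]$anomaly))

  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tj$years, 12)
  expect_equal(unname(unlist(tj$slopes)), unname(ds$truth$slopes))
})
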