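test_that("the default template generates the assumed trophic structure", {
  cfg <- generate_web(seed = 7)
  comp <- cfg$components
  expect_equal(nrow(comp), 11L)
  expect_equal(sum(comp$is_key_species), 9L)
  expect_equal(sum(comp$kind == "biomass_pool"), 4L)
  expect_equal(sum(comp$kind == "vertebrate"), 5L)
  expect_equal(sum(comp$kind == "producer"), 1L)
  expect_equal(sum(comp$kind == "detritus"), 1L)

  ## whale analogue: constant per-adult recruitment; fish: Beverton-Holt
  ## with lognormal variation; cod analogue: deterministic Beverton-Holt
  expect_equal(comp$recruitment_mode[comp$id == "MWH"], "constant_per_adult")
  fish <- comp[comp$guild == "pelagic_fish", ]
  expect_true(all(fish$recruitment_mode == "beverton_holt"))
  expect_true(all(fish$recruitment_sigma > 0))
  expect_equal(comp$recruitment_sigma[comp$id == "NCO"], 0)
  expect_true(is.null(cfg$params$MWH$BHa) && !is.null(cfg$params$MWH$KDENR))
})

test_that("web generation is a pure function of template and seed", {
  a <- generate_web(seed = 3)
  b <- generate_web(seed = 3)
  expect_equal(a, b, tolerance = 0)
  c <- generate_web(seed = 4)
  expect_false(isTRUE(all.equal(a$params, c$params)))
  ## template counts below the defaults are rejected
  expect_error(web_template(n_zooplankton = 2), "at least")
})

test_that("stability check flags excursions and counts cohorts in band", {
  cfg <- closed_web3(years = 4L)
  cfg$settings$spin_up_years <- 1L
  cfg$params$A$mQ <- 0; cfg$params$A$mL <- 0
  cfg$params$B$C <- 0   # A now inert: constant trajectory
  cfg$diet["A", "DET"] <- 0
  traj <- run_simulation(cfg)
  rep <- stability_check(traj, band = c(0.5, 1.5))
  a <- rep$components[rep$components$component == "A", ]
  expect_equal(a$min_ratio, 1)
  expect_equal(a$max_ratio, 1)
  expect_true(a$pass)

  ## a component ending at 1.6x initial fails
  traj2 <- traj
  traj2$biomass[, "A"] <- seq(1, 1.6, length.out = nrow(traj2$biomass)) *
    traj2$biomass[1, "A"]
  traj2$init_biomass <- traj2$biomass[1, ]
  rep2 <- stability_check(traj2)
  expect_false(rep2$components$pass[rep2$components$component == "A"])
  expect_false(rep2$pass)

  ## cohort fraction: 3 of 4 cohorts in band -> 0.75
  wmat <- matrix(1, nrow = 3, ncol = 4)     # annual weights, 3 years, 4 ages
  wmat[, 4] <- 2                            # one cohort doubled: out of band
  vt <- structure(list(
    biomass = matrix(100, 4, 1, dimnames = list(NULL, "F")),
    day = c(0, 365, 730, 1095),
    init_biomass = c(F = 100),
    vert_annual = list(F = list(numbers = wmat, w_struct = wmat / 2,
                                w_reserve = wmat / 2)),
    init_verts = list(F = list(numbers = rep(1, 4), w_struct = rep(0.5, 4),
                               w_reserve = rep(0.5, 4))),
    ids = "F",
    settings = list(spin_up_years = 0L, averaging_window_years = 1L)),
    class = "foodweb_trajectory")
  rep3 <- stability_check(vt, spin_up_years = 0L)
  expect_equal(nrow(rep3$cohorts), 4L)
  expect_equal(rep3$cohort_fraction_in_band, 0.75)
})

test_that("the shipped default web passes the stability band on the control run", {
  cfg <- default_web()
  traj <- run_simulation(cfg)
  rep <- stability_check(traj)
  expect_true(rep$pass)
  expect_true(all(rep$components$min_ratio >= 0.5))
  expect_true(all(rep$components$max_ratio <= 1.5))
})

test_that("tuning restores a destabilized web and reports non-convergence", {
  cfg <- default_web()
  ## already stable: returned unchanged in zero iterations
  ok <- tune_to_stability(cfg, max_iters = 2)
  expect_true(ok$converged)
  expect_equal(ok$iterations, 0L)
  expect_equal(ok$config, cfg)

  ## inflate a predator's quadratic mortality tenfold and recover
  broken <- cfg
  broken$params$NCO$mQ_juvenile <- broken$params$NCO$mQ_juvenile * 10
  broken$params$NCO$mQ_adult <- broken$params$NCO$mQ_adult * 10
  expect_false(stability_check(run_simulation(broken))$pass)
  fixed <- tune_to_stability(broken, max_iters = 15)
  expect_true(fixed$converged)
  expect_true(fixed$report$pass)
  ## tuning only rescales rates: topology and counts untouched
  expect_equal(fixed$config$components, cfg$components)
  expect_equal(fixed$config$diet > 0, cfg$diet > 0)

  ## max_iters = 0 on an unstable config: explicit failure report
  res0 <- tune_to_stability(broken, max_iters = 0)
  expect_false(res0$converged)
  expect_false(res0$report$pass)
  expect_equal(res0$iterations, 0L)
})
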