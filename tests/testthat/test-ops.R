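test_that("available prey biomass is the refuge-discounted availability product", {
  expect_equal(available_prey(0, 100), 0)
  expect_equal(available_prey(1, 100, 1, 1, 1), 100)
  expect_equal(available_prey(0.5, 200, delta_overlap = 0.8), 80)
  ## vectorized over prey
  expect_equal(available_prey(c(0.2, 0.5), c(100, 40), c(1, 0.5)), c(20, 10))
})

test_that("grazing flux follows the saturating functional response", {
  ## hand evaluation: 10 * 0.1 * 50 / (1 + 0.1 * 1 * 50 / 1) = 50/6
  gr <- grazing_flux(B = 10, C = 0.1, mum = 1, E = 1, b_star = 50)
  expect_equal(as.numeric(gr), 50 / 6, tolerance = 1e-12)
  expect_equal(attr(gr, "intake"), 50 / 6, tolerance = 1e-12)

  expect_equal(as.numeric(grazing_flux(10, 0, 1, 1, c(50, 20))), c(0, 0))
  expect_equal(as.numeric(grazing_flux(10, 0.1, 1, 1, c(0, 0))), c(0, 0))
  expect_error(grazing_flux(10, 0.1, 0, 1, 50), "mum = 0")

  ## fluxes split across prey in proportion to available biomass
  gr2 <- grazing_flux(10, 0.1, 1, 0.8, c(30, 10))
  expect_equal(gr2[1] / gr2[2], 3)
})

test_that("assimilated grazing intake is monotone in prey and bounded by mum * B", {
  set.seed(7)
  for (i in 1:50) {
    B <- runif(1, 1, 100); C <- runif(1, 1e-4, 1)
    mum <- runif(1, 0.01, 2); E <- runif(1, 0.1, 1)
    tot <- cumsum(runif(6, 1, 500))
    assim <- vapply(tot, function(b)
      E * attr(grazing_flux(B, C, mum, E, b), "intake"), numeric(1))
    expect_true(all(diff(assim) >= -1e-12))
    expect_true(all(assim <= mum * B + 1e-9))
  }
})

test_that("mortality removal implements linear + quadratic + starvation terms", {
  expect_equal(mortality_removal(100, 0, 0, 0), 0)
  expect_equal(mortality_removal(100, mL = 0.01, mQ = 0), 1.0)
  expect_equal(mortality_removal(1000, mL = 0, mQ = 1e-4), 100)
  expect_equal(mortality_removal(1000, mL = 0, mQ = 1e-4, dt = 0.5), 50)
  ## starvation adds a rate; removal never exceeds the standing stock
  expect_equal(mortality_removal(100, 0.01, 0, mSt = 0.02), 3.0)
  expect_equal(mortality_removal(10, mL = 0.5, mQ = 1), 10)
})

test_that("recruitment follows the constant and Beverton-Holt forms", {
  expect_equal(recruit_constant(0.45, 1000), 450)
  expect_equal(recruit_beverton_holt(Sp = 100, BHa = 2, Biom = 150, BHb = 50), 1.0)
  ## deterministic when the deviate is 1
  r1 <- recruit_beverton_holt(80, 3, 500, 100)
  r2 <- recruit_beverton_holt(80, 3, 500, 100)
  expect_identical(r1, r2)
  expect_error(recruit_beverton_holt(10, 1, 0, 0), "Biom \\+ BHb")
  ## nonincreasing in Biom, linear in Sp at fixed Biom
  bio <- seq(100, 5000, by = 100)
  rc <- vapply(bio, function(b) recruit_beverton_holt(100, 2, b, 50), numeric(1))
  expect_true(all(diff(rc) < 0))
  sp <- c(1, 2.5, 7)
  rs <- vapply(sp, function(s) recruit_beverton_holt(s, 2, 150, 50), numeric(1))
  expect_equal(rs, sp * recruit_beverton_holt(1, 2, 150, 50))
})

test_that("growth allocation caps gain, pays maintenance from reserve first", {
  ## cap binds: offered twice the cap, realized gain is mum * dt
  g <- grow_allocate(assimilated = 2 * 0.01 * 100, N = 100, mum = 0.01,
                     w_struct = 1, w_reserve = 1, maint_frac = 0)
  expect_equal(g$w_struct + g$w_reserve - 2, 0.01)
  expect_equal(g$overflow, 0.01 * 100)

  ## starvation direction: no intake, structural weight untouched, reserve
  ## pays the maintenance deficit
  s <- grow_allocate(0, N = 10, mum = 0.01, w_struct = 1, w_reserve = 1,
                     maint_frac = 0.1)
  expect_equal(s$w_struct, 1)
  expect_equal(s$w_reserve, 1 - 0.001)
  expect_equal(s$maintenance, 0.001 * 10)

  ## reserve is floored, never negative
  s2 <- grow_allocate(0, N = 1, mum = 1, w_struct = 1, w_reserve = 1e-9,
                      maint_frac = 1)
  expect_gte(s2$w_reserve, 0)

  ## split fraction routes gain between structural and reserve
  g2 <- grow_allocate(0.004 * 10, N = 10, mum = 0.01, w_struct = 1,
                      w_reserve = 1, growth_split = 0.25, maint_frac = 0)
  expect_equal(g2$w_struct, 1 + 0.25 * 0.004)
  expect_equal(g2$w_reserve, 1 + 0.75 * 0.004)
})

test_that("pool growth nets assimilation against losses under the mum cap", {
  p <- pool_growth(assimilated = 5, B = 100, mum = 0.1, losses = 2)
  expect_equal(p$dB, 3)
  expect_equal(p$overflow, 0)
  ## cap binds
  p2 <- pool_growth(assimilated = 50, B = 100, mum = 0.1, losses = 0)
  expect_equal(p2$gain, 10)
  expect_equal(p2$overflow, 40)
})

test_that("cohort aging shifts classes, merges the plus group, seats recruits", {
  st <- age_cohorts(c(10, 20, 30), c(1, 2, 3), c(1, 2, 3))
  expect_equal(st$numbers, c(0, 10, 50))
  st0 <- age_cohorts(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_equal(st0$numbers, c(0, 0, 0))

  ## plus-group weights are the number-weighted mean of the entrants
  st2 <- age_cohorts(c(5, 10, 40), w_struct = c(1, 2, 4), w_reserve = c(1, 1, 2),
                     recruits = 7, recruit_w_struct = 0.5, recruit_w_reserve = 0.5)
  expect_equal(st2$numbers, c(7, 5, 50))
  expect_equal(st2$w_struct[3], (10 * 2 + 40 * 4) / 50)
  expect_equal(st2$w_reserve[3], (10 * 1 + 40 * 2) / 50)
  expect_equal(st2$w_struct[1], 0.5)
})
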