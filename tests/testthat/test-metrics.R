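## small helper: fabricate a trajectory with constant biomass per component
fake_traj <- function(means, years = 20L, window = 10L) {
  days <- seq(0L, years * 365L, by = 365L)
  structure(list(
    biomass = matrix(rep(means, each = length(days)), ncol = length(means),
                     dimnames = list(NULL, names(means))),
    day = days, ids = names(means),
    settings = list(averaging_window_years = window, spin_up_years = 5L)),
    class = "foodweb_trajectory")
}

test_that("biomass change is the signed relative change of window means", {
  ctl <- fake_traj(c(A = 100, B = 100, C = 50))
  prt <- fake_traj(c(A = 125, B = 60, C = 50))
  ch <- biomass_change(prt, ctl)
  expect_equal(ch$delta, c(0.25, -0.40, 0))
  ## identical trajectories: all deltas zero
  expect_equal(biomass_change(ctl, ctl)$delta, c(0, 0, 0))
  ## zero control mean flagged undefined
  ctl0 <- fake_traj(c(A = 0, B = 100, C = 50))
  expect_true(is.na(biomass_change(prt, ctl0)$delta[1]))
})

test_that("impact categories follow the four-band weighting", {
  expect_equal(impact_category(0.03)$weight, 1L)
  expect_equal(impact_category(-0.15)$weight, 3L)
  expect_equal(impact_category(0.07)$weight, 2L)
  expect_equal(impact_category(0.30)$weight, 4L)
  ## shared endpoints are assigned upward (half-open bands)
  expect_equal(impact_category(c(0.05, 0.10, 0.20))$weight, c(2L, 3L, 4L))
  expect_equal(impact_category(0.0499999)$weight, 1L)
  expect_error(impact_category(NaN), "finite")
  ## weight is nondecreasing in |delta|
  set.seed(1)
  d <- sort(abs(rnorm(200, 0, 0.2)))
  expect_true(all(diff(impact_category(d)$weight) >= 0))
  ## sign never matters
  expect_equal(impact_category(-d)$weight, impact_category(d)$weight)
})

test_that("the impact factor is the mean category weight over the scope", {
  ch <- data.frame(component = letters[1:4], delta = c(0.02, 0.07, 0.15, 0.30))
  expect_equal(as.numeric(impact_factor(ch)), 2.5)
  expect_equal(as.numeric(impact_factor(data.frame(delta = c(0, 0.01)))), 1.0)
  expect_equal(as.numeric(impact_factor(data.frame(delta = c(0.5, -0.9)))), 4.0)

  ## key-species scope filters on the flag
  ch$is_key <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(as.numeric(impact_factor(ch, scope = "key_species")), 1.5)

  ## undefined deltas are excluded and counted
  ch2 <- data.frame(delta = c(0.3, NA, 0.02))
  f <- impact_factor(ch2)
  expect_equal(as.numeric(f), 2.5)
  expect_equal(attr(f, "n_excluded"), 1L)
  expect_error(impact_factor(data.frame(delta = NA_real_)), "no components")

  ## mean property: factor of a concatenation lies between the two set means
  s1 <- data.frame(delta = c(0.02, 0.07))   # 1.5
  s2 <- data.frame(delta = c(0.15, 0.30))   # 3.5
  both <- impact_factor(rbind(s1, s2))
  expect_gte(as.numeric(both), as.numeric(impact_factor(s1)))
  expect_lte(as.numeric(both), as.numeric(impact_factor(s2)))
})

test_that("interaction classification is exhaustive, exclusive and symmetric", {
  expect_equal(classify_interaction(0.10, 0.05, 0.15)$label, "additive")
  expect_equal(classify_interaction(0.10, 0.05, 0.30)$label, "synergistic")
  expect_equal(classify_interaction(-0.10, -0.05, -0.05)$label, "antagonistic")
  expect_equal(classify_interaction(0.10, 0.05, 0.15)$residual, 0)

  set.seed(2)
  d1 <- rnorm(300, 0, 0.2); d2 <- rnorm(300, 0, 0.2); d12 <- rnorm(300, 0, 0.4)
  cl <- classify_interaction(d1, d2, d12)
  expect_true(all(cl$label %in% c("additive", "synergistic", "antagonistic")))
  ## swapping the single-run deltas never changes the label
  expect_equal(classify_interaction(d2, d1, d12)$label, cl$label)
  ## flipping the sign of all three preserves the label
  expect_equal(classify_interaction(-d1, -d2, -d12)$label, cl$label)
})

test_that("interaction tabulation yields percentages summing to 100", {
  cl <- data.frame(component = c("a", "a", "a", "a"),
                   label = c("additive", "additive", "antagonistic",
                             "synergistic"))
  tab <- tabulate_interactions(cl, c(a = "g1"))
  expect_equal(c(tab$additive, tab$synergistic, tab$antagonistic),
               c(50, 25, 25))
  one <- tabulate_interactions(data.frame(component = "a", label = "additive"),
                               c(a = "g1"))
  expect_equal(c(one$additive, one$synergistic, one$antagonistic),
               c(100, 0, 0))
  empty <- tabulate_interactions(cl[0, ], c(a = "g1"))
  expect_equal(nrow(empty), 0L)
  expect_error(tabulate_interactions(cl, c(b = "g1")), "no group")

  set.seed(3)
  cl2 <- data.frame(component = sample(letters[1:5], 200, replace = TRUE),
                    label = sample(c("additive", "synergistic", "antagonistic"),
                                   200, replace = TRUE))
  g <- setNames(c("low", "low", "mid", "mid", "top"), letters[1:5])
  tab2 <- tabulate_interactions(cl2, g)
  expect_true(all(abs(rowSums(tab2[, c("additive", "synergistic",
                                       "antagonistic")]) - 100) < 0.1))
})

test_that("response correlations capture co-varying components", {
  d <- rbind(x = c(0.1, -0.2, 0.3, 0.05),
             y = 2 * c(0.1, -0.2, 0.3, 0.05),
             z = -c(0.1, -0.2, 0.3, 0.05),
             flat = rep(0.1, 4))
  m <- response_correlation(d)
  expect_equal(diag(m), c(x = 1, y = 1, z = 1, flat = 1))
  expect_equal(m["x", "y"], 1)
  expect_equal(m["x", "z"], -1)
  expect_true(is.na(m["x", "flat"]))  # zero variance flagged undefined
  expect_equal(m, t(m))
  expect_error(response_correlation(d[, 1, drop = FALSE]), "at least 2")
})
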