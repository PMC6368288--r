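## Synthetic food-web generator: builds a Barents Sea-like desk-scale web
## (forced primary producer, 4 zooplankton pools, 3 wasp-waist pelagic fish,
## cod- and minke-whale-analogue top predators, detritus), equilibrates it by
## an internal burn-in, and provides the stability check and tuner.

#' Template for the synthetic food web
#'
#' Guild counts, topology and parameter centers for [generate_web()]. The
#' default mirrors the structure the sensitivity design assumes: 1 forced
#' producer, 4 zooplankton biomass pools, 3 age-structured pelagic fish (all
#' Beverton-Holt with lognormal recruitment variation), 2 top predators (a
#' cod analogue with deterministic Beverton-Holt recruitment and a whale
#' analogue with constant per-adult recruitment), and 1 detritus pool; the 4
#' pools and 5 vertebrates are the key species.
#'
#' @param n_zooplankton,n_pelagic,n_top_predators guild counts (at least the
#'   defaults).
#' @param jitter relative half-width of the uniform parameter sampling around
#'   the guild centers (drawn from the generation seed).
#' @param bloom_amplitude amplitude of the producer's spring-bloom cycle,
#'   sized so the forced producer itself stays within the stability band.
#' @param recruitment_sigma lognormal sigma for the pelagic-fish recruitment
#'   deviates.
#' @param burn_in_years internal equilibration run whose end state becomes
#'   the initial state of the generated web.
#' @param band default stability band (ratio to initial biomass).
#' @return a `web_template` list.
#' @export
web_template <- function(n_zooplankton = 4, n_pelagic = 3, n_top_predators = 2,
                         jitter = 0.10, bloom_amplitude = 0.7,
                         recruitment_sigma = 0.25, burn_in_years = 40,
                         band = c(0.5, 1.5)) {
  if (n_zooplankton < 4 || n_pelagic < 3 || n_top_predators < 2)
    .stopf("template counts must be at least the defaults (4 zooplankton, 3 pelagic fish, 2 top predators)")
  structure(list(n_zooplankton = n_zooplankton, n_pelagic = n_pelagic,
                 n_top_predators = n_top_predators, jitter = jitter,
                 bloom_amplitude = bloom_amplitude,
                 recruitment_sigma = recruitment_sigma,
                 burn_in_years = burn_in_years, band = band),
            class = "web_template")
}

## Vertebrate feeding is parameterized through a target assimilation level:
## an individual of weight w aims to assimilate q * w * mum per day, with
## q = min(sat, ratio / w). Small (young) individuals are then food-limited
## relative to the growth cap (growth scales with body size), large ones
## assimilate just above their growth-plus-maintenance demand, so predators
## never crop prey far beyond what they can convert.
.Q_SAT <- 0.5      # saturation fraction x/(1+x) for small individuals
.Q_RATIO <- 1.2    # adult assimilation demand as a multiple of mum

.q_target <- function(w) pmin(.Q_SAT, .Q_RATIO / w)

## steady-state weight-at-age under the q-rule feeding model: daily net gain
## of an individual of weight w is (min(q w, 1) - maint) * mum
.init_weights <- function(mum, w0s, w0r, growth_split, maint_frac) {
  n <- length(mum)
  ws <- numeric(n); wr <- numeric(n)
  ws[1] <- w0s; wr[1] <- w0r
  for (a in seq_len(n - 1)) {
    w <- ws[a] + wr[a]
    for (d in seq_len(365)) {
      net <- (min(.q_target(w) * w, 1) - maint_frac) * mum[a]
      w <- w + net
    }
    gain <- w - (ws[a] + wr[a])
    ws[a + 1] <- ws[a] + growth_split * gain
    wr[a + 1] <- wr[a] + (1 - growth_split) * gain
  }
  list(w_struct = ws, w_reserve = wr)
}

#' Generate a synthetic food-web configuration
#'
#' Builds a fully specified, deterministic (in `template` and `seed`)
#' configuration: rates are sampled uniformly within `jitter` of
#' guild-plausible centers, initial vertebrate states are set near their
#' food-replete steady state, and the whole web is then equilibrated by a
#' burn-in run whose final state is adopted as the initial state.
#'
#' @param template a [web_template()].
#' @param seed integer seed; the generator is a pure function of
#'   `(template, seed)`.
#' @return a validated `foodweb_config`.
#' @export
generate_web <- function(template = web_template(), seed = 1L) {
  stopifnot(inherits(template, "web_template"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  jit <- function(x) x * runif(length(x), 1 - template$jitter, 1 + template$jitter)

  zoo_ids <- c("ZS", "ZM", "ZL", "ZG",
               if (template$n_zooplankton > 4)
                 paste0("Z", seq(5, template$n_zooplankton)))
  fish_ids <- c("CAP", "SSH", "PCO",
                if (template$n_pelagic > 3)
                  paste0("PF", seq(4, template$n_pelagic)))
  top_ids <- c("NCO", "MWH",
               if (template$n_top_predators > 2)
                 paste0("TP", seq(3, template$n_top_predators)))
  ids <- c("PP", zoo_ids, fish_ids, top_ids, "DET")

  comp <- data.frame(
    id = ids,
    name = ids,
    kind = c("producer", rep("biomass_pool", length(zoo_ids)),
             rep("vertebrate", length(fish_ids) + length(top_ids)), "detritus"),
    guild = c("phytoplankton", rep("zooplankton", length(zoo_ids)),
              rep("pelagic_fish", length(fish_ids)),
              rep("top_predator", length(top_ids)), "detritus"),
    n_age_classes = c(1L, rep(1L, length(zoo_ids)),
                      ifelse(fish_ids == "CAP", 5L, 10L),
                      rep(10L, length(top_ids)), 1L),
    is_key_species = c(FALSE, rep(TRUE, 4), rep(FALSE, length(zoo_ids) - 4),
                       rep(TRUE, 3), rep(FALSE, length(fish_ids) - 3),
                       rep(TRUE, 2), rep(FALSE, length(top_ids) - 2), FALSE),
    recruitment_mode = c("none", rep("none", length(zoo_ids)),
                         rep("beverton_holt", length(fish_ids)),
                         c("beverton_holt", "constant_per_adult",
                           rep("beverton_holt", length(top_ids) - 2)), "none"),
    recruitment_sigma = c(0, rep(0, length(zoo_ids)),
                          rep(template$recruitment_sigma, length(fish_ids)),
                          rep(0, length(top_ids)), 0),
    stringsAsFactors = FALSE)

  ## guild parameter centers (self-consistent desk units, mg N).
  ## sat is the x/(1+x) saturation level of the pool's functional response at
  ## the expected prey field; pools sit near-replete (their own mum dominates)
  zoo_tab <- data.frame(
    mum = c(0.25, 0.15, 0.08, 0.05), E = c(0.5, 0.5, 0.55, 0.4),
    mL = c(0.010, 0.008, 0.005, 0.004), sat = c(0.75, 0.75, 0.75, 0.5),
    B0 = c(2.0e4, 1.5e4, 1.0e4, 3.0e3))
  zoo_tab <- zoo_tab[rep(1:4, length.out = length(zoo_ids)), ]

  ## vertebrates: mum is mass gain per individual per day; R0/Z set the
  ## expected recruitment and total-mortality scale the initial age structure
  ## is built from
  fish_tab <- list(
    CAP = list(mum = c(0.010, 0.008, 0.006, 0.005, 0.004), maturity = 3L,
               w0 = 0.5, E = 0.6, mL = 5e-4,
               R0 = 1500, Z = 0.6, BHb_frac = 1, spawn_frac = 0.45),
    SSH = list(mum = c(0.012, 0.010, 0.008, 0.007, 0.006, 0.005, 0.004,
                       0.0035, 0.003, 0.0025), maturity = 4L,
               w0 = 0.6, E = 0.6, mL = 5e-4,
               R0 = 800, Z = 0.5, BHb_frac = 1, spawn_frac = 0.45),
    PCO = list(mum = c(0.008, 0.006, 0.005, 0.004, 0.0035, 0.003, 0.0028,
                       0.0026, 0.0024, 0.0022), maturity = 3L,
               w0 = 0.4, E = 0.6, mL = 5e-4,
               R0 = 600, Z = 0.5, BHb_frac = 1, spawn_frac = 0.45))
  top_tab <- list(
    NCO = list(mum = c(0.050, 0.040, 0.035, 0.030, 0.027, 0.024, 0.021,
                       0.018, 0.016, 0.014), maturity = 4L,
               w0 = 1.0, E = 0.65, mL = 3e-4,
               R0 = 40, Z = 0.35, BHb_frac = 1, spawn_frac = 0.35),
    MWH = list(mum = c(0.30, 0.25, 0.22, 0.20, 0.18, 0.16, 0.15, 0.14,
                       0.13, 0.12), maturity = 6L,
               w0 = 60, E = 0.7, mL = 1e-4,
               R0 = 2, Z = 0.2, KDENR = 0.45, spawn_frac = 0.15))
  fish_tab <- c(fish_tab,
                setNames(rep(fish_tab["PCO"], max(0, length(fish_ids) - 3)),
                         fish_ids[-(1:3)]))
  top_tab <- c(top_tab,
               setNames(rep(top_tab["NCO"], max(0, length(top_ids) - 2)),
                        top_ids[-(1:2)]))
  vtab <- c(fish_tab, top_tab)

  ## expected initial states (weights from the feeding model, numbers from
  ## the survivorship curve with a plus group)
  init_verts <- list()
  mums <- list()
  for (id in c(fish_ids, top_ids)) {
    tb <- vtab[[id]]
    mums[[id]] <- jit(tb$mum)
    nage <- length(tb$mum)
    w <- .init_weights(mums[[id]], tb$w0 / 2, tb$w0 / 2, 0.5, 0.1)
    numbers <- tb$R0 * exp(-tb$Z * (seq_len(nage) - 1))
    numbers[nage] <- numbers[nage] / (1 - exp(-tb$Z))  # plus group
    init_verts[[id]] <- list(numbers = numbers, w_struct = w$w_struct,
                             w_reserve = w$w_reserve)
  }
  init_pools <- c(PP = NA_real_)  # set from the forcing cycle below
  init_pools[zoo_ids] <- zoo_tab$B0
  init_pools["DET"] <- 2e5

  ## availability matrix (maximum potential fraction of prey available);
  ## the herring -> capelin link stands in for juvenile-herring predation on
  ## capelin recruits
  diet <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  set_diet <- function(pred, prey, p) diet[pred, prey] <<- p
  set_diet("ZS", "PP", 0.50); set_diet("ZS", "DET", 0.10)
  set_diet("ZM", "PP", 0.45)
  set_diet("ZL", "PP", 0.40)
  set_diet("ZG", "ZS", 0.08); set_diet("ZG", "ZM", 0.08)
  for (id in zoo_ids[-(1:4)]) set_diet(id, "PP", 0.40)
  set_diet("CAP", "ZS", 0.10); set_diet("CAP", "ZM", 0.10); set_diet("CAP", "ZL", 0.08)
  set_diet("SSH", "ZS", 0.08); set_diet("SSH", "ZM", 0.10); set_diet("SSH", "ZL", 0.08)
  set_diet("SSH", "CAP", 0.02)
  set_diet("PCO", "ZS", 0.06); set_diet("PCO", "ZM", 0.08); set_diet("PCO", "ZL", 0.06)
  for (id in fish_ids[-(1:3)]) {
    set_diet(id, "ZS", 0.06); set_diet(id, "ZM", 0.06)
  }
  for (id in top_ids) {
    set_diet(id, "CAP", if (id == "NCO") 0.03 else 0.02)
    set_diet(id, "SSH", if (id == "NCO") 0.03 else 0.02)
    set_diet(id, "PCO", if (id == "NCO") 0.02 else 0.015)
    set_diet(id, "ZL", 0.02)
  }

  one <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  overlap <- one
  ## the polar-cod analogue sits in the north: reduced spatial overlap with
  ## the rest of the system
  overlap["PCO", ] <- 0.7
  overlap[, "PCO"] <- 0.7
  diag(overlap) <- 1

  ## expected standing biomass per component, for sizing consumption rates
  b_expected <- init_pools
  b_expected["PP"] <- 5e4
  for (id in names(init_verts))
    b_expected[id] <- sum(init_verts[[id]]$numbers *
                            (init_verts[[id]]$w_struct + init_verts[[id]]$w_reserve))
  b_expected <- b_expected[ids]
  avail_expected <- diet * overlap
  f_typ <- as.vector(avail_expected %*% b_expected)
  names(f_typ) <- ids

  params <- list()
  for (k in seq_along(zoo_ids)) {
    id <- zoo_ids[k]; z <- zoo_tab[k, ]
    mum <- jit(z$mum)
    x <- z$sat / (1 - z$sat)
    params[[id]] <- list(
      mum = mum, C = x * mum / (z$E * f_typ[[id]]), E = z$E, mL = jit(z$mL),
      ## quadratic term sized to absorb realized growth at the target biomass
      mQ = jit((0.72 * mum - z$mL) / z$B0))
  }
  for (id in c(fish_ids, top_ids)) {
    tb <- vtab[[id]]
    mum <- mums[[id]]
    nage <- length(mum)
    v <- init_verts[[id]]
    w <- v$w_struct + v$w_reserve
    ## per-age consumption from the target assimilation q(w) * w * mum
    q <- .q_target(w)
    x <- q / (1 - q)
    Cvec <- x * mum / (tb$E * f_typ[[id]])
    biom <- sum(v$numbers * w)
    ## quadratic mortality sized to take roughly 40% of the expected total
    ## mortality at the expected abundance
    mQ <- 0.4 * (tb$Z / 365) / mean(v$numbers)
    p <- list(
      mum = mum, C = Cvec, E = tb$E,
      mL = jit(tb$mL), mQ_juvenile = jit(mQ), mQ_adult = jit(mQ),
      mSt_threshold = 0.2, mSt_rate = 1e-3, maturity_age = tb$maturity,
      spawn_fraction = tb$spawn_frac, spawn_threshold = 0.25,
      growth_split = 0.5, maint_frac = 0.1,
      recruit_w_struct = tb$w0 / 2, recruit_w_reserve = tb$w0 / 2)
    if (is.null(tb$KDENR)) {
      mat <- seq(tb$maturity, nage)
      Sp <- sum(v$numbers[mat] * tb$spawn_frac * v$w_reserve[mat])
      p$BHb <- tb$BHb_frac * biom
      p$BHa <- tb$R0 * (biom + p$BHb) / Sp
    } else {
      p$KDENR <- tb$KDENR
    }
    params[[id]] <- p
  }
  params[["DET"]] <- list(mum = 0, C = 0, E = 0, mL = 0.06, mQ = 0)

  cyc_days <- seq_len(365)
  cycle <- 5e4 * (0.78 + template$bloom_amplitude *
                    exp(-0.5 * ((cyc_days - 120) / 45)^2))
  ## reference level placed so the seasonal range sits inside the band
  init_pools["PP"] <- 1.1 * mean(cycle)

  cfg <- foodweb_config(
    components = comp, params = params, diet = diet,
    refuge = list(overlap = overlap, habitat = one, size = one),
    init = list(pools = init_pools, verts = init_verts),
    forcing = list(producer_cycle = list(PP = cycle)),
    settings = modifyList(default_settings(), list(seed = as.integer(seed))))

  ## equilibrate: adopt the end state of a burn-in run as the initial state
  if (template$burn_in_years > 0) {
    bcfg <- cfg
    bcfg$settings$years_total <- as.integer(template$burn_in_years)
    bcfg$settings$averaging_window_years <- 1L
    bcfg$settings$spin_up_years <- 0L
    bcfg$settings$record_every <- 365L
    traj <- run_simulation(bcfg, seed = seed)
    cfg$init$pools[names(traj$final_state$pools)] <- traj$final_state$pools
    cfg$init$pools["PP"] <- 1.1 * mean(cycle)
    cfg$init$verts <- traj$final_state$verts
    validate_config(cfg)
  }
  cfg
}

#' The shipped default food web
#'
#' Loads the frozen, stability-tuned default fixture from the package's
#' `extdata`. All design counts and the baseline-stability checks in the
#' test-suite run against this web.
#'
#' @return a `foodweb_config`.
#' @export
default_web <- function() {
  load_config(system.file("extdata", "default_web.yaml",
                          package = "foodwebsens", mustWork = TRUE))
}

#' Check baseline stability of a trajectory
#'
#' Applies the Atlantis-community rule of thumb: after the spin-up period,
#' each component's biomass should stay within `band` (default 0.5-1.5)
#' times its initial level. Also reports, for each vertebrate cohort, whether
#' its annual individual weight stayed within the band relative to its
#' initial weight, and the overall fraction of cohorts in band.
#'
#' @param traj a `foodweb_trajectory` (from the control run).
#' @param band lower and upper biomass ratio bounds.
#' @param spin_up_years burn-in years excluded from the check.
#' @return list of class `stability_report`: `components` (per-component
#'   min/max ratio and pass flag), `cohorts` (per species x age),
#'   `cohort_fraction_in_band`, `pass` (all components in band).
#' @export
stability_check <- function(traj, band = c(0.5, 1.5),
                            spin_up_years = traj$settings$spin_up_years) {
  sel <- traj$day > spin_up_years * 365
  if (!any(sel)) .stopf("trajectory does not extend past the spin-up period")
  init <- traj$init_biomass
  if (any(init <= 0))
    .stopf("zero initial biomass for %s", names(init)[which(init <= 0)[1]])
  ratios <- sweep(traj$biomass[sel, , drop = FALSE], 2, init, "/")
  comps <- data.frame(
    component = colnames(ratios),
    min_ratio = apply(ratios, 2, min),
    max_ratio = apply(ratios, 2, max))
  comps$pass <- comps$min_ratio >= band[1] & comps$max_ratio <= band[2]
  rownames(comps) <- NULL

  cohorts <- NULL
  for (id in names(traj$vert_annual)) {
    v <- traj$vert_annual[[id]]
    w <- v$w_struct + v$w_reserve
    w0 <- traj$init_verts[[id]]$w_struct + traj$init_verts[[id]]$w_reserve
    yrs <- seq_len(nrow(w)) > spin_up_years
    if (!any(yrs)) next
    wr <- sweep(w[yrs, , drop = FALSE], 2, w0, "/")
    cohorts <- rbind(cohorts, data.frame(
      component = id, age = seq_len(ncol(w)),
      min_ratio = apply(wr, 2, min), max_ratio = apply(wr, 2, max)))
  }
  if (!is.null(cohorts)) {
    cohorts$pass <- cohorts$min_ratio >= band[1] & cohorts$max_ratio <= band[2]
    rownames(cohorts) <- NULL
  }
  structure(list(components = comps, cohorts = cohorts,
                 cohort_fraction_in_band =
                   if (is.null(cohorts)) NA_real_ else mean(cohorts$pass),
                 band = band, pass = all(comps$pass)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %s (band %.2f-%.2f); %d/%d components in band",
              if (x$pass) "PASS" else "FAIL", x$band[1], x$band[2],
              sum(x$components$pass), nrow(x$components)))
  if (!is.na(x$cohort_fraction_in_band))
    cat(sprintf("; %.0f%% of cohorts in weight band",
                100 * x$cohort_fraction_in_band))
  cat("\n")
  invisible(x)
}

#' Tune a web to baseline stability
#'
#' Iteratively rescales mortality coefficients (quadratic `mQ` for pools and
#' vertebrates, remineralization `mL` for detritus) by the bounded ratio of
#' each failing component's post-spin-up mean biomass to its initial level,
#' pulling its equilibrium back toward the initial state; components falling
#' below the band additionally get the predation availability on them relaxed
#' by a bounded factor. Topology and component counts are never changed. The
#' procedure is deterministic given the config's seed.
#'
#' @param config a `foodweb_config`.
#' @param max_iters maximum tuning iterations.
#' @param band stability band.
#' @param step_bounds per-iteration bounds on any scaling factor.
#' @return list with `config` (tuned), `report` (final [stability_check()]),
#'   `converged`, `iterations`.
#' @export
tune_to_stability <- function(config, max_iters = 20, band = c(0.5, 1.5),
                              step_bounds = c(0.5, 2)) {
  clamp <- function(x) pmin(pmax(x, step_bounds[1]), step_bounds[2])
  comp <- config$components
  traj <- run_simulation(config)
  report <- stability_check(traj, band)
  iter <- 0L
  while (!report$pass && iter < max_iters) {
    iter <- iter + 1L
    mean_ratio <- window_mean_biomass(traj) / traj$init_biomass
    for (i in which(!report$components$pass)) {
      id <- report$components$component[i]
      kind <- comp$kind[comp$id == id]
      if (kind == "producer") next  # prescribed by forcing
      f <- clamp(mean_ratio[[id]])
      p <- config$params[[id]]
      if (kind == "vertebrate") {
        p$mQ_juvenile <- p$mQ_juvenile * f
        p$mQ_adult <- p$mQ_adult * f
      } else if (kind == "detritus") {
        p$mL <- p$mL * f
      } else {
        p$mQ <- p$mQ * f
      }
      config$params[[id]] <- p
      if (mean_ratio[[id]] < band[1]) {
        relax <- max(mean_ratio[[id]], 0.7)
        config$diet[, id] <- config$diet[, id] * relax
      }
    }
    traj <- run_simulation(config)
    report <- stability_check(traj, band)
  }
  list(config = config, report = report, converged = report$pass,
       iterations = iter)
}
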