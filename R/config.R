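## Food-web configuration: domain types, validation, YAML persistence.

.kinds <- c("vertebrate", "biomass_pool", "producer", "detritus")
.guilds <- c("phytoplankton", "zooplankton", "pelagic_fish", "demersal_fish",
             "top_predator", "detritus")
.recruitment_modes <- c("beverton_holt", "constant_per_adult", "none")

#' Construct a food-web configuration
#'
#' Bundles the component table, per-component process parameters, the diet
#' (availability) matrix, refuge factors, initial state, primary-producer
#' forcing and simulation settings into a validated `foodweb_config` object.
#'
#' @param components data.frame with columns `id`, `name`, `kind`
#'   (`"vertebrate"`, `"biomass_pool"`, `"producer"`, `"detritus"`), `guild`,
#'   `n_age_classes`, `is_key_species`, `recruitment_mode`
#'   (`"beverton_holt"`, `"constant_per_adult"`, `"none"`) and
#'   `recruitment_sigma` (lognormal sigma; 0 = deterministic recruitment).
#' @param params named list (by component id) of process parameters. Pools
#'   use scalars `mum`, `C`, `E`, `mL`, `mQ`. Vertebrates use per-age vectors
#'   `mum`, `C` plus `E`, `mL`, `mQ_juvenile`, `mQ_adult`, `mSt_threshold`,
#'   `mSt_rate`, `maturity_age`, `spawn_fraction`, `spawn_threshold`,
#'   `growth_split`, `maint_frac`, `recruit_w_struct`, `recruit_w_reserve`,
#'   and either `BHa`/`BHb` or `KDENR` according to the recruitment mode.
#' @param diet predator-by-prey availability matrix, entries in \[0, 1\]
#'   (the maximum potential fraction of the prey available to the predator).
#' @param refuge list with predator-by-prey matrices `overlap`, `habitat`,
#'   `size`, each in \[0, 1\]; `NULL` means no refuge (all ones).
#' @param init list with `pools` (named biomass vector, mg N, covering all
#'   non-vertebrates) and `verts` (named list of per-age `numbers`,
#'   `w_struct`, `w_reserve`; weights in mg N per individual).
#' @param forcing list with `producer_cycle`: named list of 365-value annual
#'   biomass cycles (mg N), one per producer, looped every simulated year;
#'   `NULL` for a closed web without producers.
#' @param settings list of simulation settings; see [default_settings()].
#' @return object of class `foodweb_config`.
#' @seealso [load_config()], [save_config()], [validate_config()]
#' @export
foodweb_config <- function(components, params, diet, refuge = NULL, init,
                           forcing = NULL, settings = default_settings()) {
  if (is.null(refuge)) {
    ids <- components$id
    one <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    refuge <- list(overlap = one, habitat = one, size = one)
  }
  settings <- modifyList(default_settings(), settings)
  cfg <- structure(
    list(components = components, params = params, diet = diet,
         refuge = refuge, init = init, forcing = forcing,
         settings = settings),
    class = "foodweb_config")
  validate_config(cfg)
  cfg
}

#' Default simulation settings
#'
#' 55 simulated years, a 25-year spin-up and a 10-year averaging window for
#' response metrics, with a daily time step, annual spawning on day 90 and
#' daily biomass recording.
#'
#' @return named list of settings.
#' @export
default_settings <- function() {
  list(years_total = 55L, spin_up_years = 25L, averaging_window_years = 10L,
       step_days = 1, spawn_day = 90L, record_every = 1L, seed = 1L)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a food-web configuration
#'
#' Checks every structural invariant: unique ids, enum membership, age-class
#' counts (pools 1, vertebrates 2-10), recruitment-mode consistency,
#' parameter-vector lengths, rate nonnegativity, availability and refuge
#' entries in \[0, 1\], matrix dimensions, initial-state completeness and
#' positivity, forcing positivity and settings sanity. Errors name the
#' offending component, parameter or matrix entry.
#'
#' @param config a `foodweb_config`.
#' @return the config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  comp <- config$components
  if (!is.data.frame(comp) || nrow(comp) == 0L)
    .stopf("config must contain at least one component")
  need <- c("id", "name", "kind", "guild", "n_age_classes", "is_key_species",
            "recruitment_mode", "recruitment_sigma")
  miss <- setdiff(need, names(comp))
  if (length(miss)) .stopf("components table lacks columns: %s",
                           paste(miss, collapse = ", "))
  if (anyDuplicated(comp$id))
    .stopf("duplicate component id: %s", comp$id[duplicated(comp$id)][1])
  bad <- setdiff(comp$kind, .kinds)
  if (length(bad)) .stopf("unknown component kind: %s", bad[1])
  bad <- setdiff(comp$guild, .guilds)
  if (length(bad)) .stopf("unknown guild: %s", bad[1])
  bad <- setdiff(comp$recruitment_mode, .recruitment_modes)
  if (length(bad)) .stopf("unknown recruitment_mode: %s", bad[1])
  ids <- comp$id

  for (i in seq_len(nrow(comp))) {
    id <- comp$id[i]; kind <- comp$kind[i]; nage <- comp$n_age_classes[i]
    if (kind == "vertebrate") {
      if (nage < 2 || nage > 10)
        .stopf("vertebrate %s must have 2-10 age classes, has %d", id, nage)
      if (comp$recruitment_mode[i] == "none")
        .stopf("vertebrate %s must have a recruitment mode", id)
    } else {
      if (nage != 1)
        .stopf("non-vertebrate %s must have n_age_classes = 1", id)
      if (comp$recruitment_mode[i] != "none")
        .stopf("non-vertebrate %s must have recruitment_mode 'none'", id)
    }
    if (comp$recruitment_sigma[i] < 0)
      .stopf("%s: recruitment_sigma must be nonnegative", id)
  }

  ## process parameters
  for (i in seq_len(nrow(comp))) {
    id <- comp$id[i]; kind <- comp$kind[i]; nage <- comp$n_age_classes[i]
    p <- config$params[[id]]
    if (kind %in% c("producer", "detritus")) next  # forced / passive, no params required
    if (is.null(p)) .stopf("missing process parameters for component %s", id)
    if (kind == "vertebrate") {
      for (v in c("mum", "C")) {
        if (length(p[[v]]) != nage)
          .stopf("%s: %s must have length %d (one per age class), has %d",
                 id, v, nage, length(p[[v]]))
      }
      scalars <- c("E", "mL", "mQ_juvenile", "mQ_adult", "mSt_threshold",
                   "mSt_rate", "maturity_age", "spawn_fraction",
                   "spawn_threshold", "growth_split", "maint_frac",
                   "recruit_w_struct", "recruit_w_reserve")
      miss <- scalars[!vapply(scalars, function(v) !is.null(p[[v]]), logical(1))]
      if (length(miss)) .stopf("%s: missing parameter %s", id, miss[1])
      mode <- comp$recruitment_mode[i]
      if (mode == "beverton_holt") {
        if (is.null(p$BHa) || is.null(p$BHb))
          .stopf("%s: beverton_holt recruitment requires BHa and BHb", id)
        if (!is.null(p$KDENR))
          .stopf("%s: KDENR set but recruitment_mode is beverton_holt", id)
      } else {
        if (is.null(p$KDENR))
          .stopf("%s: constant_per_adult recruitment requires KDENR", id)
        if (!is.null(p$BHa) || !is.null(p$BHb))
          .stopf("%s: BHa/BHb set but recruitment_mode is constant_per_adult", id)
      }
      if (p$maturity_age < 1 || p$maturity_age > nage)
        .stopf("%s: maturity_age outside 1..%d", id, nage)
      for (v in c("E", "spawn_fraction", "growth_split"))
        if (p[[v]] < 0 || p[[v]] > 1) .stopf("%s: %s must lie in [0, 1]", id, v)
    } else {
      for (v in c("mum", "C", "E", "mL", "mQ"))
        if (is.null(p[[v]])) .stopf("%s: missing parameter %s", id, v)
      if (p$E < 0 || p$E > 1) .stopf("%s: E must lie in [0, 1]", id)
    }
    rates <- unlist(p[setdiff(names(p), "maturity_age")], use.names = FALSE)
    if (any(!is.finite(rates)) || any(rates < 0))
      .stopf("%s: all rates must be finite and nonnegative", id)
  }

  ## matrices
  for (mname in c("diet", "overlap", "habitat", "size")) {
    m <- if (mname == "diet") config$diet else config$refuge[[mname]]
    if (!is.matrix(m) || !identical(dim(m), c(length(ids), length(ids))))
      .stopf("%s matrix must be %d x %d (predator x prey)",
             mname, length(ids), length(ids))
    if (!identical(rownames(m), ids) || !identical(colnames(m), ids)) {
      extra <- setdiff(union(rownames(m), colnames(m)), ids)
      if (length(extra))
        .stopf("%s matrix references unknown component: %s", mname, extra[1])
      .stopf("%s matrix dimnames must equal the component ids, in order", mname)
    }
    bad <- which(m < 0 | m > 1 | !is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
      .stopf("%s[%s, %s] = %g outside [0, 1]", mname,
             rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
             m[bad[1, 1], bad[1, 2]])
  }
  ## only consumers may have prey rows
  for (i in seq_len(nrow(comp))) {
    if (comp$kind[i] %in% c("producer", "detritus") &&
        any(config$diet[comp$id[i], ] > 0))
      .stopf("%s is a %s and cannot have prey (diet row must be zero)",
             comp$id[i], comp$kind[i])
  }

  ## initial state
  pools <- ids[comp$kind != "vertebrate"]
  verts <- ids[comp$kind == "vertebrate"]
  miss <- setdiff(pools, names(config$init$pools))
  if (length(miss)) .stopf("initial biomass missing for pool %s", miss[1])
  if (any(config$init$pools < 0))
    .stopf("initial biomass negative for %s",
           names(config$init$pools)[which(config$init$pools < 0)[1]])
  for (id in verts) {
    v <- config$init$verts[[id]]
    if (is.null(v)) .stopf("initial state missing for vertebrate %s", id)
    nage <- comp$n_age_classes[comp$id == id]
    for (f in c("numbers", "w_struct", "w_reserve")) {
      if (length(v[[f]]) != nage)
        .stopf("%s: initial %s must have length %d", id, f, nage)
      if (any(v[[f]] < 0)) .stopf("%s: initial %s has negative entries", id, f)
    }
    if (any(v$numbers > 0 & v$w_reserve <= 0))
      .stopf("%s: reserve weight must be positive where numbers > 0", id)
  }

  ## forcing
  producers <- ids[comp$kind == "producer"]
  if (length(producers)) {
    if (is.null(config$forcing$producer_cycle))
      .stopf("producer %s present but no forcing$producer_cycle", producers[1])
    for (id in producers) {
      cyc <- config$forcing$producer_cycle[[id]]
      if (is.null(cyc)) .stopf("no forcing cycle for producer %s", id)
      if (length(cyc) != 365L)
        .stopf("%s: forcing cycle must have 365 values, has %d", id, length(cyc))
      if (any(!is.finite(cyc)) || any(cyc <= 0))
        .stopf("%s: forcing cycle must be strictly positive", id)
    }
  }

  ## settings
  s <- config$settings
  for (v in c("years_total", "spin_up_years", "averaging_window_years",
              "step_days", "spawn_day", "record_every"))
    if (is.null(s[[v]]) || s[[v]] < 0) .stopf("setting %s must be set and >= 0", v)
  if (s$averaging_window_years > s$years_total - s$spin_up_years)
    .stopf("averaging window (%d y) exceeds post-spin-up horizon (%d y)",
           s$averaging_window_years, s$years_total - s$spin_up_years)
  if (s$spawn_day < 1 || s$spawn_day > 365)
    .stopf("spawn_day must lie in 1..365")
  invisible(config)
}

#' @export
print.foodweb_config <- function(x, ...) {
  comp <- x$components
  cat(sprintf("foodweb_config: %d components (%d vertebrates, %d pools), %d key species\n",
              nrow(comp), sum(comp$kind == "vertebrate"),
              sum(comp$kind == "biomass_pool"), sum(comp$is_key_species)))
  cat(sprintf("  %d years, %d-year spin-up, %d-year averaging window, seed %d\n",
              x$settings$years_total, x$settings$spin_up_years,
              x$settings$averaging_window_years, x$settings$seed))
  invisible(x)
}

.mat_to_map <- function(m) {
  out <- lapply(rownames(m), function(r) as.list(setNames(unname(m[r, ]), colnames(m))))
  setNames(out, rownames(m))
}

.map_to_mat <- function(map, ids, what, fill = 0) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in names(map)) {
    if (!r %in% ids) .stopf("%s matrix references unknown component: %s", what, r)
    row <- map[[r]]
    for (cc in names(row)) {
      if (!cc %in% ids) .stopf("%s matrix references unknown component: %s", what, cc)
      m[r, cc] <- row[[cc]]
    }
  }
  m
}

#' Save a food-web configuration to YAML
#'
#' Writes the full configuration as a single YAML document (matrices as
#' explicit predator -> prey maps) at a numeric precision that round-trips
#' doubles exactly; `load_config(save_config(x))` reproduces `x`.
#'
#' @param config a valid `foodweb_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  comp <- config$components
  doc <- list(
    components = lapply(seq_len(nrow(comp)), function(i) {
      list(id = comp$id[i], name = comp$name[i], kind = comp$kind[i],
           guild = comp$guild[i], n_age_classes = as.integer(comp$n_age_classes[i]),
           is_key_species = comp$is_key_species[i],
           recruitment_mode = comp$recruitment_mode[i],
           recruitment_sigma = comp$recruitment_sigma[i])
    }),
    params = config$params,
    diet = .mat_to_map(config$diet),
    refuge = lapply(config$refuge, .mat_to_map),
    init = list(pools = as.list(config$init$pools),
                verts = config$init$verts),
    forcing = config$forcing,
    settings = config$settings)
  ## emit doubles with 17 significant digits (unquoted) so reloading
  ## reproduces them bit-for-bit
  txt <- yaml::as.yaml(doc, handlers = list(
    numeric = function(v) structure(sprintf("%.17g", v), class = "verbatim")))
  writeLines(txt, path)
  invisible(path)
}

#' Load a food-web configuration from YAML
#'
#' Reads a configuration written by [save_config()] (or hand-edited in the
#' same schema), reconstructs matrices and state vectors and validates every
#' invariant before returning.
#'
#' @param path YAML file path.
#' @return a validated `foodweb_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$components) || !length(doc$components))
    .stopf("config file %s has no components", path)
  comp <- do.call(rbind, lapply(doc$components, function(cc)
    data.frame(id = cc$id, name = cc$name, kind = cc$kind, guild = cc$guild,
               n_age_classes = as.integer(cc$n_age_classes),
               is_key_species = isTRUE(cc$is_key_species),
               recruitment_mode = cc$recruitment_mode,
               recruitment_sigma = as.numeric(cc$recruitment_sigma),
               stringsAsFactors = FALSE)))
  ids <- comp$id
  params <- lapply(doc$params, function(p) {
    p <- lapply(p, function(v) as.numeric(unlist(v)))
    if (!is.null(p$maturity_age)) p$maturity_age <- as.integer(p$maturity_age)
    p
  })
  verts <- doc$init$verts
  verts <- lapply(verts, function(v) lapply(v, function(x) as.numeric(unlist(x))))
  forcing <- doc$forcing
  if (!is.null(forcing$producer_cycle))
    forcing$producer_cycle <- lapply(forcing$producer_cycle,
                                     function(x) as.numeric(unlist(x)))
  settings <- doc$settings
  for (v in c("years_total", "spin_up_years", "averaging_window_years",
              "spawn_day", "record_every", "seed"))
    if (!is.null(settings[[v]])) settings[[v]] <- as.integer(settings[[v]])
  if (!is.null(settings$step_days)) settings$step_days <- as.numeric(settings$step_days)
  foodweb_config(
    components = comp,
    params = params[ids[ids %in% names(params)]],
    diet = .map_to_mat(doc$diet, ids, "diet"),
    refuge = lapply(doc$refuge, .map_to_mat, ids = ids, what = "refuge", fill = 1),
    init = list(pools = unlist(doc$init$pools), verts = verts),
    forcing = forcing,
    settings = settings)
}
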