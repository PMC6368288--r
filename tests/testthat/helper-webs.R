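## Test fixtures built in code, plus an independent naive re-implementation
## of the daily forward map used as the oracle for the engine.

## minimal valid web: one producer, one grazing pool
tiny_web <- function() {
  comp <- data.frame(
    id = c("PP", "Z1"), name = c("producer", "grazer"),
    kind = c("producer", "biomass_pool"),
    guild = c("phytoplankton", "zooplankton"),
    n_age_classes = 1L, is_key_species = c(FALSE, TRUE),
    recruitment_mode = "none", recruitment_sigma = 0,
    stringsAsFactors = FALSE)
  diet <- matrix(0, 2, 2, dimnames = list(comp$id, comp$id))
  diet["Z1", "PP"] <- 0.4
  foodweb_config(
    components = comp,
    params = list(Z1 = list(mum = 0.2, C = 1e-5, E = 0.5, mL = 0.01, mQ = 5e-6)),
    diet = diet,
    init = list(pools = c(PP = 1e4, Z1 = 5e3), verts = list()),
    forcing = list(producer_cycle = list(PP = rep(1e4, 365))),
    settings = list(years_total = 2L, spin_up_years = 0L,
                    averaging_window_years = 1L))
}

## closed 3-component web (two pools + detritus), no producer forcing
closed_web3 <- function(mL_A = 0.01, mQ_A = 1e-6, mL_B = 0.005, mQ_B = 2e-6,
                        years = 3L) {
  comp <- data.frame(
    id = c("A", "B", "DET"), name = c("preyA", "predB", "detritus"),
    kind = c("biomass_pool", "biomass_pool", "detritus"),
    guild = c("zooplankton", "zooplankton", "detritus"),
    n_age_classes = 1L, is_key_species = c(TRUE, TRUE, FALSE),
    recruitment_mode = "none", recruitment_sigma = 0,
    stringsAsFactors = FALSE)
  diet <- matrix(0, 3, 3, dimnames = list(comp$id, comp$id))
  diet["B", "A"] <- 0.5
  diet["A", "DET"] <- 0.3
  foodweb_config(
    components = comp,
    params = list(
      A = list(mum = 0.10, C = 1e-5, E = 0.6, mL = mL_A, mQ = mQ_A),
      B = list(mum = 0.05, C = 2e-5, E = 0.5, mL = mL_B, mQ = mQ_B),
      DET = list(mum = 0, C = 0, E = 0, mL = 0, mQ = 0)),
    diet = diet,
    init = list(pools = c(A = 1e4, B = 5e3, DET = 2e4), verts = list()),
    settings = list(years_total = years, spin_up_years = 0L,
                    averaging_window_years = 1L))
}

## closed web with one 3-age vertebrate feeding on a pool (exercises the
## vertebrate paths: weights, recruitment, aging, quadratic mortality)
vert_web <- function(years = 2L, recruitment = c("beverton_holt",
                                                 "constant_per_adult"),
                     sigma = 0, seed = 1L) {
  recruitment <- match.arg(recruitment)
  comp <- data.frame(
    id = c("Z", "F", "DET"), name = c("pool", "fish", "detritus"),
    kind = c("biomass_pool", "vertebrate", "detritus"),
    guild = c("zooplankton", "pelagic_fish", "detritus"),
    n_age_classes = c(1L, 3L, 1L), is_key_species = c(TRUE, TRUE, FALSE),
    recruitment_mode = c("none", recruitment, "none"),
    recruitment_sigma = c(0, sigma, 0),
    stringsAsFactors = FALSE)
  diet <- matrix(0, 3, 3, dimnames = list(comp$id, comp$id))
  diet["F", "Z"] <- 0.4
  fpar <- list(mum = c(0.01, 0.008, 0.006), C = c(2e-6, 3e-6, 4e-6),
               E = 0.6, mL = 5e-4, mQ_juvenile = 1e-6, mQ_adult = 2e-6,
               mSt_threshold = 0.2, mSt_rate = 1e-3, maturity_age = 2L,
               spawn_fraction = 0.3, spawn_threshold = 0.25,
               growth_split = 0.5, maint_frac = 0.1,
               recruit_w_struct = 0.25, recruit_w_reserve = 0.25)
  if (recruitment == "beverton_holt") {
    fpar$BHa <- 5e3; fpar$BHb <- 4e3
  } else {
    fpar$KDENR <- 0.8
  }
  foodweb_config(
    components = comp,
    params = list(
      Z = list(mum = 0.15, C = 0, E = 0.5, mL = 0.002, mQ = 4e-6),
      F = fpar,
      DET = list(mum = 0, C = 0, E = 0, mL = 0, mQ = 0)),
    diet = diet,
    init = list(pools = c(Z = 2e4, DET = 1e4),
                verts = list(F = list(numbers = c(800, 400, 300),
                                      w_struct = c(0.25, 1.5, 3.0),
                                      w_reserve = c(0.25, 1.5, 3.0)))),
    settings = list(years_total = years, spin_up_years = 0L,
                    averaging_window_years = 1L, seed = seed))
}

## Independent naive recomputation of the daily map, written directly from
## the process equations with plain scalar loops. Supports pools, producer,
## detritus and vertebrates. Returns biomass rows for day 0..ndays and the
## running total nitrogen (incl. the spawn bank).
naive_run <- function(config, ndays, deviates = NULL) {
  comp <- config$components
  ids <- comp$id
  n <- length(ids)
  kind <- comp$kind
  nage <- comp$n_age_classes
  P <- config$params
  avail <- config$diet * config$refuge$overlap * config$refuge$habitat *
    config$refuge$size
  wr_floor <- 1e-8

  B <- setNames(numeric(n), ids)
  Num <- Ws <- Wr <- list()
  for (id in ids) {
    if (kind[ids == id] == "vertebrate") {
      v <- config$init$verts[[id]]
      Num[[id]] <- v$numbers; Ws[[id]] <- v$w_struct; Wr[[id]] <- v$w_reserve
    } else B[id] <- config$init$pools[[id]]
  }
  bank <- setNames(numeric(n), ids)
  pending <- setNames(numeric(n), ids)
  nyears <- ndays %/% 365 + 1
  if (is.null(deviates))
    deviates <- matrix(1, nyears, n, dimnames = list(NULL, ids))

  bio_of <- function(id) {
    if (kind[ids == id] == "vertebrate")
      sum(Num[[id]] * (Ws[[id]] + Wr[[id]]))
    else B[[id]]
  }
  out <- matrix(NA_real_, ndays + 1, n, dimnames = list(NULL, ids))
  totn <- numeric(ndays + 1)
  snap <- function(r) {
    for (id in ids) out[r, id] <<- bio_of(id)
    totn[r] <<- sum(out[r, ]) + sum(bank)
  }
  snap(1)

  for (day in seq_len(ndays)) {
    doy <- (day - 1) %% 365 + 1
    year <- (day - 1) %/% 365 + 1
    for (id in ids[kind == "producer"])
      B[id] <- config$forcing$producer_cycle[[id]][doy]
    bio <- setNames(vapply(ids, bio_of, numeric(1)), ids)

    ## grazing fluxes for every predator unit
    units <- list()
    for (id in ids[kind %in% c("biomass_pool", "vertebrate")]) {
      na <- if (kind[ids == id] == "vertebrate") nage[ids == id] else 1L
      for (a in seq_len(na)) units[[length(units) + 1]] <- list(id = id, a = a)
    }
    gr <- lapply(units, function(u) {
      p <- P[[u$id]]
      Bu <- if (kind[ids == u$id] == "vertebrate")
        Num[[u$id]][u$a] * (Ws[[u$id]][u$a] + Wr[[u$id]][u$a]) else B[[u$id]]
      bstar <- avail[u$id, ] * bio
      g <- setNames(numeric(n), ids)
      if (p$C[u$a] > 0 && Bu > 0 && sum(bstar) > 0) {
        den <- 1 + (p$C[u$a] / p$mum[u$a]) * p$E * sum(bstar)
        g <- Bu * p$C[u$a] * bstar / den
      }
      g
    })
    loss <- Reduce(`+`, gr)
    sc <- ifelse(loss > bio & loss > 0, bio / loss, 1)
    to_det <- 0
    assim <- lapply(seq_along(units), function(i) {
      e <- P[[units[[i]]$id]]$E
      e * sum(gr[[i]] * sc)
    })
    for (i in seq_along(units))
      to_det <- to_det + (1 - P[[units[[i]]$id]]$E) * sum(gr[[i]] * sc)
    loss <- pmin(loss, bio)

    ## prey removal
    for (id in ids) {
      if (loss[id] <= 0) next
      if (kind[ids == id] == "vertebrate") {
        ba <- Num[[id]] * (Ws[[id]] + Wr[[id]])
        for (a in seq_along(ba)) {
          if (ba[a] <= 0) next
          la <- loss[id] * ba[a] / bio[id]
          w <- Ws[[id]][a] + Wr[[id]][a]
          Num[[id]][a] <- max(Num[[id]][a] - la / w, 0)
        }
      } else B[id] <- max(B[id] - loss[id], 0)
    }

    ## growth allocation
    for (i in seq_along(units)) {
      u <- units[[i]]; p <- P[[u$id]]
      if (kind[ids == u$id] == "biomass_pool") {
        gain <- min(assim[[i]], p$mum * bio[u$id])
        to_det <- to_det + assim[[i]] - gain
        B[u$id] <- B[u$id] + gain
      } else {
        a <- u$a; N <- Num[[u$id]][a]
        if (N <= 0) { to_det <- to_det + assim[[i]]; next }
        gain <- min(assim[[i]] / N, p$mum[a])
        to_det <- to_det + assim[[i]] - gain * N
        m <- p$maint_frac * p$mum[a]
        pay <- min(m, gain + max(Wr[[u$id]][a] - wr_floor, 0))
        net <- gain - pay
        to_det <- to_det + pay * N
        if (net >= 0) {
          Ws[[u$id]][a] <- Ws[[u$id]][a] + p$growth_split * net
          Wr[[u$id]][a] <- Wr[[u$id]][a] + (1 - p$growth_split) * net
        } else {
          Wr[[u$id]][a] <- max(Wr[[u$id]][a] + net, wr_floor)
        }
      }
    }

    ## mortality
    for (id in ids) {
      k <- kind[ids == id]; p <- P[[id]]
      if (k == "detritus") {
        rem <- min((p$mL + p$mQ * B[id]) * B[id], B[id])
        B[id] <- B[id] - rem  # remineralization, leaves the system
      } else if (k == "biomass_pool") {
        rem <- min((p$mL + p$mQ * B[id]) * B[id], B[id])
        B[id] <- B[id] - rem
        to_det <- to_det + rem
      } else if (k == "vertebrate") {
        for (a in seq_len(nage[ids == id])) {
          N <- Num[[id]][a]
          if (N <= 0) next
          mq <- if (a < p$maturity_age) p$mQ_juvenile else p$mQ_adult
          mst <- if (Ws[[id]][a] > 0 &&
                     Wr[[id]][a] / Ws[[id]][a] < p$mSt_threshold) p$mSt_rate else 0
          rem <- min((p$mL + mq * N + mst) * N, N)
          Num[[id]][a] <- N - rem
          to_det <- to_det + rem * (Ws[[id]][a] + Wr[[id]][a])
        }
      }
    }

    ## annual recruitment on the spawn day
    if (doy == config$settings$spawn_day) {
      for (id in ids[kind == "vertebrate"]) {
        p <- P[[id]]
        mode <- comp$recruitment_mode[ids == id]
        Biom <- sum(Num[[id]] * (Ws[[id]] + Wr[[id]]))
        Sp <- 0; nm <- 0
        for (a in seq(p$maturity_age, nage[ids == id])) {
          if (Num[[id]][a] <= 0) next
          if (Ws[[id]][a] > 0 &&
              Wr[[id]][a] / Ws[[id]][a] < p$spawn_threshold) next
          take <- p$spawn_fraction * Wr[[id]][a]
          Sp <- Sp + Num[[id]][a] * take
          Wr[[id]][a] <- Wr[[id]][a] - take
          nm <- nm + Num[[id]][a]
        }
        Rc <- if (mode == "beverton_holt")
          Sp * p$BHa / (Biom + p$BHb) * deviates[year, id]
        else p$KDENR * nm
        w0 <- p$recruit_w_struct + p$recruit_w_reserve
        Rc <- max(min(Rc, if (w0 > 0) Sp / w0 else 0), 0)
        bank[id] <- bank[id] + Rc * w0
        to_det <- to_det + Sp - Rc * w0
        pending[id] <- pending[id] + Rc
      }
    }
    det_ids <- ids[kind == "detritus"]
    if (length(det_ids)) B[det_ids[1]] <- B[det_ids[1]] + to_det

    ## annual aging: promote, merge plus group, recruits into class 1
    if (doy == 365) {
      for (id in ids[kind == "vertebrate"]) {
        p <- P[[id]]
        nn <- Num[[id]]; ns <- Ws[[id]]; nr <- Wr[[id]]
        na <- length(nn)
        if (na > 1) {
          tot <- nn[na] + nn[na - 1]
          if (tot > 0) {
            ns[na] <- (Num[[id]][na] * Ws[[id]][na] +
                         Num[[id]][na - 1] * Ws[[id]][na - 1]) / tot
            nr[na] <- (Num[[id]][na] * Wr[[id]][na] +
                         Num[[id]][na - 1] * Wr[[id]][na - 1]) / tot
          }
          nn[na] <- tot
          if (na > 2) {
            nn[2:(na - 1)] <- Num[[id]][1:(na - 2)]
            ns[2:(na - 1)] <- Ws[[id]][1:(na - 2)]
            nr[2:(na - 1)] <- Wr[[id]][1:(na - 2)]
          }
        }
        nn[1] <- pending[id]
        ns[1] <- p$recruit_w_struct
        nr[1] <- p$recruit_w_reserve
        Num[[id]] <- nn; Ws[[id]] <- ns; Wr[[id]] <- nr
        bank[id] <- 0; pending[id] <- 0
      }
    }
    snap(day + 1)
  }
  list(biomass = out, total_n = totn)
}
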