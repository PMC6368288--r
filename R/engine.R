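## Simulation driver: packs a validated config into plain arrays, runs the
## compiled daily forward map (or the pure-R reference engine), and wraps the
## output as a `foodweb_trajectory`.

.kind_code <- c(biomass_pool = 0L, vertebrate = 1L, producer = 2L, detritus = 3L)

## Flatten a config (+ optional perturbation edits) into the plain-array form
## both engines consume.
.pack_config <- function(config, edits = NULL, seed = NULL) {
  if (!is.null(edits)) config <- apply_edits(config, edits)
  validate_config(config)
  comp <- config$components
  ids <- comp$id
  n <- length(ids)
  kind <- unname(.kind_code[comp$kind])
  nage <- as.integer(comp$n_age_classes)
  maxage <- max(nage)

  z <- function() numeric(n)
  mumM <- CM <- matrix(0, maxage, n, dimnames = list(NULL, ids))
  E <- mL <- mQj <- mQa <- mSt_thr <- mSt_rate <- z()
  spawn_frac <- spawn_thr <- growth_split <- maint_frac <- w0s <- w0r <- z()
  BHa <- BHb <- KDENR <- z()
  maturity <- rep(1L, n)
  rec_mode <- integer(n)

  for (i in seq_len(n)) {
    p <- config$params[[ids[i]]]
    if (is.null(p)) next
    na <- nage[i]
    mumM[seq_len(na), i] <- p$mum
    CM[seq_len(na), i] <- p$C
    E[i] <- p$E %||% 0
    mL[i] <- p$mL %||% 0
    if (kind[i] == 1L) {
      mQj[i] <- p$mQ_juvenile; mQa[i] <- p$mQ_adult
      mSt_thr[i] <- p$mSt_threshold; mSt_rate[i] <- p$mSt_rate
      maturity[i] <- as.integer(p$maturity_age)
      spawn_frac[i] <- p$spawn_fraction; spawn_thr[i] <- p$spawn_threshold
      growth_split[i] <- p$growth_split; maint_frac[i] <- p$maint_frac
      w0s[i] <- p$recruit_w_struct; w0r[i] <- p$recruit_w_reserve
      rec_mode[i] <- switch(comp$recruitment_mode[i],
                            beverton_holt = 1L, constant_per_adult = 2L, 0L)
      if (rec_mode[i] == 1L) { BHa[i] <- p$BHa; BHb[i] <- p$BHb }
      if (rec_mode[i] == 2L) KDENR[i] <- p$KDENR
    } else {
      mQa[i] <- p$mQ %||% 0; mQj[i] <- mQa[i]
    }
  }

  avail <- config$diet * config$refuge$overlap * config$refuge$habitat *
    config$refuge$size

  forcing <- matrix(0, 365, n, dimnames = list(NULL, ids))
  for (id in ids[comp$kind == "producer"])
    forcing[, id] <- config$forcing$producer_cycle[[id]]

  B0 <- z(); names(B0) <- ids
  Num0 <- Ws0 <- Wr0 <- matrix(0, maxage, n, dimnames = list(NULL, ids))
  for (i in seq_len(n)) {
    if (kind[i] == 1L) {
      v <- config$init$verts[[ids[i]]]
      Num0[seq_len(nage[i]), i] <- v$numbers
      Ws0[seq_len(nage[i]), i] <- v$w_struct
      Wr0[seq_len(nage[i]), i] <- v$w_reserve
    } else {
      B0[i] <- config$init$pools[[ids[i]]]
    }
  }

  s <- config$settings
  ndays <- as.integer(s$years_total) * 365L
  nyears <- ndays %/% 365L + 1L

  ## unit-median lognormal recruitment deviates, one column per component,
  ## drawn from the run's seed (column order fixed by the component table)
  deviates <- matrix(1, nyears, n)
  seed <- seed %||% s$seed %||% 1L
  sig <- comp$recruitment_sigma
  if (any(sig > 0 & comp$kind == "vertebrate")) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    for (i in seq_len(n))
      if (kind[i] == 1L && sig[i] > 0)
        deviates[, i] <- exp(sig[i] * rnorm(nyears))
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }

  list(ncomp = n, ids = ids, kind = kind, nage = nage, maxage = maxage,
       mum = mumM, C = CM, E = E, mL = mL, mQj = mQj, mQa = mQa,
       mSt_thr = mSt_thr, mSt_rate = mSt_rate, maturity = maturity,
       spawn_frac = spawn_frac, spawn_thr = spawn_thr,
       growth_split = growth_split, maint_frac = maint_frac,
       w0s = w0s, w0r = w0r, rec_mode = rec_mode, BHa = BHa, BHb = BHb,
       KDENR = KDENR, avail = avail, forcing = forcing, deviates = deviates,
       det_idx = if (any(kind == 3L)) which(kind == 3L)[1] - 1L else -1L,
       ndays = ndays, spawn_day = as.integer(s$spawn_day),
       record_every = as.integer(s$record_every), dt = as.numeric(s$step_days),
       B0 = unname(B0), Num0 = Num0, Ws0 = Ws0, Wr0 = Wr0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a food-web simulation
#'
#' Runs the daily forward map for the configured number of years: grazing
#' (with a prey standing-stock cap), growth allocation, mortality, annual
#' recruitment on the spawn day and annual cohort aging, with producer
#' forcing looped every year. The run is a pure function of
#' `(config, edits, seed)`.
#'
#' @param config a validated [foodweb_config()].
#' @param edits optional perturbation: a run spec from the manifest (see
#'   [build_manifest()]) or a data.frame with columns `component`,
#'   `parameter`, `multiplier`.
#' @param seed integer seed for recruitment deviates; defaults to the
#'   config's `settings$seed`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   implementation of the identical map, used for cross-validation).
#' @return a `foodweb_trajectory`: recorded biomass per component, total
#'   nitrogen, annual vertebrate age-structure state, and the final state.
#' @export
run_simulation <- function(config, edits = NULL, seed = NULL,
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  pk <- .pack_config(config, edits, seed)
  out <- if (engine == "cpp") .sim_core_cpp(pk) else .sim_core_r(pk)
  ids <- pk$ids
  colnames(out$biomass) <- ids
  verts <- ids[pk$kind == 1L]
  vert_annual <- setNames(lapply(which(pk$kind == 1L), function(j) {
    list(numbers = out$vert_num[[j]], w_struct = out$vert_ws[[j]],
         w_reserve = out$vert_wr[[j]])
  }), verts)
  final_verts <- setNames(lapply(which(pk$kind == 1L), function(j) {
    a <- seq_len(pk$nage[j])
    list(numbers = out$final_Num[a, j], w_struct = out$final_Ws[a, j],
         w_reserve = out$final_Wr[a, j])
  }), verts)
  pools <- ids[pk$kind != 1L]
  structure(list(
    biomass = out$biomass, day = out$day, total_n = out$total_n,
    vert_annual = vert_annual,
    init_biomass = setNames(out$biomass[1, ], ids),
    init_verts = config$init$verts,
    final_state = list(pools = setNames(out$final_B[pk$kind != 1L], pools),
                       verts = final_verts),
    settings = config$settings, ids = ids, engine = engine),
    class = "foodweb_trajectory")
}

#' @export
print.foodweb_trajectory <- function(x, ...) {
  cat(sprintf("foodweb_trajectory: %d components, %d recorded days (%.1f years)\n",
              ncol(x$biomass), length(x$day), max(x$day) / 365))
  invisible(x)
}

#' Tidy a trajectory into a long data frame
#'
#' @param x a `foodweb_trajectory`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return data.frame with columns `day`, `component`, `biomass`.
#' @export
as.data.frame.foodweb_trajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(day = rep(x$day, times = ncol(x$biomass)),
             component = rep(colnames(x$biomass), each = nrow(x$biomass)),
             biomass = as.vector(x$biomass))
}

#' Mean biomass per component over the final window
#'
#' @param traj a `foodweb_trajectory`.
#' @param window_years number of final simulated years to average over.
#' @return named vector of window-mean biomasses.
#' @export
window_mean_biomass <- function(traj, window_years = traj$settings$averaging_window_years) {
  from <- max(traj$day) - window_years * 365
  sel <- traj$day > from
  colMeans(traj$biomass[sel, , drop = FALSE])
}

## Pure-R reference engine: same map as the compiled engine, written
## independently in vectorized R. Slow; for small webs and cross-checks.
.sim_core_r <- function(pk) {
  n <- pk$ncomp; kind <- pk$kind; nage <- pk$nage; maxage <- pk$maxage
  B <- pk$B0; Num <- pk$Num0; Ws <- pk$Ws0; Wr <- pk$Wr0
  det <- pk$det_idx + 1L
  dt <- pk$dt
  wr_floor <- 1e-8
  nrec <- 1L + if (pk$record_every > 0) pk$ndays %/% pk$record_every else 0L
  rec_bio <- matrix(0, nrec, n); rec_totn <- numeric(nrec); rec_day <- integer(nrec)
  bank <- pending <- numeric(n)
  nyr <- pk$ndays %/% 365L
  vert_num <- vert_ws <- vert_wr <- vector("list", n)
  for (j in seq_len(n)) if (kind[j] == 1L) {
    vert_num[[j]] <- matrix(0, nyr, nage[j])
    vert_ws[[j]] <- matrix(0, nyr, nage[j])
    vert_wr[[j]] <- matrix(0, nyr, nage[j])
  }
  comp_bio <- function() {
    vapply(seq_len(n), function(j) {
      if (kind[j] != 1L) B[j] else {
        a <- seq_len(nage[j]); sum(Num[a, j] * (Ws[a, j] + Wr[a, j]))
      }
    }, numeric(1))
  }
  rec <- function(slot, day) {
    bio <- comp_bio()
    rec_bio[slot, ] <<- bio
    rec_totn[slot] <<- sum(bio) + sum(bank)
    rec_day[slot] <<- day
  }
  rec(1L, 0L); slot <- 2L

  for (day in seq_len(pk$ndays)) {
    doy <- (day - 1L) %% 365L + 1L
    year <- (day - 1L) %/% 365L + 1L
    for (j in which(kind == 2L)) B[j] <- pk$forcing[doy, j]
    bio <- comp_bio()
    ba <- Num * (Ws + Wr)

    ## grazing
    prey_loss <- numeric(n)
    units <- list(); flux <- list()
    for (j in seq_len(n)) {
      if (kind[j] %in% c(2L, 3L)) next
      na <- if (kind[j] == 1L) nage[j] else 1L
      for (a in seq_len(na)) {
        Bu <- if (kind[j] == 1L) ba[a, j] else bio[j]
        Cu <- pk$C[a, j]; mu <- pk$mum[a, j]
        bstar <- pk$avail[j, ] * bio
        f <- numeric(n)
        if (Cu > 0 && Bu > 0 && sum(bstar) > 0) {
          denom <- 1 + (Cu / mu) * pk$E[j] * sum(bstar)
          f <- Bu * Cu * dt * bstar / denom
        }
        units[[length(units) + 1L]] <- c(j, a)
        flux[[length(flux) + 1L]] <- f
        prey_loss <- prey_loss + f
      }
    }
    scale <- ifelse(prey_loss > bio & prey_loss > 0, bio / prey_loss, 1)
    assim_pool <- numeric(n); assim_age <- matrix(0, maxage, n)
    to_det <- 0
    for (u in seq_along(units)) {
      j <- units[[u]][1]; a <- units[[u]][2]
      intake <- sum(flux[[u]] * scale)
      if (kind[j] == 1L) assim_age[a, j] <- assim_age[a, j] + pk$E[j] * intake
      else assim_pool[j] <- assim_pool[j] + pk$E[j] * intake
      to_det <- to_det + (1 - pk$E[j]) * intake
    }
    prey_loss <- pmin(prey_loss, bio)

    ## prey removal
    for (k in seq_len(n)) {
      if (prey_loss[k] <= 0) next
      if (kind[k] == 1L) {
        for (a in seq_len(nage[k])) {
          if (ba[a, k] <= 0) next
          la <- prey_loss[k] * ba[a, k] / bio[k]
          w <- Ws[a, k] + Wr[a, k]
          if (w > 0) Num[a, k] <- max(Num[a, k] - la / w, 0)
        }
      } else B[k] <- max(B[k] - prey_loss[k], 0)
    }

    ## growth
    for (j in seq_len(n)) {
      if (kind[j] == 0L) {
        gain <- min(assim_pool[j], pk$mum[1, j] * bio[j] * dt)
        to_det <- to_det + assim_pool[j] - gain
        B[j] <- B[j] + gain
      } else if (kind[j] == 1L) {
        for (a in seq_len(nage[j])) {
          N <- Num[a, j]
          if (N <= 0) { to_det <- to_det + assim_age[a, j]; next }
          gain <- min(assim_age[a, j] / N, pk$mum[a, j] * dt)
          to_det <- to_det + assim_age[a, j] - gain * N
          m <- pk$maint_frac[j] * pk$mum[a, j] * dt
          pay <- min(m, gain + max(Wr[a, j] - wr_floor, 0))
          net <- gain - pay
          to_det <- to_det + pay * N
          if (net >= 0) {
            Ws[a, j] <- Ws[a, j] + pk$growth_split[j] * net
            Wr[a, j] <- Wr[a, j] + (1 - pk$growth_split[j]) * net
          } else {
            Wr[a, j] <- max(Wr[a, j] + net, wr_floor)
          }
        }
      }
    }

    ## mortality (detritus remineralization leaves the system)
    for (j in seq_len(n)) {
      if (kind[j] == 3L) {
        remv <- min((pk$mL[j] + pk$mQa[j] * B[j]) * B[j] * dt, B[j])
        B[j] <- B[j] - remv
      } else if (kind[j] == 0L) {
        remv <- min((pk$mL[j] + pk$mQa[j] * B[j]) * B[j] * dt, B[j])
        B[j] <- B[j] - remv
        to_det <- to_det + remv
      } else if (kind[j] == 1L) {
        for (a in seq_len(nage[j])) {
          N <- Num[a, j]
          if (N <= 0) next
          mq <- if (a < pk$maturity[j]) pk$mQj[j] else pk$mQa[j]
          mst <- if (Ws[a, j] > 0 && Wr[a, j] / Ws[a, j] < pk$mSt_thr[j])
            pk$mSt_rate[j] else 0
          remv <- min((pk$mL[j] + mq * N + mst) * N * dt, N)
          Num[a, j] <- Num[a, j] - remv
          to_det <- to_det + remv * (Ws[a, j] + Wr[a, j])
        }
      }
    }

    ## recruitment
    if (doy == pk$spawn_day) {
      for (j in seq_len(n)) {
        if (kind[j] != 1L || pk$rec_mode[j] == 0L) next
        a <- seq_len(nage[j])
        Biom <- sum(Num[a, j] * (Ws[a, j] + Wr[a, j]))
        Sp <- 0; nm <- 0
        for (aa in seq(pk$maturity[j], nage[j])) {
          if (Num[aa, j] <= 0) next
          if (Ws[aa, j] > 0 && Wr[aa, j] / Ws[aa, j] < pk$spawn_thr[j]) next
          take <- pk$spawn_frac[j] * Wr[aa, j]
          Sp <- Sp + Num[aa, j] * take
          Wr[aa, j] <- Wr[aa, j] - take
          nm <- nm + Num[aa, j]
        }
        Rc <- if (pk$rec_mode[j] == 1L)
          Sp * pk$BHa[j] / (Biom + pk$BHb[j]) * pk$deviates[year, j]
        else pk$KDENR[j] * nm
        w0 <- pk$w0s[j] + pk$w0r[j]
        Rc <- max(min(Rc, if (w0 > 0) Sp / w0 else 0), 0)
        bank[j] <- bank[j] + Rc * w0
        to_det <- to_det + Sp - Rc * w0
        pending[j] <- pending[j] + Rc
      }
    }
    if (det > 0) B[det] <- B[det] + to_det

    ## aging
    if (doy == 365L) {
      for (j in seq_len(n)) {
        if (kind[j] != 1L) next
        na <- nage[j]; a <- seq_len(na)
        st <- age_cohorts(Num[a, j], Ws[a, j], Wr[a, j], pending[j],
                          pk$w0s[j], pk$w0r[j])
        Num[a, j] <- st$numbers; Ws[a, j] <- st$w_struct; Wr[a, j] <- st$w_reserve
        bank[j] <- 0; pending[j] <- 0
        yr <- day %/% 365L
        if (yr >= 1 && yr <= nyr) {
          vert_num[[j]][yr, ] <- Num[a, j]
          vert_ws[[j]][yr, ] <- Ws[a, j]
          vert_wr[[j]][yr, ] <- Wr[a, j]
        }
      }
    }

    if (pk$record_every > 0 && day %% pk$record_every == 0L) {
      rec(slot, day); slot <- slot + 1L
    }
    bio_now <- comp_bio()
    if (any(!is.finite(bio_now)))
      .stopf("non-finite biomass for component %s at day %d",
             pk$ids[which(!is.finite(bio_now))[1]], day)
  }
  list(biomass = rec_bio, total_n = rec_totn, day = rec_day,
       vert_num = vert_num, vert_ws = vert_ws, vert_wr = vert_wr,
       final_B = B, final_Num = Num, final_Ws = Ws, final_Wr = Wr)
}
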