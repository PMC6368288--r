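## Process equations: grazing, mortality, recruitment, growth allocation,
## cohort aging. These are the primitives the daily engine composes; they are
## exported so each can be tested against hand evaluation in isolation.

#' Available prey biomass after refuge
#'
#' The biomass of a prey actually reachable by a predator: the availability
#' `p` (maximum potential fraction of the prey available to the predator)
#' discounted by the spatial-overlap, habitat and size (gape) refuge factors,
#' applied to the prey's standing biomass. All factors lie in \[0, 1\].
#'
#' @param p availability of the prey to the predator.
#' @param prey_biomass standing biomass of the prey (mg N).
#' @param delta_overlap,delta_habitat,delta_size refuge factors; default 1
#'   (no refuge).
#' @return available biomass, `p * delta_overlap * delta_habitat * delta_size
#'   * prey_biomass`. Vectorized over prey.
#' @export
available_prey <- function(p, prey_biomass, delta_overlap = 1,
                           delta_habitat = 1, delta_size = 1) {
  p * delta_overlap * delta_habitat * delta_size * prey_biomass
}

#' Grazing flux of a predator on its prey field
#'
#' Holling-type saturating intake with availability-modified prey biomasses:
#' for prey `i`,
#' \deqn{Gr_i = B C B^*_i / (1 + (C/mum) E \sum_j B^*_j)}
#' where `B` is the predator (age-class) biomass, `C` its consumption rate,
#' `E` its assimilation efficiency and `mum` its maximum growth rate, which
#' sets the saturation level: assimilated intake `E * sum(Gr)` approaches
#' `mum * B` as available prey grows without bound.
#'
#' @param B predator biomass (mg N).
#' @param C consumption (clearance) rate of the predator age class.
#' @param mum maximum growth rate of the predator age class; must be positive
#'   when `C > 0`.
#' @param E assimilation efficiency in \[0, 1\].
#' @param b_star vector of available prey biomasses (from [available_prey()]).
#' @param dt time step (days).
#' @return vector of grazing fluxes per prey (mg N per step), with attribute
#'   `intake` (their sum).
#' @export
grazing_flux <- function(B, C, mum, E, b_star, dt = 1) {
  if (C > 0 && mum <= 0)
    .stopf("grazing: mum = 0 with C > 0 is a degenerate configuration")
  if (C == 0 || B <= 0 || !length(b_star) || all(b_star <= 0)) {
    gr <- numeric(length(b_star))
  } else {
    gr <- B * C * b_star / (1 + (C / mum) * E * sum(b_star)) * dt
  }
  attr(gr, "intake") <- sum(gr)
  gr
}

#' Mortality removal over one step
#'
#' Linear plus density-dependent quadratic mortality, with an optional
#' starvation term: removal = `(mL + mQ * N + mSt) * N * dt`, clipped so no
#' more than the standing stock is removed. For biomass pools `N` is the pool
#' biomass; for vertebrates it is the age-class abundance and the removal is
#' in numbers.
#'
#' @param N standing stock (numbers for a vertebrate age class, biomass for
#'   a pool).
#' @param mL linear mortality rate (per day).
#' @param mQ quadratic mortality coefficient (per unit of `N` per day).
#' @param mSt starvation mortality rate (per day); nonzero only when the
#'   reserve:structural weight ratio is below the starvation threshold.
#' @param dt time step (days).
#' @return removal (same units as `N`), in `[0, N]`. Vectorized over `N`/`mQ`.
#' @export
mortality_removal <- function(N, mL, mQ, mSt = 0, dt = 1) {
  pmin(pmax((mL + mQ * N + mSt) * N * dt, 0), N)
}

#' Beverton-Holt recruitment
#'
#' `Rc = Sp * BHa / (Biom + BHb)`, optionally scaled by a unit-median
#' lognormal deviate (interannual recruitment variability).
#'
#' @param Sp spawn produced (mg N).
#' @param BHa Beverton-Holt alpha (sets the recruit scale).
#' @param Biom total biomass of the species (mg N).
#' @param BHb Beverton-Holt beta (half-saturation biomass, mg N).
#' @param deviate multiplicative lognormal deviate, median 1; default 1
#'   (deterministic).
#' @return number of recruits.
#' @export
recruit_beverton_holt <- function(Sp, BHa, Biom, BHb, deviate = 1) {
  if (Biom + BHb <= 0)
    .stopf("Beverton-Holt recruitment: Biom + BHb must be positive")
  Sp * BHa / (Biom + BHb) * deviate
}

#' Constant per-adult recruitment
#'
#' `Rc = KDENR * n_mature`: a fixed number of recruits per reproducing adult
#' per year (used for long-lived top predators such as the minke-whale
#' analogue).
#'
#' @param KDENR recruits per reproducing adult per year.
#' @param n_mature number of mature adults.
#' @return number of recruits.
#' @export
recruit_constant <- function(KDENR, n_mature) {
  KDENR * n_mature
}

#' Growth allocation for a vertebrate age class
#'
#' Converts assimilated intake into body weight. The per-individual gain is
#' capped at `mum * dt`; a maintenance cost (`maint_frac * mum * dt`) is paid
#' first, from intake and then from reserve weight. Positive net gain is
#' split between structural (irreversible) and reserve weight by
#' `growth_split`; deficits are drawn from reserve weight only, floored at
#' `wr_floor`. Assimilate above the cap (overflow) and paid maintenance are
#' routed to detritus by the engine.
#'
#' @param assimilated assimilated intake of the age class (mg N per step).
#' @param N age-class abundance.
#' @param mum maximum individual growth rate (mg N per individual per day).
#' @param w_struct,w_reserve current weights (mg N per individual).
#' @param growth_split fraction of net gain allocated to structural weight.
#' @param maint_frac maintenance cost as a fraction of `mum`.
#' @param wr_floor lower bound kept on reserve weight (mg N).
#' @param dt time step (days).
#' @return list with `w_struct`, `w_reserve` (updated weights), `overflow`
#'   (assimilate above the cap, mg N), `maintenance` (maintenance mass paid
#'   by the whole age class, mg N).
#' @export
grow_allocate <- function(assimilated, N, mum, w_struct, w_reserve,
                          growth_split = 0.5, maint_frac = 0.1,
                          wr_floor = 1e-8, dt = 1) {
  if (N <= 0)
    return(list(w_struct = w_struct, w_reserve = w_reserve,
                overflow = assimilated, maintenance = 0))
  gain <- min(assimilated / N, mum * dt)
  overflow <- assimilated - gain * N
  m <- maint_frac * mum * dt
  pay <- min(m, gain + max(w_reserve - wr_floor, 0))
  net <- gain - pay
  if (net >= 0) {
    w_struct <- w_struct + growth_split * net
    w_reserve <- w_reserve + (1 - growth_split) * net
  } else {
    w_reserve <- w_reserve + net
  }
  list(w_struct = w_struct, w_reserve = max(w_reserve, wr_floor),
       overflow = overflow, maintenance = pay * N)
}

#' Growth of a biomass pool
#'
#' Pools grow by their assimilated intake, capped at `mum * B * dt` (maximum
#' relative growth per day applied to the pool biomass); losses (grazing by
#' predators, mortality) are subtracted by the engine.
#'
#' @param assimilated assimilated intake (mg N per step).
#' @param B pool biomass (mg N).
#' @param mum maximum growth rate (per day).
#' @param losses total losses this step (mg N), for the convenience net form.
#' @param dt time step (days).
#' @return list with `gain` (realized growth), `overflow` (assimilate above
#'   the cap) and `dB = gain - losses`.
#' @export
pool_growth <- function(assimilated, B, mum, losses = 0, dt = 1) {
  gain <- min(assimilated, mum * B * dt)
  list(gain = gain, overflow = assimilated - gain, dB = gain - losses)
}

#' Advance vertebrate cohorts by one year
#'
#' Numbers are promoted one age class; the oldest class is a plus-group (the
#' promoted class merges into it, with number-weighted mean weights); the
#' first class is filled with the year's recruits at their initial weights.
#'
#' @param numbers,w_struct,w_reserve per-age state vectors.
#' @param recruits number of recruits entering age class 1.
#' @param recruit_w_struct,recruit_w_reserve initial weights of a recruit
#'   (mg N per individual).
#' @return list with updated `numbers`, `w_struct`, `w_reserve`.
#' @export
age_cohorts <- function(numbers, w_struct, w_reserve, recruits = 0,
                        recruit_w_struct = 0, recruit_w_reserve = 0) {
  n <- length(numbers)
  new_n <- numbers; new_ws <- w_struct; new_wr <- w_reserve
  if (n > 1) {
    ## plus group: merge entrants from class n-1 into class n
    tot <- numbers[n] + numbers[n - 1]
    if (tot > 0) {
      new_ws[n] <- (numbers[n] * w_struct[n] + numbers[n - 1] * w_struct[n - 1]) / tot
      new_wr[n] <- (numbers[n] * w_reserve[n] + numbers[n - 1] * w_reserve[n - 1]) / tot
    }
    new_n[n] <- tot
    if (n > 2) {
      new_n[2:(n - 1)] <- numbers[1:(n - 2)]
      new_ws[2:(n - 1)] <- w_struct[1:(n - 2)]
      new_wr[2:(n - 1)] <- w_reserve[1:(n - 2)]
    }
  }
  new_n[1] <- recruits
  new_ws[1] <- recruit_w_struct
  new_wr[1] <- recruit_w_reserve
  list(numbers = new_n, w_struct = new_ws, w_reserve = new_wr)
}
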