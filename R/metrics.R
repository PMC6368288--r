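## Response metrics: biomass changes vs control, impact categories and
## weights, per-run impact factor, additive/synergistic/antagonistic
## classification and its tabulation by trophic group.

#' Relative biomass change vs the control run
#'
#' Signed relative change of the biomass averaged over the final window:
#' `(mean_perturbed - mean_control) / mean_control` per component, both means
#' taken over the last `window_years` simulated years.
#'
#' @param perturbed,control `foodweb_trajectory` objects over the same
#'   horizon.
#' @param window_years averaging window (default: the config's setting).
#' @return data.frame with `component`, `control_mean`, `perturbed_mean`,
#'   `delta`. Components with a zero control mean get `delta = NA` (flagged
#'   undefined, excluded from downstream scoring).
#' @export
biomass_change <- function(perturbed, control,
                           window_years = control$settings$averaging_window_years) {
  if (!identical(control$ids, perturbed$ids))
    .stopf("perturbed and control runs cover different components")
  if (max(control$day) != max(perturbed$day))
    .stopf("perturbed and control runs have different horizons")
  mc <- window_mean_biomass(control, window_years)
  mp <- window_mean_biomass(perturbed, window_years)
  delta <- ifelse(mc > 0, (mp - mc) / mc, NA_real_)
  data.frame(component = control$ids, control_mean = unname(mc),
             perturbed_mean = unname(mp), delta = unname(delta))
}

#' Impact category and weight of a biomass change
#'
#' Categorizes the absolute relative biomass change: below 5% no impact
#' (weight 1), 5-10% low (2), 10-20% medium (3), 20% and above high (4).
#' Boundaries are half-open upward (a change of exactly 5% is low impact).
#'
#' @param delta signed relative biomass change(s).
#' @return data.frame with `delta`, `category`, `weight`.
#' @export
impact_category <- function(delta) {
  if (any(!is.finite(delta)))
    .stopf("impact_category requires finite deltas")
  a <- abs(delta)
  weight <- ifelse(a < 0.05, 1L, ifelse(a < 0.10, 2L, ifelse(a < 0.20, 3L, 4L)))
  category <- c("no impact", "low impact", "medium impact", "high impact")[weight]
  data.frame(delta = delta, category = category, weight = weight)
}

#' Impact factor of a run
#'
#' The mean of the impact weights over the scored components: a number in
#' \[1, 4\] summarizing how widely and strongly the run's perturbation
#' changed biomasses relative to control. Undefined deltas (zero control
#' mean) are excluded; the exclusion count is attached as an attribute.
#'
#' @param changes output of [biomass_change()], optionally with a logical
#'   `is_key` column.
#' @param scope `"all_components"` (default) or `"key_species"` (requires
#'   `is_key`).
#' @return impact factor (numeric scalar) with attributes `n` (components
#'   scored) and `n_excluded`.
#' @export
impact_factor <- function(changes, scope = c("all_components", "key_species")) {
  scope <- match.arg(scope)
  if (scope == "key_species") {
    if (is.null(changes$is_key))
      .stopf("key_species scope requires an is_key column")
    changes <- changes[changes$is_key, , drop = FALSE]
  }
  excl <- !is.finite(changes$delta)
  changes <- changes[!excl, , drop = FALSE]
  if (!nrow(changes)) .stopf("impact_factor: no components with a defined delta")
  f <- mean(impact_category(changes$delta)$weight)
  attr(f, "n") <- nrow(changes)
  attr(f, "n_excluded") <- sum(excl)
  f
}

#' Classify a combined-perturbation response
#'
#' Compares the biomass change in a combination run (`dP12`) with the sum of
#' the changes in the two single-perturbation runs (`dP1 + dP2`). Within
#' `tol` of the sum the response is additive; otherwise it is synergistic
#' when the combined change exceeds the sum in magnitude and antagonistic
#' when it is smaller.
#'
#' @param dP1,dP2 component biomass change in each single run.
#' @param dP12 component biomass change in the combination run.
#' @param tol half-width of the additive band (default 0.01, i.e. +/- 1%).
#' @return data.frame with `label` (`additive`/`synergistic`/`antagonistic`)
#'   and `residual` (`dP12 - (dP1 + dP2)`). Vectorized.
#' @export
classify_interaction <- function(dP1, dP2, dP12, tol = 0.01) {
  s <- dP1 + dP2
  residual <- dP12 - s
  label <- ifelse(abs(residual) < tol, "additive",
                  ifelse(abs(dP12) > abs(s), "synergistic", "antagonistic"))
  data.frame(label = label, residual = residual)
}

#' Tabulate interaction classes by component group
#'
#' Percent of (run, component) cells with each interaction label, per group.
#'
#' @param classes data.frame with columns `component` and `label`.
#' @param grouping named character vector mapping component id to group.
#' @return data.frame with `group`, `additive`, `synergistic`,
#'   `antagonistic`, `n` (cells); percentage columns sum to 100 per row up to
#'   rounding.
#' @export
tabulate_interactions <- function(classes, grouping) {
  if (!nrow(classes))
    return(data.frame(group = character(), additive = numeric(),
                      synergistic = numeric(), antagonistic = numeric(),
                      n = integer()))
  bad <- setdiff(classes$component, names(grouping))
  if (length(bad)) .stopf("no group defined for component %s", bad[1])
  g <- unname(grouping[classes$component])
  out <- lapply(unique(g), function(gg) {
    lab <- classes$label[g == gg]
    n <- length(lab)
    data.frame(group = gg,
               additive = 100 * sum(lab == "additive") / n,
               synergistic = 100 * sum(lab == "synergistic") / n,
               antagonistic = 100 * sum(lab == "antagonistic") / n,
               n = n)
  })
  do.call(rbind, out)
}

#' Pairwise correlation of component responses across runs
#'
#' Pearson correlation between the per-run biomass-change vectors of each
#' component pair: components whose responses track each other across the
#' perturbation set correlate highly.
#'
#' @param delta_matrix components x runs matrix of biomass changes.
#' @return symmetric correlation matrix with unit diagonal; rows with zero
#'   variance yield `NA` off-diagonal entries.
#' @export
response_correlation <- function(delta_matrix) {
  if (ncol(delta_matrix) < 2)
    .stopf("response_correlation needs at least 2 runs")
  m <- suppressWarnings(cor(t(delta_matrix)))
  diag(m) <- 1
  m
}
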