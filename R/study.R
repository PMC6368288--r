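## Study orchestration: run the full manifest against a config, score every
## run, classify combination responses, and emit the report tables.

.run_seed <- function(seed, run_id) {
  as.integer((as.numeric(seed) * 7919 + run_id) %% 2147483647)
}

#' Run a full sensitivity study
#'
#' Simulates the control run and every manifest run (each with a per-run seed
#' expanded deterministically from the study seed), computes per-component
#' biomass changes vs control over the final averaging window, their
#' impact categories and per-run impact factors, and classifies every
#' combination run's per-component response as additive, synergistic or
#' antagonistic against its parent runs.
#'
#' @param config a `foodweb_config` (the control parameterization).
#' @param manifest a `foodweb_manifest`; default: the reference design
#'   via [build_manifest()].
#' @param seed study seed; per-run seeds are `(seed * 7919 + run_id) mod
#'   (2^31 - 1)` so any run is reproducible in isolation.
#' @param scope impact-factor scope, `"all_components"` or `"key_species"`.
#' @param tol additive-band half-width for interaction classification.
#' @param keep_trajectories keep the full per-run trajectories (memory-heavy
#'   for large designs).
#' @return list of class `foodweb_study`: `manifest`, `impacts` (per-run
#'   impact factor and status), `changes` (long per-run, per-component
#'   deltas), `delta_matrix` (components x runs), `interactions` (long
#'   classification for combination runs), `stability` (control-run
#'   [stability_check()]), `control`, `scope`, `seed`, and failures if any.
#' @export
run_study <- function(config, manifest = build_manifest(config), seed = NULL,
                      scope = c("all_components", "key_species"), tol = 0.01,
                      keep_trajectories = FALSE) {
  scope <- match.arg(scope)
  seed <- seed %||% config$settings$seed
  is_key <- setNames(config$components$is_key_species, config$components$id)

  ctl_row <- manifest[manifest$provenance == "control", , drop = FALSE]
  if (nrow(ctl_row) != 1L) .stopf("manifest must contain exactly one control run")
  control <- run_simulation(config, seed = .run_seed(seed, ctl_row$run_id))
  stability <- stability_check(control)

  pert <- manifest[manifest$provenance != "control", , drop = FALSE]
  changes <- list(); impacts <- list(); failures <- list()
  trajs <- if (keep_trajectories) list() else NULL
  deltas_by_label <- list()
  for (i in seq_len(nrow(pert))) {
    rid <- pert$run_id[i]; lab <- pert$label[i]
    res <- tryCatch({
      traj <- run_simulation(config, edits = parse_edits(pert$edits[i]),
                             seed = .run_seed(seed, rid))
      ch <- biomass_change(traj, control)
      ch$is_key <- unname(is_key[ch$component])
      fac <- impact_factor(ch, scope)
      list(ch = ch, fac = fac, traj = traj)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[lab]] <- conditionMessage(res)
      impacts[[i]] <- data.frame(run_id = rid, label = lab,
                                 provenance = pert$provenance[i],
                                 impact_factor = NA_real_, status = "failed")
      next
    }
    if (keep_trajectories) trajs[[lab]] <- res$traj
    ch <- res$ch
    ch$run_id <- rid; ch$label <- lab
    cat_w <- rep(NA_integer_, nrow(ch))
    ok <- is.finite(ch$delta)
    cat_w[ok] <- impact_category(ch$delta[ok])$weight
    ch$weight <- cat_w
    changes[[i]] <- ch
    deltas_by_label[[lab]] <- setNames(ch$delta, ch$component)
    impacts[[i]] <- data.frame(run_id = rid, label = lab,
                               provenance = pert$provenance[i],
                               impact_factor = as.numeric(res$fac),
                               status = "ok")
  }
  impacts <- do.call(rbind, impacts)
  changes <- do.call(rbind, changes)
  comps <- config$components$id
  delta_matrix <- matrix(NA_real_, length(comps), length(deltas_by_label),
                         dimnames = list(comps, names(deltas_by_label)))
  for (lab in names(deltas_by_label))
    delta_matrix[names(deltas_by_label[[lab]]), lab] <- deltas_by_label[[lab]]

  ## interaction classification for combination runs
  interactions <- list()
  combos <- pert[pert$provenance == "combination", , drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    lab <- combos$label[i]
    parents <- strsplit(combos$parents[i], " + ", fixed = TRUE)[[1]]
    if (length(parents) < 2L || is.null(deltas_by_label[[lab]])) next
    ## a parent can itself be a combination ("A + B + C" = A and "B + C");
    ## resolve the first label, the rest is the second parent, falling back
    ## to the symmetric split
    p1 <- deltas_by_label[[parents[1]]]
    p2 <- deltas_by_label[[paste(parents[-1], collapse = " + ")]]
    if (is.null(p1) || is.null(p2)) {
      p1 <- deltas_by_label[[paste(parents[-length(parents)], collapse = " + ")]]
      p2 <- deltas_by_label[[parents[length(parents)]]]
    }
    if (is.null(p1) || is.null(p2)) next
    d12 <- deltas_by_label[[lab]]
    ok <- is.finite(p1) & is.finite(p2) & is.finite(d12)
    cl <- classify_interaction(p1[ok], p2[ok], d12[ok], tol)
    interactions[[i]] <- data.frame(
      run_id = combos$run_id[i], label = lab,
      component = names(d12)[ok], dP1 = unname(p1[ok]), dP2 = unname(p2[ok]),
      dP12 = unname(d12[ok]), interaction = cl$label, residual = cl$residual)
  }
  interactions <- if (length(interactions)) do.call(rbind, interactions) else
    data.frame(run_id = integer(), label = character(), component = character(),
               dP1 = numeric(), dP2 = numeric(), dP12 = numeric(),
               interaction = character(), residual = numeric())

  structure(list(manifest = manifest, impacts = impacts, changes = changes,
                 delta_matrix = delta_matrix, interactions = interactions,
                 stability = stability, control = control,
                 config = config, scope = scope, seed = seed,
                 failures = failures, trajectories = trajs),
            class = "foodweb_study")
}

#' @export
print.foodweb_study <- function(x, ...) {
  cat(sprintf("foodweb_study: %d perturbation runs (%d failed), scope %s, seed %d\n",
              nrow(x$impacts), length(x$failures), x$scope, x$seed))
  if (nrow(x$impacts))
    cat(sprintf("  impact factor: median %.2f, range %.2f-%.2f\n",
                median(x$impacts$impact_factor, na.rm = TRUE),
                min(x$impacts$impact_factor, na.rm = TRUE),
                max(x$impacts$impact_factor, na.rm = TRUE)))
  invisible(x)
}

## trophic grouping used in the interaction percentage table
.default_grouping <- function(config) {
  g <- config$components$guild
  grp <- ifelse(g == "phytoplankton", "phytoplankton",
         ifelse(g == "zooplankton", "zooplankton",
         ifelse(g %in% c("pelagic_fish", "demersal_fish"), "fish",
         ifelse(g == "top_predator", "top_predators", "detritus"))))
  setNames(grp, config$components$id)
}

#' Write the study report files
#'
#' Emits four CSV reports into `dir`: per-run impact factors annotated with
#' provenance and perturbed parameter family (`impact_factors.csv`), long
#' per-run per-component biomass changes with category weights
#' (`biomass_changes.csv`), the per-cell interaction classification of the
#' combination runs (`interactions.csv`), and the interaction percentages by
#' trophic group (`interaction_percentages.csv`), plus a `study.yaml` with
#' the seed, scope, run status and md5 hashes of every report.
#'
#' @param study a `foodweb_study`.
#' @param dir output directory (created if needed).
#' @return named vector of written file paths, invisibly.
#' @export
write_study_reports <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imp <- study$impacts
  fam <- vapply(imp$run_id, function(r) {
    e <- manifest_edits(study$manifest, r)
    paste(unique(e$parameter), collapse = "+")
  }, "")
  lvl <- vapply(imp$run_id, function(r) {
    e <- manifest_edits(study$manifest, r)
    g <- .default_grouping(study$config)[unique(e$component)]
    paste(unique(g), collapse = "+")
  }, "")
  imp$parameter_family <- fam
  imp$trophic_level <- lvl

  tab <- tabulate_interactions(
    data.frame(component = study$interactions$component,
               label = study$interactions$interaction),
    .default_grouping(study$config))

  paths <- c(impact_factors = file.path(dir, "impact_factors.csv"),
             biomass_changes = file.path(dir, "biomass_changes.csv"),
             interactions = file.path(dir, "interactions.csv"),
             interaction_percentages = file.path(dir, "interaction_percentages.csv"))
  write.csv(imp, paths["impact_factors"], row.names = FALSE)
  write.csv(study$changes, paths["biomass_changes"], row.names = FALSE)
  write.csv(study$interactions, paths["interactions"], row.names = FALSE)
  write.csv(tab, paths["interaction_percentages"], row.names = FALSE)

  meta <- list(seed = study$seed, scope = study$scope,
               n_runs = nrow(study$impacts),
               n_failed = length(study$failures),
               failed = names(study$failures),
               stability_pass = study$stability$pass,
               report_md5 = as.list(tools::md5sum(unname(paths))))
  writeLines(yaml::as.yaml(meta), file.path(dir, "study.yaml"))
  invisible(paths)
}
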