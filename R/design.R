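## Perturbation experiment design: OAT runs, extreme runs, paired combination
## runs, manifest construction and persistence, and edit application.

.param_families <- c("mum", "C", "recruitment", "mQ")

.oat_label <- function(component, parameter, multiplier) {
  dir <- if (multiplier > 1) "up" else "down"
  sprintf("%s.%s.%s", component, parameter, dir)
}

.serialize_edits <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("")
  paste(sprintf("%s:%s:%s", edits$component, edits$parameter,
                formatC(edits$multiplier, digits = 17, format = "g")),
        collapse = ";")
}

#' Parse a serialized edit string
#'
#' @param s edits serialized as `"component:parameter:multiplier;..."`.
#' @return data.frame with columns `component`, `parameter`, `multiplier`.
#' @export
parse_edits <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(component = character(), parameter = character(),
                      multiplier = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(component = vapply(parts, `[`, "", 1),
             parameter = vapply(parts, `[`, "", 2),
             multiplier = as.numeric(vapply(parts, `[`, "", 3)))
}

.applicable_params <- function(kind) {
  if (kind == "vertebrate") .param_families else c("mum", "C", "mQ")
}

#' Enumerate one-at-a-time (OAT) perturbation runs
#'
#' One run per (key species, applicable parameter family, direction).
#' Vertebrates contribute four families (growth `mum`, consumption `C`,
#' recruitment, quadratic mortality `mQ`), biomass pools three (no
#' recruitment). Per-age parameter vectors are scaled on all age classes
#' simultaneously; a mortality edit scales the juvenile and adult quadratic
#' coefficients together.
#'
#' @param config a `foodweb_config`; key species are the components flagged
#'   `is_key_species`.
#' @param magnitudes multipliers for the two directions (default +/- 25%).
#' @return data.frame with columns `label`, `component`, `parameter`,
#'   `multiplier`, in family order (`mum`, `C`, `recruitment`, `mQ`),
#'   vertebrates before pools, increase before decrease.
#' @export
enumerate_oat <- function(config, magnitudes = c(1.25, 0.75)) {
  if (any(magnitudes <= 0)) .stopf("OAT multipliers must be positive")
  comp <- config$components
  key <- comp[comp$is_key_species, , drop = FALSE]
  rows <- list()
  for (fam in .param_families) {
    for (vert_first in c(TRUE, FALSE)) {
      sel <- key[(key$kind == "vertebrate") == vert_first, , drop = FALSE]
      for (i in seq_len(nrow(sel))) {
        if (!fam %in% .applicable_params(sel$kind[i])) next
        for (m in magnitudes) {
          rows[[length(rows) + 1L]] <- data.frame(
            label = .oat_label(sel$id[i], fam, m),
            component = sel$id[i], parameter = fam, multiplier = m)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(label = character(), component = character(),
                      parameter = character(), multiplier = numeric()))
  do.call(rbind, rows)
}

#' Default extreme-perturbation set
#'
#' Four runs mimicking observed extremes: herring-analogue recruitment
#' multiplied by 3.30 (+230%) and by 0.10 (-90%), and cod-analogue growth
#' multiplied by 1.70 (+70%) and by 0.61 (-39%).
#'
#' @param cod,herring component ids of the cod and herring analogues.
#' @return data.frame with columns `label`, `component`, `parameter`,
#'   `multiplier`.
#' @export
default_extremes <- function(cod = "NCO", herring = "SSH") {
  data.frame(
    label = c(sprintf("%s.mum.x1.7", cod),
              sprintf("%s.recruitment.x3.3", herring),
              sprintf("%s.mum.x0.61", cod),
              sprintf("%s.recruitment.x0.1", herring)),
    component = c(cod, herring, cod, herring),
    parameter = c("mum", "recruitment", "mum", "recruitment"),
    multiplier = c(1.70, 3.30, 0.61, 0.10))
}

#' Enumerate extreme-perturbation runs
#'
#' @param config a `foodweb_config` (used to validate component references).
#' @param extremes data.frame like [default_extremes()]; empty for none.
#' @return the validated data.frame.
#' @export
enumerate_extremes <- function(config, extremes = default_extremes()) {
  if (!nrow(extremes)) return(extremes)
  if (any(extremes$multiplier <= 0)) .stopf("extreme multipliers must be positive")
  bad <- setdiff(extremes$component, config$components$id)
  if (length(bad)) .stopf("extreme run references unknown component %s", bad[1])
  extremes
}

#' Reference key-species combination pairings
#'
#' The eight combination runs pairing high- and low-impact responses of the
#' key species themselves. Parents are referenced by canonical OAT labels
#' (`component.parameter.up/down`); the last pairing has a combination run as
#' one parent (three edits in total).
#'
#' @return data.frame with columns `parent1`, `parent2`, `group`.
#' @export
default_key_species_pairs <- function() {
  data.frame(parent1 = c("NCO.C.down", "NCO.C.down", "CAP.recruitment.down",
                         "MWH.mQ.down", "CAP.C.down", "PCO.mum.down",
                         "MWH.mum.down", "NCO.mQ.down"),
             parent2 = c("NCO.mQ.down", "CAP.recruitment.down",
                         "SSH.recruitment.down", "CAP.mum.down",
                         "NCO.mQ.down", "CAP.mum.down", "NCO.C.down",
                         "CAP.recruitment.down + SSH.recruitment.down"),
             group = "key_species")
}

#' Reference combination pairing table
#'
#' All 36 combination pairings: the 8 key-species pairings plus the 28
#' metric pairings, the latter being every pair among 8 selected OAT runs
#' (one high-impact and one low-impact run per parameter family).
#'
#' @return data.frame with columns `parent1`, `parent2`, `group`.
#' @export
default_pairing_table <- function() {
  hi <- c(mum = "ZL.mum.down", C = "ZS.C.up",
          recruitment = "MWH.recruitment.down", mQ = "NCO.mQ.up")
  lo <- c(mum = "SSH.mum.down", C = "PCO.C.up",
          recruitment = "CAP.recruitment.up", mQ = "PCO.mQ.down")
  metric <- .all_pairs_table(hi, lo)
  rbind(default_key_species_pairs(), metric)
}

## all C(8,2) pairs of the selected family runs, in the fixed order:
## pairs within the high set, then each low run against the high set, then
## pairs within the low set
.all_pairs_table <- function(hi, lo) {
  hi <- unname(hi); lo <- unname(lo)
  rows <- list()
  add <- function(a, b) rows[[length(rows) + 1L]] <<- data.frame(
    parent1 = a, parent2 = b, group = "metric")
  nh <- length(hi)
  for (i in seq_len(nh - 1)) for (j in seq(i + 1, nh)) add(hi[i], hi[j])
  for (l in lo) for (h in hi) add(l, h)
  nl <- length(lo)
  for (i in seq_len(nl - 1)) for (j in seq(i + 1, nl)) add(lo[i], lo[j])
  unique(do.call(rbind, rows))
}

#' Select the high- and low-impact OAT run per parameter family
#'
#' For each parameter family, picks the OAT (or extreme) run with the highest
#' and the lowest impact factor; ties are broken by the lower run id.
#'
#' @param manifest a manifest (see [build_manifest()]) containing the OAT
#'   runs.
#' @param impact_factors data.frame with columns `run_id`, `impact_factor`
#'   for those runs.
#' @return list with named character vectors `high` and `low` (labels per
#'   family).
#' @export
select_high_low_runs <- function(manifest, impact_factors) {
  oat <- manifest[manifest$provenance %in% c("oat", "extreme"), , drop = FALSE]
  oat <- merge(oat, impact_factors, by = "run_id")
  oat <- oat[order(oat$run_id), , drop = FALSE]
  fam <- vapply(oat$edits, function(s) parse_edits(s)$parameter[1], "")
  hi <- lo <- character(0)
  for (f in .param_families) {
    sub <- oat[fam == f, , drop = FALSE]
    if (!nrow(sub)) next
    hi[f] <- sub$label[which.max(sub$impact_factor)]
    lo[f] <- sub$label[which.min(sub$impact_factor)]
  }
  list(high = hi, low = lo)
}

#' Build combination run specifications
#'
#' Pairs perturbation runs into combination runs whose edits are the union of
#' the parents' edits. With a `pairing_table` the pairings are explicit (the
#' reference fixture, [default_pairing_table()]); with `impact_factors`
#' the metric pairings are derived algorithmically from the per-family high-
#' and low-impact OAT runs and appended to the key-species pairings.
#'
#' @param manifest manifest containing the parent runs.
#' @param pairing_table explicit pairing data.frame (`parent1`, `parent2`,
#'   `group`), or `NULL` to derive it.
#' @param impact_factors per-run impact factors (required when
#'   `pairing_table` is `NULL`).
#' @param key_pairs key-species pairings appended in algorithmic mode.
#' @return data.frame of combination runs: `label`, `parents`, `group`,
#'   `edits` (serialized union). Parents sharing a perturbed parameter are an
#'   error.
#' @export
pair_combinations <- function(manifest, pairing_table = default_pairing_table(),
                              impact_factors = NULL,
                              key_pairs = default_key_species_pairs()) {
  if (is.null(pairing_table)) {
    if (is.null(impact_factors))
      .stopf("pair_combinations needs a pairing_table or impact_factors")
    sel <- select_high_low_runs(manifest, impact_factors)
    pairing_table <- rbind(key_pairs, .all_pairs_table(sel$high, sel$low))
  }
  known <- setNames(as.list(manifest$edits), manifest$label)
  out <- list()
  for (i in seq_len(nrow(pairing_table))) {
    p1 <- pairing_table$parent1[i]; p2 <- pairing_table$parent2[i]
    for (p in c(p1, p2))
      if (is.null(known[[p]])) .stopf("combination parent not in manifest: %s", p)
    e1 <- parse_edits(known[[p1]]); e2 <- parse_edits(known[[p2]])
    both <- rbind(e1, e2)
    dup <- duplicated(both[, c("component", "parameter")])
    if (any(dup))
      .stopf("conflicting edits: parents %s and %s both perturb %s:%s",
             p1, p2, both$component[dup][1], both$parameter[dup][1])
    label <- paste(p1, p2, sep = " + ")
    known[[label]] <- .serialize_edits(both)
    out[[i]] <- data.frame(label = label,
                           parents = paste(p1, p2, sep = " + "),
                           group = pairing_table$group[i],
                           edits = .serialize_edits(both))
  }
  do.call(rbind, out)
}

#' Build the full experiment manifest
#'
#' Control run plus OAT runs, extreme runs and combination runs, with
#' sequential run ids (control is run 0). The reference design on the
#' default web (9 key species, +/- 25%, 4 extremes, the fixture pairing
#' table) yields 105 entries: 1 control + 64 OAT + 4 extremes + 36
#' combinations.
#'
#' @param config a `foodweb_config`.
#' @param magnitudes OAT multipliers.
#' @param extremes extreme-run table ([default_extremes()]); `NULL` or an
#'   empty data.frame for none.
#' @param pairing_table combination pairing fixture; `NULL` together with
#'   `impact_factors` selects pairings algorithmically; `NA` for no
#'   combination runs.
#' @param impact_factors see [pair_combinations()].
#' @return a `foodweb_manifest`: data.frame with `run_id`, `label`,
#'   `provenance` (`control`/`oat`/`extreme`/`combination`), `parents`,
#'   `edits`.
#' @export
build_manifest <- function(config, magnitudes = c(1.25, 0.75),
                           extremes = default_extremes(),
                           pairing_table = default_pairing_table(),
                           impact_factors = NULL) {
  oat <- enumerate_oat(config, magnitudes)
  ext <- if (is.null(extremes)) default_extremes()[0, ] else
    enumerate_extremes(config, extremes)
  rows <- data.frame(label = "control", provenance = "control", parents = "",
                     edits = "")
  if (nrow(oat))
    rows <- rbind(rows, data.frame(
      label = oat$label, provenance = "oat", parents = "",
      edits = vapply(seq_len(nrow(oat)), function(i)
        .serialize_edits(oat[i, ]), "")))
  if (nrow(ext))
    rows <- rbind(rows, data.frame(
      label = ext$label, provenance = "extreme", parents = "",
      edits = vapply(seq_len(nrow(ext)), function(i)
        .serialize_edits(ext[i, ]), "")))
  rows$run_id <- seq_len(nrow(rows)) - 1L
  rows <- rows[, c("run_id", "label", "provenance", "parents", "edits")]
  class(rows) <- c("foodweb_manifest", "data.frame")
  skip_combos <- (length(pairing_table) == 1L && is.na(pairing_table)) ||
    (is.null(pairing_table) && is.null(impact_factors))
  if (!skip_combos) {
    combos <- pair_combinations(rows, pairing_table, impact_factors)
    combos <- data.frame(run_id = max(rows$run_id) + seq_len(nrow(combos)),
                         label = combos$label, provenance = "combination",
                         parents = combos$parents, edits = combos$edits)
    rows <- rbind(rows, combos)
  }
  if (anyDuplicated(rows$label))
    .stopf("duplicate run label: %s", rows$label[duplicated(rows$label)][1])
  ## every edit must reference an existing component
  for (i in seq_len(nrow(rows))) {
    e <- parse_edits(rows$edits[i])
    bad <- setdiff(e$component, config$components$id)
    if (length(bad)) .stopf("run %s references unknown component %s",
                            rows$label[i], bad[1])
  }
  rownames(rows) <- NULL
  class(rows) <- c("foodweb_manifest", "data.frame")
  attr(rows, "design") <- list(magnitudes = magnitudes,
                               n_extremes = nrow(ext))
  rows
}

#' Retrieve the edits of one manifest run
#'
#' @param manifest a `foodweb_manifest`.
#' @param run_id run id (integer) or label.
#' @return data.frame of edits (`component`, `parameter`, `multiplier`).
#' @export
manifest_edits <- function(manifest, run_id) {
  i <- if (is.character(run_id)) match(run_id, manifest$label)
  else match(run_id, manifest$run_id)
  if (is.na(i)) .stopf("run not found in manifest: %s", run_id)
  parse_edits(manifest$edits[i])
}

#' Apply perturbation edits to a configuration
#'
#' Multiplies each referenced parameter by its multiplier: `mum` and `C`
#' scale the whole per-age vector, `mQ` scales the juvenile and adult
#' coefficients together (the pool coefficient for pools), `recruitment`
#' resolves to `BHa` (Beverton-Holt) or `KDENR` (constant per-adult) by the
#' component's mode. Everything else is untouched; the input config is not
#' modified.
#'
#' @param config a `foodweb_config`.
#' @param edits data.frame with `component`, `parameter`, `multiplier`, or a
#'   serialized edit string.
#' @return the perturbed `foodweb_config`.
#' @export
apply_edits <- function(config, edits) {
  if (is.character(edits)) edits <- parse_edits(edits)
  if (!nrow(edits)) return(config)
  comp <- config$components
  for (i in seq_len(nrow(edits))) {
    id <- edits$component[i]; par <- edits$parameter[i]; m <- edits$multiplier[i]
    if (!id %in% comp$id) .stopf("edit references unknown component: %s", id)
    if (m <= 0) .stopf("edit multiplier for %s:%s must be positive", id, par)
    kind <- comp$kind[comp$id == id]
    p <- config$params[[id]]
    if (par == "mum") p$mum <- p$mum * m
    else if (par == "C") p$C <- p$C * m
    else if (par == "mQ") {
      if (kind == "vertebrate") {
        p$mQ_juvenile <- p$mQ_juvenile * m
        p$mQ_adult <- p$mQ_adult * m
      } else p$mQ <- p$mQ * m
    } else if (par == "recruitment") {
      if (kind != "vertebrate")
        .stopf("recruitment cannot be perturbed for pool %s", id)
      mode <- comp$recruitment_mode[comp$id == id]
      if (mode == "beverton_holt") p$BHa <- p$BHa * m
      else p$KDENR <- p$KDENR * m
    } else .stopf("unknown parameter family: %s", par)
    config$params[[id]] <- p
  }
  config
}

#' Save / load a manifest as CSV
#'
#' @param manifest a `foodweb_manifest`.
#' @param path CSV file path.
#' @return `path` (save) or the manifest (load).
#' @export
save_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) .stopf("manifest file not found: %s", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  m$parents[is.na(m$parents)] <- ""
  m$edits[is.na(m$edits)] <- ""
  class(m) <- c("foodweb_manifest", "data.frame")
  m
}
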