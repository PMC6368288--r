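test_that("OAT enumeration covers species x parameter family x direction", {
  cfg <- default_web()
  oat <- enumerate_oat(cfg)
  ## 5 vertebrates x 4 families x 2 + 4 pools x 3 families x 2
  expect_equal(nrow(oat), 5 * 4 * 2 + 4 * 3 * 2)
  expect_equal(nrow(oat), 64L)
  expect_false(any(oat$parameter == "recruitment" &
                     oat$component %in% c("ZS", "ZM", "ZL", "ZG")))
  expect_setequal(unique(oat$multiplier), c(1.25, 0.75))
  expect_false(anyDuplicated(oat$label) > 0)

  ## a single pool contributes 3 families x 2 directions
  solo <- tiny_web()
  expect_equal(nrow(enumerate_oat(solo)), 6L)
  solo$components$is_key_species <- FALSE
  expect_equal(nrow(enumerate_oat(solo)), 0L)
})

test_that("the default extreme set encodes the four observed-extreme runs", {
  cfg <- default_web()
  ext <- enumerate_extremes(cfg)
  expect_equal(nrow(ext), 4L)
  expect_equal(ext$multiplier[ext$component == "SSH"], c(3.30, 0.10))
  expect_equal(ext$multiplier[ext$component == "NCO"], c(1.70, 0.61))
  expect_true(all(ext$parameter[ext$component == "SSH"] == "recruitment"))
  expect_true(all(ext$parameter[ext$component == "NCO"] == "mum"))
  expect_equal(nrow(enumerate_extremes(cfg, default_extremes()[0, ])), 0L)
  expect_error(enumerate_extremes(cfg, data.frame(
    label = "x", component = "NCO", parameter = "mum", multiplier = -1)),
    "positive")
})

test_that("the reference manifest has 105 entries: 1 + 64 + 4 + 36", {
  cfg <- default_web()
  man <- build_manifest(cfg)
  expect_equal(nrow(man), 105L)
  expect_equal(sum(man$provenance == "control"), 1L)
  expect_equal(sum(man$provenance == "oat"), 64L)
  expect_equal(sum(man$provenance == "extreme"), 4L)
  expect_equal(sum(man$provenance == "combination"), 36L)
  expect_false(anyDuplicated(man$run_id) > 0)
  expect_equal(man$run_id, 0:104)
  ## manifest determinism
  expect_identical(man, build_manifest(cfg))
})

test_that("OAT runs differ from control in exactly one parameter reference", {
  man <- build_manifest(default_web())
  for (i in which(man$provenance == "oat")) {
    e <- parse_edits(man$edits[i])
    expect_equal(nrow(e), 1L)
  }
  expect_identical(man$edits[man$provenance == "control"], "")
})

test_that("combination edits are the exact union of their parents' edits", {
  man <- build_manifest(default_web())
  by_label <- setNames(man$edits, man$label)
  combos <- man[man$provenance == "combination", ]
  expect_equal(sum(grepl("recruitment.down \\+ SSH", combos$parents)), 2L)
  for (i in seq_len(nrow(combos))) {
    parents <- strsplit(combos$parents[i], " + ", fixed = TRUE)[[1]]
    p1 <- by_label[[parents[1]]]
    p2 <- by_label[[paste(parents[-1], collapse = " + ")]]
    union_edits <- rbind(parse_edits(p1), parse_edits(p2))
    expect_equal(parse_edits(combos$edits[i]), union_edits,
                 ignore_attr = TRUE)
  }
  ## the key-species pairing with a combination parent carries three edits
  triple <- combos[grepl("NCO.mQ.down \\+ CAP", combos$parents), ]
  expect_equal(nrow(parse_edits(triple$edits[1])), 3L)
})

test_that("conflicting parents (same parameter reference) are rejected", {
  man <- build_manifest(default_web(), pairing_table = NA)
  bad <- data.frame(parent1 = "ZL.mum.up", parent2 = "ZL.mum.down",
                    group = "metric")
  expect_error(pair_combinations(man, bad), "conflicting edits")
  expect_error(pair_combinations(man, data.frame(
    parent1 = "nope", parent2 = "ZL.mum.up", group = "x")), "not in manifest")
})

test_that("high/low selection follows impact factors with run-id tie-breaks", {
  man <- build_manifest(default_web(), pairing_table = NA)
  oat <- man[man$provenance %in% c("oat", "extreme"), ]
  imp <- data.frame(run_id = oat$run_id, impact_factor = 1.0)
  ## make one mum run clearly high, keep ties elsewhere
  imp$impact_factor[oat$label == "ZL.mum.down"] <- 2.5
  sel <- select_high_low_runs(man, imp)
  expect_equal(unname(sel$high["mum"]), "ZL.mum.down")
  ## all other families tie at 1.0: lowest run id wins both slots
  first_c <- oat$label[grepl("\\.C\\.", oat$label)][1]
  expect_equal(unname(sel$high["C"]), first_c)
  expect_equal(unname(sel$low["C"]), first_c)

  ## a high x low pairing of factors (2.5, 1.0) pairs (first, second)
  pair <- data.frame(parent1 = sel$high[["mum"]], parent2 = sel$low[["mum"]],
                     group = "metric")
  combo <- pair_combinations(man, pair)
  expect_equal(combo$parents, paste(sel$high[["mum"]], sel$low[["mum"]],
                                    sep = " + "))
})

test_that("algorithmic pairing yields 28 metric pairs plus the key-species 8", {
  man <- build_manifest(default_web(), pairing_table = NA)
  oat <- man[man$provenance %in% c("oat", "extreme"), ]
  set.seed(3)
  imp <- data.frame(run_id = oat$run_id,
                    impact_factor = runif(nrow(oat), 1, 4))
  combos <- pair_combinations(man, pairing_table = NULL, impact_factors = imp)
  expect_equal(nrow(combos), 36L)
  expect_equal(sum(combos$group == "metric"), 28L)
  expect_equal(sum(combos$group == "key_species"), 8L)
})

test_that("apply_edits multiplies exactly the referenced parameters", {
  cfg <- vert_web()
  cfg$params$F$mum <- c(1.2, 1.8, 2.0)
  out <- apply_edits(cfg, data.frame(component = "F", parameter = "mum",
                                     multiplier = 1.25))
  expect_equal(out$params$F$mum, c(1.5, 2.25, 2.5))
  expect_equal(out$params$F$C, cfg$params$F$C)  # untouched

  ## multiplier 1 is the identity
  same <- apply_edits(cfg, data.frame(component = "F", parameter = "C",
                                      multiplier = 1))
  expect_equal(same, cfg)

  ## a mortality edit scales juvenile and adult coefficients together
  m <- apply_edits(cfg, data.frame(component = "F", parameter = "mQ",
                                   multiplier = 1.25))
  expect_equal(m$params$F$mQ_juvenile, cfg$params$F$mQ_juvenile * 1.25)
  expect_equal(m$params$F$mQ_adult, cfg$params$F$mQ_adult * 1.25)

  ## recruitment resolves by mode
  r <- apply_edits(cfg, data.frame(component = "F", parameter = "recruitment",
                                   multiplier = 0.75))
  expect_equal(r$params$F$BHa, cfg$params$F$BHa * 0.75)
  kcfg <- vert_web(recruitment = "constant_per_adult")
  k <- apply_edits(kcfg, data.frame(component = "F", parameter = "recruitment",
                                    multiplier = 0.75))
  expect_equal(k$params$F$KDENR, kcfg$params$F$KDENR * 0.75)

  expect_error(apply_edits(cfg, data.frame(component = "Z",
                                           parameter = "recruitment",
                                           multiplier = 2)), "pool")
  expect_error(apply_edits(cfg, data.frame(component = "XX", parameter = "mum",
                                           multiplier = 2)), "unknown component")
})

test_that("manifests persist to CSV and reload identically", {
  man <- build_manifest(default_web())
  path <- withr::local_tempfile(fileext = ".csv")
  save_manifest(man, path)
  back <- load_manifest(path)
  expect_equal(back$run_id, man$run_id)
  expect_equal(back$label, man$label)
  expect_equal(back$edits, man$edits)
  expect_equal(manifest_edits(back, 1L), manifest_edits(man, 1L))
  expect_error(load_manifest(withr::local_tempfile()), "not found")
})
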