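test_that("trophic effect is the vehicle co/mono ratio", {
  expect_equal(trophic_effect(2.0e6, 1.0e6), 2.0)
  expect_equal(trophic_effect(7.3e5, 7.3e5), 1.0)
  expect_equal(trophic_effect(5.0e5, 1.0e6), 0.5)
  expect_error(trophic_effect(0, 1e6), "positive")
  expect_error(trophic_effect(1e6, -1), "positive")
})

test_that("percent inhibition matches direct evaluation of the formula", {
  expect_equal(percent_inhibition(2.0, 1.04, 1.0), 96.0)
  expect_equal(percent_inhibition(2.0, 2.0, 1.0), 0.0)
  expect_equal(percent_inhibition(2.0, 1.0, 1.0), 100.0)
  expect_equal(percent_inhibition(2.0, 1.2, 1.0), 80.0)
  # unclipped outside [0, 100]
  expect_equal(percent_inhibition(2.0, 0.5, 1.0), 150.0)
  expect_equal(percent_inhibition(2.0, 2.5, 1.0), -50.0)
  # degenerate trophic effect refuses with the ratio in the message
  expect_error(percent_inhibition(1.05, 1.0, 1.0), "degeneracy")
  expect_error(percent_inhibition(2.0, 1.0, 0), "positive")
})

test_that("mono effect ratio flags cytotoxicity below the threshold", {
  expect_equal(mono_effect_ratio(1.0e6, 1.0e6), 1.0)
  expect_equal(mono_effect_ratio(3.0e5, 1.0e6), 0.3)
  expect_error(mono_effect_ratio(1, 0), "positive")
  cfg <- hit_call_config()
  expect_true(mono_effect_ratio(3.0e5, 1.0e6) < cfg$cytotox_ratio_threshold)
  expect_false(mono_effect_ratio(1.0e6, 1.0e6) < cfg$cytotox_ratio_threshold)
})

test_that("planted pan-cytotoxic kill fraction is recovered across seeds", {
  # one compound, kill multiplier 0.3, well CV 0.1: the triplicate
  # mono-drug/vehicle ratio should land in [0.2, 0.45] nearly always
  cfg <- simulation_config(
    n_compounds = 1L,
    class_mix = c(INERT = 0, PAN_CYTOTOXIC = 1,
                  MONO_CYTOTOXIC_PROTECTED = 0, ANTI_TROPHIC = 0),
    cytotoxic_multiplier_range = c(0.3, 0.3), noise_cv = 0.1)
  ratios <- vapply(seq_len(1000), function(s) {
    cfg$seed <- s
    m <- simulate_primary_library(cfg)$measurements
    mono <- m$condition == "MONOCULTURE"
    drug <- m$compound_id != VEHICLE
    mean(m$readout[mono & drug]) / mean(m$readout[mono & !drug])
  }, numeric(1))
  expect_gte(mean(ratios >= 0.2 & ratios <= 0.45), 0.95)
})

test_that("classification separates the four compound behaviors", {
  cfg <- hit_call_config()
  # vehicle-like compound: all ratios ~ 1
  expect_equal(classify_compound(1.0, 2.0, 2.0, 0, 50, cfg), "INERT")
  # cytotoxic in mono, protected in co-culture
  expect_equal(classify_compound(0.3, 1.95, 2.0, 2.5, 50, cfg),
               "MONO_CYTOTOXIC_PROTECTED")
  # cytotoxic everywhere
  expect_equal(classify_compound(0.3, 0.6, 2.0, 140, 50, cfg),
               "PAN_CYTOTOXIC")
  # clean anti-trophic blocker
  expect_equal(classify_compound(1.0, 1.0, 2.0, 100, 50, cfg),
               "ANTI_TROPHIC")
  # undefined pct falls back on the monoculture criteria only
  expect_equal(classify_compound(1.0, 1.0, 2.0, NA_real_, 50, cfg), "INERT")
  expect_equal(classify_compound(0.3, 0.6, 2.0, NA_real_, 50, cfg),
               "PAN_CYTOTOXIC")
})

test_that("hit threshold equals a brute-force pass over the raw well table", {
  sim <- simulate_primary_library(simulation_config(seed = 21,
                                                    n_compounds = 400))
  scr <- run_primary_screen(sim$measurements, sim$compounds)

  # independent oracle: base-R aggregation over the raw wells
  m <- as.data.frame(sim$measurements)
  veh <- m[m$compound_id == "VEHICLE", ]
  vmeans <- tapply(veh$readout, list(veh$plate_id, veh$condition), mean)
  drug <- m[m$compound_id != "VEHICLE", ]
  agg <- tapply(drug$readout,
                list(drug$compound_id, drug$plate_id, drug$condition), mean)
  pct <- numeric(0)
  for (cid in dimnames(agg)[[1]]) {
    sl <- agg[cid, , ]
    p <- rownames(sl)[!is.na(sl[, "COCULTURE"])]
    A <- vmeans[p, "COCULTURE"]; C <- vmeans[p, "MONOCULTURE"]
    B <- sl[p, "COCULTURE"]
    pct[cid] <- 100 * (A - B) / (A - C)
  }
  oracle_thr <- mean(pct) + 3 * sd(pct)
  expect_equal(scr$hit_report$threshold, oracle_thr, tolerance = 1e-9)

  # and per-compound pct agrees with direct formula evaluation
  got <- scr$results$pct_inhibition[match(names(pct),
                                          scr$results$compound_id)]
  expect_equal(unname(got), unname(pct), tolerance = 1e-9)
})

test_that("identical percent inhibition everywhere yields no hits", {
  res <- tibble::tibble(compound_id = paste0("C", 1:5),
                        pct_inhibition = rep(40, 5),
                        mono_effect_ratio = rep(1, 5))
  hits <- call_hits(res)
  expect_equal(hits$threshold_report$sd_pct, 0)
  expect_false(any(hits$calls$is_hit))  # strict ">" fails at SD = 0
  expect_error(call_hits(res[1, ]), "at least 2")
})

test_that("single-compound zero-noise screen composes to 100% inhibition", {
  m2 <- make_primary_fixture(c("C1", "C2"), mono_drug = c(1, 1),
                             co_drug = c(1, 2))
  scr <- run_primary_screen(m2)
  r <- scr$results[scr$results$compound_id == "C1", ]
  expect_equal(r$pct_inhibition, 100)
  expect_equal(r$trophic_effect, 2)
  # the 3-SD threshold needs a realistically inert-dominated library for a
  # lone blocker to clear it (1 hit per ~20 compounds suffices)
  m20 <- make_primary_fixture(c("C1", sprintf("B%02d", 1:19)),
                              mono_drug = rep(1, 20),
                              co_drug = c(1, rep(2, 19)))
  scr20 <- run_primary_screen(m20)
  r20 <- scr20$results[scr20$results$compound_id == "C1", ]
  expect_equal(r20$category, "ANTI_TROPHIC")
  expect_true(r20$is_hit)
})

test_that("a Table-1-shaped zero-noise fixture reproduces its inhibition column", {
  planted <- c(100, 100, 100, 100, 96, 90, 87, 87, 83, 80)
  ids <- sprintf("T%02d", seq_along(planted))
  # co_drug = A - pct/100 * (A - C) with A = 2, C = 1
  fix <- make_primary_fixture(ids, mono_drug = rep(1, 10),
                              co_drug = 2 - planted / 100)
  # inert ballast in the library's own proportions (10 hits per ~200
  # compounds) so the mean + 3 SD threshold sits below the planted values
  ballast <- sprintf("B%03d", 1:190)
  fix <- dplyr::bind_rows(
    fix,
    make_primary_fixture(ballast, mono_drug = rep(1, 190),
                         co_drug = rep(2, 190))[-(1:6), ])
  scr <- run_primary_screen(fix)
  got <- scr$results$pct_inhibition[match(ids, scr$results$compound_id)]
  expect_equal(sort(got, decreasing = TRUE), sort(planted, decreasing = TRUE))
  expect_true(all(scr$results$is_hit[match(ids, scr$results$compound_id)]))
})

test_that("statistics are invariant to rescaling a plate's readouts", {
  sim <- simulate_primary_library(simulation_config(seed = 8,
                                                    n_compounds = 160))
  scr1 <- run_primary_screen(sim$measurements, sim$compounds)
  scaled <- dplyr::mutate(
    sim$measurements,
    readout = readout * ifelse(plate_id == "P01", 7.3, 1))
  scr2 <- run_primary_screen(scaled, sim$compounds)
  expect_equal(scr2$results$pct_inhibition, scr1$results$pct_inhibition)
  expect_equal(scr2$results$mono_effect_ratio, scr1$results$mono_effect_ratio)
  expect_equal(scr2$results$trophic_effect, scr1$results$trophic_effect)
  expect_equal(scr2$results$category, scr1$results$category)
  expect_equal(scr2$results$is_hit, scr1$results$is_hit)
})

test_that("a vehicle-like compound is inert with ~0 inhibition at zero noise", {
  ids <- c("VEHLIKE", sprintf("X%02d", 1:9))
  fix <- make_primary_fixture(ids, mono_drug = rep(1, 10),
                              co_drug = c(2, rep(1.5, 9)))
  scr <- run_primary_screen(fix)
  r <- scr$results[scr$results$compound_id == "VEHLIKE", ]
  expect_equal(r$pct_inhibition, 0)
  expect_equal(r$category, "INERT")
  expect_false(r$is_hit)
})

test_that("lowering co-culture signal never removes a compound from the hit set", {
  # threshold held fixed: call_hits on a fixed result table
  res <- tibble::tibble(compound_id = sprintf("C%02d", 1:20),
                        pct_inhibition = c(seq(0, 36, length.out = 18), 90, 95),
                        mono_effect_ratio = 1)
  thr <- call_hits(res)$threshold_report$threshold
  base_hits <- call_hits(res)$calls$is_hit
  # decreasing co_drug_mean increases pct_inhibition monotonically
  A <- 2; C <- 1
  co_drug <- A - res$pct_inhibition / 100 * (A - C)
  for (delta in c(0.05, 0.2)) {
    pct2 <- 100 * (A - (co_drug - delta)) / (A - C)
    still_hit <- pct2 > thr & res$mono_effect_ratio >= 0.7
    expect_true(all(still_hit[base_hits]))
  }
})

test_that("zero-noise synthetic libraries classify without error", {
  cfg <- simulation_config(seed = 13, n_compounds = 400, noise_cv = 0)
  sim <- simulate_primary_library(cfg)
  scr <- run_primary_screen(sim$measurements, sim$compounds)
  tt <- dplyr::left_join(scr$results, sim$ground_truth, by = "compound_id")
  expect_equal(tt$category, tt$class)
  # hit set == planted anti-trophic set
  expect_setequal(tt$compound_id[tt$is_hit],
                  tt$compound_id[tt$class == "ANTI_TROPHIC"])
})

test_that("category counts on a noisy library match the planted mix closely", {
  cfg <- simulation_config(seed = 17, n_compounds = 1000)
  sim <- simulate_primary_library(cfg)
  scr <- run_primary_screen(sim$measurements, sim$compounds)
  planted <- table(sim$ground_truth$class)
  called <- table(factor(scr$results$category, levels = names(planted)))
  # the cytotoxicity cut sits >3 triplicate SDs from both planted ratio
  # modes, so misclassification should be rare
  expect_true(all(abs(called - planted) <= 5))
})
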