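test_that("frozen dynamics leave the volume constant", {
  case <- make_test_case(sensitivity = c(doxorubicin = 0))
  cfg <- fast_config(metabolic = metabolic_parameters(mu_max = 1e-9))
  traj <- run_case(case, config = cfg)
  expect_equal(traj$V_final, traj$V_initial)
  expect_equal(diff(range(traj$volume_cm3)), 0)
})

test_that("overwhelming drug drives the volume below the pCR cutoff", {
  case <- make_test_case(diameter = 12, sensitivity = c(doxorubicin = 30))
  traj <- run_case(case, config = fast_config())
  expect_gt(traj$V_initial, 0.1)
  expect_lt(traj$V_final, 0.01)
  expect_equal(classify_pcr(traj)$class, "pCR")
})

test_that("trajectories are deterministic and extend to surgery day", {
  case <- make_test_case()
  t1 <- run_case(case, config = fast_config())
  t2 <- run_case(case, config = fast_config())
  expect_identical(t1$volume_cm3, t2$volume_cm3)
  expect_equal(max(t1$days), case$regimen$surgery_day)
  expect_true(all(t1$volume_cm3 >= 0))
  expect_true(!is.unsorted(t1$days))
})

test_that("final volume is monotone in dose, kill_max and IC50", {
  sens_levels <- c(0.3, 1, 3)
  base_case <- make_test_case(diameter = 12)
  # dose doubling never increases final volume
  vols_dose <- vapply(c(55, 110, 220), function(dd) {
    run_case(make_test_case(diameter = 12, dox_dose = dd),
             config = fast_config())$V_final
  }, numeric(1))
  expect_true(all(diff(vols_dose) <= 1e-12))
  # kill_max scaling (via the sensitivity multiplier, which multiplies it)
  vols_k <- vapply(sens_levels, function(s) {
    run_case(make_test_case(diameter = 12,
                            sensitivity = c(doxorubicin = s)),
             config = fast_config())$V_final
  }, numeric(1))
  expect_true(all(diff(vols_k) <= 1e-12))
  # larger IC50 weakens the drug
  lib <- load_drug_library()
  vols_ic <- vapply(c(0.5, 2, 8) * lib$doxorubicin$IC50, function(ic) {
    lib2 <- lib
    lib2$doxorubicin$IC50 <- ic
    run_case(base_case, drugs = lib2, config = fast_config())$V_final
  }, numeric(1))
  expect_true(all(diff(vols_ic) >= -1e-12))
})

test_that("volume trajectories change gradually between days", {
  case <- make_test_case(diameter = 12)
  traj <- run_case(case, config = fast_config())
  v <- traj$volume_cm3
  # daily change bounded by a few voxels' worth of volume
  v_vox_cm3 <- case$lattice$voxel_side^3 * 1e-3
  rel_jump <- abs(diff(v))
  expect_true(all(rel_jump <= pmax(0.25 * head(v, -1), 8 * v_vox_cm3)))
})

test_that("mesh and bookkeeping mechanics agree on strong responses", {
  case <- make_test_case(diameter = 10, sensitivity = c(doxorubicin = 30))
  tb <- run_case(case, config = fast_config())
  tm <- run_case(case, config = sim_config(mechanics = "mesh"))
  expect_lt(tb$V_final, 0.01)
  expect_lt(tm$V_final, 0.01)
  expect_equal(tm$V_initial, tb$V_initial, tolerance = 0.05)
})

test_that("classify_pcr applies the exact boundary semantics", {
  mk <- function(v0, vf) list(V_initial = v0, V_final = vf,
                              percent_reduction = 100 * (1 - vf / v0))
  # absolute-volume rule: strict inequality
  expect_equal(classify_pcr(mk(10, 0.009))$rule_fired, "absolute_volume")
  expect_equal(classify_pcr(mk(10, 0.009))$class, "pCR")
  # Vf = 0.01 exactly is NOT below the cutoff; reduction 99.9% rescues it
  at_cut <- classify_pcr(mk(10, 0.01))
  expect_equal(at_cut$class, "pCR")
  expect_equal(at_cut$rule_fired, "percent_reduction")
  # Vf = 0.01 exactly with reduction < 99.9: residual
  expect_equal(classify_pcr(mk(5, 0.01))$class, "residual")
  # reduction rule: inclusive at exactly 99.9%
  expect_equal(classify_pcr(mk(50, 0.05))$class, "pCR")
  expect_equal(classify_pcr(mk(50, 0.05))$rule_fired, "percent_reduction")
  # the printed example: 99.92% reduction despite Vf >= 0.01
  expect_equal(classify_pcr(mk(50, 0.04))$rule_fired, "percent_reduction")
  # just outside both thresholds
  expect_equal(classify_pcr(mk(10, 0.011))$class, "residual")
  # degenerate baseline below the cutoff: pCR with a warning
  expect_warning(p <- classify_pcr(mk(0.005, 0.004)), "degenerate")
  expect_equal(p$class, "pCR")
  expect_error(classify_pcr(list(V_initial = -1, V_final = 0)),
               "non-negative")
})

test_that("compare_to_followups computes percent-of-baseline errors", {
  traj <- structure(list(days = 0:100, volume_cm3 = seq(10, 0, length.out = 101),
                         V_initial = 10), class = "sim_trajectory")
  # exact agreement -> zero error
  fu <- data.frame(day = c(30, 60), volume_cm3 = traj$volume_cm3[c(31, 61)])
  tab <- compare_to_followups(traj, fu)
  expect_equal(tab$error_pct, c(0, 0))
  # worked arithmetic: V0 = 10, pred 4, obs 5 -> 10%
  traj$volume_cm3[61] <- 4
  tab2 <- compare_to_followups(traj, data.frame(day = 60, volume_cm3 = 5))
  expect_equal(tab2$error_pct, 10.0)
  expect_equal(attr(tab2, "mean_error_pct"), 10.0)
  # empty follow-up list: empty table, flagged undefined mean
  tab3 <- compare_to_followups(traj, data.frame(day = numeric(0),
                                                volume_cm3 = numeric(0)))
  expect_equal(nrow(tab3), 0)
  expect_true(is.na(attr(tab3, "mean_error_pct")))
  # out-of-range day matched to nearest with flag
  tab4 <- compare_to_followups(traj, data.frame(day = 150, volume_cm3 = 1))
  expect_equal(tab4$flag, "nearest_day")
})

test_that("case_record enforces covariate consistency", {
  expect_error(case_record("x", 50, er = 120, subtype = "TNBC"), "ER/PR")
  expect_error(case_record("x", 50, er = 80, her2 = FALSE,
                           subtype = "TNBC"), "inconsistent")
  cr <- case_record("x", 50, er = 80, pr = 10, her2 = TRUE,
                    subtype = "HR+/HER2+")
  expect_equal(cr$subtype, "HR+/HER2+")
  # subtype inferred when omitted
  expect_equal(case_record("x", 50, er = 0, pr = 0, her2 = TRUE)$subtype,
               "HR-/HER2+")
})
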