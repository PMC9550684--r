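test_that("phantom generation is a pure function of spec and seed", {
  sp <- phantom_spec(diameter = 10, geometry = "rim_enhancing",
                     necrotic_fraction = 0.3, seed = 17)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$lattice$labels, b$lattice$labels)
  expect_identical(a$perfusion$ktrans, b$perfusion$ktrans)
  expect_identical(a$density$rho, b$density$rho)
})

test_that("ellipsoid phantom volume matches the closed form within 5%", {
  sp <- phantom_spec(diameter = 10, semi_axes = c(5, 4, 3),
                     voxel_side = 0.5, seed = 2)
  ph <- generate_phantom(sp)
  v_analytic <- 4 / 3 * pi * 5 * 4 * 3          # 251.3 mm^3
  v_detect <- tumor_volume(ph$density, ph$lattice) * 1000
  expect_lt(abs(v_detect - v_analytic) / v_analytic, 0.05)
})

test_that("necrotic core comprises the requested tumor fraction", {
  sp <- phantom_spec(diameter = 12, voxel_side = 0.5,
                     necrotic_fraction = 0.3, seed = 5)
  ph <- generate_phantom(sp)
  tumor <- ph$lattice$labels == TISSUE_LABELS[["tumor"]]
  frac <- sum(ph$density$rho[tumor] == 0) / sum(tumor)
  expect_lt(abs(frac - 0.3), 0.03)
  # necrotic voxels carry (near) zero delivery
  expect_lt(max(ph$perfusion$ktrans[ph$necrotic]), 0.011)
})

test_that("phantoms carry vessels touching the margin and valid maps", {
  ph <- generate_phantom(phantom_spec(diameter = 10, seed = 9))
  expect_gt(sum(ph$lattice$labels == TISSUE_LABELS[["vessel"]]), 0)
  expect_true(all(ph$perfusion$ve > 0 & ph$perfusion$ve <= 1))
  expect_error(generate_phantom(phantom_spec(diameter = 3,
                                             voxel_side = 2)),
               "2 voxels")
})

test_that("generate_dce_series reproduces tofts_forward voxelwise", {
  ph <- generate_phantom(phantom_spec(diameter = 8, seed = 4))
  aif <- aif_model()
  times <- seq(0, 10, by = 0.25)
  ser <- generate_dce_series(ph$perfusion, aif, times, noise_sd = 0)
  for (v in list(c(5, 5, 5), c(7, 6, 5), c(3, 8, 6))) {
    p <- list(ktrans = ph$perfusion$ktrans[v[1], v[2], v[3]],
              ve = ph$perfusion$ve[v[1], v[2], v[3]],
              vp = ph$perfusion$vp[v[1], v[2], v[3]])
    expect_equal(ser[v[1], v[2], v[3], -1],
                 tofts_forward(p, aif, times[-1]), tolerance = 1e-10)
  }
  # the sparse 3-point clinical schedule is accepted
  sparse <- generate_dce_series(ph$perfusion, aif, c(0, 250 / 60, 550 / 60),
                                noise_sd = 0)
  expect_equal(dim(sparse)[4], 3)
  expect_error(generate_dce_series(ph$perfusion, aif, times,
                                   noise_sd = -1), "noise_sd")
})

test_that("fitting a dense noiseless series recovers the map", {
  ph <- generate_phantom(phantom_spec(diameter = 8, seed = 6))
  aif <- aif_model()
  times <- seq(0, 12, by = 0.25)
  ser <- generate_dce_series(ph$perfusion, aif, times, noise_sd = 0)
  for (v in list(c(5, 5, 5), c(6, 7, 4))) {
    y <- ser[v[1], v[2], v[3], -1]
    fit <- tofts_fit(y, aif, times[-1])
    expect_lt(abs(fit$params$ktrans -
                  ph$perfusion$ktrans[v[1], v[2], v[3]]) /
              ph$perfusion$ktrans[v[1], v[2], v[3]], 0.01)
    expect_lt(abs(fit$params$ve - ph$perfusion$ve[v[1], v[2], v[3]]) /
              ph$perfusion$ve[v[1], v[2], v[3]], 0.01)
  }
})

test_that("generate_cohort emits n cases with cohort-like composition", {
  spec <- cohort_spec(n = 144, seed = 5)
  coh <- generate_cohort(spec, simulate_truth = FALSE)
  expect_length(coh$cases, 144)
  expect_equal(nrow(coh$truth), 144)
  expect_equal(coh$truth$id, vapply(coh$cases, function(x) x$id,
                                    character(1)))
  # subtype counts within multinomial 95% bounds of the design mixture
  counts <- table(coh$truth$subtype)
  for (st in names(spec$subtype_mix)) {
    p <- spec$subtype_mix[[st]]
    expect_gte(counts[[st]], qbinom(0.025, 144, p) - 1)
    expect_lte(counts[[st]], qbinom(0.975, 144, p) + 1)
  }
  # HER2-directed regimens only in HER2+ cases
  her2 <- grepl("HER2\\+", coh$truth$subtype)
  expect_true(all(grepl("HER2-directed",
                        coh$truth$regimen_class[her2])))
  expect_false(any(grepl("HER2-directed",
                         coh$truth$regimen_class[!her2])))
})

test_that("cohort truth labels include designed noise and follow-ups", {
  coh <- generate_cohort(cohort_spec(n = 10, seed = 42))
  expect_false(anyNA(coh$truth$observed_pcr))
  expect_true(all(c("followup_vol_day42", "followup_vol_day84",
                    "efs_years", "efs_event") %in% names(coh$truth)))
  expect_true(all(coh$truth$efs_years > 0))
  # same spec regenerates identical truth
  coh2 <- generate_cohort(cohort_spec(n = 10, seed = 42))
  expect_identical(coh$truth, coh2$truth)
})

test_that("raising cohort drug sensitivity raises the simulated pCR rate", {
  lo <- cohort_spec(n = 12, seed = 8,
                    sens_meanlog = c("TNBC" = -1.5, "HR-/HER2+" = -1.5,
                                     "HR+/HER2+" = -1.5, "HR+/HER2-" = -1.5),
                    label_noise = 0)
  hi <- lo; hi$sens_meanlog[] <- 1.5
  rate_lo <- mean(generate_cohort(lo)$truth$observed_pcr)
  rate_hi <- mean(generate_cohort(hi)$truth$observed_pcr)
  expect_gte(rate_hi, rate_lo)
  expect_gt(rate_hi, 0.5)
  expect_lt(rate_lo, 0.5)
})
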