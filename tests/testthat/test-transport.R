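make_closed_lattice <- function(n, h = 1)
  suppressWarnings(build_lattice(array(1L, c(n, n, n)), h))

test_that("diffusion leaves a uniform field unchanged and respects dt", {
  lat <- make_closed_lattice(8)
  f <- species_field("x", array(3.7, c(8, 8, 8)), D = 1)
  f2 <- diffusion_step(f, lat, 0.5)
  expect_equal(f2$C, f$C, tolerance = 1e-14)
  expect_error(diffusion_step(f, lat, -0.1), "dt")
  # sources == sinks: pure diffusion
  set.seed(2)
  g <- species_field("y", array(runif(8^3), c(8, 8, 8)), D = 0.5)
  s <- array(runif(8^3), c(8, 8, 8))
  g1 <- diffusion_step(g, lat, 0.3, sources = s, sinks = s)
  g2 <- diffusion_step(g, lat, 0.3)
  expect_equal(g1$C, g2$C, tolerance = 1e-14)
})

test_that("point release matches the 3D heat kernel within 2% L2", {
  n <- 31; h <- 1; D <- 1; ctr <- 16
  lat <- make_closed_lattice(n, h)
  C <- array(0, c(n, n, n)); C[ctr, ctr, ctr] <- 1 / h^3
  f <- species_field("x", C, D)
  for (i in 1:10) f <- diffusion_step(f, lat, 0.4)   # substepped per CFL
  expect_gt(attr(f, "n_substeps"), 1)
  tt <- 4
  co <- (seq_len(n) - ctr) * h
  X <- array(co, c(n, n, n)); Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  exact <- exp(-(X^2 + Y^2 + Z^2) / (4 * D * tt)) / (4 * pi * D * tt)^1.5
  expect_lt(sqrt(sum((f$C - exact)^2) / sum(exact^2)), 0.02)
})

test_that("closed-domain diffusion conserves mass to 1e-12 per 1000 steps", {
  lat <- make_closed_lattice(10)
  set.seed(1)
  f <- species_field("y", array(runif(1000), c(10, 10, 10)), D = 0.5)
  m0 <- sum(f$C)
  clip_total <- 0
  for (i in 1:1000) {
    f <- diffusion_step(f, lat, 0.2)
    clip_total <- clip_total + attr(f, "clipped_mass")
  }
  expect_lt(abs(sum(f$C) - m0) / m0, 1e-12)
  expect_equal(clip_total, 0)   # nothing clipped under valid preconditions
})

test_that("monod rates: saturation, starvation, midpoint", {
  mp <- metabolic_parameters(mu_max = 0.01, K_G = 1, K_O = 0.01)
  r_sat <- monod_rates(mp, G = 500, O = 10, rho_frac = 1)
  expect_lt(abs(r_sat$growth - 0.01) / 0.01, 0.01)
  r0 <- monod_rates(mp, G = 0, O = 1, rho_frac = 1)
  expect_equal(r0$growth, 0)
  expect_equal(r0$uptake_G, 0)
  r_mid <- monod_rates(mp, G = 1, O = 1, rho_frac = 1)
  expect_lt(abs(r_mid$growth - 0.005) / 0.005, 0.015)
  expect_error(monod_rates(mp, G = -1, O = 1, rho_frac = 1), "must be >= 0")
})

test_that("lactate is produced only under hypoxia", {
  mp <- metabolic_parameters(K_O = 0.01, Y_L = 2)
  well_ox <- monod_rates(mp, G = 5, O = 10, rho_frac = 1)
  hypoxic <- monod_rates(mp, G = 5, O = 0.001, rho_frac = 1)
  expect_lt(well_ox$lactate_production, 0.002 * well_ox$uptake_G * 2)
  expect_gt(hypoxic$lactate_production, 0.9 * hypoxic$uptake_G * 2)
  # Y_L respects the 2:1 stoichiometric cap
  expect_error(metabolic_parameters(Y_L = 2.5), "Y_L")
})

test_that("density_update follows the logistic-limited closed forms", {
  rho0 <- array(1e3, c(2, 2, 2))   # far below rho_max = 1e6
  dens <- cell_density_field(rho0)
  # pure growth at small steps: exponential within 1%
  mu <- 0.01; dt <- 1
  d <- dens
  for (i in 1:100) d <- density_update(d, mu, 0, dt)
  expect_lt(abs(d$rho[1] - 1e3 * exp(0.01 * 100)) / (1e3 * exp(1)), 0.01)
  # kill-dominated: exponential decay (small per-step delta * dt)
  d2 <- dens
  for (i in 1:500) d2 <- density_update(d2, 0, 0.05, 0.2)
  expect_lt(abs(d2$rho[1] - 1e3 * exp(-5)) / (1e3 * exp(-5)), 0.05)
  # mu == delta at rho << rho_max: unchanged to first order
  d3 <- density_update(dens, 0.01, 0.01, 1)
  expect_lt(abs(d3$rho[1] - 1e3) / 1e3, 1e-4)
  # zero density is a fixed point
  d0 <- cell_density_field(array(0, c(2, 2, 2)))
  expect_equal(density_update(d0, 0.1, 0, 1)$rho, d0$rho)
  # clamped at carrying capacity
  dmax <- cell_density_field(array(1e6, c(2, 2, 2)))
  expect_true(all(density_update(dmax, 1, 0, 10)$rho <= 1e6))
})

test_that("quasi-steady oxygen matches a brute-force time-march oracle", {
  lat <- build_lattice(make_cube_labels(10, 4), 1)
  map <- make_uniform_map(lat, ktrans = 0.05, ve = 0.4)
  mp <- metabolic_parameters(uptake_max_O = 0.1)
  rho_frac <- array(0, lat$shape)
  rho_frac[lat$labels == TISSUE_LABELS[["tumor"]]] <- 1
  plasma <- 0.13; D <- 7.2
  qss <- tumorsim:::.qss_solve(array(plasma * 0.4, lat$shape), lat, map, D,
                               plasma,
                               sink_coeff = function(C)
                                 mp$uptake_max_O * rho_frac / (C + mp$K_O),
                               tol = 1e-10, max_iter = 5000)
  # oracle: explicit time marching of the same physics to steady state
  C <- array(plasma * 0.4, lat$shape)
  bg <- lat$labels == TISSUE_LABELS[["background"]]
  dt <- 0.005
  for (i in 1:8000) {
    f <- species_field("O", C, D, plasma)
    sink <- mp$uptake_max_O * (C / (C + mp$K_O)) * rho_frac
    ex <- 60 * map$ktrans * (plasma - C / map$ve)
    ex[bg] <- 0
    C <- diffusion_step(f, lat, dt, sources = pmax(ex, 0),
                        sinks = pmax(-ex, 0) + sink)$C
  }
  tissue <- lat$labels != TISSUE_LABELS[["background"]]
  expect_lt(max(abs(qss[tissue] - C[tissue])) / max(C[tissue]), 0.005)
})
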