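#' Biexponential arterial input function
#'
#' Population AIF of Weinmann type: after an onset time `t0`,
#' `Cp(t) = a1 exp(-m1 (t - t0)) + a2 exp(-m2 (t - t0))`, zero before onset.
#' Default constants are the literature biexponential
#' (a1 = 3.99, a2 = 4.78 mM, m1 = 0.144, m2 = 0.0111 1/min); they are a
#' standard population default, not fitted to any cohort here.
#'
#' @param a1,a2 amplitudes (concentration units, >= 0).
#' @param m1,m2 decay rates (1/min), `m1 > m2 > 0`.
#' @param t0 onset time in min.
#' @return object of class `aif_model`.
#' @export
aif_model <- function(a1 = 3.99, a2 = 4.78, m1 = 0.144, m2 = 0.0111,
                      t0 = 0) {
  if (a1 < 0 || a2 < 0) stop("AIF amplitudes must be >= 0", call. = FALSE)
  if (!(m1 > m2 && m2 > 0))
    stop("AIF rates must satisfy m1 > m2 > 0", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, m1 = m1, m2 = m2, t0 = t0),
            class = "aif_model")
}

#' Plasma concentration of the AIF
#'
#' @param aif an `aif_model`.
#' @param t times in min (vectorized).
#' @return Cp(t), zero for `t < t0`.
#' @export
plasma_concentration <- function(aif, t) {
  stopifnot(inherits(aif, "aif_model"))
  if (any(!is.finite(t))) stop("t must be finite", call. = FALSE)
  u <- t - aif$t0
  out <- ifelse(u >= 0,
                aif$a1 * exp(-aif$m1 * pmax(u, 0)) +
                aif$a2 * exp(-aif$m2 * pmax(u, 0)),
                0)
  as.numeric(out)
}

#' Perfusion parameters (extended Tofts)
#'
#' @param ktrans volume-transfer constant (1/min, >= 0).
#' @param ve extravascular-extracellular volume fraction, in (0, 1].
#' @param vp plasma volume fraction, in [0, 1), with `ve + vp <= 1`.
#' @return object of class `perfusion_parameters`.
#' @export
perfusion_parameters <- function(ktrans, ve, vp = 0) {
  if (ktrans < 0) stop("ktrans must be >= 0", call. = FALSE)
  if (!(ve > 0 && ve <= 1)) stop("ve must lie in (0, 1]", call. = FALSE)
  if (!(vp >= 0 && vp < 1)) stop("vp must lie in [0, 1)", call. = FALSE)
  if (ve + vp > 1 + 1e-12) stop("ve + vp must be <= 1", call. = FALSE)
  structure(list(ktrans = ktrans, ve = ve, vp = vp),
            class = "perfusion_parameters")
}

# Exact convolution of a biexponential AIF with exp(-kep t):
# int_0^u a e^{-m tau} e^{-kep (u - tau)} dtau
# = a (e^{-m u} - e^{-kep u}) / (kep - m), with the u e^{-m u} limit at
# kep == m.
.biexp_conv <- function(a, m, kep, u) {
  if (abs(kep - m) < 1e-10 * max(kep, m, 1)) {
    a * u * exp(-m * u)
  } else {
    a * (exp(-m * u) - exp(-kep * u)) / (kep - m)
  }
}

#' Forward extended Tofts tissue concentration
#'
#' `Ct(t) = vp Cp(t) + Ktrans int_0^t Cp(tau) exp(-(Ktrans/ve)(t - tau)) dtau`.
#' For a biexponential AIF the convolution is evaluated in closed form;
#' for a tabulated AIF (`aif` given as a function of t) adaptive quadrature
#' is used.
#'
#' @param params a `perfusion_parameters` object (or list with ktrans/ve/vp).
#' @param aif an `aif_model`, or a function `Cp(t)`.
#' @param times strictly increasing times in min.
#' @return tissue concentration at `times` (non-negative).
#' @export
tofts_forward <- function(params, aif, times) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  kt <- params$ktrans; ve <- params$ve; vp <- params$vp
  if (inherits(aif, "aif_model")) {
    u <- pmax(times - aif$t0, 0)
    cp <- plasma_concentration(aif, times)
    if (kt == 0) return(vp * cp)
    kep <- kt / ve
    conv <- .biexp_conv(aif$a1, aif$m1, kep, u) +
            .biexp_conv(aif$a2, aif$m2, kep, u)
    pmax(vp * cp + kt * conv, 0)
  } else if (is.function(aif)) {
    cp <- vapply(times, aif, numeric(1))
    if (kt == 0) return(vp * cp)
    kep <- kt / ve
    conv <- vapply(times, function(tt) {
      if (tt <= 0) return(0)
      stats::integrate(function(tau) aif(tau) * exp(-kep * (tt - tau)),
                       0, tt, rel.tol = 1e-9)$value
    }, numeric(1))
    pmax(vp * cp + kt * conv, 0)
  } else stop("aif must be an aif_model or a function", call. = FALSE)
}

#' Fit the extended Tofts model to a tissue concentration series
#'
#' Bounded Levenberg-Marquardt least squares (via \pkg{minpack.lm}).
#' Initialization Ktrans = 0.1, ve = 0.3, vp = 0.02; bounds enforce the
#' parameter invariants. Needs at least 3 time points. An all-zero series
#' short-circuits to Ktrans = 0, vp = 0 with a flag; non-convergence is
#' returned flagged, never thrown.
#'
#' @param tissue_series observed tissue concentrations.
#' @param aif an `aif_model`.
#' @param times acquisition times (min), strictly increasing.
#' @param lower,upper parameter bounds, order (ktrans, ve, vp).
#' @param init initial values, same order.
#' @return list with `params` (`perfusion_parameters`), `residual_norm`,
#'   `converged`, `flag`.
#' @export
tofts_fit <- function(tissue_series, aif, times,
                      lower = c(0, 1e-3, 0), upper = c(5, 1, 0.5),
                      init = c(0.1, 0.3, 0.02)) {
  if (length(times) < 3L)
    stop("at least 3 time points are required", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(tissue_series) != length(times))
    stop("tissue_series and times lengths differ", call. = FALSE)
  if (all(abs(tissue_series) < 1e-12)) {
    return(list(params = perfusion_parameters(0, init[2], 0),
                residual_norm = 0, converged = TRUE, flag = "zero_uptake"))
  }
  resid_fn <- function(p) {
    pp <- list(ktrans = p[1], ve = p[2], vp = p[3])
    tofts_forward(pp, aif, times) - tissue_series
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(params = perfusion_parameters(init[1], init[2], init[3]),
                residual_norm = NA_real_, converged = FALSE,
                flag = "fit_failed"))
  }
  p <- fit$par
  conv <- fit$info %in% 1:4
  list(params = perfusion_parameters(p[1], p[2], p[3]),
       residual_norm = sqrt(sum(fit$fvec^2)),
       converged = conv,
       flag = if (conv) "ok" else "not_converged")
}

#' Per-voxel perfusion parameter map
#'
#' Holds Ktrans, ve, vp arrays on a lattice. Parameters are defined on
#' non-background voxels; vessel-labeled voxels are flagged macrovascular
#' and act as fixed plasma-concentration (Dirichlet) sources in transport.
#'
#' @param ktrans,ve,vp 3D arrays matching the lattice shape.
#' @param lattice the `tissue_lattice`.
#' @param residual_norm optional per-voxel fit diagnostic array.
#' @return object of class `perfusion_map`.
#' @export
perfusion_map <- function(ktrans, ve, vp, lattice, residual_norm = NULL) {
  stopifnot(inherits(lattice, "tissue_lattice"))
  for (a in list(ktrans, ve, vp))
    if (!all(dim(a) == lattice$shape))
      stop("perfusion arrays must match lattice shape", call. = FALSE)
  bg <- lattice$labels == TISSUE_LABELS[["background"]]
  if (any(ktrans[!bg] < 0)) stop("ktrans must be >= 0", call. = FALSE)
  if (any(ve[!bg] <= 0) || any(ve[!bg] > 1))
    stop("ve must lie in (0, 1] on tissue voxels", call. = FALSE)
  structure(list(ktrans = ktrans, ve = ve, vp = vp,
                 macrovascular = lattice$labels == TISSUE_LABELS[["vessel"]],
                 residual_norm = residual_norm),
            class = "perfusion_map")
}

#' Per-voxel perfusion exchange rates for one species
#'
#' Microvascular coupling `Ktrans (Cp - C/ve)` on tissue voxels; vessel
#' voxels are Dirichlet plasma sources (handled by clamping in the transport
#' step, reported here via the `dirichlet` mask); background contributes 0.
#'
#' @param map a `perfusion_map`.
#' @param species_plasma_conc scalar systemic concentration of the species.
#' @param tissue_field 3D concentration array, same shape.
#' @param lattice the `tissue_lattice`.
#' @param relative_permeability species-specific scaling on Ktrans
#'   (default 1).
#' @return list with `exchange` (rate field, 1/min units of concentration)
#'   and `dirichlet` (logical mask of clamped voxels).
#' @export
perfusion_sources <- function(map, species_plasma_conc, tissue_field,
                              lattice, relative_permeability = 1) {
  stopifnot(inherits(map, "perfusion_map"),
            inherits(lattice, "tissue_lattice"))
  if (!all(dim(tissue_field) == lattice$shape))
    stop("tissue_field shape does not match lattice", call. = FALSE)
  bg <- lattice$labels == TISSUE_LABELS[["background"]]
  ex <- relative_permeability * map$ktrans *
    (species_plasma_conc - tissue_field / pmax(map$ve, 1e-12))
  ex[bg] <- 0
  ex[map$macrovascular] <- 0
  list(exchange = ex, dirichlet = map$macrovascular)
}
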