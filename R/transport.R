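# Shift a 3D array by one voxel along `axis` (+1 or -1), replicating the
# boundary plane (zero-flux / mirror boundary).
.shift3 <- function(a, axis, dir) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[axis]]
  if (dir > 0) i <- c(1L, i[-length(i)]) else i <- c(i[-1L], d[axis])
  idx[[axis]] <- i
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# cached 6-neighbor linear-index tables per lattice shape: column j holds
# each voxel's j-th neighbor, with out-of-domain neighbors mirrored to the
# voxel itself (zero-flux boundary)
.nb_cache <- new.env(parent = emptyenv())

.nb_index <- function(d) {
  key <- paste(d, collapse = "x")
  idx <- .nb_cache[[key]]
  if (!is.null(idx)) return(idx)
  nv <- prod(d)
  ii <- arrayInd(seq_len(nv), d)
  idx <- vector("list", 6L)
  col <- 0L
  for (axis in 1:3) for (dir in c(-1L, 1L)) {
    col <- col + 1L
    nb <- ii
    nb[, axis] <- pmin(pmax(nb[, axis] + dir, 1L), d[axis])
    idx[[col]] <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] +
                  nb[, 1]
  }
  .nb_cache[[key]] <- idx
  idx
}

# sum of the 6 mirror-boundary neighbors of every voxel
.nbsum <- function(a) {
  idx <- .nb_index(dim(a))
  v <- a[idx[[1]]] + a[idx[[2]]] + a[idx[[3]]] +
       a[idx[[4]]] + a[idx[[5]]] + a[idx[[6]]]
  dim(v) <- dim(a)
  v
}

# 6-neighbor (von Neumann) Laplacian with zero-flux boundaries, in units
# of 1/h when multiplied by D/h^2. Mirror boundaries make the scheme
# exactly conservative: sum(laplacian) == 0 to rounding.
.laplacian6 <- function(a, h) {
  (.nbsum(a) - 6 * a) / h^2
}

#' Chemical species field
#'
#' Per-voxel concentration of one transported species (nutrient, lactate or
#' drug) with its diffusion coefficient and systemic plasma level.
#'
#' @param name species name, e.g. "glucose", "oxygen", "amino_acids",
#'   "lactate" or "drug:<name>".
#' @param C 3D concentration array (>= 0).
#' @param D diffusion coefficient in mm^2/h (>= 0).
#' @param plasma_level systemic concentration (scalar; time-varying for
#'   drugs, supplied per step by the engine).
#' @return object of class `species_field`.
#' @export
species_field <- function(name, C, D, plasma_level = 0) {
  if (length(dim(C)) != 3L) stop("C must be a 3D array", call. = FALSE)
  if (any(C < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (D < 0) stop("D must be >= 0", call. = FALSE)
  structure(list(name = name, C = C, D = D, plasma_level = plasma_level),
            class = "species_field")
}

#' Explicit reaction-diffusion step (FTCS)
#'
#' Forward-time centered-space update
#' `C' = C + dt (D lap(C) + sources - sinks)` on the 6-neighbor stencil with
#' zero-flux boundaries. If `dt` exceeds the explicit stability bound
#' `h^2 / (6 D)` the step is internally divided into equal substeps that
#' satisfy it (sources and sinks applied per substep). Negative values
#' produced by sinks are clipped at zero and the clipped mass is logged.
#'
#' @param field a `species_field`.
#' @param lattice the `tissue_lattice` (supplies the grid spacing).
#' @param dt time step in hours (> 0 required; 0 returns the field
#'   unchanged).
#' @param sources per-voxel production rate (conc/h), scalar or array.
#' @param sinks per-voxel consumption rate (conc/h), scalar or array.
#' @param dirichlet optional logical mask of voxels clamped to
#'   `dirichlet_value` after every substep (macrovascular sources).
#' @param dirichlet_value clamp value (default the field's plasma level).
#' @return the updated `species_field`, with attribute `clipped_mass` (total
#'   concentration removed by the non-negativity clip, in conc units summed
#'   over voxels).
#' @export
diffusion_step <- function(field, lattice, dt, sources = 0, sinks = 0,
                           dirichlet = NULL,
                           dirichlet_value = field$plasma_level) {
  stopifnot(inherits(field, "species_field"),
            inherits(lattice, "tissue_lattice"))
  if (dt < 0) stop("dt must be >= 0", call. = FALSE)
  if (dt == 0) return(field)
  h <- lattice$voxel_side
  dt_max <- if (field$D > 0) h^2 / (6 * field$D) else Inf
  n_sub <- max(1L, ceiling(dt / dt_max))
  dts <- dt / n_sub
  C <- field$C
  net <- sources - sinks
  clipped <- 0
  for (s in seq_len(n_sub)) {
    C <- C + dts * (field$D * .laplacian6(C, h) + net)
    neg <- C < 0
    if (any(neg)) {
      clipped <- clipped - sum(C[neg])
      C[neg] <- 0
    }
    if (!is.null(dirichlet)) C[dirichlet] <- dirichlet_value
  }
  out <- species_field(field$name, C, field$D, field$plasma_level)
  attr(out, "clipped_mass") <- clipped
  attr(out, "n_substeps") <- n_sub
  out
}

#' Reduced Monod metabolic parameters
#'
#' Two-nutrient Monod kinetics replace a genome-scale metabolic model at
#' desk scale: growth is rate-limited by glucose and oxygen through
#' saturating Monod factors, nutrient uptake scales with cell density, and
#' lactate is produced from glucose in proportion to a hypoxia weight
#' `K_O / (O + K_O)` (anaerobic glycolysis), bounded by the 2:1
#' lactate:glucose stoichiometry.
#'
#' @param mu_max maximal specific growth rate (1/h).
#' @param K_G,K_O Monod half-saturation constants for glucose (mM) and
#'   oxygen (mM).
#' @param uptake_max_G,uptake_max_O maximal specific uptake rates
#'   (mmol per cell-unit per hour; concentration/h when multiplied by the
#'   normalized density).
#' @param Y_L lactate yield per glucose consumed under full hypoxia,
#'   in [0, 2].
#' @return object of class `metabolic_parameters`.
#' @export
metabolic_parameters <- function(mu_max = 0.002, K_G = 1.0, K_O = 0.01,
                                 uptake_max_G = 0.5, uptake_max_O = 1.0,
                                 Y_L = 2.0) {
  vals <- c(mu_max, K_G, K_O, uptake_max_G, uptake_max_O)
  if (any(vals <= 0)) stop("metabolic parameters must be positive",
                           call. = FALSE)
  if (Y_L < 0 || Y_L > 2)
    stop("Y_L must lie in [0, 2] (lactate:glucose stoichiometry)",
         call. = FALSE)
  structure(list(mu_max = mu_max, K_G = K_G, K_O = K_O,
                 uptake_max_G = uptake_max_G, uptake_max_O = uptake_max_O,
                 Y_L = Y_L),
            class = "metabolic_parameters")
}

#' Monod growth, uptake and lactate-production rates
#'
#' `mu = mu_max [G/(G+K_G)] [O/(O+K_O)]`; specific uptakes scale with the
#' same Monod factors and with the local normalized density; lactate
#' production is `Y_L * glucose_uptake * K_O/(O+K_O)`.
#'
#' @param params a `metabolic_parameters`.
#' @param G,O glucose and oxygen concentration (scalars or arrays, >= 0).
#' @param rho_frac tumor cell density as a fraction of carrying capacity
#'   (same shape).
#' @return list with `growth` (1/h), `uptake_G`, `uptake_O`,
#'   `lactate_production` (conc/h).
#' @export
monod_rates <- function(params, G, O, rho_frac) {
  stopifnot(inherits(params, "metabolic_parameters"))
  if (any(G < 0) || any(O < 0) || any(rho_frac < 0))
    stop("concentrations and density must be >= 0", call. = FALSE)
  fG <- G / (G + params$K_G)
  fO <- O / (O + params$K_O)
  w_hyp <- params$K_O / (O + params$K_O)
  upG <- params$uptake_max_G * fG * rho_frac
  list(growth = params$mu_max * fG * fO,
       uptake_G = upG,
       uptake_O = params$uptake_max_O * fO * rho_frac,
       lactate_production = params$Y_L * upG * w_hyp)
}

#' Logistic-limited density update
#'
#' `rho' = rho + dt (mu (1 - rho/rho_max) - delta) rho`, clamped to
#' `[0, rho_max]`. Zero density is a fixed point; growth saturates at the
#' carrying capacity; kill acts proportionally to the local density.
#'
#' @param density a `cell_density_field`.
#' @param mu per-voxel specific growth rate (1/h), scalar or array.
#' @param delta per-voxel specific kill rate (1/h), scalar or array.
#' @param dt step in hours (> 0).
#' @return the updated `cell_density_field`.
#' @export
density_update <- function(density, mu, delta, dt) {
  stopifnot(inherits(density, "cell_density_field"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (any(mu < 0) || any(delta < 0))
    stop("mu and delta must be >= 0", call. = FALSE)
  rho <- density$rho
  rho_new <- rho + dt * (mu * (1 - rho / density$rho_max) - delta) * rho
  rho_new[rho_new < 0] <- 0
  rho_new[rho_new > density$rho_max] <- density$rho_max
  cell_density_field(rho_new, density$rho_max, density$rho_detect)
}
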