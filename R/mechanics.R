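# node index (1-based) for corner (i, j, k) on an (nx+1, ny+1, nz+1) grid
.node_id <- function(i, j, k, nd) {
  i + (j - 1L) * nd[1] + (k - 1L) * nd[1] * nd[2]
}

#' Build a mass-spring mesh on a lattice
#'
#' Nodes sit at voxel corners; springs run along lattice edges (stiffness
#' `k`) and across face diagonals (stiffness `0.5 k`, shear resistance).
#' Rest lengths are the undeformed edge lengths.
#'
#' @param lattice a `tissue_lattice`.
#' @param k axis-spring stiffness (> 0, arbitrary force/mm units).
#' @return object of class `mass_spring_mesh` with `nodes` (N x 3 positions
#'   in mm), `edges` (E x 2 node indices), `rest0`, `stiffness`, `cell_dim`.
#' @export
build_mesh <- function(lattice, k = 1) {
  stopifnot(inherits(lattice, "tissue_lattice"))
  if (k <= 0) stop("stiffness must be positive", call. = FALSE)
  n <- lattice$shape
  nd <- n + 1L
  h <- lattice$voxel_side
  g <- expand.grid(i = seq_len(nd[1]), j = seq_len(nd[2]),
                   k = seq_len(nd[3]))
  nodes <- cbind((g$i - 1) * h, (g$j - 1) * h, (g$k - 1) * h)

  ii <- g$i; jj <- g$j; kk <- g$k
  e_from <- integer(0); e_to <- integer(0); e_k <- numeric(0)
  add <- function(mask, di, dj, dk, stiff) {
    from <- .node_id(ii[mask], jj[mask], kk[mask], nd)
    to <- .node_id(ii[mask] + di, jj[mask] + dj, kk[mask] + dk, nd)
    e_from <<- c(e_from, from); e_to <<- c(e_to, to)
    e_k <<- c(e_k, rep(stiff, sum(mask)))
  }
  # axis springs
  add(ii < nd[1], 1L, 0L, 0L, k)
  add(jj < nd[2], 0L, 1L, 0L, k)
  add(kk < nd[3], 0L, 0L, 1L, k)
  # face diagonals (both diagonals of each face), stiffness ratio 0.5
  add(ii < nd[1] & jj < nd[2], 1L, 1L, 0L, 0.5 * k)
  add(ii > 1L & jj < nd[2], -1L, 1L, 0L, 0.5 * k)
  add(ii < nd[1] & kk < nd[3], 1L, 0L, 1L, 0.5 * k)
  add(ii > 1L & kk < nd[3], -1L, 0L, 1L, 0.5 * k)
  add(jj < nd[2] & kk < nd[3], 0L, 1L, 1L, 0.5 * k)
  add(jj > 1L & kk < nd[3], 0L, -1L, 1L, 0.5 * k)

  edges <- cbind(e_from, e_to)
  rest0 <- sqrt(rowSums((nodes[e_to, , drop = FALSE] -
                         nodes[e_from, , drop = FALSE])^2))
  structure(list(nodes = nodes, edges = edges, rest0 = rest0,
                 stiffness = e_k, cell_dim = n, node_dim = nd,
                 voxel_side = h),
            class = "mass_spring_mesh")
}

#' Per-cell volumetric growth factors
#'
#' `g = exp((mu - delta) dt)`: the factor by which a voxel's preferred
#' volume changes over one mechanics interval. `g = 1` where growth and
#' kill balance.
#'
#' @param mu,delta per-voxel growth and kill rate fields (1/h).
#' @param dt interval in hours (> 0).
#' @return 3D array of growth factors (> 0).
#' @export
growth_factors <- function(mu, delta, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  exp((mu - delta) * dt)
}

# average a per-cell quantity onto nodes (mean of adjacent cells)
.cell_to_node <- function(cellvals, nd) {
  acc <- array(0, nd); cnt <- array(0, nd)
  cd <- dim(cellvals)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    acc[seq_len(cd[1]) + di, seq_len(cd[2]) + dj, seq_len(cd[3]) + dk] <-
      acc[seq_len(cd[1]) + di, seq_len(cd[2]) + dj, seq_len(cd[3]) + dk] +
      cellvals
    cnt[seq_len(cd[1]) + di, seq_len(cd[2]) + dj, seq_len(cd[3]) + dk] <-
      cnt[seq_len(cd[1]) + di, seq_len(cd[2]) + dj, seq_len(cd[3]) + dk] + 1
  }
  acc / cnt
}

# approximate deformed cell volumes from mean edge vectors (exact for
# affine deformations): vol = det[e1 e2 e3] with ei the average of the
# cell's four edges in lattice direction i.
mesh_cell_volumes <- function(mesh) {
  nd <- mesh$node_dim; cd <- mesh$cell_dim
  P <- mesh$nodes
  id <- function(di, dj, dk) {
    g <- expand.grid(i = seq_len(cd[1]) + di, j = seq_len(cd[2]) + dj,
                     k = seq_len(cd[3]) + dk)
    .node_id(g$i, g$j, g$k, nd)
  }
  corner <- lapply(0:7, function(b)
    P[id(bitwAnd(b, 1L), bitwAnd(bitwShiftR(b, 1L), 1L),
         bitwAnd(bitwShiftR(b, 2L), 1L)), , drop = FALSE])
  # mean edge vectors per direction
  e1 <- (corner[[2]] - corner[[1]] + corner[[4]] - corner[[3]] +
         corner[[6]] - corner[[5]] + corner[[8]] - corner[[7]]) / 4
  e2 <- (corner[[3]] - corner[[1]] + corner[[4]] - corner[[2]] +
         corner[[7]] - corner[[5]] + corner[[8]] - corner[[6]]) / 4
  e3 <- (corner[[5]] - corner[[1]] + corner[[6]] - corner[[2]] +
         corner[[7]] - corner[[3]] + corner[[8]] - corner[[4]]) / 4
  det3 <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
          e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
          e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  array(det3, cd)
}

.spring_energy <- function(nodes, edges, rest, stiffness) {
  d <- nodes[edges[, 2], , drop = FALSE] - nodes[edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  sum(0.5 * stiffness * (len - rest)^2)
}

#' Relax a mass-spring mesh toward equilibrium
#'
#' Spring rest lengths are scaled by `g^(1/3)` (isotropic volumetric
#' growth, with `g` averaged from cells to the edge endpoints) and the mesh
#' is relaxed by damped explicit iteration: each node moves by
#' `step_scale / K_i` times its net spring force, `K_i` the summed incident
#' stiffness. A step that would raise the total spring energy or invert a
#' cell is retried at half length (up to 30 halvings), so energy is
#' non-increasing across iterations.
#'
#' @param mesh a `mass_spring_mesh`.
#' @param g per-cell growth-factor array (from [growth_factors()]).
#' @param tol convergence threshold on the max nodal force norm.
#' @param max_iter iteration cap (reaching it flags the result).
#' @param step_scale damping factor on the per-node step (default 0.1).
#' @param fixed optional logical vector of nodes held fixed.
#' @return the deformed `mass_spring_mesh`, with attributes `converged`,
#'   `iterations`, `max_force`, `displacement` (N x 3).
#' @export
relax <- function(mesh, g, tol = 1e-4, max_iter = 2000, step_scale = 0.1,
                  fixed = NULL) {
  stopifnot(inherits(mesh, "mass_spring_mesh"))
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (any(g <= 0)) stop("growth factors must be positive", call. = FALSE)
  nd <- mesh$node_dim
  g_node <- as.vector(.cell_to_node(array(g, mesh$cell_dim), nd))
  ef <- mesh$edges[, 1]; et <- mesh$edges[, 2]
  g_edge <- 0.5 * (g_node[ef] + g_node[et])
  rest <- mesh$rest0 * g_edge^(1 / 3)
  N <- nrow(mesh$nodes)
  # summed incident stiffness per node (Jacobi-style scaling)
  Ksum <- numeric(N)
  ks <- rowsum(c(mesh$stiffness, mesh$stiffness), c(ef, et),
               reorder = FALSE)
  Ksum[as.integer(rownames(ks))] <- ks[, 1]
  Ksum[Ksum == 0] <- 1
  X0 <- mesh$nodes
  X <- X0
  free <- if (is.null(fixed)) rep(TRUE, N) else !fixed
  energy <- .spring_energy(X, mesh$edges, rest, mesh$stiffness)
  energy_trace <- energy
  it <- 0L; max_f <- Inf
  while (it < max_iter) {
    it <- it + 1L
    d <- X[et, , drop = FALSE] - X[ef, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len < 1e-12] <- 1e-12
    fmag <- mesh$stiffness * (len - rest) / len   # force per unit d
    contrib <- rbind(d * fmag, -d * fmag)         # on ef then on et
    Fr <- rowsum(contrib, c(ef, et), reorder = FALSE)
    Fnode <- matrix(0, N, 3)
    Fnode[as.integer(rownames(Fr)), ] <- Fr
    Fnode[!free, ] <- 0
    max_f <- sqrt(max(rowSums(Fnode^2)))
    if (max_f < tol) break
    step <- step_scale
    repeat {
      Xn <- X + (step / Ksum) * Fnode
      en <- .spring_energy(Xn, mesh$edges, rest, mesh$stiffness)
      vol_ok <- TRUE
      if (step < step_scale / 2) {          # only re-check when halved
        m2 <- mesh; m2$nodes <- Xn
        vol_ok <- all(mesh_cell_volumes(m2) > 0)
      }
      if (en <= energy + 1e-12 * max(energy, 1) && vol_ok) {
        X <- Xn; energy <- en; energy_trace <- c(energy_trace, en); break
      }
      step <- step / 2
      if (step < step_scale / 2^30)
        stop("relaxation step collapsed (inverted or stuck mesh)",
             call. = FALSE)
    }
  }
  out <- mesh
  out$nodes <- X
  attr(out, "converged") <- max_f < tol
  attr(out, "iterations") <- it
  attr(out, "max_force") <- max_f
  attr(out, "displacement") <- X - X0
  attr(out, "energy_trace") <- energy_trace
  out
}

#' Conservatively remap a density field after mesh deformation
#'
#' Each voxel's cell count `rho * V_cell` is preserved: the new density is
#' the old count divided by the deformed cell volume. Densities above the
#' carrying capacity are capped with the excess count pushed to the
#' 6-neighbors (a few sweeps); any unplaced remainder is logged.
#'
#' @param density a `cell_density_field` (defined per voxel/cell).
#' @param mesh_before,mesh_after meshes sharing topology, before and after
#'   deformation.
#' @return the remapped `cell_density_field`, with attribute
#'   `unplaced_cells` (count that could not be redistributed).
#' @export
remap_density <- function(density, mesh_before, mesh_after) {
  stopifnot(inherits(density, "cell_density_field"))
  if (!identical(mesh_before$cell_dim, mesh_after$cell_dim) ||
      nrow(mesh_before$edges) != nrow(mesh_after$edges))
    stop("meshes do not share topology", call. = FALSE)
  V0 <- mesh_cell_volumes(mesh_before)
  V1 <- mesh_cell_volumes(mesh_after)
  if (any(V1 <= 0)) stop("deformed mesh has non-positive cell volumes",
                         call. = FALSE)
  counts <- density$rho * V0
  rho_new <- counts / V1
  excess_total <- 0
  for (sweep in 1:3) {
    over <- rho_new > density$rho_max
    if (!any(over)) break
    excess <- (rho_new - density$rho_max) * V1
    excess[!over] <- 0
    rho_new[over] <- density$rho_max
    # push excess counts equally to 6-neighbors with spare capacity
    spread <- (.shift3(excess, 1L, +1L) + .shift3(excess, 1L, -1L) +
               .shift3(excess, 2L, +1L) + .shift3(excess, 2L, -1L) +
               .shift3(excess, 3L, +1L) + .shift3(excess, 3L, -1L)) / 6
    # mirror-boundary shifts double-count edge planes; renormalize to
    # conserve the total pushed
    tot <- sum(excess)
    if (sum(spread) > 0) spread <- spread * (tot / sum(spread))
    rho_new <- rho_new + spread / V1
  }
  over <- rho_new > density$rho_max
  if (any(over)) {
    excess_total <- sum((rho_new[over] - density$rho_max) * V1[over])
    rho_new[over] <- density$rho_max
  }
  out <- cell_density_field(rho_new, density$rho_max, density$rho_detect)
  attr(out, "unplaced_cells") <- excess_total
  out
}

#' Total tissue volume of a (possibly deformed) mesh, in mm^3
#' @param mesh a `mass_spring_mesh`.
#' @param mask optional logical per-cell mask (e.g. tumor voxels).
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, mask = NULL) {
  V <- mesh_cell_volumes(mesh)
  if (!is.null(mask)) V <- V[mask]
  sum(V)
}
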