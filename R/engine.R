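#' Simulation configuration
#'
#' Defaults chosen for desk-scale runs (2 mm voxels); every value is
#' overridable. Perfusion Ktrans is in 1/min (DCE convention) while the
#' simulation clock runs in hours; the engine applies the 60 min/h
#' conversion internally.
#'
#' @param dt_outer_h outer time step in hours (must divide 24).
#' @param mechanics_every mechanics update interval in outer steps.
#' @param mechanics "mesh" (deforming mass-spring mesh, default) or
#'   "bookkeeping" (volume tracked on the fixed lattice; used for large
#'   sweeps).
#' @param oxygen_qss solve nutrient fields in quasi-steady state each outer
#'   step (default TRUE); FALSE integrates them explicitly in time.
#' @param qss_tol,qss_max_iter fixed-point tolerance (relative) and
#'   iteration cap for the quasi-steady solver.
#' @param plasma_glucose,plasma_oxygen,plasma_lactate systemic nutrient /
#'   byproduct concentrations (mM).
#' @param D_oxygen,D_glucose,D_lactate,D_drug diffusion coefficients
#'   (mm^2/h); literature-order defaults (oxygen fastest, drugs slowest).
#' @param metabolic a `metabolic_parameters` object.
#' @param rho_max carrying capacity (cells/mm^3).
#' @param rho_detect detection threshold fraction for imaging-equivalent
#'   volume.
#' @param use_reductions honor documented dose reductions (FALSE mirrors a
#'   standard-dose sensitivity analysis).
#' @param combination_rule drug-combination rule ("additive" or "max").
#' @param drug_conc_threshold plasma concentration below which a drug field
#'   is not updated (mg/L).
#' @param clip_abort_fraction abort the run if a transport step clips more
#'   than this fraction of a field's mass (instability guard).
#' @param mesh_tol,mesh_max_iter,mesh_step_scale relaxation settings for
#'   mesh mechanics (the engine uses a larger damping step than the
#'   module default because its warm-started increments are small).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt_outer_h = 6, mechanics_every = 4,
                       mechanics = c("mesh", "bookkeeping"),
                       oxygen_qss = TRUE, qss_tol = 1e-4,
                       qss_max_iter = 200,
                       plasma_glucose = 5, plasma_oxygen = 0.13,
                       plasma_lactate = 1,
                       D_oxygen = 7.2, D_glucose = 3.2, D_lactate = 3.6,
                       D_drug = 0.36,
                       metabolic = metabolic_parameters(),
                       rho_max = 1e6, rho_detect = 0.10,
                       use_reductions = TRUE,
                       combination_rule = "additive",
                       drug_conc_threshold = 1e-6,
                       clip_abort_fraction = 0.05,
                       mesh_tol = 0.01, mesh_max_iter = 300,
                       mesh_step_scale = 0.5) {
  mechanics <- match.arg(mechanics)
  if (dt_outer_h <= 0 || 24 %% dt_outer_h != 0)
    stop("dt_outer_h must be positive and divide 24", call. = FALSE)
  if (mechanics_every < 1) stop("mechanics_every must be >= 1", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Clinical case record
#'
#' Carries the clinical covariates the platform ingests plus references to
#' the mechanistic inputs. Covariates feed the clinical comparator model
#' and reporting; only the per-drug sensitivity multipliers (which encode
#' subtype-dependent drug susceptibility) enter the mechanistic core.
#'
#' @param id case identifier.
#' @param age years.
#' @param race self-reported race (character).
#' @param t_stage,n_stage tumor / nodal stage (character, e.g. "T2", "N0").
#' @param er,pr percent staining in [0, 100].
#' @param her2 logical HER2 status.
#' @param grade tumor grade 1-3.
#' @param histology histology type (character).
#' @param subtype one of "HR+/HER2-", "HR+/HER2+", "HR-/HER2+", "TNBC";
#'   must be consistent with er/pr (1% positivity cutoff) and her2.
#' @param sensitivity named numeric vector of per-drug kill-rate
#'   multipliers (default 1 for unlisted drugs).
#' @param lattice,perfusion,density,regimen the mechanistic inputs.
#' @return object of class `case_record`.
#' @export
case_record <- function(id, age, race = "Unknown", t_stage = "T2",
                        n_stage = "N0", er = 0, pr = 0, her2 = FALSE,
                        grade = 3, histology = "IDC", subtype,
                        sensitivity = numeric(0),
                        lattice = NULL, perfusion = NULL, density = NULL,
                        regimen = NULL) {
  if (er < 0 || er > 100 || pr < 0 || pr > 100)
    stop("ER/PR percent staining must lie in [0, 100]", call. = FALSE)
  hr_pos <- er >= 1 || pr >= 1
  expected <- if (hr_pos && her2) "HR+/HER2+"
              else if (hr_pos) "HR+/HER2-"
              else if (her2) "HR-/HER2+"
              else "TNBC"
  if (!missing(subtype) && subtype != expected)
    stop(sprintf("subtype '%s' inconsistent with ER=%g, PR=%g, HER2=%s",
                 subtype, er, pr, her2), call. = FALSE)
  structure(list(id = id, age = age, race = race, t_stage = t_stage,
                 n_stage = n_stage, er = er, pr = pr, her2 = her2,
                 grade = grade, histology = histology, subtype = expected,
                 sensitivity = sensitivity, lattice = lattice,
                 perfusion = perfusion, density = density,
                 regimen = regimen),
            class = "case_record")
}

# Jacobi fixed-point solve of the steady reaction-diffusion balance
#   0 = D lap(C) + 60 rp Ktrans (Cp - C/ve) - sink_coeff(C) C
# with zero-flux boundaries and Dirichlet clamping on vessel voxels.
# sink_coeff returns the specific consumption rate (1/h) as a function of
# the current concentration field (Patankar-style linearization keeps the
# iteration positivity-preserving).
.qss_solve <- function(C, lattice, map, D, plasma, sink_coeff = NULL,
                       source = 0, relative_permeability = 1, tol = 1e-4,
                       max_iter = 200) {
  h <- lattice$voxel_side
  kt_h <- 60 * relative_permeability * map$ktrans  # 1/h
  bg <- lattice$labels == TISSUE_LABELS[["background"]]
  kt_h[bg] <- 0
  ve <- pmax(map$ve, 1e-12)
  dif <- D / h^2
  b0 <- kt_h * plasma + source
  diag0 <- 6 * dif + kt_h / ve
  for (it in seq_len(max_iter)) {
    nb <- .nbsum(C)
    a <- if (is.null(sink_coeff)) 0 else sink_coeff(C)
    Cn <- (dif * nb + b0) / (diag0 + a)
    Cn[map$macrovascular] <- plasma
    delta <- max(abs(Cn - C)) / max(max(abs(Cn)), 1e-12)
    C <- Cn
    if (delta < tol) break
  }
  C
}

# exact per-voxel relaxation of C toward ve*Cp over dt hours under
# microvascular exchange (rate 60 Ktrans / ve per hour); vessels clamped
.exchange_relax <- function(C, lattice, map, plasma, dt,
                            relative_permeability = 1) {
  bg <- lattice$labels == TISSUE_LABELS[["background"]]
  ve <- pmax(map$ve, 1e-12)
  rate <- 60 * relative_permeability * map$ktrans / ve
  rate[bg] <- 0
  target <- ve * plasma
  Cn <- target + (C - target) * exp(-rate * dt)
  Cn[bg] <- C[bg]
  Cn[map$macrovascular] <- plasma
  Cn
}

#' Simulate one case over its treatment calendar
#'
#' Outer loop (default 6 h steps): multi-dose plasma PK per drug ->
#' nutrient fields in quasi-steady state (perfusion delivery, diffusion,
#' Monod consumption) -> drug tissue fields (exact microvascular exchange +
#' explicit diffusion) -> lactate production and washout -> Hill kill and
#' Monod growth fields -> logistic density update -> mass-spring mechanics
#' every few steps -> daily volume recording. Deterministic given the case
#' and configuration.
#'
#' @param case a `case_record` with lattice, perfusion, density and regimen
#'   attached.
#' @param drugs named list of `drug_model`s covering the regimen
#'   (default: the shipped library).
#' @param config a `sim_config`.
#' @return object of class `sim_trajectory`: `days`, `volume_cm3`,
#'   `V_initial`, `V_final`, `percent_reduction`, plus diagnostics.
#' @export
run_case <- function(case, drugs = load_drug_library(),
                     config = sim_config()) {
  stopifnot(inherits(case, "case_record"))
  lattice <- case$lattice; map <- case$perfusion; dens <- case$density
  reg <- case$regimen
  if (is.null(lattice) || is.null(map) || is.null(dens) || is.null(reg))
    stop("case must carry lattice, perfusion, density and regimen",
         call. = FALSE)
  cfg <- config
  drug_names <- unique(reg$administrations$drug)
  missing_drugs <- setdiff(drug_names, names(drugs))
  if (length(missing_drugs))
    stop("regimen references unknown drug(s): ",
         paste(missing_drugs, collapse = ", "), call. = FALSE)
  sens <- vapply(drug_names, function(d) {
    if (d %in% names(case$sensitivity)) case$sensitivity[[d]] else 1
  }, numeric(1))
  names(sens) <- drug_names

  dt <- cfg$dt_outer_h
  steps_per_day <- as.integer(24 / dt)
  n_days <- ceiling(reg$surgery_day)
  n_steps <- n_days * steps_per_day
  mech_dt <- dt * cfg$mechanics_every

  # fields start at their perfusion-equilibrium values inside tissue
  ve <- map$ve
  O <- ve * cfg$plasma_oxygen; G <- ve * cfg$plasma_glucose
  L <- array(0, lattice$shape)
  Cdrug <- lapply(drug_names, function(d) array(0, lattice$shape))
  names(Cdrug) <- drug_names

  use_mesh <- cfg$mechanics == "mesh"
  tumor_mask <- lattice$labels == TISSUE_LABELS[["tumor"]]
  if (use_mesh) {
    # deformation is resolved on the tumor bounding box (+3 voxels margin)
    # with the outer nodes held fixed by the surrounding tissue
    ti <- which(tumor_mask, arr.ind = TRUE)
    lo <- pmax(apply(ti, 2, min) - 3L, 1L)
    hi <- pmin(apply(ti, 2, max) + 3L, lattice$shape)
    sub <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    sub_lab <- lattice$labels[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
    sub_lat <- suppressWarnings(build_lattice(sub_lab, lattice$voxel_side))
    mesh <- build_mesh(sub_lat)
    nd <- mesh$node_dim
    gidx <- arrayInd(seq_len(prod(nd)), nd)
    fixed_nodes <- gidx[, 1] == 1L | gidx[, 1] == nd[1] |
                   gidx[, 2] == 1L | gidx[, 2] == nd[2] |
                   gidx[, 3] == 1L | gidx[, 3] == nd[3]
    sub_tumor <- sub_lab == TISSUE_LABELS[["tumor"]]
  }
  detect_volume <- function() {
    above <- dens$rho >= dens$rho_detect * dens$rho_max
    v_vox <- lattice$voxel_side^3
    if (use_mesh) {
      above_sub <- above[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
      n_outside <- sum(above) - sum(above_sub)
      (sum(mesh_cell_volumes(mesh)[above_sub]) + n_outside * v_vox) * 1e-3
    } else {
      sum(above) * v_vox * 1e-3
    }
  }

  days <- 0:n_days
  vols <- numeric(n_days + 1)
  vols[1] <- detect_volume()
  mu_acc <- array(0, lattice$shape)
  delta_acc <- array(0, lattice$shape)
  total_clipped <- 0

  for (step in seq_len(n_steps)) {
    t_mid <- (step - 0.5) * dt

    # nutrients: quasi-steady balance of delivery, diffusion, consumption
    rho_frac <- dens$rho / dens$rho_max
    mp <- cfg$metabolic
    if (cfg$oxygen_qss) {
      O <- .qss_solve(O, lattice, map, cfg$D_oxygen, cfg$plasma_oxygen,
                      sink_coeff = function(C)
                        mp$uptake_max_O * rho_frac / (C + mp$K_O),
                      tol = cfg$qss_tol, max_iter = cfg$qss_max_iter)
      G <- .qss_solve(G, lattice, map, cfg$D_glucose, cfg$plasma_glucose,
                      sink_coeff = function(C)
                        mp$uptake_max_G * rho_frac / (C + mp$K_G),
                      tol = cfg$qss_tol, max_iter = cfg$qss_max_iter)
    } else {
      for (nm in c("O", "G")) {
        C0 <- get(nm)
        D <- if (nm == "O") cfg$D_oxygen else cfg$D_glucose
        pl <- if (nm == "O") cfg$plasma_oxygen else cfg$plasma_glucose
        upm <- if (nm == "O") mp$uptake_max_O else mp$uptake_max_G
        K <- if (nm == "O") mp$K_O else mp$K_G
        C0 <- .exchange_relax(C0, lattice, map, pl, dt)
        f <- species_field(nm, C0, D, pl)
        f <- diffusion_step(f, lattice, dt,
                            sinks = upm * (C0 / (C0 + K)) * rho_frac,
                            dirichlet = map$macrovascular,
                            dirichlet_value = pl)
        total_clipped <- total_clipped + attr(f, "clipped_mass")
        assign(nm, f$C)
      }
    }
    rates <- monod_rates(mp, G, O, rho_frac)

    # lactate: hypoxic production, diffusion, perfusion washout
    step_clipped <- 0
    if (cfg$oxygen_qss) {
      L <- .qss_solve(L, lattice, map, cfg$D_lactate, cfg$plasma_lactate,
                      source = rates$lactate_production,
                      tol = cfg$qss_tol, max_iter = cfg$qss_max_iter)
    } else {
      L <- .exchange_relax(L, lattice, map, cfg$plasma_lactate, dt)
      fL <- species_field("lactate", L, cfg$D_lactate, cfg$plasma_lactate)
      fL <- diffusion_step(fL, lattice, dt,
                           sources = rates$lactate_production,
                           dirichlet = map$macrovascular,
                           dirichlet_value = cfg$plasma_lactate)
      step_clipped <- attr(fL, "clipped_mass")
      L <- fL$C
    }

    # drugs: plasma PK -> tissue exchange + diffusion -> kill field
    delta <- array(0, lattice$shape)
    growth_mult <- 1
    for (d in drug_names) {
      drug <- drugs[[d]]
      cp <- plasma_drug_concentration(drug, reg, t_mid,
                                      use_reductions = cfg$use_reductions)
      if (cp > cfg$drug_conc_threshold || any(Cdrug[[d]] > cfg$drug_conc_threshold)) {
        Cd <- .exchange_relax(Cdrug[[d]], lattice, map, cp, dt,
                              drug$relative_permeability)
        fd <- species_field(paste0("drug:", d), Cd, cfg$D_drug, cp)
        fd <- diffusion_step(fd, lattice, dt, dirichlet = map$macrovascular,
                             dirichlet_value = cp)
        step_clipped <- step_clipped + attr(fd, "clipped_mass")
        Cdrug[[d]] <- fd$C
        kr <- kill_rate(drug, fd$C) * sens[[d]]
        delta <- if (cfg$combination_rule == "additive") delta + kr
                 else pmax(delta, kr)
        if (drug$growth_multiplier < 1) {
          hillf <- fd$C^drug$hill /
            (fd$C^drug$hill + drug$IC50^drug$hill)
          growth_mult <- growth_mult * (1 - (1 - drug$growth_multiplier) * hillf)
        }
      }
    }
    mass_scale <- sum(L) + sum(vapply(Cdrug, sum, numeric(1))) + 1e-9
    if (step_clipped > cfg$clip_abort_fraction * mass_scale)
      stop(sprintf(paste0("transport instability at step %d (day %.1f): ",
                          "clipped %.3g of field mass %.3g; reduce ",
                          "dt_outer_h or check source fields"),
                   step, t_mid / 24, step_clipped, mass_scale),
           call. = FALSE)
    total_clipped <- total_clipped + step_clipped

    mu <- rates$growth * growth_mult
    dens <- density_update(dens, mu, delta, dt)

    if (use_mesh) {
      mu_acc <- mu_acc + mu * dt
      delta_acc <- delta_acc + delta * dt
      if (step %% cfg$mechanics_every == 0) {
        g_full <- exp(mu_acc - delta_acc)
        g <- g_full[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
        # only tumor-occupied cells change preferred volume
        g[!sub_tumor] <- 1
        mesh_prev <- mesh
        mesh <- relax(mesh, g, tol = cfg$mesh_tol,
                      max_iter = cfg$mesh_max_iter,
                      step_scale = cfg$mesh_step_scale,
                      fixed = fixed_nodes)
        sub_rho <- dens$rho[sub[[1]], sub[[2]], sub[[3]], drop = FALSE]
        sub_dens <- cell_density_field(sub_rho, dens$rho_max,
                                       dens$rho_detect)
        sub_dens <- remap_density(sub_dens, mesh_prev, mesh)
        rho_new <- dens$rho
        rho_new[sub[[1]], sub[[2]], sub[[3]]] <- sub_dens$rho
        dens <- cell_density_field(rho_new, dens$rho_max, dens$rho_detect)
        mu_acc[] <- 0; delta_acc[] <- 0
      }
    }

    if (step %% steps_per_day == 0) {
      vols[step / steps_per_day + 1] <- detect_volume()
    }
  }

  V0 <- vols[1]; Vf <- vols[length(vols)]
  structure(list(days = days, volume_cm3 = vols,
                 V_initial = V0, V_final = Vf,
                 percent_reduction = if (V0 > 0) 100 * (1 - Vf / V0)
                                     else NA_real_,
                 clipped_mass = total_clipped,
                 config = cfg, case_id = case$id),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("sim_trajectory (%s): V0 = %.4g cm^3, Vf = %.4g cm^3 (%.2f%% reduction) over %d days\n",
              x$case_id %||% "?", x$V_initial, x$V_final,
              x$percent_reduction, max(x$days)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify pathologic complete response from a trajectory
#'
#' The predefined rule: predicted pCR iff the residual volume at surgery is
#' strictly below 0.01 cm^3, or the volume reduction is at least 99.9%
#' (inclusive). Reports which rule fired. A tumor already below the
#' absolute cutoff at baseline is classified pCR with a degenerate-input
#' warning.
#'
#' @param trajectory a `sim_trajectory` (or any list with `V_initial`,
#'   `V_final`, `percent_reduction`).
#' @param volume_cutoff_cm3 absolute residual-volume cutoff (default 0.01).
#' @param reduction_cutoff_pct percent-reduction cutoff (default 99.9).
#' @return object of class `response_prediction` with `class`
#'   ("pCR"/"residual"), `V_initial`, `V_final`, `percent_reduction`,
#'   `rule_fired`.
#' @export
classify_pcr <- function(trajectory, volume_cutoff_cm3 = 0.01,
                         reduction_cutoff_pct = 99.9) {
  V0 <- trajectory$V_initial; Vf <- trajectory$V_final
  if (is.null(V0) || is.null(Vf) || V0 < 0 || Vf < 0)
    stop("trajectory volumes must be non-negative", call. = FALSE)
  degenerate <- V0 < volume_cutoff_cm3
  if (degenerate)
    warning("baseline volume already below the absolute cutoff; ",
            "pCR predicted degenerately", call. = FALSE)
  red <- if (V0 > 0) 100 * (1 - Vf / V0) else NA_real_
  if (Vf < volume_cutoff_cm3) {
    cls <- "pCR"; rule <- "absolute_volume"
  } else if (!is.na(red) && red >= reduction_cutoff_pct) {
    cls <- "pCR"; rule <- "percent_reduction"
  } else {
    cls <- "residual"; rule <- "none"
  }
  structure(list(class = cls, V_initial = V0, V_final = Vf,
                 percent_reduction = red, rule_fired = rule,
                 degenerate = degenerate),
            class = "response_prediction")
}

#' Compare a predicted trajectory to follow-up scan volumes
#'
#' Per-scan error as a percent of the pre-treatment volume:
#' `100 |V_pred(day) - V_obs| / V_initial`. Scan days outside the
#' trajectory are matched to the nearest recorded day and flagged.
#'
#' @param trajectory a `sim_trajectory`.
#' @param followup_volumes data.frame with columns `day`, `volume_cm3`.
#' @return data.frame with day, observed, predicted, error_pct, flag;
#'   attribute `mean_error_pct` (NA for an empty table).
#' @export
compare_to_followups <- function(trajectory, followup_volumes) {
  if (trajectory$V_initial <= 0)
    stop("degenerate case: baseline volume is zero", call. = FALSE)
  fv <- as.data.frame(followup_volumes)
  if (nrow(fv) == 0) {
    out <- data.frame(day = numeric(0), observed = numeric(0),
                      predicted = numeric(0), error_pct = numeric(0),
                      flag = character(0))
    attr(out, "mean_error_pct") <- NA_real_
    attr(out, "flag") <- "empty_followup_list"
    return(out)
  }
  stopifnot(all(c("day", "volume_cm3") %in% names(fv)))
  pred <- numeric(nrow(fv)); flag <- character(nrow(fv))
  for (i in seq_len(nrow(fv))) {
    j <- which.min(abs(trajectory$days - fv$day[i]))
    pred[i] <- trajectory$volume_cm3[j]
    flag[i] <- if (abs(trajectory$days[j] - fv$day[i]) > 0.5)
      "nearest_day" else "ok"
  }
  err <- 100 * abs(pred - fv$volume_cm3) / trajectory$V_initial
  out <- data.frame(day = fv$day, observed = fv$volume_cm3,
                    predicted = pred, error_pct = err, flag = flag)
  attr(out, "mean_error_pct") <- mean(err)
  out
}

#' Write a trajectory to CSV (day, volume_cm3)
#' @param trajectory a `sim_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(data.frame(day = trajectory$days,
                              volume_cm3 = trajectory$volume_cm3),
                   path, row.names = FALSE)
  invisible(path)
}
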