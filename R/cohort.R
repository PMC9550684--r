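# repeated 6-neighbor averaging (mirror boundaries); by the central limit
# theorem this approximates a Gaussian filter with sigma ~ sqrt(n/3) voxels
.smooth3 <- function(a, n_iter) {
  for (i in seq_len(n_iter)) {
    a <- (a * 2 + .nbsum(a)) / 8
  }
  a
}

#' Phantom tumor specification
#'
#' @param geometry "ellipsoid", "multifocal" or "rim_enhancing".
#' @param diameter largest tumor diameter in mm.
#' @param semi_axes optional explicit ellipsoid semi-axes (mm); default
#'   `diameter/2 * c(1, 0.8, 0.65)`.
#' @param voxel_side lattice resolution in mm (default 2, the desk-scale
#'   resolution; set 0.5 for imaging-native runs).
#' @param ktrans_mean,ktrans_sd moments of the spatially correlated Ktrans
#'   field (1/min) on tumor voxels.
#' @param correlation_length spatial correlation length of the perfusion
#'   heterogeneity (mm).
#' @param necrotic_fraction fraction of tumor voxels in the avascular core
#'   (rho = 0), in [0, 1).
#' @param margin_voxels padding between tumor and lattice boundary.
#' @param seed RNG seed; generation is a pure function of (spec, seed).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("ellipsoid", "multifocal",
                                      "rim_enhancing"),
                         diameter = 14, semi_axes = NULL, voxel_side = 2,
                         ktrans_mean = 0.25, ktrans_sd = 0.08,
                         correlation_length = 4, necrotic_fraction = 0,
                         margin_voxels = 3, seed = 1) {
  geometry <- match.arg(geometry)
  if (diameter <= 0) stop("diameter must be positive", call. = FALSE)
  if (necrotic_fraction < 0 || necrotic_fraction >= 1)
    stop("necrotic_fraction must lie in [0, 1)", call. = FALSE)
  if (diameter < 2 * voxel_side)
    stop("tumor diameter must span at least 2 voxels", call. = FALSE)
  if (is.null(semi_axes)) semi_axes <- diameter / 2 * c(1, 0.8, 0.65)
  structure(list(geometry = geometry, diameter = diameter,
                 semi_axes = semi_axes, voxel_side = voxel_side,
                 ktrans_mean = ktrans_mean, ktrans_sd = ktrans_sd,
                 correlation_length = correlation_length,
                 necrotic_fraction = necrotic_fraction,
                 margin_voxels = margin_voxels, seed = seed),
            class = "phantom_spec")
}

#' Generate a phantom tumor (lattice, perfusion map, density field)
#'
#' Stands in for a segmented patient DCE-MRI: an ellipsoidal (optionally
#' multifocal or rim-enhancing) tumor embedded in fat, a branching vessel
#' path reaching the tumor margin, a spatially correlated Ktrans field
#' (smoothed white noise rescaled to the requested moments), and full-density
#' tumor voxels outside the necrotic core.
#'
#' @param spec a `phantom_spec`.
#' @param rho_max,rho_detect density-field settings.
#' @return list with `lattice` (`tissue_lattice`), `perfusion`
#'   (`perfusion_map`), `density` (`cell_density_field`).
#' @export
generate_phantom <- function(spec, rho_max = 1e6, rho_detect = 0.10) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$voxel_side
  ax <- spec$semi_axes
  half <- ceiling(max(ax) / h) + spec$margin_voxels
  n <- 2L * half + 1L
  ctr <- half + 1L
  co <- (seq_len(n) - ctr) * h          # cell-center coords (mm)
  X <- array(co, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))

  rnorm2 <- function(cx, cy, cz, axes)
    sqrt(((X - cx) / axes[1])^2 + ((Y - cy) / axes[2])^2 +
         ((Z - cz) / axes[3])^2)

  r1 <- rnorm2(0, 0, 0, ax)
  tumor <- r1 <= 1
  rnorm_field <- r1
  if (spec$geometry == "multifocal") {
    # satellite focus at ~60% scale offset along the largest axis
    off <- 1.3 * ax[1]
    half_needed <- ceiling((off + 0.6 * max(ax)) / h) + spec$margin_voxels
    if (half_needed > half) {
      # regenerate on a larger box
      half <- half_needed; n <- 2L * half + 1L; ctr <- half + 1L
      co <- (seq_len(n) - ctr) * h
      X <- array(co, c(n, n, n)); Y <- aperm(X, c(2, 1, 3))
      Z <- aperm(X, c(3, 2, 1))
      r1 <- rnorm2(0, 0, 0, ax)
    }
    r2 <- rnorm2(off, 0.4 * ax[2], 0, 0.6 * ax)
    tumor <- r1 <= 1 | r2 <= 1
    rnorm_field <- pmin(r1, r2)
  }

  labels <- array(TISSUE_LABELS[["fat"]], c(n, n, n))
  # one-voxel background shell (body boundary)
  labels[c(1, n), , ] <- TISSUE_LABELS[["background"]]
  labels[, c(1, n), ] <- TISSUE_LABELS[["background"]]
  labels[, , c(1, n)] <- TISSUE_LABELS[["background"]]
  labels[tumor] <- TISSUE_LABELS[["tumor"]]

  # branching vessel: a trunk along +x reaching the tumor margin, with a
  # short branch in +y
  margin_i <- max(which(apply(tumor, 1, any)))
  if (margin_i < n - 1L) {
    labels[(margin_i + 1L):(n - 1L), ctr, ctr] <- TISSUE_LABELS[["vessel"]]
    branch_i <- min(margin_i + 2L, n - 1L)
    labels[branch_i, ctr:(n - 1L), ctr] <- TISSUE_LABELS[["vessel"]]
    labels[tumor] <- TISSUE_LABELS[["tumor"]]   # tumor wins at overlaps
  }

  lattice <- build_lattice(labels, h)

  # spatially correlated Ktrans: smoothed white noise, rescaled
  n_iter <- max(1L, round(3 * (spec$correlation_length / h)^2))
  noise <- .smooth3(array(stats::rnorm(n^3), c(n, n, n)), n_iter)
  noise <- (noise - mean(noise)) / max(stats::sd(noise), 1e-12)
  ktrans <- pmax(spec$ktrans_mean + spec$ktrans_sd * noise, 0.01)
  necrotic <- array(FALSE, c(n, n, n))
  if (spec$necrotic_fraction > 0 ||
      spec$geometry == "rim_enhancing") {
    frac <- if (spec$geometry == "rim_enhancing")
      max(spec$necrotic_fraction, 0.3) else spec$necrotic_fraction
    r_t <- rnorm_field[tumor]
    thr <- stats::quantile(r_t, frac, names = FALSE)
    necrotic[tumor] <- rnorm_field[tumor] <= thr
    ktrans[necrotic] <- 0.01    # avascular core: near-zero delivery
  }
  ve <- pmax(pmin(0.3 + 0.05 * noise, 0.6), 0.05)
  vp <- array(0.02, c(n, n, n))
  bg <- labels == TISSUE_LABELS[["background"]]
  ktrans[bg] <- 0; ve[bg] <- 0.3; vp[bg] <- 0
  map <- perfusion_map(ktrans, ve, vp, lattice)

  rho <- array(0, c(n, n, n))
  rho[tumor] <- rho_max
  rho[necrotic] <- 0
  density <- cell_density_field(rho, rho_max, rho_detect, lattice)
  list(lattice = lattice, perfusion = map, density = density,
       necrotic = necrotic)
}

#' Synthetic per-voxel DCE concentration series
#'
#' Applies the forward extended Tofts model voxelwise to a perfusion map
#' (vectorized closed form for the biexponential AIF) and adds Gaussian
#' noise. Supports both the sparse 3-point clinical schedule and dense
#' research schedules.
#'
#' @param map a `perfusion_map`.
#' @param aif an `aif_model`.
#' @param times acquisition times in min, starting at 0 with at least two
#'   post-contrast points.
#' @param noise_sd Gaussian noise SD (concentration units, >= 0).
#' @param seed RNG seed for the noise.
#' @return 4D array (lattice shape x time).
#' @export
generate_dce_series <- function(map, aif, times, noise_sd = 0, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(times) < 3 || times[1] != 0)
    stop("times must start at 0 with at least two post-contrast points",
         call. = FALSE)
  kt <- map$ktrans; ve <- pmax(map$ve, 1e-12); vp <- map$vp
  kep <- kt / ve
  shp <- dim(kt)
  out <- array(0, c(shp, length(times)))
  conv1 <- function(a, m, u) {
    # vectorized over the kep array at scalar time offset u
    near <- abs(kep - m) < 1e-10
    r <- a * (exp(-m * u) - exp(-kep * u)) / (kep - m)
    r[near] <- a * u * exp(-m * u)
    r
  }
  for (ti in seq_along(times)) {
    u <- times[ti] - aif$t0
    if (u < 0) next
    cp <- plasma_concentration(aif, times[ti])
    conv <- conv1(aif$a1, aif$m1, u) + conv1(aif$a2, aif$m2, u)
    out[, , , ti] <- pmax(vp * cp + kt * conv, 0)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    out <- out + array(stats::rnorm(length(out), 0, noise_sd), dim(out))
  }
  out
}

#' Cohort specification
#'
#' Defaults mirror the published validation cohort's marginals: the
#' subtype mixture (41% TNBC, 17.4% HR-/HER2+, 16.7% HR+/HER2+, 25%
#' HR+/HER2-), the four regimen classes, and two follow-up scans per case.
#' Per-subtype drug-sensitivity multipliers are lognormal; their defaults
#' were calibrated once so the simulated pCR rate sits near the targeted
#' design rate (~35%).
#'
#' @param n number of cases (>= 1).
#' @param subtype_mix named proportions over the four subtypes (sums to 1).
#' @param sens_meanlog named per-subtype meanlog of the lognormal
#'   kill-multiplier distribution.
#' @param sens_sdlog lognormal sdlog (shared).
#' @param truth_perturb_sdlog sdlog of the multiplicative perturbation
#'   applied when re-simulating a case to produce its "observed" outcome.
#' @param label_noise probability an observed outcome label is flipped.
#' @param followup_days scan days for follow-up volumes.
#' @param followup_noise_sd relative noise on observed follow-up volumes.
#' @param diameter_range tumor diameter range (mm), sampled uniformly.
#' @param voxel_side lattice resolution (mm).
#' @param dose_reduction_prob probability a case has a documented dose
#'   reduction (fraction 0.75) on its later administrations.
#' @param hazard_pcr,hazard_residual exponential event hazards (1/year)
#'   for survival-time generation by observed outcome.
#' @param seed master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 144,
                        subtype_mix = c("TNBC" = 0.41, "HR-/HER2+" = 0.174,
                                        "HR+/HER2+" = 0.167,
                                        "HR+/HER2-" = 0.249),
                        sens_meanlog = c("TNBC" = 0.0, "HR-/HER2+" = -0.05,
                                         "HR+/HER2+" = -0.60,
                                         "HR+/HER2-" = -0.80),
                        sens_sdlog = 0.55,
                        truth_perturb_sdlog = 0.25,
                        label_noise = 0.04,
                        followup_days = c(42, 84),
                        followup_noise_sd = 0.05,
                        diameter_range = c(8, 14),
                        voxel_side = 2,
                        dose_reduction_prob = 0.2,
                        hazard_pcr = 0.004, hazard_residual = 0.05,
                        seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  subtype_mix <- subtype_mix / sum(subtype_mix)
  if (abs(sum(subtype_mix) - 1) > 1e-9)
    stop("subtype mixture must sum to 1", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

# the four regimen classes; returns a regimen object and its class label
.make_regimen <- function(class_label, reduced) {
  red <- if (reduced) 0.75 else 1
  adm <- switch(class_label,
    "Chemotherapy, Anthracycline containing" = {
      # dose-dense AC x4 then weekly paclitaxel x12
      rbind(
        data.frame(drug = "doxorubicin", dose = 110, day = seq(0, 42, 14)),
        data.frame(drug = "cyclophosphamide", dose = 1100,
                   day = seq(0, 42, 14)),
        data.frame(drug = "paclitaxel", dose = 150, day = 56 + 7 * (0:11)))
    },
    "Chemotherapy, Anthracycline free" = {
      rbind(
        data.frame(drug = "docetaxel", dose = 140, day = seq(0, 63, 21)),
        data.frame(drug = "cyclophosphamide", dose = 1100,
                   day = seq(0, 63, 21)))
    },
    "HER2-directed, Anthracycline containing" = {
      rbind(
        data.frame(drug = "doxorubicin", dose = 110, day = seq(0, 42, 14)),
        data.frame(drug = "cyclophosphamide", dose = 1100,
                   day = seq(0, 42, 14)),
        data.frame(drug = "paclitaxel", dose = 150, day = 56 + 7 * (0:11)),
        data.frame(drug = "trastuzumab", dose = 420, day = 56 + 21 * (0:3)))
    },
    "HER2-directed, Anthracycline free" = {
      rbind(
        data.frame(drug = "docetaxel", dose = 140, day = seq(0, 105, 21)),
        data.frame(drug = "carboplatin", dose = 600, day = seq(0, 105, 21)),
        data.frame(drug = "trastuzumab", dose = 420, day = seq(0, 105, 21)),
        data.frame(drug = "pertuzumab", dose = 420, day = seq(0, 105, 21)))
    },
    stop("unknown regimen class: ", class_label, call. = FALSE))
  adm$reduction <- 1
  if (reduced) {
    late <- adm$day > stats::median(adm$day)
    adm$reduction[late] <- red
  }
  regimen(adm)
}

#' Generate a synthetic validation cohort
#'
#' Each case gets a phantom, a regimen from the four regimen classes
#' (HER2-directed regimens only for HER2+ cases), clinical covariates drawn
#' from cohort-like marginals, and per-drug sensitivity multipliers drawn
#' from the subtype's lognormal distribution. "Observed" outcomes are
#' produced independently of the predictor by re-simulating each case with
#' perturbed sensitivity multipliers, classifying with the volume rule, and
#' flipping labels with a small probability; follow-up volumes (with noise)
#' and exponential survival times (lower hazard for observed pCR) complete
#' the ground truth.
#'
#' @param spec a `cohort_spec`.
#' @param drugs drug library (default shipped).
#' @param config `sim_config` used for the truth simulations (default:
#'   bookkeeping mechanics for speed at cohort scale).
#' @param simulate_truth run the perturbed truth simulations (default
#'   TRUE); FALSE leaves truth columns NA for callers that only need case
#'   material.
#' @param progress print a dot per case.
#' @return list with `cases` (list of `case_record`) and `truth`
#'   (data.frame: id, subtype, regimen_class, observed_pcr,
#'   truth_final_volume, followup day/volume columns, dfi_years,
#'   dfi_event, efs_years, efs_event, os_years, os_event).
#' @export
generate_cohort <- function(spec, drugs = load_drug_library(),
                            config = sim_config(mechanics = "bookkeeping"),
                            simulate_truth = TRUE, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  subtypes <- sample(names(spec$subtype_mix), n, replace = TRUE,
                     prob = spec$subtype_mix)
  races <- sample(c("African American", "Caucasian", "Asian", "Other"),
                  n, replace = TRUE, prob = c(0.50, 0.35, 0.03, 0.12))
  ages <- round(stats::rnorm(n, 52, 13))
  grades <- sample(2:3, n, replace = TRUE, prob = c(0.22, 0.78))
  t_stages <- sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                     prob = c(0.19, 0.60, 0.19, 0.02))
  n_stages <- sample(c("N0", "N1", "N2", "N3"), n, replace = TRUE,
                     prob = c(0.50, 0.41, 0.07, 0.02))
  diams <- stats::runif(n, spec$diameter_range[1], spec$diameter_range[2])
  geoms <- sample(c("ellipsoid", "multifocal", "rim_enhancing"), n,
                  replace = TRUE, prob = c(0.6, 0.2, 0.2))
  reduced <- stats::runif(n) < spec$dose_reduction_prob
  case_seeds <- sample.int(.Machine$integer.max %/% 2, n)
  truth_seeds <- sample.int(.Machine$integer.max %/% 2, n)

  cases <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    st <- subtypes[i]
    her2 <- grepl("HER2\\+", st)
    hr <- grepl("^HR\\+", st)
    set.seed(case_seeds[i])
    er <- if (hr) stats::runif(1, 10, 100) else stats::runif(1, 0, 0.9)
    pr <- if (hr) stats::runif(1, 0, 100) else stats::runif(1, 0, 0.9)
    reg_class <- if (her2) {
      sample(c("HER2-directed, Anthracycline containing",
               "HER2-directed, Anthracycline free"), 1,
             prob = c(0.35, 0.65))
    } else {
      sample(c("Chemotherapy, Anthracycline containing",
               "Chemotherapy, Anthracycline free"), 1,
             prob = c(0.93, 0.07))
    }
    reg <- .make_regimen(reg_class, reduced[i])
    ph <- generate_phantom(phantom_spec(
      geometry = geoms[i], diameter = diams[i],
      voxel_side = spec$voxel_side,
      necrotic_fraction = if (geoms[i] == "rim_enhancing") 0.3 else 0,
      seed = case_seeds[i]))
    set.seed(case_seeds[i] + 1L)
    drug_names <- unique(reg$administrations$drug)
    sens <- stats::rlnorm(length(drug_names),
                          meanlog = spec$sens_meanlog[[st]],
                          sdlog = spec$sens_sdlog)
    names(sens) <- drug_names
    cases[[i]] <- case_record(
      id = sprintf("case%03d", i), age = ages[i], race = races[i],
      t_stage = t_stages[i], n_stage = n_stages[i], er = er, pr = pr,
      her2 = her2, grade = grades[i], subtype = st, sensitivity = sens,
      lattice = ph$lattice, perfusion = ph$perfusion,
      density = ph$density, regimen = reg)
    attr(cases[[i]], "regimen_class") <- reg_class

    row <- data.frame(id = cases[[i]]$id, subtype = st,
                      regimen_class = reg_class,
                      observed_pcr = NA, truth_final_volume = NA_real_)
    for (fd in spec$followup_days)
      row[[paste0("followup_vol_day", fd)]] <- NA_real_
    if (simulate_truth) {
      set.seed(truth_seeds[i])
      sens_t <- sens * stats::rlnorm(length(sens), 0,
                                     spec$truth_perturb_sdlog)
      names(sens_t) <- names(sens)
      case_t <- cases[[i]]
      case_t$sensitivity <- sens_t
      traj_t <- run_case(case_t, drugs, config)
      pred_t <- classify_pcr(traj_t)
      set.seed(truth_seeds[i] + 1L)
      obs <- (pred_t$class == "pCR")
      if (stats::runif(1) < spec$label_noise) obs <- !obs
      row$observed_pcr <- obs
      row$truth_final_volume <- traj_t$V_final
      for (fd in spec$followup_days) {
        j <- which.min(abs(traj_t$days - fd))
        v <- traj_t$volume_cm3[j]
        row[[paste0("followup_vol_day", fd)]] <-
          max(v * (1 + stats::rnorm(1, 0, spec$followup_noise_sd)), 0)
      }
      # survival: exponential event hazards, censoring at 3-8 years,
      # events concentrated in residual-disease cases
      haz <- if (obs) spec$hazard_pcr else spec$hazard_residual
      for (ep in c("dfi", "efs", "os")) {
        ev_t <- stats::rexp(1, haz)
        cens <- stats::runif(1, 3, 8)
        row[[paste0(ep, "_years")]] <- min(ev_t, cens)
        row[[paste0(ep, "_event")]] <- as.integer(ev_t <= cens)
      }
    }
    truth[[i]] <- row
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  truth <- do.call(rbind, truth)
  list(cases = cases, truth = truth)
}
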