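#' Drug pharmacokinetic / pharmacodynamic model
#'
#' One- or two-compartment plasma kinetics plus a Hill-type kill law.
#' Time unit is hours throughout the PK/PD layer.
#'
#' @param name drug name.
#' @param k_el elimination rate (1/h, > 0).
#' @param V_d distribution volume (L, > 0).
#' @param kill_max maximal specific kill rate (1/h, >= 0).
#' @param IC50 half-maximal inhibitory concentration (> 0), in the same
#'   units as tissue concentration (mg/L).
#' @param hill Hill coefficient (> 0).
#' @param n_compartments 1 or 2; if 2, `k12`, `k21` (1/h) are required.
#' @param k12,k21 inter-compartment rates for the 2-compartment model.
#' @param relative_permeability scaling on Ktrans for tissue delivery of
#'   this drug (dimensionless, default 1).
#' @param growth_multiplier multiplicative factor on tumor growth rate while
#'   the drug is above IC50 (for agents modeled as growth suppressors rather
#'   than direct cytotoxics; default 1 = no suppression).
#' @return object of class `drug_model`.
#' @export
drug_model <- function(name, k_el, V_d, kill_max, IC50, hill = 1,
                       n_compartments = 1, k12 = NULL, k21 = NULL,
                       relative_permeability = 1, growth_multiplier = 1) {
  if (k_el < 0 || kill_max < 0 || relative_permeability < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (V_d <= 0) stop("V_d must be positive", call. = FALSE)
  if (IC50 <= 0) stop("IC50 must be positive", call. = FALSE)
  if (hill <= 0) stop("hill must be positive", call. = FALSE)
  if (!n_compartments %in% c(1, 2))
    stop("n_compartments must be 1 or 2", call. = FALSE)
  if (n_compartments == 2 && (is.null(k12) || is.null(k21)))
    stop("2-compartment model requires k12 and k21", call. = FALSE)
  structure(list(name = name, k_el = k_el, V_d = V_d, kill_max = kill_max,
                 IC50 = IC50, hill = hill, n_compartments = n_compartments,
                 k12 = k12, k21 = k21,
                 relative_permeability = relative_permeability,
                 growth_multiplier = growth_multiplier),
            class = "drug_model")
}

#' Dosing regimen
#'
#' An ordered calendar of administrations plus the surgery (response
#' assessment) day. Days are converted to hours (24 h/day) at use.
#'
#' @param administrations data.frame with columns `drug` (name), `dose`
#'   (mg), `day` (non-negative, sorted), and optional `reduction` (fraction
#'   of the planned dose actually given, in (0, 1], default 1).
#' @param surgery_day day of response assessment; must be at or after the
#'   last administration. Defaults to 21 days after the last dose.
#' @return object of class `regimen`.
#' @export
regimen <- function(administrations, surgery_day = NULL) {
  adm <- as.data.frame(administrations)
  stopifnot(all(c("drug", "dose", "day") %in% names(adm)))
  if (is.null(adm$reduction)) adm$reduction <- 1
  adm$reduction[is.na(adm$reduction)] <- 1
  if (any(adm$day < 0)) stop("administration days must be >= 0", call. = FALSE)
  if (is.unsorted(adm$day)) adm <- adm[order(adm$day), , drop = FALSE]
  if (any(adm$reduction <= 0 | adm$reduction > 1))
    stop("dose-reduction fraction must lie in (0, 1]", call. = FALSE)
  if (is.null(surgery_day)) surgery_day <- max(adm$day) + 21
  if (surgery_day < max(adm$day))
    stop("surgery_day must be >= the last administration day", call. = FALSE)
  structure(list(administrations = adm, surgery_day = surgery_day),
            class = "regimen")
}

#' Plasma drug concentration under a regimen
#'
#' Linear superposition of bolus responses: for the 1-compartment model each
#' administration at time `t_i` contributes
#' `(dose_i reduction_i / V_d) exp(-k_el (t - t_i))` for `t >= t_i`; the
#' 2-compartment model contributes the standard biexponential with hybrid
#' rates derived from (k_el, k12, k21). Zero before the first dose.
#'
#' @param drug a `drug_model`.
#' @param reg a `regimen` (administrations of other drugs are ignored).
#' @param t time in hours (vectorized).
#' @param use_reductions apply documented dose reductions (default TRUE);
#'   FALSE mirrors a standard-dose sensitivity analysis.
#' @return concentration (mg/L) at `t`.
#' @export
plasma_drug_concentration <- function(drug, reg, t, use_reductions = TRUE) {
  stopifnot(inherits(drug, "drug_model"), inherits(reg, "regimen"))
  adm <- reg$administrations[reg$administrations$drug == drug$name, ,
                             drop = FALSE]
  if (nrow(adm) == 0L) return(rep(0, length(t)))
  t_dose_h <- adm$day * 24
  red <- if (use_reductions) adm$reduction else rep(1, nrow(adm))
  out <- numeric(length(t))
  if (drug$n_compartments == 1) {
    for (i in seq_len(nrow(adm))) {
      dt <- t - t_dose_h[i]
      on <- dt >= 0
      out[on] <- out[on] +
        (adm$dose[i] * red[i] / drug$V_d) * exp(-drug$k_el * dt[on])
    }
  } else {
    # hybrid rates alpha, beta of the standard 2-compartment bolus model
    s <- drug$k_el + drug$k12 + drug$k21
    disc <- sqrt(s^2 - 4 * drug$k_el * drug$k21)
    alpha <- (s + disc) / 2
    beta <- (s - disc) / 2
    A <- (alpha - drug$k21) / (alpha - beta)
    B <- (drug$k21 - beta) / (alpha - beta)
    for (i in seq_len(nrow(adm))) {
      dt <- t - t_dose_h[i]
      on <- dt >= 0
      c0 <- adm$dose[i] * red[i] / drug$V_d
      out[on] <- out[on] +
        c0 * (A * exp(-alpha * dt[on]) + B * exp(-beta * dt[on]))
    }
  }
  out
}

#' Hill-type specific kill rate
#'
#' `kill_max C^h / (C^h + IC50^h)`: zero at zero concentration, half-maximal
#' at the IC50, saturating below `kill_max`.
#'
#' @param drug a `drug_model`.
#' @param local_conc local tissue concentration (>= 0; vectorized, arrays
#'   allowed).
#' @return specific kill rate (1/h), same shape as `local_conc`.
#' @export
kill_rate <- function(drug, local_conc) {
  stopifnot(inherits(drug, "drug_model"))
  if (any(local_conc < 0))
    stop("concentration must be >= 0", call. = FALSE)
  ch <- local_conc^drug$hill
  drug$kill_max * ch / (ch + drug$IC50^drug$hill)
}

#' Combined kill rate of several drugs
#'
#' Default combination rule is additive independent action (sum of the
#' per-drug Hill kill rates); `rule = "max"` takes the strongest single
#' agent instead. The empty combination kills at rate 0.
#'
#' @param drugs_and_concs list of `list(drug = <drug_model>, conc = <field>)`.
#' @param rule "additive" (default) or "max".
#' @return combined specific kill rate (1/h).
#' @export
combined_kill <- function(drugs_and_concs, rule = c("additive", "max")) {
  rule <- match.arg(rule)
  if (length(drugs_and_concs) == 0L) return(0)
  rates <- lapply(drugs_and_concs,
                  function(x) kill_rate(x$drug, x$conc))
  out <- rates[[1]]
  if (length(rates) > 1L) {
    for (r in rates[-1]) {
      out <- if (rule == "additive") out + r else pmax(out, r)
    }
  }
  out
}

#' Load the shipped drug parameter library
#'
#' Reads the YAML drug library (literature-plausible defaults; every entry
#' is overridable by passing a custom file). Returns a named list of
#' `drug_model` objects.
#'
#' @param path YAML file; default the library shipped with the package.
#' @return named list of `drug_model`s.
#' @export
load_drug_library <- function(path = system.file("extdata",
                                                 "drug_library.yaml",
                                                 package = "tumorsim")) {
  y <- yaml::read_yaml(path)
  out <- lapply(y$drugs, function(d) {
    drug_model(name = d$name, k_el = d$k_el, V_d = d$V_d,
               kill_max = d$kill_max, IC50 = d$IC50,
               hill = if (is.null(d$hill)) 1 else d$hill,
               n_compartments = if (is.null(d$n_compartments)) 1
                                else d$n_compartments,
               k12 = d$k12, k21 = d$k21,
               relative_permeability =
                 if (is.null(d$relative_permeability)) 1
                 else d$relative_permeability,
               growth_multiplier = if (is.null(d$growth_multiplier)) 1
                                   else d$growth_multiplier)
  })
  names(out) <- vapply(out, function(d) d$name, character(1))
  out
}

#' Resolved dosing calendar
#'
#' Expands a regimen into a flat table (drug, day, hour, dose, reduction,
#' effective dose), suitable for CSV export or regimen validation.
#'
#' @param reg a `regimen`.
#' @param use_reductions apply dose reductions (default TRUE).
#' @return data.frame.
#' @export
dosing_calendar <- function(reg, use_reductions = TRUE) {
  adm <- reg$administrations
  red <- if (use_reductions) adm$reduction else rep(1, nrow(adm))
  data.frame(drug = adm$drug, day = adm$day, hour = adm$day * 24,
             dose = adm$dose, reduction = red,
             effective_dose = adm$dose * red)
}
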