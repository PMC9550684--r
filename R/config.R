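# recognized run-configuration keys and their constraints
.RUNCONFIG_SCHEMA <- list(
  voxel_side = function(v) v > 0,
  dt_outer_h = function(v) v > 0 && 24 %% v == 0,
  mechanics_every = function(v) v >= 1,
  mechanics = function(v) v %in% c("mesh", "bookkeeping"),
  oxygen_qss = function(v) is.logical(v),
  seed_simulation = function(v) v == round(v),
  seed_bootstrap = function(v) v == round(v),
  seed_cv = function(v) v == round(v),
  seed_cohort = function(v) v == round(v),
  n_cases = function(v) v >= 1,
  out_dir = function(v) is.character(v),
  verbosity = function(v) v %in% 0:2,
  use_reductions = function(v) is.logical(v)
)

.RUNCONFIG_DEFAULTS <- list(
  voxel_side = 2, dt_outer_h = 6, mechanics_every = 4,
  mechanics = "bookkeeping", oxygen_qss = TRUE,
  seed_simulation = 1L, seed_bootstrap = 1L, seed_cv = 1L,
  seed_cohort = 1L, n_cases = 12, out_dir = "tumorsim_out",
  verbosity = 1, use_reductions = TRUE
)

#' Validate a run configuration file
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys (suggesting
#' the nearest known key), checks each value's constraint, fills defaults,
#' and optionally echoes the fully resolved configuration to the output
#' directory for provenance.
#'
#' @param path YAML/JSON file path.
#' @param echo write the resolved config to `<out_dir>/resolved_config.yaml`
#'   (default TRUE).
#' @return object of class `run_config` (named list).
#' @export
validate_config <- function(path, echo = TRUE) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.RUNCONFIG_SCHEMA))
  if (length(unknown)) {
    sug <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(.RUNCONFIG_SCHEMA))
      best <- names(.RUNCONFIG_SCHEMA)[which.min(d)]
      if (min(d) <= 3) sprintf(" (did you mean '%s'?)", best) else ""
    }, character(1))
    stop("unknown config key(s): ",
         paste0("'", unknown, "'", sug, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(.RUNCONFIG_DEFAULTS, raw)
  for (k in names(cfg)) {
    ok <- tryCatch(isTRUE(.RUNCONFIG_SCHEMA[[k]](cfg[[k]])),
                   error = function(e) FALSE)
    if (!ok)
      stop(sprintf("config key '%s' violates its constraint (value: %s)",
                   k, paste(format(cfg[[k]]), collapse = ", ")),
           call. = FALSE)
  }
  cfg <- structure(cfg, class = "run_config")
  if (echo) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(unclass(cfg),
                     file.path(cfg$out_dir, "resolved_config.yaml"))
  }
  cfg
}

#' Run the full pipeline: cohort -> simulate -> classify -> evaluate
#'
#' Generates a synthetic cohort, simulates every case with its documented
#' regimen, classifies pCR with the volume rule, and evaluates against the
#' cohort's observed outcomes: the outcome-metrics table with exact CIs,
#' AUROC of the continuous predictors (final volume and percent reduction)
#' with bootstrap CIs, the cross-validated clinical logistic comparator,
#' survival comparisons between prediction groups, and the correlation of
#' predicted with observed follow-up volumes. Writes CSV outputs plus a
#' manifest with MD5 checksums; a failing case is recorded in the manifest
#' and does not stop the others.
#'
#' @param cohort a `cohort_spec`, or an existing `generate_cohort()` result.
#' @param config `sim_config` for the predictor simulations.
#' @param stats a `stats_config`.
#' @param out_dir output directory (created); NULL skips file output.
#' @param drugs drug library.
#' @param progress print a dot per simulated case.
#' @return list with `predictions` (per-case data.frame), `report`
#'   (`table2_report`), `auroc_volume`, `auroc_reduction` (each value +
#'   CI), `comparator` (CV logistic result), `survival` (per endpoint),
#'   `followup_correlation`, `manifest`.
#' @export
pipeline_end_to_end <- function(cohort,
                                config = sim_config(mechanics = "bookkeeping"),
                                stats = stats_config(),
                                out_dir = NULL,
                                drugs = load_drug_library(),
                                progress = FALSE) {
  if (inherits(cohort, "cohort_spec"))
    cohort <- generate_cohort(cohort, drugs = drugs, config = config,
                              progress = progress)
  cases <- cohort$cases; truth <- cohort$truth
  n <- length(cases)
  rows <- vector("list", n)
  failures <- character(0)
  fu_days <- as.numeric(sub("followup_vol_day", "",
                            grep("^followup_vol_day", names(truth),
                                 value = TRUE)))
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      traj <- run_case(cases[[i]], drugs, config)
      pred <- classify_pcr(traj)
      r <- data.frame(id = cases[[i]]$id,
                      subtype = cases[[i]]$subtype,
                      regimen_class = attr(cases[[i]], "regimen_class"),
                      predicted_pcr = pred$class == "pCR",
                      V_initial = pred$V_initial, V_final = pred$V_final,
                      percent_reduction = pred$percent_reduction,
                      rule_fired = pred$rule_fired)
      for (fd in fu_days) {
        j <- which.min(abs(traj$days - fd))
        r[[paste0("pred_vol_day", fd)]] <- traj$volume_cm3[j]
      }
      r
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", cases[[i]]$id,
                                       conditionMessage(e)))
      NULL
    })
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  preds <- do.call(rbind, rows)
  ok <- truth$id %in% preds$id
  tr <- truth[ok, , drop = FALSE]
  preds <- preds[match(tr$id, preds$id), , drop = FALSE]

  report <- table2_report(preds$predicted_pcr, tr$observed_pcr,
                          subgroup = preds$subtype, cfg = stats)
  # continuous predictors of observed pCR: smaller final volume and larger
  # reduction should both score pCR cases higher
  sc_vol <- -preds$V_final
  sc_red <- preds$percent_reduction
  auroc_volume <- list(value = auroc(sc_vol, tr$observed_pcr),
                       ci = auroc_bootstrap_ci(sc_vol, tr$observed_pcr,
                                               stats))
  auroc_reduction <- list(value = auroc(sc_red, tr$observed_pcr),
                          ci = auroc_bootstrap_ci(sc_red, tr$observed_pcr,
                                                  stats))
  feat <- data.frame(
    age = vapply(cases, function(cc) cc$age, numeric(1))[ok],
    race = factor(vapply(cases, function(cc) cc$race, character(1))[ok]),
    subtype = factor(tr$subtype),
    grade = factor(vapply(cases, function(cc) cc$grade, numeric(1))[ok]),
    t_stage = factor(vapply(cases, function(cc) cc$t_stage,
                            character(1))[ok]),
    n_stage = factor(vapply(cases, function(cc) cc$n_stage,
                            character(1))[ok]),
    regimen = factor(tr$regimen_class))
  comparator <- cv_logistic_comparator(feat, tr$observed_pcr, stats)

  surv <- list()
  for (ep in c("dfi", "efs", "os")) {
    tc <- paste0(ep, "_years"); ec <- paste0(ep, "_event")
    if (tc %in% names(tr) && !anyNA(tr[[tc]])) {
      surv[[ep]] <- survival_compare(tr[[tc]], tr[[ec]],
                                     groups = !preds$predicted_pcr,
                                     cfg = stats)
    }
  }

  fu_corr <- NULL
  pv <- unlist(preds[paste0("pred_vol_day", fu_days)])
  ov <- unlist(tr[paste0("followup_vol_day", fu_days)])
  if (length(pv) >= 4 && !anyNA(ov)) fu_corr <- pearson_fisher(pv, ov)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(predictions = file.path(out_dir, "predictions.csv"),
               truth = file.path(out_dir, "truth.csv"),
               metrics = file.path(out_dir, "metrics.csv"))
    utils::write.csv(preds, paths["predictions"], row.names = FALSE)
    utils::write.csv(tr, paths["truth"], row.names = FALSE)
    write_table2_csv(report, paths["metrics"])
    manifest <- data.frame(artifact = names(paths), path = unname(paths),
                           md5 = unname(tools::md5sum(unname(paths))))
    if (length(failures))
      manifest <- rbind(manifest,
                        data.frame(artifact = "failure", path = failures,
                                   md5 = NA_character_))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(predictions = preds, truth = tr, report = report,
       auroc_volume = auroc_volume, auroc_reduction = auroc_reduction,
       comparator = comparator, survival = surv,
       followup_correlation = fu_corr, failures = failures,
       manifest = manifest)
}
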