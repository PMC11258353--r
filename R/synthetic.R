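# Seeded generators reproducing the statistical structure of the study
# conditions: a 454-position insertion library with ~51% permissive and
# ~16% allosteric sites, triplicate colorimetric activities at the assay
# CVs (11% whole-cell, 7.6% purified protein), multinomial read counts,
# and blood cohorts around the adult baseline glucose of 5.6 mM.

#' Simulation configuration
#'
#' Defaults encode the study conditions: 454 insertion positions, 232
#' (51.1%) permissive of which 71 are allosteric, a mean allosteric
#' activity change of 31% (sd 0.10, truncated above 0.1) as seen in the
#' whole-cell context, whole-cell assay CV 11%, purified-protein assay CV
#' 7.6%, blood glucose Normal(5.6, 1.0) mM truncated positive, a 1 uM
#' 4-HT dose, and 140,340 sequencing reads.
#'
#' @param seed Integer RNG seed (required).
#' @param n_positions Number of insertion positions.
#' @param frac_permissive Fraction of permissive sites.
#' @param frac_allosteric_given_permissive Fraction of permissive sites
#'   that are allosteric.
#' @param allosteric_effect_mean,allosteric_effect_sd,allosteric_effect_min
#'   Truncated-normal distribution of the fractional activity change at
#'   allosteric sites.
#' @param cv_whole_cell,cv_protein Assay coefficients of variation.
#' @param blood_glucose_mean,blood_glucose_sd Blood-glucose distribution,
#'   mM (truncated > 0).
#' @param ligand_conc_M Ligand dose carried by positive samples, molar.
#' @param n_reads_total Total sequencing reads over all positions.
#' @param r1_control_rate Round-1 negative-control decay rate, a.u./s.
#' @param r1_permissive_fold Fold decay-rate effect of a permissive
#'   insertion over control.
#' @param loop_bias_odds Odds favouring loop/interface residues when
#'   placing allosteric truth sites.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_positions = 454L,
                       frac_permissive = 0.511,
                       frac_allosteric_given_permissive = 71 / 232,
                       allosteric_effect_mean = 0.31,
                       allosteric_effect_sd = 0.10,
                       allosteric_effect_min = 0.1,
                       cv_whole_cell = 0.11,
                       cv_protein = 0.076,
                       blood_glucose_mean = 5.6,
                       blood_glucose_sd = 1.0,
                       ligand_conc_M = 1e-6,
                       n_reads_total = 140340L,
                       r1_control_rate = 0.002,
                       r1_permissive_fold = 5,
                       loop_bias_odds = 3) {
  check_that(!missing(seed), "`seed` is required")
  check_that(frac_permissive >= 0 && frac_permissive <= 1 &&
               frac_allosteric_given_permissive >= 0 &&
               frac_allosteric_given_permissive <= 1,
             "fractions must lie in [0, 1]")
  check_that(cv_whole_cell >= 0 && cv_protein >= 0, "CVs must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Synthetic secondary-structure annotation of a beta-propeller scaffold
#'
#' Deterministic annotation mimicking a six-bladed beta-propeller: each
#' blade is a four-stranded antiparallel sheet with connecting loops and a
#' short helical insert, and a subset of loop residues is flagged as the
#' dimer interface. This is a synthetic stand-in for a structure-derived
#' annotation; real annotations can be supplied anywhere one is accepted.
#'
#' @param n_positions Number of residues (default 454).
#' @return Data frame with `residue`, `ss_class`, `interface`.
#' @export
generate_ss_annotation <- function(n_positions = 454L) {
  blade <- c(rep("loop", 10),
             rep(c(rep("sheet", 9), rep("loop", 4)), 4),
             rep("helix", 6), rep("loop", 7)) # 75 residues per blade
  ss <- rep(blade, length.out = n_positions)
  interface <- rep(FALSE, n_positions)
  idx <- c(1:45, 100:115) # N-terminal face + blade-2 entry loop
  interface[idx[idx <= n_positions]] <- TRUE
  data.frame(residue = seq_len(n_positions), ss_class = ss,
             interface = interface)
}

# Truncated-normal draw by rejection (vectorised).
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic screening table with truth labels
#'
#' Label assignment is deterministic in count: exactly
#' `round(frac_permissive * n)` permissive positions, of which exactly
#' `round(frac_allosteric_given_permissive * n_permissive)` are allosteric
#' (232 and 71 at defaults). Allosteric truth sites are biased toward
#' loop and dimer-interface residues (odds `loop_bias_odds` : 1).
#' Round-1 decay rates and round-2 triplicate activities carry
#' multiplicative Gaussian noise at the whole-cell CV; read counts are
#' multinomial over positions.
#'
#' @param cfg `sim_config`.
#' @param ss Annotation data frame (defaults to
#'   [generate_ss_annotation()]).
#' @return Data frame with columns `position`, `reads`, `r1_rate`,
#'   `r1_control_rate`, `dmso_1..3`, `ht_1..3`, `truth_label`.
#' @export
generate_screen_table <- function(cfg, ss = generate_ss_annotation(cfg$n_positions)) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_positions
  n_perm <- round(cfg$frac_permissive * n)
  n_allo <- round(cfg$frac_allosteric_given_permissive * n_perm)
  check_that(n_allo <= n_perm && n_perm <= n,
             "infeasible permissive/allosteric fractions")
  with_seed_local(cfg$seed, {
    perm_pos <- sort(sample.int(n, n_perm))
    w <- ifelse(ss$ss_class[perm_pos] == "loop" | ss$interface[perm_pos],
                cfg$loop_bias_odds, 1)
    allo_pos <- sort(sample(perm_pos, n_allo, prob = w))
    label <- rep("inactive", n)
    label[perm_pos] <- "permissive"
    label[allo_pos] <- "allosteric"

    noise <- function(m) m * (1 + stats::rnorm(length(m), 0, cfg$cv_whole_cell))
    r1_true <- ifelse(label == "inactive", cfg$r1_control_rate,
                      cfg$r1_permissive_fold * cfg$r1_control_rate)
    base <- ifelse(label == "inactive", 0.05, 1)
    effect <- numeric(n)
    effect[label == "allosteric"] <- rnorm_trunc(
      n_allo, cfg$allosteric_effect_mean, cfg$allosteric_effect_sd,
      cfg$allosteric_effect_min)
    reads <- as.integer(stats::rmultinom(1, cfg$n_reads_total, rep(1, n)))
    tab <- data.frame(
      position = seq_len(n),
      reads = reads,
      r1_rate = pmax(0, noise(r1_true)),
      r1_control_rate = cfg$r1_control_rate,
      dmso_1 = pmax(0, noise(base)), dmso_2 = pmax(0, noise(base)),
      dmso_3 = pmax(0, noise(base)),
      ht_1 = pmax(0, noise(base * (1 - effect))),
      ht_2 = pmax(0, noise(base * (1 - effect))),
      ht_3 = pmax(0, noise(base * (1 - effect))),
      truth_label = label
    )
    tab
  })
}

#' Generate replicate assay activities for one enzyme and condition
#'
#' Multiplicative Gaussian noise around the model rate, the noise model
#' under which assay reproducibility is quantified as a CV.
#'
#' @param enzyme `enzyme_params`.
#' @param glucose_mM Glucose concentration, mM.
#' @param dose `ligand_dose`.
#' @param n Number of replicates (>= 1).
#' @param cv Coefficient of variation.
#' @param seed RNG seed.
#' @return Numeric vector of activities, a.u./s.
#' @export
generate_assay_replicates <- function(enzyme, glucose_mM,
                                      dose = ligand_dose(), n = 3L,
                                      cv = 0.076, seed) {
  check_that(n >= 1, "`n` must be >= 1")
  rate <- catalytic_rate(enzyme, glucose_mM, dose)
  if (cv == 0) return(rep(rate, n))
  with_seed_local(seed, rate * (1 + stats::rnorm(n, 0, cv)))
}

#' Generate a synthetic blood cohort with truth labels
#'
#' Glucose is drawn from the configured truncated-normal distribution;
#' positive samples carry the configured 4-HT dose, negatives the vehicle
#' only.
#'
#' @param cfg `sim_config`.
#' @param n_samples Cohort size (>= 1).
#' @param positive_fraction Fraction of 4-HT-positive samples.
#' @param volume_uL,electrolyte_mL Sample and electrolyte volumes for the
#'   dual-electrode cell.
#' @return List with `samples` (list of [blood_sample()]) and `truth`
#'   (logical: 4-HT present).
#' @export
generate_blood_cohort <- function(cfg, n_samples = 200L,
                                  positive_fraction = 0.5,
                                  volume_uL = 200, electrolyte_mL = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  check_that(n_samples >= 1, "`n_samples` must be >= 1")
  with_seed_local(cfg$seed + 1L, {
    glucose <- rnorm_trunc(n_samples, cfg$blood_glucose_mean,
                           cfg$blood_glucose_sd, 0)
    n_pos <- round(positive_fraction * n_samples)
    truth <- sample(rep(c(TRUE, FALSE), c(n_pos, n_samples - n_pos)))
    samples <- lapply(seq_len(n_samples), function(i) {
      dose <- if (truth[i])
        ligand_dose("4-HT", cfg$ligand_conc_M, vehicle_dmso = 0.01)
      else
        ligand_dose("none", 0, vehicle_dmso = 0.01)
      blood_sample(glucose_mM = glucose[i], dose = dose,
                   volume_uL = volume_uL, electrolyte_mL = electrolyte_mL)
    })
    list(samples = samples, truth = truth)
  })
}

#' Decode a synthetic blood cohort end to end
#'
#' Simulates a dual-electrode measurement for every cohort sample and runs
#' the ratiometric decoder, returning the per-sample calls alongside the
#' truth labels.
#'
#' @param cohort Output of [generate_blood_cohort()].
#' @param refs `ratio_reference`.
#' @param noise_cv Replicate CV of each electrode current.
#' @param n Replicates per electrode.
#' @param seed Base RNG seed (sample i uses `seed + i`).
#' @return Data frame with `truth`, `call`, `ratio`, `ratio_sd`.
#' @export
decode_blood_cohort <- function(cohort, refs = ratio_reference(),
                                noise_cv = 0.02, n = 3L, seed = 1L) {
  rows <- lapply(seq_along(cohort$samples), function(i) {
    m <- simulate_dual_measurement(cohort$samples[[i]], noise_cv = noise_cv,
                                   n = n, seed = seed + i)
    d <- decode_measurement(m, refs)
    data.frame(truth = cohort$truth[i], call = d$call, ratio = d$ratio,
               ratio_sd = d$ratio_sd)
  })
  do.call(rbind, rows)
}

#' Diagnostic performance of decoded cohort calls
#'
#' Sensitivity and specificity are computed over determinate calls only:
#' `OUT_OF_RANGE` (the operational-range gate refused the sample) and
#' `INDETERMINATE` are refusals, reported as a separate rate rather than
#' counted as errors -- the decoder's contract is to refuse rather than
#' guess outside its validated regime.
#'
#' @param decoded Data frame from [decode_blood_cohort()] (`truth`,
#'   `call`).
#' @return List with `sensitivity`, `specificity`, `refusal_rate`, and
#'   the determinate-call counts `tp`, `fn`, `tn`, `fp`.
#' @export
cohort_performance <- function(decoded) {
  det <- decoded$call %in% c("POSITIVE_4HT", "NEGATIVE")
  tp <- sum(det & decoded$truth & decoded$call == "POSITIVE_4HT")
  fn <- sum(det & decoded$truth & decoded$call == "NEGATIVE")
  tn <- sum(det & !decoded$truth & decoded$call == "NEGATIVE")
  fp <- sum(det & !decoded$truth & decoded$call == "POSITIVE_4HT")
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       refusal_rate = mean(!det), tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Write the full fixture set for offline pipelines
#'
#' Emits every tabular input the pipeline consumes -- screen table,
#' secondary-structure annotation, dual-electrode measurements, a DCPIP
#' assay trace, an amperometric staircase trace with its event sidecar --
#' plus the configuration as YAML and a JSON manifest with per-file MD5
#' checksums. Deterministic for a fixed configuration.
#'
#' @param out_dir Output directory (created if absent).
#' @param cfg `sim_config`.
#' @return The manifest, invisibly; also written to `manifest.json`.
#' @export
write_fixtures <- function(out_dir, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(fname) { p <- file.path(out_dir, fname); paths[[fname]] <<- p; p }

  tab <- generate_screen_table(cfg)
  utils::write.csv(tab, put("screen_table.csv"), row.names = FALSE)
  utils::write.csv(generate_ss_annotation(cfg$n_positions),
                   put("ss_annotation.csv"), row.names = FALSE)

  cohort <- generate_blood_cohort(cfg, n_samples = 6L)
  dm <- lapply(seq_along(cohort$samples), function(i)
    simulate_dual_measurement(cohort$samples[[i]], seed = cfg$seed + i))
  dual <- do.call(rbind, lapply(seq_along(dm), function(i) {
    m <- dm[[i]]
    data.frame(sample_id = i,
               electrode_id = c("WE1_gdh5e", "WE2_wt"),
               mean_uA = c(m$i_5e$mean_uA, m$i_wt$mean_uA),
               sd_uA = c(m$i_5e$sd_uA, m$i_wt$sd_uA),
               n = c(m$i_5e$n, m$i_wt$n),
               glucose_mM_est = m$glucose_mM_est)
  }))
  utils::write.csv(dual, put("dual_measurements.csv"), row.names = FALSE)

  tr <- simulate_dcpip_trace(gdh_5e_plus(vmax_blank = 0.002), 80,
                             ligand_dose("4-HT", 1e-9, 0.01),
                             cv = cfg$cv_protein, seed = cfg$seed)
  utils::write.csv(data.frame(time_s = tr$times_s,
                              absorbance = tr$absorbance_600,
                              replicate_id = tr$replicate_id,
                              condition_id = "glucose80_4HT1nM"),
                   put("assay_trace.csv"), row.names = FALSE)

  sched <- list(injection_event(180, 1, ligand_dose("4-HT", 12.5e-6, 0.01)),
                injection_event(360, 1))
  amp <- simulate_it_trace(electrode_spec(), gdh_5e_plus(immobilized_alpha_max()),
                           sched, duration_s = 540, seed = cfg$seed)
  utils::write.csv(data.frame(time_s = amp$times_s,
                              current_uA = amp$current_uA),
                   put("amperogram.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    time_s = vapply(sched, `[[`, numeric(1), "time_s"),
    delta_glucose_mM = vapply(sched, `[[`, numeric(1), "delta_glucose_mM"),
    species = c("4-HT", ""),
    concentration_M = c(12.5e-6, NA)),
    put("amperogram_events.csv"), row.names = FALSE)

  yaml::write_yaml(unclass(cfg), put("config.yaml"))

  manifest <- list(
    seed = cfg$seed,
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
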