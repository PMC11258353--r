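# Ratiometric decoder: the dual-electrode current ratio with first-order
# error propagation, the operational-range gate, and the binary ligand
# call. The engineered-enzyme electrode (WE-1, GDH-5E+) responds to both
# glucose and 4-HT; the wild-type electrode (WE-2) responds to glucose
# only, so their ratio cancels the glucose dependence above the
# saturation threshold.

#' Summary statistics for one working electrode
#'
#' @param mean_uA Mean steady current, uA.
#' @param sd_uA Standard deviation, uA (>= 0).
#' @param n Number of replicates (>= 1).
#' @return Named list.
#' @export
electrode_summary <- function(mean_uA, sd_uA, n = 3L) {
  check_that(sd_uA >= 0, "`sd_uA` must be >= 0")
  check_that(n >= 1, "`n` must be >= 1")
  list(mean_uA = mean_uA, sd_uA = sd_uA, n = as.integer(n))
}

#' Dual-electrode measurement
#'
#' @param i_5e [electrode_summary()] of the GDH-5E+ working electrode.
#' @param i_wt [electrode_summary()] of the wild-type GDH electrode.
#' @param glucose_mM_est Optional external glucose estimate for the
#'   operational-range gate.
#' @return Object of class `dual_measurement`.
#' @export
dual_measurement <- function(i_5e, i_wt, glucose_mM_est = NULL) {
  structure(list(i_5e = i_5e, i_wt = i_wt,
                 glucose_mM_est = glucose_mM_est),
            class = "dual_measurement")
}

#' Reference current ratios for the binary call
#'
#' Calibration of the decoder: within the operational glucose range the
#' blank (no 4-HT) ratio sits at 6.37 +/- 0.1 (n = 8) and the
#' 4-HT-containing ratio at 4.85 +/- 0.1 (n = 9). The implied effective
#' attenuation of the immobilised enzyme, 1 - 4.85/6.37 ~ 24%, exceeds the
#' 18% seen in solution; the two contexts are therefore calibrated
#' independently (see [immobilized_alpha_max()]).
#'
#' @param r_blank,r_positive Lists with `mean`, `sd`, `n`.
#' @param indeterminate_z z-score beyond which, to both references, the
#'   decoder refuses a call (default 3).
#' @return Object of class `ratio_reference`.
#' @export
ratio_reference <- function(r_blank = list(mean = 6.37, sd = 0.1, n = 8),
                            r_positive = list(mean = 4.85, sd = 0.1, n = 9),
                            indeterminate_z = 3) {
  check_that(r_blank$mean > r_positive$mean,
             "blank reference ratio must exceed the positive reference")
  check_that(r_blank$sd > 0 && r_positive$sd > 0, "reference sds must be > 0")
  structure(list(r_blank = r_blank, r_positive = r_positive,
                 indeterminate_z = indeterminate_z),
            class = "ratio_reference")
}

#' Effective maximal inhibition of the immobilised enzyme
#'
#' Back-calculated from the reference ratios: `1 - r_positive / r_blank`.
#'
#' @param refs `ratio_reference`.
#' @return Fraction in (0, 1).
#' @export
immobilized_alpha_max <- function(refs = ratio_reference()) {
  1 - refs$r_positive$mean / refs$r_blank$mean
}

#' Current ratio with first-order error propagation
#'
#' `r = i_5e / i_wt`; assuming independent errors,
#' `sd_r = r * sqrt((sd_5e/i_5e)^2 + (sd_wt/i_wt)^2)`.
#'
#' @param m `dual_measurement` (both means must be > 0).
#' @return List with `r` and `sd_r`.
#' @export
current_ratio <- function(m) {
  stopifnot(inherits(m, "dual_measurement"))
  if (m$i_5e$mean_uA <= 0 || m$i_wt$mean_uA <= 0)
    abort_gbas("current ratio undefined for non-positive mean currents",
               class = "gbas_undefined_ratio")
  r <- m$i_5e$mean_uA / m$i_wt$mean_uA
  sd_r <- r * sqrt((m$i_5e$sd_uA / m$i_5e$mean_uA)^2 +
                     (m$i_wt$sd_uA / m$i_wt$mean_uA)^2)
  list(r = r, sd_r = sd_r)
}

#' Default electrode loadings for the dual-electrode device
#'
#' Effective current-per-rate gains (k1 for the GDH-5E+ electrode, k2 for
#' the wild-type electrode), calibrated so that the blank saturated ratio
#' equals the blank reference 6.37 when the engineered enzyme turns over
#' twice as fast as wild type.
#'
#' @param refs `ratio_reference`.
#' @param e5,ew `enzyme_params` of the two electrodes.
#' @return Named numeric vector `c(k1, k2)`.
#' @export
default_loadings <- function(refs = ratio_reference(), e5 = gdh_5e_plus(),
                             ew = gdh_wildtype()) {
  k1 <- refs$r_blank$mean * ew$vmax_blank / e5$vmax_blank
  c(k1 = k1, k2 = 1)
}

#' Ratio of electrode currents across a glucose grid
#'
#' `r(S) = k1 * v_5e(S, dose) / (k2 * v_wt(S, dose))`. With distinct
#' Michaelis constants the curve varies at low glucose and plateaus once
#' both enzymes saturate; a cognate ligand lowers the whole curve through
#' the engineered enzyme only. The immobilised-context `alpha_max` is used
#' for the engineered electrode by default.
#'
#' @param e5 `enzyme_params` for the GDH-5E+ electrode.
#' @param ew `enzyme_params` for the wild-type electrode.
#' @param loadings Numeric `c(k1, k2)` current-per-rate gains.
#' @param glucose_grid Positive, sorted glucose concentrations, mM.
#' @param dose `ligand_dose` applied to the cell (both electrodes see it;
#'   only the engineered enzyme responds).
#' @return Numeric vector `r(S)` along the grid.
#' @export
ratio_curve <- function(e5 = gdh_5e_plus(immobilized_alpha_max()),
                        ew = gdh_wildtype(),
                        loadings = default_loadings(e5 = e5, ew = ew),
                        glucose_grid, dose = ligand_dose()) {
  check_that(all(glucose_grid > 0), "glucose grid must be positive")
  check_that(!is.unsorted(glucose_grid), "glucose grid must be sorted")
  v5 <- catalytic_rate(e5, glucose_grid, dose)
  vw <- catalytic_rate(ew, glucose_grid, dose)
  (loadings[["k1"]] * v5) / (loadings[["k2"]] * vw)
}

#' Operational-range gate on glucose concentration
#'
#' The ratio is glucose-invariant only once both electrodes saturate;
#' the device is rated for glucose strictly above 0.4 mM. Blood normally
#' sits at 4-6 mM, so an absent estimate passes the gate with a warning.
#'
#' @param glucose_mM_est Glucose estimate, mM, or `NULL` if unavailable.
#' @param threshold_mM Gate threshold (default 0.4; strict inequality).
#' @return Logical flag.
#' @export
in_operational_range <- function(glucose_mM_est, threshold_mM = 0.4) {
  if (is.null(glucose_mM_est) || is.na(glucose_mM_est)) {
    warning("no glucose estimate supplied; assuming blood-range glucose (4-6 mM)",
            call. = FALSE)
    return(TRUE)
  }
  check_that(glucose_mM_est >= 0, "glucose estimate must be >= 0")
  glucose_mM_est > threshold_mM
}

#' Binary 4-HT call from a measured ratio
#'
#' Gate first: if the glucose estimate fails the operational range the
#' call is `OUT_OF_RANGE`. Otherwise the call is the nearest reference,
#' with the boundary at the midpoint of the two reference means
#' ((6.37 + 4.85)/2 = 5.61 by default): above it `NEGATIVE`, below it
#' `POSITIVE_4HT`, exactly on it (or with z-scores beyond
#' `indeterminate_z` to both references) `INDETERMINATE`. z-scores are
#' computed against each reference with the measurement and reference
#' sds combined in quadrature.
#'
#' @param r Measured ratio.
#' @param sd_r Its standard deviation (>= 0).
#' @param refs `ratio_reference`.
#' @param range_ok Logical from [in_operational_range()].
#' @return A `decision`: list with `call`, `ratio`, `ratio_sd`, `z_blank`,
#'   `z_positive`.
#' @export
classify_ratio <- function(r, sd_r = 0, refs = ratio_reference(),
                           range_ok = TRUE) {
  check_that(is.numeric(r) && length(r) == 1 && r > 0, "`r` must be positive")
  check_that(sd_r >= 0, "`sd_r` must be >= 0")
  z_b <- (r - refs$r_blank$mean) / sqrt(sd_r^2 + refs$r_blank$sd^2)
  z_p <- (r - refs$r_positive$mean) / sqrt(sd_r^2 + refs$r_positive$sd^2)
  call <- if (!isTRUE(range_ok)) {
    "OUT_OF_RANGE"
  } else if (abs(z_b) > refs$indeterminate_z && abs(z_p) > refs$indeterminate_z) {
    "INDETERMINATE"
  } else {
    mid <- (refs$r_blank$mean + refs$r_positive$mean) / 2
    if (r > mid) "NEGATIVE" else if (r < mid) "POSITIVE_4HT" else "INDETERMINATE"
  }
  structure(list(call = call, ratio = r, ratio_sd = sd_r,
                 z_blank = z_b, z_positive = z_p),
            class = "decision")
}

#' @export
print.decision <- function(x, ...) {
  cat(sprintf("<decision> %s  (ratio %.3f +/- %.3f; z_blank %.2f, z_pos %.2f)\n",
              x$call, x$ratio, x$ratio_sd, x$z_blank, x$z_positive))
  invisible(x)
}

#' Decode a dual-electrode measurement end to end
#'
#' Convenience wrapper: ratio with propagation, range gate, classification.
#'
#' @param m `dual_measurement`.
#' @param refs `ratio_reference`.
#' @param threshold_mM Operational-range threshold, mM.
#' @return A `decision`.
#' @export
decode_measurement <- function(m, refs = ratio_reference(),
                               threshold_mM = 0.4) {
  cr <- current_ratio(m)
  ok <- if (is.null(m$glucose_mM_est)) TRUE else
    in_operational_range(m$glucose_mM_est, threshold_mM)
  classify_ratio(cr$r, cr$sd_r, refs, range_ok = ok)
}

#' Two-sample t test on replicates or summary statistics
#'
#' Two-tailed unpaired t test, pooled-variance by default with a Welch
#' variant, accepting either raw replicate vectors or (mean, sd, n)
#' summaries -- sensor characterisation is typically reported as
#' mean +/- sd with n.
#'
#' @param a,b Numeric replicate vectors (each n >= 2), or lists with
#'   `mean`, `sd`, `n`.
#' @param var_equal Pooled variance if `TRUE` (default), Welch otherwise.
#' @return List with `t`, `p`, `df`.
#' @examples
#' compare_groups(list(mean = 112, sd = 2, n = 3),
#'                list(mean = 92, sd = 2, n = 3))
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  as_summ <- function(x) {
    if (is.list(x)) {
      check_that(all(c("mean", "sd", "n") %in% names(x)),
                 "summary input needs `mean`, `sd`, `n`")
      x
    } else {
      if (length(x) < 2)
        abort_gbas("each group needs at least 2 replicates",
                   class = "gbas_insufficient_replicates")
      list(mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  sa <- as_summ(a); sb <- as_summ(b)
  if (sa$n < 2 || sb$n < 2)
    abort_gbas("each group needs at least 2 replicates",
               class = "gbas_insufficient_replicates")
  if (var_equal) {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  } else {
    va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  if (se == 0) {
    tt <- if (sa$mean == sb$mean) 0 else sign(sa$mean - sb$mean) * Inf
  } else {
    tt <- (sa$mean - sb$mean) / se
  }
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Simulate a dual-electrode measurement of one blood sample
#'
#' Computes the noiseless steady currents of the two electrodes for the
#' diluted sample and adds independent Gaussian replicate noise, returning
#' per-electrode summaries ready for [decode_measurement()].
#'
#' @param sample `blood_sample`.
#' @param e5,ew `enzyme_params` of the two electrodes (immobilised-context
#'   attenuation on the engineered enzyme by default).
#' @param loadings Numeric `c(k1, k2)` current-per-rate gains, uA per a.u./s.
#' @param noise_cv Replicate coefficient of variation on each current.
#' @param n Replicates per electrode.
#' @param seed RNG seed.
#' @return `dual_measurement` with `glucose_mM_est` set to the diluted
#'   concentration.
#' @export
simulate_dual_measurement <- function(sample,
                                      e5 = gdh_5e_plus(immobilized_alpha_max()),
                                      ew = gdh_wildtype(),
                                      loadings = default_loadings(e5 = e5, ew = ew),
                                      noise_cv = 0.02, n = 3L, seed = NULL) {
  stopifnot(inherits(sample, "blood_sample"))
  S <- diluted_glucose_mM(sample)
  i5 <- loadings[["k1"]] * catalytic_rate(e5, S, sample$dose)
  iw <- loadings[["k2"]] * catalytic_rate(ew, S, sample$dose)
  draw <- function(mu) mu * (1 + stats::rnorm(n, 0, noise_cv))
  reps <- if (is.null(seed)) list(a = draw(i5), b = draw(iw)) else
    with_seed_local(seed, list(a = draw(i5), b = draw(iw)))
  dual_measurement(
    i_5e = electrode_summary(mean(reps$a), stats::sd(reps$a), n),
    i_wt = electrode_summary(mean(reps$b), stats::sd(reps$b), n),
    glucose_mM_est = S
  )
}
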