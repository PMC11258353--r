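# Self-powered sensor physics: Nernstian open-circuit potential (OCP) of
# the glucose/O2 enzymatic fuel cell, its time course under zero-order
# glucose consumption, polarization and power curves, and the
# depletion-mode OECT readout including the drain-current derivative
# statistic that carries the allosteric signal.

#' Enzymatic fuel cell specification
#'
#' `K_total_V` lumps the cathodic O2/H2O couple, the standard potential of
#' the gluconolactone/glucose couple and the fixed-activity terms into a
#' single calibratable constant, anchored by the glucose-free cell
#' (~620 mV) and the blood-fuelled cell (690 +/- 22 mV). The polarization
#' defaults (`R_int_ohm_cm2`, `j_lim_scale`) are calibrated so a
#' 200 uL blood sample with a non-cognate ligand delivers a maximum
#' current density of ~179 uA cm^-2 and a peak power of ~32 uW cm^-2.
#'
#' @param K_total_V Lumped OCP constant, V.
#' @param T_K Temperature, K.
#' @param R_int_ohm_cm2 Internal areal resistance, ohm cm^2.
#' @param j_lim_scale Limiting current density per unit enzymatic rate,
#'   uA cm^-2 per a.u./s.
#' @param C0_glucose_mM Initial anolyte glucose, mM.
#' @param anode_area_cm2 Anode area, cm^2.
#' @return Object of class `fuel_cell_spec`.
#' @export
fuel_cell_spec <- function(K_total_V = 0.62, T_K = 298.15,
                           R_int_ohm_cm2 = 3624, j_lim_scale = 2.039,
                           C0_glucose_mM = 19.8, anode_area_cm2 = 0.25) {
  check_that(T_K > 0, "`T_K` must be > 0")
  check_that(R_int_ohm_cm2 > 0, "`R_int_ohm_cm2` must be > 0")
  check_that(j_lim_scale > 0, "`j_lim_scale` must be > 0")
  check_that(C0_glucose_mM >= 0, "`C0_glucose_mM` must be >= 0")
  structure(list(K_total_V = K_total_V, T_K = T_K,
                 R_int_ohm_cm2 = R_int_ohm_cm2, j_lim_scale = j_lim_scale,
                 C0_glucose_mM = C0_glucose_mM,
                 anode_area_cm2 = anode_area_cm2),
            class = "fuel_cell_spec")
}

# Nernstian slope RT/2F for the two-electron glucose oxidation, volts.
nernst_slope <- function(fc) {
  k <- physical_constants()
  k$R * fc$T_K / (2 * k$F)
}

#' Open-circuit potential from the glucose/gluconolactone couple
#'
#' `OCP = K_total + (RT/2F) ln(C_glucose / C_gluconolactone)`: the glucose
#' contribution to the cell potential rides on the lumped constant.
#'
#' @param fc `fuel_cell_spec`.
#' @param c_glucose,c_gluconolactone Concentrations (> 0, same units;
#'   only their ratio matters).
#' @return OCP, volts.
#' @export
ocp_nernst <- function(fc, c_glucose, c_gluconolactone) {
  stopifnot(inherits(fc, "fuel_cell_spec"))
  if (any(c_glucose <= 0) || any(c_gluconolactone <= 0))
    abort_gbas("concentrations must be strictly positive",
               class = "gbas_domain_error")
  fc$K_total_V + nernst_slope(fc) * log(c_glucose / c_gluconolactone)
}

#' OCP time course under zero-order glucose consumption
#'
#' With the enzyme saturated, glucose is consumed at the constant rate
#' `vmax` and gluconolactone accumulates stoichiometrically:
#' `OCP(t) = K_total + (RT/2F) ln((C0 - vmax t)/(vmax t))`, strictly
#' decreasing on `0 < t < C0/vmax` and singular at both ends (no product
#' at t = 0, no fuel at exhaustion).
#'
#' @param fc `fuel_cell_spec`.
#' @param vmax_mM_per_s Zero-order consumption rate, mM/s (> 0).
#' @param t_s Time(s) since glucose injection, s; each must lie strictly
#'   inside `(0, C0/vmax)`.
#' @return OCP, volts (vectorised over `t_s`).
#' @export
ocp_time_course <- function(fc, vmax_mM_per_s, t_s) {
  stopifnot(inherits(fc, "fuel_cell_spec"))
  check_that(vmax_mM_per_s > 0, "`vmax_mM_per_s` must be > 0")
  t_end <- fc$C0_glucose_mM / vmax_mM_per_s
  if (any(t_s <= 0) || any(t_s >= t_end))
    abort_gbas(sprintf(
      "t must lie strictly inside (0, %.6g) s for this cell", t_end),
      class = "gbas_domain_error")
  fc$K_total_V + nernst_slope(fc) *
    log((fc$C0_glucose_mM - vmax_mM_per_s * t_s) / (vmax_mM_per_s * t_s))
}

#' Polarization and power curve of the fuel cell
#'
#' Cell voltage under load combines ohmic and Nernstian concentration
#' losses: `V(j) = OCP - R_int j + (RT/2F) ln(1 - j/j_lim)`, where the
#' limiting current density `j_lim = j_lim_scale * catalytic_rate(...)`
#' ties fuel-cell capacity to the allosterically modulated enzymatic
#' rate -- a cognate ligand lowers `j_lim`, hence the whole discharge
#' curve. Power density is `P = V j`.
#'
#' @param fc `fuel_cell_spec`.
#' @param enzyme `enzyme_params` of the bioanode (immobilised context).
#' @param glucose_mM Anolyte glucose, mM.
#' @param dose `ligand_dose`.
#' @param ocp_V Open-circuit voltage used as the sweep origin (default
#'   0.690 V, the blood-fuelled cell).
#' @param n_grid Number of sweep points.
#' @return Object of class `polarization_curve`: data frame `curve`
#'   (`j_uA_cm2`, `V_volt`, `P_uW_cm2`) plus `j_max` (V = 0 crossing,
#'   uA cm^-2), `P_max` (uW cm^-2), `j_at_Pmax`, `j_lim`, `ocp_V`.
#' @export
polarization_curve <- function(fc, enzyme, glucose_mM, dose = ligand_dose(),
                               ocp_V = 0.690, n_grid = 400) {
  stopifnot(inherits(fc, "fuel_cell_spec"), inherits(enzyme, "enzyme_params"))
  j_lim <- fc$j_lim_scale * catalytic_rate(enzyme, glucose_mM, dose)
  if (j_lim <= 0)
    abort_gbas("limiting current is zero: no fuel or inactive enzyme",
               class = "gbas_no_fuel")
  b <- nernst_slope(fc)
  Vfun <- function(j) ocp_V - fc$R_int_ohm_cm2 * j * 1e-6 + b * log(1 - j / j_lim)
  j_max <- stats::uniroot(Vfun, c(j_lim * 1e-12, j_lim * (1 - 1e-12)),
                          tol = 1e-12)$root
  opt <- stats::optimize(function(j) Vfun(j) * j, c(0, j_max), maximum = TRUE)
  j <- seq(0, j_max, length.out = n_grid)
  V <- Vfun(j)
  V[1] <- ocp_V
  structure(list(
    curve = data.frame(j_uA_cm2 = j, V_volt = V, P_uW_cm2 = V * j),
    j_max = j_max, P_max = opt$objective, j_at_Pmax = opt$maximum,
    j_lim = j_lim, ocp_V = ocp_V
  ), class = "polarization_curve")
}

#' @export
print.polarization_curve <- function(x, ...) {
  cat(sprintf(
    "<polarization_curve> OCP %.3f V | j_max %.1f uA/cm2 | P_max %.1f uW/cm2 (at %.1f uA/cm2)\n",
    x$ocp_V, x$j_max, x$P_max, x$j_at_Pmax))
  invisible(x)
}

#' OECT specification
#'
#' Linear small-signal model of a depletion-mode PEDOT:PSS transistor held
#' at fixed `V_sd`: a positive gate voltage dedopes the channel and
#' reduces the drain-current magnitude by `g_m * V_g`. The default
#' transconductance (11.3 mS) is calibrated so gating by the glucose-free
#' fuel cell (~0.62 V) steps the drain current by ~7.0 mA.
#'
#' @param v_sd_V Source-drain voltage, V (default -0.6).
#' @param i_sd0_mA Baseline drain-current magnitude at `V_g = 0`, mA.
#' @param g_m_mS Transconductance, mS (>= 0).
#' @param channel_L_um,channel_W_mm Channel geometry (informational).
#' @return Object of class `oect_spec`.
#' @export
oect_spec <- function(v_sd_V = -0.6, i_sd0_mA = 10, g_m_mS = 11.3,
                      channel_L_um = 50, channel_W_mm = 1) {
  check_that(g_m_mS >= 0, "`g_m_mS` must be >= 0")
  check_that(i_sd0_mA >= 0, "`i_sd0_mA` must be >= 0")
  structure(list(v_sd_V = v_sd_V, i_sd0_mA = i_sd0_mA, g_m_mS = g_m_mS,
                 channel_L_um = channel_L_um, channel_W_mm = channel_W_mm),
            class = "oect_spec")
}

#' Drain current under a gate voltage
#'
#' `|i_sd| = max(0, i_sd0 - g_m * v_g)`; the sign follows `v_sd`
#' (negative for the standard `V_sd = -0.6 V` bias).
#'
#' @param oect `oect_spec`.
#' @param v_g Gate voltage, V (vectorised).
#' @return Signed drain current, mA.
#' @export
oect_drain_current <- function(oect, v_g) {
  stopifnot(inherits(oect, "oect_spec"))
  sign(oect$v_sd_V) * pmax(0, oect$i_sd0_mA - oect$g_m_mS * v_g)
}

#' Rate of drain-current decrease during fuel consumption
#'
#' Chains the OCP decay through the OECT gain. The `"reduced"` variant keeps
#' only the fuel-depletion term,
#' `|dI_sd/dt| = g_m (RT/2F) vmax / (C0 - vmax t)`, the form used to
#' reason about the sensor (slower decay under allosteric inhibition at
#' all times). The `"exact"` variant differentiates the full OCP time
#' course, retaining the product-accumulation term `1/t`:
#' `|dI_sd/dt| = g_m (RT/2F) |{-vmax/(C0 - vmax t)} - 1/t|`.
#'
#' @param fc `fuel_cell_spec`.
#' @param oect `oect_spec`.
#' @param vmax_mM_per_s Zero-order consumption rate, mM/s.
#' @param t_s Time(s) since injection, inside the [ocp_time_course()]
#'   domain.
#' @param variant `"reduced"` (default) or `"exact"`.
#' @return |dI_sd/dt| in mA/s (vectorised over `t_s`).
#' @export
disd_dt <- function(fc, oect, vmax_mM_per_s, t_s,
                    variant = c("reduced", "exact")) {
  variant <- match.arg(variant)
  stopifnot(inherits(fc, "fuel_cell_spec"), inherits(oect, "oect_spec"))
  check_that(vmax_mM_per_s >= 0, "`vmax_mM_per_s` must be >= 0")
  if (vmax_mM_per_s == 0) return(rep(0, length(t_s)))
  t_end <- fc$C0_glucose_mM / vmax_mM_per_s
  if (any(t_s <= 0) || any(t_s >= t_end))
    abort_gbas(sprintf(
      "t must lie strictly inside (0, %.6g) s for this cell", t_end),
      class = "gbas_domain_error")
  b <- nernst_slope(fc)
  depletion <- vmax_mM_per_s / (fc$C0_glucose_mM - vmax_mM_per_s * t_s)
  docp <- switch(variant,
                 reduced = depletion,
                 exact = abs(-depletion - 1 / t_s))
  oect$g_m_mS * b * docp
}

#' Simulate the coupled EFC-OECT drain-current trace
#'
#' Piecewise trace of the semi-powered readout: before connection the
#' channel sits at its baseline; connecting the fuel-cell cathode to the
#' gate steps the current by `g_m * OCP`; injecting glucose adds the
#' Nernstian glucose contribution and starts the zero-order depletion
#' clock, after which the drain-current magnitude relaxes at the
#' [disd_dt()] rate; disconnection restores the baseline. The OCP decay
#' is evaluated from `t_min` after injection (the Nernstian expression is
#' singular at the instant of injection, before any product exists).
#'
#' @param fc `fuel_cell_spec`.
#' @param oect `oect_spec`.
#' @param schedule Named list of event times (s): `connect`, optional
#'   `inject`, optional `disconnect`; must be increasing.
#' @param vmax_mM_per_s Zero-order glucose consumption rate after
#'   injection, mM/s.
#' @param enzyme Optional `enzyme_params`; used only to warn when the
#'   configured anolyte glucose does not saturate the enzyme (the
#'   zero-order assumption needs `C0 >> Km`).
#' @param duration_s,dt_s Trace length and sampling interval, s.
#' @param t_min_s Offset after injection at which the Nernstian time
#'   course is first evaluated (default 30 s).
#' @param noise_mA Additive Gaussian noise sd, mA.
#' @param seed RNG seed (required when `noise_mA > 0`).
#' @return An `oect_trace`: list with `times_s`, `i_sd_mA`, `events`.
#' @export
coupled_simulation <- function(fc, oect, schedule = list(connect = 50),
                               vmax_mM_per_s = 0.02, enzyme = NULL,
                               duration_s = 300, dt_s = 0.5, t_min_s = 30,
                               noise_mA = 0, seed = NULL) {
  stopifnot(inherits(fc, "fuel_cell_spec"), inherits(oect, "oect_spec"))
  ev <- schedule[c("connect", "inject", "disconnect")]
  ev <- ev[!vapply(ev, is.null, logical(1))]
  tv <- unlist(ev)
  if (length(tv) > 1 && any(diff(tv) <= 0))
    abort_gbas("schedule events must be in increasing time order",
               class = "gbas_invalid_schedule")
  if (!is.null(enzyme) && fc$C0_glucose_mM < 10 * enzyme$km_mM)
    warning("anolyte glucose is not saturating (C0 < 10 Km); ",
            "the zero-order consumption assumption is dubious", call. = FALSE)
  times <- seq(0, duration_s, by = dt_s)
  v_g <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    connected <- !is.null(ev$connect) && t >= ev$connect &&
      (is.null(ev$disconnect) || t < ev$disconnect)
    if (!connected) { v_g[k] <- 0; next }
    if (is.null(ev$inject) || t < ev$inject) {
      v_g[k] <- fc$K_total_V # glucose-free cell
    } else {
      tau <- t - ev$inject + t_min_s
      t_end <- fc$C0_glucose_mM / vmax_mM_per_s
      tau <- min(tau, t_end * (1 - 1e-9))
      v_g[k] <- ocp_time_course(fc, vmax_mM_per_s, tau)
    }
  }
  i_sd <- oect_drain_current(oect, v_g)
  if (noise_mA > 0) {
    check_that(!is.null(seed), "a `seed` is required when noise_mA > 0")
    i_sd <- with_seed_local(seed,
      i_sd + stats::rnorm(length(i_sd), 0, noise_mA))
  }
  structure(list(times_s = times, i_sd_mA = i_sd, events = ev),
            class = "oect_trace")
}
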