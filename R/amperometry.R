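# Electrode-current forward model: staircase amperometric i-t traces under
# successive injections into a stirred cell, steady-state extraction,
# background correction against a protein-free control, and the
# whole-blood response.

#' Electrode specification
#'
#' @param area_cm2 Geometric area; 0.0707 cm^2 for a 3 mm glassy carbon
#'   disc, 0.25 cm^2 for an AvCarb carbon-paper electrode.
#' @param sensitivity_uA_per_rate Conversion from enzymatic rate (a.u./s)
#'   to steady-state oxidation current (uA). The default (0.0848) is
#'   calibrated so a whole-blood sample (5.6 mM glucose, 60 uL into 8 mL)
#'   on a GDH-5E+ electrode yields ~3.9 uA with a non-cognate ligand.
#' @param baseline_uA Condition-independent current offset.
#' @param tau_s First-order settling time of the stirred cell, s.
#' @param applied_potential_mV_SHE Applied potential vs SHE (544 mV for the
#'   staircase experiments; SCE-referenced measurements convert by
#'   adding 244 mV).
#' @return Object of class `electrode_spec`.
#' @export
electrode_spec <- function(area_cm2 = 0.25,
                           sensitivity_uA_per_rate = 0.0848,
                           baseline_uA = 0.2,
                           tau_s = 10,
                           applied_potential_mV_SHE = 544) {
  check_that(area_cm2 > 0, "`area_cm2` must be > 0")
  check_that(sensitivity_uA_per_rate >= 0, "`sensitivity_uA_per_rate` must be >= 0")
  check_that(tau_s > 0, "`tau_s` must be > 0")
  structure(list(area_cm2 = area_cm2,
                 sensitivity_uA_per_rate = sensitivity_uA_per_rate,
                 baseline_uA = baseline_uA, tau_s = tau_s,
                 applied_potential_mV_SHE = applied_potential_mV_SHE),
            class = "electrode_spec")
}

#' Injection event for a stirred-cell experiment
#'
#' @param time_s Injection time, s (>= 0).
#' @param delta_glucose_mM Increment to the final glucose concentration in
#'   the cell, mM.
#' @param dose `ligand_dose` in force after the event (defaults to keeping
#'   the previous dose).
#' @return Object of class `injection_event`.
#' @export
injection_event <- function(time_s, delta_glucose_mM = 0, dose = NULL) {
  check_that(time_s >= 0, "`time_s` must be >= 0")
  structure(list(time_s = time_s, delta_glucose_mM = delta_glucose_mM,
                 dose = dose), class = "injection_event")
}

#' Whole-blood sample descriptor
#'
#' Blood carries a persistent baseline of glucose (about 5.6 mM in adults),
#' so a blood drop injected into electrolyte produces an oxidation current
#' without any external glucose supplement. The final cell concentration is
#' the dilution `glucose_mM * volume / (volume + electrolyte)`.
#'
#' @param glucose_mM Blood glucose, mM (default 5.6).
#' @param dose `ligand_dose` carried by the sample.
#' @param volume_uL Blood volume, uL (> 0).
#' @param electrolyte_mL Electrolyte volume, mL (> 0).
#' @return Object of class `blood_sample`.
#' @export
blood_sample <- function(glucose_mM = 5.6, dose = ligand_dose(),
                         volume_uL = 60, electrolyte_mL = 8) {
  check_that(glucose_mM >= 0, "`glucose_mM` must be >= 0")
  check_that(volume_uL > 0 && electrolyte_mL > 0, "volumes must be > 0")
  structure(list(glucose_mM = glucose_mM, dose = dose,
                 volume_uL = volume_uL, electrolyte_mL = electrolyte_mL),
            class = "blood_sample")
}

#' Final cell glucose concentration after diluting a blood sample
#' @param sample `blood_sample`.
#' @return Concentration in mM.
#' @export
diluted_glucose_mM <- function(sample) {
  stopifnot(inherits(sample, "blood_sample"))
  vb <- sample$volume_uL / 1000 # mL
  sample$glucose_mM * vb / (vb + sample$electrolyte_mL)
}

#' Simulate an amperometric i-t trace under an injection schedule
#'
#' The current relaxes first-order (time constant `tau_s`) toward the
#' steady state `i_ss = baseline + sensitivity * catalytic_rate(enzyme, S, dose)`
#' after each injection; glucose increments accumulate and the dose updates
#' when an event carries one. Additive Gaussian noise of standard deviation
#' `noise_uA` is applied per sample.
#'
#' @param electrode `electrode_spec`.
#' @param enzyme `enzyme_params`.
#' @param schedule List of `injection_event`, strictly increasing in time.
#' @param duration_s Trace length, s.
#' @param dt_s Sampling interval, s.
#' @param noise_uA Additive noise sd, uA (default 0.05).
#' @param seed RNG seed (required when `noise_uA > 0`).
#' @param dose0 `ligand_dose` in force before the first event.
#' @return An `amperogram`: list with `times_s`, `current_uA`, `events`,
#'   `electrode`, `enzyme`, and the per-segment noiseless steady states
#'   `i_ss_uA`.
#' @export
simulate_it_trace <- function(electrode, enzyme, schedule,
                              duration_s = 600, dt_s = 1, noise_uA = 0.05,
                              seed = NULL, dose0 = ligand_dose()) {
  stopifnot(inherits(electrode, "electrode_spec"),
            inherits(enzyme, "enzyme_params"))
  ev_times <- vapply(schedule, `[[`, numeric(1), "time_s")
  if (length(ev_times) && any(diff(ev_times) <= 0))
    abort_gbas("injection events must be strictly increasing in time",
               class = "gbas_invalid_schedule")
  check_that(all(ev_times <= duration_s), "events must fall within the trace")

  times <- seq(0, duration_s, by = dt_s)
  S <- 0
  dose <- dose0
  i <- electrode$baseline_uA
  current <- numeric(length(times))
  i_ss_per_segment <- numeric(length(schedule) + 1)
  seg <- 1L
  i_ss <- electrode$baseline_uA +
    electrode$sensitivity_uA_per_rate * catalytic_rate(enzyme, S, dose)
  i_ss_per_segment[1] <- i_ss
  next_ev <- 1L
  for (k in seq_along(times)) {
    while (next_ev <= length(schedule) && times[k] >= ev_times[next_ev]) {
      ev <- schedule[[next_ev]]
      S <- S + ev$delta_glucose_mM
      check_that(S >= -1e-12, "glucose concentration became negative")
      S <- max(S, 0)
      if (!is.null(ev$dose)) dose <- ev$dose
      i_ss <- electrode$baseline_uA +
        electrode$sensitivity_uA_per_rate * catalytic_rate(enzyme, S, dose)
      seg <- seg + 1L
      i_ss_per_segment[seg] <- i_ss
      next_ev <- next_ev + 1L
    }
    if (k > 1) i <- i_ss + (i - i_ss) * exp(-dt_s / electrode$tau_s)
    current[k] <- i
  }
  if (noise_uA > 0) {
    check_that(!is.null(seed), "a `seed` is required when noise_uA > 0")
    current <- with_seed_local(seed,
      current + stats::rnorm(length(current), 0, noise_uA))
  }
  structure(list(times_s = times, current_uA = current, events = schedule,
                 electrode = electrode, enzyme = enzyme,
                 i_ss_uA = i_ss_per_segment),
            class = "amperogram")
}

#' Extract per-step steady-state currents from a staircase trace
#'
#' For every inter-event segment, takes the trailing `window_s` seconds of
#' the segment, requiring the segment to be at least `settle_s + window_s`
#' long so the first-order transient has decayed.
#'
#' @param amp `amperogram`.
#' @param settle_s Settling time excluded at the start of each segment
#'   (default `5 * tau_s`).
#' @param window_s Averaging window at the end of each segment.
#' @return `data.frame` with `event_index` (0 = pre-injection baseline),
#'   `mean_uA`, `sd_uA`, `n`.
#' @export
steady_state_currents <- function(amp, settle_s = NULL, window_s = 20) {
  stopifnot(inherits(amp, "amperogram"))
  if (is.null(settle_s)) settle_s <- 5 * amp$electrode$tau_s
  ev_times <- vapply(amp$events, `[[`, numeric(1), "time_s")
  bounds <- c(0, ev_times, max(amp$times_s))
  out <- data.frame(event_index = integer(0), mean_uA = numeric(0),
                    sd_uA = numeric(0), n = integer(0))
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    if (t1 - t0 < settle_s + window_s)
      abort_gbas(sprintf(
        "segment %d (%.0f-%.0f s) shorter than settle_s + window_s", s - 1, t0, t1),
        class = "gbas_insufficient_data")
    keep <- amp$times_s >= (t1 - window_s) & amp$times_s < t1
    x <- amp$current_uA[keep]
    out <- rbind(out, data.frame(event_index = s - 1L, mean_uA = mean(x),
                                 sd_uA = stats::sd(x), n = length(x)))
  }
  out
}

#' Background-correct sample steady states against a control trace
#'
#' Subtracts, step by step, the steady-state currents of a control
#' experiment (e.g. a BSA-coated electrode accounting for non-enzymatic
#' blood signal) from those of the sample. Schedules must match in event
#' count and times.
#'
#' @param sample `amperogram` from the enzyme electrode.
#' @param control `amperogram` from the control electrode.
#' @param settle_s,window_s Passed to [steady_state_currents()].
#' @return `data.frame` with `event_index`, `mean_uA` (difference), `sd_uA`
#'   (quadrature-combined), `n`.
#' @export
background_correct <- function(sample, control, settle_s = NULL,
                               window_s = 20) {
  ts_s <- vapply(sample$events, `[[`, numeric(1), "time_s")
  ts_c <- vapply(control$events, `[[`, numeric(1), "time_s")
  if (length(ts_s) != length(ts_c) || any(ts_s != ts_c))
    abort_gbas("sample and control schedules do not match",
               class = "gbas_incompatible")
  a <- steady_state_currents(sample, settle_s, window_s)
  b <- steady_state_currents(control, settle_s, window_s)
  data.frame(event_index = a$event_index,
             mean_uA = a$mean_uA - b$mean_uA,
             sd_uA = sqrt(a$sd_uA^2 + b$sd_uA^2),
             n = a$n)
}

#' Background-corrected steady current from a whole-blood sample
#'
#' Dilutes the sample into the electrolyte, simulates the enzyme electrode
#' and a protein-free (apo) control electrode under the same single-injection
#' schedule, and returns the background-corrected post-injection steady
#' current.
#'
#' @param electrode `electrode_spec`.
#' @param enzyme `enzyme_params`.
#' @param sample `blood_sample`.
#' @param inject_at_s Injection time, s.
#' @param duration_s Trace length, s.
#' @param noise_uA Additive noise sd, uA.
#' @param seed RNG seed; the control trace uses `seed + 1`.
#' @return Single corrected steady current, uA.
#' @export
blood_response <- function(electrode, enzyme, sample, inject_at_s = 180,
                           duration_s = 600, noise_uA = 0.05, seed = NULL) {
  stopifnot(inherits(sample, "blood_sample"))
  S <- diluted_glucose_mM(sample)
  sched <- list(injection_event(inject_at_s, delta_glucose_mM = S,
                                dose = sample$dose))
  tr <- simulate_it_trace(electrode, enzyme, sched, duration_s = duration_s,
                          noise_uA = noise_uA, seed = seed)
  ctrl_seed <- if (is.null(seed)) NULL else seed + 1
  tr_ctrl <- simulate_it_trace(electrode, gdh_apo(enzyme), sched,
                               duration_s = duration_s, noise_uA = noise_uA,
                               seed = ctrl_seed)
  corr <- background_correct(tr, tr_ctrl)
  corr$mean_uA[corr$event_index == 1L]
}
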