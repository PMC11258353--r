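fc <- fuel_cell_spec()
oe <- oect_spec()

test_that("Nernstian OCP obeys logarithmic concentration dependence", {
  expect_equal(ocp_nernst(fc, 3, 3), fc$K_total_V) # ln(1) = 0
  b <- 8.314 * fc$T_K / (2 * 96485)
  expect_equal(ocp_nernst(fc, 10, 1) - fc$K_total_V, b * log(10)) # 0.029578 V
  expect_equal(ocp_nernst(fc, 5, 1) - ocp_nernst(fc, 10, 1), -b * log(2))
  expect_error(ocp_nernst(fc, 0, 1), class = "gbas_domain_error")
})

test_that("OCP time course decays through half-conversion", {
  cell <- fuel_cell_spec(K_total_V = 0.62, C0_glucose_mM = 20)
  vmax <- 1 / 60 # 1 mM/min in mM/s
  # half-conversion: glucose equals gluconolactone
  expect_equal(ocp_time_course(cell, vmax, cell$C0_glucose_mM / (2 * vmax)),
               cell$K_total_V)
  # direct evaluation at 5 min: K + (RT/2F) ln 3
  b <- 8.314 * cell$T_K / (2 * 96485)
  expect_equal(ocp_time_course(cell, vmax, 300), 0.62 + b * log(3))
  expect_equal(ocp_time_course(cell, vmax, 300), 0.634, tolerance = 1e-3)
  # strictly decreasing over its domain
  ts <- seq(10, 1100, by = 10)
  expect_true(all(diff(ocp_time_course(cell, vmax, ts)) < 0))
  # lower vmax before half-conversion raises OCP
  expect_gt(ocp_time_course(cell, 0.8 * vmax, 300),
            ocp_time_course(cell, vmax, 300))
  expect_error(ocp_time_course(cell, vmax, 1200), class = "gbas_domain_error")
  expect_error(ocp_time_course(cell, vmax, 0), class = "gbas_domain_error")
})

test_that("polarization curve has the right endpoints and ligand ordering", {
  e5i <- gdh_5e_plus(immobilized_alpha_max())
  S <- diluted_glucose_mM(blood_sample(volume_uL = 200, electrolyte_mL = 4))
  es <- polarization_curve(fc, e5i, S, ligand_dose("17b-estradiol", 100e-6, 0.01))
  ht <- polarization_curve(fc, e5i, S, ligand_dose("4-HT", 100e-6, 0.01))
  # V(0) = OCP, V non-increasing, P >= 0 with zero endpoints
  expect_equal(es$curve$V_volt[1], es$ocp_V)
  expect_true(all(diff(es$curve$V_volt) <= 0))
  expect_true(all(es$curve$P_uW_cm2 >= -1e-9))
  expect_lt(abs(es$curve$P_uW_cm2[nrow(es$curve)]), 1e-3)
  # unique interior power maximum
  expect_gt(es$P_max, max(es$curve$P_uW_cm2[c(1, nrow(es$curve))]))
  # blood calibration anchors (non-cognate ligand)
  expect_equal(es$j_max, 179, tolerance = 0.01)
  expect_equal(es$P_max, 32, tolerance = 0.01)
  # the cognate ligand lowers both figures of merit
  expect_lt(ht$j_max, es$j_max)
  expect_lt(ht$P_max, es$P_max)
  # ohmic closed form in the fuel-unlimited limit
  big <- fuel_cell_spec(j_lim_scale = 1e9)
  p <- polarization_curve(big, e5i, S, ocp_V = 0.69)
  expect_equal(p$P_max, 0.69^2 / (4 * big$R_int_ohm_cm2) * 1e6,
               tolerance = 1e-5) # uW cm^-2
  expect_equal(p$j_at_Pmax, 0.69 / (2 * big$R_int_ohm_cm2) * 1e6,
               tolerance = 1e-4)
  expect_error(polarization_curve(fc, gdh_apo(e5i), S),
               class = "gbas_no_fuel")
})

test_that("OECT drain current is linear in gate voltage with a floor", {
  expect_equal(oect_drain_current(oe, 0), -oe$i_sd0_mA)
  # glucose-free fuel cell as gate: ~7.0 mA step
  step <- abs(oect_drain_current(oe, 0)) - abs(oect_drain_current(oe, 0.62))
  expect_equal(step, 7.0, tolerance = 0.01)
  # zero transconductance: gate has no effect
  dead <- oect_spec(g_m_mS = 0)
  expect_equal(oect_drain_current(dead, 0.62), oect_drain_current(dead, 0))
  # floor at zero
  expect_equal(abs(oect_drain_current(oe, 100)), 0)
})

test_that("drain-current derivative variants are ordered and vanish without fuel", {
  expect_equal(disd_dt(fc, oe, 0, 50), 0)
  ts <- seq(50, 900, by = 50)
  slow <- disd_dt(fc, oe, 0.0164, ts) # 18% lower vmax
  fast <- disd_dt(fc, oe, 0.02, ts)
  expect_true(all(slow < fast)) # reduced variant: slower decay at all t
  # exact variant: ordering holds beyond half-conversion
  t_half <- fc$C0_glucose_mM / (2 * 0.0164)
  tt <- seq(t_half * 1.05, fc$C0_glucose_mM / 0.02 * 0.95, length.out = 20)
  expect_true(all(disd_dt(fc, oe, 0.0164, tt, "exact") <
                    disd_dt(fc, oe, 0.02, tt, "exact")))
})

test_that("exact derivative matches numerical differentiation of the composed model", {
  vmax <- 0.02
  isd <- function(t) oect_drain_current(oe, ocp_time_course(fc, vmax, t))
  richardson <- function(t, h) {
    d1 <- (isd(t + h) - isd(t - h)) / (2 * h)
    d2 <- (isd(t + h / 2) - isd(t - h / 2)) / h
    (4 * d2 - d1) / 3
  }
  t_end <- fc$C0_glucose_mM / vmax
  ts <- seq(0.02 * t_end, 0.95 * t_end, length.out = 25)
  num <- abs(vapply(ts, function(t) richardson(t, 1e-4 * t), numeric(1)))
  ana <- disd_dt(fc, oe, vmax, ts, variant = "exact")
  expect_lt(max(abs(num - ana) / ana), 1e-6)
})

test_that("coupled simulation steps on connect and drifts only with fuel", {
  # never connected: flat baseline
  tr0 <- coupled_simulation(fc, oe, schedule = list(connect = NULL),
                            duration_s = 100)
  expect_true(all(tr0$i_sd_mA == -oe$i_sd0_mA))
  # glucose-free connect: one step, no further drift
  tr1 <- coupled_simulation(fc, oe, schedule = list(connect = 50),
                            duration_s = 200)
  post <- tr1$i_sd_mA[tr1$times_s >= 50]
  expect_equal(unique(post), -oe$i_sd0_mA + oe$g_m_mS * fc$K_total_V)
  expect_equal(abs(tr1$i_sd_mA[1]) - abs(post[1]), 7.0, tolerance = 0.01)
  # injection adds the glucose contribution and starts the decay
  run <- function(vmax) coupled_simulation(
    fc, oe, schedule = list(connect = 50, inject = 100, disconnect = 280),
    vmax_mM_per_s = vmax, duration_s = 300, dt_s = 0.5)
  blank <- run(0.02); ht <- run(0.0164)
  i_at <- function(tr, t) tr$i_sd_mA[match(t, tr$times_s)]
  # injection step sizes are practically indistinguishable (the OCP jump
  # carries almost none of the ligand signal)
  step_b <- i_at(blank, 100) - i_at(blank, 99.5)
  step_h <- i_at(ht, 100) - i_at(ht, 99.5)
  expect_lt(abs(step_b - step_h) / abs(step_b), 0.1)
  # post-injection decay slope is smaller in magnitude with 4-HT
  slope <- function(tr) (i_at(tr, 250) - i_at(tr, 150)) / 100
  expect_lt(abs(slope(ht)), abs(slope(blank)))
  # disconnect restores baseline
  expect_equal(i_at(blank, 290), -oe$i_sd0_mA)
  expect_error(
    coupled_simulation(fc, oe, schedule = list(connect = 100, inject = 50)),
    class = "gbas_invalid_schedule")
})
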