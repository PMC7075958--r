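test_that("leak subtraction recovers a known signal decomposition", {
  rec <- simulate_step_currents(noise_sd_pA = 0)
  zero <- rec; zero$currents_pA[] <- 0

  expect_equal(leak_subtract(rec, rec)$currents_pA,
               rec$currents_pA * 0)
  expect_equal(leak_subtract(rec, zero)$currents_pA, rec$currents_pA)

  leak <- rec
  leak$currents_pA <- outer(rep(1, length(rec$time_ms)),
                            0.4 * (rec$voltages_mV + 26))  # ohmic leak
  contaminated <- rec
  contaminated$currents_pA <- rec$currents_pA + leak$currents_pA
  expect_equal(leak_subtract(contaminated, leak)$currents_pA,
               rec$currents_pA, tolerance = 1e-12)

  other <- simulate_step_currents(voltages_mV = c(-40, 0))
  expect_error(leak_subtract(rec, other), "protocol mismatch")
})

test_that("conductance curves normalize correctly", {
  # ohmic conductor: G/Gmax identically 1 away from the reversal potential
  V <- seq(-60, 40, by = 20)
  ipeak <- 2.5 * (V - (-75))
  gv <- conductance_curve(ipeak, reversal_mV = -75, voltages = V)
  expect_equal(gv$g, rep(1, length(V)))

  rec <- simulate_step_currents(V_half = -25, k = 9, noise_sd_pA = 0)
  gv2 <- conductance_curve(rec)
  expect_equal(max(gv2$g), 1)
  # recovered activation matches the generating sigmoid up to its own
  # normalization (the largest step sits near saturation)
  po <- 1 / (1 + exp((-25 - gv2$V) / 9))
  expect_equal(gv2$g, po / max(po), tolerance = 1e-9)

  expect_warning(conductance_curve(c(1, 2, 3), reversal_mV = -20,
                                   voltages = c(-20, 0, 20)),
                 "reversal potential")
})

test_that("Boltzmann fits recover noiseless parameters and the midpoint", {
  V <- seq(-100, 20, by = 10)
  g <- 1 / (1 + exp((-25 - V) / 9))
  fit <- fit_boltzmann(V, g)
  expect_lt(abs(fit$V_half - (-25)), 0.1)
  expect_lt(abs(fit$k - 9), 0.1)
  expect_lt(fit$residual_norm, 1e-6)
  # the fitted curve equals one half at V = V_half by construction
  mid <- 1 / (1 + exp((fit$V_half - fit$V_half) / fit$k))
  expect_equal(mid, 0.5)
  expect_error(fit_boltzmann(c(-10, 0), c(0.2, 0.8)), "at least 4")
})

test_that("activation time constants are recovered from step traces", {
  tt <- seq(0, 1500, by = 2)
  ii <- 800 * (1 - exp(-tt / 120)) + 30
  fit <- fit_activation_tau(tt, ii)
  expect_lt(abs(fit$tau_ms - 120), 1)

  set.seed(12)
  noisy <- ii + rnorm(length(tt), sd = 0.05 * 800)
  fit2 <- fit_activation_tau(tt, noisy)
  expect_lt(abs(fit2$tau_ms - 120) / 120, 0.10)

  expect_error(fit_activation_tau(tt, rep(5, length(tt))), "flat trace")
})

test_that("phosphatase-driven decay ratios follow the analytic trace", {
  tt <- seq(0, 10000, by = 10)
  # constant current: no decay
  rec_const <- step_recording(tt, c(40, 60),
                              cbind(rep(100, length(tt)),
                                    rep(250, length(tt))))
  d0 <- vsp_decay(rec_const)
  expect_equal(d0$ratio, c(1, 1))
  expect_equal(d0$decay_pct, c(0, 0))

  # exponential decay to a plateau: closed-form ratio at 10 s
  plateau <- 0.468; tau <- 2000
  ii <- (plateau + (1 - plateau) * exp(-tt / tau)) * 500
  rec <- step_recording(tt, 100, matrix(ii, ncol = 1))
  d1 <- vsp_decay(rec)
  expect_equal(d1$ratio,
               plateau + (1 - plateau) * exp(-10000 / tau),
               tolerance = 1e-9)
  # invariant to uniform current scaling
  rec2 <- rec; rec2$currents_pA <- rec2$currents_pA * 7.3
  expect_equal(vsp_decay(rec2)$ratio, d1$ratio)

  short <- step_recording(seq(0, 500, 10), 40,
                          matrix(1, nrow = 51, ncol = 1))
  expect_error(vsp_decay(short), "does not span")
  neg <- step_recording(tt, 40, matrix(-1, nrow = length(tt), ncol = 1))
  expect_error(vsp_decay(neg), "non-positive peak")
})

test_that("trace tables round-trip through the reader", {
  rec <- simulate_step_currents(voltages_mV = c(-40, -20, 0),
                                t_max_ms = 100, dt_ms = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(time_ms = rec$time_ms, rec$currents_pA,
                   check.names = FALSE)
  names(df) <- c("time_ms", rec$voltages_mV)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_step_recording(f, reversal_mV = -75)
  expect_equal(back$voltages_mV, rec$voltages_mV)
  expect_equal(back$currents_pA, rec$currents_pA, tolerance = 1e-9,
               ignore_attr = TRUE)
})
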