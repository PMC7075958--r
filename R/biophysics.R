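#' Construct a voltage-step recording
#'
#' Container for a family of current traces evoked by a series of command
#' voltages: one trace (column) per voltage, sampled on a common time base.
#'
#' @param time_ms Numeric vector of sample times in ms (strictly
#'   increasing).
#' @param voltages_mV Numeric vector of command voltages in mV.
#' @param currents_pA Numeric matrix, `length(time_ms)` rows x
#'   `length(voltages_mV)` columns, in pA.
#' @param capacitance_pF Cell capacitance in pF (> 0); used for current
#'   densities.
#' @param reversal_mV Reversal potential in mV, or `NA` if not measured.
#' @return An object of class `step_recording`.
#' @export
step_recording <- function(time_ms, voltages_mV, currents_pA,
                           capacitance_pF = 1, reversal_mV = NA_real_) {
  currents_pA <- as.matrix(currents_pA)
  if (length(time_ms) != nrow(currents_pA) ||
      length(voltages_mV) != ncol(currents_pA)) {
    stop("currents must be time x voltage", call. = FALSE)
  }
  if (is.unsorted(time_ms, strictly = TRUE)) {
    stop("time base must be strictly increasing", call. = FALSE)
  }
  if (capacitance_pF <= 0) stop("capacitance must be positive", call. = FALSE)
  structure(list(time_ms = as.numeric(time_ms),
                 voltages_mV = as.numeric(voltages_mV),
                 currents_pA = currents_pA,
                 capacitance_pF = capacitance_pF,
                 reversal_mV = reversal_mV),
            class = "step_recording")
}

#' Read a voltage-step recording from a tabular time-series file
#'
#' Expected format: a delimited table whose first column is `time_ms` and
#' whose remaining column names are the command voltages in mV (e.g.
#' `-100`, `-90`, ..., `20`).
#'
#' @param path Path to the file.
#' @param sep Field separator (default tab).
#' @param capacitance_pF,reversal_mV Passed to [step_recording()].
#' @return A `step_recording`.
#' @export
read_step_recording <- function(path, sep = "\t", capacitance_pF = 1,
                                reversal_mV = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE)
  if (!identical(tolower(names(df)[1L]), "time_ms")) {
    stop("first column must be time_ms", call. = FALSE)
  }
  volts <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(volts)) stop("voltage column names must be numeric (mV)",
                         call. = FALSE)
  step_recording(df[[1L]], volts, as.matrix(df[, -1L, drop = FALSE]),
                 capacitance_pF = capacitance_pF, reversal_mV = reversal_mV)
}

#' Subtract leak current estimated from a control recording
#'
#' Subtracts the control trace at each voltage pointwise in time (after
#' checking the two protocols share voltages and time base). The control is
#' typically the mean recording from cells expressing no channel, whose
#' non-voltage-dependent current defines the leak.
#'
#' @param recording,control `step_recording`s with matching voltages.
#' @return A leak-subtracted `step_recording`.
#' @export
leak_subtract <- function(recording, control) {
  stopifnot(inherits(recording, "step_recording"),
            inherits(control, "step_recording"))
  if (!isTRUE(all.equal(recording$voltages_mV, control$voltages_mV))) {
    stop("protocol mismatch: recording and control voltage sets differ",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(recording$time_ms, control$time_ms))) {
    stop("protocol mismatch: time bases differ", call. = FALSE)
  }
  out <- recording
  out$currents_pA <- recording$currents_pA - control$currents_pA
  out
}

#' Normalized conductance-voltage curve
#'
#' Computes the chord conductance \eqn{G(V) = I_{peak}(V) / (V - V_{rev})}
#' from per-voltage peak currents and normalizes by the maximum over steps
#' (G/Gmax). Steps at the reversal potential are excluded with a warning.
#'
#' @param recording A `step_recording`, or a numeric vector of peak
#'   currents (then `voltages` must be given).
#' @param reversal_mV Reversal potential; defaults to the recording's.
#' @param voltages Voltages when `recording` is a plain vector.
#' @return data.frame with columns `V` (mV), `G` (pA/mV) and `g` (G/Gmax).
#' @export
conductance_curve <- function(recording, reversal_mV = NULL,
                              voltages = NULL) {
  if (inherits(recording, "step_recording")) {
    if (is.null(reversal_mV)) reversal_mV <- recording$reversal_mV
    V <- recording$voltages_mV
    ipeak <- apply(recording$currents_pA, 2L, function(x) x[which.max(abs(x))])
  } else {
    V <- voltages
    ipeak <- as.numeric(recording)
  }
  if (is.null(reversal_mV) || is.na(reversal_mV)) {
    stop("a reversal potential is required", call. = FALSE)
  }
  at_rev <- V == reversal_mV
  if (any(at_rev)) {
    warning("excluding step(s) at the reversal potential: ",
            paste(V[at_rev], collapse = ", "), " mV", call. = FALSE)
    V <- V[!at_rev]; ipeak <- ipeak[!at_rev]
  }
  G <- ipeak / (V - reversal_mV)
  gmax <- max(G)
  if (gmax <= 0) stop("non-positive maximal conductance", call. = FALSE)
  data.frame(V = V, G = G, g = G / gmax)
}

#' Fit a Boltzmann activation curve
#'
#' Least-squares fit of the two-parameter Boltzmann
#' \deqn{G/G_{max} = 1 / (1 + \exp((V_{1/2} - V) / k))}
#' to normalized conductances, by Levenberg-Marquardt. `V_half` is the
#' half-activation voltage and `k` the slope factor, both in mV; at
#' `V = V_half` the fitted curve equals 0.5 by construction.
#'
#' @param V Command voltages in mV (>= 4 points spanning the transition).
#' @param g Normalized conductance at each voltage.
#' @return An object of class `boltzmann_fit`: list with `V_half`, `k`,
#'   `residual_norm`, `fitted` and the `nls` fit object.
#' @examples
#' V <- seq(-80, 40, by = 10)
#' g <- 1 / (1 + exp((-25 - V) / 9))
#' fit_boltzmann(V, g)
#' @export
fit_boltzmann <- function(V, g) {
  stopifnot(is.numeric(V), is.numeric(g), length(V) == length(g))
  if (length(V) < 4L) stop("need at least 4 points to fit", call. = FALSE)
  # starting values: V_half from the point nearest half activation, k from
  # a logit-linear regression over the transition
  v0 <- V[which.min(abs(g - 0.5))]
  gi <- pmin(pmax(g, 1e-4), 1 - 1e-4)
  lf <- stats::lm(stats::qlogis(gi) ~ V)
  k0 <- 1 / max(abs(stats::coef(lf)[2L]), 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(g ~ 1 / (1 + exp((vh - V) / k)),
                      start = list(vh = unname(v0),
                                   k = unname(sign(stats::coef(lf)[2L]) * k0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Boltzmann fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  co <- stats::coef(fit)
  if (co[["k"]] == 0) stop("degenerate Boltzmann fit: k = 0", call. = FALSE)
  structure(list(V_half = unname(co[["vh"]]), k = unname(co[["k"]]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit), fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V_half = %.2f mV, k = %.2f mV (||resid|| = %.3g)\n",
              x$V_half, x$k, x$residual_norm))
  invisible(x)
}

#' Fit the activation time constant of a depolarizing step
#'
#' Single-exponential rise \eqn{I(t) = A (1 - e^{-t/\tau}) + C} fitted by
#' Levenberg-Marquardt over the activation window (stimulus onset to peak
#' by default).
#'
#' @param time_ms Sample times in ms.
#' @param current_pA Current trace.
#' @param window Optional `c(t0, t1)` restricting the fit, in ms.
#' @return List with `tau_ms`, `A`, `C`, `residual_norm`.
#' @export
fit_activation_tau <- function(time_ms, current_pA, window = NULL) {
  stopifnot(length(time_ms) == length(current_pA))
  if (!is.null(window)) {
    keep <- time_ms >= window[1L] & time_ms <= window[2L]
    time_ms <- time_ms[keep]; current_pA <- current_pA[keep]
  }
  if (length(time_ms) < 4L) stop("too few samples in window", call. = FALSE)
  rng <- diff(range(current_pA))
  if (rng <= .Machine$double.eps^0.5 * max(1, abs(current_pA[1L]))) {
    stop("flat trace: no activation to fit", call. = FALSE)
  }
  t0 <- time_ms[1L]
  tt <- time_ms - t0
  a0 <- current_pA[length(current_pA)] - current_pA[1L]
  tau0 <- max(tt[length(tt)] / 5, diff(time_ms)[1L])
  fit <- tryCatch(
    minpack.lm::nlsLM(current_pA ~ A * (1 - exp(-tt / tau)) + C,
                      start = list(A = a0, tau = tau0, C = current_pA[1L]),
                      lower = c(-Inf, 1e-6, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("activation fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  co <- stats::coef(fit)
  list(tau_ms = unname(co[["tau"]]), A = unname(co[["A"]]),
       C = unname(co[["C"]]),
       residual_norm = sqrt(sum(stats::resid(fit)^2)))
}

#' Current decay ratio during phosphatase-activating depolarization
#'
#' For each voltage step of a long (>= 10 s) depolarization, returns the
#' ratio of the current at `t_ratio` (default 10 s) over the peak current,
#' and the corresponding percent decay `(1 - ratio) * 100`. The ratio
#' indexes current loss as the activated voltage-sensitive phosphatase
#' depletes PIP2; it is invariant to uniform scaling of the trace.
#'
#' @param recording A `step_recording` spanning at least `t_ratio`.
#' @param t_ratio_ms Time at which the late current is read (default
#'   10000 ms).
#' @return An object of class `vsp_decay_result`: data.frame with columns
#'   `V`, `I_peak`, `I_late`, `ratio`, `decay_pct`.
#' @export
vsp_decay <- function(recording, t_ratio_ms = 10000) {
  stopifnot(inherits(recording, "step_recording"))
  if (max(recording$time_ms) < t_ratio_ms) {
    stop("trace does not span ", t_ratio_ms, " ms", call. = FALSE)
  }
  i_late_idx <- which.min(abs(recording$time_ms - t_ratio_ms))
  ipeak <- apply(recording$currents_pA, 2L, max)
  if (any(ipeak <= 0)) {
    stop("undefined decay ratio: non-positive peak current", call. = FALSE)
  }
  ilate <- recording$currents_pA[i_late_idx, ]
  ratio <- pmin(pmax(ilate / ipeak, 0), 1)
  structure(data.frame(V = recording$voltages_mV, I_peak = ipeak,
                       I_late = as.numeric(ilate), ratio = ratio,
                       decay_pct = (1 - ratio) * 100),
            class = c("vsp_decay_result", "data.frame"))
}

#' Simulate Boltzmann-gated step currents
#'
#' Forward model used by the parameter-recovery tests: ohmic driving force
#' times Boltzmann open probability, with a mono-exponential activation
#' time course, plus optional Gaussian noise.
#'
#' @param voltages_mV Command voltages.
#' @param V_half,k Boltzmann parameters (mV).
#' @param gmax_nS Maximal conductance (nS).
#' @param reversal_mV Reversal potential.
#' @param tau_ms Activation time constant.
#' @param t_max_ms,dt_ms Time base.
#' @param noise_sd_pA Gaussian noise added to each sample.
#' @param seed Seed for the noise.
#' @return A `step_recording`.
#' @export
simulate_step_currents <- function(voltages_mV = seq(-100, 20, by = 10),
                                   V_half = -26.8, k = 9, gmax_nS = 5,
                                   reversal_mV = -75, tau_ms = 120,
                                   t_max_ms = 1500, dt_ms = 5,
                                   noise_sd_pA = 0, seed = 1L) {
  tt <- seq(0, t_max_ms, by = dt_ms)
  po <- 1 / (1 + exp((V_half - voltages_mV) / k))
  iss <- gmax_nS * po * (voltages_mV - reversal_mV)  # nS * mV = pA
  act <- 1 - exp(-tt / tau_ms)
  cur <- outer(act, iss)
  if (noise_sd_pA > 0) {
    cur <- cur + with_seed(seed, {
      matrix(stats::rnorm(length(cur), sd = noise_sd_pA), nrow = nrow(cur))
    })
  }
  step_recording(tt, voltages_mV, cur, reversal_mV = reversal_mV)
}
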