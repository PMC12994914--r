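#' Physiological model parameters
#'
#' The full coefficient set of the coupled sleep-wake / circadian / melatonin
#' model. Neuronal mean-field and homeostatic constants follow the
#' Phillips-Robinson sleep-wake flip-flop; the circadian pacemaker and
#' photoreceptor (process-L) constants follow the Kronauer/Jewett lineage
#' with the photic drive expressed in melanopic irradiance; melatonin
#' synthesis/clearance and the alertness regressions are package
#' calibrations documented in the methods vignette. Every constant is a
#' plain list entry so substitution is trivial.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of class `insom_params`.
#'
#' @section Groups:
#' \describe{
#' \item{flip-flop}{`Qmax` (s^-1), `theta`, `sigma_v` (mV): firing-rate
#'   sigmoid; `tau_v`, `tau_m` (s): relaxation times of the sleep-active
#'   (VLPO) and wake-active (monoaminergic) populations; `nu_vm`, `nu_mv`
#'   (mV s): mutual inhibition; `nu_vh` (mV nM^-1): homeostatic drive
#'   weight; `nu_vc` (mV): circadian drive weight; `A_v` (mV): constant
#'   VLPO drive; `D_m` (mV): constant wake drive; `F_w` (mV): forcing used
#'   to impose a sleep schedule; `theta_nat` (mV): natural-sleep threshold
#'   on the wake-active voltage (hysteretic).}
#' \item{homeostat}{`chi_wake`, `chi_sleep` (s): sleep-pressure time
#'   constants during wake (slow rise) and sleep (fast dissipation);
#'   `mu` (nM s):
#'   production per unit wake-active firing.}
#' \item{pacemaker}{`tau_c` (h): intrinsic period; `f_c`: period-scaling
#'   constant; `gamma_c`: van-der-Pol stiffness; `q_c`, `k_c`: photic
#'   modulation of the oscillator; `G_c`: photic drive gain; `alpha0`
#'   (s^-1), `beta_c` (s^-1), `p_c`, `E0_mel` (W m^-2): photoreceptor
#'   activation/recovery and dose normalization; `rho_c`: nonphotic
#'   (sleep-state) drive.}
#' \item{melatonin}{`phi_m` (rad), `theta_m`, `s_m`: circadian synthesis
#'   gate (rotation of the oscillator plane, activation threshold on the
#'   rotated coordinate, and shape exponent of the curved activation);
#'   `r_m` (pmol L^-1 s^-1): maximal synthesis rate; `k_syn`, `k_clr`
#'   (s^-1): pineal release and plasma clearance; `E_i50` (W m^-2), `h_i`:
#'   half-inhibition melanopic irradiance and Hill slope of the
#'   instantaneous light inhibition.}
#' \item{alertness}{`kss_0`, `kss_H` (nM^-1), `kss_C`, `kss_L`:
#'   KSS regression intercept, homeostatic and circadian weights and
#'   instantaneous light-term depth; `kss_E50` (W m^-2), `kss_hill`: light
#'   term half-saturation (saturates near 0.075 W m^-2) and slope;
#'   `rt_0`, `rt_H`, `rt_C` (ms): vPVTRT regression (no light term);
#'   `rt_floor` (ms): lower bound.}
#' }
#' @export
insom_params <- function(...) {
  p <- list(
    # sleep-wake flip-flop (Phillips-Robinson lineage)
    Qmax = 100, theta = 10, sigma_v = 3,
    tau_v = 10, tau_m = 10,
    nu_vm = -2.1, nu_mv = -1.8,
    nu_vh = 1.0, nu_vc = -2.9, A_v = -10.2, D_m = 1.3,
    F_w = 12, theta_nat = -2,
    # homeostat: sleep pressure rises slowly during wake and dissipates
    # fast during sleep (classic two-process asymmetry)
    chi_wake = 18.2 * 3600, chi_sleep = 4.2 * 3600, mu = 4.4,
    # circadian pacemaker + photoreceptor (Kronauer/Jewett lineage)
    tau_c = 24.2, f_c = 0.99946, gamma_c = 0.23, q_c = 1 / 3, k_c = 0.55,
    G_c = 37, alpha0 = 0.05 / 60, beta_c = 0.0075 / 60, p_c = 0.5,
    E0_mel = 7.6, rho_c = 0.08,
    # melatonin synthesis gate + plasma kinetics (package calibration)
    phi_m = 1.17, theta_m = 0.15, s_m = 1.3,
    r_m = 0.0462, k_syn = 1 / 1800, k_clr = log(2) / 2700,
    E_i50 = 0.10, h_i = 2,
    # alertness regressions (package calibration)
    kss_0 = 3.4, kss_H = 0.18, kss_C = 1.9, kss_L = 1.5,
    kss_E50 = 0.01, kss_hill = 2,
    rt_0 = 286, rt_H = 8, rt_C = 230, rt_floor = 100
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(over)] <- over
  }
  rates <- c("tau_v", "tau_m", "chi_wake", "chi_sleep", "alpha0",
             "beta_c", "k_syn", "k_clr")
  if (any(unlist(p[rates]) <= 0)) {
    stop("all rate constants must be positive", call. = FALSE)
  }
  if (p$tau_c <= 20 || p$tau_c >= 28) {
    stop("intrinsic circadian period must lie in (20 h, 28 h)", call. = FALSE)
  }
  structure(p, class = "insom_params")
}

#' Documented initial physiological state
#'
#' The state used to seed entrainment pre-runs: shortly after sleep onset at
#' midnight for a conventionally entrained subject. Entrainment (7 days by
#' default) makes downstream results insensitive to these values.
#'
#' @return Named numeric vector with components `Vv`, `Vm` (mV), `H` (nM),
#'   `x`, `y` (dimensionless oscillator pair), `n` (photoreceptor activity,
#'   0-1), `Ms`, `Mp` (pineal and plasma melatonin, pmol L^-1) and attribute
#'   `awake = FALSE`.
#' @export
initial_state <- function() {
  structure(
    c(Vv = 1.0, Vm = -8.0, H = 16.0, x = -0.3, y = -1.0, n = 0.05,
      Ms = 60, Mp = 80),
    awake = FALSE, class = "insom_state"
  )
}

#' @export
print.insom_state <- function(x, ...) {
  cat("<insom_state>", if (isTRUE(attr(x, "awake"))) "awake" else "asleep",
      "\n")
  print(unclass(structure(x, awake = NULL, class = NULL)))
  invisible(x)
}
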