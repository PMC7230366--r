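# Closed-form disposition model used by the synthetic cohort generator:
# two-compartment distribution with a constant-rate intravenous infusion,
# and a first-order tissue link driven by unbound plasma concentration.
#
# The bi-exponential solution is kept as explicit exponential terms so
# that concentrations, interval averages and areas are all evaluated
# analytically (no integrator error enters the simulator).

#' Closed-form plasma / ISF concentration model for one subject
#'
#' Builds the analytic solution of a two-compartment disposition model
#' with a constant-rate infusion, plus the first-order interstitial-fluid
#' (ISF) link \eqn{dC_{ISF}/dt = k_{isf}(p \cdot f_u C_p - C_{ISF})},
#' whose steady-state ISF / unbound-plasma AUC ratio equals the
#' penetration `p` by construction.
#'
#' @param CL,V1,V2,Q Disposition parameters: clearance (L/h), central and
#'   peripheral volumes (L), inter-compartmental clearance (L/h).
#' @param dose Dose (mg) infused at constant rate over `t_inf`.
#' @param t_inf Infusion duration (h).
#' @param fu Unbound fraction in plasma.
#' @param k_isf First-order plasma-ISF equilibration rate (1/h).
#' @param penetration Steady-state ISF / unbound-plasma AUC ratio.
#'
#' @return A list of class `tpk_model` with functions
#'   `conc_plasma(t)` (total), `conc_unbound(t)`, `conc_isf(t)`,
#'   `isf_interval_avg(t_start, t_end)` (analytic time-average), and the
#'   analytic ground truths `auc_plasma_inf`, `auc_unbound_inf`,
#'   `auc_isf_inf`, `mrt_true`, `vss`.
#' @examples
#' m <- pk_model(CL = 7, V1 = 15.4, V2 = 15.4, Q = 14)
#' m$conc_plasma(c(0.5, 1, 8))
#' m$auc_plasma_inf  # dose / CL
#' @export
pk_model <- function(CL, V1, V2, Q, dose = 600, t_inf = 0.5,
                     fu = 0.86, k_isf = 2, penetration = 0.6) {
  stopifnot(CL > 0, V1 > 0, V2 > 0, Q > 0, dose > 0, t_inf > 0)
  if (k_isf <= 0) abort("k_isf must be > 0", class = "tpk_invalid_config")
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(s^2 - 4 * p)
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  r0 <- dose / t_inf
  # bolus macro-coefficients A, B; infusion response per eigenmode:
  # C(t <= T) = sum_i c_i (1 - exp(-l_i t)),  c_i = (R0/V1) * coef_i / l_i
  coef_a <- (al - k21) / (al - be)
  coef_b <- (k21 - be) / (al - be)
  ca <- r0 / V1 * coef_a / al
  cb <- r0 / V1 * coef_b / be
  # degenerate tie-break: nudge k_isf off the eigenvalues so every
  # convolution coefficient k/(k - l) stays finite
  if (min(abs(k_isf - c(al, be))) < 1e-9 * k_isf) k_isf <- k_isf * (1 + 1e-7)

  conc_plasma <- function(t) {
    during <- ca * (1 - exp(-al * t)) + cb * (1 - exp(-be * t))
    after <- ca * (exp(-al * pmax(t - t_inf, 0)) - exp(-al * t)) +
      cb * (exp(-be * pmax(t - t_inf, 0)) - exp(-be * t))
    out <- ifelse(t <= t_inf, during, after)
    out[t <= 0] <- 0
    out
  }

  # ISF solution as explicit exponential terms per phase.
  w <- penetration * fu
  k <- k_isf
  ga <- k / (k - al) # convolution gains
  gb <- k / (k - be)
  # phase 1 (0 <= t <= t_inf): const + exp terms in t
  p1_const <- w * (ca + cb)
  p1 <- list(rate = c(al, be, k),
             coef = c(-w * ca * ga, -w * cb * gb,
                      -w * (ca + cb) + w * ca * ga + w * cb * gb))
  isf_phase1 <- function(t) {
    p1_const +
      p1$coef[1] * exp(-p1$rate[1] * t) +
      p1$coef[2] * exp(-p1$rate[2] * t) +
      p1$coef[3] * exp(-p1$rate[3] * t)
  }
  c_at_tinf <- isf_phase1(t_inf)
  da <- ca * (1 - exp(-al * t_inf)) # post-infusion plasma coefficients
  db <- cb * (1 - exp(-be * t_inf))
  # phase 2 (s = t - t_inf >= 0): pure exponentials in s
  p2 <- list(rate = c(al, be, k),
             coef = c(w * da * ga, w * db * gb,
                      c_at_tinf - w * da * ga - w * db * gb))
  isf_phase2 <- function(s) {
    p2$coef[1] * exp(-p2$rate[1] * s) +
      p2$coef[2] * exp(-p2$rate[2] * s) +
      p2$coef[3] * exp(-p2$rate[3] * s)
  }
  conc_isf <- function(t) {
    out <- ifelse(t <= t_inf, isf_phase1(pmax(t, 0)), isf_phase2(t - t_inf))
    out[t <= 0] <- 0
    out
  }

  # analytic integral of the ISF curve over [a, b]
  int_exp <- function(coef, rate, a, b) {
    sum(coef / rate * (exp(-rate * a) - exp(-rate * b)))
  }
  isf_integral <- function(a, b) {
    stopifnot(b >= a)
    a <- max(a, 0)
    tot <- 0
    if (a < t_inf) {
      b1 <- min(b, t_inf)
      tot <- tot + p1_const * (b1 - a) + int_exp(p1$coef, p1$rate, a, b1)
    }
    if (b > t_inf) {
      a2 <- max(a, t_inf) - t_inf
      tot <- tot + int_exp(p2$coef, p2$rate, a2, b - t_inf)
    }
    tot
  }
  isf_interval_avg <- function(t_start, t_end) {
    mapply(function(a, b) isf_integral(a, b) / (b - a), t_start, t_end)
  }

  structure(
    list(conc_plasma = conc_plasma,
         conc_unbound = function(t) fu * conc_plasma(t),
         conc_isf = conc_isf,
         isf_interval_avg = isf_interval_avg,
         isf_integral = isf_integral,
         auc_plasma_inf = dose / CL,
         auc_unbound_inf = fu * dose / CL,
         auc_isf_inf = penetration * fu * dose / CL,
         mrt_true = (V1 + V2) / CL + t_inf / 2,
         vss = V1 + V2,
         params = list(CL = CL, V1 = V1, V2 = V2, Q = Q, dose = dose,
                       t_inf = t_inf, fu = fu, k_isf = k_isf,
                       penetration = penetration),
         alpha = al, beta = be),
    class = "tpk_model"
  )
}

#' @export
print.tpk_model <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<tpk_model> 2-cmt infusion: CL=%.2f V1=%.1f V2=%.1f Q=%.2f, %g mg/%g h\n",
    p$CL, p$V1, p$V2, p$Q, p$dose, p$t_inf))
  cat(sprintf("  alpha=%.3f beta=%.3f /h (terminal t1/2 %.2f h), k_isf=%.2f, penetration=%.2f\n",
              x$alpha, x$beta, log(2) / x$beta, p$k_isf, p$penetration))
  invisible(x)
}
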