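#' Two-stage model parameters
#'
#' Container for the parameters of the two-stage discrete-window model.
#' The defaults are the hand-fitted values used for all simulations:
#' `tau = 0.3` s, `c = 0.3`, `sigma = 0.2`, `mu0 = 0.2` and a window
#' length `T_readout = 425` ms (475 ms models observers with prolonged
#' integration windows).
#'
#' @param tau Integration time constant of the memory-box leaky
#'   integrator, in seconds.
#' @param c Readout gain applied to the summed window evidence before it
#'   enters the decision network (dimensionless).
#' @param sigma Standard deviation of the Gaussian noise on the decision
#'   network input (dimensionless).
#' @param mu0 Background input to the decision network in the absence of
#'   stimulus evidence (dimensionless).
#' @param T_readout Duration of one integration window, in ms.
#' @param evidence_scale Normalisation constant dividing each buffered
#'   memory-box value, so that `summed_evidence` is expressed in units of
#'   one isolated 20-ms vernier. The default, `tau * (1 - exp(-0.02/tau))`,
#'   makes a single vernier read out as exactly +/-1; set
#'   `evidence_scale = 1` to work on the raw integrator scale.
#'
#' @return An object of class `"sqm_params"`.
#' @examples
#' p <- model_params()
#' p$T_readout
#' @export
model_params <- function(tau = 0.3, c = 0.3, sigma = 0.2, mu0 = 0.2,
                         T_readout = 425, evidence_scale = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number (seconds)")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (T_readout <= 0) stop("'T_readout' must be > 0 (ms)")
  if (is.null(evidence_scale))
    evidence_scale <- tau * (1 - exp(-0.020 / tau))
  if (evidence_scale <= 0) stop("'evidence_scale' must be > 0")
  structure(
    list(tau = tau, c = c, sigma = sigma, mu0 = mu0,
         T_readout = T_readout, evidence_scale = evidence_scale),
    class = "sqm_params"
  )
}

#' @export
print.sqm_params <- function(x, ...) {
  cat("Two-stage SQM model parameters\n")
  cat(sprintf("  tau = %g s, c = %g, sigma = %g, mu0 = %g\n",
              x$tau, x$c, x$sigma, x$mu0))
  cat(sprintf("  T_readout = %g ms, evidence_scale = %g\n",
              x$T_readout, x$evidence_scale))
  invisible(x)
}

#' Reduced attractor decision-network parameters
#'
#' Constants of the reduced two-variable attractor network used as the
#' decision stage: two NMDA gating variables with recurrent
#' self-excitation and cross-inhibition, the nonlinear firing-rate
#' transfer function `H(x) = (a*x - b) / (1 - exp(-d*(a*x - b)))`, and an
#' Ornstein-Uhlenbeck background-noise current per population. Defaults
#' are the published physiological values of the reference
#' mean-field reduction; `j_ext` scales how strongly the (dimensionless)
#' evidence-biased drive `mu0 * (1 +/- input)` converts to external
#' current, and is the one constant fitted so that a single isolated
#' vernier yields about 75% dominance under the default
#' [model_params()].
#'
#' @param a,b,d Transfer-function constants (Hz/nA, Hz, s).
#' @param gamma Gating-variable rise constant (dimensionless).
#' @param tau_S NMDA gating time constant (s).
#' @param J11,J22 Recurrent self-coupling strengths (nA).
#' @param J12,J21 Cross-inhibition coupling strengths (nA).
#' @param j_ext External input scaling (nA per unit of `mu0*(1 + input)`).
#' @param I0 Common background current (nA).
#' @param tau_noise Time constant of the background OU noise current (s).
#' @param sigma_noise Stationary standard deviation of the OU noise (nA).
#' @param threshold Decision threshold on population firing rate (Hz).
#' @param dt Integration time step (s).
#' @param t_max Maximum decision time (s); if no population crosses
#'   threshold by `t_max` the higher-rate population wins.
#'
#' @return An object of class `"sqm_network_params"`.
#' @export
decision_network_params <- function(a = 270, b = 108, d = 0.154,
                                    gamma = 0.641, tau_S = 0.1,
                                    J11 = 0.2609, J22 = 0.2609,
                                    J12 = 0.0497, J21 = 0.0497,
                                    j_ext = 0.0105, I0 = 0.3255,
                                    tau_noise = 0.002, sigma_noise = 0.02,
                                    threshold = 15, dt = 5e-4, t_max = 2) {
  if (tau_S <= 0 || tau_noise <= 0 || dt <= 0 || t_max <= 0)
    stop("all time constants must be > 0")
  if (threshold <= 0) stop("'threshold' must be > 0")
  structure(
    list(a = a, b = b, d = d, gamma = gamma, tau_S = tau_S,
         J11 = J11, J22 = J22, J12 = J12, J21 = J21,
         j_ext = j_ext, I0 = I0,
         tau_noise = tau_noise, sigma_noise = sigma_noise,
         threshold = threshold, dt = dt, t_max = t_max),
    class = "sqm_network_params"
  )
}

#' @export
print.sqm_network_params <- function(x, ...) {
  cat("Reduced two-variable attractor decision network\n")
  cat(sprintf("  H(x): a = %g Hz/nA, b = %g Hz, d = %g s\n", x$a, x$b, x$d))
  cat(sprintf("  gating: gamma = %g, tau_S = %g s\n", x$gamma, x$tau_S))
  cat(sprintf("  couplings (nA): J11 = J22 = %g, J12 = J21 = %g\n",
              x$J11, x$J12))
  cat(sprintf("  I0 = %g nA, j_ext = %g nA, OU noise sd = %g nA (tau %g ms)\n",
              x$I0, x$j_ext, x$sigma_noise, 1000 * x$tau_noise))
  cat(sprintf("  threshold = %g Hz, dt = %g ms, t_max = %g s\n",
              x$threshold, 1000 * x$dt, x$t_max))
  invisible(x)
}
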