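#' Draw the decision-network input for a window
#'
#' The scalar entering the decision network is a Gaussian draw centred
#' on the gain-scaled summed evidence:
#' `input ~ N(c * summed_evidence, sigma)`.
#'
#' @param summed_evidence Window readout (dimensionless; +/-1 per
#'   isolated vernier under the default normalisation).
#' @param c Readout gain.
#' @param sigma Noise standard deviation (`sigma = 0` gives the
#'   deterministic value `c * summed_evidence`).
#' @param n Number of independent draws.
#' @return Numeric vector of length `n`.
#' @export
draw_decision_input <- function(summed_evidence, c = 0.3, sigma = 0.2, n = 1) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  stats::rnorm(n, mean = c * summed_evidence, sd = sigma)
}

# nonlinear firing-rate transfer function H(x) = (a x - b)/(1 - exp(-d (a x - b)))
# with the removable singularity at a x = b handled explicitly
transfer_rate <- function(x, net) {
  z <- net$a * x - net$b
  dz <- net$d * z
  r <- ifelse(abs(dz) < 1e-9, 1 / net$d, z / (1 - exp(-dz)))
  pmax(r, 0)
}

#' Simulate attractor-network decisions for a batch of inputs
#'
#' Integrates the reduced two-variable attractor network once per input:
#' gating variables `S_pro`, `S_anti` evolve as
#' `dS/dt = -S/tau_S + (1 - S) * gamma * H(x)` with total currents
#' `x_pro = J11*S_pro - J12*S_anti + I0 + j_ext*mu0*(1 + input) + I_noise`
#' (and symmetrically for anti, with `1 - input`), where `I_noise` is an
#' Ornstein-Uhlenbeck background current per population. The first
#' population whose rate `H(x)` crosses `threshold` wins; if none
#' crosses by `t_max`, the population with the higher final rate wins
#' (exact ties broken by a fair coin).
#'
#' All trials are advanced in lockstep (vectorised), so a batch of
#' thousands of trials costs little more than a single one.
#'
#' @param inputs Numeric vector of decision-network inputs (one trial
#'   per element); must be finite.
#' @param mu0 Background input in the absence of stimulus evidence.
#' @param net An [decision_network_params()] object.
#' @return Data frame with one row per trial: `choice` (`"pro"` /
#'   `"anti"`), `decided` (logical: threshold reached before `t_max`)
#'   and `decision_time` (s; `NA` when undecided).
#' @export
simulate_decisions <- function(inputs, mu0 = 0.2,
                               net = decision_network_params()) {
  if (length(inputs) == 0L)
    return(data.frame(choice = character(0), decided = logical(0),
                      decision_time = numeric(0)))
  if (any(!is.finite(inputs))) stop("'inputs' must be finite")
  n <- length(inputs)
  dt <- net$dt
  n_steps <- as.integer(round(net$t_max / dt))
  # external currents are constant within a trial
  Ie1 <- net$j_ext * mu0 * (1 + inputs)
  Ie2 <- net$j_ext * mu0 * (1 - inputs)

  S1 <- rep(0.1, n)
  S2 <- rep(0.1, n)
  # OU noise initialised at its stationary distribution
  nu1 <- stats::rnorm(n, 0, net$sigma_noise)
  nu2 <- stats::rnorm(n, 0, net$sigma_noise)
  ou_k <- dt / net$tau_noise
  ou_s <- net$sigma_noise * sqrt(2 * dt / net$tau_noise)

  choice <- integer(n)           # 0 = undecided, 1 = pro, 2 = anti
  dtime <- rep(NA_real_, n)
  act <- seq_len(n)              # indices of still-running trials
  r1 <- r2 <- numeric(n)

  for (k in seq_len(n_steps)) {
    x1 <- net$J11 * S1[act] - net$J12 * S2[act] + net$I0 + Ie1[act] + nu1[act]
    x2 <- net$J22 * S2[act] - net$J21 * S1[act] + net$I0 + Ie2[act] + nu2[act]
    h1 <- transfer_rate(x1, net)
    h2 <- transfer_rate(x2, net)
    r1[act] <- h1
    r2[act] <- h2
    S1[act] <- S1[act] + dt * (-S1[act] / net$tau_S +
                                 (1 - S1[act]) * net$gamma * h1)
    S2[act] <- S2[act] + dt * (-S2[act] / net$tau_S +
                                 (1 - S2[act]) * net$gamma * h2)
    nu1[act] <- nu1[act] - ou_k * nu1[act] + ou_s * stats::rnorm(length(act))
    nu2[act] <- nu2[act] - ou_k * nu2[act] + ou_s * stats::rnorm(length(act))

    crossed <- h1 >= net$threshold | h2 >= net$threshold
    if (any(crossed)) {
      idx <- act[crossed]
      win1 <- h1[crossed] > h2[crossed]
      tie <- h1[crossed] == h2[crossed]
      if (any(tie))
        win1[tie] <- stats::runif(sum(tie)) < 0.5
      choice[idx] <- ifelse(win1, 1L, 2L)
      dtime[idx] <- k * dt
      act <- act[!crossed]
      if (length(act) == 0L) break
    }
  }

  if (length(act) > 0L) {        # no threshold crossing: higher rate wins
    win1 <- r1[act] > r2[act]
    tie <- r1[act] == r2[act]
    if (any(tie))
      win1[tie] <- stats::runif(sum(tie)) < 0.5
    choice[act] <- ifelse(win1, 1L, 2L)
  }
  data.frame(choice = c("pro", "anti")[choice],
             decided = !is.na(dtime),
             decision_time = dtime)
}

#' Run the decision network for a single input
#'
#' Scalar convenience wrapper around [simulate_decisions()].
#'
#' @param input Decision-network input (finite scalar).
#' @inheritParams simulate_decisions
#' @return A one-row data frame (`choice`, `decided`, `decision_time`).
#' @export
run_decision_network <- function(input, mu0 = 0.2,
                                 net = decision_network_params()) {
  if (length(input) != 1L || !is.finite(input))
    stop("'input' must be a single finite number")
  simulate_decisions(input, mu0 = mu0, net = net)
}
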