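#' Leaky integration of a piecewise-constant signal
#'
#' Integrates `dE/dt = -E/tau + stim(t)` exactly, segment by segment,
#' starting from `E = 0` at the first segment onset. For a constant
#' input `s` held for `d` ms the solution is
#' `E = s * tau * (1 - exp(-d/1000/tau))`; consecutive segments chain the
#' closed form, with pure decay across gaps between them. This is the
#' noise-free feature-evidence process inside one memory box.
#'
#' @param signal Data frame with columns `t_on`, `t_off` (ms) and
#'   `value`, as produced by [element_signal()]; rows must be
#'   non-overlapping and time-ordered. The signal is 0 between rows.
#' @param tau Integration time constant in seconds.
#' @return The integrated evidence at the end of the last segment.
#' @examples
#' integrate_box(data.frame(t_on = 0, t_off = 20, value = 1), tau = 0.3)
#' @export
integrate_box <- function(signal, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number (seconds)")
  stopifnot(is.data.frame(signal),
            all(c("t_on", "t_off", "value") %in% names(signal)))
  if (nrow(signal) == 0L) return(0)
  if (any(signal$t_off < signal$t_on)) stop("segment with t_off < t_on")
  if (is.unsorted(signal$t_on) ||
      any(signal$t_on[-1] < signal$t_off[-nrow(signal)]))
    stop("signal segments must be time-ordered and non-overlapping")
  E <- 0
  t <- signal$t_on[1]
  for (i in seq_len(nrow(signal))) {
    gap <- (signal$t_on[i] - t) / 1000
    E <- E * exp(-gap / tau)
    d <- (signal$t_off[i] - signal$t_on[i]) / 1000
    E <- E * exp(-d / tau) + signal$value[i] * tau * (1 - exp(-d / tau))
    t <- signal$t_off[i]
  }
  E
}

#' Assign a memory box to an integration window
#'
#' Windows tile time from stimulus onset in steps of `T_readout`;
#' a box opened at `t_open` belongs to window
#' `floor(t_open / T_readout) + 1`. At the default 425-ms window, a box
#' opened at 330 ms (frame 8) is in window 1 and one opened at 490 ms
#' (frame 12) is in window 2.
#'
#' @param t_open Box opening time(s) in ms (vectorised).
#' @param T_readout Window duration in ms.
#' @return Integer window index (1-based).
#' @export
assign_window <- function(t_open, T_readout = 425) {
  if (any(t_open < 0)) stop("'t_open' must be >= 0")
  if (T_readout <= 0) stop("'T_readout' must be > 0")
  as.integer(floor(t_open / T_readout) + 1)
}

#' Build the memory boxes of a stimulus sequence
#'
#' One box per element of the attended stream (plus the central line):
#' each opens at its element's onset, integrates the element's feature
#' signal, and closes 20 ms later, buffering the integrated evidence
#' unchanged until its window's readout.
#'
#' @param seq An [build_sequence()] result.
#' @param params An [model_params()] object.
#' @return Data frame with one row per box: `location_id`, `t_open`,
#'   `t_close`, `E_buffered` and `window_index`.
#' @export
memory_boxes <- function(seq, params = model_params()) {
  stopifnot(inherits(seq, "sqm_sequence"))
  att <- if (seq$attended_stream == "right") 1L else -1L
  el <- seq$elements[seq$elements$location_id == 0L |
                       sign(seq$elements$location_id) == att, ]
  # E for a single 20-ms pulse of amplitude s: s * tau * (1 - exp(-d/tau))
  pulse <- params$tau * (1 - exp(-(el$duration_ms / 1000) / params$tau))
  data.frame(
    location_id = el$location_id,
    t_open = el$onset_ms,
    t_close = el$onset_ms + el$duration_ms,
    E_buffered = el$offset_sign * pulse,
    window_index = assign_window(el$onset_ms, params$T_readout)
  )
}

#' Summed readout of one integration window
#'
#' At the end of a window the buffered evidence of all its boxes is
#' summed (the attended stream is perceived as one moving object) and
#' normalised by `evidence_scale`. An empty window reads out 0 and
#' drives a chance-level decision.
#'
#' @param boxes A [memory_boxes()] data frame.
#' @param window_index Window to read out (1-based).
#' @param params An [model_params()] object.
#' @return A one-row data frame: `window_index`, `t_readout_ms`,
#'   `summed_evidence`.
#' @export
window_readout <- function(boxes, window_index, params = model_params()) {
  inwin <- boxes$window_index == window_index
  data.frame(
    window_index = as.integer(window_index),
    t_readout_ms = window_index * params$T_readout,
    summed_evidence = sum(boxes$E_buffered[inwin]) / params$evidence_scale
  )
}

#' Stage-1 readouts of a whole sequence
#'
#' Runs the deterministic first stage: builds all memory boxes and reads
#' out every window up to `ceiling(duration / T_readout)`.
#'
#' @inheritParams memory_boxes
#' @return Data frame with one row per window (`window_index`,
#'   `t_readout_ms`, `summed_evidence`).
#' @examples
#' stage1_readouts(build_sequence(get_condition("V-AV8-PV12 [R2]")))
#' @export
stage1_readouts <- function(seq, params = model_params()) {
  boxes <- memory_boxes(seq, params)
  n_win <- max(1L, as.integer(ceiling(seq$duration_ms / params$T_readout)))
  do.call(rbind, lapply(seq_len(n_win), window_readout,
                        boxes = boxes, params = params))
}
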