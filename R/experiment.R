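#' Map a report instruction to an integration window
#'
#' `"R1"` (report the first vernier) reads window 1, `"R2"` (report the
#' second vernier) reads window 2. Naive observers report the percept of
#' the most recent window carrying any evidence — the latest window with
#' non-zero summed evidence, falling back to the last window when every
#' readout is zero.
#'
#' @param readouts A [stage1_readouts()] data frame.
#' @param instruction `"naive"`, `"R1"` or `"R2"`.
#' @return Integer window index.
#' @export
report_window <- function(readouts, instruction = c("naive", "R1", "R2")) {
  instruction <- match.arg(instruction)
  if (nrow(readouts) == 0L) stop("no windows to report from")
  n_win <- max(readouts$window_index)
  if (instruction == "R1") return(1L)
  if (instruction == "R2") {
    if (n_win < 2L)
      stop("instruction 'R2' requires a second window, but only ",
           n_win, " was simulated")
    return(2L)
  }
  nz <- readouts$window_index[abs(readouts$summed_evidence) > 1e-12]
  if (length(nz) == 0L) return(as.integer(n_win))
  as.integer(max(nz))
}

#' Monte-Carlo dominance estimate for one condition
#'
#' Runs the full two-stage model on one condition: the deterministic
#' first stage (memory boxes, windowed readout) once, then `n_trials`
#' independent second-stage decisions on the reported window, each with
#' its own Gaussian input draw and attractor-network run. Dominance is
#' the percentage of choices in accordance with the condition's
#' reference vernier.
#'
#' @param condition A [condition_spec()] object or a name in
#'   [condition_library()].
#' @param params An [model_params()] object.
#' @param n_trials Number of Monte-Carlo trials.
#' @param seed Optional integer seed for reproducibility.
#' @param report Optional instruction override (`"naive"`, `"R1"`,
#'   `"R2"`); defaults to the condition's own instruction.
#' @param net An [decision_network_params()] object.
#' @param keep_trials Keep the per-trial choice table in the result?
#' @return An object of class `"sqm_dominance"`: a list with
#'   `condition_name`, `report`, `window_used`, `n_trials`, `dominance`
#'   (percent), `sem` (binomial standard error, percentage points),
#'   `readouts`, and optionally `trials`.
#' @examples
#' \donttest{
#' simulate_condition("V", n_trials = 500, seed = 1)
#' }
#' @export
simulate_condition <- function(condition, params = model_params(),
                               n_trials = 10000, seed = NULL, report = NULL,
                               net = decision_network_params(),
                               keep_trials = FALSE) {
  if (is.character(condition)) condition <- get_condition(condition)
  stopifnot(inherits(condition, "sqm_condition"))
  if (n_trials < 1) stop("'n_trials' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  instr <- if (is.null(report)) condition$instruction else
    match.arg(report, c("naive", "R1", "R2"))

  seq <- build_sequence(condition)
  readouts <- stage1_readouts(seq, params)
  win <- report_window(readouts, instr)
  ev <- readouts$summed_evidence[readouts$window_index == win]

  inputs <- draw_decision_input(ev, c = params$c, sigma = params$sigma,
                                n = n_trials)
  dec <- simulate_decisions(inputs, mu0 = params$mu0, net = net)
  ref <- reference_sign(condition)
  accord <- (dec$choice == "pro") == (ref > 0)
  p <- mean(accord)
  out <- list(
    condition_name = condition$name,
    report = instr,
    window_used = win,
    n_trials = as.integer(n_trials),
    dominance = 100 * p,
    sem = 100 * sqrt(p * (1 - p) / n_trials),
    readouts = readouts
  )
  if (keep_trials)
    out$trials <- data.frame(trial = seq_len(n_trials), input = inputs,
                             choice = dec$choice, decided = dec$decided,
                             decision_time = dec$decision_time,
                             in_accordance = accord)
  structure(out, class = "sqm_dominance")
}

#' @export
print.sqm_dominance <- function(x, ...) {
  lbl <- if (grepl(sprintf("[%s]", x$report), x$condition_name, fixed = TRUE))
    x$condition_name else sprintf("%s [%s]", x$condition_name, x$report)
  cat(sprintf("%s: dominance %.1f%% (SE %.1f, n = %d, window %d)\n",
              lbl, x$dominance, x$sem, x$n_trials, x$window_used))
  invisible(x)
}

# condition sets per experiment (names in condition_library())
experiment_conditions <- function(id) {
  switch(as.character(id),
    "1" = {
      probes <- c(1, 2, 3, 5, 7, 11, 14)
      c("V",
        sprintf("V-AV%d", probes), sprintf("V-PV%d", probes),
        sprintf("V-AV%d [R1]", probes), sprintf("V-PV%d [R1]", probes))
    },
    "2" = c("V-AV8 [R2]", "V-AV12 [R2]",
            "V-AV8-PV12 [R1]", "V-AV8-PV12 [R2]"),
    "3" = c("PV8-PV12 [R1]", "PV8-PV12 [R2]",
            "PV8-AV12 [R1]", "PV8-AV12 [R2]"),
    "4" = as.vector(outer(paste0("C", 1:5), c(" [R1]", " [R2]"), paste0)),
    stop("'experiment_id' must be 1, 2, 3 or 4")
  )
}

#' Simulate every condition of one experiment
#'
#' Runs [simulate_condition()] over the full condition set of an
#' experiment. For the informed (`[R1]`) conditions of experiment 1 the
#' cohort was heterogeneous in window duration, so those conditions are
#' simulated under both a 425-ms and a 475-ms window (one row each,
#' distinguished by the `T_readout` column); all other rows use the
#' window length in `params`.
#'
#' @param experiment_id 1, 2, 3 or 4.
#' @param params An [model_params()] object.
#' @param n_trials Monte-Carlo trials per condition.
#' @param seed Optional integer seed.
#' @param net An [decision_network_params()] object.
#' @return Data frame: `condition`, `report`, `T_readout`, `n_trials`,
#'   `dominance`, `sem`, `window_used`.
#' @export
reproduce_experiment <- function(experiment_id, params = model_params(),
                                 n_trials = 10000, seed = NULL,
                                 net = decision_network_params()) {
  conds <- experiment_conditions(experiment_id)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in conds) {
    spec <- get_condition(nm)
    T_set <- if (experiment_id == 1 && spec$instruction == "R1")
      c(425, 475) else params$T_readout
    for (Tw in T_set) {
      p <- params
      p$T_readout <- Tw
      est <- simulate_condition(spec, params = p, n_trials = n_trials,
                                net = net)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = est$condition_name, report = est$report,
        T_readout = Tw, n_trials = est$n_trials,
        dominance = est$dominance, sem = est$sem,
        window_used = est$window_used)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
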