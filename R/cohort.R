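#' Observer profiles for a synthetic cohort
#'
#' Each synthetic observer has an individual integration-window duration
#' (real observers differ: some integrate for ~425 ms, others for
#' ~475 ms) and a lapse rate (probability of a random response).
#'
#' @param n_observers Number of observers.
#' @param T_window Window durations in ms, recycled across observers; a
#'   mixed vector such as `c(425, 475)` models a heterogeneous cohort.
#' @param lapse_rate Lapse probability in `[0, 0.5]`, recycled.
#' @return Data frame: `observer_id`, `T_window`, `lapse_rate`.
#' @export
observer_profiles <- function(n_observers, T_window = 425,
                              lapse_rate = 0.02) {
  if (n_observers < 1) stop("'n_observers' must be >= 1")
  if (any(T_window <= 0)) stop("'T_window' must be > 0")
  if (any(lapse_rate < 0 | lapse_rate > 0.5))
    stop("'lapse_rate' must lie in [0, 0.5]")
  data.frame(
    observer_id = sprintf("O%02d", seq_len(n_observers)),
    T_window = rep_len(T_window, n_observers),
    lapse_rate = rep_len(lapse_rate, n_observers)
  )
}

#' Specify a synthetic observer cohort
#'
#' @param conditions Character vector of condition names (entries of
#'   [condition_library()]).
#' @param profiles An [observer_profiles()] data frame.
#' @param trials_per_condition Binary responses per observer and
#'   condition; the default 160 mirrors the block design (80-trial
#'   blocks, each condition measured twice).
#' @param probs Either a named numeric vector of response probabilities
#'   (per condition, in `[0, 1]`), or the string `"model"` to derive each
#'   observer's probability by simulating the two-stage model under that
#'   observer's `T_window`.
#' @param model_args List of arguments passed on to
#'   [simulate_condition()] in `"model"` mode (e.g. `params`, `net`,
#'   `n_trials` for the probability-estimation run).
#' @return An object of class `"sqm_cohort_spec"`.
#' @export
cohort_spec <- function(conditions, profiles = observer_profiles(10),
                        trials_per_condition = 160, probs = "model",
                        model_args = list()) {
  if (trials_per_condition < 1) stop("'trials_per_condition' must be >= 1")
  if (is.numeric(probs)) {
    if (is.null(names(probs)) || !all(conditions %in% names(probs)))
      stop("'probs' must be named with every entry of 'conditions'")
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  } else if (!identical(probs, "model")) {
    stop("'probs' must be a named probability vector or \"model\"")
  }
  structure(list(conditions = conditions, profiles = profiles,
                 trials_per_condition = as.integer(trials_per_condition),
                 probs = probs, model_args = model_args),
            class = "sqm_cohort_spec")
}

#' Generate a synthetic observer cohort
#'
#' Draws per-observer binary responses: in accordance with the reference
#' vernier with probability `p * (1 - lapse) + lapse / 2`, where `p` is
#' either supplied per condition or produced by the two-stage model under
#' the observer's individual window duration.
#'
#' @param spec An [cohort_spec()] object.
#' @param seed Optional integer seed.
#' @return A list with two data frames sharing the analysis-module
#'   schema: `summary` (`observer_id`, `condition`, `report`,
#'   `dominance`, `n_trials`) and `trials` (`observer_id`, `condition`,
#'   `trial`, `in_accordance`).
#' @examples
#' spec <- cohort_spec("V", observer_profiles(3, lapse_rate = 0),
#'   trials_per_condition = 40, probs = c(V = 0.75))
#' generate_cohort(spec, seed = 1)$summary
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sqm_cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  prof <- spec$profiles
  n_tr <- spec$trials_per_condition
  sum_rows <- list()
  trial_rows <- list()
  for (i in seq_len(nrow(prof))) {
    for (cn in spec$conditions) {
      cond <- get_condition(cn)
      p <- if (is.numeric(spec$probs)) {
        spec$probs[[cn]]
      } else {
        args <- spec$model_args
        params <- if (is.null(args$params)) model_params() else args$params
        params$T_readout <- prof$T_window[i]
        args$params <- params
        args$condition <- cond
        if (is.null(args$n_trials)) args$n_trials <- 1000
        do.call(simulate_condition, args)$dominance / 100
      }
      p_eff <- p * (1 - prof$lapse_rate[i]) + prof$lapse_rate[i] / 2
      resp <- stats::runif(n_tr) < p_eff
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        observer_id = prof$observer_id[i], condition = cn,
        report = cond$instruction, dominance = 100 * mean(resp),
        n_trials = n_tr)
      trial_rows[[length(trial_rows) + 1L]] <- data.frame(
        observer_id = prof$observer_id[i], condition = cn,
        trial = seq_len(n_tr), in_accordance = resp)
    }
  }
  list(summary = do.call(rbind, sum_rows),
       trials = do.call(rbind, trial_rows))
}

#' Exclude observers who fail the window-integration prerequisite
#'
#' The window-boundary conditions V-AV8 and V-AV12 serve as a
#' prerequisite check: frame 8 must integrate with the central vernier
#' (dominance near 50%), and if it does not, frame 12 — which is further
#' from the central vernier — must certainly not, i.e. its dominance
#' should favour the flank. An observer whose V-AV8 dominance indicates
#' no integration (<= `av8_max`) while V-AV12 does not indicate flank
#' dominance (> `av12_max`) responds inconsistently with any window
#' duration and is excluded.
#'
#' @param summary A cohort summary data frame (`observer_id`,
#'   `condition`, `dominance`); condition labels must contain entries
#'   matching `cond_av8` and `cond_av12`.
#' @param av8_max Dominance threshold below which V-AV8 counts as "no
#'   integration" (percent).
#' @param av12_max Dominance threshold below which V-AV12 counts as
#'   flank dominance (percent).
#' @param cond_av8,cond_av12 Names of the two prerequisite conditions.
#' @return A list: `retained` (summary rows of retained observers),
#'   `excluded_ids`, and `log` (per-observer prerequisite dominances and
#'   the verdict).
#' @export
exclusion_filter <- function(summary, av8_max = 35, av12_max = 35,
                             cond_av8 = "V-AV8 [R2]",
                             cond_av12 = "V-AV12 [R2]") {
  stopifnot(is.data.frame(summary))
  need <- c(cond_av8, cond_av12)
  if (!all(need %in% summary$condition))
    stop("summary lacks prerequisite conditions: ",
         paste(setdiff(need, summary$condition), collapse = ", "))
  ids <- unique(summary$observer_id)
  dom <- function(id, cn) {
    v <- summary$dominance[summary$observer_id == id & summary$condition == cn]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  log <- data.frame(
    observer_id = ids,
    dominance_av8 = vapply(ids, dom, numeric(1), cn = cond_av8),
    dominance_av12 = vapply(ids, dom, numeric(1), cn = cond_av12)
  )
  log$excluded <- !is.na(log$dominance_av8) & !is.na(log$dominance_av12) &
    log$dominance_av8 <= av8_max & log$dominance_av12 > av12_max
  excluded_ids <- log$observer_id[log$excluded]
  list(retained = summary[!summary$observer_id %in% excluded_ids, ],
       excluded_ids = excluded_ids,
       log = log)
}
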