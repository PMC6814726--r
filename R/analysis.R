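#' Group dominance summary
#'
#' Mean dominance and standard error of the mean across observers, per
#' condition (and report instruction when present).
#'
#' @param per_observer Data frame with at least `condition` and
#'   `dominance` columns (one row per observer and condition), e.g. the
#'   `summary` table of [generate_cohort()].
#' @return Data frame: `condition` (and `report` if supplied),
#'   `n_observers`, `mean_dominance`, `sem`.
#' @examples
#' dominance_summary(data.frame(condition = "V", dominance = c(40, 60)))
#' @export
dominance_summary <- function(per_observer) {
  stopifnot(is.data.frame(per_observer))
  if (nrow(per_observer) == 0L) stop("no observer rows supplied")
  if (!all(c("condition", "dominance") %in% names(per_observer)))
    stop("'per_observer' needs columns 'condition' and 'dominance'")
  if (any(per_observer$dominance < 0 | per_observer$dominance > 100))
    stop("dominance values must lie in [0, 100]")
  keys <- intersect(c("condition", "report"), names(per_observer))
  agg <- function(v) c(n_observers = length(v), mean_dominance = mean(v),
                       sem = stats::sd(v) / sqrt(length(v)))
  sp <- split(per_observer$dominance,
              per_observer[keys], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(sp, agg))
  key_df <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  key_df <- stats::setNames(as.data.frame(key_df), keys)
  res <- cbind(key_df, as.data.frame(out))
  rownames(res) <- NULL
  res$n_observers <- as.integer(res$n_observers)
  res
}

#' Paired comparison of two conditions
#'
#' Classical two-sided paired t test on matched observer dominances,
#' with Cohen's d for paired designs (`mean(diff)/sd(diff)`) and its 95%
#' confidence interval by noncentral-t pivot inversion. Zero-variance
#' differences are flagged as degenerate (no p value is produced).
#'
#' @param cond_a,cond_b Equal-length numeric vectors of per-observer
#'   dominances, matched by observer.
#' @param conf_level Confidence level for the d interval.
#' @return An object of class `"sqm_paired"`: `t_statistic`, `df`,
#'   `p_value`, `cohens_d`, `ci95` (length-2 vector), `n`, `degenerate`.
#' @export
paired_test <- function(cond_a, cond_b, conf_level = 0.95) {
  if (length(cond_a) != length(cond_b))
    stop("'cond_a' and 'cond_b' must be matched samples of equal length")
  n <- length(cond_a)
  if (n < 2) stop("need at least 2 matched observations")
  d_vec <- cond_a - cond_b
  if (stats::sd(d_vec) == 0) {
    return(structure(list(t_statistic = NA_real_, df = n - 1L,
                          p_value = NA_real_, cohens_d = NA_real_,
                          ci95 = c(NA_real_, NA_real_), n = n,
                          degenerate = TRUE),
                     class = "sqm_paired"))
  }
  tt <- stats::t.test(cond_a, cond_b, paired = TRUE)
  t_obs <- unname(tt$statistic)
  d <- mean(d_vec) / stats::sd(d_vec)
  ci <- cohens_d_ci(t_obs, n, conf_level) / sqrt(n)
  structure(list(t_statistic = t_obs, df = as.integer(n - 1L),
                 p_value = tt$p.value, cohens_d = d,
                 ci95 = unname(ci), n = n, degenerate = FALSE),
            class = "sqm_paired")
}

# CI for the noncentrality parameter of a t statistic (pivot inversion):
# lower ncp has P(T <= t_obs | ncp) = 1 - (1-conf)/2, upper the mirror.
cohens_d_ci <- function(t_obs, n, conf_level = 0.95) {
  df <- n - 1
  alpha <- (1 - conf_level) / 2
  bound <- function(prob) {
    # pnt precision warnings at extreme ncp are irrelevant at root scale
    f <- function(ncp)
      suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - prob
    lim <- abs(t_obs) + 10 + 10 * sqrt(df)
    stats::uniroot(f, interval = c(-lim, lim), extendInt = "yes",
                   tol = 1e-8)$root
  }
  c(bound(1 - alpha), bound(alpha))
}

#' @export
print.sqm_paired <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired comparison (n = %d): degenerate (zero-variance differences)\n",
                x$n))
  } else {
    cat(sprintf("t(%d) = %.2f, p = %.3g, Cohen's d = %.2f, 95%% CI [%.2f, %.2f]\n",
                x$df, x$t_statistic, x$p_value, x$cohens_d,
                x$ci95[1], x$ci95[2]))
  }
  invisible(x)
}

#' Holm step-down multiple-comparison adjustment
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04)) # 0.02, 0.04
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Power of a two-sided paired t test
#'
#' Exact power via the noncentral t distribution: with effect size `d`
#' (Cohen's d on the paired differences) and `n` observers, the test
#' statistic under the alternative is noncentral t with `n - 1` degrees
#' of freedom and noncentrality `d * sqrt(n)`; power is the probability
#' that it exceeds the two-sided critical value.
#'
#' @param d Effect size (Cohen's d of the paired differences); `d = 0`
#'   recovers the significance level.
#' @param n Number of observers (pairs); must be >= 2.
#' @param alpha Significance level.
#' @param tails `"two"` (default) or `"one"`.
#' @return Power in `(0, 1)`.
#' @examples
#' power_paired_t(d = 1.47, n = 8) # about 0.943
#' @export
power_paired_t <- function(d, n, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n < 2 || n != floor(n)) stop("'n' must be an integer >= 2")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "two") {
    tcrit <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tcrit, df, ncp = ncp) + stats::pt(-tcrit, df, ncp = ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    1 - stats::pt(tcrit, df, ncp = ncp)
  }
}

#' Smallest sample size reaching a target power
#'
#' @param d Effect size (> 0).
#' @param target_power Desired power, in `(alpha, 1)`.
#' @param alpha Significance level.
#' @param tails `"two"` or `"one"`.
#' @param n_max Search cap; a target not reached by `n_max` observers is
#'   rejected with an error.
#' @return Smallest integer `n` with
#'   `power_paired_t(d, n, alpha, tails) >= target_power`.
#' @examples
#' min_n_for_power(d = 2.0, target_power = 0.90) # 5
#' @export
min_n_for_power <- function(d, target_power, alpha = 0.05,
                            tails = c("two", "one"), n_max = 10000) {
  tails <- match.arg(tails)
  if (d <= 0) stop("'d' must be > 0")
  if (target_power <= alpha || target_power >= 1)
    stop("'target_power' must lie in (alpha, 1)")
  for (n in 2:n_max)
    if (power_paired_t(d, n, alpha, tails) >= target_power) return(n)
  stop("target power not reached by n = ", n_max, " observers")
}
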