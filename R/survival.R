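# Kaplan-Meier estimation, the two-group log-rank test, and expression-based
# stratification by maximally selected rank statistics.

#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive survival times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return A `km_curve` tibble with one row per distinct time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`. S(0) = 1 and the curve drops
#'   only at event times.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) abort("Empty input.")
  if (any(times <= 0)) abort("Survival times must be > 0.")
  if (any(!events %in% c(0, 1))) abort("Events must be 0/1.")
  tt <- sort(unique(times))
  n <- length(times)
  n_risk <- vapply(tt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(tibble(time = tt, n_risk = n_risk, n_event = n_event,
                   n_censor = n_censor, surv = surv),
            class = c("km_curve", class(tibble())))
}

# Core log-rank machinery shared by the test and the cutpoint scan: observed
# and expected events in group 1 and the hypergeometric variance, summed over
# distinct event times.
logrank_oev <- function(times, events, group1) {
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V)
}

#' Two-group log-rank test
#'
#' Standard log-rank: observed minus expected events summed over distinct
#' event times, hypergeometric variance, chi-square with 1 df.
#'
#' @param times_a,events_a,times_b,events_b Times and event indicators of the
#'   two groups.
#' @return A list: `chi_square`, `p`, `observed`, `expected` (group A), `var`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b)) abort("Both groups must be non-empty.")
  times <- c(times_a, times_b)
  events <- c(events_a, events_b)
  grp_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  oev <- logrank_oev(times, events, grp_a)
  if (oev$V == 0) {
    warn("No events (or no variance); log-rank statistic is 0.")
    return(list(chi_square = 0, p = 1, observed = oev$O, expected = oev$E,
                var = 0))
  }
  chi <- (oev$O - oev$E)^2 / oev$V
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE),
       observed = oev$O, expected = oev$E, var = oev$V)
}

#' Optimal expression cutpoint by maximally selected rank statistics
#'
#' Scans every observed expression value whose induced high/low split leaves
#' at least `minprop` of the subjects on each side, computes the standardized
#' log-rank statistic (O - E) / sqrt(V) for high vs low at each candidate,
#' and returns the threshold maximising the absolute standardized statistic
#' (ties: lower threshold). The selection across many candidate thresholds
#' inflates the naive log-rank p-value at the chosen cutpoint, so that
#' p-value is reported with a `selection_caveat` flag rather than silently
#' corrected.
#'
#' @param expr_values Numeric expression values, one per subject.
#' @param times,events Survival times and event indicators, aligned with
#'   `expr_values`.
#' @param minprop Minimum fraction of subjects in each stratum (default 0.1).
#' @return A `surv_cutpoint_fit` list: `threshold`, `statistic` (standardized,
#'   signed for high vs low), `n_high`, `n_low`, `minprop`, `p_naive`,
#'   `selection_caveat`, and the two stratum [km_estimate()] curves.
#' @export
optimal_cutpoint <- function(expr_values, times, events, minprop = 0.1) {
  n <- length(expr_values)
  if (n < 10) abort("Need >= 10 subjects.")
  if (any(!is.finite(expr_values))) abort("Expression values must be finite.")
  stopifnot(length(times) == n, length(events) == n)
  vals <- sort(unique(expr_values))
  min_n <- minprop * n
  stats <- rep(NA_real_, length(vals))
  for (i in seq_along(vals)) {
    high <- expr_values > vals[i]
    if (sum(high) < min_n || sum(!high) < min_n) next
    oev <- logrank_oev(times, events, high)
    if (oev$V > 0) stats[i] <- (oev$O - oev$E) / sqrt(oev$V)
  }
  if (all(is.na(stats))) {
    abort("No candidate threshold satisfies `minprop` on both sides.")
  }
  best <- which(abs(stats) == max(abs(stats), na.rm = TRUE))
  if (length(best) > 1) {
    inform("optimal_cutpoint: tie between thresholds; taking the lower one.")
  }
  i_star <- min(best)
  thr <- vals[i_star]
  high <- expr_values > thr
  lr <- logrank_test(times[high], events[high], times[!high], events[!high])
  structure(list(threshold = thr, statistic = stats[i_star],
                 n_high = sum(high), n_low = sum(!high), minprop = minprop,
                 p_naive = lr$p, selection_caveat = TRUE,
                 n_candidates = sum(!is.na(stats)),
                 km_high = km_estimate(times[high], events[high]),
                 km_low = km_estimate(times[!high], events[!high])),
            class = "surv_cutpoint_fit")
}

#' @export
print.surv_cutpoint_fit <- function(x, ...) {
  cat(sprintf("<surv_cutpoint_fit> threshold = %.4g (|z| = %.2f), %d high / %d low\n",
              x$threshold, abs(x$statistic), x$n_high, x$n_low))
  cat(sprintf("naive log-rank p = %.3g (uncorrected for cutpoint selection over %d candidates)\n",
              x$p_naive, x$n_candidates))
  invisible(x)
}

#' @rdname optimal_cutpoint
#' @param x A `surv_cutpoint_fit`.
#' @param ... Unused.
#' @export
tidy.surv_cutpoint_fit <- function(x, ...) {
  bind_rows(
    mutate(as_tibble(x$km_high), stratum = "high"),
    mutate(as_tibble(x$km_low), stratum = "low")
  )
}

#' @rdname optimal_cutpoint
#' @export
glance.surv_cutpoint_fit <- function(x, ...) {
  tibble(threshold = x$threshold, statistic = x$statistic,
         n_high = x$n_high, n_low = x$n_low, minprop = x$minprop,
         p_naive = x$p_naive, selection_caveat = x$selection_caveat,
         n_candidates = x$n_candidates)
}
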