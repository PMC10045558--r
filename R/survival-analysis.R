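## Animal survival analysis ---------------------------------------------------
##
## Grouped time-to-event records (days since implantation, event = death or
## euthanasia, censored = alive at study end).  Kaplan-Meier estimation and
## the asymptotic log-rank test are delegated to the survival package; the
## exact permutation log-rank p-value, median conventions and the percent
## increase in life span (%ILS) summary are implemented here.

#' Kaplan-Meier curve
#'
#' Product-limit estimator for one group.  Thin wrapper around
#' [survival::survfit()] exposing the step function and the median
#' convention used in the report tables (for an even number of uncensored
#' animals whose curve sits exactly at 0.5, the median is the midpoint of the
#' two central times).
#'
#' @param time Positive times in days.
#' @param event Event indicator: 1/TRUE = death or euthanasia,
#'   0/FALSE = censored (alive at study end). Defaults to all events.
#' @return An object of class `km_curve` with elements `time`, `surv`,
#'   `n_risk`, `n_event`, and the underlying `survfit` object as `fit`.
#' @export
#' @examples
#' km <- km_curve(c(26, 28, 30, 32, 34))
#' km_survival_at(km, 30)   # 0.4
km_curve <- function(time, event = rep(1L, length(time))) {
  check_numeric_vec(time, "time")
  if (any(time <= 0))
    stop_borondose("survival times must be > 0", "borondose_validation_error")
  event <- as.integer(event)
  if (length(event) != length(time) || any(!event %in% c(0L, 1L)))
    stop_borondose("'event' must be a 0/1 vector matching 'time'",
                   "borondose_validation_error")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, n = length(time), fit = fit),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation: `S(t)` with `S(0) = 1`.
#'
#' @param curve A [km_curve()].
#' @param t Times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  check_numeric_vec(t, "t", min = 0)
  vapply(t, function(ti) {
    i <- which(curve$time <= ti)
    if (!length(i)) 1 else curve$surv[max(i)]
  }, 0)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d animals, %d events, median %s days\n",
              x$n, sum(x$n_event),
              {
                m <- median_survival(x)
                if (is.na(m)) "not reached" else format(m)
              }))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$fit, xlab = "Days", ylab = "Survival probability", ...)
  invisible(x)
}

#' Median survival time
#'
#' Smallest time with `S(t) <= 0.5`; when the curve sits exactly at 0.5 over
#' an interval (even n, no ties at the centre) the midpoint of the interval
#' is reported, matching the usual table convention.  `NA` (with attribute
#' `reached = FALSE`) when the curve never falls to 0.5.
#'
#' @param curve A [km_curve()] object (or times, passed to [km_curve()]).
#' @return Median in days, or `NA` if not reached.
#' @export
median_survival <- function(curve) {
  if (!inherits(curve, "km_curve")) curve <- km_curve(curve)
  med <- unname(stats::quantile(curve$fit, probs = 0.5)$quantile)
  if (is.na(med)) return(structure(NA_real_, reached = FALSE))
  med
}

#' Percent increase in life span
#'
#' `(mst_group - mst_ref) * 100 / mst_ref`.
#'
#' @param mst_group Group median survival time, days.
#' @param mst_ref Reference (untreated) median survival time, days (> 0).
#' @return Percent ILS (full precision; round to one decimal for reports).
#' @export
#' @examples
#' percent_ils(35, 30)  # 16.67
percent_ils <- function(mst_group, mst_ref) {
  if (is.na(mst_group) || is.na(mst_ref)) return(NA_real_)
  check_number(mst_ref, "mst_ref")
  if (mst_ref <= 0)
    stop_borondose("'mst_ref' must be > 0", "borondose_validation_error")
  check_number(mst_group, "mst_group", min = 0)
  (mst_group - mst_ref) * 100 / mst_ref
}

#' Two-group log-rank test
#'
#' Standard log-rank test with hypergeometric variance.  The asymptotic
#' p-value comes from the chi-square(1) reference distribution (via
#' [survival::survdiff()]); `p_method = "permutation"` computes the exact
#' permutation p-value by enumerating all group-label assignments (up to
#' `max_enum` assignments; larger problems fall back to `n_perm` random
#' permutations).
#'
#' @param time,event Survival times and 0/1 event flags.
#' @param group Two-level group labels.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param max_enum Enumeration cap for the exact permutation p (default
#'   20000 assignments).
#' @param n_perm Monte Carlo permutations beyond the cap (default 10000).
#' @param seed Optional seed for the Monte Carlo fallback.
#' @return List with `chisq`, `p_value`, `p_method`, `significant` (0.05),
#'   and `n_assignments` (permutation mode only).
#' @export
logrank_test <- function(time, event, group, p_method = c("asymptotic", "permutation"),
                         max_enum = 20000L, n_perm = 10000L, seed = NULL) {
  p_method <- match.arg(p_method)
  check_numeric_vec(time, "time")
  if (any(time <= 0))
    stop_borondose("survival times must be > 0", "borondose_validation_error")
  event <- as.integer(event)
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop_borondose("'group' must have exactly two levels", "borondose_validation_error")
  if (sum(event) < 1L)
    stop_borondose("no events: log-rank test undefined", "borondose_validation_error")
  chisq_of <- function(g) {
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  }
  obs <- chisq_of(group)
  if (p_method == "asymptotic") {
    p <- stats::pchisq(obs, 1, lower.tail = FALSE)
    return(list(chisq = obs, p_value = p, p_method = "asymptotic",
                significant = p < 0.05))
  }
  n <- length(time)
  n1 <- sum(group == levels(group)[1L])
  n_assign <- choose(n, n1)
  if (n_assign <= max_enum) {
    idx <- utils::combn(n, n1)
    stats_perm <- apply(idx, 2L, function(i) {
      g <- factor(ifelse(seq_len(n) %in% i, "a", "b"))
      chisq_of(g)
    })
    p <- mean(stats_perm >= obs - 1e-12)
  } else {
    stats_perm <- with_preserved_seed(seed, {
      vapply(seq_len(n_perm), function(k) chisq_of(sample(group)), 0)
    })
    p <- (1 + sum(stats_perm >= obs - 1e-12)) / (n_perm + 1)
    n_assign <- n_perm
  }
  list(chisq = obs, p_value = p, p_method = "permutation",
       significant = p < 0.05, n_assignments = n_assign)
}

#' Group survival summary with %ILS
#'
#' Per-group summary in the layout of a preclinical survival table: n,
#' mean +/- SD of the recorded times, Kaplan-Meier median, 95% CI of the
#' median, %ILS relative to a reference group, and the pairwise log-rank
#' p-value against that reference.
#'
#' @param records Data frame with columns `group`, `animal_id`, `days`,
#'   `event` (1 = death/euthanasia, 0 = censored).
#' @param ref_group Reference group label for %ILS and pairwise tests.
#' @param ref_stat Reference location used for %ILS: `"median"` (default,
#'   the definition of %ILS) or `"mean"`.
#' @return Data frame, one row per group (reference first), with columns
#'   `group`, `n`, `mean`, `sd`, `median`, `ci_low`, `ci_high`, `pct_ils`,
#'   `p_logrank`.
#' @export
survival_summary <- function(records, ref_group, ref_stat = c("median", "mean")) {
  ref_stat <- match.arg(ref_stat)
  req <- c("group", "days", "event")
  if (!all(req %in% names(records)))
    stop_borondose("survival table needs columns group, days, event",
                   "borondose_validation_error")
  if (!ref_group %in% records$group)
    stop_borondose(sprintf("reference group '%s' not present", ref_group),
                   "borondose_validation_error")
  groups <- unique(c(ref_group, as.character(records$group)))
  ref <- records[records$group == ref_group, ]
  ref_curve <- km_curve(ref$days, ref$event)
  ref_loc <- if (ref_stat == "median") median_survival(ref_curve) else mean(ref$days)
  rows <- lapply(groups, function(g) {
    d <- records[records$group == g, ]
    cv <- km_curve(d$days, d$event)
    qt <- stats::quantile(cv$fit, probs = 0.5)
    med <- median_survival(cv)
    data.frame(
      group = g, n = nrow(d),
      mean = mean(d$days),
      sd = if (nrow(d) > 1L) stats::sd(d$days) else NA_real_,
      median = as.numeric(med),
      ci_low = unname(qt$lower), ci_high = unname(qt$upper),
      pct_ils = if (g == ref_group) NA_real_
                else percent_ils(as.numeric(med), as.numeric(ref_loc)),
      p_logrank = if (g == ref_group) NA_real_ else {
        both <- rbind(d, ref)
        logrank_test(both$days, both$event, both$group)$p_value
      },
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
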