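# Cohort-level statistics: Kaplan-Meier lifespan estimation, log-rank
# group comparison, and per-descriptor one-way ANOVA with Fisher's LSD
# post hoc. Implemented from the defining formulas; the test suite checks
# them against the survival package and hand-worked tables.

#' Construct a survival table
#'
#' Per-group lifespan records. Deaths are recorded on the day of the vial
#' transfer at which they were observed; flies alive at the end of the
#' experiment (or lost, e.g. having lost climbing ability) are
#' right-censored at their last observation.
#'
#' @param group Group label (single string).
#' @param lifespan_days Numeric vector of lifespans in days (>= 0).
#' @param event Logical/0-1 vector: `TRUE`/1 = died, `FALSE`/0 = censored.
#'   Defaults to all died.
#' @return Data frame of class `survival_table` with columns `group`,
#'   `lifespan_days`, `event`.
#' @export
survival_table <- function(group, lifespan_days, event = NULL) {
  if (is.null(event)) event <- rep(TRUE, length(lifespan_days))
  if (!is.numeric(lifespan_days) || any(!is.finite(lifespan_days)) ||
      any(lifespan_days < 0))
    stop_vt("'lifespan_days' must be finite and >= 0")
  if (length(event) != length(lifespan_days))
    stop_vt("'event' must match 'lifespan_days' in length")
  structure(data.frame(group = rep_len(as.character(group),
                                       length(lifespan_days)),
                       lifespan_days = as.numeric(lifespan_days),
                       event = as.logical(event)),
            class = c("survival_table", "data.frame"))
}

#' Kaplan-Meier estimate with lifetime summaries
#'
#' Product-limit estimator of the survival function, plus the three
#' lifetime summaries: mean lifetime (area under the survival curve up to
#' the largest event time, the standard restricted-mean convention),
#' median lifetime (smallest time with S(t) <= 0.5; `NA` = not reached),
#' and maximum lifetime (largest observed death time).
#'
#' @param table A [survival_table()] (single group).
#' @return List of class `km_fit`: `time`, `n_risk`, `n_event`, `surv`
#'   (step function values after each event time), `mean_lifetime`,
#'   `median_lifetime`, `max_lifetime`, `n`.
#' @export
km_estimate <- function(table) {
  if (!nrow(table)) stop_vt("empty survival table")
  t <- table$lifespan_days; e <- table$event
  times <- sort(unique(t[e]))
  n <- length(t)
  if (!length(times)) {
    return(structure(list(time = numeric(0), n_risk = integer(0),
                          n_event = integer(0), surv = numeric(0),
                          mean_lifetime = NA_real_, median_lifetime = NA_real_,
                          max_lifetime = NA_real_, n = n),
                     class = "km_fit"))
  }
  n_risk <- vapply(times, function(tt) sum(t >= tt), numeric(1))
  n_event <- vapply(times, function(tt) sum(t == tt & e), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # area under the step function from 0 to the largest event time
  prev_t <- c(0, times[-length(times)])
  prev_s <- c(1, surv[-length(surv)])
  mean_lt <- sum(prev_s * (times - prev_t))
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(time = times, n_risk = n_risk, n_event = n_event,
                 surv = surv, mean_lifetime = mean_lt, median_lifetime = med,
                 max_lifetime = max(times), n = n),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, %d event time(s); mean %.3g, median %s, max %.3g days\n",
              x$n, length(x$time), x$mean_lifetime,
              if (is.na(x$median_lifetime)) "not reached"
              else format(x$median_lifetime), x$max_lifetime))
  invisible(x)
}

#' Log-rank test between two survival curves
#'
#' Standard two-group log-rank chi-square (1 df) from observed minus
#' expected events accumulated over the pooled distinct event times, with
#' the hypergeometric variance.
#'
#' @param a,b [survival_table()] objects, each with at least one event.
#' @return List of class `comparison_result`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (per group).
#' @export
log_rank <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop_vt("both groups must be non-empty")
  if (!any(a$event) && !any(b$event)) stop_vt("no events in either group")
  t1 <- a$lifespan_days; e1 <- a$event
  t2 <- b$lifespan_days; e2 <- b$event
  times <- sort(unique(c(t1[e1], t2[e2])))
  n1 <- vapply(times, function(tt) sum(t1 >= tt), numeric(1))
  n2 <- vapply(times, function(tt) sum(t2 >= tt), numeric(1))
  d1 <- vapply(times, function(tt) sum(t1 == tt & e1), numeric(1))
  d2 <- vapply(times, function(tt) sum(t2 == tt & e2), numeric(1))
  n <- n1 + n2; d <- d1 + d2
  expect1 <- d * n1 / n
  varj <- ifelse(n > 1, d * (n1 / n) * (n2 / n) * (n - d) / (n - 1), 0)
  O <- sum(d1); E <- sum(expect1); V <- sum(varj)
  stat <- if (V > 0) (O - E)^2 / V else 0
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = c(O, sum(d2)), expected = c(E, sum(d) - E)),
            class = "comparison_result")
}

#' One-way ANOVA with Fisher's LSD post hoc
#'
#' Per-descriptor univariate one-way ANOVA across treatment groups,
#' followed by Fisher's protected least-significant-difference pairwise
#' t-tests using the pooled within-group mean square (no further
#' multiplicity correction; protection comes from requiring a significant
#' F at the 95% confidence level before flagging pairs).
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   descriptor values (>= 2 groups, each with >= 2 values).
#' @return List of class `comparison_result`: `statistic` (F), `df`
#'   (between, within), `p_value`, and `pairwise` (data frame `group_a`,
#'   `group_b`, `p`, `significant`).
#' @export
anova_fisher_lsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_vt("'groups' must be a named list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop_vt("every group needs >= 2 values (group '%s' has %d)",
            names(groups)[which(sizes < 2L)[1L]], min(sizes))
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  k <- length(groups)
  n_i <- as.numeric(sizes)
  N <- sum(n_i)
  m_i <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * m_i) / N
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- k - 1; df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    f_stat <- if (ms_b == 0) 0 else Inf
    p <- if (ms_b == 0) 1 else 0
  } else {
    f_stat <- ms_b / ms_w
    p <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  }
  pairs <- utils::combn(seq_len(k), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c_) {
    i <- pairs[1, c_]; j <- pairs[2, c_]
    se <- sqrt(ms_w * (1 / n_i[i] + 1 / n_i[j]))
    p_ij <- if (se == 0) {
      if (m_i[i] == m_i[j]) 1 else 0
    } else {
      2 * stats::pt(abs(m_i[i] - m_i[j]) / se, df_w, lower.tail = FALSE)
    }
    data.frame(group_a = labels[i], group_b = labels[j], p = p_ij)
  }))
  pw$significant <- p < 0.05 & pw$p < 0.05
  structure(list(statistic = f_stat, df = c(df_b, df_w), p_value = p,
                 pairwise = pw),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, paste(x$df, collapse = ","), x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Fisher's LSD):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Read a lifespan CSV into survival tables
#'
#' Expects columns `group,lifespan_days,event` (event: 1 = died,
#' 0 = censored).
#'
#' @param path CSV file path.
#' @return Named list of [survival_table()] objects, one per group.
#' @export
read_lifespans <- function(path) {
  df <- read_csv_checked(path, c("group", "lifespan_days", "event"),
                         "lifespan", c("lifespan_days", "event"))
  lapply(split(df, df$group), function(g)
    survival_table(g$group[1L], g$lifespan_days, g$event != 0))
}
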