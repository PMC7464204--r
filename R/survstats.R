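#' Kaplan-Meier product-limit estimate
#'
#' Single-group product-limit estimator of the survival function from
#' right-censored follow-up. Ties between an event and a censoring at the
#' same time are resolved events-first (the standard convention), so the
#' censored observation is still in the risk set for that event.
#'
#' @param time Non-negative follow-up times (months by convention).
#' @param event 1 = event observed, 0 = censored.
#' @return An object of class `"km_estimate"`: data.frame with one row per
#'   observed time, columns `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @examples
#' km <- km_curve(c(1, 2, 3), c(1, 0, 1))
#' km$surv   # 2/3 after t=1, 0 after t=3
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(time < 0)) stop("survival times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' @export
plot.km_estimate <- function(x, xlab = "months", ylab = "survival", ...) {
  tt <- c(0, x$time)
  ss <- c(1, x$surv)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  cens <- x$n_censor > 0
  graphics::points(x$time[cens], x$surv[cens], pch = 3)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Compares censored survival between two groups via observed-minus-expected
#' event counts summed over distinct event times, with the hypergeometric
#' variance; the statistic is chi-square with 1 degree of freedom.
#'
#' @param time Follow-up times for all samples.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return An object of class `"logrank_test"`: list with `statistic`, `df`,
#'   `p_value`, and per-group `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("survival times must be non-negative")
  group <- as.character(group)
  if (length(unique(group)) != 2L) stop("exactly 2 groups are required")
  if (sum(event) == 0) stop("log-rank test needs at least one observed event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  structure(list(statistic = unname(sd$chisq), df = 1L,
                 p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
                 observed = stats::setNames(sd$obs, sub("^group=", "", names(sd$n))),
                 expected = stats::setNames(sd$exp, sub("^group=", "", names(sd$n)))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = x$expected)
  print(round(tab, 2))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on an
#' r x c contingency table of non-negative integer counts, with
#' `df = (r - 1)(c - 1)`.
#'
#' @param table Matrix of non-negative counts with positive row and column
#'   margins.
#' @return An object of class `"chisq_independence"`: list with `statistic`,
#'   `df`, `p_value`, and the `expected` count table.
#' @examples
#' chi_square_independence(matrix(c(30, 10, 10, 30), 2))  # statistic = 20
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integer counts")
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("table must be at least 2 x 2")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("every row and column margin must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), expected = ct$expected),
            class = "chisq_independence")
}

#' @export
print.chisq_independence <- function(x, ...) {
  cat(sprintf("Pearson chi-square: statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson correlation between two numeric vectors
#'
#' Sample Pearson correlation, e.g. between a BCCP posterior and a metagene
#' score across samples.
#'
#' @param x,y Equal-length numeric vectors (>= 3 values, non-constant).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired values are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation is undefined for a constant vector")
  }
  stats::cor(x, y, method = "pearson")
}
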