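#' Kaplan-Meier survival curve
#'
#' Product-limit estimate via \code{survival::survfit}. Ties between events
#' and censorings at the same time are handled with the standard convention
#' (events precede censorings).
#'
#' @param time positive follow-up times.
#' @param event 0/1 indicator (1 = death).
#' @param all_times if FALSE (default) only times with at least one event are
#'   returned; otherwise every risk-set change.
#' @return data.frame: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{survival} (right-continuous step values).
#' @export
kmCurve <- function(time, event, all_times = FALSE) {
  if (length(time) == 0) stop("empty survival input")
  if (length(time) != length(event)) stop("time/event length mismatch")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  if (!all_times) out <- out[out$n_event > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median survival from a Kaplan-Meier fit
#'
#' Smallest time at which the survival estimate drops to 0.5 or below
#' (NA when the curve never reaches 0.5).
#'
#' @param time,event survival input as in \code{\link{kmCurve}}.
#' @return median survival time or NA.
#' @export
kmMedian <- function(time, event) {
  cv <- kmCurve(time, event)
  hit <- which(cv$survival <= 0.5)
  if (length(hit) == 0) return(NA_real_)
  cv$time[hit[1]]
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank statistic via \code{survival::survdiff};
#' df = number of groups - 1, p from the upper chi-square tail.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups, >= 1 event overall).
#' @return list: \code{chi_square}, \code{df}, \code{p_value}.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("at least two non-empty groups required")
  if (sum(event) == 0) stop("no events; log-rank undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(chi_square = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Pairwise log-rank tests
#'
#' Applies the two-group log-rank test to every pair of groups. P-values are
#' unadjusted by default, mirroring how pairwise stratification contrasts are
#' usually reported; Bonferroni adjustment is available.
#'
#' @param time,event survival data.
#' @param group group labels.
#' @param p_adjust \code{"none"} (default) or \code{"bonferroni"}.
#' @return symmetric matrix of p-values with NA diagonal.
#' @export
pairwiseLogrank <- function(time, event, group, p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  group <- as.factor(group)
  lv <- levels(droplevels(group))
  if (length(lv) < 2) stop("at least two groups required")
  P <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  pairs <- utils::combn(length(lv), 2)
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    sel <- group %in% lv[c(i, j)]
    p <- logrankTest(time[sel], event[sel], droplevels(group[sel]))$p_value
    P[i, j] <- P[j, i] <- p
  }
  if (p_adjust == "bonferroni")
    P <- pmin(P * ncol(pairs), 1)
  P
}
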