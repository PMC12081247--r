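#' Cumulative/dynamic AUC at a horizon under censoring
#'
#' Discrimination of a risk score for the endpoint "death by the horizon":
#' cases are patients with an observed event at or before the horizon,
#' controls are patients still under observation past the horizon. Censoring
#' is handled by inverse-probability-of-censoring weights from the
#' Kaplan-Meier estimator of the censoring distribution G: cases are
#' weighted by 1/G(T-), controls by 1/G(horizon). With no censoring every
#' weight is 1 and the estimate equals the plain binary AUC. Tied risk
#' scores count 1/2.
#'
#' @param risk predicted risk scores (higher = higher mortality risk).
#' @param time,event survival outcome.
#' @param horizon_months evaluation horizon (must lie within the observed
#'   time range, with at least one case and one control).
#' @param ipcw use censoring weights (TRUE, default) or the simple
#'   complete-case variant that drops patients censored before the horizon.
#' @return AUC in [0, 1].
#' @export
ipcwAUC <- function(risk, time, event, horizon_months, ipcw = TRUE) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  case <- time <= horizon_months & event == 1
  control <- time > horizon_months
  if (!any(case)) stop("no events before the horizon")
  if (!any(control)) stop("no subjects under observation past the horizon")
  if (ipcw) {
    # KM of the censoring law (censoring as the event)
    gf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
    Gfun <- stats::stepfun(gf$time, c(1, gf$surv), right = FALSE)
    Gminus <- function(t) {   # left limit G(t-)
      vapply(t, function(ti) {
        prev <- gf$time < ti
        if (!any(prev)) 1 else min(1, gf$surv[max(which(prev))])
      }, numeric(1))
    }
    w_case <- 1 / pmax(Gminus(time[case]), 1e-10)
    w_ctrl <- rep(1 / pmax(Gfun(horizon_months), 1e-10), sum(control))
  } else {
    w_case <- rep(1, sum(case))
    w_ctrl <- rep(1, sum(control))
  }
  rc <- risk[case]; rk <- risk[control]
  num <- 0
  for (i in seq_along(rc)) {
    gt <- sum(w_ctrl[rc[i] > rk])
    eq <- sum(w_ctrl[rc[i] == rk])
    num <- num + w_case[i] * (gt + 0.5 * eq)
  }
  num / (sum(w_case) * sum(w_ctrl))
}

#' Mean and sd of per-model AUCs
#'
#' Aggregates the horizon AUCs of the Cox, Lasso-Cox and forest models into
#' the single summary reported per feature tier.
#'
#' @param aucs named numeric vector with entries for \code{cox},
#'   \code{cox_lasso} and \code{rsf}.
#' @return named numeric: \code{mean}, \code{sd}.
#' @export
meanModelAUC <- function(aucs) {
  need <- c("cox", "cox_lasso", "rsf")
  if (!all(need %in% names(aucs)))
    stop("aucs must carry entries for ", paste(need, collapse = ", "))
  v <- as.numeric(aucs[need])
  if (any(!is.finite(v))) stop("non-finite AUC")
  c(mean = mean(v), sd = sd(v))
}

#' Summed concordance across the three model families per K_f
#'
#' @param sweep_summary output of \code{\link{summarizeSweep}}; every K_f
#'   must carry all three model families.
#' @return data.frame \code{kf}, \code{summed_cindex}, with the arg-max K_f
#'   in attribute \code{"best_kf"}.
#' @export
summedCindexCurve <- function(sweep_summary) {
  need <- c("cox", "cox_lasso", "rsf")
  counts <- table(sweep_summary$kf, sweep_summary$model)
  if (!all(need %in% colnames(counts)) ||
      any(counts[, need] != 1))
    stop("every K_f needs exactly one summary per model family")
  kfs <- sort(unique(sweep_summary$kf))
  summed <- vapply(kfs, function(kf)
    sum(sweep_summary$mean[sweep_summary$kf == kf &
                             sweep_summary$model %in% need]),
    numeric(1))
  out <- data.frame(kf = kfs, summed_cindex = summed)
  attr(out, "best_kf") <- kfs[which.max(summed)]
  out
}
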