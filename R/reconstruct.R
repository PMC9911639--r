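#' Reconstruct pseudo individual-patient data from a published curve
#'
#' Rebuilds (time, event) records from digitized survival-curve coordinates
#' and a numbers-at-risk table, in the spirit of the Hoyle & Henley / Guyot
#' family of algorithms: within each at-risk interval, events are allocated
#' at the digitized coordinate times from the relative drops of the curve,
#' and censorings are spread with proportional spacing across the interval,
#' iterating the number of censorings until the reconstructed number at risk
#' at the next at-risk time matches the published count. Patients still at
#' risk after the last coordinate are censored there.
#'
#' The dialect implemented here: coordinates in the half-open interval
#' `(T_k, T_{k+1}]` belong to interval `k`; candidate events at a coordinate
#' with survival `S_j` are `round(n * (1 - S_j / S_prev))`, where `S_prev` is
#' the reconstructed Kaplan-Meier level before the coordinate (so rounding
#' drift self-corrects); censorings are placed at the midpoints of equal
#' subdivisions of the interval.
#'
#' @param curve Data frame with columns `time_months` and `survival`
#'   (non-increasing; a (0, 1) first coordinate is implied if absent).
#' @param at_risk Data frame with columns `time_months` and `n_at_risk`
#'   (non-increasing counts at increasing times).
#' @param total_n Total sample size; defaults to the first at-risk count.
#' @return Data frame with columns `time` and `event` (1 = event,
#'   0 = censored), one row per reconstructed patient (`total_n` rows).
#' @export
reconstruct_ipd <- function(curve, at_risk, total_n = NULL) {
  tc <- curve$time_months
  S <- curve$survival
  if (is.unsorted(tc, strictly = TRUE))
    stop("curve coordinates must have strictly increasing times", call. = FALSE)
  if (any(diff(S) > 1e-12))
    stop("curve survival must be non-increasing", call. = FALSE)
  if (any(S < 0 | S > 1)) stop("survival must lie in [0, 1]", call. = FALSE)
  Ta <- at_risk$time_months
  Na <- at_risk$n_at_risk
  if (is.unsorted(Ta, strictly = TRUE))
    stop("at-risk times must be strictly increasing", call. = FALSE)
  if (any(diff(Na) > 0))
    stop("at-risk counts must be non-increasing over time", call. = FALSE)
  total_n <- total_n %||% Na[1]
  if (Na[1] > total_n) stop("first at-risk count exceeds total_n", call. = FALSE)

  # drop the implied (<= first at-risk time, S = 1) anchor coordinates
  keep <- tc > Ta[1] | S < 1
  tc <- tc[keep]; S <- S[keep]

  ev_times <- numeric(0)
  cs_times <- numeric(0)
  n_cur <- Na[1]
  S_run <- 1
  K <- length(Ta)

  # walk one interval for a given censoring count; returns the bookkeeping
  walk <- function(tj, Sj, n0, S0, c_guess, t_lo, t_span) {
    ct <- if (c_guess > 0)
      t_lo + (seq_len(c_guess) - 0.5) / c_guess * t_span
    else numeric(0)
    d_out <- numeric(length(tj))
    n <- n0; Sp <- S0
    ci <- 1
    for (j in seq_along(tj)) {
      while (ci <= length(ct) && ct[ci] < tj[j]) {   # censored before event
        n <- n - 1; ci <- ci + 1
      }
      d <- if (Sp > 0) round(n * (1 - Sj[j] / Sp)) else 0
      d <- max(0, min(d, n))
      if (n > 0 && d > 0) Sp <- Sp * (1 - d / n)
      d_out[j] <- d
      n <- n - d
    }
    n <- n - (length(ct) - ci + 1)                   # censored after last event
    list(d = d_out, n_end = max(n, 0), S_end = Sp, cens = ct)
  }

  for (k in seq_len(K)) {
    t_lo <- Ta[k]
    t_hi <- if (k < K) Ta[k + 1] else max(c(tc, Ta))
    in_k <- tc > t_lo & tc <= t_hi
    tj <- tc[in_k]; Sj <- S[in_k]
    t_span <- max(t_hi - t_lo, .Machine$double.eps)
    c_guess <- 0
    res <- walk(tj, Sj, n_cur, S_run, c_guess, t_lo, t_span)
    if (k < K) {
      for (iter in 1:25) {
        diff_n <- res$n_end - Na[k + 1]
        if (diff_n == 0) break
        c_new <- max(0, min(c_guess + diff_n, n_cur))
        if (c_new == c_guess) break
        c_guess <- c_new
        res <- walk(tj, Sj, n_cur, S_run, c_guess, t_lo, t_span)
      }
    }
    ev_times <- c(ev_times, rep(tj, res$d))
    cs_times <- c(cs_times, res$cens)
    n_cur <- res$n_end
    S_run <- res$S_end
  }
  # survivors at the end of follow-up are administratively censored there
  if (n_cur > 0) cs_times <- c(cs_times, rep(max(c(tc, Ta)), n_cur))
  # patients never entering the at-risk table (total_n > Na[1]) are censored
  # before the first at-risk time (rare; only when the table starts late)
  if (total_n > Na[1]) cs_times <- c(cs_times, rep(Ta[1], total_n - Na[1]))

  out <- data.frame(time = c(ev_times, cs_times),
                    event = rep(c(1, 0), c(length(ev_times),
                                           length(cs_times))))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}
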