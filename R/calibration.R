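#' Estimate the overall hazard ratio between two simulated arms
#'
#' Semiparametric proportional-hazards (Cox partial-likelihood) estimate of
#' the treatment-arm effect on a survival endpoint, used as the "outHR"
#' measurement during calibration: the whole-arm hazard ratio of the
#' treatment arm versus the comparator.
#'
#' @param time_trt,event_trt Times and event indicators of the treatment arm
#'   (`event_*` defaults to all events; infinite times are treated as
#'   censored at the largest finite time).
#' @param time_ref,event_ref Comparator arm.
#' @param covars_trt,covars_ref Optional data frames of numeric baseline
#'   covariates (same columns in both arms). When supplied, the Cox model
#'   adjusts for them, so the arm coefficient estimates the conditional
#'   hazard ratio — the scale the input hazard ratios live on — rather than
#'   the marginal one, which is attenuated over heterogeneous baselines
#'   (non-collapsibility).
#' @return List with `hr` (treatment vs comparator), `se_loghr`, `n`.
#' @export
estimate_out_hr <- function(time_trt, event_trt = NULL,
                            time_ref, event_ref = NULL,
                            covars_trt = NULL, covars_ref = NULL) {
  if (length(time_trt) < 2L || length(time_ref) < 2L)
    stop("each arm needs at least 2 observations", call. = FALSE)
  event_trt <- event_trt %||% rep(1, length(time_trt))
  event_ref <- event_ref %||% rep(1, length(time_ref))
  time <- c(time_trt, time_ref)
  event <- c(event_trt, event_ref)
  event[is.infinite(time)] <- 0
  fin_max <- max(time[is.finite(time)])
  time[is.infinite(time)] <- fin_max
  arm <- rep(c(1, 0), c(length(time_trt), length(time_ref)))
  if (sum(event[arm == 1]) == 0 || sum(event[arm == 0]) == 0)
    stop("an arm has no events; hazard ratio not estimable", call. = FALSE)
  d <- data.frame(.time = time, .event = event, .arm = arm)
  fml <- survival::Surv(.time, .event) ~ .arm
  if (!is.null(covars_trt)) {
    stopifnot(identical(names(covars_trt), names(covars_ref)))
    d <- cbind(d, rbind(covars_trt, covars_ref))
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~ .arm +",
                                   paste(names(covars_trt), collapse = " + ")))
  }
  fit <- survival::coxph(fml, data = d)
  list(hr = unname(exp(stats::coef(fit)[".arm"])),
       se_loghr = unname(sqrt(stats::vcov(fit)[".arm", ".arm"])),
       n = length(time))
}

#' Calibrate the moderate-group input hazard ratio for immunotherapy
#'
#' Under a mixture-cure survival law, a fraction `f` of patients are
#' long-term survivors subject only to background mortality, so the hazard
#' ratio applied to the moderate (non-cured) group — the input HR, "inHR" —
#' must be calibrated for the whole arm's hazard ratio versus chemotherapy
#' (the output HR, "outHR") to equal the trial target. This function
#' root-finds the inHR by bisection on
#' \eqn{g(\mathrm{inHR}) = \mathrm{outHR}(\mathrm{inHR}) - \mathrm{target}},
#' re-simulating both arms at each iterate with common random numbers (the
#' same seed for every evaluation), which makes \eqn{g} effectively
#' deterministic and monotone so the bisection converges.
#'
#' With `f = 0` the cure contributes nothing and the calibrated inHR equals
#' the target; with `f > 0` the calibrated inHR exceeds the target (the
#' moderate group needs less benefit because the cured group already supplies
#' some).
#'
#' @param target Target whole-arm hazard ratio (positive).
#' @param sim_fun Function `function(in_hr, seed)` simulating both arms under
#'   moderate-group hazard ratio `in_hr` and returning a list with
#'   `time_trt`, `time_ref` (and optionally `event_trt`, `event_ref`), as
#'   produced e.g. by [calibration_context()].
#' @param bounds Search interval for the inHR; must bracket the target.
#' @param tol Tolerance on `|outHR - target|`.
#' @param max_iter Maximum bisection iterations.
#' @param seed Seed reused at every evaluation (common random numbers).
#' @return List of class `inhr_calibration`: `in_hr`, `achieved_out_hr`,
#'   `target`, `iterations`, `converged`, `trace` (data frame of iterates),
#'   `bounds`, `seed`.
#' @export
calibrate_in_hr <- function(target, sim_fun, bounds = c(0.05, 1.5),
                            tol = 0.01, max_iter = 40, seed = 1L) {
  stopifnot(target > 0, tol > 0, length(bounds) == 2L, bounds[1] < bounds[2])
  g <- function(in_hr) {
    arms <- sim_fun(in_hr, seed)
    est <- estimate_out_hr(arms$time_trt, arms$event_trt,
                           arms$time_ref, arms$event_ref,
                           arms$covars_trt, arms$covars_ref)
    est$hr - target
  }
  lo <- bounds[1]; hi <- bounds[2]
  g_lo <- g(lo); g_hi <- g(hi)
  if (g_lo * g_hi > 0)
    stop(sprintf(paste0("bounds [%.3g, %.3g] do not bracket the target ",
                        "(g = %.4f and %.4f)"), lo, hi, g_lo, g_hi),
         call. = FALSE)
  trace <- data.frame(iter = 0:1, in_hr = c(lo, hi),
                      out_hr = c(g_lo, g_hi) + target)
  mid <- NA_real_; g_mid <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    g_mid <- g(mid)
    trace <- rbind(trace, data.frame(iter = it + 1L, in_hr = mid,
                                     out_hr = g_mid + target))
    if (abs(g_mid) <= tol) { converged <- TRUE; break }
    if (g_mid * g_lo < 0) { hi <- mid; g_hi <- g_mid }
    else { lo <- mid; g_lo <- g_mid }
  }
  if (!converged)
    warning("bisection did not reach tolerance ", tol, " in ", max_iter,
            " iterations; |g| = ", format(abs(g_mid)))
  structure(list(in_hr = mid, achieved_out_hr = g_mid + target,
                 target = target, iterations = nrow(trace) - 2L,
                 converged = converged, trace = trace,
                 bounds = bounds, tol = tol, seed = seed),
            class = "inhr_calibration")
}

#' @export
print.inhr_calibration <- function(x, ...) {
  cat(sprintf(paste0("Calibrated inHR = %.4f (target outHR %.3f, achieved ",
                     "%.4f, %d iterations%s)\n"),
              x$in_hr, x$target, x$achieved_out_hr, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Default two-arm simulation context for inHR calibration
#'
#' Builds the `sim_fun` used by [calibrate_in_hr()]: both arms draw baseline
#' attributes from the supplied pool and first-line competing transitions
#' (next line vs disease death) from the fitted models. In the treatment arm
#' a fraction `f` of patients are long-term survivors whose endpoint time is
#' their background-mortality time; the rest progress under the
#' moderate-group hazard ratio applied to both competing transitions. The
#' comparator arm is plain chemotherapy (hazard ratio 1). The endpoint is
#' first-line progression-free survival (next line or death, the endpoint
#' the trial hazard ratios refer to) or first-line-phase overall survival.
#'
#' @param models Transition model list (needs `l1t_l2t`, `l1t_death`).
#' @param attributes Attribute pool (data frame) to resample covariates from.
#' @param f Long-term survivor fraction in the treatment arm.
#' @param life_table [life_table()] for the long-term survivors' death times.
#' @param n_per_arm Simulated patients per arm per evaluation.
#' @param endpoint `"pfs"` (default) or `"os"` (first-line phase).
#' @return Function `(in_hr, seed) -> list(time_trt, time_ref)`.
#' @export
calibration_context <- function(models, attributes, f, life_table,
                                n_per_arm = 50000, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  stopifnot(f >= 0, f <= 1)
  force(models); force(attributes); force(life_table); force(n_per_arm)
  adj <- intersect(c("age65", "sex_female", "ps_bad", "cci"),
                   names(attributes))
  one_arm <- function(hr, f_arm) {
    idx <- sample.int(nrow(attributes), n_per_arm, replace = TRUE)
    nd <- attributes[idx, , drop = FALSE]
    lt <- if (f_arm > 0) assign_longterm(n_per_arm, f_arm) else
      rep(FALSE, n_per_arm)
    t_next <- sample_event_time(with_hr(models$l1t_l2t, hr), n_per_arm, nd)
    t_die <- sample_event_time(with_hr(models$l1t_death, hr), n_per_arm, nd)
    # the endpoint counts disease events only (trial hazard ratios describe
    # disease progression/death); the cured group's time is its
    # background-mortality time, the only risk it retains
    out <- if (endpoint == "pfs") pmin(t_next, t_die) else t_die
    if (any(lt)) {
      t_doc <- sample_background_time(life_table, nd$age, nd$sex)
      out[lt] <- t_doc[lt]
    }
    list(time = out, covars = nd[adj])
  }
  function(in_hr, seed) {
    set.seed(child_seed(seed, "calibration"))
    trt <- one_arm(in_hr, f)
    ref <- one_arm(1, 0)
    list(time_trt = trt$time, time_ref = ref$time,
         covars_trt = trt$covars, covars_ref = ref$covars)
  }
}

#' Calibrate the wear-out time against a reference survival curve
#'
#' Finds the time at which a modelled survival curve (simulated under a
#' durable treatment benefit) starts to deviate from a reference curve:
#' the earliest grid time at which the absolute survival difference exceeds
#' `threshold` for at least `persist` consecutive grid points. "Started to
#' deviate" has no canonical definition, so both knobs are explicit
#' parameters.
#'
#' @param modeled,reference Curves: data frames with `time_months` (or
#'   `time`) and `survival` (or `surv`) columns; evaluated by step
#'   interpolation on the union where grids differ.
#' @param threshold Absolute survival-difference threshold (default 0.02).
#' @param persist Number of consecutive grid points the deviation must be
#'   sustained for (default 3).
#' @return Deviation onset time in months, or `NA` when the curves never
#'   deviate persistently.
#' @export
calibrate_wearout <- function(modeled, reference, threshold = 0.02,
                              persist = 3) {
  getcol <- function(d, a, b) d[[a]] %||% d[[b]]
  tm <- getcol(modeled, "time_months", "time")
  sm <- getcol(modeled, "survival", "surv")
  tr <- getcol(reference, "time_months", "time")
  sr <- getcol(reference, "survival", "surv")
  if (max(min(tm), min(tr)) > min(max(tm), max(tr)))
    stop("curves have disjoint time ranges", call. = FALSE)
  grid <- sort(unique(c(tm, tr)))
  grid <- grid[grid >= max(min(tm), min(tr)) & grid <= min(max(tm), max(tr))]
  step <- function(tt, ss, at) c(ss[1], ss)[findInterval(at, tt) + 1L]
  dev <- abs(step(tm, sm, grid) - step(tr, sr, grid)) > threshold
  if (persist < 1) persist <- 1
  run <- 0L
  for (i in seq_along(dev)) {
    run <- if (dev[i]) run + 1L else 0L
    if (run >= persist) return(grid[i - persist + 1L])
  }
  NA_real_
}
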