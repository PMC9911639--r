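#' @export
print.nsclc_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d patients, strategy '%s'\n", nrow(x),
              attr(x, "strategy") %||% "?"))
  cat(sprintf("  treated %d (%.1f%%), BSC %d; deaths: disease %d, other %d, never %d\n",
              sum(x$treated), 100 * mean(x$treated), sum(!x$treated),
              sum(x$cause == "disease", na.rm = TRUE),
              sum(x$cause == "other", na.rm = TRUE),
              sum(is.infinite(x$t_death) | is.na(x$cause))))
  invisible(x)
}

#' Endpoint times of a simulated cohort
#'
#' Extracts, per patient, the time for one of the model's survival endpoints.
#' Progression-free survival is operationalized as time from line start to
#' the start of the next treatment line or death, whichever comes first (the
#' model has no separate progression event); overall survival for treated
#' subgroups is measured from first-line start, while the best-supportive-care
#' endpoint runs from diagnosis. All simulated patients are followed to
#' death, so the times are fully observed (no censoring).
#'
#' @param cohort An `nsclc_cohort`.
#' @param endpoint One of `"pfs1"`, `"os1"`, `"pfs2"`, `"os2"`, `"os3"`,
#'   `"os_bsc"`.
#' @return Numeric vector of times in months for the eligible patients
#'   (patients who entered the endpoint's origin state).
#' @export
endpoint_times <- function(cohort, endpoint = c("pfs1", "os1", "pfs2", "os2",
                                                "os3", "os_bsc")) {
  endpoint <- match.arg(endpoint)
  x <- cohort
  switch(endpoint,
         pfs1 = {
           i <- !is.na(x$t_l1t)
           pmin(x$t_l2t[i], x$t_death[i], na.rm = TRUE) - x$t_l1t[i]
         },
         os1 = {
           i <- !is.na(x$t_l1t)
           x$t_death[i] - x$t_l1t[i]
         },
         pfs2 = {
           i <- !is.na(x$t_l2t)
           pmin(x$t_l3t[i], x$t_death[i], na.rm = TRUE) - x$t_l2t[i]
         },
         os2 = {
           i <- !is.na(x$t_l2t)
           x$t_death[i] - x$t_l2t[i]
         },
         os3 = {
           i <- !is.na(x$t_l3t)
           x$t_death[i] - x$t_l3t[i]
         },
         os_bsc = x$t_death[!x$treated])
}

summary_row <- function(label, n_total, pfs, os) {
  data.frame(subgroup = label,
             n = length(os),
             pct = 100 * length(os) / n_total,
             median_pfs = med_or_na(pfs), mean_pfs = mean_or_na(pfs),
             median_os = med_or_na(os), mean_os = mean_or_na(os),
             stringsAsFactors = FALSE)
}

#' Summarize a simulated cohort by treatment subgroup
#'
#' Builds the cohort summary table: per subgroup the number and percentage of
#' patients and the median and mean progression-free and overall survival in
#' months. PFS and OS for treated subgroups are measured from first-line
#' start; the BSC row is measured from diagnosis and has no PFS. Because
#' every simulated patient is followed to death, means are plain averages.
#' For a personalized cohort the table is broken down by treatment class,
#' first-line treatment (with its driver/PD-L1 subgroup) and, for
#' mixture-cure treatments, the long-term and moderate survivor strata.
#'
#' @param cohort An `nsclc_cohort`.
#' @return Data frame with columns `subgroup`, `n`, `pct`, `median_pfs`,
#'   `mean_pfs`, `median_os`, `mean_os`. Subgroup `n` values within a
#'   breakdown sum to the cohort total.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "nsclc_cohort"))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  x <- cohort
  n_total <- nrow(x)
  started <- !is.na(x$t_l1t)
  pfs <- rep(NA_real_, n_total)
  os <- rep(NA_real_, n_total)
  pfs[started] <- endpoint_times(x, "pfs1")
  os[started] <- endpoint_times(x, "os1")

  rows <- list(
    summary_row("BSC", n_total, numeric(0), x$t_death[!x$treated]),
    summary_row("Treated (all)", n_total, pfs[started], os[started]))
  trt1 <- x$treatment1
  personalized <- any(!is.na(trt1) & trt1 != "chemo")
  if (personalized) {
    cls <- rep(NA_character_, n_total)
    strat_class <- attr(x, "class_map")
    for (tr in unique(trt1[started]))
      cls[started & trt1 == tr] <-
        (strat_class[[tr]] %||% if (tr == "chemo") "chemo" else "other")
    for (cl in intersect(c("targeted", "immunotherapy", "chemo", "other"),
                         unique(cls[started]))) {
      i <- started & cls == cl & !is.na(cls)
      rows[[length(rows) + 1L]] <-
        summary_row(paste0("Treated: ", cl), n_total, pfs[i], os[i])
    }
    for (tr in sort(unique(trt1[started]))) {
      i <- started & trt1 == tr
      rows[[length(rows) + 1L]] <- summary_row(paste0("  ", tr), n_total,
                                               pfs[i], os[i])
      if (any(x$long_term[i])) {
        rows[[length(rows) + 1L]] <-
          summary_row(paste0("    ", tr, " / long-term"), n_total,
                      pfs[i & x$long_term], os[i & x$long_term])
        rows[[length(rows) + 1L]] <-
          summary_row(paste0("    ", tr, " / moderate"), n_total,
                      pfs[i & !x$long_term], os[i & !x$long_term])
      }
    }
  }
  never <- x$treated & !started
  if (any(never))
    rows[[length(rows) + 1L]] <- summary_row("Treated, died before L1T",
                                             n_total, numeric(0),
                                             x$t_death[never])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.nsclc_cohort <- function(object, ...) summarize_cohort(object)

#' Write a cohort or summary to CSV
#'
#' Times are serialized in months with 6 decimal places and fixed column
#' order for diffability.
#'
#' @param x An `nsclc_cohort` or a summary data frame.
#' @param path Output file.
#' @export
write_cohort <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], function(v) ifelse(is.na(v), NA,
                                              sprintf("%.6f", v)))
  utils::write.csv(x, path, row.names = FALSE, na = "")
}
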