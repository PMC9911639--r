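#' Transition labels of the diagnosis-to-death pathway
#'
#' The pathway has five events — diagnosis (DIAG), start of first-, second-
#' and third-line systemic treatment (L1T, L2T, L3T) and death — and seven
#' transitions. The two DIAG-phase transitions are modelled by independent
#' distributions (starting treatment and dying under best supportive care are
#' not treated as competing events); the five post-L1T transitions form the
#' parametric multistate model with competing next-line/death pairs.
#'
#' @return Character vector of the seven transition labels.
#' @export
pathway_transitions <- function() {
  c("diag_l1t", "diag_death_bsc",
    "l1t_l2t", "l1t_death",
    "l2t_l3t", "l2t_death",
    "l3t_death")
}

#' Read a patient registry from CSV
#'
#' Expected columns: `id,year,age,sex,ps,cci,t_l1t,t_l2t,t_l3t,t_death,dead`.
#' Times are months from diagnosis; empty line-start cells mean the line was
#' never reached; `t_death` is the death time when `dead == 1`, otherwise the
#' administrative censoring time.
#'
#' @param path CSV file path.
#' @return Data frame with those columns.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "year", "age", "sex", "ps", "cci",
            "t_l1t", "t_l2t", "t_l3t", "t_death", "dead")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  reg
}

#' Write a registry to CSV
#' @param registry Registry data frame.
#' @param path Output file.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(registry, path, row.names = FALSE, na = "")
}

# numeric design columns used by all regression models
#' Derive numeric covariate columns from registry attributes
#'
#' Translates the categorical baseline attributes into the numeric design
#' columns every regression in the package uses: `age65` (age minus 65
#' years), `sex_female` (1 = female), `ps_bad` (1 = bad-or-unknown ECOG
#' performance status, the contrast the pathway models use), `cci`
#' (Charlson comorbidity index as a score) and `year0` (calendar year minus
#' the earliest year).
#'
#' @param data Data frame with columns `age`, `sex`, `ps`, `cci`, `year`.
#' @return `data` with the derived numeric columns appended.
#' @export
derive_covariates <- function(data) {
  data$age65 <- data$age - 65
  data$sex_female <- as.numeric(data$sex == "female")
  data$ps_bad <- as.numeric(data$ps != "good")
  data$cci <- as.numeric(data$cci)
  data$year0 <- data$year - min(data$year)
  data
}

#' Prepare long-format transition rows from a registry
#'
#' Expands each patient into one row per transition leaving every state the
#' patient occupied, on the line-local clock (time 0 at entry into the line;
#' the clock convention is semi-Markov throughout). For a pair of competing
#' transitions, the transition that did not occur is censored at the time of
#' the one that did; patients alive at the end of follow-up are
#' administratively censored in all transitions leaving their current state.
#' Treated patients contribute a `diag_l1t` row (always an event: the line
#' start is observed); best-supportive-care patients contribute a single
#' `diag_death_bsc` row.
#'
#' Records with non-monotone event times (or a line reached without its
#' predecessor) are rejected, mirroring registry cleaning practice; their ids
#' and reasons are attached as attribute `"rejected"`.
#'
#' @param registry Registry data frame (see [read_registry()]).
#' @return Data frame with columns `id`, `transition`, `time` (line-local exit
#'   time, months), `status` (1 = transition occurred, 0 = censored —
#'   competing or administrative), the original attributes and the derived
#'   covariate columns of [derive_covariates()]. Attribute `"rejected"` lists
#'   excluded records.
#' @export
prep_multistate <- function(registry) {
  reg <- as.data.frame(registry)
  reg <- derive_covariates(reg)
  n <- nrow(reg)
  for (col in c("t_l1t", "t_l2t", "t_l3t", "t_death"))
    reg[[col]] <- suppressWarnings(as.numeric(reg[[col]]))

  reject <- character(0)
  reject_why <- character(0)
  bad <- function(i, why) {
    reject <<- c(reject, as.character(reg$id[i]))
    reject_why <<- c(reject_why, why)
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    tt <- c(0, reg$t_l1t[i], reg$t_l2t[i], reg$t_l3t[i])
    present <- !is.na(tt)
    # line k present requires line k-1 present
    if (any(diff(present) > 0)) { keep[i] <- FALSE; bad(i, "line without predecessor"); next }
    tv <- tt[present]
    if (any(diff(tv) <= 0)) { keep[i] <- FALSE; bad(i, "non-increasing event times"); next }
    if (is.na(reg$t_death[i]) || reg$t_death[i] < max(tv)) {
      keep[i] <- FALSE; bad(i, "death/censor time before last line start"); next
    }
    if (reg$dead[i] == 0 && reg$t_death[i] == max(tv) && length(tv) > 1) {
      keep[i] <- FALSE; bad(i, "zero exposure after last line start"); next
    }
  }
  reg <- reg[keep, , drop = FALSE]

  rows <- list()
  emit <- function(id_idx, transition, time, status, status_type) {
    data.frame(id = reg$id[id_idx], transition = transition,
               time = time, status = status, status_type = status_type,
               reg[id_idx, c("year", "age", "sex", "ps", "cci",
                             "age65", "sex_female", "ps_bad", "year0"),
                   drop = FALSE],
               row.names = NULL, stringsAsFactors = FALSE)
  }

  treated <- !is.na(reg$t_l1t)
  if (any(!treated)) {
    i <- which(!treated)
    rows[[length(rows) + 1L]] <- emit(i, "diag_death_bsc",
                                      reg$t_death[i], reg$dead[i],
                                      ifelse(reg$dead[i] == 1, "event", "admin"))
  }
  if (any(treated)) {
    i <- which(treated)
    rows[[length(rows) + 1L]] <- emit(i, "diag_l1t", reg$t_l1t[i],
                                      rep(1, length(i)), "event")
    # line state occupancy: exit = next line start or death/censor
    line_rows <- function(i_state, t_entry, t_next, next_lab, death_lab) {
      if (length(t_next) == 1L) t_next <- rep(t_next, length(i_state))
      exit <- ifelse(!is.na(t_next), t_next, reg$t_death[i_state])
      local <- exit - t_entry
      to_next <- as.numeric(!is.na(t_next))
      died <- ifelse(is.na(t_next), reg$dead[i_state], 0)
      d_type <- ifelse(died == 1, "event",
                       ifelse(to_next == 1, "competing", "admin"))
      out <- list(emit(i_state, death_lab, local, died, d_type))
      if (!is.null(next_lab)) {
        n_type <- ifelse(to_next == 1, "event",
                         ifelse(died == 1, "competing", "admin"))
        out <- c(out, list(emit(i_state, next_lab, local, to_next, n_type)))
      }
      out
    }
    rows <- c(rows, line_rows(i, reg$t_l1t[i], reg$t_l2t[i],
                              "l1t_l2t", "l1t_death"))
    i2 <- which(!is.na(reg$t_l2t))
    if (length(i2))
      rows <- c(rows, line_rows(i2, reg$t_l2t[i2], reg$t_l3t[i2],
                                "l2t_l3t", "l2t_death"))
    i3 <- which(!is.na(reg$t_l3t))
    if (length(i3))
      rows <- c(rows, line_rows(i3, reg$t_l3t[i3], NA_real_,
                                NULL, "l3t_death"))
  }
  out <- do.call(rbind, rows)
  out <- out[out$time > 0, , drop = FALSE]
  out <- out[order(match(out$transition, pathway_transitions()), out$id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(id = reject, reason = reject_why,
                                      stringsAsFactors = FALSE)
  out
}
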