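# ---- vectorized decision-tree resolution -----------------------------------

# Resolve treatments for many patients at once; u is a per-patient uniform
# consumed only by mixture entries. previous is NULL (line 1) or a vector.
resolve_treatment_vec <- function(driver, pdl1, line, previous, strategy, u) {
  n <- length(driver)
  out <- character(n)
  if (line == 3L) return(rep("chemo", n))
  pick <- function(entry, pdl1_branch, idx) {
    if (is.character(entry) && identical(entry, "pdl1")) {
      for (cat in unique(pdl1[idx])) {
        sub <- idx[pdl1[idx] == cat]
        out[sub] <<- pick_flat(pdl1_branch[[cat]], sub)
      }
    } else out[idx] <<- pick_flat(entry, idx)
  }
  pick_flat <- function(entry, idx) {
    if (is.character(entry)) return(rep(entry, length(idx)))
    w <- unlist(entry$mix)
    names(w)[findInterval(u[idx], cumsum(w) / sum(w)) + 1L]
  }
  if (line == 1L) {
    for (d in unique(driver)) {
      idx <- which(driver == d)
      pick(strategy$tree$line1[[d]], strategy$tree$pdl1_line1, idx)
    }
  } else {
    for (p in unique(previous)) {
      idx <- which(previous == p)
      entry <- strategy$tree$line2[[p]] %||% strategy$tree$line2$default
      pick(entry, strategy$tree$pdl1_line2, idx)
    }
  }
  out
}

# parametric model with an extra hazard-ratio multiplier folded in
with_hr <- function(model, m) {
  if (m == 1) return(model)
  parametric_model(model$family, model$params, coefs = model$coefs,
                   hr = model$hr * m)
}

# sampler for one line transition under modifiers (wear-out composite when
# the benefit is limited)
line_sampler <- function(base_model, hr, wearout) {
  if (hr == 1 || is.infinite(wearout)) return(with_hr(base_model, hr))
  compose_wearout(with_hr(base_model, hr), base_model, wearout)
}

# ---- baseline population ----------------------------------------------------

#' Sample a baseline patient population
#'
#' Draws `n` patients' baseline attributes (empirical resampling of an
#' attribute pool, or a user-supplied sampler function) and the
#' treated-vs-best-supportive-care decision from the logistic decision model.
#' Uses the current RNG stream.
#'
#' @param n Number of patients.
#' @param attributes Either a data frame pool to resample rows from (it is
#'   passed through [derive_covariates()] if the derived columns are absent)
#'   or a function `function(n)` returning a data frame of `n` rows.
#' @param decision A [fit_treatment_decision()] object, or a single
#'   probability of being treated.
#' @return Data frame of attributes with a logical `treated` column.
#' @export
sample_baseline_population <- function(n, attributes, decision) {
  if (n == 0L) {
    attrs <- if (is.function(attributes)) attributes(0L) else attributes[0, ]
    attrs$treated <- logical(0)
    return(attrs)
  }
  attrs <- if (is.function(attributes)) {
    attributes(n)
  } else {
    attributes[sample.int(nrow(attributes), n, replace = TRUE), , drop = FALSE]
  }
  if (!all(c("age65", "sex_female", "ps_bad") %in% names(attrs)))
    attrs <- derive_covariates(attrs)
  rownames(attrs) <- NULL
  p <- if (is.numeric(decision)) rep(decision, n)
       else predict_decision(decision, attrs)
  attrs$treated <- stats::runif(n) < p
  attrs
}

# ---- the discrete-event core ------------------------------------------------

# Simulate treated patients' pathways from first-line start to death.
# attrs: covariate rows; t_l1t/t_doc: months from diagnosis. Consumes the
# current RNG stream. Returns a data.frame of path columns.
simulate_treated_paths <- function(attrs, t_l1t, t_doc, models, strategy) {
  n <- nrow(attrs)
  res <- data.frame(
    driver = rep("none", n), pdl1 = rep(NA_character_, n),
    treatment1 = rep("chemo", n), treatment2 = rep(NA_character_, n),
    treatment3 = rep(NA_character_, n),
    long_term = rep(FALSE, n),
    t_l2t = rep(NA_real_, n), t_l3t = rep(NA_real_, n),
    t_death = rep(NA_real_, n), cause = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (n == 0L) return(res)

  personalized <- !is.null(strategy)
  if (!is.null(strategy)) {
    bm <- assign_biomarkers(n, strategy$prevalence, strategy$pdl1)
    res$driver <- bm$driver
    res$pdl1 <- bm$pdl1
    u_mix1 <- stats::runif(n)
    res$treatment1 <- resolve_treatment_vec(res$driver, res$pdl1, 1L, NULL,
                                            strategy, u_mix1)
    u_cure <- stats::runif(n)
  }

  # patients whose other-cause death precedes first-line start never start it
  pre <- t_doc <= t_l1t
  res$t_death[pre] <- t_doc[pre]
  res$cause[pre] <- "other"
  res$treatment1[pre] <- NA_character_

  # per-patient effective modifiers for line 1
  mods <- list(hr_next = rep(1, n), hr_death = rep(1, n),
               wearout = rep(Inf, n), cure = rep(0, n))
  if (personalized) {
    key <- paste(res$treatment1, res$driver)
    for (k in unique(key[!pre])) {
      idx <- which(key == k & !pre)
      m <- build_transition_modifiers(res$treatment1[idx[1]],
                                      res$driver[idx[1]], strategy, line = 1)
      mods$hr_next[idx] <- m$hr_next
      mods$hr_death[idx] <- m$hr_death
      mods$wearout[idx] <- m$wearout
      mods$cure[idx] <- m$cure
    }
    lt <- !pre & mods$cure > 0 & u_cure < mods$cure
    res$long_term <- lt
    res$t_death[lt] <- t_doc[lt]
    res$cause[lt] <- "other"
  }

  clock <- t_l1t
  active <- !pre & !res$long_term
  for (line in 1:3) {
    if (!any(active)) break
    next_model <- switch(line, models$l1t_l2t, models$l2t_l3t, NULL)
    death_model <- switch(line, models$l1t_death, models$l2t_death,
                          models$l3t_death)
    idx_all <- which(active)
    treatment_col <- paste0("treatment", line)
    # group patients by shared modifiers so sampling stays vectorized
    gkey <- if (line <= 2)
      paste(mods$hr_next[idx_all], mods$hr_death[idx_all], mods$wearout[idx_all])
    else rep("1 1 Inf", length(idx_all))
    t_next <- rep(Inf, length(idx_all))
    t_die <- rep(Inf, length(idx_all))
    for (k in unique(gkey)) {
      g <- gkey == k
      idx <- idx_all[g]
      hrn <- mods$hr_next[idx[1]]
      hrd <- mods$hr_death[idx[1]]
      wo <- mods$wearout[idx[1]]
      nd <- attrs[idx, , drop = FALSE]
      # death has tie-break priority over next-line start: sample it first
      t_die[g] <- sample_event_time(line_sampler(death_model, hrd, wo),
                                    length(idx), nd)
      if (!is.null(next_model))
        t_next[g] <- sample_event_time(line_sampler(next_model, hrn, wo),
                                       length(idx), nd)
    }
    died <- t_die <= t_next                  # ties resolve to death
    t_local <- pmin(t_die, t_next)
    t_global <- clock[idx_all] + t_local
    doc_first <- t_doc[idx_all] < t_global   # other-cause death preempts
    i_doc <- idx_all[doc_first]
    res$t_death[i_doc] <- t_doc[i_doc]
    res$cause[i_doc] <- "other"
    active[i_doc] <- FALSE
    i_die <- idx_all[!doc_first & died]
    res$t_death[i_die] <- t_global[!doc_first & died]
    res$cause[i_die] <- "disease"
    active[i_die] <- FALSE
    i_next <- idx_all[!doc_first & !died & is.finite(t_local)]
    if (line < 3 && length(i_next)) {
      tcol <- paste0("t_l", line + 1, "t")
      res[[tcol]][i_next] <- clock[i_next] +
        t_local[match(i_next, idx_all)]
      clock[i_next] <- res[[tcol]][i_next]
      nxt_treat <- if (personalized) {
        u_mix <- stats::runif(length(i_next))
        resolve_treatment_vec(res$driver[i_next], res$pdl1[i_next],
                              min(line + 1L, 2L),
                              res[[treatment_col]][i_next], strategy, u_mix)
      } else rep("chemo", length(i_next))
      res[[paste0("treatment", line + 1)]][i_next] <- nxt_treat
      if (personalized && line + 1L == 2L) {
        for (tr in unique(nxt_treat)) {
          jj <- i_next[nxt_treat == tr]
          m <- build_transition_modifiers(tr, "none", strategy, line = 2)
          mods$hr_next[jj] <- m$hr_next
          mods$hr_death[jj] <- m$hr_death
          mods$wearout[jj] <- m$wearout
        }
      } else {
        mods$hr_next[i_next] <- 1
        mods$hr_death[i_next] <- 1
        mods$wearout[i_next] <- Inf
      }
    }
    still <- idx_all[!doc_first & !died & !is.finite(t_local)]
    if (length(still)) {
      # both competing draws infinite (improper laws, no background mortality):
      # the patient never experiences another event
      res$t_death[still] <- Inf
      res$cause[still] <- NA_character_
    }
    # only patients who started the next line remain active
    if (line < 3) {
      keep <- rep(FALSE, n)
      keep[i_next] <- TRUE
      active <- keep
    } else active <- rep(FALSE, n)
  }
  res
}

#' Simulate a patient cohort from diagnosis to death
#'
#' Runs the discrete-event simulation: each patient starts at diagnosis,
#' either receives best supportive care (death time from the BSC model) or
#' starts first-line treatment (time from the diagnosis-to-first-line model;
#' the two are deliberately not competing events), then progresses through up
#' to three treatment lines. Within each line the next-line start and disease
#' death compete by event-specific distributions (one draw per cause, minimum
#' wins, ties resolved to death), with treatment-specific hazard ratios,
#' prognostic effects, benefit wear-out and mixture-cure membership applied
#' under a personalized strategy. Death from other causes, sampled from the
#' life table, competes with every event on the global clock.
#'
#' Randomness is split into two reproducible streams derived from `seed`: the
#' baseline stream (attributes, treatment decision, other-cause death, BSC
#' death, time to first-line start) and the strategy stream (biomarkers,
#' treatment mixtures, cure membership, line transitions). The baseline
#' stream is shared across strategies, so the BSC subgroup is identical
#' between two strategies simulated with the same seed.
#'
#' @param n Cohort size.
#' @param models Named list of transition models (one [parametric_model()]
#'   per [pathway_transitions()] label).
#' @param decision A [fit_treatment_decision()] object or a probability.
#' @param attributes Attribute pool or sampler (see
#'   [sample_baseline_population()]).
#' @param strategy `NULL` for the non-personalized strategy (platinum-doublet
#'   chemotherapy in every line), or a validated strategy object.
#' @param life_table Optional [life_table()] for background mortality; without
#'   it patients can only die of the disease (and improper disease laws can
#'   leave the death time infinite).
#' @param seed Integer seed; `NULL` uses the current RNG state (one stream).
#' @return A data frame of class `nsclc_cohort`, one row per patient:
#'   attributes, `treated`, biomarkers, per-line treatments, `long_term`,
#'   event times `t_l1t`, `t_l2t`, `t_l3t`, `t_death` (months from
#'   diagnosis) and `cause` (`"disease"`/`"other"`).
#' @seealso [summarize_cohort()], [trajectories_long()], [simulate.parmssm()]
#' @export
simulate_cohort <- function(n, models, decision, attributes, strategy = NULL,
                            life_table = NULL, seed = NULL) {
  stopifnot(n >= 0)
  miss <- setdiff(pathway_transitions(), names(models))
  if (length(miss))
    stop("models lacks transition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(strategy) && is.null(life_table) &&
      any(unlist(strategy$cure) > 0))
    warning("mixture-cure strategy without a life table: long-term survivors",
            " never die in simulation")

  # -- baseline stream --------------------------------------------------------
  if (!is.null(seed)) set.seed(child_seed(seed, "baseline"))
  attrs <- sample_baseline_population(n, attributes, decision)
  n <- nrow(attrs)
  t_doc <- if (!is.null(life_table))
    sample_background_time(life_table, attrs$age, attrs$sex)
  else rep(Inf, n)
  treated <- attrs$treated
  t_l1t <- rep(NA_real_, n)
  t_death <- rep(NA_real_, n)
  cause <- rep(NA_character_, n)
  if (any(!treated)) {
    tb <- sample_event_time(models$diag_death_bsc, sum(!treated),
                            attrs[!treated, , drop = FALSE])
    doc_b <- t_doc[!treated]
    t_death[!treated] <- pmin(tb, doc_b)
    cause[!treated] <- ifelse(doc_b < tb, "other", "disease")
  }
  if (any(treated))
    t_l1t[treated] <- sample_event_time(models$diag_l1t, sum(treated),
                                        attrs[treated, , drop = FALSE])

  # -- strategy stream --------------------------------------------------------
  if (!is.null(seed)) set.seed(child_seed(seed, "strategy"))
  paths <- simulate_treated_paths(attrs[treated, , drop = FALSE],
                                  t_l1t[treated], t_doc[treated],
                                  models, strategy)

  out <- data.frame(
    id = seq_len(n),
    attrs[, c("year", "age", "sex", "ps", "cci",
              "age65", "sex_female", "ps_bad"), drop = FALSE],
    treated = treated,
    driver = NA_character_, pdl1 = NA_character_,
    treatment1 = NA_character_, treatment2 = NA_character_,
    treatment3 = NA_character_,
    long_term = FALSE,
    t_l1t = t_l1t, t_l2t = NA_real_, t_l3t = NA_real_,
    t_death = t_death, cause = cause,
    stringsAsFactors = FALSE)
  if (any(treated)) {
    for (col in c("driver", "pdl1", "treatment1", "treatment2", "treatment3",
                  "long_term", "t_l2t", "t_l3t", "t_death", "cause"))
      out[[col]][treated] <- paths[[col]]
    # treated-arm patients pre-empted by other-cause death never start the
    # line: no t_l1t, but they remain counted in the treated arm
    pre <- treated & !is.na(out$t_death) & is.na(out$treatment1)
    out$t_l1t[pre] <- NA_real_
  }
  attr(out, "strategy") <- if (is.null(strategy)) "non-personalized"
                           else strategy$name %||% "personalized"
  if (!is.null(strategy)) attr(out, "class_map") <- strategy$class
  class(out) <- c("nsclc_cohort", "data.frame")
  out
}

#' Simulate a single patient trajectory
#'
#' Convenience wrapper around the cohort engine for one patient with fixed
#' baseline attributes and treated/BSC status.
#'
#' @param attrs One-row data frame with `year`, `age`, `sex`, `ps`, `cci`.
#' @param treated Logical: starts first-line treatment (vs BSC).
#' @inheritParams simulate_cohort
#' @return One-row `nsclc_cohort`.
#' @export
simulate_patient <- function(attrs, treated, models, strategy = NULL,
                             life_table = NULL, seed = NULL) {
  stopifnot(nrow(attrs) == 1L)
  simulate_cohort(1L, models, decision = as.numeric(treated),
                  attributes = derive_covariates(attrs),
                  strategy = strategy, life_table = life_table, seed = seed)
}

#' Simulate cohorts from a fitted pathway model
#'
#' The `simulate` method of [fit_parmssm()] objects: draws a cohort of
#' `nsim` patients under the fitted transition models, empirical attribute
#' resampling and the fitted treatment-decision model.
#'
#' @param object A `parmssm` fit.
#' @param nsim Number of patients to simulate.
#' @param seed Integer seed (see [simulate_cohort()]).
#' @param strategy `NULL` (non-personalized) or a strategy object.
#' @param life_table Optional [life_table()].
#' @param ... Unused.
#' @return An `nsclc_cohort` data frame.
#' @export
simulate.parmssm <- function(object, nsim = 1, seed = NULL, strategy = NULL,
                             life_table = NULL, ...) {
  simulate_cohort(nsim, transition_models(object), object$decision,
                  object$attributes, strategy = strategy,
                  life_table = life_table, seed = seed)
}

#' Simulated cohort as long-format event sequences
#'
#' @param cohort An `nsclc_cohort`.
#' @return Data frame `id,event,time_months,cause` with one row per event
#'   (DIAG at 0, line starts, Death), ordered by patient and time.
#' @export
trajectories_long <- function(cohort) {
  stopifnot(inherits(cohort, "nsclc_cohort"))
  rows <- list(data.frame(id = cohort$id, event = "DIAG", time_months = 0,
                          cause = NA_character_))
  for (ev in c("l1t", "l2t", "l3t")) {
    col <- paste0("t_", ev)
    i <- which(!is.na(cohort[[col]]))
    if (length(i))
      rows[[length(rows) + 1L]] <- data.frame(
        id = cohort$id[i], event = toupper(ev),
        time_months = cohort[[col]][i], cause = NA_character_)
  }
  i <- which(!is.na(cohort$t_death))
  rows[[length(rows) + 1L]] <- data.frame(
    id = cohort$id[i], event = "Death", time_months = cohort$t_death[i],
    cause = cohort$cause[i])
  out <- do.call(rbind, rows)
  out[order(out$id, out$time_months), , drop = FALSE]
}
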