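biomarker_drivers <- function() {
  c("egfr_classic", "egfr_nonclassic", "alk", "ros1", "braf", "ntrk",
    "kras", "met", "ret", "none")
}
pdl1_categories <- function() c("ge50", "pd1_49", "lt1")

#' Default personalized treatment strategy
#'
#' The shipped strategy encodes a molecular diagnosis-treatment decision
#' tree for first- and second-line treatment: patients with a targetable
#' driver (classic and non-classic EGFR mutations, ALK, ROS1, BRAF, NTRK)
#' receive the corresponding first-line targeted therapy; all other patients
#' (including KRAS/MET/RET, for which no targeted first-line therapy is
#' assigned) are treated according to PD-L1 expression with pembrolizumab
#' alone or combined with platinum doublet chemotherapy. Second-line
#' treatment depends on first-line treatment (alectinib is followed by
#' lorlatinib; the BRAF combination falls back to the PD-L1 branch; all other
#' groups receive chemotherapy). Third-line treatment is always standard
#' chemotherapy.
#'
#' Hazard ratios for first-line EGFR-TKIs (0.43 gefitinib / 0.36 erlotinib,
#' mixed 50/50 by default), the prognostic hazard ratio of 0.82 for a classic
#' EGFR mutation, larotrectinib's 0.82, the pembrolizumab hazard ratio of 0.5
#' and its 23% long-term survivor fraction follow the published evidence the
#' model encodes; the remaining entries are illustrative literature-typical
#' defaults and are meant to be replaced by the user's own evidence table.
#' Benefit of first-line targeted therapy wears out 15 months after line
#' start, except for alectinib, whose benefit is durable.
#'
#' @return A validated strategy object (see [validate_strategy()]).
#' @export
default_strategy <- function() {
  s <- list(
    name = "personalized",
    prevalence = list(
      egfr_classic = 0.071, egfr_nonclassic = 0.010, alk = 0.020,
      ros1 = 0.019, braf = 0.021, ntrk = 0.002,
      kras = 0.250, met = 0.030, ret = 0.020, none = 0.557),
    pdl1 = list(ge50 = 0.30, pd1_49 = 0.35, lt1 = 0.35),
    tree = list(
      line1 = list(
        egfr_classic = list(mix = list(gefitinib = 0.5, erlotinib = 0.5)),
        egfr_nonclassic = "afatinib",
        alk = "alectinib",
        ros1 = "crizotinib",
        braf = "dabrafenib_trametinib",
        ntrk = "larotrectinib",
        kras = "pdl1", met = "pdl1", ret = "pdl1", none = "pdl1"),
      pdl1_line1 = list(
        ge50 = list(mix = list(pembrolizumab = 0.25, pembro_chemo = 0.75)),
        pd1_49 = "pembro_chemo",
        lt1 = "pembro_chemo"),
      line2 = list(
        alectinib = "lorlatinib",
        dabrafenib_trametinib = "pdl1",
        default = "chemo"),
      pdl1_line2 = list(
        ge50 = "pembrolizumab",
        pd1_49 = "chemo",
        lt1 = "chemo")),
    hr = list(
      chemo = 1,
      gefitinib = 0.43, erlotinib = 0.36, afatinib = 0.43,
      alectinib = 0.47, crizotinib = 0.45,
      dabrafenib_trametinib = 0.56, larotrectinib = 0.82,
      pembrolizumab = 0.50, pembro_chemo = 0.52,
      lorlatinib = 0.40),
    prognostic_hr = list(egfr_classic = 0.82, alk = 0.80),
    wearout = list(
      gefitinib = 15, erlotinib = 15, afatinib = 15,
      crizotinib = 15, dabrafenib_trametinib = 15, larotrectinib = 15),
    cure = list(pembrolizumab = 0.23, pembro_chemo = 0.23),
    class = list(
      chemo = "chemo",
      gefitinib = "targeted", erlotinib = "targeted", afatinib = "targeted",
      alectinib = "targeted", crizotinib = "targeted",
      dabrafenib_trametinib = "targeted", larotrectinib = "targeted",
      lorlatinib = "targeted",
      pembrolizumab = "immunotherapy", pembro_chemo = "immunotherapy")
  )
  validate_strategy(s)
}

#' Validate a strategy configuration
#'
#' Checks a strategy object for structural soundness and decision-tree
#' totality: prevalence and PD-L1 distributions sum to 1 (within 1e-9) with
#' non-negative entries; all hazard ratios are positive; cure fractions lie
#' in `[0, 1]`; wear-out times are non-negative; treatment mixtures sum to 1;
#' and every (line, driver, PD-L1, previous-treatment) combination reachable
#' in simulation resolves to exactly one treatment. All violations are
#' collected and reported together.
#'
#' @param strategy A strategy list (see [default_strategy()] for the shape).
#' @return The strategy, classed `nsclc_strategy`, invisibly usable downstream.
#' @export
validate_strategy <- function(strategy) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  s <- strategy
  for (fld in c("prevalence", "pdl1", "tree", "hr"))
    if (is.null(s[[fld]])) add(paste0("missing section '", fld, "'"))
  if (length(errs)) stop(paste(errs, collapse = "\n  "), call. = FALSE)

  pv <- unlist(s$prevalence)
  if (!setequal(names(pv), biomarker_drivers()))
    add(paste0("prevalence must cover exactly the drivers: ",
               paste(biomarker_drivers(), collapse = ", ")))
  if (any(pv < 0)) add("prevalence entries must be non-negative")
  if (abs(sum(pv) - 1) > 1e-9) add("driver prevalences must sum to 1")
  pd <- unlist(s$pdl1)
  if (!setequal(names(pd), pdl1_categories()))
    add("pdl1 must cover categories ge50, pd1_49, lt1")
  if (any(pd < 0) || abs(sum(pd) - 1) > 1e-9)
    add("pdl1 distribution must be non-negative and sum to 1")

  hrv <- unlist(s$hr)
  if (any(hrv <= 0)) add("all hazard ratios must be positive")
  if (!is.null(s$prognostic_hr) && any(unlist(s$prognostic_hr) <= 0))
    add("prognostic hazard ratios must be positive")
  if (!is.null(s$cure)) {
    cv <- unlist(s$cure)
    if (any(cv < 0 | cv > 1)) add("cure fractions must lie in [0, 1]")
  }
  if (!is.null(s$wearout) && any(unlist(s$wearout) < 0))
    add("wear-out times must be non-negative")

  resolve_all <- function(entry, where) {
    # returns the treatment names an entry can produce; validates mixtures
    if (is.character(entry)) return(entry)
    if (is.list(entry) && !is.null(entry$mix)) {
      w <- unlist(entry$mix)
      if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
        add(paste0("mixture weights at ", where,
                   " must be non-negative and sum to 1"))
      return(names(w))
    }
    add(paste0("unresolvable tree entry at ", where))
    character(0)
  }

  line1_treatments <- character(0)
  for (d in biomarker_drivers()) {
    e <- s$tree$line1[[d]]
    if (is.null(e)) { add(paste0("tree$line1 lacks driver '", d, "'")); next }
    tr <- resolve_all(e, paste0("line1/", d))
    if (identical(tr, "pdl1")) {
      for (cat in pdl1_categories()) {
        pe <- s$tree$pdl1_line1[[cat]]
        if (is.null(pe)) add(paste0("tree$pdl1_line1 lacks category '", cat, "'"))
        else line1_treatments <- c(line1_treatments,
                                   resolve_all(pe, paste0("pdl1_line1/", cat)))
      }
    } else line1_treatments <- c(line1_treatments, tr)
  }
  line1_treatments <- setdiff(unique(line1_treatments), "pdl1")

  line2_treatments <- character(0)
  for (tr1 in line1_treatments) {
    e <- s$tree$line2[[tr1]] %||% s$tree$line2$default
    if (is.null(e)) {
      add(paste0("tree$line2 resolves neither '", tr1, "' nor a default"))
      next
    }
    t2 <- resolve_all(e, paste0("line2/", tr1))
    if (identical(t2, "pdl1")) {
      for (cat in pdl1_categories()) {
        pe <- s$tree$pdl1_line2[[cat]]
        if (is.null(pe)) add(paste0("tree$pdl1_line2 lacks category '", cat, "'"))
        else line2_treatments <- c(line2_treatments,
                                   resolve_all(pe, paste0("pdl1_line2/", cat)))
      }
    } else line2_treatments <- c(line2_treatments, t2)
  }
  line2_treatments <- setdiff(unique(line2_treatments), "pdl1")

  all_trt <- unique(c(line1_treatments, line2_treatments, "chemo"))
  no_hr <- setdiff(all_trt, names(s$hr))
  if (length(no_hr))
    add(paste0("hr table lacks treatment(s): ", paste(no_hr, collapse = ", ")))

  if (length(errs))
    stop("invalid strategy configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  s$line1_treatments <- line1_treatments
  s$line2_treatments <- line2_treatments
  class(s) <- "nsclc_strategy"
  s
}

#' @export
print.nsclc_strategy <- function(x, ...) {
  cat(sprintf("Treatment strategy '%s'\n", x$name %||% "(unnamed)"))
  cat("  first-line treatments:", paste(x$line1_treatments, collapse = ", "), "\n")
  cat("  second-line treatments:", paste(x$line2_treatments, collapse = ", "), "\n")
  cured <- names(which(unlist(x$cure) > 0))
  if (length(cured))
    cat("  mixture-cure treatments:",
        paste(sprintf("%s (f = %.2f)", cured, unlist(x$cure)[cured]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Load a strategy configuration from YAML
#'
#' Reads a structured YAML file with sections `prevalence`, `pdl1`, `tree`,
#' `hr`, and optionally `prognostic_hr`, `wearout`, `cure`, `class`, and
#' validates it with [validate_strategy()] (all schema violations are
#' reported together, including decision-tree totality).
#'
#' @param path YAML file path.
#' @return A validated `nsclc_strategy`.
#' @export
load_strategy <- function(path) {
  validate_strategy(yaml::read_yaml(path))
}

#' Write a strategy configuration to YAML
#' @param strategy A strategy object.
#' @param path Output file.
#' @export
write_strategy <- function(strategy, path) {
  s <- unclass(strategy)
  s$line1_treatments <- NULL
  s$line2_treatments <- NULL
  yaml::write_yaml(s, path)
}

#' Draw molecular biomarker profiles
#'
#' Independent categorical draws of the driver alteration and the PD-L1
#' expression category, reflecting the modelling assumption that molecular
#' biomarkers are independent of the clinical baseline attributes.
#' Uses the current RNG stream; `set.seed()` for reproducibility.
#'
#' @param n Number of patients.
#' @param prevalence Named probabilities over [biomarker_drivers()].
#' @param pdl1_dist Named probabilities over [pdl1_categories()].
#' @return Data frame with columns `driver` and `pdl1`.
#' @export
assign_biomarkers <- function(n, prevalence, pdl1_dist) {
  pv <- unlist(prevalence)[biomarker_drivers()]
  pd <- unlist(pdl1_dist)[pdl1_categories()]
  if (anyNA(pv) || anyNA(pd))
    stop("prevalence/pdl1_dist must cover all categories", call. = FALSE)
  if (any(pv < 0) || any(pd < 0) || abs(sum(pv) - 1) > 1e-9 ||
      abs(sum(pd) - 1) > 1e-9)
    stop("probabilities must be non-negative and sum to 1", call. = FALSE)
  if (n == 0L)
    return(data.frame(driver = character(0), pdl1 = character(0)))
  data.frame(
    driver = sample(names(pv), n, replace = TRUE, prob = pv),
    pdl1 = sample(names(pd), n, replace = TRUE, prob = pd),
    stringsAsFactors = FALSE)
}

# resolve one tree entry (scalar treatment, mixture, or "pdl1" indirection)
resolve_entry <- function(entry, pdl1, pdl1_branch, u) {
  if (is.character(entry) && identical(entry, "pdl1"))
    entry <- pdl1_branch[[pdl1]]
  if (is.character(entry)) return(entry)
  if (is.list(entry) && !is.null(entry$mix)) {
    w <- unlist(entry$mix)
    if (is.null(u))
      stop("mixture tree entry requires a uniform draw u", call. = FALSE)
    return(names(w)[findInterval(u, cumsum(w) / sum(w)) + 1L])
  }
  stop("unresolvable tree entry", call. = FALSE)
}

#' Resolve the treatment for a patient profile and line
#'
#' Deterministic lookup in the strategy's decision tree. First-line treatment
#' depends on the driver alteration (falling back to the PD-L1 branch where
#' no targeted therapy is assigned); second-line treatment depends on the
#' first-line treatment received; third-line treatment is always standard
#' chemotherapy. Entries configured as mixtures (e.g. the gefitinib/erlotinib
#' split within classic EGFR) consume the supplied uniform draw `u` and are
#' deterministic given it.
#'
#' @param driver,pdl1 Biomarker profile (see [assign_biomarkers()]).
#' @param line Treatment line, 1, 2 or 3.
#' @param previous Treatment received in the previous line (`NULL` for line 1).
#' @param strategy A validated strategy.
#' @param u Optional uniform(0,1) draw used only for mixture entries.
#' @return Treatment name (character scalar).
#' @export
resolve_treatment <- function(driver, pdl1, line, previous = NULL, strategy,
                              u = NULL) {
  stopifnot(inherits(strategy, "nsclc_strategy"))
  if (!line %in% 1:3) stop("line must be 1, 2 or 3", call. = FALSE)
  if (line == 3) return("chemo")
  if (line == 1) {
    entry <- strategy$tree$line1[[driver]]
    return(resolve_entry(entry, pdl1, strategy$tree$pdl1_line1, u))
  }
  entry <- strategy$tree$line2[[previous]] %||% strategy$tree$line2$default
  resolve_entry(entry, pdl1, strategy$tree$pdl1_line2, u)
}

#' Effective transition modifiers for a treatment
#'
#' Translates a treatment (and the patient's driver profile) into the
#' hazard modifiers the engine applies to the two competing transitions of a
#' line: the treatment hazard ratio times the prognostic hazard ratio of the
#' driver (first line only), the benefit wear-out switch time, and the
#' long-term survivor (cure) fraction. By default the same hazard ratio is
#' applied to both competing transitions of the line (the assumption needed
#' when only a progression hazard ratio is available from trials); an `hr`
#' entry may instead be a list with components `next_line` and `death` for
#' transition-specific ratios.
#'
#' @param treatment Treatment name.
#' @param driver Driver alteration of the patient (for the prognostic effect).
#' @param strategy A validated strategy.
#' @param line Treatment line the modifiers apply to (prognostic effects are
#'   applied in line 1 only).
#' @return List with `hr_next`, `hr_death` (effective multipliers),
#'   `wearout` (months, `Inf` = durable) and `cure` (fraction).
#' @export
build_transition_modifiers <- function(treatment, driver = "none", strategy,
                                       line = 1) {
  stopifnot(inherits(strategy, "nsclc_strategy"))
  e <- strategy$hr[[treatment]]
  if (is.null(e)) stop("no hazard ratio configured for treatment '",
                       treatment, "'", call. = FALSE)
  if (is.list(e)) {
    hr_next <- e$next_line %||% stop("hr list entry needs 'next_line'")
    hr_death <- e$death %||% stop("hr list entry needs 'death'")
  } else hr_next <- hr_death <- e
  prog <- 1
  if (line == 1 && !is.null(strategy$prognostic_hr[[driver]]))
    prog <- strategy$prognostic_hr[[driver]]
  list(hr_next = hr_next * prog,
       hr_death = hr_death * prog,
       wearout = strategy$wearout[[treatment]] %||% Inf,
       cure = strategy$cure[[treatment]] %||% 0)
}

#' Assign long-term survivor status
#'
#' Bernoulli draws of mixture-cure membership: a fraction `f` of patients
#' starting an immunotherapy line are long-term survivors who are no longer
#' at risk of disease progression or disease death and die from background
#' mortality instead (and are not eligible for a next treatment line).
#' `f = 0` reproduces the standard (non-cure) time-to-event distribution.
#'
#' @param n Number of patients.
#' @param f Long-term survivor fraction in `[0, 1]`.
#' @return Logical vector of length `n`.
#' @export
assign_longterm <- function(n, f) {
  if (!is.numeric(f) || length(f) != 1L || f < 0 || f > 1)
    stop("f must be a single fraction in [0, 1]", call. = FALSE)
  if (n == 0L) return(logical(0))
  stats::runif(n) < f
}
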