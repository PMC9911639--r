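#' Age- and sex-specific life table
#'
#' Validates (and classes) a life table giving, per sex and integer age, the
#' annual probability of dying from other (non-disease) causes. Used to model
#' background mortality: simulated patients can die of other causes at any
#' point of their disease pathway.
#'
#' Annual probabilities \eqn{q_x} are converted to constant within-year rates
#' \eqn{r_x = -\log(1 - q_x)}, giving a piecewise-constant hazard that
#' advances with the patient's attained age on the simulation clock. The last
#' tabulated age per sex acts as a terminal open band: its rate applies to
#' all higher ages.
#'
#' @param data Data frame with columns `sex` (values `"male"`/`"female"`),
#'   `age` (integer years, contiguous within sex) and `qx` (annual mortality
#'   probability in `[0, 1)`).
#' @return The validated data frame, classed `life_table`.
#' @seealso [sample_background_time()], [read_life_table()],
#'   [generate_life_table()]
#' @export
life_table <- function(data) {
  data <- as.data.frame(data)
  need <- c("sex", "age", "qx")
  if (!all(need %in% names(data)))
    stop("life table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(data$sex %in% c("male", "female")))
    stop("life table sex must be 'male' or 'female'", call. = FALSE)
  if (any(data$qx < 0 | data$qx >= 1))
    stop("annual probabilities qx must lie in [0, 1)", call. = FALSE)
  if (any(data$age != floor(data$age)))
    stop("ages must be integers", call. = FALSE)
  for (s in unique(data$sex)) {
    a <- sort(data$age[data$sex == s])
    if (any(diff(a) != 1L))
      stop("ages must be contiguous within sex (", s, ")", call. = FALSE)
  }
  data <- data[order(data$sex, data$age), , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("life_table", "data.frame")
  data
}

#' Read a life table from CSV
#'
#' @param path CSV file with header `sex,age,qx`.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

# per-sex annual rate schedule starting at min tabulated age
lt_rates <- function(lt, sex) {
  rows <- lt[lt$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0L) stop("sex '", sex, "' not in life table", call. = FALSE)
  list(age0 = min(rows$age), rates = -log1p(-rows$qx))
}

#' Sample time to death from other causes
#'
#' Simulates, per patient, the time (months from diagnosis) at which the
#' patient would die from causes other than the disease, under the
#' piecewise-constant annual hazards of a life table. The hazard band in force
#' at simulation time \eqn{u} (years after diagnosis) is the one for attained
#' integer age \eqn{\lfloor \mathrm{age}_0 + u \rfloor}; beyond the last
#' tabulated age the terminal band's rate applies indefinitely. When all
#' remaining rates are zero the sampled time is `Inf` (the patient never dies
#' of other causes).
#'
#' @param lt A [life_table()].
#' @param age Numeric vector of ages at diagnosis in years.
#' @param sex Character vector (`"male"`/`"female"`), length 1 or `length(age)`.
#' @return Numeric vector of times in months (possibly `Inf`).
#' @export
sample_background_time <- function(lt, age, sex) {
  stopifnot(inherits(lt, "life_table"))
  n <- length(age)
  if (length(sex) == 1L) sex <- rep(sex, n)
  if (length(sex) != n) stop("sex must have length 1 or length(age)", call. = FALSE)
  if (n == 0L) return(numeric(0))
  sched <- list(male = NULL, female = NULL)
  for (s in unique(sex)) sched[[s]] <- lt_rates(lt, s)
  for (s in unique(sex)) {
    if (any(age[sex == s] < sched[[s]]$age0))
      stop("age below the youngest tabulated age for sex '", s, "'", call. = FALSE)
  }
  # flatten the two per-sex schedules into vectorized lookups
  is_m <- sex == "male"
  age0 <- ifelse(is_m, sched$male$age0 %||% NA_real_, sched$female$age0 %||% NA_real_)
  len <- ifelse(is_m, length(sched$male$rates), length(sched$female$rates))
  rate_at <- function(band) {
    # band: 1-based index into the per-sex rate schedule, already clamped
    r <- numeric(length(band))
    if (any(is_m)) r[is_m] <- sched$male$rates[band[is_m]]
    if (any(!is_m)) r[!is_m] <- sched$female$rates[band[!is_m]]
    r
  }
  E <- stats::rexp(n)               # target cumulative hazard
  t_years <- numeric(n)             # time elapsed since diagnosis (years)
  need <- E                         # hazard still to accumulate
  done <- logical(n)
  age_now <- age
  repeat {
    idx <- !done
    if (!any(idx)) break
    band <- pmin(floor(age_now) - age0 + 1, len)
    r <- rate_at(band)
    terminal <- band >= len
    nxt <- floor(age_now) + 1 - age_now   # years to the next band
    nxt[nxt == 0] <- 1
    nxt[terminal] <- Inf
    gain <- r * nxt
    gain[r == 0] <- 0                     # incl. 0 * Inf in a terminal band
    hit <- idx & (r > 0) & (need <= gain)
    t_years[hit] <- t_years[hit] + need[hit] / r[hit]
    done[hit] <- TRUE
    stuck <- idx & !hit & terminal        # terminal band cannot be left
    t_years[stuck] <- Inf
    done[stuck] <- TRUE
    move <- idx & !hit & !stuck
    need[move] <- need[move] - gain[move]
    t_years[move] <- t_years[move] + nxt[move]
    age_now[move] <- floor(age_now[move]) + 1
  }
  t_years * 12
}
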