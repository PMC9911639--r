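`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a bounded child seed from a base seed and a stream label, so the
# engine's independent randomness streams (baseline/BSC vs strategy-dependent
# draws) are reproducible from one user-facing seed. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(baseline = 0, strategy = 1, validation = 2, calibration = 3,
            synth = 4)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 48271 + offs[[stream]] * 104729) %% 2147483587) + 1L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}

# weighted/unweighted median of a fully observed sample; NA when empty
med_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_
mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
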