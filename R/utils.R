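`%||%` <- function(a, b) if (is.null(a)) b else a

## derive a per-stage seed from the single global seed; kept below 2^31-1
stage_seed <- function(seed, stage) {
  stages <- c("latents", "qpcr", "otu", "measurements", "misc")
  k <- match(stage, stages)
  if (is.na(k)) stop("unknown simulation stage: ", stage)
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483629)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " must be finite", call. = FALSE)
  invisible(x)
}

assert_nonneg <- function(x, what) {
  assert_finite(x, what)
  if (any(x < 0)) stop(what, " must be non-negative", call. = FALSE)
  invisible(x)
}

## compartment -> reporting unit for concentrations
compartment_units <- c(water = "mL", mucous = "cm2", digesta = "g", fin = "cm2")

## measurement unit vocabulary (closed)
measurement_units <- c("ng/kg", "ng/L", "pg/g", "ng/cm2", "ng/intestine", "copies/mL")
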