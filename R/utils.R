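# Internal helpers: classed errors, local RNG scoping, child-seed policy.

rfd_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "rotifd_error", "error", "condition")))
}

rfd_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream. All exported stochastic operations route through this, so a fixed
# configuration yields byte-identical output regardless of ambient RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# One master seed per simulation; per-stage child seeds at fixed documented
# offsets so any stage can be regenerated independently. Kept < 2^31 - 1.
STAGE_OFFSETS <- c(traits = 1L, environment = 2L, community = 3L, missing = 4L)

child_seed <- function(master_seed, stage) {
  stage <- match.arg(stage, names(STAGE_OFFSETS))
  (abs(as.integer(master_seed)) %% 2146483L) * 1000L + STAGE_OFFSETS[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
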