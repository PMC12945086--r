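`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a child seed from a base seed and a counter
#'
#' Deterministic integer mixing used to give every ranking call, simulated
#' participant, and simulation replicate its own reproducible random stream
#' without consuming the caller's RNG state. All arithmetic stays below
#' 2^53 so the result is exact in double precision.
#'
#' @param seed Integer base seed (< 2^31).
#' @param counter Non-negative integer stream index.
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  x <- abs(as.double(seed)) %% 2147483647
  for (v in c(as.double(counter) %% 2147483647, 40507)) {
    x <- (x * 69069 + v + 1) %% 2147483647
  }
  as.integer(x + 1)
}

# Evaluate `fun()` under a temporarily seeded RNG, restoring the caller's
# .Random.seed afterwards so library code never perturbs user randomness.
with_local_seed <- function(seed, fun) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  fun()
}

# ISO-8601 timestamp helpers; all timestamps are stored in UTC and
# re-expressed in a participant's local timezone only for calendar-day
# boundaries (use-rate denominators).
parse_ts <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out)) stop("unparseable ISO-8601 timestamp: ", x[which(is.na(out))[1]])
  out
}

fmt_ts <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

calendar_day <- function(ts, tz = "UTC") format(ts, "%Y-%m-%d", tz = tz)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
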