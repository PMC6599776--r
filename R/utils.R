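#' @importFrom stats pnorm dnorm qnorm quantile rnorm rbinom runif rpois
#'   rexp optim nlminb pchisq integrate median setNames optimHess sd
#' @importFrom utils write.csv read.csv
#' @importFrom rlang .data
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic child seed for a named sub-stream, kept inside 32-bit range.
child_seed <- function(master, stream) {
  if (is.null(master)) return(NULL)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483399L) + 1L
}

# All quantiles in the package use linear interpolation between order
# statistics with plotting position (k-1)/(n-1) (stats::quantile type 7).
quantile7 <- function(x, probs) unname(stats::quantile(x, probs, type = 7, names = FALSE))

utc <- function(x) as.POSIXct(x, tz = "UTC")

floor_hour <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 3600) * 3600, tz = "UTC", origin = "1970-01-01")
}

is_hour_aligned <- function(t) all(as.numeric(t) %% 3600 == 0)

hours <- function(h) h * 3600

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
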