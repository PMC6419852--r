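#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded helpers do not disturb
#' the caller's random stream. `seed = NULL` leaves the stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a seed to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Timestamped, leveled log line
#' @noRd
icpmir_log <- function(level, stage, msg) {
  message(sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, stage, msg))
}

#' Stop with a classed condition
#' @noRd
icpmir_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "icpmir_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Case-insensitive pair key "regulator|target"
#' @noRd
pair_key <- function(regulator, target) {
  paste(tolower(trimws(regulator)), tolower(trimws(target)), sep = "\r")
}

#' Check a scalar is a count in a range
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    icpmir_stop("icpmir_bad_argument", "`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}
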