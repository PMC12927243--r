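# Shared small helpers: time handling, seeded evaluation, distances.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' Parse a timestamp as UTC
#'
#' @param x Character, Date or POSIXct.
#' @return POSIXct in UTC.
#' @keywords internal
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

#' UTC calendar date of a timestamp
#' @keywords internal
utc_date <- function(x) as.Date(x, tz = "UTC")

#' Great-circle distance between points, km
#'
#' Thin wrapper over [geosphere::distHaversine()] returning kilometres.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84),
#'   recycled to a common length.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2) / 1000
}

#' Month-day integer (mmdd) of a timestamp, UTC
#' @keywords internal
mmdd <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  (lt$mon + 1L) * 100L + lt$mday
}

# stop() with a class so callers can distinguish configuration/schema errors
abort_coastnet <- function(msg, class) {
  stop(structure(class = c(class, "coastnet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
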