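#' Round or truncate to a fixed number of decimals
#'
#' Printed trigger-tool tables mix conventional rounding with plain truncation
#' (for example an agreement of 0.8959 shown as 0.89). Both presentation modes
#' are available everywhere a report is rendered; computation always keeps full
#' precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @param mode `"round"` (default) or `"truncate"`.
#' @return numeric vector at the requested precision.
#' @examples
#' att_round(0.8959, 2)               # 0.90
#' att_round(0.8959, 2, "truncate")   # 0.89
#' @export
att_round <- function(x, digits = 1, mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (mode == "round") return(round(x, digits))
  # nudge to keep exactly-representable values from truncating one ulp low
  trunc(x * 10^digits + sign(x) * 1e-9) / 10^digits
}

# whole minutes between two timestamps, rounding down; NA when either is missing
minutes_between <- function(from, to) {
  ifelse(is.na(from) | is.na(to), NA_real_,
         floor(as.numeric(difftime(to, from, units = "mins"))))
}

# run code with a locally seeded Mersenne-Twister stream, restoring the caller's
# RNG state afterwards so library calls never disturb user randomness
with_mt_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister")
  }
  force(code)
}

# derive independent substream seeds (< 2^31) from one master seed
substream_seed <- function(seed, stream) {
  offsets <- c(cohort = 11L, sampling = 23L, rater1 = 37L, rater2 = 41L,
               judgement = 53L, stats = 67L)
  if (!stream %in% names(offsets)) abort(paste0("unknown seed stream: ", stream))
  (as.integer(seed) * 2654435L + offsets[[stream]]) %% 2147483629L
}

fmt_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- !is.na(x) & x != "" & is.na(out)
  # tolerate a space separator
  out[bad] <- as.POSIXct(x[bad], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out
}
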