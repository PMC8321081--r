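#' Round half away from zero
#'
#' Fixed-precision rounding with halves rounded up, matching how percentages
#' are conventionally printed in migration summary tables (`round()` in R
#' rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count, printed-table style
#'
#' @param count,total non-negative counts.
#' @param digits decimal places (default 1, as in migration tables).
#' @return `100 * count / total` rounded half-up; `NA` when `total` is 0.
#' @export
pct_of <- function(count, total, digits = 1) {
  ifelse(total > 0, round_half_up(100 * count / total, digits), NA_real_)
}

#' Number of frames spanned by an acquisition
#'
#' Uses the convention that an acquisition of duration `T` at interval
#' `dt` comprises `T / dt` frames (24 h at 30 s gives 2880 frames).
#'
#' @param duration_s total acquisition duration in seconds.
#' @param interval_s time step interval in seconds.
#' @return integer frame count.
#' @export
n_frames_for <- function(duration_s, interval_s) {
  stopifnot(duration_s > 0, interval_s > 0)
  as.integer(round(duration_s / interval_s))
}

# Restore the RNG state on exit; returns invisibly whether a seed was set.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(FALSE))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(TRUE)
}

stop_config <- function(...) {
  stop(structure(class = c("phasetrack_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
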