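#' Gate a contact-pressure trace
#'
#' Reproduces the probe's measurement trigger: a sample is accepted when the
#' contact pressure lies inside the window `[p_min, p_max]` (inclusive; the
#' defaults 24-72 mmHg are the window previously found to give consistent
#' probe contact), and a trigger interval is a maximal run of accepted samples
#' spanning at least `dwell` seconds of sustained in-window contact.
#'
#' @param trace A data frame whose first two columns are time (s, strictly
#'   ascending) and pressure (mmHg, finite and nonnegative).
#' @param p_min,p_max Window bounds, mmHg (defaults 24 and 72).
#' @param dwell Minimum continuous in-window time before a trigger, s
#'   (default 0.5; must be positive — use a value below the sampling interval
#'   to trigger on a single in-window reading).
#' @return A tibble of trigger intervals (`start`, `end`, `duration`,
#'   `n_samples`), with the per-sample accept flags attached as attribute
#'   `"accepted"`.
#' @export
#' @examples
#' tr <- data.frame(time = seq(0, 5, 0.1), pressure = 50)
#' gate_trace(tr)
gate_trace <- function(trace, p_min = 24, p_max = 72, dwell = 0.5) {
  if (dwell <= 0) abort("dwell must be positive", class = "drsquant_config_error")
  if (p_min < 0 || p_min >= p_max) {
    abort("window bounds require 0 <= p_min < p_max", class = "drsquant_config_error")
  }
  trace <- as.data.frame(trace)
  if (nrow(trace) == 0) abort("pressure trace is empty")
  tm <- as.numeric(trace[[1]]); pr <- as.numeric(trace[[2]])
  if (is.unsorted(tm, strictly = TRUE)) abort("trace times must be strictly ascending")
  if (any(!is.finite(pr)) || any(pr < 0)) abort("pressures must be finite and >= 0")

  ok <- pr >= p_min & pr <= p_max
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  iv <- tibble(
    start = tm[starts[keep]], end = tm[ends[keep]],
    n_samples = r$lengths[keep]
  )
  iv$duration <- iv$end - iv$start
  iv <- iv[iv$duration >= dwell, c("start", "end", "duration", "n_samples")]
  attr(iv, "accepted") <- ok
  iv
}

#' Per-sample accept flags of the pressure gate
#'
#' Returns the trace with a logical `accepted` column (in-window by the
#' inclusive bounds), without the dwell requirement.
#'
#' @inheritParams gate_trace
#' @return The trace as a tibble with an added `accepted` column.
#' @export
gate_flags <- function(trace, p_min = 24, p_max = 72) {
  trace <- as.data.frame(trace)
  out <- tibble(time = as.numeric(trace[[1]]), pressure = as.numeric(trace[[2]]))
  out$accepted <- out$pressure >= p_min & out$pressure <= p_max
  out
}

#' Read a pressure trace from delimited text
#'
#' Two-column format: `time_s`, `pressure_mmHg`, optional header.
#'
#' @param path File path.
#' @return A tibble with columns `time`, `pressure`.
#' @export
read_pressure_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  tibble(time = as.numeric(d[[1]]), pressure = as.numeric(d[[2]]))
}
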