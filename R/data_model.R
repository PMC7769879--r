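#' Concentration time series for one compound in one chamber
#'
#' @param cell_id identifier of the cell.
#' @param chamber `"cathode"` or `"anode"`.
#' @param compound compound name (must be registered).
#' @param time_h sampling times, hours, strictly increasing.
#' @param conc_mM concentrations, mM, non-negative.
#' @param registry compound registry used for validation.
#' @return data.frame of class `concentration_series` with columns
#'   `time_h`, `conc_mM` and attributes `cell_id`, `chamber`, `compound`.
#' @export
concentration_series <- function(cell_id, chamber, compound, time_h, conc_mM,
                                 registry = compound_registry()) {
  chamber <- match.arg(chamber, c("cathode", "anode"))
  if (length(time_h) != length(conc_mM))
    stop("time_h and conc_mM must have equal length")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(conc_mM < 0)) stop("concentrations must be non-negative")
  get_compound(compound, registry)  # errors on unknown compound
  out <- data.frame(time_h = as.numeric(time_h), conc_mM = as.numeric(conc_mM))
  attr(out, "cell_id") <- cell_id
  attr(out, "chamber") <- chamber
  attr(out, "compound") <- tolower(compound)
  class(out) <- c("concentration_series", "data.frame")
  out
}

#' Chronoamperometric current trace
#'
#' @param cell_id identifier.
#' @param time_h times, hours, strictly increasing.
#' @param current_mA currents, mA (cathodic current is negative by
#'   convention; integration uses the magnitude).
#' @param segments data.frame with columns `t_start`, `t_end`,
#'   `potential_V` describing the applied-potential program; segments must
#'   not overlap and must cover the trace span.
#' @return data.frame of class `current_trace`.
#' @export
current_trace <- function(cell_id, time_h, current_mA, segments = NULL) {
  if (length(time_h) != length(current_mA))
    stop("time_h and current_mA must have equal length")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (is.null(segments))
    segments <- data.frame(t_start = min(time_h), t_end = max(time_h),
                           potential_V = NA_real_)
  o <- order(segments$t_start)
  segments <- segments[o, , drop = FALSE]
  if (any(segments$t_end <= segments$t_start))
    stop("each potential segment needs t_end > t_start")
  if (nrow(segments) > 1 &&
      any(segments$t_start[-1] < segments$t_end[-nrow(segments)] - 1e-9))
    stop("potential segments must not overlap")
  if (segments$t_start[1] > min(time_h) + 1e-9 ||
      segments$t_end[nrow(segments)] < max(time_h) - 1e-9)
    stop("potential segments must cover the trace span")
  out <- data.frame(time_h = as.numeric(time_h), current_mA = as.numeric(current_mA))
  attr(out, "cell_id") <- cell_id
  attr(out, "segments") <- segments
  class(out) <- c("current_trace", "data.frame")
  out
}

#' Batch cycle manifest entry
#'
#' @param index cycle ordinal (1-based).
#' @param t_start,t_end cycle boundaries, hours.
#' @param additions data.frame `time_h, compound, mmol` of substrate fed
#'   (the time-zero charge of a cycle is an addition at `t_start`).
#' @param withdrawals data.frame `time_h, volume_mL, chamber` of samples
#'   removed for analysis.
#' @return list of class `batch_cycle`.
#' @export
batch_cycle <- function(index, t_start, t_end,
                        additions = NULL, withdrawals = NULL) {
  if (t_start >= t_end) stop("cycle needs t_start < t_end")
  if (is.null(additions))
    additions <- data.frame(time_h = numeric(), compound = character(),
                            mmol = numeric())
  if (is.null(withdrawals))
    withdrawals <- data.frame(time_h = numeric(), volume_mL = numeric(),
                              chamber = character())
  eps <- 1e-9
  if (nrow(additions) &&
      any(additions$time_h < t_start - eps | additions$time_h > t_end + eps))
    stop("additions must lie within the cycle")
  if (nrow(withdrawals)) {
    if (any(withdrawals$time_h < t_start - eps | withdrawals$time_h > t_end + eps))
      stop("withdrawals must lie within the cycle")
    if (any(withdrawals$volume_mL <= 0))
      stop("withdrawal volumes must be positive")
  }
  structure(list(index = index, t_start = t_start, t_end = t_end,
                 additions = additions, withdrawals = withdrawals),
            class = "batch_cycle")
}

#' A complete cell-experiment record
#'
#' Bundles the cycle manifest, concentration series (both chambers),
#' current trace (absent for non-electrochemical controls) and headspace
#' gas readings for one cell. All invariants are validated on
#' construction; total sample withdrawal above 5 % of the working volume
#' raises a warning (the usual practice keeps it below that).
#'
#' @param cell_id identifier.
#' @param working_volume working (catholyte) volume, L.
#' @param cycles list of [batch_cycle()] objects.
#' @param series list of [concentration_series()] objects.
#' @param current optional [current_trace()].
#' @param gas data.frame `cycle, compound, mmol` of end-of-cycle headspace
#'   amounts (missing readings are treated as zero outlet).
#' @param registry compound registry.
#' @return list of class `cell_experiment`.
#' @export
cell_experiment <- function(cell_id, working_volume, cycles, series,
                            current = NULL, gas = NULL,
                            registry = compound_registry()) {
  if (working_volume <= 0) stop("working_volume must be positive")
  if (!length(cycles)) stop("at least one cycle is required")
  idx <- vapply(cycles, `[[`, numeric(1), "index")
  cycles <- cycles[order(idx)]
  span <- range(unlist(lapply(cycles, function(cy) c(cy$t_start, cy$t_end))))
  for (s in series) {
    if (min(s$time_h) < span[1] - 1e-9 || max(s$time_h) > span[2] + 1e-9)
      stop("series ", attr(s, "compound"), " (", attr(s, "chamber"),
           ") has samples outside all cycles [", span[1], ", ", span[2], "] h")
  }
  if (is.null(gas))
    gas <- data.frame(cycle = integer(), compound = character(), mmol = numeric())
  if (nrow(gas) && any(gas$mmol < 0)) stop("gas amounts must be non-negative")
  # volume is reintegrated at each cycle start, so depletion is per cycle
  for (cy in cycles) {
    wv <- sum(cy$withdrawals$volume_mL)
    if (wv / 1000 > 0.05 * working_volume) {
      warning("withdrawn volume in cycle ", cy$index, " exceeds 5% of the ",
              "working volume; withdrawal corrections become material",
              call. = FALSE)
      break
    }
  }
  structure(list(cell_id = cell_id, working_volume = working_volume,
                 cycles = cycles, series = series, current = current,
                 gas = gas, registry = registry),
            class = "cell_experiment")
}

#' @export
print.cell_experiment <- function(x, ...) {
  cat("cell_experiment", x$cell_id, "\n")
  cat("  working volume:", x$working_volume, "L;",
      length(x$cycles), "cycle(s);", length(x$series), "series;",
      if (is.null(x$current)) "no current trace (control)" else "current trace",
      "\n")
  invisible(x)
}

#' Is this a non-electrochemical control?
#' @param exp a [cell_experiment()].
#' @return logical.
#' @export
is_control <- function(exp) is.null(exp$current)

series_key <- function(s)
  paste(attr(s, "chamber"), attr(s, "compound"), sep = ":")

#' Find a series by chamber and compound
#' @param exp a [cell_experiment()].
#' @param compound compound name.
#' @param chamber `"cathode"` (default) or `"anode"`.
#' @return a `concentration_series`, or `NULL` if absent.
#' @export
get_series <- function(exp, compound, chamber = "cathode") {
  key <- paste(chamber, tolower(compound), sep = ":")
  for (s in exp$series) if (series_key(s) == key) return(s)
  NULL
}

interp_conc <- function(series, time) {
  if (time < min(series$time_h) - 1e-9 || time > max(series$time_h) + 1e-9)
    stop("time ", time, " h is outside the sampled span of ",
         attr(series, "compound"), " (", min(series$time_h), "-",
         max(series$time_h), " h); extrapolation is not supported")
  stats::approx(series$time_h, series$conc_mM, xout = time, rule = 1)$y
}

#' Moles of a compound present in a chamber at a time
#'
#' Linear interpolation between samples; extrapolation outside the sampled
#' span is an error.
#'
#' @param series a [concentration_series()].
#' @param time time, h.
#' @param volume chamber volume, L.
#' @return mmol.
#' @export
moles_in_chamber <- function(series, time, volume) {
  interp_conc(series, time) * volume
}

#' Moles removed with analytical samples over a cycle
#'
#' Each withdrawal removes `concentration at withdrawal time x withdrawal
#' volume` of the compound (the default convention; see the methods
#' vignette for the cycle-average alternative).
#'
#' @param series a [concentration_series()].
#' @param cycle a [batch_cycle()].
#' @param method `"at_withdrawal"` (default) uses the interpolated
#'   concentration at each withdrawal time; `"cycle_average"` uses the
#'   time-averaged concentration over the cycle for every withdrawal.
#' @return mmol removed.
#' @export
withdrawn_moles <- function(series, cycle, method = c("at_withdrawal",
                                                      "cycle_average")) {
  method <- match.arg(method)
  w <- cycle$withdrawals
  w <- w[w$chamber == attr(series, "chamber"), , drop = FALSE]
  if (!nrow(w)) return(0)
  if (method == "at_withdrawal") {
    conc <- vapply(w$time_h, interp_conc, numeric(1), series = series)
  } else {
    tt <- series$time_h[series$time_h >= cycle$t_start - 1e-9 &
                        series$time_h <= cycle$t_end + 1e-9]
    cc <- vapply(tt, interp_conc, numeric(1), series = series)
    conc <- rep(pracma::trapz(tt, cc) / diff(range(tt)), nrow(w))
  }
  sum(conc * w$volume_mL / 1000)
}
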