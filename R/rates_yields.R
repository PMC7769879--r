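#' Interval production rates between consecutive samples
#'
#' The rate over each consecutive sample pair is the concentration
#' increment divided by the time interval, converted to mM per day
#' (1 d = 24 h). Negative rates indicate consumption. No smoothing is
#' applied.
#'
#' @param series a [concentration_series()] with at least two samples.
#' @return data.frame of class `rate_series` with columns `t_start`,
#'   `t_end`, `t_mid` (h) and `rate_mM_d`.
#' @export
interval_rates <- function(series) {
  if (nrow(series) < 2) stop("at least two samples are required")
  dt <- diff(series$time_h)
  if (any(dt == 0)) stop("duplicate timestamps")
  rate <- diff(series$conc_mM) / dt * 24
  out <- data.frame(t_start = utils::head(series$time_h, -1),
                    t_end = series$time_h[-1],
                    t_mid = (utils::head(series$time_h, -1) + series$time_h[-1]) / 2,
                    rate_mM_d = rate)
  attr(out, "compound") <- attr(series, "compound")
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Highest production rate
#'
#' Maximum positive interval rate, optionally restricted to one batch
#' cycle; 0 if no interval shows net production.
#'
#' @param rates a `rate_series` from [interval_rates()].
#' @param window optional [batch_cycle()] restricting the intervals
#'   considered (an interval counts if its midpoint falls in the cycle).
#' @return mM per day.
#' @export
max_rate <- function(rates, window = NULL) {
  if (!nrow(rates)) stop("empty rate series")
  r <- rates$rate_mM_d
  if (!is.null(window))
    r <- r[rates$t_mid >= window$t_start & rates$t_mid <= window$t_end]
  r <- r[r > 0]
  if (!length(r)) 0 else max(r)
}

#' Net amounts formed and substrate consumed over a cycle
#'
#' Computes, per compound, the net mmol formed during a batch cycle,
#' counting product left in the catholyte, product removed with samples,
#' and product that migrated to the anolyte by cycle end; and the mmol of
#' substrate consumed (fed at cycle start plus re-additions, minus
#' residual, minus substrate removed unconsumed with samples).
#'
#' @param exp a [cell_experiment()].
#' @param cycle_index which cycle.
#' @param substrate substrate compound (default `"lactate"`).
#' @param withdrawal_method passed to [withdrawn_moles()].
#' @return list with `formed` (named mmol per compound, net of the initial
#'   inventory), `consumed` (mmol substrate), and the per-compound
#'   breakdown `detail` (residual, withdrawn, anolyte, initial mmol).
#' @export
cycle_deltas <- function(exp, cycle_index = 1, substrate = "lactate",
                         withdrawal_method = "at_withdrawal") {
  cy <- exp$cycles[[cycle_index]]
  V <- exp$working_volume
  compounds <- unique(vapply(exp$series, attr, character(1), "compound"))
  detail <- lapply(compounds, function(cmp) {
    s <- get_series(exp, cmp, "cathode")
    initial <- if (is.null(s)) 0 else moles_in_chamber(s, cy$t_start, V)
    residual <- if (is.null(s)) 0 else moles_in_chamber(s, cy$t_end, V)
    withdrawn <- if (is.null(s)) 0 else
      withdrawn_moles(s, cy, method = withdrawal_method)
    a <- get_series(exp, cmp, "anode")
    anolyte <- if (is.null(a)) 0 else {
      end_mmol <- moles_in_chamber(a, min(cy$t_end, max(a$time_h)), V)
      start_mmol <- moles_in_chamber(a, max(cy$t_start, min(a$time_h)), V)
      max(end_mmol - start_mmol, 0)
    }
    # additions at the cycle-start instant are already part of the initial
    # sampled inventory; only later re-additions add to it
    added <- if (nrow(cy$additions))
      sum(cy$additions$mmol[tolower(cy$additions$compound) == cmp &
                            cy$additions$time_h > cy$t_start + 1e-9]) else 0
    list(compound = cmp, initial = initial, residual = residual,
         withdrawn = withdrawn, anolyte = anolyte, added = added)
  })
  names(detail) <- compounds

  formed <- vapply(detail, function(d)
    d$residual + d$withdrawn + d$anolyte - d$initial - d$added, numeric(1))
  sub <- detail[[tolower(substrate)]]
  if (is.null(sub)) stop("no series for substrate ", substrate)
  consumed <- sub$initial + sub$added - sub$residual - sub$withdrawn - sub$anolyte
  list(formed = formed, consumed = consumed, detail = detail)
}

#' Per-cycle molar product yield
#'
#' Yield on the whole batch cycle: mmol product formed (including product
#' withdrawn with samples and product that migrated to the anolyte)
#' divided by mmol substrate consumed.
#'
#' @param formed mmol product formed over the cycle.
#' @param consumed mmol substrate consumed over the cycle (> 0).
#' @return mol product per mol substrate consumed.
#' @export
cycle_yield <- function(formed, consumed) {
  if (consumed <= 0) stop("substrate consumption must be positive")
  max(formed, 0) / consumed
}

#' Rates-and-yields report for one experiment
#'
#' One row per batch cycle with duration, average current (excluding any
#' startup segment at a different applied potential if
#' `exclude_startup = TRUE`), per-product molar yields and highest
#' production rates.
#'
#' @param exp a [cell_experiment()].
#' @param products product compounds to report.
#' @param substrate substrate compound.
#' @param exclude_startup drop the first applied-potential segment from
#'   the average-current window when more than one segment exists.
#' @return data.frame, one row per cycle.
#' @export
report_rates <- function(exp, products = c("propionate", "acetate", "butyrate"),
                         substrate = "lactate", exclude_startup = TRUE) {
  rows <- lapply(seq_along(exp$cycles), function(i) {
    cy <- exp$cycles[[i]]
    d <- cycle_deltas(exp, i, substrate)
    row <- data.frame(cell = exp$cell_id, batch = cy$index,
                      duration_h = cy$t_end - cy$t_start,
                      avg_current_mA = if (is.null(exp$current)) NA_real_ else
                        average_current(exp$current, cy, exclude_startup))
    for (p in products) {
      formed <- if (p %in% names(d$formed)) d$formed[[p]] else 0
      row[[paste0("yield_", p)]] <-
        if (d$consumed > 0) cycle_yield(formed, d$consumed) else NA_real_
      s <- get_series(exp, p, "cathode")
      row[[paste0("max_rate_", p)]] <-
        if (is.null(s) || nrow(s) < 2) 0 else max_rate(interval_rates(s), cy)
    }
    row
  })
  do.call(rbind, rows)
}

#' Average current over a cycle
#'
#' Time-weighted mean of the current magnitude over the cycle window.
#' With `exclude_startup = TRUE` and a multi-segment potential program,
#' the first segment (the startup at a more negative applied potential)
#' is excluded from the window.
#'
#' @param trace a [current_trace()].
#' @param cycle a [batch_cycle()], or NULL for the whole trace.
#' @param exclude_startup logical.
#' @return mA.
#' @export
average_current <- function(trace, cycle = NULL, exclude_startup = FALSE) {
  t0 <- if (is.null(cycle)) min(trace$time_h) else cycle$t_start
  tf <- if (is.null(cycle)) max(trace$time_h) else cycle$t_end
  seg <- attr(trace, "segments")
  if (exclude_startup && nrow(seg) > 1)
    t0 <- max(t0, seg$t_end[1])
  keep <- trace$time_h >= t0 - 1e-9 & trace$time_h <= tf + 1e-9
  tt <- trace$time_h[keep]; ii <- abs(trace$current_mA[keep])
  if (length(tt) < 2) stop("too few current samples in window")
  pracma::trapz(tt, ii) / (max(tt) - min(tt))
}
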