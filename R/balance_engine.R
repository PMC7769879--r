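FARADAY <- 96485  # C per mol e-
GAS_R <- 8.314462618  # J per mol per K
GASES <- c("h2", "co2", "ch4", "o2")

ledger_entries <- function(x, registry, side) {
  if (is.null(x) || !nrow(x))
    return(data.frame(compound = character(), mmol = numeric(),
                      mmol_c = numeric(), mmol_e = numeric()))
  x$compound <- tolower(x$compound)
  if (all(c("mmol_c", "mmol_e") %in% names(x))) {
    if (!"mmol" %in% names(x)) x$mmol <- NA_real_
  } else {
    if (!"mmol" %in% names(x))
      stop(side, " entries need either mmol or mmol_c/mmol_e columns")
    ce <- t(vapply(seq_len(nrow(x)), function(i)
      mmol_to_carbon_and_electrons(x$mmol[i], x$compound[i], registry),
      numeric(2)))
    x$mmol_c <- ce[, 1]
    x$mmol_e <- ce[, 2]
  }
  if (any(x$mmol_c < 0 | x$mmol_e < 0, na.rm = TRUE))
    stop(side, " carbon/electron entries must be non-negative")
  x[, c("compound", "mmol", "mmol_c", "mmol_e")]
}

#' Carbon and electron inventory for one cell (or cycle)
#'
#' Collects the inlet (substrates fed: initial charge plus re-additions),
#' the charge delivered to the cathode, and the outlet (residual
#' substrates, soluble products in both chambers and in withdrawn samples,
#' and headspace gases) as carbon and electron equivalents.
#'
#' Entries may be given as `data.frame(compound, mmol)` — carbon and
#' electron contents are derived from the registry — or directly as
#' `data.frame(compound, mmol_c, mmol_e)` when only the equivalents are
#' known (e.g. when re-auditing a published ledger). Amounts of the same
#' compound may be split over several rows (chambers, withdrawn samples);
#' balances are additive.
#'
#' @param inlet inlet entries (substrates fed).
#' @param outlet outlet entries (residuals, products, gases).
#' @param charge_mmol_e charge delivered to the cathode, mmol electrons
#'   (from [integrate_charge()]); 0 for non-electrochemical controls.
#' @param fed_substrates compounds fed as substrate in this cell; these
#'   are excluded from the electrofermentation-coefficient denominator.
#'   Defaults to the inlet compounds.
#' @param cell_id identifier carried into reports.
#' @param registry compound registry.
#' @return list of class `balance_ledger`.
#' @export
balance_ledger <- function(inlet, outlet, charge_mmol_e = 0,
                           fed_substrates = NULL, cell_id = "cell",
                           registry = compound_registry()) {
  inlet <- ledger_entries(inlet, registry, "inlet")
  outlet <- ledger_entries(outlet, registry, "outlet")
  if (charge_mmol_e < 0) stop("delivered charge must be non-negative")
  if (is.null(fed_substrates)) fed_substrates <- unique(inlet$compound)
  structure(list(cell_id = cell_id, inlet = inlet, outlet = outlet,
                 charge_mmol_e = charge_mmol_e,
                 fed_substrates = tolower(fed_substrates)),
            class = "balance_ledger")
}

#' @export
print.balance_ledger <- function(x, ...) {
  cat("balance_ledger", x$cell_id, "\n")
  cat("  inlet:", sum(x$inlet$mmol_c), "mmol C,", sum(x$inlet$mmol_e),
      "mmol e-; charge:", x$charge_mmol_e, "mmol e-\n")
  cat("  outlet:", sum(x$outlet$mmol_c), "mmol C,", sum(x$outlet$mmol_e),
      "mmol e-\n")
  cat("  carbon balance:", round(carbon_balance(x), 1), "%; electron balance:",
      round(electron_balance(x), 1), "%\n")
  invisible(x)
}

#' Charge delivered to the cathode
#'
#' Trapezoidal integral of the current magnitude over a time window,
#' converted to electron equivalents by the Faraday constant
#' (96485 C per mol).
#'
#' @param trace a [current_trace()].
#' @param window optional `c(t0, tf)` in hours; defaults to the whole trace.
#' @return mmol electrons.
#' @export
integrate_charge <- function(trace, window = NULL) {
  if (is.null(window)) window <- range(trace$time_h)
  if (window[2] <= window[1]) stop("empty integration window")
  if (window[1] < min(trace$time_h) - 1e-9 ||
      window[2] > max(trace$time_h) + 1e-9)
    stop("window extends beyond the recorded trace")
  tt <- sort(unique(c(window, trace$time_h[trace$time_h > window[1] &
                                           trace$time_h < window[2]])))
  ii <- stats::approx(trace$time_h, abs(trace$current_mA), xout = tt)$y
  coulombs <- pracma::trapz(tt, ii) * 3600 / 1000  # mA*h -> C
  coulombs / FARADAY * 1000
}

#' Carbon balance
#'
#' Percentage of the carbon fed (substrates at cycle starts) recovered at
#' the outlet as residual substrates, soluble products and CO2.
#'
#' @param ledger a [balance_ledger()].
#' @return percent.
#' @export
carbon_balance <- function(ledger) {
  cin <- sum(ledger$inlet$mmol_c)
  if (cin <= 0) stop("inlet carbon must be positive")
  100 * sum(ledger$outlet$mmol_c) / cin
}

#' Electron balance
#'
#' Percentage of the electrons fed as substrates plus the charge delivered
#' to the cathode that is recovered at the outlet (residual substrates,
#' soluble products, H2).
#'
#' @param ledger a [balance_ledger()].
#' @return percent.
#' @export
electron_balance <- function(ledger) {
  den <- sum(ledger$inlet$mmol_e) + ledger$charge_mmol_e
  if (den <= 0) stop("inlet electrons plus delivered charge must be positive")
  100 * sum(ledger$outlet$mmol_e) / den
}

#' Electrofermentation coefficient
#'
#' Charge delivered to the cathode divided by the electron content of the
#' soluble fermentation products formed in the cell. Gases are excluded
#' (soluble products only), and so is any compound fed as substrate in
#' that cell (its outlet entries are residual/unconsumed substrate, not
#' product). Returns 0 when no charge was delivered (non-electrochemical
#' control).
#'
#' @param ledger a [balance_ledger()].
#' @return dimensionless coefficient.
#' @export
ef_coefficient <- function(ledger) {
  if (ledger$charge_mmol_e == 0) return(0)
  keep <- !(ledger$outlet$compound %in% c(ledger$fed_substrates, GASES))
  qprod <- sum(ledger$outlet$mmol_e[keep])
  if (qprod <= 0) stop("no soluble product electrons in the ledger")
  ledger$charge_mmol_e / qprod
}

#' Specific energy consumption
#'
#' Electrical energy invested per kg of product formed:
#' `I_avg * V_cell * t / sum(masses)`.
#'
#' @param i_avg_mA average current during the batch, mA (excluding any
#'   startup at a different applied potential).
#' @param v_cell_V cell voltage, V.
#' @param t_h batch duration, hours.
#' @param masses_kg produced masses, kg (named per product or a vector).
#' @return kWh per kg product.
#' @export
energy_consumption <- function(i_avg_mA, v_cell_V, t_h, masses_kg) {
  if (t_h <= 0) stop("duration must be positive")
  m <- sum(masses_kg)
  if (m <= 0) stop("total product mass must be positive")
  (i_avg_mA / 1000) * v_cell_V * t_h / 1000 / m
}

#' Headspace gas amount from a bag fraction
#'
#' Ideal-gas conversion of a molar fraction in a gas bag to mmol.
#'
#' @param fraction molar fraction of the gas, in `[0, 1]`.
#' @param bag_volume_L bag volume, L.
#' @param temp_K temperature, K.
#' @param pressure_Pa pressure, Pa.
#' @return mmol.
#' @export
gas_amount <- function(fraction, bag_volume_L, temp_K = 298.15,
                       pressure_Pa = 101325) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must be in [0, 1]")
  if (any(bag_volume_L <= 0 | temp_K <= 0 | pressure_Pa <= 0))
    stop("volume, temperature and pressure must be positive")
  fraction * pressure_Pa * (bag_volume_L / 1000) / (GAS_R * temp_K) * 1000
}

#' Build a balance ledger from a cell experiment
#'
#' Aggregates inlet (initial charge plus re-additions of fed substrates),
#' delivered charge, and outlet (residual catholyte inventory at the final
#' cycle end, withdrawn-sample amounts, anolyte accumulation, and headspace
#' gases) over one cycle or over all cycles.
#'
#' @param exp a [cell_experiment()].
#' @param cycle_index one cycle, or `NULL` (default) to aggregate all.
#' @param withdrawal_method passed to [withdrawn_moles()].
#' @return a [balance_ledger()].
#' @export
experiment_ledger <- function(exp, cycle_index = NULL,
                              withdrawal_method = "at_withdrawal") {
  cycles <- if (is.null(cycle_index)) exp$cycles else exp$cycles[cycle_index]
  V <- exp$working_volume
  t_first <- cycles[[1]]$t_start
  t_last <- cycles[[length(cycles)]]$t_end

  adds <- do.call(rbind, lapply(cycles, `[[`, "additions"))
  inlet <- if (!is.null(adds) && nrow(adds)) {
    agg <- stats::aggregate(mmol ~ compound, data = adds, FUN = sum)
    agg$compound <- tolower(agg$compound)
    agg
  } else stop("no substrate additions recorded; inlet would be empty")

  compounds <- unique(vapply(exp$series, attr, character(1), "compound"))
  out_rows <- list()
  for (cmp in compounds) {
    s <- get_series(exp, cmp, "cathode")
    if (!is.null(s)) {
      resid <- moles_in_chamber(s, min(t_last, max(s$time_h)), V)
      wdr <- sum(vapply(cycles, function(cy)
        withdrawn_moles(s, cy, method = withdrawal_method), numeric(1)))
      if (resid + wdr > 0)
        out_rows[[length(out_rows) + 1]] <-
          data.frame(compound = cmp, mmol = resid + wdr)
    }
    a <- get_series(exp, cmp, "anode")
    if (!is.null(a)) {
      mig <- moles_in_chamber(a, min(t_last, max(a$time_h)), V) -
        moles_in_chamber(a, max(t_first, min(a$time_h)), V)
      if (mig > 0)
        out_rows[[length(out_rows) + 1]] <-
          data.frame(compound = cmp, mmol = mig)
    }
  }
  if (!is.null(exp$gas) && nrow(exp$gas)) {
    g <- exp$gas[exp$gas$cycle %in% vapply(cycles, `[[`, numeric(1), "index") &
                 !(tolower(exp$gas$compound) %in% "o2"), , drop = FALSE]
    if (nrow(g)) {
      agg <- stats::aggregate(mmol ~ compound, data = g, FUN = sum)
      out_rows[[length(out_rows) + 1]] <- agg
    }
  }
  outlet <- do.call(rbind, out_rows)

  charge <- if (is.null(exp$current)) 0 else
    integrate_charge(exp$current, c(max(t_first, min(exp$current$time_h)),
                                    min(t_last, max(exp$current$time_h))))
  balance_ledger(inlet, outlet, charge, cell_id = exp$cell_id,
                 registry = exp$registry)
}

#' Ledger report table
#'
#' One-row delimited-ready summary of a ledger: per-compound inlet and
#' outlet carbon/electron equivalents, delivered charge, both balances
#' (1 d.p.) and the electrofermentation coefficient (2 d.p.; `NA` for
#' controls, where it is not applicable).
#'
#' @param ledger a [balance_ledger()].
#' @return one-row data.frame.
#' @export
report_balance <- function(ledger) {
  row <- data.frame(cell = ledger$cell_id)
  for (i in seq_len(nrow(ledger$inlet))) {
    cmp <- ledger$inlet$compound[i]
    row[[paste0("in_", cmp, "_C")]] <- round(ledger$inlet$mmol_c[i], 1)
    row[[paste0("in_", cmp, "_e")]] <- round(ledger$inlet$mmol_e[i], 1)
  }
  row$charge_e <- round(ledger$charge_mmol_e, 1)
  out <- ledger$outlet
  for (cmp in unique(out$compound)) {
    k <- out$compound == cmp
    row[[paste0("out_", cmp, "_C")]] <- round(sum(out$mmol_c[k]), 1)
    row[[paste0("out_", cmp, "_e")]] <- round(sum(out$mmol_e[k]), 1)
  }
  row$carbon_balance_pct <- round(carbon_balance(ledger), 1)
  row$electron_balance_pct <- round(electron_balance(ledger), 1)
  row$eta_EF <- if (ledger$charge_mmol_e == 0) NA_real_ else
    round(ef_coefficient(ledger), 2)
  if (row$carbon_balance_pct > 100 || row$electron_balance_pct > 100)
    warning("balance exceeds 100%: inputs are inconsistent", call. = FALSE)
  row
}
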