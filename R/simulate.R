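#' One simulated batch cycle specification
#'
#' @param duration_h cycle duration, hours (the study's cycles run 5-10
#'   days; default 144 h).
#' @param lactate_mM lactate concentration restored at cycle start, mM.
#' @param butyrate_mM butyrate concentration restored at cycle start, mM
#'   (co-substrate experiments only).
#' @param extents named total reaction extents over the cycle, mmol, for
#'   `ferm`, `acet`, `ce`, `her` (reactions of [builtin_network()]);
#'   `her = NA` defaults to the acetogenic H2 demand `4*acet`.
#' @param midpoint_frac midpoint of the logistic cumulative-extent curve
#'   as a fraction of the cycle duration.
#' @param steepness logistic steepness, per hour.
#' @return list of class `sim_cycle`.
#' @export
sim_cycle <- function(duration_h = 144, lactate_mM = 20, butyrate_mM = 0,
                      extents = c(ferm = 0.7, acet = 0.35, ce = 0, her = NA),
                      midpoint_frac = 0.4, steepness = 0.08) {
  ex <- c(ferm = 0, acet = 0, ce = 0, her = NA)
  ex[names(extents)] <- extents
  if (is.na(ex["her"])) ex["her"] <- 4 * ex["acet"]
  if (any(ex < 0)) stop("extents must be non-negative")
  if (ex["her"] < 4 * ex["acet"])
    stop("hydrogen evolution extent cannot be below the acetogenic H2 demand")
  if (duration_h <= 0 || midpoint_frac <= 0 || midpoint_frac >= 1 ||
      steepness <= 0)
    stop("invalid cycle shape parameters")
  structure(list(duration_h = duration_h, lactate_mM = lactate_mM,
                 butyrate_mM = butyrate_mM, extents = ex,
                 midpoint_frac = midpoint_frac, steepness = steepness),
            class = "sim_cycle")
}

#' Simulation parameters
#'
#' Defaults emulate the study conditions: a 150 mL working volume, 20 mM
#' lactate feeding restored at each cycle start, daily 1 mL sampling,
#' additive Gaussian HPLC noise, zero-order butyrate migration across the
#' membrane (0.35 mM/d, the abiotic-control rate; active only when
#' butyrate is present), a cathodic potential program of -1.2 V for the
#' first 24 h then -1.0 V, and full gas capture in the headspace bag.
#'
#' @param seed RNG seed for the measurement noise.
#' @param working_volume catholyte volume, L.
#' @param cycles list of [sim_cycle()] specs, run consecutively.
#' @param sample_every_h sampling interval, h.
#' @param feed_gap_h downtime between consecutive cycles for volume
#'   reintegration and feeding, h; the end-of-cycle sample is taken before
#'   feeding and the next cycle-start sample after it.
#' @param sample_volume_mL catholyte volume removed per interior sample.
#' @param noise_sd concentration measurement noise sd, mM (truncated at 0).
#' @param butyrate_migration zero-order membrane migration rate, mM/d.
#' @param current_baseline non-faradaic/side current added to the trace, mA.
#' @param gas_capture_fraction fraction of evolved gas recovered in the bag.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1, working_volume = 0.15,
                       cycles = list(sim_cycle()),
                       sample_every_h = 24, sample_volume_mL = 1,
                       noise_sd = 0.2, butyrate_migration = 0.35,
                       current_baseline = 0, gas_capture_fraction = 1,
                       feed_gap_h = 0.1) {
  stopifnot(working_volume > 0, sample_every_h > 0, sample_volume_mL > 0,
            noise_sd >= 0, butyrate_migration >= 0, current_baseline >= 0,
            gas_capture_fraction >= 0, gas_capture_fraction <= 1,
            feed_gap_h > 0)
  structure(list(seed = seed, working_volume = working_volume,
                 cycles = cycles, sample_every_h = sample_every_h,
                 sample_volume_mL = sample_volume_mL, noise_sd = noise_sd,
                 butyrate_migration = butyrate_migration,
                 current_baseline = current_baseline,
                 gas_capture_fraction = gas_capture_fraction,
                 feed_gap_h = feed_gap_h),
            class = "sim_params")
}

# Scaled logistic cumulative extent: 0 at t0, `total` at t1, non-decreasing.
logistic_extent <- function(t, total, t0, t1, midpoint_frac, steepness) {
  tm <- t0 + midpoint_frac * (t1 - t0)
  f <- function(x) 1 / (1 + exp(-steepness * (x - tm)))
  total * (f(t) - f(t0)) / (f(t1) - f(t0))
}

logistic_extent_rate <- function(t, total, t0, t1, midpoint_frac, steepness) {
  tm <- t0 + midpoint_frac * (t1 - t0)
  f <- function(x) 1 / (1 + exp(-steepness * (x - tm)))
  total * steepness * f(t) * (1 - f(t)) / (f(t1) - f(t0))
}

#' Simulate a complete cell experiment
#'
#' Applies the built-in stoichiometric network to per-cycle logistic
#' cumulative-extent curves, moves butyrate to the anolyte by zero-order
#' migration (mass moved, not lost), removes analytical samples at the
#' recorded withdrawal times, strips evolved CO2 and surplus H2 to the
#' headspace, and emits a current trace whose integrated charge matches
#' the hydrogen-evolution electron demand (plus any configured baseline
#' current). Measurement noise is additive Gaussian on the recorded
#' concentrations, truncated at zero; the underlying mass bookkeeping is
#' exact, so noiseless runs close their carbon and electron balances.
#'
#' @param params a [sim_params()].
#' @param cell_id identifier for the generated experiment.
#' @return list with `experiment` (a [cell_experiment()]) and `truth`
#'   (per-cycle list: configured extents, H2 and CO2 evolved, charge
#'   demand in mmol e-).
#' @export
simulate_batch <- function(params, cell_id = "SIM") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  V <- params$working_volume
  S <- builtin_network()
  solutes <- c("lactate", "propionate", "acetate", "butyrate")

  n <- c(lactate = 0, propionate = 0, acetate = 0, butyrate = 0)  # mmol
  anode_butyrate <- 0
  t0 <- 0
  cycles <- list()
  truth <- list()
  rec <- list(time = numeric(), conc = list())  # cathode records
  rec_anode <- list(time = numeric(), but = numeric())
  gas <- NULL
  cur_t <- numeric(); cur_i <- numeric()

  for (ci in seq_along(params$cycles)) {
    cy <- params$cycles[[ci]]
    if (ci > 1) {
      # feeding downtime: only the baseline (non-faradaic) current flows
      cur_t <- c(cur_t, t0 + 1e-6, t0 + params$feed_gap_h - 1e-6)
      cur_i <- c(cur_i, params$current_baseline, params$current_baseline)
      t0 <- t0 + params$feed_gap_h
    }
    t1 <- t0 + cy$duration_h

    add_lac <- max(0, cy$lactate_mM * V - n[["lactate"]])
    add_but <- max(0, cy$butyrate_mM * V - n[["butyrate"]])
    n[["lactate"]] <- n[["lactate"]] + add_lac
    n[["butyrate"]] <- n[["butyrate"]] + add_but
    additions <- data.frame(time_h = 0, compound = "lactate", mmol = add_lac)[0, ]
    if (add_lac > 0) additions <- rbind(additions,
      data.frame(time_h = t0, compound = "lactate", mmol = add_lac))
    if (add_but > 0) additions <- rbind(additions,
      data.frame(time_h = t0, compound = "butyrate", mmol = add_but))

    migrate <- if (n[["butyrate"]] > 0) params$butyrate_migration else 0
    mig_rate <- migrate * V / 24  # mmol per hour

    interior <- seq(t0 + params$sample_every_h, t1,
                    by = params$sample_every_h)
    interior <- interior[interior < t1 - 1e-6]
    times <- unique(c(t0, interior, t1))
    xi_at <- function(t) vapply(c("ferm", "acet", "ce", "her"), function(r)
      logistic_extent(t, cy$extents[[r]], t0, t1, cy$midpoint_frac,
                      cy$steepness), numeric(1))

    # feasibility on a fine grid: solute inventories and gas pools stay >= 0
    tfine <- seq(t0, t1, length.out = 501)
    base_w <- n  # upper bound check ignoring withdrawals (withdrawals scale down)
    for (tf in tfine) {
      d <- as.numeric(S[solutes, c("ferm", "acet", "ce", "her")] %*% xi_at(tf))
      names(d) <- solutes
      nn <- base_w + d
      nn[["butyrate"]] <- nn[["butyrate"]] - mig_rate * (tf - t0)
      if (any(nn < -1e-9))
        stop("extent schedule infeasible at t = ", round(tf, 1), " h: ",
             paste(names(nn)[nn < -1e-9], collapse = ", "),
             " would become negative")
      xi <- xi_at(tf)
      co2 <- xi[["ferm"]] - 2 * xi[["acet"]] + xi[["ce"]]
      h2 <- xi[["her"]] - 4 * xi[["acet"]]
      if (co2 < -1e-9 || h2 < -1e-9)
        stop("extent schedule infeasible at t = ", round(tf, 1),
             " h: gas pool (CO2 or H2) would become negative")
    }

    withdrawals <- data.frame(time_h = numeric(), volume_mL = numeric(),
                              chamber = character())
    tc <- t0
    xi_prev <- xi_at(t0)
    for (tt in times) {
      xi_now <- xi_at(tt)
      d <- as.numeric(S[solutes, ] %*% (xi_now - xi_prev))
      names(d) <- solutes
      n <- n + d
      moved <- mig_rate * (tt - tc)
      n[["butyrate"]] <- n[["butyrate"]] - moved
      anode_butyrate <- anode_butyrate + moved
      # record pre-withdrawal (the sampled material)
      rec$time <- c(rec$time, tt)
      rec$conc[[length(rec$conc) + 1]] <- n / V
      rec_anode$time <- c(rec_anode$time, tt)
      rec_anode$but <- c(rec_anode$but, anode_butyrate / V)
      if (tt > t0 + 1e-9 && tt < t1 - 1e-9) {  # interior sample withdrawal
        n <- n * (1 - params$sample_volume_mL / 1000 / V)
        withdrawals <- rbind(withdrawals,
          data.frame(time_h = tt, volume_mL = params$sample_volume_mL,
                     chamber = "cathode"))
      }
      xi_prev <- xi_now
      tc <- tt
    }

    xi_tot <- xi_at(t1)
    co2_tot <- xi_tot[["ferm"]] - 2 * xi_tot[["acet"]] + xi_tot[["ce"]]
    h2_tot <- xi_tot[["her"]] - 4 * xi_tot[["acet"]]
    gas <- rbind(gas, data.frame(
      cycle = ci, compound = c("co2", "h2"),
      mmol = c(co2_tot, h2_tot) * params$gas_capture_fraction))

    # current: baseline + faradaic HER demand, emitted as a staircase
    # (interval-mean current held constant between knots, with 1e-6 h
    # ramps at the transitions) so that the trapezoidal charge integral
    # reproduces the cumulative HER electron demand to rounding error.
    tg <- seq(t0, t1, by = max(0.05, cy$duration_h / 4000))
    if (tg[length(tg)] < t1 - 1e-9) tg <- c(tg, t1) else tg[length(tg)] <- t1
    xi_her_t <- logistic_extent(tg, cy$extents[["her"]], t0, t1,
                                cy$midpoint_frac, cy$steepness)
    dq_mAh <- 2 * diff(xi_her_t) * FARADAY / 1000 / 3.6  # mmol e- -> mA h
    m <- params$current_baseline + dq_mAh / diff(tg)
    nseg <- length(m)
    tg2 <- as.vector(rbind(tg[-length(tg)], tg[-1] - 1e-6))
    i_mA <- rep(m, each = 2)
    tg <- c(tg2, tg[length(tg)])
    i_mA <- c(i_mA, m[nseg])
    cur_t <- c(cur_t, tg)
    cur_i <- c(cur_i, i_mA)

    cycles[[ci]] <- batch_cycle(ci, t0, t1, additions = additions,
                                withdrawals = withdrawals)
    truth[[ci]] <- list(extents = xi_tot, co2_evolved = co2_tot,
                        h2_evolved = h2_tot,
                        charge_demand = 2 * xi_tot[["her"]])
    t0 <- t1
  }

  noisy <- function(x) if (params$noise_sd == 0) x else
    pmax(x + stats::rnorm(length(x), 0, params$noise_sd), 0)

  conc_mat <- do.call(rbind, rec$conc)
  series <- list()
  for (cmp in solutes) {
    if (all(conc_mat[, cmp] < 1e-12)) next
    series[[length(series) + 1]] <- concentration_series(
      cell_id, "cathode", cmp, rec$time, noisy(conc_mat[, cmp]))
  }
  if (any(rec_anode$but > 1e-12))
    series[[length(series) + 1]] <- concentration_series(
      cell_id, "anode", "butyrate", rec_anode$time, noisy(rec_anode$but))

  tspan <- range(cur_t)
  seg <- data.frame(t_start = c(tspan[1], min(24, tspan[2])),
                    t_end = c(min(24, tspan[2]), tspan[2]),
                    potential_V = c(-1.2, -1.0))
  seg <- seg[seg$t_end > seg$t_start, , drop = FALSE]
  trace <- current_trace(cell_id, cur_t, cur_i, segments = seg)

  exp <- cell_experiment(cell_id, V, cycles, series, current = trace,
                         gas = gas)
  list(experiment = exp, truth = truth)
}

gaussian_peak <- function(E, center, height, width_mV)
  height * exp(-0.5 * ((E - center) / (width_mV / 1000))^2)

#' Simulate a cyclic voltammogram
#'
#' Four replicate cycles over the potential window on a 1 mV grid:
#' a capacitive offset of opposite sign per branch, Gaussian faradaic
#' peaks (reduction peaks on the cathodic branch, oxidation on the
#' anodic), an exponential hydrogen-evolution tail below the HER onset,
#' and seeded Gaussian noise.
#'
#' @param peaks data.frame `center_V, height_mA, width_mV, direction`
#'   (direction `"reduction"` or `"oxidation"`); may be empty.
#' @param baseline_mA capacitive current magnitude per branch.
#' @param her_onset_V potential below which the HER tail rises.
#' @param her_mA tail magnitude at the onset potential.
#' @param her_slope_V exponential decay constant of the tail, V.
#' @param noise_sd Gaussian noise sd, mA.
#' @param seed RNG seed.
#' @param n_cycles number of replicate cycles (default 4).
#' @param window potential window, V.
#' @param cell_id,stage annotations for the [voltammogram()].
#' @return a [voltammogram()].
#' @export
simulate_cv <- function(peaks = NULL, baseline_mA = 0.05,
                        her_onset_V = -0.9, her_mA = 0.2,
                        her_slope_V = 0.05, noise_sd = 0, seed = 1,
                        n_cycles = 4, window = c(-1.2, 0),
                        cell_id = "SIM", stage = "end") {
  set.seed(seed)
  if (is.null(peaks))
    peaks <- data.frame(center_V = numeric(), height_mA = numeric(),
                        width_mV = numeric(), direction = character())
  if (nrow(peaks) && any(peaks$center_V < window[1] | peaks$center_V > window[2]))
    stop("peak centers must lie within the potential window")
  grid <- seq(window[2], window[1], by = -0.001)  # cathodic sweep
  her <- function(E) -her_mA * exp((her_onset_V - E) / her_slope_V)
  branch_current <- function(E, dir) {
    I <- if (dir == "reduction") -baseline_mA else baseline_mA
    I <- I + her(E)
    p <- peaks[peaks$direction == dir, , drop = FALSE]
    for (i in seq_len(nrow(p))) {
      g <- gaussian_peak(E, p$center_V[i], p$height_mA[i], p$width_mV[i])
      I <- I + if (dir == "reduction") -g else g
    }
    I
  }
  cycles <- lapply(seq_len(n_cycles), function(k) {
    cath <- branch_current(grid, "reduction")
    anod <- branch_current(rev(grid), "oxidation")
    cy <- data.frame(potential_V = c(grid, rev(grid)),
                     current_mA = c(cath, anod))
    if (noise_sd > 0)
      cy$current_mA <- cy$current_mA + stats::rnorm(nrow(cy), 0, noise_sd)
    cy
  })
  voltammogram(cell_id, stage, cycles, scan_rate_mV_s = 1, window = window)
}
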