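#' Voltammogram container
#'
#' @param cell_id identifier.
#' @param stage `"begin"` or `"end"` (scan taken at start or conclusion of
#'   the experiment).
#' @param cycles list of data.frames `potential_V, current_mA` in sweep
#'   order, one per cycle; the cathodic and anodic branches are identified
#'   from the sweep direction.
#' @param scan_rate_mV_s scan rate, mV/s.
#' @param window potential window `c(V_min, V_max)` vs the reference
#'   electrode.
#' @return list of class `voltammogram`.
#' @export
voltammogram <- function(cell_id, stage = c("begin", "end"), cycles,
                         scan_rate_mV_s = 1, window = c(-1.2, 0)) {
  stage <- match.arg(stage)
  if (scan_rate_mV_s <= 0) stop("scan rate must be positive")
  cycles <- lapply(cycles, function(cy) {
    if (!all(c("potential_V", "current_mA") %in% names(cy)))
      stop("each cycle needs potential_V and current_mA columns")
    dE <- diff(cy$potential_V)
    if (!any(dE < 0) || !any(dE > 0))
      stop("each cycle must contain both a cathodic and an anodic sweep")
    cy
  })
  structure(list(cell_id = cell_id, stage = stage, cycles = cycles,
                 scan_rate_mV_s = scan_rate_mV_s, window = window),
            class = "voltammogram")
}

#' Read voltammograms from a delimited file
#'
#' Expects columns `cell_id, stage, cycle, potential_V, current_mA`.
#'
#' @param file CSV path.
#' @param scan_rate_mV_s scan rate annotation.
#' @return named list of [voltammogram()] objects, one per
#'   cell_id/stage combination.
#' @export
read_voltammogram <- function(file, scan_rate_mV_s = 1) {
  d <- read_checked(file, c("cell_id", "stage", "cycle", "potential_V",
                            "current_mA"))
  out <- lapply(split(d, paste(d$cell_id, d$stage, sep = ":")), function(g) {
    cycles <- lapply(split(g, g$cycle), function(cy)
      data.frame(potential_V = cy$potential_V, current_mA = cy$current_mA))
    voltammogram(g$cell_id[1], g$stage[1], cycles, scan_rate_mV_s,
                 window = range(g$potential_V))
  })
  out
}

#' Select one replicate cycle
#'
#' Conditioning sweeps make early cycles unrepresentative; the third
#' replicate cycle is the conventional choice reported.
#'
#' @param vg a [voltammogram()].
#' @param k cycle index (default 3).
#' @return one cycle data.frame.
#' @export
select_cycle <- function(vg, k = 3) {
  if (k < 1 || k > length(vg$cycles))
    stop("cycle ", k, " not recorded; available cycles: 1-", length(vg$cycles))
  vg$cycles[[k]]
}

split_branches <- function(cycle) {
  dE <- diff(cycle$potential_V)
  dir <- c(dE[1], dE)  # carry first direction to first point
  list(cathodic = cycle[dir < 0, , drop = FALSE],
       anodic = cycle[dir >= 0, , drop = FALSE])
}

# Resample a branch onto a uniform potential grid (ascending), then apply
# centered Savitzky-Golay polynomial smoothing.
branch_grid <- function(branch, grid_mV = 1, smooth_window_mV = 25,
                        poly_order = 2) {
  o <- order(branch$potential_V)
  E <- branch$potential_V[o]; I <- branch$current_mA[o]
  keep <- !duplicated(E)
  E <- E[keep]; I <- I[keep]
  grid <- seq(min(E), max(E), by = grid_mV / 1000)
  y <- stats::approx(E, I, xout = grid)$y
  n <- 2 * floor(smooth_window_mV / grid_mV / 2) + 1  # odd point count
  if (n > length(grid)) stop("smoothing window larger than the branch")
  if (n > poly_order + 1) y <- signal::sgolayfilt(y, p = poly_order, n = n)
  data.frame(potential_V = grid, current_mA = y)
}

#' First derivative of a voltammogram branch
#'
#' Resamples each branch onto a uniform 1 mV potential grid, applies
#' centered polynomial (Savitzky-Golay) smoothing, and differentiates by
#' central differences (one-sided at the endpoints).
#'
#' @param cycle one cycle from [select_cycle()].
#' @param smooth_window_mV smoothing window, mV (default 25).
#' @param poly_order smoothing polynomial order (default 2).
#' @param grid_mV resampling step, mV (default 1).
#' @return data.frame `potential_V, dI_dE, branch` (mA per V), both
#'   branches concatenated.
#' @export
first_derivative <- function(cycle, smooth_window_mV = 25, poly_order = 2,
                             grid_mV = 1) {
  br <- split_branches(cycle)
  out <- lapply(names(br), function(nm) {
    g <- branch_grid(br[[nm]], grid_mV, smooth_window_mV, poly_order)
    d <- pracma::gradient(g$current_mA, g$potential_V)
    data.frame(potential_V = g$potential_V, dI_dE = d, branch = nm)
  })
  do.call(rbind, out)
}

# Local maxima of y with topographic prominence.
local_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), prominence = numeric()))
  idx <- which(diff(sign(diff(y))) < 0) + 1
  prom <- vapply(idx, function(i) {
    base <- vapply(list(seq(i - 1, 1), seq(i + 1, n)), function(side) {
      higher <- side[y[side] > y[i]]
      stretch <- if (length(higher)) {
        side[seq_len(which(side == higher[1]))]
      } else side
      min(y[stretch])
    }, numeric(1))
    y[i] - max(base)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Detect faradaic peaks in a voltammogram cycle
#'
#' Each branch is resampled and smoothed; faradaic peaks are the local
#' extrema of the smoothed current (minima on the cathodic branch =
#' reduction; maxima on the anodic branch = oxidation) whose topographic
#' prominence reaches the threshold — the hydrogen-evolution tail is
#' monotone on each branch and therefore produces no extremum. The
#' reported magnitude is the peak current after subtracting a per-branch
#' linear baseline fit by Huber robust regression (robust to the HER
#' tail); peaks whose baseline-subtracted magnitude is not positive are
#' dropped. An empty result is valid (flat scans).
#'
#' @param cycle one cycle from [select_cycle()].
#' @param prominence_mA minimum peak prominence, mA.
#' @param direction `"both"`, `"reduction"` or `"oxidation"`.
#' @param baseline `"linear"` (default) or `"none"`.
#' @param smooth_window_mV,poly_order,grid_mV smoothing parameters as in
#'   [first_derivative()].
#' @return data.frame `potential_V, direction, magnitude_mA,
#'   prominence_mA`, sorted by potential.
#' @export
detect_peaks <- function(cycle, prominence_mA = 0.05,
                         direction = c("both", "reduction", "oxidation"),
                         baseline = c("linear", "none"),
                         smooth_window_mV = 25, poly_order = 2, grid_mV = 1) {
  direction <- match.arg(direction)
  baseline <- match.arg(baseline)
  br <- split_branches(cycle)
  want <- switch(direction, both = c("reduction", "oxidation"),
                 reduction = "reduction", oxidation = "oxidation")
  rows <- list()
  for (dir in want) {
    branch <- if (dir == "reduction") br$cathodic else br$anodic
    if (nrow(branch) < 5) next
    g <- branch_grid(branch, grid_mV, smooth_window_mV, poly_order)
    y_raw <- if (dir == "reduction") -g$current_mA else g$current_mA
    y_bs <- y_raw
    if (baseline == "linear") {
      # a coarse robust line; exact IRLS convergence is immaterial here
      fit <- suppressWarnings(MASS::rlm(y_raw ~ g$potential_V, maxit = 100))
      y_bs <- y_raw - as.numeric(stats::fitted(fit))
    }
    pk <- local_peaks(y_raw)
    pk <- pk[pk$prominence >= prominence_mA & y_bs[pk$index] > 0, ,
             drop = FALSE]
    if (nrow(pk))
      rows[[dir]] <- data.frame(potential_V = g$potential_V[pk$index],
                                direction = dir,
                                magnitude_mA = y_bs[pk$index],
                                prominence_mA = pk$prominence)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(potential_V = numeric(), direction = character(),
               magnitude_mA = numeric(), prominence_mA = numeric())
  out <- out[order(out$potential_V), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair reduction and oxidation peaks into redox couples
#'
#' Greedy nearest-potential pairing of opposite-direction peaks within a
#' maximum separation; each peak joins at most one couple.
#'
#' @param peaks output of [detect_peaks()] covering both branches.
#' @param max_separation_V pairing threshold, V (default 0.10).
#' @return data.frame `e_red, e_ox, midpoint_V, separation_V`.
#' @export
pair_couples <- function(peaks, max_separation_V = 0.10) {
  red <- peaks[peaks$direction == "reduction", , drop = FALSE]
  ox <- peaks[peaks$direction == "oxidation", , drop = FALSE]
  empty <- data.frame(e_red = numeric(), e_ox = numeric(),
                      midpoint_V = numeric(), separation_V = numeric())
  if (!nrow(red) || !nrow(ox)) return(empty)
  cand <- expand.grid(i = seq_len(nrow(red)), j = seq_len(nrow(ox)))
  cand$sep <- abs(red$potential_V[cand$i] - ox$potential_V[cand$j])
  cand <- cand[cand$sep <= max_separation_V, , drop = FALSE]
  cand <- cand[order(cand$sep), , drop = FALSE]
  used_i <- used_j <- integer()
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (i %in% used_i || j %in% used_j) next
    used_i <- c(used_i, i); used_j <- c(used_j, j)
    rows[[length(rows) + 1]] <- data.frame(
      e_red = red$potential_V[i], e_ox = ox$potential_V[j],
      midpoint_V = (red$potential_V[i] + ox$potential_V[j]) / 2,
      separation_V = cand$sep[k])
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Shift of the cathodic onset potential between two scans
#'
#' The onset is the most positive potential at which the cathodic current
#' magnitude first exceeds a threshold (sweeping toward negative
#' potentials). A positive shift (end minus begin) means the reduction
#' starts at a less negative potential, i.e. reduced overpotential —
#' the signature of electroactive biofilm development.
#'
#' @param begin_cycle,end_cycle cycles from [select_cycle()] of the begin
#'   and end scans.
#' @param threshold_mA current-magnitude threshold, mA (set above the
#'   capacitive envelope).
#' @return onset shift, V (end minus begin).
#' @export
onset_shift <- function(begin_cycle, end_cycle, threshold_mA) {
  onset <- function(cycle) {
    b <- split_branches(cycle)$cathodic
    o <- order(b$potential_V, decreasing = TRUE)  # sweep + -> -
    E <- b$potential_V[o]; I <- abs(b$current_mA[o])
    hit <- which(I >= threshold_mA)
    if (!length(hit)) stop("threshold ", threshold_mA,
                           " mA never reached on the cathodic branch")
    E[hit[1]]
  }
  onset(end_cycle) - onset(begin_cycle)
}

#' Peak-and-couple report for a voltammogram
#'
#' @param vg a [voltammogram()].
#' @param k cycle index (default 3).
#' @param prominence_mA peak prominence threshold.
#' @param max_separation_V couple pairing threshold.
#' @param ... further arguments to [detect_peaks()].
#' @return list with data.frames `peaks` and `couples`, both carrying
#'   cell/stage columns.
#' @export
report_cv <- function(vg, k = 3, prominence_mA = 0.05,
                      max_separation_V = 0.10, ...) {
  cyc <- select_cycle(vg, k)
  peaks <- detect_peaks(cyc, prominence_mA = prominence_mA, ...)
  couples <- pair_couples(peaks, max_separation_V)
  if (nrow(peaks)) {
    peaks <- cbind(cell = vg$cell_id, stage = vg$stage, peaks)
  }
  if (nrow(couples)) {
    couples <- cbind(cell = vg$cell_id, stage = vg$stage, couples)
  }
  list(peaks = peaks, couples = couples)
}
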