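#' Load a cell experiment from a manifest
#'
#' The manifest is a YAML file with keys `cell_id`, `working_volume_L`,
#' `timeseries` (CSV path), optional `current` and `gas` (CSV paths,
#' relative to the manifest), and `cycles`, a list of cycle blocks with
#' `index`, `t_start_h`, `t_end_h` and optional `additions`
#' (`time_h, compound, mmol`) and `withdrawals`
#' (`time_h, volume_mL, chamber`).
#'
#' File formats (comma-delimited, header required, "." decimal):
#' \describe{
#'   \item{timeseries}{`cell_id, chamber, time_h, compound, conc_mM`}
#'   \item{current}{`cell_id, time_h, current_mA, potential_V`}
#'   \item{gas}{`cell_id, cycle, compound, amount_mmol` or
#'     `fraction, bag_volume_L, temp_K, pressure_Pa` (converted by the
#'     ideal-gas law)}
#' }
#'
#' @param manifest path to the YAML manifest.
#' @param registry compound registry.
#' @return a validated [cell_experiment()].
#' @export
load_experiment <- function(manifest, registry = compound_registry()) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  cfg <- yaml::read_yaml(manifest)
  for (key in c("cell_id", "working_volume_L", "timeseries", "cycles"))
    if (is.null(cfg[[key]])) stop("manifest is missing key: ", key)
  dir <- dirname(manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)

  ts_file <- resolve(cfg$timeseries)
  ts <- read_checked(ts_file, c("cell_id", "chamber", "time_h", "compound",
                                "conc_mM"))
  series <- lapply(split(ts, paste(ts$chamber, tolower(ts$compound))),
                   function(d) {
                     d <- d[order(d$time_h), ]
                     concentration_series(cfg$cell_id, d$chamber[1],
                                          d$compound[1], d$time_h, d$conc_mM,
                                          registry)
                   })
  names(series) <- NULL

  current <- NULL
  if (!is.null(cfg$current)) {
    cu <- read_checked(resolve(cfg$current),
                       c("cell_id", "time_h", "current_mA", "potential_V"))
    cu <- cu[order(cu$time_h), ]
    current <- current_trace(cfg$cell_id, cu$time_h, cu$current_mA,
                             segments_from_potentials(cu$time_h, cu$potential_V))
  }

  gas <- NULL
  if (!is.null(cfg$gas)) {
    g <- read_checked(resolve(cfg$gas), c("cell_id", "cycle", "compound"))
    mmol <- if ("amount_mmol" %in% names(g) && any(!is.na(g$amount_mmol))) {
      g$amount_mmol
    } else {
      for (col in c("fraction", "bag_volume_L", "temp_K", "pressure_Pa"))
        if (is.null(g[[col]])) stop("gas file needs amount_mmol or the ",
                                    "fraction/bag_volume_L/temp_K/pressure_Pa columns")
      gas_amount(g$fraction, g$bag_volume_L, g$temp_K, g$pressure_Pa)
    }
    gas <- data.frame(cycle = g$cycle, compound = tolower(g$compound),
                      mmol = mmol)
  }

  cycles <- lapply(cfg$cycles, function(cy) {
    adds <- bind_records(cy$additions, c("time_h", "compound", "mmol"))
    if (!is.null(adds)) {
      adds$time_h <- as.numeric(adds$time_h); adds$mmol <- as.numeric(adds$mmol)
    }
    wdr <- bind_records(cy$withdrawals, c("time_h", "volume_mL", "chamber"))
    if (!is.null(wdr)) {
      wdr$time_h <- as.numeric(wdr$time_h)
      wdr$volume_mL <- as.numeric(wdr$volume_mL)
    }
    batch_cycle(as.integer(cy$index), as.numeric(cy$t_start_h),
                as.numeric(cy$t_end_h), additions = adds, withdrawals = wdr)
  })

  cell_experiment(cfg$cell_id, cfg$working_volume_L, cycles, series,
                  current = current, gas = gas, registry = registry)
}

read_checked <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("file ", basename(path), " is missing columns: ",
         paste(missing, collapse = ", "))
  d
}

# serialise doubles at 17 significant digits so reloading is bit-exact
write_csv17 <- function(df, path) {
  df[] <- lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

bind_records <- function(recs, cols) {
  if (is.null(recs) || !length(recs)) return(NULL)
  out <- do.call(rbind, lapply(recs, function(r) as.data.frame(r[cols])))
  names(out) <- cols
  out
}

segments_from_potentials <- function(time_h, potential_V) {
  r <- rle(potential_V)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  data.frame(t_start = time_h[starts],
             t_end = time_h[c(utils::head(ends, -1) + 1, length(time_h))],
             potential_V = r$values)
}

#' Write a cell experiment to delimited files plus a manifest
#'
#' Writes the same formats [load_experiment()] reads, so that a written
#' experiment reloads identically on all numeric fields.
#'
#' @param exp a [cell_experiment()].
#' @param dir output directory (created if needed).
#' @return path to the written manifest, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts <- do.call(rbind, lapply(exp$series, function(s)
    data.frame(cell_id = exp$cell_id, chamber = attr(s, "chamber"),
               time_h = s$time_h, compound = attr(s, "compound"),
               conc_mM = s$conc_mM)))
  write_csv17(ts, file.path(dir, "timeseries.csv"))

  cfg <- list(cell_id = exp$cell_id,
              working_volume_L = exp$working_volume,
              timeseries = "timeseries.csv")

  if (!is.null(exp$current)) {
    seg <- attr(exp$current, "segments")
    pot <- vapply(exp$current$time_h, function(t) {
      i <- which(t >= seg$t_start - 1e-9 & t <= seg$t_end + 1e-9)[1]
      seg$potential_V[i]
    }, numeric(1))
    write_csv17(data.frame(cell_id = exp$cell_id,
                           time_h = exp$current$time_h,
                           current_mA = exp$current$current_mA,
                           potential_V = pot),
                file.path(dir, "current.csv"))
    cfg$current <- "current.csv"
  }
  if (!is.null(exp$gas) && nrow(exp$gas)) {
    write_csv17(data.frame(cell_id = exp$cell_id, cycle = exp$gas$cycle,
                           compound = exp$gas$compound,
                           amount_mmol = exp$gas$mmol),
                file.path(dir, "gas.csv"))
    cfg$gas <- "gas.csv"
  }
  cfg$cycles <- lapply(exp$cycles, function(cy) {
    out <- list(index = cy$index, t_start_h = cy$t_start, t_end_h = cy$t_end)
    if (nrow(cy$additions))
      out$additions <- lapply(seq_len(nrow(cy$additions)), function(i)
        as.list(cy$additions[i, ]))
    if (nrow(cy$withdrawals))
      out$withdrawals <- lapply(seq_len(nrow(cy$withdrawals)), function(i)
        as.list(cy$withdrawals[i, ]))
    out
  })
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
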