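SPECIES <- c("lactate", "propionate", "acetate", "butyrate", "h2", "co2", "e")

#' Built-in metabolic reaction network
#'
#' The four reactions hypothesised to run in a lactate-fed cathodic
#' electrofermentation cell, as a signed stoichiometric matrix over
#' \{lactate, propionate, acetate, butyrate, H2, CO2, cathode electrons\}
#' (negative = consumed, water and protons omitted):
#'
#' \describe{
#'   \item{ferm}{lactate fermentation:
#'     3 lactate -> 2 propionate + 1 acetate + 1 CO2}
#'   \item{acet}{homoacetogenesis (Wood-Ljungdahl):
#'     4 H2 + 2 CO2 -> 1 acetate}
#'   \item{ce}{chain elongation (reverse beta-oxidation):
#'     1 lactate + 1 acetate -> 1 butyrate + 1 CO2}
#'   \item{her}{hydrogen evolution at the cathode: 2 e- -> 1 H2}
#' }
#'
#' Bicarbonate consumed by acetogenesis is accounted as CO2 (the carbon
#' ledger does not distinguish speciation). Every reaction is carbon- and
#' electron-balanced; see [check_reaction_balance()].
#'
#' @return numeric matrix, species in rows, reactions in columns.
#' @export
builtin_network <- function() {
  S <- matrix(0, nrow = length(SPECIES), ncol = 4,
              dimnames = list(SPECIES, c("ferm", "acet", "ce", "her")))
  S[c("lactate", "propionate", "acetate", "co2"), "ferm"] <- c(-3, 2, 1, 1)
  S[c("h2", "co2", "acetate"), "acet"] <- c(-4, -2, 1)
  S[c("lactate", "acetate", "butyrate", "co2"), "ce"] <- c(-1, -1, 1, 1)
  S[c("e", "h2"), "her"] <- c(-2, 1)
  S
}

#' Check carbon and electron balance of a reaction network
#'
#' For each reaction column verifies that (i) carbon atoms balance
#' (counting CO2) and (ii) electron equivalents balance, counting cathode
#' electrons at 1 mol e- each and every compound at its degree of
#' reduction from the registry.
#'
#' @param S stoichiometric matrix as in [builtin_network()].
#' @param registry compound registry.
#' @return data.frame with per-reaction `carbon` and `electron` residuals
#'   (both zero for a balanced network).
#' @export
check_reaction_balance <- function(S, registry = compound_registry()) {
  cmp <- setdiff(rownames(S), "e")
  cvec <- vapply(cmp, function(x) get_compound(x, registry)$carbon_equiv,
                 numeric(1))
  evec <- vapply(cmp, function(x) get_compound(x, registry)$electron_equiv,
                 numeric(1))
  carbon <- as.numeric(cvec %*% S[cmp, , drop = FALSE])
  electron <- as.numeric(evec %*% S[cmp, , drop = FALSE]) +
    (if ("e" %in% rownames(S)) S["e", ] else 0)
  data.frame(reaction = colnames(S), carbon = carbon, electron = electron)
}

#' Theoretical yields of coupled fermentation and acetogenesis
#'
#' Couples lactate fermentation with homoacetogenesis consuming all the
#' fermentation-derived CO2 (one acetogenesis turnover per 2 CO2, i.e.
#' extent ratio 1:2 per 3 lactate) and reports the product yields per mol
#' lactate, computed from the built-in network rather than hard-coded.
#'
#' @return list with `propionate` and `acetate` (mol per mol lactate) and
#'   `ratio` (propionate:acetate). Fermentation alone gives ratio 2; full
#'   CO2 recycling gives 2/3, 1/2 and 4/3.
#' @export
theoretical_combined_yields <- function() {
  S <- builtin_network()
  xi <- c(ferm = 1, acet = S["co2", "ferm"] / -S["co2", "acet"], ce = 0, her = 0)
  d <- as.numeric(S %*% xi)
  names(d) <- rownames(S)
  lac <- -d[["lactate"]]
  list(propionate = d[["propionate"]] / lac,
       acetate = d[["acetate"]] / lac,
       ratio = d[["propionate"]] / d[["acetate"]])
}

#' Decompose measured concentration changes into reaction extents
#'
#' Algebraic attribution of net mmol changes over a production window to
#' the built-in reactions: butyrate fixes chain elongation, propionate
#' fixes fermentation, and the acetate formed in excess of fermentation
#' (plus the acetate consumed by elongation) fixes acetogenesis. The H2
#' and cathodic-charge demand implied by the acetogenic extent, and the
#' net CO2 evolved, follow from the stoichiometry. This is the attribution
#' logic of the metabolic-pathway analysis, not a least-squares fit:
#' residuals expose substrate consumed by unmodelled fates (biomass,
#' aerobic loss).
#'
#' @param deltas named mmol changes over the window; requires
#'   `propionate`, `acetate`, `butyrate` (each >= 0: choose a production
#'   window) and optionally `lactate` (net change, negative when
#'   consumed) to obtain the lactate residual.
#' @param h2_out mmol H2 recovered in the headspace over the window
#'   (adds to the hydrogen-evolution extent beyond the acetogenic demand).
#' @return object of class `pathway_extents`: extents `xi_ferm`,
#'   `xi_acet`, `xi_ce`, `xi_her` (mmol), `h2_demand`, `charge_demand`
#'   (mmol e-), `co2_net`, and per-compound `residual` (observed minus
#'   reconstructed; propionate and butyrate are zero by construction).
#' @export
decompose_extents <- function(deltas, h2_out = 0) {
  deltas <- as.list(deltas)
  for (k in c("propionate", "acetate", "butyrate"))
    if (is.null(deltas[[k]])) stop("deltas must include ", k)
  if (deltas$propionate < 0 || deltas$acetate < 0 || deltas$butyrate < 0)
    stop("negative product change: select a window over the production ",
         "phase (product deltas must be non-negative)")
  xi_ce <- deltas$butyrate
  xi_ferm <- deltas$propionate / 2
  xi_acet <- deltas$acetate - xi_ferm + xi_ce
  res_acet <- 0
  if (xi_acet < 0) {        # less acetate than fermentation alone implies
    res_acet <- xi_acet     # shortfall reported, extent floored
    xi_acet <- 0
  }
  h2_demand <- 4 * xi_acet
  xi_her <- h2_demand + h2_out
  res_lac <- if (is.null(deltas$lactate)) NA_real_ else
    deltas$lactate - (-3 * xi_ferm - xi_ce)
  structure(list(xi_ferm = xi_ferm, xi_acet = xi_acet, xi_ce = xi_ce,
                 xi_her = xi_her,
                 h2_demand = h2_demand, charge_demand = 2 * xi_her,
                 co2_net = xi_ferm - 2 * xi_acet + xi_ce,
                 residual = c(lactate = res_lac, propionate = 0,
                              acetate = res_acet, butyrate = 0)),
            class = "pathway_extents")
}

#' @export
print.pathway_extents <- function(x, ...) {
  cat("pathway_extents (mmol): ferm", signif(x$xi_ferm, 4),
      "| acet", signif(x$xi_acet, 4), "| ce", signif(x$xi_ce, 4),
      "| her", signif(x$xi_her, 4), "\n")
  cat("  H2 demand", signif(x$h2_demand, 4), "mmol; charge demand",
      signif(x$charge_demand, 4), "mmol e-; net CO2",
      signif(x$co2_net, 4), "mmol\n")
  invisible(x)
}

#' Reconstruct species changes from reaction extents
#'
#' The forward map inverted by [decompose_extents()]: applies the built-in
#' stoichiometric matrix to an extents vector.
#'
#' @param extents a `pathway_extents` object or a named vector/list with
#'   `xi_ferm`, `xi_acet`, `xi_ce` (and optionally `xi_her`).
#' @return named mmol changes over the species of [builtin_network()].
#' @export
reconstruct_deltas <- function(extents) {
  e <- as.list(extents)
  xi <- c(ferm = e$xi_ferm, acet = e$xi_acet, ce = e$xi_ce,
          her = if (is.null(e$xi_her)) 4 * e$xi_acet else e$xi_her)
  d <- as.numeric(builtin_network() %*% xi)
  names(d) <- SPECIES
  d
}

#' Propionate:acetate ratio predicted by an extents vector
#'
#' @param extents a `pathway_extents` object (or compatible list).
#' @return dimensionless ratio `2*xi_ferm / (xi_ferm + xi_acet - xi_ce)`;
#'   4/3 in fully CO2-recycling combined mode, 2 for fermentation alone.
#' @export
predicted_ratio <- function(extents) {
  e <- as.list(extents)
  den <- e$xi_ferm + e$xi_acet - e$xi_ce
  if (den <= 0) stop("reconstructed acetate must be positive")
  2 * e$xi_ferm / den
}

#' CO2 recycled into acetate
#'
#' Acetogenesis fixes 2 mmol CO2 per mmol acetate formed. The amount
#' recycled from fermentation-derived CO2 is capped at the CO2 actually
#' produced by fermentation and chain elongation; any excess demand is
#' reported as externally sourced CO2 with a flag.
#'
#' @param extents a `pathway_extents` object.
#' @return list with `fixed` (total mmol CO2 consumed by acetogenesis),
#'   `recycled` (share attributable to fermentation-derived CO2),
#'   `external` (excess over internal production) and `flag` (TRUE when
#'   external CO2 would be required).
#' @export
co2_recycled <- function(extents) {
  e <- as.list(extents)
  fixed <- 2 * e$xi_acet
  produced <- e$xi_ferm + e$xi_ce
  recycled <- min(fixed, produced)
  external <- max(fixed - produced, 0)
  list(fixed = fixed, recycled = recycled, external = external,
       flag = external > 0)
}

#' Extents report for an experiment
#'
#' Runs [cycle_deltas()] and [decompose_extents()] per cycle and tabulates
#' extents, CO2 recycling and demands.
#'
#' @param exp a [cell_experiment()].
#' @param cycle_index cycles to report (default all).
#' @return data.frame, one row per cycle.
#' @export
report_extents <- function(exp, cycle_index = seq_along(exp$cycles)) {
  rows <- lapply(cycle_index, function(i) {
    d <- cycle_deltas(exp, i)
    get0 <- function(k) if (k %in% names(d$formed)) max(d$formed[[k]], 0) else 0
    h2g <- if (!is.null(exp$gas) && nrow(exp$gas)) {
      k <- exp$gas$cycle == exp$cycles[[i]]$index & exp$gas$compound == "h2"
      sum(exp$gas$mmol[k])
    } else 0
    ex <- decompose_extents(list(propionate = get0("propionate"),
                                 acetate = get0("acetate"),
                                 butyrate = get0("butyrate"),
                                 lactate = -d$consumed),
                            h2_out = h2g)
    rc <- co2_recycled(ex)
    data.frame(cell = exp$cell_id, batch = exp$cycles[[i]]$index,
               xi_ferm = ex$xi_ferm, xi_acet = ex$xi_acet, xi_ce = ex$xi_ce,
               xi_her = ex$xi_her, h2_demand = ex$h2_demand,
               charge_demand = ex$charge_demand, co2_net = ex$co2_net,
               co2_recycled = rc$recycled, co2_external = rc$external,
               residual_lactate = ex$residual[["lactate"]],
               ratio = if (ex$xi_ferm + ex$xi_acet - ex$xi_ce > 0)
                 predicted_ratio(ex) else NA_real_)
  })
  do.call(rbind, rows)
}
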