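#' Worked-example carbon/charge ledgers
#'
#' Packaged end-of-run carbon and electron inventories (mmol C and mmol
#' e-, printed to 1 decimal) from a lactate electrofermentation campaign:
#' five cathodic cells fed lactate (L1-L3) or lactate plus butyrate
#' (LB1, LB2), and eight non-electrochemical control incubations at
#' initial pH 5 or 7. These rows serve as worked examples for
#' [balance_ledger()], [carbon_balance()], [electron_balance()] and
#' [ef_coefficient()], together with the balance and coefficient values
#' published alongside them (`printed_cb`, `printed_eb`, `printed_eta`).
#'
#' Missing gas readings (`NA`) follow the not-detected convention and
#' enter the ledgers as zero outlet.
#'
#' @return data.frame, one row per cell.
#' @export
worked_example_table <- function() {
  utils::read.csv(system.file("extdata", "worked_example_ledgers.csv",
                              package = "electroferm", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Build a balance ledger from one worked-example row
#'
#' @param cell cell identifier in [worked_example_table()].
#' @return a [balance_ledger()]; butyrate is listed among the fed
#'   substrates only for the LB/C_LB cells, where it was supplied as a
#'   co-substrate.
#' @export
worked_example_ledger <- function(cell) {
  tab <- worked_example_table()
  r <- tab[tab$cell == cell, , drop = FALSE]
  if (!nrow(r)) stop("unknown worked-example cell: ", cell)
  z <- function(x) ifelse(is.na(x), 0, x)
  inlet <- data.frame(compound = c("lactate", "butyrate"),
                      mmol_c = c(r$in_lactate_c, r$in_butyrate_c),
                      mmol_e = c(r$in_lactate_e, r$in_butyrate_e))
  fed <- inlet$compound[inlet$mmol_c > 0 | inlet$mmol_e > 0]
  inlet <- inlet[inlet$compound %in% fed, , drop = FALSE]
  outlet <- data.frame(
    compound = c("lactate", "acetate", "propionate", "butyrate", "h2", "co2"),
    mmol_c = c(z(r$out_lactate_c), z(r$out_acetate_c), z(r$out_propionate_c),
               z(r$out_butyrate_c), 0, z(r$out_co2_c)),
    mmol_e = c(z(r$out_lactate_e), z(r$out_acetate_e), z(r$out_propionate_e),
               z(r$out_butyrate_e), z(r$out_h2_e), 0))
  balance_ledger(inlet, outlet, charge_mmol_e = z(r$charge_e),
                 fed_substrates = fed, cell_id = cell)
}
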