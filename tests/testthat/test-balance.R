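test_that("charge integration converts current-time to electron equivalents", {
  sec <- 1000 / 3600
  tr <- current_trace("x", c(0, sec), c(-96.485, -96.485))
  expect_equal(integrate_charge(tr), 1, tolerance = 1e-9)
  tr0 <- current_trace("x", c(0, 10), c(0, 0))
  expect_equal(integrate_charge(tr0), 0)
  tr2 <- current_trace("x", c(0, 158.4), c(2.19, 2.19))
  expect_equal(round(integrate_charge(tr2), 2), 12.94)
  expect_error(integrate_charge(tr2, c(5, 5)), "empty")
  expect_error(integrate_charge(tr2, c(0, 200)), "beyond the recorded trace")
})

test_that("balances and the EF coefficient reproduce every worked-example row", {
  # printed ledger entries are rounded to 1 d.p.; the recomputed balance is
  # asserted inside the interval-arithmetic envelope implied by +/-0.05 on
  # every printed entry (plus 0.05 on the printed balance itself)
  tab <- worked_example_table()
  for (i in seq_len(nrow(tab))) {
    led <- worked_example_ledger(tab$cell[i])
    n_out <- nrow(led$outlet); n_in <- nrow(led$inlet)
    env <- function(num, den, n_num, n_den) {
      hi <- 100 * (num + 0.05 * n_num) / max(den - 0.05 * n_den, 1e-9)
      lo <- 100 * (num - 0.05 * n_num) / (den + 0.05 * n_den)
      c(lo - 0.051, hi + 0.051)
    }
    cb <- carbon_balance(led)
    bound <- env(sum(led$outlet$mmol_c), sum(led$inlet$mmol_c), n_out, n_in)
    expect_gte(tab$printed_cb[i], bound[1])
    expect_lte(tab$printed_cb[i], bound[2])
    expect_lt(abs(cb - tab$printed_cb[i]), 0.55)
    eb <- electron_balance(led)
    boundE <- env(sum(led$outlet$mmol_e),
                  sum(led$inlet$mmol_e) + led$charge_mmol_e, n_out, n_in + 1)
    expect_gte(tab$printed_eb[i], boundE[1])
    expect_lte(tab$printed_eb[i], boundE[2])
    expect_lt(abs(eb - tab$printed_eb[i]), 0.55)
    if (!is.na(tab$printed_eta[i]))
      expect_lt(abs(ef_coefficient(led) - tab$printed_eta[i]), 0.0105)
  }
})

test_that("balance identities: zero outlet, full recovery, additivity", {
  inlet <- data.frame(compound = "lactate", mmol = 3)
  zero <- balance_ledger(inlet, data.frame(compound = character(),
                                           mmol = numeric()))
  expect_equal(carbon_balance(zero), 0)
  expect_equal(electron_balance(zero), 0)
  full <- balance_ledger(inlet, inlet)
  expect_equal(electron_balance(full), 100)
  expect_equal(carbon_balance(full), 100)
  # splitting one compound across chambers leaves balances unchanged
  a <- balance_ledger(inlet, data.frame(compound = "acetate", mmol = 2))
  b <- balance_ledger(inlet, data.frame(compound = c("acetate", "acetate"),
                                        mmol = c(0.75, 1.25)))
  expect_equal(carbon_balance(a), carbon_balance(b))
  expect_equal(electron_balance(a), electron_balance(b))
})

test_that("the EF coefficient excludes fed substrates and gases, is 0 for controls", {
  lb1 <- worked_example_ledger("LB1")
  # butyrate was fed: only acetate + propionate electrons count
  expect_equal(ef_coefficient(lb1), 123.8 / (31.6 + 59.6))
  l3 <- worked_example_ledger("L3")
  # butyrate was produced, not fed: it counts
  expect_equal(ef_coefficient(l3), 36.9 / (49.7 + 135.8 + 36.4))
  ctrl <- worked_example_ledger("C_L1_pH5")
  expect_equal(ef_coefficient(ctrl), 0)
  # homogeneity of degree 0 under joint scaling of charge and products
  scaled <- balance_ledger(lb1$inlet,
                           transform(lb1$outlet, mmol_c = mmol_c * 3,
                                     mmol_e = mmol_e * 3),
                           charge_mmol_e = lb1$charge_mmol_e * 3,
                           fed_substrates = lb1$fed_substrates)
  expect_equal(ef_coefficient(scaled), ef_coefficient(lb1))
  # no product electrons at all -> error
  bad <- balance_ledger(data.frame(compound = "lactate", mmol = 3),
                        data.frame(compound = "lactate", mmol = 3),
                        charge_mmol_e = 10)
  expect_error(ef_coefficient(bad), "no soluble product")
})

test_that("specific energy consumption follows I*V*t over mass", {
  expect_equal(energy_consumption(1000, 1, 1, 1), 0.001)
  m_l3 <- c(propionic = 9.7 * 74.08, acetic = 6.2 * 60.05,
            butyric = 1.825 * 88.11) / 1e6  # mmol * g/mol -> kg
  e_l3 <- energy_consumption(2.18, 3, 381.6, m_l3)
  expect_equal(e_l3, 1.99, tolerance = 0.01)
  expect_equal(energy_consumption(2.18, 3, 381.6, m_l3 * 2), e_l3 / 2)
  expect_error(energy_consumption(1, 1, 0, 1), "positive")
  expect_error(energy_consumption(1, 1, 1, 0), "positive")
})

test_that("gas bag fractions convert by the ideal-gas law", {
  expect_equal(gas_amount(1, 1, 298.15, 101325), 40.87, tolerance = 0.01)
  expect_equal(gas_amount(0, 1), 0)
  expect_equal(gas_amount(0.5, 0.5, 298.15, 101325),
               gas_amount(0.5, 1, 298.15, 101325) / 2)
  expect_error(gas_amount(1.2, 1), "fraction")
})

test_that("the ledger report rounds like the published tables and flags > 100%", {
  rep <- report_balance(worked_example_ledger("LB1"))
  expect_equal(rep$electron_balance_pct, 67.9)
  expect_equal(rep$carbon_balance_pct, 70.8)
  expect_equal(rep$eta_EF, 1.36)
  bogus <- balance_ledger(data.frame(compound = "lactate", mmol = 1),
                          data.frame(compound = "lactate", mmol = 2))
  expect_warning(report_balance(bogus), "exceeds 100")
})
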