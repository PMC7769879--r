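# Independent atom-count oracle: own atom table, electrons from the
# half-reaction solver in helper-fixtures.R (not the registry).
oracle_atoms <- data.frame(
  species = c("lactate", "propionate", "acetate", "butyrate", "h2", "co2"),
  c = c(3, 3, 2, 4, 0, 1), h = c(6, 6, 4, 8, 2, 0), o = c(3, 2, 2, 2, 0, 2))

test_that("every built-in reaction balances carbon and electrons (independent oracle)", {
  S <- builtin_network()
  for (rx in colnames(S)) {
    carbon <- 0; electrons <- 0
    for (sp in rownames(S)) {
      coef <- S[sp, rx]
      if (coef == 0) next
      if (sp == "e") {
        electrons <- electrons + coef
      } else {
        a <- oracle_atoms[oracle_atoms$species == sp, ]
        carbon <- carbon + coef * a$c
        electrons <- electrons + coef * half_reaction_electrons(a$c, a$h, a$o)
      }
    }
    expect_equal(carbon, 0, info = rx)
    expect_equal(electrons, 0, info = rx)
  }
  # and the packaged checker agrees
  chk <- check_reaction_balance(S)
  expect_true(all(chk$carbon == 0) && all(chk$electron == 0))
})

test_that("coupled fermentation + full CO2 recycling gives 2/3, 1/2 and ratio 4/3", {
  y <- theoretical_combined_yields()
  expect_equal(y$propionate, 2 / 3)
  expect_equal(y$acetate, 1 / 2)
  expect_equal(y$ratio, 4 / 3)
  expect_equal(round(y$ratio, 2), 1.33)
  # fermentation alone: 2 propionate to 1 acetate
  S <- builtin_network()
  expect_equal(S["propionate", "ferm"] / S["acetate", "ferm"], 2)
  # acetogenic share of acetate in combined mode
  expect_equal((y$acetate - 1 / 3) / y$acetate, 1 / 3)
})

test_that("extent decomposition implements the attribution algebra", {
  ex <- decompose_extents(list(propionate = 12, acetate = 9, butyrate = 0))
  expect_equal(ex$xi_ferm, 6)
  expect_equal(ex$xi_acet, 3)
  expect_equal(ex$co2_net, 0)
  expect_equal(ex$h2_demand, 12)
  expect_equal(ex$charge_demand, 24)

  z <- decompose_extents(list(propionate = 0, acetate = 0, butyrate = 0))
  expect_equal(c(z$xi_ferm, z$xi_acet, z$xi_ce, z$xi_her), rep(0, 4))

  l3 <- decompose_extents(list(propionate = 9.7, acetate = 6.2,
                               butyrate = 1.825))
  expect_equal(l3$xi_ferm, 4.85)
  expect_equal(l3$xi_acet, 3.175)
  expect_equal(l3$xi_ce, 1.825)

  expect_error(decompose_extents(list(propionate = -1, acetate = 0,
                                      butyrate = 0)), "production")
  # acetate shortfall floors acetogenesis at zero and reports the residual
  fl <- decompose_extents(list(propionate = 10, acetate = 2, butyrate = 0))
  expect_equal(fl$xi_acet, 0)
  expect_equal(fl$residual[["acetate"]], -3)
  # lactate residual exposes unmodelled consumption
  lr <- decompose_extents(list(propionate = 12, acetate = 9, butyrate = 0,
                               lactate = -20))
  expect_equal(lr$residual[["lactate"]], -2)
})

test_that("decomposition inverts reconstruction for random feasible extents", {
  set.seed(7)
  for (rep in 1:100) {
    xf <- runif(1, 0, 10); xa <- runif(1, 0, 5)
    xc <- runif(1, 0, 0.99) * (xf + xa)  # keep the acetate delta positive
    xh <- 4 * xa + runif(1, 0, 3)
    d <- reconstruct_deltas(list(xi_ferm = xf, xi_acet = xa, xi_ce = xc,
                                 xi_her = xh))
    ex <- decompose_extents(list(propionate = d[["propionate"]],
                                 acetate = d[["acetate"]],
                                 butyrate = d[["butyrate"]],
                                 lactate = d[["lactate"]]),
                            h2_out = d[["h2"]])
    expect_equal(ex$xi_ferm, xf)
    expect_equal(ex$xi_acet, xa)
    expect_equal(ex$xi_ce, xc)
    expect_equal(ex$xi_her, xh)
    expect_equal(ex$residual[["lactate"]], 0)
    expect_equal(ex$co2_net, d[["co2"]])
  }
})

test_that("the predicted propionate:acetate ratio obeys its identities", {
  expect_equal(predicted_ratio(list(xi_ferm = 4, xi_acet = 2, xi_ce = 0)),
               4 / 3)
  expect_equal(predicted_ratio(list(xi_ferm = 4, xi_acet = 0, xi_ce = 0)), 2)
  expect_equal(round(predicted_ratio(list(xi_ferm = 6, xi_acet = 3,
                                          xi_ce = 0)), 2), 1.33)
  # scale invariance
  expect_equal(predicted_ratio(list(xi_ferm = 1.7, xi_acet = 0.4, xi_ce = 0.2)),
               predicted_ratio(list(xi_ferm = 17, xi_acet = 4, xi_ce = 2)))
  expect_error(predicted_ratio(list(xi_ferm = 0, xi_acet = 0, xi_ce = 0)),
               "positive")
})

test_that("CO2 recycling is 2 per acetogenic extent, capped at internal production", {
  expect_equal(co2_recycled(list(xi_ferm = 6, xi_acet = 3, xi_ce = 0))$fixed, 6)
  expect_equal(co2_recycled(list(xi_ferm = 6, xi_acet = 0, xi_ce = 0))$fixed, 0)
  cap <- co2_recycled(list(xi_ferm = 6, xi_acet = 4, xi_ce = 0))
  expect_equal(cap$recycled, 6)
  expect_equal(cap$external, 2)
  expect_true(cap$flag)
})

test_that("the extents report recovers configured pathway activity from a simulation", {
  sim <- sim_fix(c(ferm = 0.6, acet = 0.3, ce = 0.05, her = 1.3),
                 lactate_mM = 20)
  rep <- report_extents(sim$experiment)
  expect_equal(rep$xi_ferm, 0.6, tolerance = 1e-9)
  expect_equal(rep$xi_acet, 0.3, tolerance = 1e-9)
  expect_equal(rep$xi_ce, 0.05, tolerance = 1e-9)
  expect_equal(rep$co2_recycled, 2 * 0.3, tolerance = 1e-9)
})
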