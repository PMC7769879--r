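# triangular sweep fixture: current is a function of potential per branch
tri_cycle <- function(f_cath, f_anod = f_cath, window = c(-1.2, 0),
                      step = 0.001) {
  down <- seq(window[2], window[1], by = -step)
  up <- rev(down)
  data.frame(potential_V = c(down, up),
             current_mA = c(f_cath(down), f_anod(up)))
}

test_that("cycle selection defaults to the third replicate", {
  vg <- simulate_cv(n_cycles = 4)
  expect_equal(select_cycle(vg), vg$cycles[[3]])
  expect_equal(select_cycle(vg, 1), vg$cycles[[1]])
  vg2 <- simulate_cv(n_cycles = 2)
  expect_error(select_cycle(vg2), "available cycles: 1-2")
})

test_that("the first derivative is exact for linear and constant branches", {
  lin <- tri_cycle(function(E) 2.5 * E + 0.3)
  d <- first_derivative(lin)
  expect_equal(d$dI_dE, rep(2.5, nrow(d)), tolerance = 1e-6)
  flat <- tri_cycle(function(E) rep(0.2, length(E)))
  d0 <- first_derivative(flat)
  expect_equal(d0$dI_dE, rep(0, nrow(d0)), tolerance = 1e-9)
  # derivative of a Gaussian peak crosses zero at its center
  g <- tri_cycle(function(E) -0.5 * exp(-0.5 * ((E + 0.46) / 0.03)^2))
  dg <- first_derivative(g)
  cath <- dg[dg$branch == "cathodic" & dg$potential_V > -0.56 &
               dg$potential_V < -0.36, ]
  cross <- cath$potential_V[which(diff(sign(cath$dI_dE)) != 0)[1]]
  expect_lt(abs(cross - (-0.46)), 0.002)
  # adding a constant offset leaves the derivative unchanged
  g2 <- g; g2$current_mA <- g2$current_mA + 5
  expect_equal(first_derivative(g2)$dI_dE, dg$dI_dE, tolerance = 1e-9)
  expect_error(first_derivative(lin, smooth_window_mV = 5000),
               "window larger")
})

test_that("peak detection finds injected extrema and respects the threshold", {
  flat <- tri_cycle(function(E) rep(0, length(E)))
  expect_equal(nrow(detect_peaks(flat, 0.01)), 0)
  two <- tri_cycle(
    function(E) -0.05 - 0.4 * exp(-0.5 * ((E + 0.46) / 0.03)^2) -
      0.3 * exp(-0.5 * ((E + 0.24) / 0.03)^2),
    function(E) rep(0.05, length(E)))
  pk <- detect_peaks(two, 0.05, direction = "reduction")
  expect_equal(nrow(pk), 2)
  expect_equal(pk$potential_V, c(-0.46, -0.24), tolerance = 0.002)
  expect_equal(nrow(detect_peaks(two, 0.5)), 0)
  # monotone in the prominence threshold
  lo <- detect_peaks(two, 0.05)
  hi <- detect_peaks(two, 0.35)
  expect_true(all(hi$potential_V %in% lo$potential_V))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("redox couples pair nearest opposite peaks within the threshold", {
  peaks <- data.frame(potential_V = c(-0.24, -0.29),
                      direction = c("reduction", "oxidation"),
                      magnitude_mA = c(0.3, 0.2), prominence_mA = c(0.3, 0.2))
  cp <- pair_couples(peaks)
  expect_equal(cp$midpoint_V, -0.265)
  expect_equal(cp$separation_V, 0.05)
  # a single unpaired reduction peak yields no couple
  expect_equal(nrow(pair_couples(peaks[1, ])), 0)
  # two reductions near one oxidation: nearest wins (brute-force check)
  three <- data.frame(potential_V = c(-0.30, -0.22, -0.26),
                      direction = c("reduction", "reduction", "oxidation"),
                      magnitude_mA = 1, prominence_mA = 1)
  cp3 <- pair_couples(three)
  expect_equal(nrow(cp3), 1)
  seps <- abs(c(-0.30, -0.22) - (-0.26))
  expect_equal(cp3$separation_V, min(seps))
  expect_equal(cp3$e_red, c(-0.30, -0.22)[which.min(seps)])
  # out of range: no pairing
  far <- data.frame(potential_V = c(-0.9, -0.2),
                    direction = c("reduction", "oxidation"),
                    magnitude_mA = 1, prominence_mA = 1)
  expect_equal(nrow(pair_couples(far)), 0)
})

test_that("onset shift measures the displacement of the cathodic threshold crossing", {
  her <- function(onset) function(E) -0.1 * exp((onset - E) / 0.05)
  begin <- tri_cycle(her(-0.9))
  end <- tri_cycle(her(-0.65))
  expect_equal(onset_shift(begin, begin, 0.1), 0)
  expect_equal(onset_shift(begin, end, 0.1), 0.25, tolerance = 0.002)
  expect_error(onset_shift(begin, end, 1e6), "never reached")
})

test_that("end-to-end: simulated couple is recovered through the report", {
  pk <- data.frame(center_V = c(-0.24, -0.29), height_mA = c(0.3, 0.25),
                   width_mV = 30, direction = c("reduction", "oxidation"))
  vg <- simulate_cv(pk, baseline_mA = 0.05, noise_sd = 0.002, seed = 11)
  rep <- report_cv(vg)
  expect_equal(nrow(rep$couples), 1)
  expect_lt(abs(rep$couples$midpoint_V - (-0.265)), 0.0011)
})

test_that("simulated voltammograms are deterministic and respect their spec", {
  a <- simulate_cv(noise_sd = 0.01, seed = 5)
  b <- simulate_cv(noise_sd = 0.01, seed = 5)
  expect_identical(a$cycles, b$cycles)
  # no peaks, no noise: branch currents are the capacitive offset + HER tail
  bare <- simulate_cv(baseline_mA = 0.07, her_mA = 0, noise_sd = 0)
  cyc <- select_cycle(bare)
  expect_true(all(abs(abs(cyc$current_mA) - 0.07) < 1e-12))
  expect_error(simulate_cv(data.frame(center_V = 0.4, height_mA = 1,
                                      width_mV = 30,
                                      direction = "reduction")),
               "within the potential window")
})
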