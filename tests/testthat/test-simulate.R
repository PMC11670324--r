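test_that("methanogenic library entries are BES sensitive", {
  lib <- default_reaction_library()
  makes_ch4 <- purrr::map_lgl(lib$stoichiometry,
                              ~ "CH4" %in% names(.x) && .x[["CH4"]] > 0)
  expect_true(all(lib$bes_sensitive[makes_ch4]))
  # primary fermentation routes exactly 32 e- per amino sugar into products
  st <- lib$stoichiometry[[which(lib$name == "nag_fermentation")]]
  reg <- compound_registry()
  prod <- st[st > 0]
  e_products <- sum(prod * reg$reductant_factor[match(names(prod), reg$name)])
  expect_equal(e_products, 32)
})

test_that("trajectories conserve total carbon and electrons without a sink", {
  m <- closed_model()
  sim <- simulate_microcosm(m, simple_design()[1, ], seed = 2, n_replicates = 1)
  ct <- conservation_totals(sim)
  expect_lt(max(abs(ct$total_C_uM - ct$total_C_uM[1])) / ct$total_C_uM[1], 1e-6)
  expect_lt(max(abs(ct$total_e_uM - ct$total_e_uM[1])) / ct$total_e_uM[1], 1e-6)
})

test_that("identical seeds reproduce byte-identical output, different seeds do not", {
  m <- fermentation_model(noise_sd = 4)
  a <- simulate_microcosm(m, simple_design()[1, ], seed = 9)
  b <- simulate_microcosm(m, simple_design()[1, ], seed = 9)
  expect_identical(serialize(a$series, NULL), serialize(b$series, NULL))
  c <- simulate_microcosm(m, simple_design()[1, ], seed = 10)
  expect_false(identical(a$series, c$series))
})

test_that("the amino-sugar scenario reproduces the expected product succession", {
  m <- fermentation_model(noise_sd = 0)
  sim <- simulate_microcosm(m, nag_design()[2, ], seed = 1, n_replicates = 1)
  tr <- function(p) dplyr::filter(sim$truth, .data$pool == p)
  # substrate effectively exhausted by day 4
  expect_lt(tr("NAG")$uM[tr("NAG")$day == 4], 1)
  # transient ethanol and formate maxima before day 4
  eth <- tr("ethanol"); fo <- tr("formate")
  expect_lt(eth$day[which.max(eth$uM)], 4)
  expect_lt(fo$day[which.max(fo$uM)], 4)
  expect_lt(eth$uM[eth$day == 10], 0.1 * max(eth$uM))
  # methane increases monotonically and mostly after the fermentation stage
  ch4 <- tr("CH4")
  expect_false(is.unsorted(ch4$uM))
  expect_gt(ch4$uM[ch4$day == 10], ch4$uM[ch4$day == 4])
})

test_that("BES zeroes methanogenesis and enlarges transient fermentation pools", {
  m <- fermentation_model(noise_sd = 0)
  des <- nag_design()
  no_bes <- simulate_microcosm(m, des[2, ], seed = 1, n_replicates = 1)
  with_bes <- simulate_microcosm(m, des[3, ], seed = 1, n_replicates = 1)
  ch4 <- dplyr::filter(with_bes$truth, .data$pool == "CH4")
  expect_true(all(ch4$uM == 0))
  mx <- function(sim, p) max(dplyr::filter(sim$truth, .data$pool == p)$uM)
  expect_gt(mx(with_bes, "formate"), mx(no_bes, "formate"))
  expect_gt(mx(with_bes, "ethanol"), mx(no_bes, "ethanol"))
})

test_that("the unmeasured sink diverts carbon in proportion and monotonically", {
  des <- simple_design()
  rec <- purrr::map_dbl(c(0, 0.2, 0.4, 0.6), function(s) {
    m <- closed_model(unmeasured_sink_fraction = s)
    ex <- simulate_experiment(m, des, seed = 3, n_replicates = 1)
    rr <- recovery_ratio(net_turnover(ex$series, ex$design, "trt"),
                         basis = "carbon")
    rr$recovery_pct[rr$t_start == 0 & rr$t_end == 10]
  })
  expect_true(all(diff(rec) < 0))
  # and the sink pool carries exactly what the products lost
  m <- closed_model(unmeasured_sink_fraction = 0.3)
  sim <- simulate_microcosm(m, des[1, ], seed = 3, n_replicates = 1)
  ct <- conservation_totals(sim)
  expect_lt(max(abs(ct$total_C_uM - ct$total_C_uM[1])) / ct$total_C_uM[1], 1e-6)
})

test_that("simulated chambers invert exactly without noise and honour contracts", {
  ser <- simulate_chamber(true_flux = 120, seed = 1)
  est <- tidy(chamber_flux(ser, volume_m3 = 0.05, area_m2 = 0.25))
  expect_equal(est$flux_umol_m2_h, 120, tolerance = 1e-9)
  flat <- simulate_chamber(true_flux = 0, seed = 1)
  expect_true(all(flat$ppmv == flat$ppmv[1]))
  expect_error(simulate_chamber(1, timepoints = 0, seed = 1), "2 timepoints")
  expect_error(simulate_chamber(1, volume_m3 = 0, seed = 1), "positive")
  expect_error(simulate_chamber(1), "seed")
})

test_that("measurement noise is truncated at zero and only touches measured analytes", {
  m <- fermentation_model(noise_sd = 50)
  sim <- simulate_microcosm(m, simple_design()[1, ], seed = 4)
  expect_true(all(sim$series$concentration_uM >= 0))
  expect_setequal(unique(sim$series$analyte), m$measured_analytes)
  # truth is noiseless: replicate-independent
  expect_equal(nrow(dplyr::distinct(sim$truth, .data$pool, .data$day)),
               nrow(sim$truth))
})
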