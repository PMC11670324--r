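test_that("frame differencing: constant, forced-arithmetic and replicate cases", {
  days <- c(0, 2, 4)
  flat <- make_series(days, list(acetate = c(100, 100, 100)))
  d <- frame_delta(flat, "trt", c(0, 4))
  expect_equal(d$delta_uM, 0)
  expect_equal(d$se, 0)

  two_rep <- dplyr::bind_rows(
    make_series(c(0, 4), list(NAG = c(0, 100)), replicate = "a"),
    make_series(c(0, 4), list(NAG = c(0, 120)), replicate = "b")
  )
  d2 <- frame_delta(two_rep, "trt", c(0, 4))
  expect_equal(d2$delta_uM, 110)
  # SE of the endpoint mean of {100, 120}: sd/sqrt(2) = 10
  expect_equal(d2$se, 10)
  # per-replicate differencing agrees on the mean
  d3 <- frame_delta(two_rep, "trt", c(0, 4), replicate_policy = "per_replicate")
  expect_equal(d3$delta_uM, 110)
})

test_that("unsampled frame boundaries interpolate with a warning, or reject", {
  ser <- make_series(c(0, 3, 5), list(acetate = c(0, 30, 50)))
  expect_warning(d <- frame_delta(ser, "trt", c(0, 4)), "interpolated")
  expect_equal(d$delta_uM, 40)  # linear between day 3 (30) and day 5 (50)
  expect_error(
    suppressWarnings(frame_delta(ser, "trt", c(0, 4), interpolate = FALSE)),
    "not sampled"
  )
  expect_error(frame_delta(ser, "trt", c(0, 7)), "not sampled")
  expect_error(frame_delta(ser, "trt", c(0, 4), analytes = "CH4"), "absent")
  expect_error(frame_delta(ser, "trt", c(4, 0)), "t_start < t_end")
})

test_that("control subtraction nets out shared background and enforces BES match", {
  days <- c(0, 4)
  trt <- make_series(days, list(acetate = c(0, 500)), treatment = "trt")
  ctl <- make_series(days, list(acetate = c(0, 100)), treatment = "ctl")
  td <- frame_delta(trt, "trt", c(0, 4))
  cd <- frame_delta(ctl, "ctl", c(0, 4))
  net <- control_subtract(td, cd)
  expect_equal(net$delta_uM, 400)
  # identity subtraction gives exactly zero
  expect_equal(control_subtract(td, td)$delta_uM, 0)
  expect_error(control_subtract(td, cd, treatment_bes = TRUE, control_bes = FALSE),
               "BES mismatch")
})

test_that("carbon/reductant conversion multiplies by the factor pair", {
  net <- tibble::tibble(analyte = c("NAG", "CO2", "H2O"),
                        delta_uM = c(-500, 100, 0))
  out <- to_carbon_reductant(net)
  expect_equal(out$carbon_uM, c(-4000, 100, 0))
  expect_equal(out$reductant_uM, c(-16000, 0, 0))
  expect_error(to_carbon_reductant(tibble::tibble(analyte = "krypton", delta_uM = 1)),
               "Unregistered")
})

test_that("recovery ratio matches the factor-arithmetic oracle", {
  # consumed 100 NAG (800 uM-C); products: 200 acetate + 100 ethanol
  # + 100 formate + 100 CO2 = 400+200+100+100 = 800 uM-C -> 100%
  mk <- function(scale) {
    to_carbon_reductant(tibble::tibble(
      t_start = 0, t_end = 4,
      analyte = c("NAG", "acetate", "ethanol", "formate", "CO2"),
      delta_uM = c(-100, scale * c(200, 100, 100, 100))
    ))
  }
  rr <- recovery_ratio(mk(1), basis = "carbon")
  expect_equal(rr$recovery_pct, 100)
  expect_true(rr$defined)
  rr_half <- recovery_ratio(mk(0.5), basis = "carbon")
  expect_equal(rr_half$recovery_pct, 50)
  # > 100% is reported as-is with the flag, never clipped
  rr_over <- recovery_ratio(mk(1.5), basis = "carbon")
  expect_equal(rr_over$recovery_pct, 150)
  expect_true(rr_over$exceeds_100)
  # no net consumption -> undefined with flag, not a number
  prod_only <- to_carbon_reductant(tibble::tibble(
    t_start = 0, t_end = 4, analyte = "acetate", delta_uM = 50))
  rr_undef <- recovery_ratio(prod_only, basis = "carbon")
  expect_false(rr_undef$defined)
  expect_true(is.na(rr_undef$recovery_pct))
})

test_that("product fractions partition the recovered pool", {
  tbl <- to_carbon_reductant(tibble::tibble(
    t_start = 0, t_end = 4,
    analyte = c("NAG", "acetate", "ethanol", "formate", "CO2"),
    delta_uM = c(-100, 200, 100, 100, 100)
  ))
  # acetate: 400 uM-C of 800 uM-C produced -> 50%
  fr <- product_fraction(tbl, "acetate", basis = "carbon")
  expect_equal(fr$fraction_pct, 50)
  # single product -> 100%; absent compound -> 0%; consumed compound -> 0%
  one <- to_carbon_reductant(tibble::tibble(
    t_start = 0, t_end = 4, analyte = c("NAG", "acetate"), delta_uM = c(-10, 5)))
  expect_equal(product_fraction(one, "acetate", "carbon")$fraction_pct, 100)
  expect_equal(product_fraction(one, "CH4", "carbon")$fraction_pct, 0)
  expect_equal(product_fraction(one, "NAG", "carbon")$fraction_pct, 0)
  # all fractions over all products sum to 100%
  all_fr <- product_fraction(tbl, basis = "carbon")
  expect_equal(sum(all_fr$fraction_pct), 100)
})

test_that("frame additivity: delta(0-4) + delta(4-10) = delta(0-10) exactly", {
  m <- closed_model()
  ex <- simulate_experiment(m, simple_design(), seed = 11, n_replicates = 1)
  nt <- net_turnover(ex$series, ex$design, "trt")
  wide <- nt |>
    dplyr::mutate(frame = paste0(t_start, "_", t_end)) |>
    dplyr::select(frame, analyte, delta_uM) |>
    tidyr::pivot_wider(names_from = frame, values_from = delta_uM)
  expect_equal(wide$`0_4` + wide$`4_10`, wide$`0_10`)
})

test_that("net turnover table keeps sign coherence across its three unit columns", {
  m <- fermentation_model(noise_sd = 3)
  ex <- simulate_experiment(m, nag_design(), seed = 5)
  nt <- net_turnover(ex$series, ex$design, "NAG")
  reg <- compound_registry()
  fac <- reg[match(nt$analyte, reg$name), ]
  expect_equal(nt$carbon_uM, nt$delta_uM * fac$carbon_factor)
  expect_equal(nt$reductant_uM, nt$delta_uM * fac$reductant_factor)
  nonzero <- fac$carbon_factor > 0 & fac$reductant_factor > 0
  expect_equal(sign(nt$carbon_uM[nonzero]), sign(nt$delta_uM[nonzero]))
  expect_equal(sign(nt$reductant_uM[nonzero]), sign(nt$delta_uM[nonzero]))
  expect_true(all(nt$reductant_uM[fac$reductant_factor == 0] == 0))
})

test_that("design validation refuses a BES-mismatched or dangling control", {
  bad <- tibble::tibble(treatment_id = c("a", "b"), bes = c(TRUE, FALSE),
                        control_id = c("b", "b"))
  expect_error(net_turnover(
    make_series(c(0, 4, 10), list(acetate = c(1, 2, 3)), treatment = "a"),
    bad, "a"), "BES")
  dangling <- tibble::tibble(treatment_id = "a", bes = FALSE, control_id = "zz")
  expect_error(net_turnover(
    make_series(c(0, 4, 10), list(acetate = c(1, 2, 3)), treatment = "a"),
    dangling, "a"), "not a design row")
})
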