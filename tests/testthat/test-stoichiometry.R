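test_that("formula parsing reflects the string exactly, with implied 1s", {
  expect_identical(parse_formula("C8H15NO6"), c(C = 8L, H = 15L, N = 1L, O = 6L))
  expect_identical(parse_formula("CH4"), c(C = 1L, H = 4L))
  expect_identical(parse_formula("CO2"), c(C = 1L, O = 2L))
  expect_identical(parse_formula("H2"), c(H = 2L))
  # repeated element symbols accumulate
  expect_identical(parse_formula("CH3COOH")[["C"]], 2L)
})

test_that("malformed formulas are rejected with the failure position", {
  expect_error(parse_formula("C2x4"), "position 3")
  expect_error(parse_formula("Xy2"), "Unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C0H4"), "Invalid atom count")
  expect_error(degree_of_reduction("C2H6S"), "S")
})

test_that("degree of reduction and factor pairs match the standard table", {
  cases <- tibble::tribble(
    ~formula,   ~carbon, ~electrons,
    "C8H15NO6",  8L, 32L,  # N-acetylglucosamine
    "CH2O2",     1L,  2L,  # formic acid
    "C2H6O",     2L, 12L,  # ethanol
    "C2H4O2",    2L,  8L,  # acetic acid
    "C3H6O2",    3L, 14L,  # propionic acid
    "CH4",       1L,  8L,  # methane
    "CO2",       1L,  0L,  # carbon dioxide
    "H2",        0L,  2L,
    "C6H12O6",   6L, 24L   # glucose
  )
  for (i in seq_len(nrow(cases))) {
    fac <- carbon_reductant_factors(cases$formula[i])
    expect_identical(fac$carbon_factor, cases$carbon[i], label = cases$formula[i])
    expect_identical(fac$reductant_factor, cases$electrons[i], label = cases$formula[i])
  }
})

test_that("the shipped registry reproduces all printed factor pairs", {
  reg <- compound_registry()
  expected <- c(NAG = "8/32", formate = "1/2", ethanol = "2/12", acetate = "2/8",
                propionate = "3/14", CH4 = "1/8", CO2 = "1/0")
  got <- with(reg, paste0(carbon_factor, "/", reductant_factor)[match(names(expected), name)])
  expect_identical(unname(got), unname(expected))
})

test_that("degree of reduction is additive over combined atom counts", {
  set.seed(42)
  for (rep in 1:25) {
    a <- c(C = sample(0:8, 1), H = sample(0:16, 1), N = sample(0:2, 1), O = sample(0:6, 1))
    b <- c(C = sample(0:8, 1), H = sample(0:16, 1), N = sample(0:2, 1), O = sample(0:6, 1))
    a <- a[a > 0]; b <- b[b > 0]
    if (length(a) == 0 || length(b) == 0) next
    ab <- tapply(c(a, b), names(c(a, b)), sum)
    ab <- stats::setNames(as.integer(ab), names(ab))
    expect_equal(
      suppressWarnings(degree_of_reduction(ab)),
      suppressWarnings(degree_of_reduction(a)) + suppressWarnings(degree_of_reduction(b))
    )
  }
})

test_that("negative degree of reduction warns but does not abort", {
  expect_warning(g <- degree_of_reduction(c(O = 2)), "oxidant")
  expect_identical(g, -4L)
})

test_that("balance checker computes per-element and electron residuals", {
  # 4 HCOOH -> CH4 + 3 CO2 + 2 H2O
  rx <- reaction("formate disproportionation",
                 c(formate = -4, CH4 = 1, CO2 = 3, H2O = 2))
  rep <- check_reaction_balance(rx)
  expect_true(all(rep$balanced))
  expect_true(all(abs(rep$residual) < 1e-12))

  # ethanol + H2O -> acetate + 2 H2 (electrons: 12 = 8 + 4)
  expect_true(reaction_balanced(reaction("etoh", c(ethanol = -1, H2O = -1,
                                                   acetate = 1, H2 = 2))))

  # CH4 -> CO2 misses the reductant sink: H residual -4, electron residual -8
  bad <- check_reaction_balance(c(CH4 = -1, CO2 = 1))
  expect_false(any(bad$balanced))
  expect_equal(bad$residual[bad$quantity == "H"], -4)
  expect_equal(bad$residual[bad$quantity == "electrons"], -8)
})

test_that("balanced reactions conserve carbon and electrons by construction", {
  lib <- default_reaction_library()
  reg <- compound_registry()
  expect_gte(nrow(lib), 6)
  for (i in seq_len(nrow(lib))) {
    st <- lib$stoichiometry[[i]]
    expect_true(reaction_balanced(reaction(lib$name[i], st)), label = lib$name[i])
    rows <- reg[match(names(st), reg$name), ]
    expect_equal(sum(st * rows$carbon_factor), 0, label = lib$name[i])
    expect_equal(sum(st * rows$reductant_factor), 0, label = lib$name[i])
  }
})

test_that("degenerate reactions are rejected", {
  expect_error(reaction("r", c(acetate = -1)), "at least one")
  expect_error(reaction("r", c(acetate = 1, CH4 = 2)), "at least one")
  expect_error(check_reaction_balance(numeric(0)), "named numeric|Empty")
  expect_error(check_reaction_balance(c(unobtainium = -1, CO2 = 1)), "Unregistered")
})
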