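#' Default anaerobic food-chain reaction library
#'
#' The element- and electron-balanced reaction set used by the microcosm
#' simulator, covering the processes inferred from product successions in
#' anoxic peat slurries:
#'
#' * primary mixed-acid fermentation of N-acetylglucosamine:
#'   `C8H15NO6 + 3 H2O -> 2 acetate + ethanol + formate + CO2 + H2 + NH3`
#' * formate methanogenesis: `4 HCOOH -> CH4 + 3 CO2 + 2 H2O`
#' * hydrogenotrophic methanogenesis: `4 H2 + CO2 -> CH4 + 2 H2O`
#' * syntrophic ethanol oxidation: `C2H5OH + H2O -> acetate + 2 H2`
#' * hydrogenotrophic acetogenesis: `4 H2 + 2 CO2 -> acetate + 2 H2O`
#' * aceticlastic methanogenesis: `CH3COOH -> CH4 + CO2`
#' * methylotrophic methanogenesis: `4 CH3OH -> 3 CH4 + CO2 + 2 H2O`
#'
#' Every entry passes [check_reaction_balance()]. Kinetics are first order in
#' one designated limiting substrate; rate constants (per day) and lags were
#' chosen so that a 500 uM amino-sugar pulse is consumed within about four
#' days, transient formate/ethanol pools peak before day 4, and methanogenesis
#' dominates the second incubation stage. Reactions performed by (or, for
#' syntrophic ethanol oxidation, obligately coupled to) methanogens are marked
#' `bes_sensitive` and are switched off by bromoethanesulfonate (BES).
#'
#' @return A tibble with columns `name`, `stoichiometry` (list of named signed
#'   coefficient vectors), `limiting`, `rate_constant` (d-1), `bes_sensitive`,
#'   `lag_days`.
#' @export
default_reaction_library <- function() {
  tibble::tribble(
    ~name, ~stoichiometry, ~limiting, ~rate_constant, ~bes_sensitive, ~lag_days,
    "nag_fermentation",
    c(NAG = -1, H2O = -3, acetate = 2, ethanol = 1, formate = 1,
      CO2 = 1, H2 = 1, NH3 = 1), "NAG", 1.6, FALSE, 0,
    "formate_methanogenesis",
    c(formate = -4, CH4 = 1, CO2 = 3, H2O = 2), "formate", 0.8, TRUE, 2,
    "hydrogenotrophic_methanogenesis",
    c(H2 = -4, CO2 = -1, CH4 = 1, H2O = 2), "H2", 1.0, TRUE, 2,
    "syntrophic_ethanol_oxidation",
    c(ethanol = -1, H2O = -1, acetate = 1, H2 = 2), "ethanol", 0.6, TRUE, 2,
    "hydrogenotrophic_acetogenesis",
    c(H2 = -4, CO2 = -2, acetate = 1, H2O = 2), "H2", 0.1, FALSE, 0,
    "aceticlastic_methanogenesis",
    c(acetate = -1, CH4 = 1, CO2 = 1), "acetate", 0.02, TRUE, 4,
    "methylotrophic_methanogenesis",
    c(methanol = -4, CH4 = 3, CO2 = 1, H2O = 2), "methanol", 0.3, TRUE, 2
  )
}

#' Fermentation model for the microcosm simulator
#'
#' Bundles the reaction set, initial pools, endogenous background and
#' observation model that [simulate_microcosm()] integrates. Initial pools
#' default to anoxic peat-slurry conditions: 500 uM dissolved CO2, bulk water,
#' and an endogenous carbon reservoir from which background CO2 is released at
#' a constant rate (electron-neutral by convention; the unresolved respiratory
#' electron acceptors of peat are out of scope, so the reservoir is carried as
#' CO2-equivalent carbon).
#'
#' @param reactions Reaction tibble as from [default_reaction_library()].
#' @param initial Named numeric vector of initial concentrations, uM.
#' @param endogenous_co2_rate Zero-order background CO2 release, uM d-1.
#' @param unmeasured_sink_fraction Fraction (0-1) of each reaction's substrate
#'   carbon and electrons diverted to an unmeasured pool instead of the
#'   measured products.
#' @param noise_sd Gaussian measurement noise SD, uM, applied to measured
#'   analytes only and truncated at zero.
#' @param measured_analytes Compound names reported in the noisy series; the
#'   default is the pools quantified in slurry incubations (amino sugar,
#'   volatile fatty acids, ethanol, CO2, CH4 — H2 is typically not reliably
#'   quantifiable).
#' @param registry Compound registry tibble.
#' @return A list of class `"fermentation_model"`.
#' @export
fermentation_model <- function(reactions = default_reaction_library(),
                               initial = c(CO2 = 500, H2O = 5.5e7),
                               endogenous_co2_rate = 200,
                               unmeasured_sink_fraction = 0,
                               noise_sd = 5,
                               measured_analytes = c("NAG", "acetate", "formate",
                                                     "ethanol", "propionate",
                                                     "CO2", "CH4"),
                               registry = compound_registry()) {
  if (unmeasured_sink_fraction < 0 || unmeasured_sink_fraction > 1) {
    stop("`unmeasured_sink_fraction` must be in [0, 1].", call. = FALSE)
  }
  if (any(initial < 0)) stop("Initial concentrations must be >= 0.", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0.", call. = FALSE)
  if (any(reactions$rate_constant < 0) || any(reactions$lag_days < 0)) {
    stop("Rate constants and lags must be >= 0.", call. = FALSE)
  }
  for (i in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[i]]
    rx <- reaction(reactions$name[i], st)
    if (!reaction_balanced(rx, registry)) {
      stop(sprintf("Reaction '%s' is not element/electron balanced.",
                   reactions$name[i]), call. = FALSE)
    }
    lim <- reactions$limiting[i]
    if (!lim %in% names(st) || st[[lim]] >= 0) {
      stop(sprintf("Reaction '%s': limiting substrate '%s' must be consumed.",
                   reactions$name[i], lim), call. = FALSE)
    }
  }
  structure(list(reactions = reactions, initial = initial,
                 endogenous_co2_rate = endogenous_co2_rate,
                 unmeasured_sink_fraction = unmeasured_sink_fraction,
                 noise_sd = noise_sd, measured_analytes = measured_analytes,
                 registry = registry),
            class = "fermentation_model")
}

#' Standard amino-sugar (NAG) microcosm design
#'
#' The four fermentation-potential treatments: unsupplemented control, 500 uM
#' N-acetylglucosamine, both repeated with 20 mM BES. Controls map to the
#' control of matching BES status; controls are their own controls.
#'
#' @param nag_uM Supplement amount, uM.
#' @return Design tibble with columns `treatment_id`, `supplement` (list of
#'   named uM vectors), `bes`, `preincubation_days`, `control_id`.
#' @export
nag_design <- function(nag_uM = 500) {
  tibble::tibble(
    treatment_id = c("control", "NAG", "NAG_BES", "control_BES"),
    supplement = list(NULL, c(NAG = nag_uM), c(NAG = nag_uM), NULL),
    bes = c(FALSE, FALSE, TRUE, TRUE),
    preincubation_days = 0L,
    control_id = c("control", "control", "control_BES", "control_BES")
  )
}

#' Methanogenic-substrate microcosm design
#'
#' Treatments probing methanogenic potentials: 1 mM formate, acetate or
#' methanol, or a hydrogen/CO2 headspace (8 vol% H2 = 8.4 mmol and 2 vol%
#' CO2 = 2.1 mmol per litre of slurry), next to unsupplemented controls with
#' and without BES.
#'
#' @param preincubation_days Days of anoxic preincubation before substrate
#'   addition.
#' @return Design tibble, see [nag_design()].
#' @export
methanogenic_design <- function(preincubation_days = 0L) {
  tibble::tibble(
    treatment_id = c("control", "control_BES", "formate", "acetate",
                     "methanol", "H2_CO2"),
    supplement = list(NULL, NULL, c(formate = 1000), c(acetate = 1000),
                      c(methanol = 1000), c(H2 = 8400, CO2 = 2100)),
    bes = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    preincubation_days = as.integer(preincubation_days),
    control_id = c("control", "control_BES", "control", "control",
                   "control", "control")
  )
}

# name of the endogenous carbon reservoir pool in the truth trajectories
ENDO_POOL <- "endogenous_dic"

#' Simulate an anoxic microcosm incubation
#'
#' Deterministic fixed-step Runge-Kutta (RK4, 0.01 d) integration of
#' first-order kinetics over the model's reaction set. For each reaction the
#' rate is `k * [limiting substrate]` after its lag; a BES treatment zeroes
#' all `bes_sensitive` rates. A fraction `unmeasured_sink_fraction` of each
#' reaction's substrate carbon and electrons is routed to an unmeasured sink
#' pool instead of the products, so total carbon and electron equivalents over
#' all pools (including the sink) are conserved exactly up to round-off.
#' Gaussian measurement noise (truncated at zero) is added to the measured
#' analytes of each replicate; the noiseless truth of every pool is returned
#' alongside.
#'
#' @param model A [fermentation_model()].
#' @param design One design row (tibble or list) with at least `treatment_id`,
#'   `supplement` (named uM vector or `NULL`) and `bes`.
#' @param duration Incubation length, days.
#' @param sampling_days Days at which the measured series is reported.
#' @param n_replicates Replicate microcosms (noise realisations).
#' @param seed Integer seed; identical seeds give identical output.
#' @param step RK4 step, days.
#' @return An object of class `"microcosm_sim"`: `series` (noisy long-format
#'   measured tibble), `truth` (noiseless trajectories of all pools including
#'   the unmeasured sink), `bookkeeping` (cumulative extent and carbon /
#'   electron throughput per reaction). [tidy()] returns the series;
#'   [ggplot2::autoplot()] plots measured series over the truth.
#' @export
simulate_microcosm <- function(model, design, duration = 10,
                               sampling_days = c(0, 1, 2, 3, 4, 6, 8, 10),
                               n_replicates = 3, seed, step = 0.01) {
  stopifnot(inherits(model, "fermentation_model"))
  if (missing(seed)) stop("A `seed` is required.", call. = FALSE)
  if (is.data.frame(design)) {
    if (nrow(design) != 1L) stop("`design` must be a single treatment row.", call. = FALSE)
    design <- as.list(design)
    design$supplement <- design$supplement[[1]]
  }
  if (any(sampling_days < 0) || any(sampling_days > duration)) {
    stop("`sampling_days` must lie within [0, duration].", call. = FALSE)
  }
  bes <- isTRUE(as.logical(design$bes))

  reactions <- model$reactions
  pools <- sort(unique(c(names(model$initial),
                         unlist(purrr::map(reactions$stoichiometry, names)),
                         names(design$supplement), model$measured_analytes,
                         ENDO_POOL)))
  y0 <- stats::setNames(numeric(length(pools)), pools)
  y0[names(model$initial)] <- model$initial
  if (!is.null(design$supplement)) {
    y0[names(design$supplement)] <- y0[names(design$supplement)] + design$supplement
  }
  # endogenous reservoir large enough to feed the background release
  y0[ENDO_POOL] <- max(y0[ENDO_POOL], model$endogenous_co2_rate * duration * 10 + 1)

  # carbon / electron factors per pool (endogenous reservoir is CO2-equivalent)
  reg <- model$registry
  cfac <- efac <- stats::setNames(numeric(length(pools)), pools)
  for (p in setdiff(pools, ENDO_POOL)) {
    row <- registry_lookup(reg, p)
    cfac[p] <- row$carbon_factor
    efac[p] <- row$reductant_factor
  }
  cfac[ENDO_POOL] <- 1
  efac[ENDO_POOL] <- 0

  s <- model$unmeasured_sink_fraction
  nrx <- nrow(reactions)
  k_eff <- ifelse(bes & reactions$bes_sensitive, 0, reactions$rate_constant)
  scale <- purrr::map2_dbl(reactions$stoichiometry, reactions$limiting,
                           ~ abs(.x[[.y]]))
  # per unit extent: substrate carbon / electrons consumed (== produced, balanced)
  sub_c <- purrr::map_dbl(reactions$stoichiometry, function(st) {
    sub <- st[st < 0]
    sum(abs(sub) * cfac[names(sub)])
  })
  sub_e <- purrr::map_dbl(reactions$stoichiometry, function(st) {
    sub <- st[st < 0]
    sum(abs(sub) * efac[names(sub)])
  })

  npool <- length(pools)
  state0 <- c(y0, sink_C = 0, sink_e = 0,
              stats::setNames(numeric(nrx), paste0("extent_", seq_len(nrx))))

  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    names(dy) <- names(y)
    for (i in seq_len(nrx)) {
      if (k_eff[i] == 0 || t < reactions$lag_days[i]) next
      lim <- reactions$limiting[i]
      v <- k_eff[i] * max(y[[lim]], 0) / scale[i]  # extent rate, uM d-1
      st <- reactions$stoichiometry[[i]]
      for (nm in names(st)) {
        co <- st[[nm]]
        dy[nm] <- dy[nm] + if (co < 0) co * v else co * v * (1 - s)
      }
      dy["sink_C"] <- dy["sink_C"] + s * v * sub_c[i]
      dy["sink_e"] <- dy["sink_e"] + s * v * sub_e[i]
      dy[paste0("extent_", i)] <- dy[paste0("extent_", i)] + v
    }
    if (model$endogenous_co2_rate > 0) {
      dy["CO2"] <- dy["CO2"] + model$endogenous_co2_rate
      dy[ENDO_POOL] <- dy[ENDO_POOL] - model$endogenous_co2_rate
    }
    list(dy)
  }

  times <- sort(unique(c(seq(0, duration, by = step), sampling_days, duration)))
  out <- deSolve::ode(y = state0, times = times, func = deriv, parms = NULL,
                      method = "rk4")
  traj <- as.data.frame(out)

  neg_tol <- 1e-6 * max(abs(state0), 1)
  worst <- min(as.matrix(traj[, pools, drop = FALSE]))
  if (worst < -neg_tol) {
    stop(sprintf("Integrator failure: pool went negative (min %.3g uM); reduce rates or supply the missing co-substrate.",
                 worst), call. = FALSE)
  }

  truth <- traj |>
    tibble::as_tibble() |>
    dplyr::select("time", dplyr::all_of(c(pools, "sink_C", "sink_e"))) |>
    tidyr::pivot_longer(-"time", names_to = "pool", values_to = "uM") |>
    dplyr::rename(day = "time") |>
    dplyr::mutate(treatment = design$treatment_id, .before = 1)

  at_sampling <- traj[match(sampling_days, traj$time), , drop = FALSE]
  measured <- intersect(model$measured_analytes, pools)
  series <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      purrr::map_dfr(measured, function(an) {
        mu <- at_sampling[[an]]
        obs <- if (model$noise_sd > 0) {
          pmax(0, mu + stats::rnorm(length(mu), 0, model$noise_sd))
        } else mu
        tibble::tibble(treatment = design$treatment_id,
                       replicate = paste0("rep", r),
                       day = sampling_days, analyte = an,
                       concentration_uM = obs)
      })
    })
  }) |>
    dplyr::arrange(.data$treatment, .data$replicate, .data$analyte, .data$day)

  final <- traj[nrow(traj), , drop = FALSE]
  bookkeeping <- tibble::tibble(
    reaction = reactions$name,
    extent_uM = purrr::map_dbl(seq_len(nrx), ~ final[[paste0("extent_", .x)]]),
    carbon_routed_uM = .data$extent_uM * sub_c,
    electrons_routed_uM = .data$extent_uM * sub_e
  )

  structure(list(series = series, truth = truth, bookkeeping = bookkeeping,
                 model = model, design = design, seed = as.integer(seed),
                 sampling_days = sampling_days,
                 factors = tibble::tibble(pool = c(pools, "sink_C", "sink_e"),
                                          carbon = c(cfac, 1, 0),
                                          electrons = c(efac, 0, 1))),
            class = "microcosm_sim")
}

#' @export
print.microcosm_sim <- function(x, ...) {
  cat(sprintf("Simulated microcosm '%s' (BES: %s), %d sampling days, %d replicates\n",
              x$design$treatment_id, isTRUE(as.logical(x$design$bes)),
              length(x$sampling_days),
              length(unique(x$series$replicate))))
  print(x$series)
  invisible(x)
}

#' @rdname simulate_microcosm
#' @param x A `microcosm_sim` object.
#' @param ... Unused.
#' @export
tidy.microcosm_sim <- function(x, ...) x$series

#' Total carbon and electron equivalents along a simulated trajectory
#'
#' Sums every pool (including the unmeasured sink) weighted by its carbon and
#' reductant factors; with zero sink and noise these totals are conserved to
#' round-off, which is the simulator's core correctness guarantee.
#'
#' @param sim A [simulate_microcosm()] result.
#' @return Tibble with columns `day`, `total_C_uM`, `total_e_uM`.
#' @export
conservation_totals <- function(sim) {
  stopifnot(inherits(sim, "microcosm_sim"))
  sim$truth |>
    dplyr::left_join(sim$factors, by = "pool") |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      total_C_uM = sum(.data$uM * .data$carbon),
      total_e_uM = sum(.data$uM * .data$electrons),
      .groups = "drop"
    )
}

#' Simulate a full replicated microcosm experiment
#'
#' Runs [simulate_microcosm()] for every treatment of a design under a shared
#' model (so treatments differ only in supplement and BES status) and binds
#' the measured series, ready for [net_turnover()].
#'
#' @param model A [fermentation_model()].
#' @param design Design tibble, e.g. [nag_design()].
#' @param seed Integer seed; per-treatment seeds are derived from it.
#' @inheritParams simulate_microcosm
#' @return List with `series` (combined measured tibble), `design`, and
#'   `sims` (named list of `microcosm_sim` objects).
#' @export
simulate_experiment <- function(model, design = nag_design(), duration = 10,
                                sampling_days = c(0, 1, 2, 3, 4, 6, 8, 10),
                                n_replicates = 3, seed, step = 0.01) {
  if (missing(seed)) stop("A `seed` is required.", call. = FALSE)
  validate_design(design)
  sims <- purrr::map(seq_len(nrow(design)), function(i) {
    simulate_microcosm(model, design[i, ], duration = duration,
                       sampling_days = sampling_days,
                       n_replicates = n_replicates,
                       seed = (as.integer(seed) + 7919L * i) %% 2147483647L,
                       step = step)
  })
  names(sims) <- design$treatment_id
  list(series = purrr::map_dfr(sims, "series"), design = design, sims = sims)
}

#' Simulate a closed-chamber accumulation series
#'
#' Generates the mixing-ratio series a chamber with a known, constant true
#' flux would record: linear accumulation
#' `baseline + flux * A R T / (P V) * t` plus Gaussian noise.
#'
#' @param true_flux True gas flux, umol m-2 h-1.
#' @param volume_m3,area_m2,temperature_K,pressure_Pa Chamber geometry and
#'   conditions.
#' @param baseline_ppmv Mixing ratio at closure.
#' @param noise_sd Gaussian noise SD, ppmv.
#' @param timepoints Sampling times, hours (default four points over 0-3 h).
#' @param seed Integer seed.
#' @param plot,gas Identifiers carried into the output.
#' @return Tibble with columns `plot`, `gas`, `hour`, `ppmv`, suitable for
#'   [chamber_flux()].
#' @export
simulate_chamber <- function(true_flux, volume_m3 = 0.05, area_m2 = 0.25,
                             temperature_K = 293.15, pressure_Pa = 101325,
                             baseline_ppmv = 400, noise_sd = 0,
                             timepoints = c(0, 1, 2, 3), seed,
                             plot = "plot1", gas = "CO2") {
  if (missing(seed)) stop("A `seed` is required.", call. = FALSE)
  if (length(timepoints) < 2L) stop("Need at least 2 timepoints.", call. = FALSE)
  geom <- c(volume_m3, area_m2, temperature_K, pressure_Pa)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("Chamber geometry and conditions must be finite and positive.", call. = FALSE)
  }
  slope <- true_flux * area_m2 * R_GAS * temperature_K / (pressure_Pa * volume_m3)
  ppmv <- baseline_ppmv + slope * timepoints
  if (noise_sd > 0) {
    ppmv <- withr::with_seed(as.integer(seed),
                             ppmv + stats::rnorm(length(timepoints), 0, noise_sd))
  }
  tibble::tibble(plot = plot, gas = gas, hour = timepoints, ppmv = ppmv)
}
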