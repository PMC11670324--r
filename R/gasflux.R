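#' Molar gas constant, J mol-1 K-1
#' @keywords internal
R_GAS <- 8.31446261815324

#' Gas conversion context for slurry incubations
#'
#' Physical constants and flask geometry used when converting between
#' headspace volume-percent, slurry concentration (uM per litre of slurry),
#' and amounts per gram dry weight of soil.
#'
#' @param headspace_volume_L Flask headspace volume, litres.
#' @param slurry_volume_L Slurry volume, litres.
#' @param temperature_K Incubation temperature, kelvin (default 293.15 K, i.e.
#'   20 degrees C).
#' @param pressure_Pa Headspace pressure, pascal.
#' @param gdw_per_liter Grams soil dry weight per litre of slurry; the divisor
#'   that converts uM slurry concentration to umol per g dry weight. The
#'   default 10.5 is a configured constant for 1:10 peat-slurry dilutions, not
#'   derived from the flask geometry.
#' @return A list of class `"gas_context"`.
#' @export
gas_context <- function(headspace_volume_L = 0.3, slurry_volume_L = 0.2,
                        temperature_K = 293.15, pressure_Pa = 101325,
                        gdw_per_liter = 10.5) {
  vals <- c(headspace_volume_L, slurry_volume_L, temperature_K, pressure_Pa,
            gdw_per_liter)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("All gas-context quantities must be finite and positive.", call. = FALSE)
  }
  structure(list(headspace_volume_L = headspace_volume_L,
                 slurry_volume_L = slurry_volume_L,
                 temperature_K = temperature_K,
                 pressure_Pa = pressure_Pa,
                 gdw_per_liter = gdw_per_liter),
            class = "gas_context")
}

#' Closed-chamber flux estimation
#'
#' Estimates the soil-atmosphere flux of each gas from the linear accumulation
#' of its mixing ratio inside a sealed chamber: an ordinary least-squares
#' slope (ppmv per hour) is converted to umol m-2 h-1 through the moles of air
#' the chamber holds (ideal gas law),
#' \deqn{F = b \; P V / (R T A)}
#' with slope b, pressure P, chamber volume V, temperature T and footprint
#' area A. Negative fluxes (uptake) are reported as-is.
#'
#' @param data Tibble with columns `plot`, `gas`, `hour`, `ppmv` (one row per
#'   sampling timepoint; additional columns such as `treatment` are carried
#'   through).
#' @param volume_m3 Chamber volume, cubic metres.
#' @param area_m2 Chamber footprint, square metres.
#' @param temperature_K Air temperature, kelvin.
#' @param pressure_Pa Air pressure, pascal.
#' @return An object of class `"chamber_flux"`; [tidy()] returns one row per
#'   (plot, gas) with `slope_ppmv_h`, `flux_umol_m2_h`, `stderr` (same units
#'   as the flux), `r_squared` and `n_points`; [glance()] summarises the fit
#'   set; [ggplot2::autoplot()] shows the series with the fitted lines.
#' @export
chamber_flux <- function(data, volume_m3, area_m2,
                         temperature_K = 293.15, pressure_Pa = 101325) {
  needed <- c("plot", "gas", "hour", "ppmv")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("Chamber data is missing column(s): %s.",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  geom <- c(volume_m3, area_m2, temperature_K, pressure_Pa)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("Chamber geometry and conditions must be finite and positive.", call. = FALSE)
  }
  # ppmv h-1 -> umol m-2 h-1: ppmv of n_air = P V / (R T) moles, per m2
  conv <- pressure_Pa * volume_m3 / (R_GAS * temperature_K * area_m2)
  estimates <- data |>
    dplyr::group_by(.data$plot, .data$gas) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2L) stop("Chamber flux needs at least 2 timepoints.", call. = FALSE)
      if (anyDuplicated(g$hour)) stop("Duplicate chamber timepoints.", call. = FALSE)
      if (diff(range(g$hour)) <= 0) stop("Zero time span in chamber series.", call. = FALSE)
      fit <- stats::lm(ppmv ~ hour, data = g)
      # noiseless series are legitimate input; silence the perfect-fit notice
      sm <- withCallingHandlers(
        summary(fit),
        warning = function(w) {
          if (grepl("essentially perfect fit", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      )
      slope <- stats::coef(fit)[["hour"]]
      se <- if (nrow(g) >= 3L) sm$coefficients["hour", "Std. Error"] else NA_real_
      r2 <- if (all(g$ppmv == g$ppmv[1])) 1 else sm$r.squared
      tibble::tibble(slope_ppmv_h = slope,
                     flux_umol_m2_h = slope * conv,
                     stderr = se * conv,
                     r_squared = r2,
                     n_points = nrow(g))
    }) |>
    dplyr::ungroup()
  structure(list(estimates = estimates, data = data,
                 geometry = list(volume_m3 = volume_m3, area_m2 = area_m2,
                                 temperature_K = temperature_K,
                                 pressure_Pa = pressure_Pa)),
            class = "chamber_flux")
}

#' @export
print.chamber_flux <- function(x, ...) {
  cat(sprintf("Closed-chamber flux estimates (%d series; V/A = %.3g m)\n",
              nrow(x$estimates), x$geometry$volume_m3 / x$geometry$area_m2))
  print(x$estimates)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname chamber_flux
#' @param x A `chamber_flux` object.
#' @param ... Unused.
#' @export
tidy.chamber_flux <- function(x, ...) x$estimates

#' @rdname chamber_flux
#' @export
glance.chamber_flux <- function(x, ...) {
  tibble::tibble(
    n_series = nrow(x$estimates),
    n_points = sum(x$estimates$n_points),
    mean_r_squared = mean(x$estimates$r_squared),
    min_r_squared = min(x$estimates$r_squared)
  )
}

#' CO2:CH4 ratio series
#'
#' Elementwise ratio of two matched series (fluxes or concentrations), joined
#' on their shared key columns (everything except the value column). Points
#' where the denominator gas is zero or negative are flagged undefined rather
#' than dropped or returned as infinities.
#'
#' @param co2,ch4 Tibbles with identical key columns plus one value column
#'   named by `value`.
#' @param value Name of the value column (default `"value"`).
#' @return The key columns plus `co2`, `ch4`, `ratio` (`NA` where undefined)
#'   and `defined`.
#' @export
ratio_series <- function(co2, ch4, value = "value") {
  for (nm in list(co2, ch4)) {
    if (!value %in% names(nm)) {
      stop(sprintf("Value column '%s' missing from a series.", value), call. = FALSE)
    }
  }
  keys <- setdiff(intersect(names(co2), names(ch4)), value)
  if (length(keys) == 0L) stop("Series share no key columns.", call. = FALSE)
  if (nrow(co2) != nrow(ch4)) {
    stop("Series are misaligned: different numbers of points.", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::rename(co2, co2 = dplyr::all_of(value)),
    dplyr::rename(ch4, ch4 = dplyr::all_of(value)),
    by = keys
  )
  if (nrow(joined) != nrow(co2)) {
    stop("Series are misaligned: keys do not match one-to-one.", call. = FALSE)
  }
  joined |>
    dplyr::mutate(
      defined = .data$ch4 > 0,
      ratio = ifelse(.data$defined, .data$co2 / .data$ch4, NA_real_)
    )
}

#' Convert headspace volume-percent to slurry concentration
#'
#' Amount of a gas added to the flask headspace, expressed per litre of
#' slurry: moles in the headspace from the ideal gas law, divided by the
#' slurry volume.
#'
#' @param vol_percent Headspace mixing ratio, volume percent (0-100).
#' @param ctx A [gas_context()].
#' @return mmol per litre of slurry (vectorised over `vol_percent`).
#' @export
headspace_to_slurry <- function(vol_percent, ctx = gas_context()) {
  stopifnot(inherits(ctx, "gas_context"))
  if (any(vol_percent < 0 | vol_percent > 100)) {
    stop("`vol_percent` must be between 0 and 100.", call. = FALSE)
  }
  mol <- (vol_percent / 100) * ctx$pressure_Pa * (ctx$headspace_volume_L / 1000) /
    (R_GAS * ctx$temperature_K)
  1000 * mol / ctx$slurry_volume_L
}

#' Convert slurry concentration to amount per gram dry weight
#'
#' Divides a uM (per litre slurry) concentration by the grams of soil dry
#' weight per litre of slurry (default divisor 10.5).
#'
#' @param conc_uM Concentration, uM of slurry (vectorised).
#' @param ctx A [gas_context()], or a single positive number used directly as
#'   the divisor.
#' @return umol per g dry weight.
#' @export
umol_per_gdw <- function(conc_uM, ctx = gas_context()) {
  divisor <- if (inherits(ctx, "gas_context")) ctx$gdw_per_liter else ctx
  if (!is.numeric(divisor) || length(divisor) != 1L || !is.finite(divisor) ||
      divisor <= 0) {
    stop("The uM to umol/gDW divisor must be a single positive number.", call. = FALSE)
  }
  conc_uM / divisor
}
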