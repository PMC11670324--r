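#' Concentration change of analytes over a time frame
#'
#' Subtracts the concentration at the start of a time frame from the
#' concentration at its end. Replicates are averaged at each endpoint first
#' (the replicate means are what incubation studies report), and the standard
#' errors of the two endpoint means are combined in quadrature. With
#' `replicate_policy = "per_replicate"` the difference is taken within each
#' replicate and the SE is that of the per-replicate differences.
#'
#' If a frame boundary was not sampled exactly, the concentration there is
#' linearly interpolated between the bracketing sampling days and a warning is
#' emitted; set `interpolate = FALSE` to require exact matches.
#'
#' @param series Long-format tibble with columns `treatment`, `replicate`,
#'   `day`, `analyte`, `concentration_uM`.
#' @param treatment Treatment identifier to difference.
#' @param frame Numeric length-2 vector `c(t_start, t_end)`, days,
#'   `t_start < t_end`.
#' @param analytes Analytes to include; default all analytes present for the
#'   treatment.
#' @param replicate_policy `"mean_first"` (default) or `"per_replicate"`.
#' @param interpolate Allow linear interpolation of unsampled frame
#'   boundaries (with a warning).
#' @return Tibble with columns `treatment`, `t_start`, `t_end`, `analyte`,
#'   `delta_uM` (positive = net production), `se`.
#' @export
frame_delta <- function(series, treatment, frame, analytes = NULL,
                        replicate_policy = c("mean_first", "per_replicate"),
                        interpolate = TRUE) {
  replicate_policy <- match.arg(replicate_policy)
  validate_slurry_series(series)
  if (!is.numeric(frame) || length(frame) != 2L || frame[1] >= frame[2]) {
    stop("`frame` must be c(t_start, t_end) with t_start < t_end.", call. = FALSE)
  }
  trt <- dplyr::filter(series, .data$treatment == .env$treatment)
  if (nrow(trt) == 0L) {
    stop(sprintf("Treatment '%s' not present in series.", treatment), call. = FALSE)
  }
  if (is.null(analytes)) analytes <- sort(unique(trt$analyte))
  missing_an <- setdiff(analytes, unique(trt$analyte))
  if (length(missing_an) > 0L) {
    stop(sprintf("Analyte(s) absent for treatment '%s': %s.", treatment,
                 paste(missing_an, collapse = ", ")), call. = FALSE)
  }

  # concentration of one replicate series at an arbitrary day
  value_at <- function(days, conc, t) {
    hit <- which(abs(days - t) < 1e-8)
    if (length(hit) > 0L) return(list(value = conc[hit[1]], interpolated = FALSE))
    if (!interpolate || t < min(days) || t > max(days)) {
      stop(sprintf("Day %g not sampled and not bracketed for interpolation (sampled: %s).",
                   t, paste(sort(unique(days)), collapse = ", ")), call. = FALSE)
    }
    list(value = stats::approx(days, conc, xout = t, ties = "ordered")$y,
         interpolated = TRUE)
  }

  interpolated_any <- FALSE
  out <- purrr::map_dfr(analytes, function(an) {
    sub <- dplyr::filter(trt, .data$analyte == .env$an)
    per_rep <- sub |>
      dplyr::group_by(.data$replicate) |>
      dplyr::arrange(.data$day, .by_group = TRUE) |>
      dplyr::summarise(
        start = list(value_at(.data$day, .data$concentration_uM, frame[1])),
        end = list(value_at(.data$day, .data$concentration_uM, frame[2])),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        c_start = purrr::map_dbl(.data$start, "value"),
        c_end = purrr::map_dbl(.data$end, "value"),
        interp = purrr::map_lgl(.data$start, "interpolated") |
          purrr::map_lgl(.data$end, "interpolated")
      )
    if (any(per_rep$interp)) interpolated_any <<- TRUE
    n <- nrow(per_rep)
    if (replicate_policy == "mean_first") {
      se_mean <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
      delta <- mean(per_rep$c_end) - mean(per_rep$c_start)
      se <- sqrt(se_mean(per_rep$c_end)^2 + se_mean(per_rep$c_start)^2)
    } else {
      d <- per_rep$c_end - per_rep$c_start
      delta <- mean(d)
      se <- if (n > 1L) stats::sd(d) / sqrt(n) else 0
    }
    tibble::tibble(treatment = treatment, t_start = frame[1], t_end = frame[2],
                   analyte = an, delta_uM = delta, se = se)
  })
  if (interpolated_any) {
    warning(sprintf("Frame [%g, %g]: boundary not sampled; linearly interpolated.",
                    frame[1], frame[2]), call. = FALSE)
  }
  out
}

#' Subtract a matched unsupplemented control from a treatment
#'
#' Net turnover attributable to the supplement: the control's concentration
#' change over the same frame is subtracted from the treatment's, analyte by
#' analyte; standard errors combine in quadrature. Controls must share the
#' treatment's methanogenesis-inhibitor (BES) status — a mismatch is an error,
#' because BES changes which products accumulate and an inhibited control
#' cannot stand in for an uninhibited one.
#'
#' @param treatment_delta,control_delta Tibbles from [frame_delta()] for the
#'   same frame and analyte set.
#' @param treatment_bes,control_bes Optional logical BES flags; when both are
#'   given they must match.
#' @return Tibble like [frame_delta()] output with `delta_uM` replaced by the
#'   control-subtracted net value, plus a `control` column.
#' @export
control_subtract <- function(treatment_delta, control_delta,
                             treatment_bes = NULL, control_bes = NULL) {
  if (!is.null(treatment_bes) && !is.null(control_bes) &&
      !identical(as.logical(treatment_bes), as.logical(control_bes))) {
    stop("BES mismatch: control must share the treatment's BES status.",
         call. = FALSE)
  }
  keys <- c("t_start", "t_end", "analyte")
  joined <- dplyr::inner_join(
    treatment_delta, control_delta,
    by = keys, suffix = c("", ".ctl")
  )
  if (nrow(joined) != nrow(treatment_delta) || nrow(joined) != nrow(control_delta)) {
    stop("Treatment and control deltas are not aligned on (frame, analyte).",
         call. = FALSE)
  }
  joined |>
    dplyr::transmute(
      treatment = .data$treatment,
      control = .data$treatment.ctl,
      t_start = .data$t_start, t_end = .data$t_end,
      analyte = .data$analyte,
      delta_uM = .data$delta_uM - .data$delta_uM.ctl,
      se = sqrt(.data$se^2 + .data$se.ctl^2)
    )
}

#' Convert net concentration turnover to carbon and reductant units
#'
#' Multiplies each compound's net concentration change by its carbon factor
#' (C atoms per molecule) and reductant factor (degree of reduction, electron
#' equivalents per molecule). The signs of `delta_uM`, `carbon_uM` and
#' `reductant_uM` agree compound-wise except where a factor is zero, in which
#' case that column is exactly zero.
#'
#' @param net Tibble with at least `analyte` and `delta_uM` columns (e.g. from
#'   [control_subtract()] or [frame_delta()]).
#' @param registry Compound registry tibble, see [compound_registry()].
#' @return Input tibble with `carbon_uM` and `reductant_uM` columns appended.
#' @export
to_carbon_reductant <- function(net, registry = compound_registry()) {
  rows <- registry_lookup(registry, unique(net$analyte), what = "analyte")
  net |>
    dplyr::left_join(
      dplyr::select(rows, analyte = "name", "carbon_factor", "reductant_factor"),
      by = "analyte"
    ) |>
    dplyr::mutate(
      carbon_uM = .data$delta_uM * .data$carbon_factor,
      reductant_uM = .data$delta_uM * .data$reductant_factor
    ) |>
    dplyr::select(-"carbon_factor", -"reductant_factor")
}

#' Net carbon and reductant turnover table
#'
#' The full accounting pipeline for one supplemented treatment: for each time
#' frame, endpoint concentrations are differenced ([frame_delta()]), the
#' matched unsupplemented control (same BES status, from `design`) is
#' subtracted ([control_subtract()]), and net concentration changes are
#' converted to carbon and electron-equivalent units
#' ([to_carbon_reductant()]). Analytes measured for the treatment but absent
#' in a frame enter as zero turnover.
#'
#' @inheritParams frame_delta
#' @param design Treatment design tibble with columns `treatment_id`,
#'   `supplement`, `amount_uM`, `bes`, `preincubation_days`, `control_id`.
#'   A control may map to itself.
#' @param frames List of `c(t_start, t_end)` frames, e.g.
#'   `list(c(0, 4), c(4, 10), c(0, 10))`.
#' @param registry Compound registry tibble.
#' @return A tibble of class `"net_turnover"` with columns `treatment`,
#'   `control`, `t_start`, `t_end`, `analyte`, `delta_uM`, `carbon_uM`,
#'   `reductant_uM`, `se`. Positive values are net production, negative net
#'   consumption.
#' @export
net_turnover <- function(series, design, treatment,
                         frames = list(c(0, 4), c(4, 10), c(0, 10)),
                         registry = compound_registry(),
                         replicate_policy = "mean_first",
                         interpolate = TRUE) {
  validate_design(design)
  drow <- design[design$treatment_id == treatment, , drop = FALSE]
  if (nrow(drow) != 1L) {
    stop(sprintf("Treatment '%s' not (uniquely) present in design.", treatment),
         call. = FALSE)
  }
  crow <- design[design$treatment_id == drow$control_id, , drop = FALSE]
  if (nrow(crow) != 1L) {
    stop(sprintf("Control '%s' for treatment '%s' missing from design.",
                 drow$control_id, treatment), call. = FALSE)
  }
  analytes <- sort(unique(series$analyte[series$treatment == treatment]))
  out <- purrr::map_dfr(frames, function(fr) {
    td <- frame_delta(series, treatment, fr, analytes = analytes,
                      replicate_policy = replicate_policy,
                      interpolate = interpolate)
    cd <- frame_delta(series, drow$control_id, fr, analytes = analytes,
                      replicate_policy = replicate_policy,
                      interpolate = interpolate)
    control_subtract(td, cd, treatment_bes = drow$bes, control_bes = crow$bes)
  })
  out <- to_carbon_reductant(out, registry)
  class(out) <- c("net_turnover", class(out))
  out
}

positive_part <- function(x) sum(x[x > 0])
negative_part <- function(x) sum(x[x < 0])

#' Recovery (mass-balance closure) ratio
#'
#' Per time frame, the carbon (or electron equivalents) recovered in net-
#' produced compounds as a percentage of the carbon (or electrons) released by
#' net-consumed compounds:
#' \deqn{R = 100 \; \Sigma(\mathrm{positive\ turnovers}) / |\Sigma(\mathrm{negative\ turnovers})|}
#' 100\% means a closed measured budget. Values above 100\% are reported
#' as-is with a flag (more product than substrate accounted for — a real
#' observation in peat incubations, not an error); a frame with no net
#' consumption has an undefined ratio, flagged rather than numeric.
#'
#' @param table A [net_turnover()] table.
#' @param basis `"carbon"`, `"reductant"`, or `"both"` (default).
#' @return Tibble with columns `t_start`, `t_end`, `basis`, `consumed`,
#'   `produced` (both in uM of the basis unit), `recovery_pct` (`NA` when
#'   undefined), `defined`, `exceeds_100`.
#' @export
recovery_ratio <- function(table, basis = c("both", "carbon", "reductant")) {
  basis <- match.arg(basis)
  bases <- if (basis == "both") c("carbon", "reductant") else basis
  purrr::map_dfr(bases, function(b) {
    col <- paste0(b, "_uM")
    table |>
      dplyr::group_by(.data$t_start, .data$t_end) |>
      dplyr::summarise(
        basis = b,
        consumed = abs(negative_part(.data[[col]])),
        produced = positive_part(.data[[col]]),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        defined = .data$consumed > 0,
        recovery_pct = ifelse(.data$defined, 100 * .data$produced / .data$consumed, NA_real_),
        exceeds_100 = .data$defined & .data$recovery_pct > 100
      )
  })
}

#' Share of each product in the recovered carbon or reductant
#'
#' Per time frame, the percentage that one net-produced compound contributes
#' to the summed positive turnover on the chosen basis. Net-consumed
#' compounds contribute zero to the numerator; a compound absent from the
#' table has a 0\% share.
#'
#' @inheritParams recovery_ratio
#' @param compound Compound name, or `NULL` for all compounds in the table.
#' @param basis `"carbon"` or `"reductant"`.
#' @return Tibble with columns `t_start`, `t_end`, `analyte`, `basis`,
#'   `fraction_pct` (`NA` with `defined = FALSE` when the frame has no
#'   production at all).
#' @export
product_fraction <- function(table, compound = NULL,
                             basis = c("carbon", "reductant")) {
  basis <- match.arg(basis)
  col <- paste0(basis, "_uM")
  totals <- table |>
    dplyr::group_by(.data$t_start, .data$t_end) |>
    dplyr::summarise(total_pos = positive_part(.data[[col]]), .groups = "drop")
  compounds <- if (is.null(compound)) sort(unique(table$analyte)) else compound
  grid <- tidyr::expand_grid(
    dplyr::distinct(table, .data$t_start, .data$t_end),
    analyte = compounds
  )
  grid |>
    dplyr::left_join(
      dplyr::select(table, "t_start", "t_end", "analyte", value = dplyr::all_of(col)),
      by = c("t_start", "t_end", "analyte")
    ) |>
    dplyr::left_join(totals, by = c("t_start", "t_end")) |>
    dplyr::mutate(
      basis = basis,
      defined = .data$total_pos > 0,
      fraction_pct = dplyr::case_when(
        !.data$defined ~ NA_real_,
        is.na(.data$value) | .data$value <= 0 ~ 0,
        TRUE ~ 100 * .data$value / .data$total_pos
      )
    ) |>
    dplyr::select("t_start", "t_end", "analyte", "basis", "fraction_pct", "defined")
}

validate_design <- function(design) {
  needed <- c("treatment_id", "bes", "control_id")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0L) {
    stop(sprintf("Design is missing column(s): %s.", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (i in seq_len(nrow(design))) {
    ctl <- design$control_id[i]
    j <- which(design$treatment_id == ctl)
    if (length(j) != 1L) {
      stop(sprintf("Control '%s' of treatment '%s' is not a design row.",
                   ctl, design$treatment_id[i]), call. = FALSE)
    }
    if (!identical(as.logical(design$bes[i]), as.logical(design$bes[j]))) {
      stop(sprintf("Treatment '%s' and its control '%s' differ in BES status.",
                   design$treatment_id[i], ctl), call. = FALSE)
    }
  }
  invisible(design)
}
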