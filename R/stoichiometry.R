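#' Parse a Hill-style molecular formula
#'
#' Parses a plain-text elemental formula such as `"C8H15NO6"` into named
#' integer atom counts. Only the elements C, H, N, O, S and P are recognised;
#' an omitted count means one atom. Parentheses, hydration dots, charges and
#' isotopes are not supported.
#'
#' @param text A single formula string, e.g. `"CH4"` or `"C2H4O2"`.
#' @return A named integer vector of atom counts (names are element symbols).
#' @examples
#' parse_formula("C8H15NO6")
#' parse_formula("CO2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("`text` must be a single non-empty formula string.", call. = FALSE)
  }
  known <- c("C", "H", "N", "O", "S", "P")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- unlist(regmatches(rest, regexpr("^([A-Z][a-z]?)([0-9]*)", rest)))
    if (length(m) == 0L || !nzchar(m)) {
      stop(sprintf("Malformed formula '%s': cannot parse at position %d ('%s').",
                   text, pos, substr(text, pos, pos)), call. = FALSE)
    }
    sym <- regmatches(m, regexpr("^[A-Z][a-z]?", m))
    if (!sym %in% known) {
      stop(sprintf("Unknown element '%s' in formula '%s' at position %d.",
                   sym, text, pos), call. = FALSE)
    }
    digits <- sub("^[A-Z][a-z]?", "", m)
    k <- if (nzchar(digits)) as.integer(digits) else 1L
    if (is.na(k) || k <= 0L) {
      stop(sprintf("Invalid atom count in formula '%s' at position %d.",
                   text, pos), call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(m)
  }
  if (length(counts) == 0L) {
    stop(sprintf("Formula '%s' contains no elements.", text), call. = FALSE)
  }
  counts
}

as_formula_counts <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (is.null(names(formula)) || any(!nzchar(names(formula)))) {
    stop("Formula atom counts must be a named vector.", call. = FALSE)
  }
  if (any(formula < 0)) stop("Atom counts must be non-negative.", call. = FALSE)
  formula
}

#' Generalised degree of reduction of a molecular formula
#'
#' Electron equivalents liberated per molecule on full oxidation to the
#' CO2 / H2O / NH3 reference state:
#' \deqn{\gamma = 4 n_C + 1 n_H - 2 n_O - 3 n_N}
#' Only C, H, N and O are admissible; a negative result (an oxidant relative
#' to the reference) is returned with a warning, never an error.
#'
#' @param formula A formula string or a named atom-count vector as returned
#'   by [parse_formula()].
#' @return Integer electron equivalents per molecule (may be zero or negative).
#' @examples
#' degree_of_reduction("C8H15NO6") # N-acetylglucosamine: 32
#' degree_of_reduction("CO2")      # 0
#' @export
degree_of_reduction <- function(formula) {
  counts <- as_formula_counts(formula)
  allowed <- c(C = 4, H = 1, O = -2, N = -3)
  bad <- setdiff(names(counts), names(allowed))
  if (length(bad) > 0L) {
    stop(sprintf("Degree of reduction is only defined for C, H, N, O; found: %s.",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  gamma <- sum(allowed[names(counts)] * counts)
  if (gamma < 0) {
    warning(sprintf("Negative degree of reduction (%d): compound is an oxidant relative to the CO2/H2O/NH3 reference.",
                    gamma), call. = FALSE)
  }
  as.integer(gamma)
}

#' Carbon and reductant conversion factors of a compound
#'
#' The pair (carbon atoms per molecule, electron equivalents per molecule)
#' used to convert a net concentration change into carbon and reductant
#' turnover. Both are recomputed from the molecular formula, never free text.
#'
#' @inheritParams degree_of_reduction
#' @return A one-row tibble with columns `carbon_factor` and `reductant_factor`.
#' @examples
#' carbon_reductant_factors("C2H4O2") # acetate (as acetic acid): 2 / 8
#' @export
carbon_reductant_factors <- function(formula) {
  counts <- as_formula_counts(formula)
  tibble::tibble(
    carbon_factor = as.integer(if ("C" %in% names(counts)) counts[["C"]] else 0L),
    reductant_factor = degree_of_reduction(counts)
  )
}

#' Compound registry
#'
#' Reads a compound registry (name, molecular formula, phase) and derives the
#' carbon and reductant factors of every entry. With no path, the registry
#' shipped with the package is used; it covers the compounds tracked in
#' anoxic peat slurry incubations (N-acetylglucosamine, glucose, the volatile
#' fatty acids, ethanol, methanol, CO2, CH4, H2, H2O, NH3).
#'
#' @param path Optional path to a YAML registry mapping compound name to
#'   `{formula: <string>, phase: dissolved|gaseous}`.
#' @return A tibble with columns `name`, `formula`, `phase`, `carbon_factor`,
#'   `reductant_factor`.
#' @examples
#' compound_registry()
#' @export
compound_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "compounds.yml", package = "anoxbal", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) stop("Compound registry is empty.", call. = FALSE)
  purrr::imap_dfr(raw, function(entry, nm) {
    if (is.null(entry$formula)) {
      stop(sprintf("Registry entry '%s' has no formula.", nm), call. = FALSE)
    }
    phase <- entry$phase %||% "dissolved"
    if (!phase %in% c("dissolved", "gaseous")) {
      stop(sprintf("Registry entry '%s': phase must be 'dissolved' or 'gaseous'.", nm),
           call. = FALSE)
    }
    fac <- carbon_reductant_factors(entry$formula)
    tibble::tibble(name = nm, formula = entry$formula, phase = phase,
                   carbon_factor = fac$carbon_factor,
                   reductant_factor = fac$reductant_factor)
  })
}

registry_lookup <- function(registry, names_needed, what = "compound") {
  missing <- setdiff(names_needed, registry$name)
  if (length(missing) > 0L) {
    stop(sprintf("Unregistered %s(s): %s.", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  registry[match(names_needed, registry$name), , drop = FALSE]
}

#' Define a reaction
#'
#' A reaction is a named, signed stoichiometry over registered compounds:
#' negative coefficients are consumed, positive produced. Coefficients may be
#' non-integer (rational stoichiometries are common in anaerobic food-chain
#' bookkeeping); atom counts inside formulas stay integral.
#'
#' @param name Reaction identifier.
#' @param stoichiometry Named numeric vector of signed coefficients
#'   (names are compound names; negative = consumed, positive = produced).
#' @return A list of class `"anox_reaction"`.
#' @examples
#' reaction("formate methanogenesis",
#'          c(formate = -4, CH4 = 1, CO2 = 3, H2O = 2))
#' @export
reaction <- function(name, stoichiometry) {
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop("`stoichiometry` must be a named numeric vector.", call. = FALSE)
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop("Duplicate compound in reaction stoichiometry.", call. = FALSE)
  }
  if (!any(stoichiometry < 0) || !any(stoichiometry > 0)) {
    stop("A reaction needs at least one consumed (negative) and one produced (positive) compound.",
         call. = FALSE)
  }
  structure(list(name = name, stoichiometry = stoichiometry),
            class = "anox_reaction")
}

#' Check elemental and electron balance of a reaction
#'
#' For each element the residual is the coefficient-weighted sum of atom
#' counts over the reaction; the electron residual weights each compound by
#' its degree of reduction. A reaction is balanced iff every residual is zero
#' (to floating tolerance). Balance is always reported explicitly — an
#' unbalanced reaction yields `balanced = FALSE`, never a silent pass.
#'
#' @param rx An [reaction()] object, or a named numeric stoichiometry vector.
#' @param registry Compound registry tibble, see [compound_registry()].
#' @param tol Absolute residual tolerance.
#' @return A tibble with one row per quantity (`C`, `H`, `N`, `O`, `S`, `P`
#'   as present, plus `electrons`), columns `quantity`, `residual`,
#'   `balanced` (the same overall verdict on every row).
#' @examples
#' rx <- reaction("aceticlastic methanogenesis",
#'                c(acetate = -1, CH4 = 1, CO2 = 1))
#' check_reaction_balance(rx)
#' @export
check_reaction_balance <- function(rx, registry = compound_registry(),
                                   tol = 1e-9) {
  stoich <- if (inherits(rx, "anox_reaction")) rx$stoichiometry else rx
  if (length(stoich) == 0L) stop("Empty reaction.", call. = FALSE)
  rows <- registry_lookup(registry, names(stoich))
  counts <- purrr::map(rows$formula, parse_formula)
  elements <- sort(unique(unlist(purrr::map(counts, names))))
  elem_res <- purrr::map_dbl(elements, function(el) {
    sum(stoich * purrr::map_dbl(counts, ~ if (el %in% names(.x)) .x[[el]] else 0))
  })
  e_res <- sum(stoich * rows$reductant_factor)
  res <- c(elem_res, e_res)
  tibble::tibble(
    quantity = c(elements, "electrons"),
    residual = res,
    balanced = all(abs(res) <= tol)
  )
}

#' @rdname check_reaction_balance
#' @return `reaction_balanced()`: a single logical.
#' @export
reaction_balanced <- function(rx, registry = compound_registry(), tol = 1e-9) {
  all(check_reaction_balance(rx, registry, tol)$balanced)
}
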