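# Mass arithmetic for metabolite annotation: monoisotopic masses from
# molecular formulas, positive-mode adduct m/z, signed ppm errors, and
# tolerance matching against a local compound table. Atomic masses are
# most-abundant-isotope values (CODATA/IUPAC); adduct deltas subtract one
# electron mass per positive charge.

.atomic_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322
)

.electron_mass <- 5.48579909070e-4

#' Parse a molecular formula into element counts
#'
#' @param formula character scalar like `"C9H13N5O3"`; an empty string parses
#'   to an empty count vector.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  formula <- trimws(formula)
  if (formula == "") return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(el, names(.atomic_masses))
  if (length(unknown)) {
    stop("unknown element(s) in formula ", formula, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(cnt, factor(el, levels = unique(el)), sum)
  stats::setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses.
#'
#' @param formula character molecular formula; `""` yields 0.
#' @return Mass in Da (full precision; display rounding is the caller's
#'   concern).
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (!length(counts)) return(0)
  sum(.atomic_masses[names(counts)] * as.numeric(counts))
}

#' Positive-mode adduct registry
#'
#' Mass deltas are derived from the atomic masses, minus one electron mass
#' per positive charge (the charge carrier is ionised, so the electron mass
#' matters at ppm accuracy).
#'
#' @return data.frame with `name`, `mass_delta` (Da) and `charge`.
#' @export
adduct_registry <- function() {
  am <- .atomic_masses
  deltas <- c(
    "[M+H]+"      = am[["H"]] - .electron_mass,
    "[M+Na]+"     = am[["Na"]] - .electron_mass,
    "[M+K]+"      = am[["K"]] - .electron_mass,
    "[M+NH4]+"    = am[["N"]] + 4 * am[["H"]] - .electron_mass,
    "[M+H-2H2O]+" = am[["H"]] - 2 * (2 * am[["H"]] + am[["O"]]) -
      .electron_mass
  )
  data.frame(name = names(deltas), mass_delta = unname(deltas), charge = 1L,
             stringsAsFactors = FALSE)
}

#' Theoretical m/z of an adduct of a neutral molecule
#'
#' @param neutral_mass monoisotopic neutral mass in Da, > 0.
#' @param adduct adduct name (see [adduct_registry()]) or one row of the
#'   registry.
#' @return Theoretical m/z in Da at full precision; round to 4 decimals for
#'   display.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(is.numeric(neutral_mass), neutral_mass > 0)
  if (is.character(adduct)) {
    reg <- adduct_registry()
    i <- match(adduct, reg$name)
    if (is.na(i)) stop("unknown adduct: ", adduct, call. = FALSE)
    adduct <- reg[i, ]
  }
  neutral_mass + adduct$mass_delta
}

#' Signed parts-per-million mass error
#'
#' `(measured - theoretical) / theoretical * 1e6`; positive when the measured
#' mass is high. Values are full precision; [ppm_display()] applies the
#' report convention of truncation toward zero at two decimals.
#'
#' @param measured,theoretical masses in Da; `theoretical` must be > 0.
#' @return Signed ppm error.
#' @export
ppm_error <- function(measured, theoretical) {
  stopifnot(all(theoretical > 0))
  (measured - theoretical) / theoretical * 1e6
}

#' @rdname ppm_error
#' @param ppm numeric ppm value(s).
#' @export
ppm_display <- function(ppm) {
  trunc(ppm * 100) / 100
}

#' Match a measured m/z against a compound table
#'
#' Computes the theoretical m/z of every (compound, adduct) pair and returns
#' those within the ppm tolerance, sorted by absolute ppm error. Following the
#' report convention for annotation tables, the ppm error is computed against
#' the theoretical mass at its 4-decimal display precision. Pairs whose
#' theoretical m/z is non-positive (e.g. a water-loss adduct of a molecule
#' lighter than the loss) are physically impossible and skipped. An empty
#' result is a valid outcome.
#'
#' @param query_mz measured m/z in Da.
#' @param compound_table data.frame with columns `name` and `formula`.
#' @param adducts adduct names to consider (default: the full registry).
#' @param tolerance_ppm acceptance threshold on `abs(ppm_error)`, > 0;
#'   default 2.
#' @return data.frame of matches: `name`, `formula`, `adduct`,
#'   `theoretical_mz`, `ppm_error` (full precision), `ppm_display`.
#' @export
match_candidates <- function(query_mz, compound_table,
                             adducts = adduct_registry()$name,
                             tolerance_ppm = 2) {
  stopifnot(is.numeric(query_mz), length(query_mz) == 1, tolerance_ppm > 0)
  compound_table <- as.data.frame(compound_table)
  if (!all(c("name", "formula") %in% names(compound_table))) {
    stop("`compound_table` must have columns `name` and `formula`",
         call. = FALSE)
  }
  reg <- adduct_registry()
  bad <- setdiff(adducts, reg$name)
  if (length(bad)) stop("unknown adduct(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(compound_table))) {
    f <- compound_table$formula[i]
    if (is.na(f) || !nzchar(trimws(f))) {
      stop("malformed compound table row ", i, ": empty formula",
           call. = FALSE)
    }
    M <- tryCatch(monoisotopic_mass(f), error = function(e) {
      stop("malformed compound table row ", i, " (", compound_table$name[i],
           "): ", conditionMessage(e), call. = FALSE)
    })
    for (a in adducts) {
      if (M <= 0) next
      th <- round(adduct_mz(M, a), 4)
      if (th <= 0) next
      pe <- ppm_error(query_mz, th)
      if (abs(pe) < tolerance_ppm) {
        out[[length(out) + 1L]] <- data.frame(
          name = compound_table$name[i], formula = f, adduct = a,
          theoretical_mz = th, ppm_error = pe, ppm_display = ppm_display(pe),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), ppm_display = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(abs(res$ppm_error)), , drop = FALSE]
}

#' Bundled compound table of annotated marker candidates
#'
#' Small local table of weight-gain marker candidate metabolites (name,
#' molecular formula, reported adduct and measured exact mass) used by the
#' annotation examples and tests; no network lookup is ever performed.
#'
#' Two entries (PGB2 and argininosuccinate) carry reported theoretical masses
#' that differ by a few ppm from plain monoisotopic arithmetic on their usual
#' formulas; their `reported_theoretical_mz` column preserves the reported
#' values for ppm bookkeeping.
#'
#' @return data.frame with columns `name`, `formula`, `adduct`,
#'   `measured_mz`, `reported_theoretical_mz`, `mass_derivable`.
#' @export
marker_compounds <- function() {
  path <- system.file("extdata", "marker_compounds.csv",
                      package = "maldimarkers", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
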