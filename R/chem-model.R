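#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Monoisotopic atomic masses (Da). Only the elements that occur in
# triterpene glycosides and their sodium sulfate salts are supported.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  Na = 22.98976928
)

# Charge-carrier conventions. The electron mass is ignored throughout
# (its effect is far below the matching tolerances used here); the one
# exception is the bisulfate diagnostic anion, pinned at its observed m/z.
.PROTON  <- 1.007276
.NA_ION  <- 22.989770
.H_ATOM  <- 1.0078250319

#' Common neutral-loss and building-block masses
#'
#' Named monoisotopic (and, where integer bookkeeping is wanted, nominal)
#' masses used in glycoside fragment arithmetic: water, carbon dioxide,
#' acetic acid, the combined acetic acid + CO2 loss seen for acetoxylated
#' 18(20)-lactone aglycons, the SO3 sulfonation increment, bisulfate, the
#' C5H10 side-chain fragment, and the C2H2O2 0,2-type cross-ring increment.
#'
#' @param mode `"mono"` for monoisotopic masses or `"nominal"` for the
#'   integer masses conventionally quoted in fragment ladders.
#' @return Named numeric vector.
#' @examples
#' mass_constants("nominal")[["AcOH_CO2"]]  # 104
#' @export
mass_constants <- function(mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  if (mode == "mono") {
    c(
      H2O     = formula_mass("H2O"),
      CO2     = formula_mass("CO2"),
      AcOH    = formula_mass("C2H4O2"),
      AcOH_CO2 = formula_mass("C2H4O2") + formula_mass("CO2"),
      SO3     = formula_mass("SO3"),
      HSO4    = formula_mass("HSO4"),
      C5H10   = formula_mass("C5H10"),
      C2H2O2  = formula_mass("C2H2O2"),
      proton  = .PROTON,
      Na      = .NA_ION,
      H       = .H_ATOM,
      HSO4_anion = 96.9601
    )
  } else {
    c(
      H2O = 18, CO2 = 44, AcOH = 60, AcOH_CO2 = 104, SO3 = 80,
      HSO4 = 97, C5H10 = 70, C2H2O2 = 58,
      proton = 1, Na = 23, H = 1, HSO4_anion = 96.9601
    )
  }
}

#' Parse an elemental formula string
#'
#' Accepts plain Hill-style strings over the supported element set
#' {C, H, N, O, S, Na}, e.g. `"C7H12O5"` or `"HSO4"`.
#'
#' @param formula Formula string, or a named numeric vector of element counts.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    if (is.null(names(counts)) && length(counts) > 0) {
      abort("A numeric formula must be a named vector of element counts.")
    }
  } else {
    stopifnot(is.character(formula), length(formula) == 1)
    if (formula == "") {
      counts <- stats::setNames(numeric(0), character(0))
    } else {
      m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
      toks <- regmatches(formula, list(m))[[1]]
      if (sum(nchar(toks)) != nchar(formula)) {
        abort(sprintf("Cannot parse formula '%s'.", formula))
      }
      sym <- sub("[0-9]*$", "", toks)
      n <- sub("^[A-Z][a-z]?", "", toks)
      n <- ifelse(n == "", 1L, suppressWarnings(as.integer(n)))
      counts <- tapply(n, sym, sum)
      counts <- stats::setNames(as.numeric(counts), names(counts))
    }
  }
  bad <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown element symbol(s): %s (supported: %s).",
      paste(bad, collapse = ", "), paste(names(.ATOMIC_MASS), collapse = ", ")
    ))
  }
  if (any(counts < 0)) abort("Element counts must be non-negative.")
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Formula string (see [parse_formula()]) or named count vector.
#' @return Monoisotopic mass in Da; the empty formula has mass 0.
#' @examples
#' formula_mass("C7H12O5")  # 3-O-methylglucose residue, 176.0685
#' formula_mass("CO2")      # 43.9898
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0) return(0)
  sum(counts * .ATOMIC_MASS[names(counts)])
}

#' Monosaccharide residue table
#'
#' The five monosaccharides of sea cucumber glycoside oligosaccharide
#' chains, as dehydrated residues (the increment lost at a glycosidic
#' cleavage): xylose, quinovose, glucose, 3-O-methylglucose and
#' 3-O-methylxylose. Quinovose and 3-O-methylxylose are isobaric
#' (C6H10O4, 146 Da nominal) and cannot be told apart by mass.
#'
#' @return A tibble with columns `code`, `formula`, `mass` (monoisotopic
#'   residue mass, Da), `nominal` (integer residue mass) and `methylated`.
#' @export
monosaccharides <- function() {
  tibble(
    code = c("Xyl", "Qui", "Glc", "MeGlc", "MeXyl"),
    formula = c("C5H8O4", "C6H10O4", "C6H10O5", "C7H12O5", "C6H10O4"),
    methylated = c(FALSE, FALSE, FALSE, TRUE, TRUE)
  ) |>
    mutate(
      mass = purrr::map_dbl(.data$formula, formula_mass),
      nominal = round(.data$mass)
    ) |>
    select("code", "formula", "mass", "nominal", "methylated")
}

.residue_mass <- function(code, mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  tab <- monosaccharides()
  i <- match(code, tab$code)
  if (anyNA(i)) {
    abort(sprintf(
      "Unknown monosaccharide code(s): %s (supported: %s).",
      paste(unique(code[is.na(i)]), collapse = ", "),
      paste(tab$code, collapse = ", ")
    ))
  }
  if (mode == "mono") tab$mass[i] else tab$nominal[i]
}

#' Nominal (integer) residue mass of a monosaccharide
#'
#' The integer neutral-loss masses conventionally quoted for glycosidic
#' cleavages: 176 (MeGlc), 162 (Glc), 146 (Qui or MeXyl), 132 (Xyl).
#'
#' @param code Monosaccharide code (`"Xyl"`, `"Qui"`, `"Glc"`, `"MeGlc"`,
#'   `"MeXyl"`); vectorised.
#' @return Integer residue mass in Da.
#' @examples
#' residue_nominal_mass(c("MeGlc", "Xyl"))  # 176 132
#' @export
residue_nominal_mass <- function(code) {
  as.integer(.residue_mass(code, "nominal"))
}

#' Precursor m/z of a glycoside in negative mode
#'
#' Non-sulfated glycosides ionise as `[M-H]-`; sulfated glycosides are
#' modelled as sodium salts (one Na per sulfate) and lose n sodium cations
#' to give `[M-nNa]n-`. Multiply-charged precursors are only available to
#' polysulfated structures: `n_charges` may not exceed the sulfate count
#' (with a minimum of one charge for any structure).
#'
#' @param g A `glycoside` object (see [glycoside()]).
#' @param n_charges Number of charges n; defaults to the sulfate count for
#'   polysulfated structures, else 1.
#' @param mode Mass mode, `"mono"` or `"nominal"`.
#' @return A one-row tibble with columns `mz`, `charge`, `adduct`,
#'   `neutral_mass` (of the neutral molecule: free acid if non-sulfated,
#'   sodium salt otherwise) and `n_sulfates`.
#' @export
precursor_mz <- function(g, n_charges = NULL, mode = c("mono", "nominal")) {
  mode <- match.arg(mode)
  g <- validate_glycoside(g)
  ns <- sum(g$glycan$sulfated)
  if (is.null(n_charges)) n_charges <- if (ns >= 2) ns else 1L
  n_charges <- as.integer(n_charges)
  if (n_charges < 1) {
    abort("`n_charges` must be at least 1.")
  }
  if (n_charges > max(1L, ns)) {
    abort(sprintf(
      "`n_charges` = %d exceeds the sulfate count (%d): a glycoside can carry at most one charge per sulfate (minimum one).",
      n_charges, ns
    ))
  }
  k <- mass_constants(mode)
  res <- .residue_mass(g$glycan$code, mode)
  agl <- aglycon_mass(g$aglycon, mode)
  if (ns == 0) {
    neutral <- agl + sum(res)
    mz <- neutral - k[["proton"]]
    adduct <- "[M-H]-"
  } else {
    # neutral sodium salt: each sulfate ester contributes SO3, and Na
    # replaces the sulfate proton
    neutral <- agl + sum(res) + ns * (k[["SO3"]] + k[["Na"]] - k[["H"]])
    mz <- (neutral - n_charges * k[["Na"]]) / n_charges
    adduct <- if (n_charges == 1) "[M-Na]-" else sprintf("[M-%dNa]%d-", n_charges, n_charges)
  }
  tibble(
    mz = mz, charge = n_charges, adduct = adduct,
    neutral_mass = neutral, n_sulfates = ns
  )
}

#' Parts-per-million mass error
#'
#' @param calc Calculated (theoretical) m/z, must be positive.
#' @param meas Measured m/z.
#' @return `(calc - meas) / calc * 1e6`, in ppm. Vectorised.
#' @examples
#' ppm_error(1281.5216, 1281.5135)  # 6.3 ppm
#' @export
ppm_error <- function(calc, meas) {
  if (any(!is.finite(calc)) || any(calc <= 0)) {
    abort("`calc` must be positive and finite.")
  }
  (calc - meas) / calc * 1e6
}
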