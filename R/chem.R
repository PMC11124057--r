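#' @importFrom rlang .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Gas constant, J/(mol K)
GAS_CONSTANT <- 8.31446

# Conventional atomic weights, g/mol
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Br = 79.904, I = 126.904
)

#' Compounds used in the DES solubility study
#'
#' Registry of the solutes (ibuprofen, ketoprofen and their analogs), the
#' hydrogen-bond acceptors (choline chloride, betaine), the polyol donors and
#' the auxiliary solvents, with molecular formulas. Molar masses are computed
#' from the formulas by [molar_mass()], not stored.
#'
#' @return A tibble with columns `compound_id`, `name`, `formula`, `role`
#'   (`solute`, `hba`, `hbd` or `solvent`) and `mw` (g/mol).
#' @export
#' @examples
#' compound_registry()
compound_registry <- function() {
  reg <- tibble::tribble(
    ~compound_id,          ~name,                  ~formula,     ~role,
    "IP",                  "ibuprofen",            "C13H18O2",   "solute",
    "KP",                  "ketoprofen",           "C16H14O3",   "solute",
    "FLU",                 "flurbiprofen",         "C15H13FO2",  "solute",
    "FEL",                 "felbinac",             "C14H12O2",   "solute",
    "PAA",                 "phenylacetic acid",    "C8H8O2",     "solute",
    "DPA",                 "diphenylacetic acid",  "C14H12O2",   "solute",
    "ChCl",                "choline chloride",     "C5H14ClNO",  "hba",
    "BI",                  "betaine",              "C5H11NO2",   "hba",
    "ETG",                 "ethylene glycol",      "C2H6O2",     "hbd",
    "DEG",                 "diethylene glycol",    "C4H10O3",    "hbd",
    "TEG",                 "triethylene glycol",   "C6H14O4",    "hbd",
    "GLY",                 "glycerol",             "C3H8O3",     "hbd",
    "P2D",                 "1,2-propanediol",      "C3H8O2",     "hbd",
    "B3D",                 "1,3-butanediol",       "C4H10O2",    "hbd",
    "water",               "water",                "H2O",        "solvent",
    "methanol",            "methanol",             "CH4O",       "solvent"
  )
  dplyr::mutate(reg, mw = molar_mass(.data$formula))
}

#' Molar mass from a molecular formula
#'
#' Parses a Hill-style formula (element symbols followed by optional counts,
#' e.g. `"C13H18O2"`) and sums conventional atomic weights.
#'
#' @param formula Character vector of molecular formulas.
#' @return Numeric vector of molar masses in g/mol.
#' @export
#' @examples
#' molar_mass("C13H18O2") # ibuprofen, 206.28 g/mol
molar_mass <- function(formula) {
  vapply(formula, function(f) {
    stopifnot(is.character(f), length(f) == 1L, nzchar(f))
    m <- gregexpr("([A-Z][a-z]?)(\\d*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(f)) {
      stop("cannot parse molecular formula: ", f, call. = FALSE)
    }
    total <- 0
    for (tok in toks) {
      sym <- sub("\\d+$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!sym %in% names(ATOMIC_MASSES)) {
        stop("unknown element '", sym, "' in formula ", f, call. = FALSE)
      }
      total <- total + ATOMIC_MASSES[[sym]] * n
    }
    total
  }, numeric(1), USE.NAMES = !is.null(names(formula)))
}

# Molar mass lookup by compound id; errors on unknown ids.
lookup_mw <- function(compound_id, registry = compound_registry()) {
  idx <- match(compound_id, registry$compound_id)
  if (anyNA(idx)) {
    stop("no molar mass registered for compound(s): ",
         paste(unique(compound_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  registry$mw[idx]
}
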