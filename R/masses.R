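## Monoisotopic chemistry tables. Every derived constant (residue masses,
## modification deltas, BS3 linker arithmetic) is computed from elemental
## monoisotopic masses so that no decimal is hard-coded twice.

# CODATA/IUPAC monoisotopic element masses (Da)
.element_masses <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

#' Monoisotopic mass of a molecular formula
#'
#' Parses a Hill-style formula restricted to C, H, N, O, S (e.g. `"C8H10O2"`)
#' and returns its monoisotopic mass in Daltons.
#'
#' @param formula Character scalar such as `"C8H10O2"`.
#' @return Numeric mass in Da.
#' @examples
#' formula_mass("H2O")
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([CHNOS])([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("malformed molecular formula: ", formula)
  }
  total <- 0
  for (tok in toks) {
    el <- substr(tok, 1, 1)
    n <- if (nchar(tok) > 1L) as.integer(substr(tok, 2, nchar(tok))) else 1L
    total <- total + .element_masses[[el]] * n
  }
  total
}

# residue (amino acid minus water) elemental formulas
.residue_formulas <- c(
  A = "C3H5NO",   R = "C6H12N4O",  N = "C4H6N2O2", D = "C4H5NO3",
  C = "C3H5NOS",  E = "C5H7NO3",   Q = "C5H8N2O2", G = "C2H3NO",
  H = "C6H7N3O",  I = "C6H11NO",   L = "C6H11NO",  K = "C6H12N2O",
  M = "C5H9NOS",  F = "C9H9NO",    P = "C5H7NO",   S = "C3H5NO2",
  T = "C4H7NO2",  W = "C11H10N2O", Y = "C9H9NO2",  V = "C5H9NO"
)

#' Monoisotopic residue masses
#'
#' Named vector of the 20 standard amino-acid residue masses (amino acid minus
#' water), derived from elemental formulas.
#'
#' @return Named numeric vector of length 20.
#' @export
residue_masses <- function() {
  vapply(.residue_formulas, formula_mass, numeric(1))
}

.residue_mass_tab <- vapply(.residue_formulas, formula_mass, numeric(1))

.mass_water  <- 1.00782503207 * 2 + 15.9949146196
.mass_proton <- 1.007276466879

# BS3 chemistry: bridge = linker minus both NHS leaving groups;
# dead-ends = one arm reacted, the other hydrolyzed (water) / aminolyzed (ammonia)
.mass_bs3_bridge       <- NULL # filled in .onLoad-free style below
.mass_bs3_bridge       <- formula_mass("C8H10O2")
.mass_bs3_deadend_h2o  <- formula_mass("C8H12O3")
.mass_bs3_deadend_nh2  <- formula_mass("C8H13NO2")
.mass_carbamidomethyl  <- formula_mass("C2H3NO")
.mass_oxidation        <- formula_mass("O")
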