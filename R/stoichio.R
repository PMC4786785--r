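# Preparative-reaction arithmetic: molar masses, catalyst loading,
# fold-excess and molar yields with contaminant correction.

# IUPAC standard atomic weights (conventional values).
ATOMIC_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998403, Na = 22.98977, P = 30.973762,
                    S = 32.06, Cl = 35.45, K = 39.0983, Br = 79.904,
                    I = 126.90447)

#' Parse a molecular formula
#'
#' @param formula Hill-style formula string, e.g. `"C10H11NO3"`.
#' @return Named integer vector element -> count.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula)) {
    stop("formula must be a non-empty string", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?\\d*", formula)[[1L]]
  tokens <- regmatches(formula, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  el <- sub("\\d+$", "", tokens)
  ct <- as.integer(sub("^[A-Za-z]+", "", tokens))
  ct[is.na(ct)] <- 1L
  if (any(ct <= 0L)) stop("element counts must be positive", call. = FALSE)
  tapply(ct, el, sum)[unique(el)]
}

#' Molar mass of a compound
#'
#' Sum of standard atomic weights over a molecular formula.
#'
#' @param formula Formula string or named count vector.
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) stop("empty formula", call. = FALSE)
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0L) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(ATOMIC_WEIGHTS[names(counts)] * as.numeric(counts))
}

#' Catalyst loading in mol%
#'
#' Monomer-based catalyst concentration over the limiting substrate:
#' 14.7 uM enzyme against 2 mM substrate is a 0.7 mol% loading (one
#' decimal, reporting convention).
#'
#' @param catalyst_uM Catalyst concentration (uM, monomer basis).
#' @param substrate_mM Limiting substrate concentration (mM).
#' @return mol% at full precision; round to one decimal for reporting.
#' @export
catalyst_molpercent <- function(catalyst_uM, substrate_mM) {
  stopifnot(substrate_mM > 0, catalyst_uM >= 0)
  100 * catalyst_uM / (substrate_mM * 1000)
}

#' Fold-excess of the donor over the acceptor
#'
#' @param donor_mM,acceptor_mM Concentrations in mM.
#' @return Dimensionless ratio (e.g. 50 mM over 2 mM = 25-fold).
#' @export
fold_excess <- function(donor_mM, acceptor_mM) {
  stopifnot(acceptor_mM > 0)
  donor_mM / acceptor_mM
}

#' Molar yield from an isolated mass
#'
#' Converts an isolated product mass to mmol and percent of the
#' theoretical amount set by the limiting substrate. An optional
#' contaminant weight fraction (e.g. 6% w/w unreacted nitroalkene
#' detected by NMR) is removed from the mass before conversion.
#'
#' @param mass_mg Isolated mass (mg).
#' @param formula Product molecular formula (string or counts).
#' @param substrate_mM Limiting substrate concentration (mM).
#' @param volume_ml Reaction volume (ml).
#' @param contaminant_w_fraction Weight fraction of contaminant in the
#'   isolated mass (0 = identity correction).
#' @return Tibble: `mass_mg`, `effective_mg`, `mmol`, `percent`,
#'   `theoretical_mmol`.
#' @export
isolated_yield <- function(mass_mg, formula, substrate_mM, volume_ml,
                           contaminant_w_fraction = 0) {
  stopifnot(mass_mg >= 0, contaminant_w_fraction >= 0,
            contaminant_w_fraction < 1)
  theoretical <- substrate_mM * volume_ml / 1000  # mmol
  if (theoretical <= 0) {
    stop("zero theoretical amount: check substrate and volume", call. = FALSE)
  }
  eff <- mass_mg * (1 - contaminant_w_fraction)
  mmol <- eff / molar_mass(formula)
  tibble::tibble(mass_mg = mass_mg, effective_mg = eff, mmol = mmol,
                 percent = 100 * mmol / theoretical,
                 theoretical_mmol = theoretical)
}

#' Packaged compound table
#'
#' Product identities and molecular formulas of the gamma-nitroaldehyde
#' products (formulas derived from the IUPAC names).
#'
#' @return Tibble: `id`, `formula`, `name`.
#' @export
compound_table <- function() {
  readr::read_csv(system.file("extdata", "compounds.csv",
                              package = "mutscape"),
                  show_col_types = FALSE)
}

#' Packaged preparative-reaction table
#'
#' Conditions and printed outcomes (isolated mass, mmol, percent yield)
#' of the semi-preparative syntheses, used as inputs for reproducing the
#' yield arithmetic. `printed_mmol_unit` / `printed_percent_unit` give
#' one unit in the last printed digit of each value.
#'
#' @return Tibble, one row per preparative reaction.
#' @export
prep_reactions <- function() {
  readr::read_csv(system.file("extdata", "prep_reactions.csv",
                              package = "mutscape"),
                  show_col_types = FALSE)
}

#' Recompute every preparative yield
#'
#' Applies [isolated_yield()] to each row of [prep_reactions()] and
#' returns computed and printed values side by side.
#'
#' @return Tibble with `mmol`, `percent` (computed) next to the printed
#'   columns.
#' @export
prep_scale_report <- function() {
  rx <- prep_reactions()
  cmp <- compound_table()
  rows <- lapply(seq_len(nrow(rx)), function(i) {
    f <- cmp$formula[cmp$id == rx$product[i]]
    y <- isolated_yield(rx$mass_mg[i], f, rx$substrate_mM[i],
                        rx$volume_ml[i], rx$contaminant_w_fraction[i])
    tibble::tibble(product = rx$product[i], catalyst = rx$catalyst[i],
                   pH = rx$pH[i], mass_mg = rx$mass_mg[i],
                   mmol = y$mmol, percent = y$percent,
                   printed_mmol = rx$printed_mmol[i],
                   printed_mmol_unit = rx$printed_mmol_unit[i],
                   printed_percent = rx$printed_percent[i])
  })
  dplyr::bind_rows(rows)
}
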