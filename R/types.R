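#' Define an iron(III) chelator
#'
#' A chelator is described by the stoichiometry of its highest complex
#' (`n_max` ligands per Fe3+), the cumulative (global) stability constants
#' \eqn{\beta_i} of Fe + i L = FeL_i as log10 values, optional ligand
#' protonation constants (as pKa), and the molar mass of the free ligand.
#'
#' The `log_beta` values refer to the fully deprotonated ligand; at
#' physiological pH most hydroxypyridinone-class ligands are largely
#' protonated, so conditional constants at a working pH are obtained with
#' [effective_betas()] via the standard side-reaction coefficient.
#'
#' @param name Chelator name.
#' @param n_max Integer, ligands per Fe3+ in the highest complex (>= 1).
#' @param log_beta Numeric vector of length `n_max`: log10 cumulative
#'   stability constants, `beta_i` in (L/mol)^i.
#' @param pka Optional numeric vector of ligand proton dissociation
#'   constants as pKa (\eqn{-\log_{10} K_a}), sorted ascending.
#' @param ligand_molar_mass Molar mass of the free ligand in g/mol.
#' @return An object of class `"chelator"`.
#' @examples
#' deferiprone()
#' chelator("EDTA-like", 1, 25.1, ligand_molar_mass = 292.2)
#' @export
chelator <- function(name, n_max, log_beta, pka = NULL, ligand_molar_mass) {
  if (!is.character(name) || length(name) != 1L)
    abort_validation("'name' must be a single string")
  check_number(n_max, "n_max", min = 1)
  n_max <- as.integer(n_max)
  if (!is.numeric(log_beta) || length(log_beta) != n_max || any(!is.finite(log_beta)))
    abort_validation("'log_beta' must be a finite numeric vector of length n_max = %d", n_max)
  if (!is.null(pka)) {
    if (!is.numeric(pka) || any(!is.finite(pka)))
      abort_validation("'pka' must be finite numeric")
    if (is.unsorted(pka, strictly = FALSE))
      abort_validation("'pka' must be sorted ascending")
  }
  check_number(ligand_molar_mass, "ligand_molar_mass", min = 0, strict = TRUE)
  structure(
    list(name = name, n_max = n_max, log_beta = as.numeric(log_beta),
         pka = pka, ligand_molar_mass = ligand_molar_mass),
    class = "chelator"
  )
}

#' @export
print.chelator <- function(x, ...) {
  cat(sprintf("<chelator> %s: FeL_%d, log beta = %s, M = %.1f g/mol\n",
              x$name, x$n_max, paste(format(x$log_beta), collapse = ", "),
              x$ligand_molar_mass))
  if (!is.null(x$pka))
    cat(sprintf("  ligand pKa: %s\n", paste(format(x$pka), collapse = ", ")))
  invisible(x)
}

#' Deferiprone (1,2-dimethyl-3-hydroxypyridin-4-one)
#'
#' Built-in definition of deferiprone, a bidentate hydroxypyridinone that
#' forms a 3:1 ligand:iron complex with log cumulative stability constants
#' 15.01, 27.30 and 37.43 for FeL, FeL2 and FeL3, ligand pKa 3.68 and 9.77,
#' and a ligand molar mass of 139.1 g/mol.
#'
#' @return A `"chelator"` object.
#' @export
deferiprone <- function() {
  chelator("deferiprone", 3L, c(15.01, 27.30, 37.43),
           pka = c(3.68, 9.77), ligand_molar_mass = 139.1)
}

#' Built-in chelator stoichiometry table
#'
#' Stoichiometries and ligand molar masses for the four chelators used in
#' iron-loaded form in erythroid culture work: deferiprone (3:1),
#' deferoxamine (1:1), deferasirox (2:1) and hinokitiol (3:1). Only
#' deferiprone ships with stability constants; for the others, `log_beta`
#' (and optionally `pka`) must be supplied to [get_chelator()].
#'
#' @return A data frame with columns `name`, `n_max`, `ligand_molar_mass`,
#'   `has_constants`.
#' @export
builtin_chelators <- function() {
  data.frame(
    name = c("deferiprone", "deferoxamine", "deferasirox", "hinokitiol"),
    n_max = c(3L, 1L, 2L, 3L),
    ligand_molar_mass = c(139.1, 560.7, 373.4, 164.2),
    has_constants = c(TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Look up a built-in chelator by name
#'
#' @param name One of `"deferiprone"`, `"deferoxamine"`, `"deferasirox"`,
#'   `"hinokitiol"`.
#' @param log_beta Cumulative stability constants (log10), required for all
#'   chelators except deferiprone.
#' @param pka Optional ligand pKa values.
#' @return A `"chelator"` object.
#' @export
get_chelator <- function(name, log_beta = NULL, pka = NULL) {
  tab <- builtin_chelators()
  i <- match(tolower(name), tab$name)
  if (is.na(i))
    abort_validation("unknown chelator '%s'; known: %s", name,
                     paste(tab$name, collapse = ", "))
  if (tab$name[i] == "deferiprone" && is.null(log_beta)) return(deferiprone())
  if (is.null(log_beta))
    abort_validation("no built-in stability constants for '%s'; supply 'log_beta'",
                     tab$name[i])
  chelator(tab$name[i], tab$n_max[i], log_beta, pka = pka,
           ligand_molar_mass = tab$ligand_molar_mass[i])
}

#' Transferrin binding parameters
#'
#' Human serum transferrin binds two Fe3+ ions sequentially. The defaults
#' are the conditional association constants at culture conditions
#' (pH 7.4, 3.5 mmol/L bicarbonate): K1 = 7.0e22 L/mol for the first and
#' K2 = 3.6e21 L/mol for the second ion. The two monoferric forms (N- vs
#' C-lobe) are lumped into a single pool since no lobe-specific constants
#' are used.
#'
#' Two molar-mass conventions are carried deliberately:
#' `molar_mass_equivalence` (76,900 g/mol) converts between ug/mL medium
#' recipes and mol/L (it is the value under which 1000 ug/mL corresponds
#' to 26 umol/L of chelated iron equivalents), while `molar_mass_budget`
#' (80,000 g/mol, the nominal ~80 kDa) is used for per-cell protein mass
#' budgets. The two differ by ~4%; keeping both reproduces the standard
#' worked numbers of each kind exactly.
#'
#' @param k1,k2 Conditional association constants, L/mol; `k1 > k2 > 0`.
#' @param molar_mass_equivalence g/mol, for concentration conversions.
#' @param molar_mass_budget g/mol, for protein mass budgets.
#' @return An object of class `"transferrin"` with fixed `iron_sites = 2`.
#' @export
transferrin <- function(k1 = 7.0e22, k2 = 3.6e21,
                        molar_mass_equivalence = 76900,
                        molar_mass_budget = 80000) {
  check_number(k1, "k1", min = 0, strict = TRUE)
  check_number(k2, "k2", min = 0, strict = TRUE)
  if (!(k1 > k2)) abort_validation("require k1 > k2 (sequential binding)")
  check_number(molar_mass_equivalence, "molar_mass_equivalence", min = 0, strict = TRUE)
  check_number(molar_mass_budget, "molar_mass_budget", min = 0, strict = TRUE)
  structure(
    list(k1 = k1, k2 = k2,
         molar_mass_equivalence = molar_mass_equivalence,
         molar_mass_budget = molar_mass_budget,
         iron_sites = 2L),
    class = "transferrin"
  )
}

#' @export
print.transferrin <- function(x, ...) {
  cat(sprintf("<transferrin> K1 = %.3g, K2 = %.3g L/mol; M(equivalence) = %g, M(budget) = %g g/mol\n",
              x$k1, x$k2, x$molar_mass_equivalence, x$molar_mass_budget))
  invisible(x)
}

#' Medium composition (total pools)
#'
#' Total analytical pools of the three components whose speciation is
#' solved: transferrin protein, iron (bound + free) and chelator ligand
#' monomer, plus the recorded pH and bicarbonate condition at which the
#' conditional constants are taken to be valid.
#'
#' @param tf_total Transferrin protein, mol/L.
#' @param fe_total Total iron, mol/L.
#' @param ligand_total Chelator ligand monomer, mol/L.
#' @param ph Medium pH, in (0, 14).
#' @param bicarbonate Bicarbonate, mol/L (recorded condition only).
#' @return An object of class `"medium"`.
#' @seealso [medium_from_recipe()] for ug/mL / umol/L recipe units.
#' @export
medium <- function(tf_total = 0, fe_total = 0, ligand_total = 0,
                   ph = 7.4, bicarbonate = 3.5e-3) {
  check_number(tf_total, "tf_total", min = 0)
  check_number(fe_total, "fe_total", min = 0)
  check_number(ligand_total, "ligand_total", min = 0)
  check_number(ph, "ph", min = 0, max = 14, strict = TRUE)
  check_number(bicarbonate, "bicarbonate", min = 0)
  structure(
    list(tf_total = tf_total, fe_total = fe_total, ligand_total = ligand_total,
         ph = ph, bicarbonate = bicarbonate),
    class = "medium"
  )
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> Tf %.4g umol/L, Fe %.4g umol/L, ligand %.4g umol/L, pH %.2f, HCO3- %.2f mmol/L\n",
              x$tf_total * 1e6, x$fe_total * 1e6, x$ligand_total * 1e6,
              x$ph, x$bicarbonate * 1e3))
  invisible(x)
}
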