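# Stoichiometric iron-budget and chelator-dosimetry calculators. All
# calculators are linear in their leading argument and return full
# precision; display rounding is left to the caller.

#' Stoichiometry constants for erythroid iron budgets
#'
#' Defaults: 3e8 hemoglobin tetramers per red cell (about 30 pg), 4 heme
#' irons per tetramer, 2e12 cells per transfusion unit, 62 kg reference
#' adult. `cell_volume` defaults to 2e-13 L (200 fL): the femtolitre scale
#' is the physically consistent one for a reticulocyte and is the value
#' under which the residual-chelator dose per kg comes out at the
#' conventional 0.14 mg/kg ("200 pL" sometimes seen in print is a
#' unit slip three orders of magnitude too large).
#'
#' @param hb_per_cell Hemoglobin tetramers per cell.
#' @param fe_per_hb Iron ions per hemoglobin tetramer.
#' @param hb_mass_per_cell Hemoglobin mass per cell, pg.
#' @param cells_per_unit Cells in one transfusion unit.
#' @param cell_volume Cell volume, L.
#' @param body_mass Reference body mass, kg.
#' @param avogadro Avogadro constant, 1/mol.
#' @return An object of class `"stoichiometry_constants"`.
#' @export
stoichiometry_constants <- function(hb_per_cell = 3e8, fe_per_hb = 4,
                                    hb_mass_per_cell = 30,
                                    cells_per_unit = 2e12,
                                    cell_volume = 2e-13,
                                    body_mass = 62,
                                    avogadro = 6.02214076e23) {
  for (nm in c("hb_per_cell", "fe_per_hb", "hb_mass_per_cell",
               "cells_per_unit", "cell_volume", "body_mass", "avogadro"))
    check_number(get(nm), nm, min = 0)
  if (body_mass <= 0 || avogadro <= 0 || cell_volume <= 0 || fe_per_hb <= 0)
    abort_validation("body_mass, avogadro, cell_volume and fe_per_hb must be > 0")
  structure(list(hb_per_cell = hb_per_cell, fe_per_hb = fe_per_hb,
                 hb_mass_per_cell = hb_mass_per_cell,
                 cells_per_unit = cells_per_unit, cell_volume = cell_volume,
                 body_mass = body_mass, avogadro = avogadro),
            class = "stoichiometry_constants")
}

#' Iron ions per fully hemoglobinized cell
#'
#' `hb_per_cell * fe_per_hb`; with defaults, 1.2e9 Fe3+ ions.
#'
#' @param consts [stoichiometry_constants()].
#' @return Count of iron ions.
#' @export
fe_ions_per_cell <- function(consts = stoichiometry_constants()) {
  consts$hb_per_cell * consts$fe_per_hb
}

#' Transferrin mass that must be internalized per cell
#'
#' Each transferrin delivers two iron ions, so a cell needs
#' `fe_ions_per_cell / 2` transferrin passages; at the budget molar mass
#' (80 kDa by default) this is about 80 pg per cell.
#'
#' @param consts [stoichiometry_constants()].
#' @param tf [transferrin()] (uses `molar_mass_budget`).
#' @return Mass in pg.
#' @export
tf_demand_per_cell <- function(consts = stoichiometry_constants(),
                               tf = transferrin()) {
  mol <- fe_ions_per_cell(consts) / tf$iron_sites / consts$avogadro
  mol * tf$molar_mass_budget * 1e12
}

#' Transferrin demand per transfusion unit
#'
#' Per-cell demand times cells per unit; about 160 g with defaults.
#'
#' @inheritParams tf_demand_per_cell
#' @return Mass in g.
#' @export
tf_demand_per_unit <- function(consts = stoichiometry_constants(),
                               tf = transferrin()) {
  tf_demand_per_cell(consts, tf) * 1e-12 * consts$cells_per_unit
}

#' Chelated-iron equivalent of a holotransferrin concentration
#'
#' Iron carried by holotransferrin at a given protein mass concentration:
#' two ions per molecule at the equivalence molar mass (76,900 g/mol), so
#' 1000 ug/mL corresponds to 26 umol/L of iron.
#'
#' @param tf_conc Holotransferrin, ug/mL.
#' @param tf [transferrin()] (uses `molar_mass_equivalence`).
#' @return Iron equivalent, umol/L.
#' @export
chelated_fe_equivalent <- function(tf_conc, tf = transferrin()) {
  if (any(tf_conc < 0)) abort_validation("'tf_conc' must be >= 0")
  tf$iron_sites * (tf_conc * 1e-3 / tf$molar_mass_equivalence) * 1e6
}

#' Holotransferrin equivalent of an iron-chelator complex concentration
#'
#' Inverse of [chelated_fe_equivalent()], one iron per complex:
#' 52 umol/L of complex matches the iron content of 2000 ug/mL hTf.
#'
#' @param complex_conc Iron-loaded complex, umol/L.
#' @param tf [transferrin()].
#' @return Holotransferrin, ug/mL.
#' @export
htf_equivalent_of_complex <- function(complex_conc, tf = transferrin()) {
  if (any(complex_conc < 0)) abort_validation("'complex_conc' must be >= 0")
  (complex_conc / tf$iron_sites) * 1e-6 * tf$molar_mass_equivalence * 1e3
}

#' Free-ligand mass concentration behind an iron-complex dose
#'
#' Mass of chelator ligand (iron excluded) in a medium containing the
#' given complex concentration: `complex * n_max * ligand_molar_mass`.
#' For 52 umol/L of the 3:1 deferiprone complex this is 21.7 mg/L.
#'
#' @param complex_conc Complex concentration, umol/L.
#' @param chelator [chelator()].
#' @return Ligand mass concentration, mg/L.
#' @export
ligand_mass_concentration <- function(complex_conc, chelator = deferiprone()) {
  if (any(complex_conc < 0)) abort_validation("'complex_conc' must be >= 0")
  complex_conc * 1e-6 * chelator$n_max * chelator$ligand_molar_mass * 1e3
}

#' Residual chelator dose per kg from a transfused unit
#'
#' Assuming the chelator distributes equally between medium and cell
#' water, the chelator carried by one transfusion unit is
#' `medium_conc * cells_per_unit * cell_volume`; divided by body mass this
#' is about 0.14 mg/kg for deferiprone differentiation medium (21.7 mg/L).
#'
#' @param consts [stoichiometry_constants()].
#' @param chelator [chelator()] (for the record; the dose is mass-based).
#' @param medium_ligand_conc Ligand in the medium, mg/L.
#' @return Dose in mg per kg body mass.
#' @export
residual_dose_per_kg <- function(consts = stoichiometry_constants(),
                                 chelator = deferiprone(),
                                 medium_ligand_conc) {
  if (any(medium_ligand_conc < 0)) abort_validation("'medium_ligand_conc' must be >= 0")
  medium_ligand_conc * consts$cells_per_unit * consts$cell_volume / consts$body_mass
}

#' Component amounts for an iron-loaded chelator stock
#'
#' Ligand and iron(III) chloride amounts for a stock with the requested
#' chelated-iron concentration, mixed at the chelator's n:1 stoichiometric
#' ratio.
#'
#' @param chelator [chelator()].
#' @param target_fe_conc Chelated Fe3+ in the stock, mmol/L.
#' @return List with `fe_mmol_per_l`, `ligand_mmol_per_l`,
#'   `ligand_g_per_l`, `fecl3_g_per_l` (anhydrous FeCl3, 162.2 g/mol).
#' @export
stock_preparation <- function(chelator, target_fe_conc) {
  if (!inherits(chelator, "chelator")) abort_validation("'chelator' must be a chelator")
  if (any(target_fe_conc < 0)) abort_validation("'target_fe_conc' must be >= 0")
  lig <- target_fe_conc * chelator$n_max
  list(fe_mmol_per_l = target_fe_conc,
       ligand_mmol_per_l = lig,
       ligand_g_per_l = lig * chelator$ligand_molar_mass / 1000,
       fecl3_g_per_l = target_fe_conc * 162.2 / 1000)
}

#' Full iron budget table
#'
#' All derived stoichiometric and dosimetry quantities for a constants
#' set, as a labeled table.
#'
#' @param consts [stoichiometry_constants()].
#' @param tf [transferrin()].
#' @param chelator [chelator()].
#' @param htf_ug_per_ml Reference holotransferrin dose, ug/mL.
#' @param complex_umol_per_l Reference complex dose, umol/L.
#' @return Data frame with columns `quantity`, `value`, `unit`.
#' @export
iron_budget <- function(consts = stoichiometry_constants(), tf = transferrin(),
                        chelator = deferiprone(),
                        htf_ug_per_ml = 1000, complex_umol_per_l = 52) {
  lig_mg <- ligand_mass_concentration(complex_umol_per_l, chelator)
  data.frame(
    quantity = c("fe_ions_per_cell", "tf_demand_per_cell",
                 "tf_demand_per_unit", "chelated_fe_equivalent",
                 "htf_equivalent_of_complex", "ligand_mass_concentration",
                 "residual_dose_per_kg"),
    value = c(fe_ions_per_cell(consts),
              tf_demand_per_cell(consts, tf),
              tf_demand_per_unit(consts, tf),
              chelated_fe_equivalent(htf_ug_per_ml, tf),
              htf_equivalent_of_complex(complex_umol_per_l, tf),
              lig_mg,
              residual_dose_per_kg(consts, chelator, lig_mg)),
    unit = c("ions", "pg", "g", "umol/L", "ug/mL", "mg/L", "mg/kg"),
    stringsAsFactors = FALSE
  )
}
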