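# Config parsing and tabular input/output.

.RECIPE_KEYS <- c("htf_ug_per_ml", "atf_ug_per_ml", "complex_umol_per_l",
                  "chelator_name", "ph", "bicarbonate_mmol_per_l", "label")

#' Build a medium composition from a culture recipe
#'
#' Converts the usual recipe units (transferrin in ug/mL, iron-chelator
#' complex in umol/L) into molar pools: holotransferrin contributes
#' protein and two irons per molecule, apotransferrin protein only, and
#' each complex one iron plus `n_max` ligands. Conversions use the
#' transferrin equivalence molar mass (see [transferrin()]).
#'
#' @param htf_ug_per_ml Holotransferrin, ug/mL.
#' @param atf_ug_per_ml Apotransferrin, ug/mL.
#' @param complex_umol_per_l Iron-loaded chelator complex, umol/L.
#' @param chelator_name Built-in chelator name (default "deferiprone"),
#'   or a [chelator()] object.
#' @param ph Medium pH.
#' @param bicarbonate_mmol_per_l Bicarbonate, mmol/L.
#' @param label Optional scenario label.
#' @param tf [transferrin()] used for the mass/mol conversion.
#' @return List with `medium`, `chelator` (or `NULL`), `label`.
#' @examples
#' medium_from_recipe(htf_ug_per_ml = 100, complex_umol_per_l = 52)
#' @export
medium_from_recipe <- function(htf_ug_per_ml = 0, atf_ug_per_ml = 0,
                               complex_umol_per_l = 0,
                               chelator_name = "deferiprone",
                               ph = 7.4, bicarbonate_mmol_per_l = 3.5,
                               label = NULL, tf = transferrin()) {
  check_number(htf_ug_per_ml, "htf_ug_per_ml", min = 0)
  check_number(atf_ug_per_ml, "atf_ug_per_ml", min = 0)
  check_number(complex_umol_per_l, "complex_umol_per_l", min = 0)
  chel <- if (inherits(chelator_name, "chelator")) chelator_name
          else get_chelator(chelator_name)
  htf_mol <- htf_ug_per_ml * 1e-3 / tf$molar_mass_equivalence
  atf_mol <- atf_ug_per_ml * 1e-3 / tf$molar_mass_equivalence
  cx_mol <- complex_umol_per_l * 1e-6
  comp <- medium(
    tf_total = htf_mol + atf_mol,
    fe_total = tf$iron_sites * htf_mol + cx_mol,
    ligand_total = chel$n_max * cx_mol,
    ph = ph, bicarbonate = bicarbonate_mmol_per_l * 1e-3
  )
  list(medium = comp,
       chelator = if (cx_mol > 0) chel else NULL,
       label = label %||% sprintf("%g ug/mL hTf + %g ug/mL aTf + %g umol/L %s complex",
                                  htf_ug_per_ml, atf_ug_per_ml,
                                  complex_umol_per_l, chel$name))
}

.parse_recipe <- function(x, where = "config") {
  bad <- setdiff(names(x), .RECIPE_KEYS)
  if (length(bad))
    abort_validation("unknown %s key(s): %s (allowed: %s)", where,
                     paste(bad, collapse = ", "),
                     paste(.RECIPE_KEYS, collapse = ", "))
  do.call(medium_from_recipe, x)
}

#' Read a medium recipe config file
#'
#' Flat key-value YAML with the keys `htf_ug_per_ml`, `atf_ug_per_ml`,
#' `complex_umol_per_l`, `chelator_name`, `ph`, `bicarbonate_mmol_per_l`,
#' `label`; unknown keys are rejected with an error naming them.
#'
#' @param path Path to the YAML file.
#' @return As [medium_from_recipe()].
#' @export
read_medium_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  .parse_recipe(yaml::read_yaml(path), where = basename(path))
}

#' Read a multi-scenario config file
#'
#' YAML with a single top-level `scenarios:` list, each entry a medium
#' recipe in the dialect of [read_medium_config()].
#'
#' @param path Path to the YAML file.
#' @return List of recipe lists (`medium`, `chelator`, `label`).
#' @export
read_scenarios_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (!identical(names(y), "scenarios"))
    abort_validation("scenario config must have a single top-level 'scenarios' key")
  lapply(seq_along(y$scenarios), function(i)
    .parse_recipe(y$scenarios[[i]], where = sprintf("scenarios[%d]", i)))
}

#' Species table of a solved state
#'
#' One row per species with its concentration and its fraction of the
#' relevant component pool (transferrin species of the transferrin pool,
#' free ligand of the ligand pool, iron-carrying species of the iron
#' pool).
#'
#' @param state A `"speciation_state"`.
#' @return Data frame with columns `species`, `concentration_mol_per_l`,
#'   `fraction_of_pool`.
#' @export
speciation_table <- function(state) {
  if (!inherits(state, "speciation_state"))
    abort_validation("'state' must be a speciation_state")
  pool <- function(x, tot) if (tot > 0) x / tot else NA_real_
  sp <- c("free_fe", "tf0", "tf1", "tf2", "free_ligand", names(state$complexes))
  conc <- c(state$free_fe, state$tf0, state$tf1, state$tf2, state$free_ligand,
            unname(state$complexes))
  frac <- c(pool(state$free_fe, state$fe_total),
            pool(state$tf0, state$tf_total),
            pool(state$tf1, state$tf_total),
            pool(state$tf2, state$tf_total),
            pool(state$free_ligand, state$ligand_total),
            vapply(unname(state$complexes), pool, 0, tot = state$fe_total))
  data.frame(species = sp, concentration_mol_per_l = conc,
             fraction_of_pool = frac, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.speciation_state <- function(x, ...) speciation_table(x)

#' Write a solved state to CSV or JSON
#'
#' The JSON form carries a header with the package version and the
#' constants actually used (conditional log beta values, totals, pH) so
#' every number in the file is auditable; the CSV form is the bare
#' species table.
#'
#' @param state A `"speciation_state"`.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_speciation <- function(state, path,
                             format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  tab <- speciation_table(state)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(package = "ferrispec",
           version = as.character(utils::packageVersion("ferrispec")),
           constants = list(log_beta_conditional = state$log_beta_conditional,
                            chelator = state$chelator_name,
                            ph = state$ph, rtol = state$rtol),
           totals = list(fe_total = state$fe_total, tf_total = state$tf_total,
                         ligand_total = state$ligand_total),
           species = tab),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  invisible(path)
}

#' Read a two-column delimited dose-response or saturation table
#'
#' Comma-separated with a header row; the first two numeric columns are
#' used.
#'
#' @param path Input path.
#' @param sep Field separator (default ",").
#' @return Data frame.
#' @export
read_curve_table <- function(path, sep = ",") {
  if (!file.exists(path)) abort_validation("input file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, strip.white = TRUE)
}

#' Write a fit report as JSON
#'
#' @param fit A `"dr_fit"` or `"hill_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, c("dr_fit", "hill_fit")))
    abort_validation("'fit' must be a dr_fit or hill_fit")
  rep <- list(package = "ferrispec",
              version = as.character(utils::packageVersion("ferrispec")),
              model = if (inherits(fit, "dr_fit")) "hyperbolic_dose_response"
                      else "hill_oxygen_saturation",
              coefficients = as.list(fit$coefficients),
              rss = fit$rss, converged = fit$converged, n_obs = fit$n_obs)
  if (inherits(fit, "hill_fit")) rep$p50_interp <- fit$p50_interp
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a scenario comparison to CSV
#'
#' @param cmp A `"scenario_comparison"`.
#' @param path Output path for the long table; the per-time summary goes
#'   to `<path base>.summary.csv`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  if (!inherits(cmp, "scenario_comparison"))
    abort_validation("'cmp' must be a scenario_comparison")
  utils::write.csv(cmp$table, path, row.names = FALSE)
  utils::write.csv(cmp$summary,
                   sub("(\\.[^.]+)?$", ".summary.csv", path, perl = TRUE),
                   row.names = FALSE)
  invisible(path)
}
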