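# Seeded synthetic-data generators: every tabular input the fitting
# stages consume can be produced offline with known ground truth, so
# parameter recovery is testable end to end.

.syn_defaults <- list(
  dose_response = list(
    hb_max = 30,                      # pg/cell, near the ~30 pg/cell scale
    ec50 = 5,                         # umol/L
    concentrations = c(0, 1.3, 2.6, 5.2, 13, 26, 52),  # umol/L design
    n_points = 24L,
    noise_sd = 0.05                   # fraction of hb_max
  ),
  oxy = list(
    p50 = 26.8,                       # mmHg
    hill_n = 2.7,
    po2 = seq(0, 150, by = 5),        # mmHg grid
    noise_sd = 0.01                   # absolute, on fractional saturation
  ),
  timecourse_obs = list(
    noise_sd = 0.01                   # absolute, on Tf fractions
  )
)

.merge_strict <- function(defaults, user, where) {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    abort_validation("unknown %s key(s): %s", where, paste(bad, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles a seed with the ground-truth parameters and noise levels of the
#' three generators. Defaults: a hyperbolic dose-response with
#' `hb_max = 30` pg/cell and `ec50 = 5` umol/L sampled at the culture
#' design concentrations 0, 1.3, 2.6, 5.2, 13, 26, 52 umol/L (24 points,
#' additive Gaussian noise with sd 5% of `hb_max`, truncated at 0); a
#' Hill oxygen-saturation curve with `p50 = 26.8` mmHg and `hill_n = 2.7`
#' on a 0-150 mmHg grid (noise sd 0.01, clipped to [0, 1]); and additive
#' noise (sd 0.01) on simulated transferrin fractions. Unknown keys are
#' rejected.
#'
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @param dose_response,oxy,timecourse_obs Named lists overriding the
#'   defaults above.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L, dose_response = list(), oxy = list(),
                             timecourse_obs = list()) {
  check_number(seed, "seed")
  cfg <- list(
    seed = as.integer(seed),
    dose_response = .merge_strict(.syn_defaults$dose_response, dose_response,
                                  "dose_response"),
    oxy = .merge_strict(.syn_defaults$oxy, oxy, "oxy"),
    timecourse_obs = .merge_strict(.syn_defaults$timecourse_obs,
                                   timecourse_obs, "timecourse_obs")
  )
  if (cfg$dose_response$noise_sd < 0 || cfg$oxy$noise_sd < 0 ||
      cfg$timecourse_obs$noise_sd < 0)
    abort_validation("noise parameters must be >= 0")
  structure(cfg, class = "synthetic_config")
}

.manifest <- function(cfg, module, truth) {
  list(package = "ferrispec",
       version = as.character(utils::packageVersion("ferrispec")),
       seed = cfg$seed, module = module, truth = truth,
       config = unclass(cfg)[[module]])
}

#' Generate a synthetic iron/hemoglobin dose-response dataset
#'
#' Draws `n_points` observations from the hyperbolic model at the design
#' concentrations (recycled and sorted), adds Gaussian noise with sd
#' `noise_sd * hb_max`, and truncates at zero. The caller's RNG state is
#' left untouched; the same config always yields the same dataset.
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame (`fe_conc`, `hb`) with a `manifest` attribute
#'   recording seed, ground truth and generator config.
#' @export
gen_dose_response <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) abort_validation("'cfg' must be a synthetic_config")
  p <- cfg$dose_response
  conc <- sort(rep_len(p$concentrations, p$n_points))
  mu <- p$hb_max * conc / (p$ec50 + conc)
  hb <- with_seed(cfg$seed, pmax(mu + stats::rnorm(length(mu), 0, p$noise_sd * p$hb_max), 0))
  out <- data.frame(fe_conc = conc, hb = hb)
  attr(out, "manifest") <- .manifest(cfg, "dose_response",
                                     list(hb_max = p$hb_max, ec50 = p$ec50))
  out
}

#' Generate a synthetic oxygen-saturation curve
#'
#' Hill model plus Gaussian noise, clipped to the physical range [0, 1].
#'
#' @param cfg A [synthetic_config()].
#' @return Data frame (`po2`, `saturation`) with a `manifest` attribute.
#' @export
gen_oxy_curve <- function(cfg = synthetic_config()) {
  if (!inherits(cfg, "synthetic_config")) abort_validation("'cfg' must be a synthetic_config")
  p <- cfg$oxy
  mu <- p$po2^p$hill_n / (p$p50^p$hill_n + p$po2^p$hill_n)
  sat <- with_seed(cfg$seed + 1L,
                   pmin(pmax(mu + stats::rnorm(length(mu), 0, p$noise_sd), 0), 1))
  out <- data.frame(po2 = p$po2, saturation = sat)
  attr(out, "manifest") <- .manifest(cfg, "oxy",
                                     list(p50 = p$p50, hill_n = p$hill_n))
  out
}

#' Noisy observations of a simulated time course
#'
#' Adds truncated Gaussian noise to the simulated transferrin fractions
#' and renormalizes each (apo, mono, holo) triple to sum to one, giving
#' an observation-like view of a [simulate_timecourse()] result.
#'
#' @param cfg A [synthetic_config()].
#' @param tc An `"iron_timecourse"`.
#' @return Data frame (`scenario`, `time`, `frac_apo`, `frac_mono`,
#'   `frac_holo`) with a `manifest` attribute.
#' @export
gen_timecourse_observations <- function(cfg = synthetic_config(), tc) {
  if (!inherits(cfg, "synthetic_config")) abort_validation("'cfg' must be a synthetic_config")
  if (!inherits(tc, "iron_timecourse")) abort_validation("'tc' must be an iron_timecourse")
  sd <- cfg$timecourse_obs$noise_sd
  fr <- as.matrix(as.data.frame(tc)[, c("frac_apo", "frac_mono", "frac_holo")])
  noisy <- with_seed(cfg$seed + 2L,
                     pmin(pmax(fr + matrix(stats::rnorm(length(fr), 0, sd),
                                           nrow(fr)), 0), 1))
  noisy <- noisy / rowSums(noisy)
  out <- data.frame(scenario = attr(tc, "scenario_label"), time = tc$time,
                    frac_apo = noisy[, 1], frac_mono = noisy[, 2],
                    frac_holo = noisy[, 3])
  attr(out, "manifest") <- .manifest(cfg, "timecourse_obs",
                                     list(scenario = attr(tc, "scenario_label")))
  out
}

#' Manifest of a generated dataset
#'
#' @param x A data frame returned by one of the generators.
#' @return The manifest list (package version, seed, module, ground
#'   truth, generator config), or `NULL` if absent.
#' @export
manifest <- function(x) attr(x, "manifest")

#' Write a generated dataset with its manifest
#'
#' Writes the data as CSV and the manifest as JSON next to it
#' (`<path>.manifest.json`), so regeneration is fully specified.
#'
#' @param x A generated data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  m <- manifest(x)
  if (!is.null(m))
    jsonlite::write_json(m, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
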