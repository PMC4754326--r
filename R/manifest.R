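# Feature manifest: the ordered list of the 55 regional MRI measures
# (34 cortical thickness means + 21 subcortical volumes, left/right averaged)
# that every cohort table must carry, in this order.

# One internal table drives both the manifest and the simulator defaults:
#   baseline     healthy mean at the reference age of 75 y (mm or mm^3)
#   age_slope    linear age drift, units per year (negative = atrophy,
#                positive = expansion, e.g. ventricles/CSF)
#   residual_sd  residual spread around the age trend
#   effect_ad    AD shift in units of residual_sd (negative = loss);
#                largest in medial temporal structures
feature_param_table <- function() {
  th <- function(name, baseline, slope, sd, eff)
    data.frame(name = name, type = "thickness", baseline = baseline,
               age_slope = slope, residual_sd = sd, effect_ad = eff,
               stringsAsFactors = FALSE)
  vol <- function(name, baseline, slope, sd, eff)
    data.frame(name = name, type = "volume", baseline = baseline,
               age_slope = slope, residual_sd = sd, effect_ad = eff,
               stringsAsFactors = FALSE)
  rbind(
    th("bankssts",                 2.45, -0.006, 0.14, -0.6),
    th("caudalanteriorcingulate",  2.65, -0.004, 0.18, -0.3),
    th("caudalmiddlefrontal",      2.55, -0.006, 0.14, -0.3),
    th("cuneus",                   1.85, -0.004, 0.12, -0.2),
    th("entorhinal",               3.35, -0.009, 0.28, -1.5),
    th("frontalpole",              2.75, -0.006, 0.22, -0.3),
    th("fusiform",                 2.70, -0.007, 0.15, -1.0),
    th("inferiorparietal",         2.45, -0.006, 0.13, -0.6),
    th("inferiortemporal",         2.75, -0.007, 0.15, -1.0),
    th("insula",                   2.95, -0.006, 0.16, -0.4),
    th("isthmuscingulate",         2.40, -0.005, 0.16, -0.4),
    th("lateraloccipital",         2.20, -0.005, 0.12, -0.2),
    th("lateralorbitofrontal",     2.65, -0.007, 0.15, -0.3),
    th("lingual",                  1.95, -0.004, 0.11, -0.2),
    th("medialorbitofrontal",      2.45, -0.006, 0.15, -0.3),
    th("middletemporal",           2.85, -0.008, 0.15, -1.0),
    th("paracentral",              2.40, -0.005, 0.13, -0.2),
    th("parahippocampal",          2.75, -0.008, 0.25, -1.0),
    th("parsopercularis",          2.60, -0.006, 0.14, -0.3),
    th("parsorbitalis",            2.70, -0.007, 0.17, -0.3),
    th("parstriangularis",         2.50, -0.006, 0.14, -0.3),
    th("pericalcarine",            1.60, -0.003, 0.11, -0.1),
    th("postcentral",              2.05, -0.005, 0.12, -0.2),
    th("posteriorcingulate",       2.50, -0.005, 0.14, -0.4),
    th("precentral",               2.55, -0.006, 0.13, -0.2),
    th("precuneus",                2.35, -0.006, 0.13, -0.5),
    th("rostralanteriorcingulate", 2.85, -0.005, 0.19, -0.3),
    th("rostralmiddlefrontal",     2.40, -0.006, 0.13, -0.3),
    th("superiorfrontal",          2.70, -0.007, 0.14, -0.4),
    th("superiorparietal",         2.20, -0.005, 0.12, -0.3),
    th("superiortemporal",         2.75, -0.008, 0.14, -1.0),
    th("supramarginal",            2.50, -0.006, 0.13, -0.5),
    th("temporalpole",             3.70, -0.008, 0.28, -1.0),
    th("transversetemporal",       2.35, -0.006, 0.17, -0.3),
    vol("lateral.ventricle",            10500, 160.0, 5500, 0.8),
    vol("inferior.lateral.ventricle",     450,  12.0,  280, 0.9),
    vol("cerebellum.white.matter",      14000, -40.0, 1700, -0.1),
    vol("cerebellum.cortex",            52000, -120.0, 5200, -0.1),
    vol("thalamus",                      6400, -25.0,  650, -0.4),
    vol("caudate",                       3500,  -8.0,  430, -0.1),
    vol("putamen",                       4800, -20.0,  560, -0.3),
    vol("pallidum",                      1650,  -6.0,  230, -0.2),
    vol("hippocampus",                   3900, -22.0,  440, -1.5),
    vol("amygdala",                      1500,  -9.0,  210, -1.5),
    vol("accumbens",                      550,  -3.5,   95, -0.4),
    vol("ventral.dc",                    3900, -12.0,  390, -0.3),
    vol("third.ventricle",               1050,  16.0,  480, 0.6),
    vol("fourth.ventricle",              1750,   6.0,  470, 0.2),
    vol("brainstem",                    21000, -40.0, 2200, -0.2),
    vol("csf",                           1000,  10.0,  330, 0.4),
    vol("white.matter.hypointensities",  1800,  55.0, 2100, 0.4),
    vol("optic.chiasm",                   180,  -0.2,   45, -0.1),
    vol("corpus.callosum",               3300, -12.0,  480, -0.3),
    vol("choroid.plexus",                 800,   6.0,  270, 0.2),
    vol("vessel",                          55,  -0.1,   28, 0.0)
  )
}

#' Default feature manifest
#'
#' The packaged default manifest: 34 regional cortical thickness means
#' followed by 21 subcortical volumes (FreeSurfer aparc/aseg region names,
#' left/right averaged).  The manifest fixes both the set and the order of
#' the feature columns a cohort table must carry; the names are
#' configuration, and any manifest with the same `thickness`/`volume`
#' structure can be supplied instead.
#'
#' @return a data frame with columns `name` and `type`
#'   (`"thickness"`/`"volume"`), 55 rows.
#' @seealso [read_manifest()], [read_cohort()]
#' @export
#' @examples
#' m <- default_manifest()
#' table(m$type)
default_manifest <- function() {
  feature_param_table()[, c("name", "type")]
}

validate_manifest <- function(manifest) {
  if (!is.data.frame(manifest) || !all(c("name", "type") %in% names(manifest)))
    stop_schema("manifest must be a data frame with 'name' and 'type' columns")
  if (anyDuplicated(manifest$name))
    stop_schema("manifest feature names must be unique")
  if (!all(manifest$type %in% c("thickness", "volume")))
    stop_schema("manifest 'type' must be 'thickness' or 'volume'")
  invisible(manifest)
}

#' Read or write a feature manifest as JSON
#'
#' A manifest file is a JSON array of `{"name": ..., "type": ...}` records,
#' in feature order.
#'
#' @param path file path.
#' @param manifest a manifest data frame (see [default_manifest()]).
#' @return `read_manifest()` returns the manifest data frame;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::fromJSON(path)
  validate_manifest(as.data.frame(m, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(manifest[, c("name", "type")], path,
                       dataframe = "rows", auto_unbox = FALSE)
  invisible(path)
}
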