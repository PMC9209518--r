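#' Named presets for the synthetic-data generators
#'
#' Presets encode the experimental conditions the generators emulate:
#' acquisition timing, kinetic parameters, localization probabilities,
#' dilution series and lifetimes. They live in a single editable registry
#' (`inst/extdata/presets.yaml`), never hard-coded in the generator code.
#'
#' @param group One of `"frap"`, `"dynamics"`, `"nucleus"`, `"droplets"`,
#'   `"flim"`.
#' @param name Preset name within the group (e.g. `"tale_ctrl"`); `NULL`
#'   lists available names.
#' @param registry Optional path to an alternative YAML registry.
#'
#' @return A named list of preset fields (with `name` attached), or a
#'   character vector of available names when `name` is `NULL`.
#' @examples
#' chromodyn_preset("frap")            # available FRAP presets
#' chromodyn_preset("frap", "tale_ctrl")$k_per_s
#' @export
chromodyn_preset <- function(group, name = NULL, registry = NULL) {
  path <- registry %||% system.file("extdata", "presets.yaml", package = "chromodyn")
  reg <- yaml::read_yaml(path)
  if (!group %in% names(reg)) {
    abort(sprintf("Unknown preset group '%s' (have: %s).",
                  group, paste(names(reg), collapse = ", ")))
  }
  if (is.null(name)) {
    return(names(reg[[group]]))
  }
  if (!name %in% names(reg[[group]])) {
    abort(sprintf("Unknown %s preset '%s' (have: %s).",
                  group, name, paste(names(reg[[group]]), collapse = ", ")))
  }
  preset <- reg[[group]][[name]]
  preset$name <- name
  preset
}

validate_frap_preset <- function(p) {
  for (f in c("pre_bleach_frames", "frame_interval_s", "post_interval_s",
              "n_frames", "bleach_depth", "mobile_fraction", "k_per_s",
              "acq_bleach_per_s", "noise_sd")) {
    if (is.null(p[[f]])) abort(sprintf("FRAP preset is missing field `%s`.", f))
    assert_finite_scalar(p[[f]], f)
  }
  assert_fraction(p$mobile_fraction, "mobile_fraction")
  assert_fraction(p$bleach_depth, "bleach_depth", open_upper = TRUE)
  assert_finite_scalar(p$k_per_s, "k_per_s", positive = TRUE)
  if (p$pre_bleach_frames < 1) abort("`pre_bleach_frames` must be >= 1.")
  if (p$n_frames <= p$pre_bleach_frames) abort("`n_frames` must exceed `pre_bleach_frames`.")
  invisible(p)
}

validate_dynamics_preset <- function(p) {
  for (f in c("n_foci", "d_app", "alpha", "velocity", "fusion_rate",
              "fission_rate", "frame_interval_s", "duration_s")) {
    if (is.null(p[[f]])) abort(sprintf("Dynamics preset is missing field `%s`.", f))
    assert_finite_scalar(p[[f]], f)
  }
  if (p$alpha <= 0 || p$alpha > 2) abort("`alpha` must lie in (0, 2].")
  if (p$fusion_rate < 0 || p$fission_rate < 0) abort("Event rates must be >= 0.")
  if (p$d_app < 0) abort("`d_app` must be >= 0.")
  invisible(p)
}

validate_nucleus_preset <- function(p) {
  if (!is.null(p$rna_class_probs)) {
    probs <- unlist(p$rna_class_probs)
    if (length(probs) != 3 || any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
      abort("`rna_class_probs` must be 3 nonnegative probabilities summing to 1.")
    }
  }
  for (f in c("cc_intensity", "eu_intensity", "background")) {
    if (!is.null(p[[f]]) && p[[f]] < 0) abort(sprintf("`%s` must be >= 0.", f))
  }
  invisible(p)
}

validate_droplet_preset <- function(p) {
  concs <- unlist(p$protein_concs_uM)
  if (any(diff(concs) >= 0)) abort("`protein_concs_uM` must be strictly decreasing.")
  for (sp in p$rna_species) {
    if (!(sp$critical_conc_uM > 0)) abort("`critical_conc_uM` must be > 0 (or Inf).")
  }
  invisible(p)
}
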