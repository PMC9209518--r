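#' Generate a synthetic HP1a droplet plate
#'
#' One field-of-view image per (RNA species x protein concentration) well.
#' Wells at protein concentration >= the species' critical concentration
#' contain a Poisson number (floored at the preset minimum) of bright disks
#' whose diameters are lognormal around the species' size scale; wells below
#' the critical concentration contain at most a few sub-threshold specks.
#' A species with infinite critical concentration (e.g. protein without RNA)
#' never forms droplets.
#'
#' @param preset Droplet-plate preset list or name (see
#'   [chromodyn_preset()]`("droplets")`).
#' @param seed Integer seed.
#' @return A list of class `droplet_plate`: `wells` (tibble: `rna_species`,
#'   `conc_uM` on the dilution-series label scale, `final_conc_uM` after
#'   equal-volume mixing, `image` list-column), `pixel_size_um`, `truth`
#'   (tibble with per-well true droplet count and mean diameter, and the
#'   per-species generative critical concentration).
#' @export
make_droplet_plate <- function(preset = "msr_plate", seed = 1L) {
  if (is.character(preset)) preset <- chromodyn_preset("droplets", preset)
  validate_droplet_preset(preset)
  concs <- unlist(preset$protein_concs_uM)
  shape <- unlist(preset$field_shape_px)
  ny <- shape[1]; nx <- shape[2]
  ps <- preset$pixel_size_um

  wells <- list(); truths <- list()
  k <- 0L
  for (sp in preset$rna_species) {
    for (conc in concs) {
      k <- k + 1L
      with_seed(derive_seed(seed, k), {
        img <- matrix(preset$background, ny, nx)
        above <- is.finite(sp$critical_conc_uM) && conc >= sp$critical_conc_uM
        diams <- numeric(0)
        if (above) {
          n_dr <- max(rpois(1, preset$droplet_count_mean), preset$droplet_count_min)
          diams <- sp$droplet_size_scale_um * exp(rnorm(n_dr, 0, 0.25))
          for (i in seq_len(n_dr)) {
            r_px <- diams[i] / 2 / ps
            cy <- runif(1, r_px + 2, ny - r_px - 2)
            cx <- runif(1, r_px + 2, nx - r_px - 2)
            img[disk_mask(ny, nx, cy, cx, r_px)] <- preset$droplet_intensity
          }
        } else if (conc > 0) {
          # sparse sub-threshold specks
          for (i in seq_len(rpois(1, 2))) {
            cy <- runif(1, 3, ny - 3); cx <- runif(1, 3, nx - 3)
            img[disk_mask(ny, nx, cy, cx, 0.8)] <- preset$droplet_intensity
          }
        }
        img <- img + rnorm(ny * nx, sd = preset$noise_sd)
        wells[[k]] <- tibble(
          rna_species = sp$name, conc_uM = conc, final_conc_uM = conc / 2,
          image = list(img)
        )
        truths[[k]] <- tibble(
          rna_species = sp$name, conc_uM = conc,
          true_droplet_count = length(diams),
          true_mean_diameter_um = if (length(diams)) mean(diams) else NA_real_,
          critical_conc_uM = sp$critical_conc_uM
        )
      })
    }
  }
  structure(
    list(wells = dplyr::bind_rows(wells), pixel_size_um = ps,
         truth = dplyr::bind_rows(truths)),
    class = "droplet_plate"
  )
}
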