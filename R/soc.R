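# Soil organic carbon stock, 0-30 cm, from composite core samples.

#' Soil corer specification and volume
#'
#' The inventory corer is 100 mm long with a 37 mm cutting-edge diameter
#' (the upper diameter, 40 mm, is metadata only: the sample volume is set
#' by the cutting edge). The cylinder volume at the cutting edge,
#' `pi * (d/2)^2 * length`, reproduces the protocol's printed sub-sample
#' volume of 107.5 cm^3.
#'
#' @param length_mm corer length, mm.
#' @param cutting_edge_diameter_mm diameter at the cutting edge, mm.
#' @param upper_diameter_mm upper diameter, mm (metadata only).
#' @return For `corer_spec()`, a list of class `corer_spec`; for
#'   `corer_volume()`, the sub-sample volume in cm^3.
#' @examples
#' corer_volume() # ~107.5 cm^3
#' @export
corer_spec <- function(length_mm = 100, cutting_edge_diameter_mm = 37,
                       upper_diameter_mm = 40) {
  check_number(length_mm, "length_mm", lower = 0, strict_lower = TRUE)
  check_number(cutting_edge_diameter_mm, "cutting_edge_diameter_mm",
               lower = 0, strict_lower = TRUE)
  structure(list(length_mm = length_mm,
                 cutting_edge_diameter_mm = cutting_edge_diameter_mm,
                 upper_diameter_mm = upper_diameter_mm),
            class = "corer_spec")
}

#' @rdname corer_spec
#' @param spec a [corer_spec()].
#' @export
corer_volume <- function(spec = corer_spec()) {
  r_cm <- spec$cutting_edge_diameter_mm / 2 / 10
  len_cm <- spec$length_mm / 10
  pi * r_cm^2 * len_cm
}

#' Bulk density of the soil fine fraction
#'
#' The composite sample volume is `n_pits` corer volumes; the volume of
#' the coarse fraction (> 2 mm stones, measured by water replacement and
#' assumed void of organic carbon) is subtracted, and the fine-fraction
#' (< 2 mm sieved) oven-dry mass is divided by the remaining volume.
#'
#' @param fine_mass_g oven-dry mass of the fine fraction, g.
#' @param coarse_volume_cm3 coarse-fraction volume, cm^3.
#' @param n_pits number of pits pooled into the composite (4 by design).
#' @param spec a [corer_spec()].
#' @return Fine-fraction bulk density, g cm^-3.
#' @export
bulk_density_fine <- function(fine_mass_g, coarse_volume_cm3, n_pits = 4,
                              spec = corer_spec()) {
  check_number(fine_mass_g, "fine_mass_g", lower = 0)
  check_number(coarse_volume_cm3, "coarse_volume_cm3", lower = 0)
  denom <- n_pits * corer_volume(spec) - coarse_volume_cm3
  if (any(denom <= 0)) {
    stopf("coarse-fraction volume %s cm^3 >= composite volume %s cm^3",
          paste(signif(coarse_volume_cm3[denom <= 0], 6), collapse = ","),
          signif(n_pits * corer_volume(spec), 6))
  }
  fine_mass_g / denom
}

#' Total organic carbon mass fraction from Walkley-Black OC%
#'
#' The Walkley-Black partial wet-combustion assay recovers only part of
#' the organic carbon; the conventional correction multiplies by 1.33 to
#' approximate total organic carbon, then converts percent to a mass
#' fraction.
#'
#' @param oc_wb_pct Walkley-Black organic carbon, percent of
#'   fine-fraction mass.
#' @param correction recovery correction factor (default 1.33).
#' @return Total organic carbon as a mass fraction (g C per g fine soil).
#' @examples
#' total_oc_fraction(1.0) # 0.0133
#' @export
total_oc_fraction <- function(oc_wb_pct, correction = 1.33) {
  check_number(oc_wb_pct, "oc_wb_pct", lower = 0)
  oc_wb_pct * correction / 100
}

#' Volumetric organic carbon density of the fine fraction
#'
#' @param bd_ff fine-fraction bulk density, g cm^-3.
#' @param oc_fraction total organic carbon mass fraction.
#' @return Carbon density, g C cm^-3 of fine earth.
#' @export
soc_ff <- function(bd_ff, oc_fraction) {
  check_number(bd_ff, "bd_ff", lower = 0)
  check_number(oc_fraction, "oc_fraction", lower = 0)
  bd_ff * oc_fraction
}

#' Stoniness (coarse-fragment) adjustment of SOC
#'
#' Downscales the fine-fraction carbon density by the field-observed
#' volumetric stone proportion: `soc_adj = soc * (100 - stone_pct) / 100`.
#'
#' Note on the source formula: the inventory report prints the
#' adjustment as `(100 - Stone%/100) * SOC_FF`, which is dimensionally
#' inconsistent (it would inflate SOC by a factor near 100). This
#' function implements the standard coarse-fragment correction
#' `((100 - Stone%)/100) * SOC_FF`, which is the identity at 0% stones
#' and zero at 100% stones.
#'
#' @param soc carbon density of the fine fraction, g C cm^-3.
#' @param stone_pct volumetric stoniness, percent in `[0, 100]`.
#' @return Adjusted carbon density, g C cm^-3 of whole soil.
#' @examples
#' adjust_stoniness(0.02, 25) # 0.015
#' @export
adjust_stoniness <- function(soc, stone_pct) {
  check_number(soc, "soc", lower = 0)
  check_number(stone_pct, "stone_pct", lower = 0, upper = 100)
  soc * (100 - stone_pct) / 100
}

#' Per-layer SOC stock
#'
#' Converts an adjusted volumetric carbon density into an areal stock
#' over the layer thickness: 1 g C cm^-2 equals 100 t C ha^-1.
#'
#' @param soc_adj adjusted carbon density, g C cm^-3.
#' @param thickness_cm layer thickness, cm (10 by design).
#' @return Layer stock in t C ha^-1.
#' @examples
#' layer_stock(0.01) # 10 t/ha
#' @export
layer_stock <- function(soc_adj, thickness_cm = 10) {
  check_number(soc_adj, "soc_adj", lower = 0)
  check_number(thickness_cm, "thickness_cm", lower = 0)
  soc_adj * thickness_cm * 100
}

soc_layers <- c("0-10", "10-20", "20-30")

#' Plot-level SOC stock for 0-30 cm
#'
#' Runs the full per-layer chain -- fine-fraction bulk density,
#' Walkley-Black total-carbon correction, volumetric carbon density,
#' stoniness adjustment, areal stock -- and sums the three design layers
#' (0-10, 10-20, 20-30 cm).
#'
#' @param samples tibble with one row per layer and columns `plot_id`,
#'   `layer` (exactly `"0-10"`, `"10-20"`, `"20-30"`), `n_pits`,
#'   `fine_mass_g`, `coarse_volume_cm3`, `oc_wb_pct`, `stone_pct`.
#' @param spec a [corer_spec()].
#' @param correction Walkley-Black correction factor (default 1.33).
#' @param thickness_cm layer thickness, cm.
#' @return SOC stock in t ha^-1 for 0-30 cm.
#' @export
plot_soc <- function(samples, spec = corer_spec(), correction = 1.33,
                     thickness_cm = 10) {
  found <- as.character(samples$layer)
  if (!setequal(found, soc_layers) || anyDuplicated(found)) {
    stopf("plot %s: need exactly layers %s, found {%s}",
          paste(unique(samples$plot_id), collapse = ","),
          paste(soc_layers, collapse = ", "),
          paste(found, collapse = ", "))
  }
  bd <- bulk_density_fine(samples$fine_mass_g, samples$coarse_volume_cm3,
                          n_pits = samples$n_pits, spec = spec)
  ocf <- total_oc_fraction(samples$oc_wb_pct, correction = correction)
  adj <- adjust_stoniness(soc_ff(bd, ocf), samples$stone_pct)
  sum(layer_stock(adj, thickness_cm))
}

#' Per-plot SOC table for a whole soil sample list
#'
#' @param soil tibble of layer samples for many plots (see [plot_soc()]).
#' @inheritParams plot_soc
#' @return A tibble with columns `plot_id`, `soc_t_ha`.
#' @export
soc_by_plot <- function(soil, spec = corer_spec(), correction = 1.33,
                        thickness_cm = 10) {
  ids <- unique(soil$plot_id)
  soc <- vapply(ids, function(id) {
    plot_soc(soil[soil$plot_id == id, , drop = FALSE], spec = spec,
             correction = correction, thickness_cm = thickness_cm)
  }, numeric(1))
  tibble::tibble(plot_id = ids, soc_t_ha = unname(soc))
}
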