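# Plot-level aboveground biomass: tree biomass expanded to per hectare
# through the CCSP design.

# Per-tree biomass (kg) for a joined tree x species table.
tree_biomass_kg <- function(trees, policy = default_component_policy(),
                            profile = taper_parabolic,
                            stump_height = 0.15) {
  n <- nrow(trees)
  vol <- numeric(n)
  whole <- trees$status %in% c("live", "dead")
  if (any(whole)) {
    vol[whole] <- stem_volume(trees$dbh_cm[whole], trees$height_m[whole],
                              trees$a[whole], trees$b[whole], trees$c[whole])
  }
  for (i in which(!whole)) {
    cut_h <- trees$cut_height_m[i]
    if (is.na(cut_h)) {
      cut_h <- if (trees$status[i] == "stump") stump_height else
        trees$height_m[i]
    }
    vol[i] <- suppressWarnings(
      broken_stem_volume(trees$dbh_cm[i], trees$height_m[i], cut_h,
                         trees$a[i], trees$b[i], trees$c[i],
                         stump_height = stump_height, profile = profile)
    )
  }
  bs <- vol * trees$density
  b <- numeric(n)
  for (s in unique(trees$status)) {
    sel <- trees$status == s
    b[sel] <- total_tree_biomass(bs[sel], trees$branch_ratio[sel],
                                 trees$foliage_ratio[sel], s, policy)
  }
  b
}

resolve_species <- function(trees, species, fallback = TRUE,
                            context = "plot") {
  species <- validate_species_table(species)
  unknown <- setdiff(unique(trees$species_code), species$species_code)
  if (length(unknown)) {
    if (!fallback) {
      stopf("%s %s: unresolvable species code(s) %s",
            context,
            paste(unique(trees$plot_id), collapse = ","),
            paste(unknown, collapse = ", "))
    }
    avg <- average_species_row(species)
    trees$species_code[trees$species_code %in% unknown] <- avg$species_code
    species <- dplyr::bind_rows(species, avg)
  }
  dplyr::left_join(trees, species, by = "species_code")
}

#' Plot-level aboveground biomass (t ha^-1)
#'
#' Computes each standing tree's total biomass, assigns the tree to its
#' CCSP ring by DBH class, multiplies by the ring's per-hectare expansion
#' factor, and sums over the plot:
#' `AGB = sum_i B_i [kg] * (10000 / A_ring(i)) / 1000` in t ha^-1.
#'
#' Standing live, dead and broken trees and stumps are included; records
#' with any other status (e.g. fallen deadwood, climbers) are filtered
#' out and tallied in the `n_filtered` attribute, as are trees below the
#' smallest measured DBH class.
#'
#' @param trees tibble with columns `plot_id`, `species_code`, `dbh_cm`,
#'   `height_m`, `status`, and `cut_height_m` (may be `NA` for
#'   live/dead trees).
#' @param species species allometry table (see [read_species_table()]).
#' @param design a [ccsp_design()].
#' @param fallback if `TRUE` (default), species codes absent from the
#'   table resolve to a table-average species row; if `FALSE`, unknown
#'   codes are an error naming the plot and species.
#' @param policy biomass component policy (see [total_tree_biomass()]).
#' @param profile taper profile for broken stems.
#' @return AGB in t ha^-1 (0 for an empty tree list), with attributes
#'   `n_trees` (used) and `n_filtered` (excluded records).
#' @examples
#' sp <- tibble::tibble(species_code = "S1", a = -3, b = 1.9, c = 0.9,
#'                      density = 550, branch_ratio = 0.4,
#'                      foliage_ratio = 0.1)
#' tr <- tibble::tibble(plot_id = "p1", species_code = "S1",
#'                      dbh_cm = 35, height_m = 22, status = "live",
#'                      cut_height_m = NA_real_)
#' plot_agb(tr, sp)
#' @export
plot_agb <- function(trees, species, design = ccsp_design(),
                     fallback = TRUE,
                     policy = default_component_policy(),
                     profile = taper_parabolic) {
  if (nrow(trees) == 0L) {
    return(structure(0, n_trees = 0L, n_filtered = 0L))
  }
  keep <- trees$status %in% c("live", "dead", "broken", "stump")
  ring <- rep(NA_integer_, nrow(trees))
  ring[keep] <- assign_subplot(trees$dbh_cm[keep], design)
  use <- keep & !is.na(ring)
  n_filtered <- sum(!use)
  trees <- trees[use, , drop = FALSE]
  ring <- ring[use]
  if (nrow(trees) == 0L) {
    return(structure(0, n_trees = 0L, n_filtered = n_filtered))
  }
  joined <- resolve_species(trees, species, fallback = fallback)
  b_kg <- tree_biomass_kg(joined, policy = policy, profile = profile)
  ef <- expansion_factor(design$area_m2[ring])
  structure(sum(b_kg * ef) / 1000,
            n_trees = nrow(trees), n_filtered = n_filtered)
}

#' Per-plot AGB table for a whole tree list
#'
#' Applies [plot_agb()] to every plot in `trees` (grouped by `plot_id`).
#' Plots present in `plot_ids` but absent from `trees` get 0 t ha^-1
#' (measured plot with no trees in any measured class).
#'
#' @inheritParams plot_agb
#' @param plot_ids optional character vector of all measured plot ids.
#' @return A tibble with columns `plot_id`, `agb_t_ha`, `n_trees`,
#'   `n_filtered`.
#' @export
agb_by_plot <- function(trees, species, design = ccsp_design(),
                        plot_ids = NULL, fallback = TRUE,
                        policy = default_component_policy(),
                        profile = taper_parabolic) {
  ids <- if (is.null(plot_ids)) unique(trees$plot_id) else plot_ids
  rows <- lapply(ids, function(id) {
    sub <- trees[trees$plot_id == id, , drop = FALSE]
    est <- plot_agb(sub, species, design, fallback = fallback,
                    policy = policy, profile = profile)
    tibble::tibble(plot_id = id, agb_t_ha = as.numeric(est),
                   n_trees = attr(est, "n_trees"),
                   n_filtered = attr(est, "n_filtered"))
  })
  dplyr::bind_rows(rows)
}
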