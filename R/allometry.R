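#' Stem volume over bark from a log-linear allometric equation
#'
#' Computes stem volume as `exp(a + b*ln(d) + c*ln(h))`, the standard
#' log-linear form used by national allometry tables, with species-specific
#' coefficients `a`, `b`, `c`. Natural logarithms throughout.
#'
#' @param d diameter at breast height (DBH), cm. Must be positive.
#' @param h total tree height, m. Must be positive.
#' @param a,b,c species-specific coefficients (dimensionless).
#' @return Stem volume in m^3 (vectorised over `d`, `h`).
#' @examples
#' stem_volume(30, 20, a = -3.0, b = 1.9, c = 0.9)
#' @export
stem_volume <- function(d, h, a, b, c) {
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  check_number(h, "h", lower = 0, strict_lower = TRUE)
  exp(a + b * log(d) + c * log(h))
}

#' Relative stem diameter at a relative height (taper profile)
#'
#' The default taper profile is parabolic in cross-section: relative
#' diameter `(1 - rel_height)`, so the tree tapers linearly in diameter
#' from the base to zero at the tip. The original inventory used national
#' taper-curve parameters that are not publicly reproduced; any profile
#' can be supplied as a function via `profile`, and all partial-volume
#' arithmetic rescales the profile so that the full-stem integral matches
#' the allometric total volume, making unbroken-tree biomass insensitive
#' to the profile choice.
#'
#' @param rel_height height above ground as a fraction of total height,
#'   in `[0, 1]`.
#' @param profile a function mapping relative height to relative diameter;
#'   must be nonincreasing with `profile(1) == 0`.
#' @return Diameter as a fraction of basal diameter.
#' @examples
#' taper_relative_diameter(c(0, 0.5, 1))
#' @export
taper_relative_diameter <- function(rel_height, profile = taper_parabolic) {
  check_number(rel_height, "rel_height", lower = 0, upper = 1)
  profile(rel_height)
}

#' @rdname taper_relative_diameter
#' @export
taper_parabolic <- function(rel_height) 1 - rel_height

# Integral of the squared profile (cross-sectional area shape) over
# relative height [z1, z2] in [0, 1]. Quadrature tolerance is tight so
# consistency identities hold to ~1e-12 relative.
profile_area_integral <- function(z1, z2, profile) {
  if (z2 <= z1) return(0)
  stats::integrate(function(z) profile(z)^2, lower = z1, upper = z2,
                   rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Partial stem volume of a broken tree or stump
#'
#' Integrates cross-sectional area `pi/4 * diam(z)^2` along the taper
#' profile from stump height (0.15 m) up to the cut point, rescaled so
#' that the full-profile integral over the whole (modelled) stem equals
#' the allometric stem volume for (`dbh`, `height`). The result is
#' therefore always a fraction of [stem_volume()] for the same tree.
#'
#' @param dbh DBH, cm.
#' @param height total (modelled) tree height, m.
#' @param cut_height height of the break or cut point above ground, m.
#' @param a,b,c allometric volume coefficients (see [stem_volume()]).
#' @param stump_height lower integration bound, m (0.15 by the inventory
#'   protocol).
#' @param profile taper profile function (see [taper_relative_diameter()]).
#' @return Volume in m^3, in `(0, stem_volume(dbh, height))`. A cut point
#'   at or below stump height returns 0 with a warning.
#' @export
broken_stem_volume <- function(dbh, height, cut_height, a, b, c,
                               stump_height = 0.15,
                               profile = taper_parabolic) {
  check_number(dbh, "dbh", lower = 0, strict_lower = TRUE)
  check_number(height, "height", lower = 0, strict_lower = TRUE)
  check_number(cut_height, "cut_height", lower = 0)
  if (cut_height <= stump_height) {
    warning("cut point at or below stump height; returning 0 m^3",
            call. = FALSE)
    return(0)
  }
  z_top <- min(cut_height, height) / height
  v_total <- stem_volume(dbh, height, a, b, c)
  frac <- profile_area_integral(stump_height / height, z_top, profile) /
    profile_area_integral(0, 1, profile)
  v_total * frac
}

#' Stem biomass from volume and wood density
#'
#' @param volume stem volume, m^3 (nonnegative).
#' @param density air-dried wood density, kg m^-3 (positive).
#' @return Stem biomass in kg.
#' @examples
#' stem_biomass(0.8514, 640)
#' @export
stem_biomass <- function(volume, density) {
  check_number(volume, "volume", lower = 0)
  check_number(density, "density", lower = 0, strict_lower = TRUE)
  volume * density
}

#' Total tree biomass from stem biomass and component ratios
#'
#' Total biomass is stem + branch + foliage, with branch and foliage
#' biomass obtained from species-specific branch-to-stem and
#' foliage-to-stem ratios. Which components are included depends on tree
#' status. The default policy: live trees carry all three components;
#' standing dead trees carry stem + branch (foliage assumed shed); broken
#' trees and stumps carry the (partial) stem only. The inventory report
#' states only that dead, broken trees and stumps are included, so the
#' component policy is a documented package choice and can be overridden.
#'
#' @param stem_kg stem biomass, kg (for broken trees/stumps, the partial
#'   stem from [broken_stem_volume()] times density).
#' @param branch_ratio,foliage_ratio component-to-stem biomass ratios
#'   (nonnegative, dimensionless).
#' @param status one of `"live"`, `"dead"`, `"broken"`, `"stump"`.
#' @param policy named list giving, per status, which ratio components
#'   apply; see `default_component_policy()`.
#' @return Total biomass in kg, always `>= stem_kg`.
#' @examples
#' total_tree_biomass(100, 0.4, 0.1, "live") # 150
#' total_tree_biomass(100, 0.4, 0.1, "dead") # 140
#' @export
total_tree_biomass <- function(stem_kg, branch_ratio, foliage_ratio, status,
                               policy = default_component_policy()) {
  check_number(stem_kg, "stem_kg", lower = 0)
  check_number(branch_ratio, "branch_ratio", lower = 0)
  check_number(foliage_ratio, "foliage_ratio", lower = 0)
  status <- match.arg(status, c("live", "dead", "broken", "stump"))
  comp <- policy[[status]]
  rb <- if ("branch" %in% comp) branch_ratio else 0
  rf <- if ("foliage" %in% comp) foliage_ratio else 0
  stem_kg * (1 + rb + rf)
}

#' @rdname total_tree_biomass
#' @export
default_component_policy <- function() {
  list(live   = c("branch", "foliage"),
       dead   = "branch",
       broken = character(0),
       stump  = character(0))
}

#' Read and validate a species allometry table
#'
#' Expects a CSV with columns `species_code, a, b, c, density,
#' branch_ratio, foliage_ratio`. Validation failures report the
#' offending line numbers.
#'
#' @param path path to the CSV file.
#' @return A tibble with one row per species.
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(species_code = "character"))
  validate_species_table(tibble::as_tibble(df), context = path)
}

validate_species_table <- function(species, context = "species table") {
  required <- c("species_code", "a", "b", "c", "density",
                "branch_ratio", "foliage_ratio")
  missing <- setdiff(required, names(species))
  if (length(missing)) {
    stopf("%s: missing column(s) %s", context,
          paste(missing, collapse = ", "))
  }
  bad <- which(!(species$density > 0) | !(species$b > 0) |
                 !(species$c > 0) | species$branch_ratio < 0 |
                 species$foliage_ratio < 0)
  if (length(bad)) {
    stopf("%s: invalid allometry values at data line(s) %s",
          context, paste(bad + 1L, collapse = ", "))
  }
  if (anyDuplicated(species$species_code)) {
    stopf("%s: duplicated species_code", context)
  }
  species
}

# Region-level "average species" fallback row, mirroring national tables
# that assume average values for minor species.
average_species_row <- function(species) {
  tibble::tibble(
    species_code  = ".average",
    a             = mean(species$a),
    b             = mean(species$b),
    c             = mean(species$c),
    density       = mean(species$density),
    branch_ratio  = mean(species$branch_ratio),
    foliage_ratio = mean(species$foliage_ratio)
  )
}
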