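# Seeded synthetic inventory generator: clusters, plots, tree lists,
# species tables and soil samples with the structure the field design
# assumes, plus the generator's own ground-truth per-plot AGB and SOC
# for recovery tests.

regions <- c("Terai", "Siwalik", "MiddleMountain", "HighMountain",
             "HighHimal")

#' Configuration for the synthetic inventory generator
#'
#' Defaults describe a mid-hill broadleaf stand: 400 stems per hectare
#' above the 5 cm measurement threshold, DBH from a Weibull(shape 1.3,
#' scale 18 cm) truncated to \[5, 150\] cm (a right-skewed uneven-aged
#' diameter structure), heights from the allometric model
#' `h = alpha * d^beta * exp(eps)`, `eps ~ N(0, sigma^2)`, and mineral
#' soil with fine-fraction bulk density 0.8-1.4 g cm^-3, surface
#' Walkley-Black OC 1-3.5% declining with depth, and volumetric
#' stoniness up to 40%.
#'
#' The Terai region has 4 plots per cluster; the four mountain regions
#' have 6, matching the two cluster designs of the inventory.
#'
#' @param seed master seed; all per-plot substreams derive from it by
#'   stable hashing of the plot id, so generation order never matters.
#' @param n_clusters number of clusters to lay out on the 4 km grid.
#' @param region one of `"Terai"`, `"Siwalik"`, `"MiddleMountain"`,
#'   `"HighMountain"`, `"HighHimal"`.
#' @param n_species number of rows in the synthetic allometry table.
#' @param stems_per_ha stand density above the 5 cm DBH threshold.
#' @param dbh_weibull list with `shape` and `scale` (cm) of the Weibull
#'   DBH distribution, truncated to `[5, 150]` cm.
#' @param height_model list with `alpha`, `beta`, `sigma` of the
#'   lognormal height-diameter model.
#' @param status_probs named probabilities over
#'   `live`, `dead`, `broken`, `stump`; must sum to 1.
#' @param soil_params list with elements `bd` (bulk-density range,
#'   g cm^-3), `oc_surface` (surface-layer OC% range), `oc_depth_decay`
#'   (multiplicative decline per 10 cm layer), `stone` (stoniness range,
#'   %, max 95).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_clusters = 5L,
                             region = "MiddleMountain",
                             n_species = 12L,
                             stems_per_ha = 400,
                             dbh_weibull = list(shape = 1.3, scale = 18),
                             height_model = list(alpha = 1.3, beta = 0.75,
                                                 sigma = 0.15),
                             status_probs = c(live = 0.85, dead = 0.06,
                                              broken = 0.06, stump = 0.03),
                             soil_params = list(bd = c(0.8, 1.4),
                                                oc_surface = c(1.0, 3.5),
                                                oc_depth_decay = 0.6,
                                                stone = c(0, 40))) {
  region <- match.arg(region, regions)
  check_number(stems_per_ha, "stems_per_ha", lower = 0)
  check_number(dbh_weibull$shape, "dbh_weibull$shape", lower = 0,
               strict_lower = TRUE)
  check_number(dbh_weibull$scale, "dbh_weibull$scale", lower = 0,
               strict_lower = TRUE)
  check_number(height_model$sigma, "height_model$sigma", lower = 0)
  statuses <- c("live", "dead", "broken", "stump")
  if (!setequal(names(status_probs), statuses)) {
    stopf("status_probs must be named %s", paste(statuses, collapse = ", "))
  }
  status_probs <- status_probs[statuses]
  if (abs(sum(status_probs) - 1) > 1e-9 || any(status_probs < 0)) {
    stopf("status_probs must be nonnegative and sum to 1 (within 1e-9)")
  }
  check_number(soil_params$stone, "soil_params$stone", lower = 0, upper = 95)
  structure(list(seed = as.integer(seed), n_clusters = as.integer(n_clusters),
                 region = region, n_species = as.integer(n_species),
                 stems_per_ha = stems_per_ha, dbh_weibull = dbh_weibull,
                 height_model = height_model, status_probs = status_probs,
                 soil_params = soil_params),
            class = "synthetic_config")
}

plots_per_cluster <- function(region) if (region == "Terai") 4L else 6L

#' Generate a synthetic species allometry table
#'
#' Coefficient ranges are stand-ins chosen to produce plausible stem
#' volumes for the log-linear volume equation (the national tables are
#' not publicly reproduced): `a` in \[-4.5, -2.0\], `b` in \[1.5, 2.2\],
#' `c` in \[0.6, 1.1\], wood density in \[300, 900\] kg m^-3, branch
#' ratio in \[0.1, 0.6\], foliage ratio in \[0.02, 0.15\].
#'
#' @param n_species number of species rows (>= 1).
#' @param seed seed for this table.
#' @return A species tibble as accepted by [plot_agb()].
#' @export
gen_species_table <- function(n_species, seed = 1L) {
  if (!is.numeric(n_species) || n_species < 1) {
    stopf("`n_species` must be a positive integer")
  }
  n <- as.integer(n_species)
  with_substream(seed, "species", {
    tibble::tibble(
      species_code  = sprintf("SP%03d", seq_len(n)),
      a             = stats::runif(n, -4.5, -2.0),
      b             = stats::runif(n, 1.5, 2.2),
      c             = stats::runif(n, 0.6, 1.1),
      density       = stats::runif(n, 300, 900),
      branch_ratio  = stats::runif(n, 0.1, 0.6),
      foliage_ratio = stats::runif(n, 0.02, 0.15)
    )
  })
}

#' Lay out clusters and plots on the systematic grid
#'
#' Clusters sit on a 4 km square grid; within a cluster, plots are 300 m
#' apart along an L-shaped track (the within-cluster geometry is
#' metadata only and does not enter any estimate). Coordinates are
#' WGS84 degrees around a central-Nepal anchor.
#'
#' @param config a [synthetic_config()].
#' @return A tibble with columns `plot_id`, `cluster_id`, `region`,
#'   `longitude`, `latitude`.
#' @export
gen_cluster_plots <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_clusters
  ppc <- plots_per_cluster(config$region)
  ncol_grid <- ceiling(sqrt(n))
  lat0 <- 28.0
  lon0 <- 84.0
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(lat0 * pi / 180)
  # L-shaped track: north first, then east.
  north <- pmin(seq_len(ppc) - 1L, 3L) * 300
  east <- pmax(seq_len(ppc) - 4L, 0L) * 300
  rows <- lapply(seq_len(n), function(k) {
    gx <- ((k - 1L) %% ncol_grid) * 4000
    gy <- ((k - 1L) %/% ncol_grid) * 4000
    cluster_id <- sprintf("C%03d", k)
    tibble::tibble(
      plot_id    = sprintf("%s_P%d", cluster_id, seq_len(ppc)),
      cluster_id = cluster_id,
      region     = config$region,
      longitude  = lon0 + (gx + east) / m_per_deg_lon,
      latitude   = lat0 + (gy + north) / m_per_deg_lat
    )
  })
  dplyr::bind_rows(rows)
}

# Weibull CDF restricted to the DBH truncation window [5, 150] cm.
dbh_window <- c(5, 150)

trunc_weibull_probs <- function(lo, hi, wb) {
  lo <- max(lo, dbh_window[1])
  hi <- min(hi, dbh_window[2])
  if (hi <= lo) return(c(0, 0))
  stats::pweibull(c(lo, hi), shape = wb$shape, scale = wb$scale)
}

#' Generate the tree list of one plot
#'
#' Trees are drawn per DBH class: the expected count in each class is
#' `stems_per_ha * P(class) * subplot area in ha`, so smaller trees are
#' (realistically) sampled on smaller subplots and the expansion-factor
#' arithmetic is exercised nontrivially. Counts are Poisson; DBH within
#' a class comes from the truncated Weibull by inverse-CDF; heights from
#' the lognormal height model; statuses i.i.d. from `status_probs`.
#' Broken trees carry a cut point uniform on (20%, 90%) of total height;
#' stumps a cut height uniform on (0.3, 1.3) m. DBH is recorded at
#' 0.1 cm precision, as in the field protocol.
#'
#' @param plot_id plot identifier (drives the random substream).
#' @param config a [synthetic_config()].
#' @param species species table (codes are assigned uniformly).
#' @param design a [ccsp_design()].
#' @return A tree tibble as accepted by [plot_agb()], plus `bearing_deg`
#'   and `distance_m` columns (recorded in the field for relocation but
#'   unused by estimation).
#' @export
gen_plot_trees <- function(plot_id, config, species,
                           design = ccsp_design()) {
  stopifnot(inherits(config, "synthetic_config"), nrow(species) >= 1)
  wb <- config$dbh_weibull
  hm <- config$height_model
  p_window <- diff(stats::pweibull(dbh_window, shape = wb$shape,
                                   scale = wb$scale))
  with_substream(config$seed, paste0("trees:", plot_id), {
    per_ring <- lapply(seq_len(nrow(design)), function(r) {
      pr <- trunc_weibull_probs(design$dbh_min_cm[r], design$dbh_max_cm[r],
                                wb)
      p_class <- (pr[2] - pr[1]) / p_window
      lambda <- config$stems_per_ha * p_class * design$area_m2[r] / 10000
      n <- stats::rpois(1L, lambda)
      if (n == 0L) return(NULL)
      u <- stats::runif(n, pr[1], pr[2])
      dbh <- round(stats::qweibull(u, shape = wb$shape, scale = wb$scale), 1)
      tibble::tibble(dbh_cm = dbh)
    })
    trees <- dplyr::bind_rows(per_ring)
    n <- nrow(trees)
    if (n == 0L) {
      return(tibble::tibble(plot_id = character(), species_code = character(),
                            dbh_cm = numeric(), height_m = numeric(),
                            status = character(), cut_height_m = numeric(),
                            bearing_deg = numeric(), distance_m = numeric()))
    }
    height <- pmax(hm$alpha * trees$dbh_cm^hm$beta *
                     exp(stats::rnorm(n, 0, hm$sigma)), 1.35)
    status <- sample(names(config$status_probs), n, replace = TRUE,
                     prob = config$status_probs)
    cut <- rep(NA_real_, n)
    brk <- status == "broken"
    cut[brk] <- stats::runif(sum(brk), 0.2, 0.9) * height[brk]
    stp <- status == "stump"
    cut[stp] <- stats::runif(sum(stp), 0.3, 1.3)
    tibble::tibble(
      plot_id      = plot_id,
      species_code = sample(species$species_code, n, replace = TRUE),
      dbh_cm       = trees$dbh_cm,
      height_m     = round(height, 1),
      status       = status,
      cut_height_m = round(cut, 2),
      bearing_deg  = round(stats::runif(n, 0, 360), 1),
      distance_m   = round(stats::runif(n, 0, 20), 2)
    )
  })
}

#' Generate the three composite soil-layer samples of one plot
#'
#' One composite sample per depth layer (0-10, 10-20, 20-30 cm), pooled
#' over 4 pits. The layer OC% declines geometrically with depth by
#' `oc_depth_decay`; the coarse-fraction volume is a sub-proportion of
#' the field-observed stoniness applied to the composite volume; fine
#' mass follows from the drawn fine-fraction bulk density; oven-dry mass
#' adds the coarse fraction at a rock density of 2.6 g cm^-3.
#'
#' @param plot_id plot identifier (drives the random substream).
#' @param config a [synthetic_config()].
#' @param spec a [corer_spec()].
#' @param n_pits pits per composite (4 by design).
#' @return A tibble of three rows as accepted by [plot_soc()], with an
#'   additional `oven_dry_mass_g` column.
#' @export
gen_soil_samples <- function(plot_id, config, spec = corer_spec(),
                             n_pits = 4L) {
  stopifnot(inherits(config, "synthetic_config"))
  sp <- config$soil_params
  v_comp <- n_pits * corer_volume(spec)
  with_substream(config$seed, paste0("soil:", plot_id), {
    bd <- stats::runif(3, sp$bd[1], sp$bd[2])
    oc1 <- stats::runif(1, sp$oc_surface[1], sp$oc_surface[2])
    oc <- oc1 * sp$oc_depth_decay^(0:2) *
      exp(stats::rnorm(3, 0, 0.05))
    stone <- stats::runif(3, sp$stone[1], sp$stone[2])
    coarse_vol <- stats::runif(3, 0, stone / 100) * v_comp
    fine_mass <- bd * (v_comp - coarse_vol)
    tibble::tibble(
      plot_id           = plot_id,
      layer             = soc_layers,
      n_pits            = n_pits,
      oven_dry_mass_g   = round(fine_mass + 2.6 * coarse_vol, 1),
      fine_mass_g       = round(fine_mass, 1),
      coarse_volume_cm3 = round(coarse_vol, 1),
      oc_wb_pct         = round(oc, 2),
      stone_pct         = round(stone, 1)
    )
  })
}

#' Generate a full synthetic inventory with ground truth
#'
#' Produces the species table, plot layout, tree lists and soil samples
#' for every plot, and the generator's own per-plot ground-truth AGB and
#' SOC, computed through [agb_by_plot()] and [soc_by_plot()] on the
#' generated records (the same arithmetic path the estimation pipeline
#' uses, so recovery tests can demand exact agreement).
#'
#' @param config a [synthetic_config()].
#' @param design a [ccsp_design()].
#' @param spec a [corer_spec()].
#' @param species optional species table to use instead of generating
#'   one (e.g. to share a table across regional strata).
#' @return A list with tibbles `species`, `plots`, `trees`, `soil`,
#'   `ground_truth` (columns `plot_id`, `true_agb_t_ha`, `true_soc_t_ha`).
#' @export
gen_inventory <- function(config, design = ccsp_design(),
                          spec = corer_spec(), species = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(species)) {
    species <- gen_species_table(config$n_species, seed = config$seed)
  }
  plots <- gen_cluster_plots(config)
  trees <- dplyr::bind_rows(lapply(plots$plot_id, gen_plot_trees,
                                   config = config, species = species,
                                   design = design))
  soil <- dplyr::bind_rows(lapply(plots$plot_id, gen_soil_samples,
                                  config = config, spec = spec))
  agb <- agb_by_plot(trees, species, design, plot_ids = plots$plot_id)
  soc <- soc_by_plot(soil, spec = spec)
  truth <- dplyr::left_join(
    tibble::tibble(plot_id = plots$plot_id),
    tibble::tibble(plot_id = agb$plot_id, true_agb_t_ha = agb$agb_t_ha),
    by = "plot_id")
  truth <- dplyr::left_join(
    truth, tibble::tibble(plot_id = soc$plot_id,
                          true_soc_t_ha = soc$soc_t_ha),
    by = "plot_id")
  list(species = species, plots = plots, trees = trees, soil = soil,
       ground_truth = truth)
}

#' Write a synthetic inventory to plain CSV fixtures
#'
#' Writes `species.csv`, `plots.csv`, `trees.csv`, `soil.csv` and
#' `ground_truth.csv` (UTF-8, "." decimal separator) into `dir`.
#'
#' @param inventory result of [gen_inventory()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_inventory_csv <- function(inventory, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("species", "plots", "trees", "soil", "ground_truth")) {
    utils::write.csv(inventory[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8",
                     na = "")
  }
  invisible(dir)
}

#' Read inventory CSV fixtures back into tibbles
#'
#' @param dir directory holding the files written by
#'   [write_inventory_csv()].
#' @return A list of tibbles (`species`, `plots`, `trees`, `soil`, and
#'   `ground_truth` when present).
#' @export
read_inventory_csv <- function(dir) {
  read1 <- function(nm, classes = NA) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) return(NULL)
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                      colClasses = classes))
  }
  out <- list(
    species      = validate_species_table(
      read1("species", c(species_code = "character")), "species.csv"),
    plots        = read1("plots", c(plot_id = "character",
                                    cluster_id = "character")),
    trees        = read1("trees", c(plot_id = "character",
                                    species_code = "character")),
    soil         = read1("soil", c(plot_id = "character",
                                   layer = "character")),
    ground_truth = read1("ground_truth", c(plot_id = "character"))
  )
  out[!vapply(out, is.null, logical(1))]
}
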