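# Independent brute-force oracles: plain scalar loops, no shared code
# path with the package implementation (closed-form taper integral
# instead of quadrature, linear search instead of joins).

# Closed-form partial stem volume under the parabolic profile
# diam(z) ~ (1 - z/h): fraction of total volume between heights z1 < z2
# is (1 - z1/h)^3 - (1 - z2/h)^3.
oracle_partial_volume <- function(v_total, h, z1, z2) {
  z2 <- min(z2, h)
  v_total * ((1 - z1 / h)^3 - (1 - z2 / h)^3)
}

oracle_tree_biomass <- function(dbh, height, status, cut, sp) {
  v_full <- exp(sp$a + sp$b * log(dbh) + sp$c * log(height))
  if (status %in% c("live", "dead")) {
    v <- v_full
  } else {
    if (is.na(cut)) cut <- if (status == "stump") 0.15 else height
    v <- if (cut <= 0.15) 0 else oracle_partial_volume(v_full, height,
                                                       0.15, cut)
  }
  bs <- v * sp$density
  if (status == "live") {
    bs * (1 + sp$branch_ratio + sp$foliage_ratio)
  } else if (status == "dead") {
    bs * (1 + sp$branch_ratio)
  } else {
    bs
  }
}

# Plot AGB by explicit per-tree loop over the default CCSP design.
oracle_plot_agb <- function(trees, species) {
  rings <- list(c(5, 10, 4), c(10, 20, 8), c(20, 30, 15), c(30, Inf, 20))
  # average-species fallback computed by explicit column means
  avg <- list(a = mean(species$a), b = mean(species$b), c = mean(species$c),
              density = mean(species$density),
              branch_ratio = mean(species$branch_ratio),
              foliage_ratio = mean(species$foliage_ratio))
  total_kg_per_ha <- 0
  for (i in seq_len(nrow(trees))) {
    if (!(trees$status[i] %in% c("live", "dead", "broken", "stump"))) next
    d <- trees$dbh_cm[i]
    ring <- NULL
    for (r in rings) if (d >= r[1] && d < r[2]) ring <- r
    if (is.null(ring)) next
    row <- which(species$species_code == trees$species_code[i])
    sp <- if (length(row) == 1) as.list(species[row, ]) else avg
    b <- oracle_tree_biomass(d, trees$height_m[i], trees$status[i],
                             trees$cut_height_m[i], sp)
    total_kg_per_ha <- total_kg_per_ha + b * 10000 / (pi * ring[3]^2)
  }
  total_kg_per_ha / 1000
}

# Plot SOC by explicit spreadsheet-style chain over the three layers.
oracle_plot_soc <- function(samples, correction = 1.33) {
  corer_cm3 <- pi * (3.7 / 2)^2 * 10
  total <- 0
  for (i in seq_len(nrow(samples))) {
    v_fine <- samples$n_pits[i] * corer_cm3 - samples$coarse_volume_cm3[i]
    bd <- samples$fine_mass_g[i] / v_fine
    ocf <- samples$oc_wb_pct[i] * correction / 100
    soc <- bd * ocf * (100 - samples$stone_pct[i]) / 100
    total <- total + soc * 10 * 100
  }
  total
}

# Mean of a Weibull truncated to [lo, hi], by quadrature.
trunc_weibull_mean <- function(shape, scale, lo = 5, hi = 150) {
  p <- stats::pweibull(c(lo, hi), shape, scale)
  stats::integrate(function(x) x * stats::dweibull(x, shape, scale),
                   lo, hi, rel.tol = 1e-10)$value / (p[2] - p[1])
}

# Small hand-built fixtures used across test files.
fixture_species <- function() {
  tibble::tibble(
    species_code  = c("S1", "S2"),
    a             = c(-3.0, -2.5),
    b             = c(1.9, 1.8),
    c             = c(0.9, 0.8),
    density       = c(550, 700),
    branch_ratio  = c(0.4, 0.2),
    foliage_ratio = c(0.1, 0.05)
  )
}

fixture_soil_layers <- function(plot_id = "p1", oc = c(2.5, 1.5, 0.9),
                                stone = c(10, 20, 30),
                                fine = c(420, 400, 380),
                                coarse = c(20, 35, 50), n_pits = 4) {
  tibble::tibble(
    plot_id = plot_id, layer = c("0-10", "10-20", "20-30"),
    n_pits = n_pits, fine_mass_g = fine, coarse_volume_cm3 = coarse,
    oc_wb_pct = oc, stone_pct = stone
  )
}
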