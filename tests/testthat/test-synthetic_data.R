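test_that("species table generation is seeded and range-bounded", {
  expect_identical(gen_species_table(8, seed = 7), gen_species_table(8, seed = 7))
  sp <- gen_species_table(20, seed = 1)
  expect_equal(nrow(sp), 20)
  expect_true(all(sp$density >= 300 & sp$density <= 900))
  expect_true(all(sp$a >= -4.5 & sp$a <= -2.0))
  expect_true(all(sp$b >= 1.5 & sp$b <= 2.2))
  expect_true(all(sp$c >= 0.6 & sp$c <= 1.1))
  expect_true(all(sp$branch_ratio >= 0.1 & sp$branch_ratio <= 0.6))
  expect_true(all(sp$foliage_ratio >= 0.02 & sp$foliage_ratio <= 0.15))
  expect_error(gen_species_table(0), "positive")
  # every generated species yields a finite positive volume at (30 cm, 20 m)
  sp5 <- gen_species_table(5, seed = 3)
  v <- exp(sp5$a + sp5$b * log(30) + sp5$c * log(20)) # independent evaluation
  expect_equal(stem_volume(30, 20, sp5$a, sp5$b, sp5$c), v)
  expect_true(all(is.finite(v) & v > 0))
})

test_that("cluster layout follows the region's plot count on the grid", {
  terai <- gen_cluster_plots(synthetic_config(seed = 2, n_clusters = 3,
                                              region = "Terai"))
  expect_equal(nrow(terai), 12) # 3 clusters x 4 plots
  mm <- gen_cluster_plots(synthetic_config(seed = 2, n_clusters = 5,
                                           region = "MiddleMountain"))
  expect_equal(nrow(mm), 30) # 5 clusters x 6 plots
  expect_false(anyDuplicated(mm$plot_id) > 0)
  expect_identical(mm, gen_cluster_plots(
    synthetic_config(seed = 2, n_clusters = 5, region = "MiddleMountain")))
})

test_that("config validation rejects malformed inputs", {
  expect_error(synthetic_config(status_probs = c(live = 0.9, dead = 0.2,
                                                 broken = 0, stump = 0)),
               "sum to 1")
  expect_error(synthetic_config(status_probs = c(live = 1, dead = 0)),
               "named")
  expect_error(synthetic_config(dbh_weibull = list(shape = 0, scale = 18)))
  expect_error(synthetic_config(region = "Lowlands"))
  expect_error(synthetic_config(
    soil_params = list(bd = c(0.8, 1.4), oc_surface = c(1, 3),
                       oc_depth_decay = 0.6, stone = c(0, 99))),
    "stone")
})

test_that("tree lists respect the measurement design and status model", {
  cfg0 <- synthetic_config(seed = 5, stems_per_ha = 0)
  sp <- gen_species_table(4, seed = 5)
  expect_equal(nrow(gen_plot_trees("z", cfg0, sp)), 0)

  cfg <- synthetic_config(seed = 5, stems_per_ha = 800)
  tr <- gen_plot_trees("a_plot", cfg, sp)
  expect_true(all(tr$dbh_cm >= 5.0))
  expect_true(all(tr$height_m > 1.3))
  expect_true(all(tr$status %in% c("live", "dead", "broken", "stump")))
  brk <- tr$status == "broken"
  expect_true(all(tr$cut_height_m[brk] < tr$height_m[brk]))
  expect_true(all(is.na(tr$cut_height_m[tr$status %in% c("live", "dead")])))

  all_live <- synthetic_config(seed = 5, stems_per_ha = 800,
                               status_probs = c(live = 1, dead = 0,
                                                broken = 0, stump = 0))
  expect_true(all(gen_plot_trees("a_plot", all_live, sp)$status == "live"))
})

test_that("per-plot substreams make generation order-independent", {
  cfg <- synthetic_config(seed = 31)
  sp <- gen_species_table(4, seed = 31)
  a1 <- gen_plot_trees("p_A", cfg, sp)
  b1 <- gen_plot_trees("p_B", cfg, sp)
  b2 <- gen_plot_trees("p_B", cfg, sp) # regenerate B first this time
  a2 <- gen_plot_trees("p_A", cfg, sp)
  expect_identical(a1, a2)
  expect_identical(b1, b2)
})

test_that("soil samples have the three design layers and consistent masses", {
  cfg <- synthetic_config(seed = 9)
  s <- gen_soil_samples("p1", cfg)
  expect_equal(s$layer, c("0-10", "10-20", "20-30"))
  expect_true(all(s$fine_mass_g <= s$oven_dry_mass_g))
  expect_true(all(s$coarse_volume_cm3 < s$n_pits * corer_volume()))
  expect_true(all(s$stone_pct >= 0 & s$stone_pct <= 95))
  expect_identical(s, gen_soil_samples("p1", cfg))
  # stoniness disabled: adjustment is the identity, so plot SOC equals
  # the unadjusted chain
  cfg0 <- synthetic_config(seed = 9,
                           soil_params = list(bd = c(0.8, 1.4),
                                              oc_surface = c(1, 3),
                                              oc_depth_decay = 0.6,
                                              stone = c(0, 0)))
  s0 <- gen_soil_samples("p1", cfg0)
  expect_true(all(s0$stone_pct == 0))
  expect_equal(plot_soc(s0), oracle_plot_soc(s0), tolerance = 1e-12)
})

test_that("full inventory generation is deterministic with complete ground truth", {
  cfg <- synthetic_config(seed = 77, n_clusters = 2)
  inv1 <- gen_inventory(cfg)
  inv2 <- gen_inventory(cfg)
  expect_identical(inv1, inv2)
  expect_equal(inv1$ground_truth$plot_id, inv1$plots$plot_id)
  expect_true(all(inv1$ground_truth$true_agb_t_ha >= 0))
  expect_true(all(inv1$ground_truth$true_soc_t_ha >= 0))
})

test_that("inventory CSV fixtures round-trip through the readers", {
  cfg <- synthetic_config(seed = 15, n_clusters = 1)
  inv <- gen_inventory(cfg)
  dir <- withr::local_tempdir()
  write_inventory_csv(inv, dir)
  expect_true(all(file.exists(file.path(
    dir, c("species.csv", "plots.csv", "trees.csv", "soil.csv",
           "ground_truth.csv")))))
  back <- read_inventory_csv(dir)
  expect_equal(back$species$species_code, inv$species$species_code)
  expect_equal(nrow(back$trees), nrow(inv$trees))
  res <- run_pipeline(back, quiet = TRUE)
  expect_equal(res$estimates$soc_t_ha,
               inv$ground_truth$true_soc_t_ha, tolerance = 1e-9)
})

test_that("design-weighted mean DBH converges to the truncated Weibull mean", {
  # raw tree lists are size-biased by subplot area, so the design-unbiased
  # estimator weights each tree by its expansion factor
  cfg <- synthetic_config(seed = 123, n_clusters = 2, region = "Terai",
                          stems_per_ha = 30000)
  sp <- gen_species_table(3, seed = 123)
  plots <- gen_cluster_plots(cfg)
  tr <- dplyr::bind_rows(lapply(plots$plot_id, gen_plot_trees,
                                config = cfg, species = sp))
  expect_gte(nrow(tr), 10000)
  design <- ccsp_design()
  w <- expansion_factor(design$area_m2[assign_subplot(tr$dbh_cm, design)])
  m_hat <- sum(w * tr$dbh_cm) / sum(w)
  se <- sqrt(sum(w^2 * (tr$dbh_cm - m_hat)^2)) / sum(w)
  mu <- trunc_weibull_mean(cfg$dbh_weibull$shape, cfg$dbh_weibull$scale)
  expect_lt(abs(m_hat - mu), 3 * se)
})
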