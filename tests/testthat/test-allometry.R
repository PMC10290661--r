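test_that("stem volume follows the log-linear equation", {
  # all-zero coefficients force exp(0) = 1 m^3 regardless of size
  expect_equal(stem_volume(30, 20, 0, 0, 0), 1.0)
  expect_equal(stem_volume(7.3, 4.1, 0, 0, 0), 1.0)
  # direct transcendental evaluation, frozen from an independent calculator
  expect_equal(stem_volume(30, 20, a = -3.0, b = 1.9, c = 0.9),
               472.68730040322595, tolerance = 1e-9)
  # power-law scaling: doubling d with b = 2 multiplies V by exactly 4
  expect_equal(stem_volume(24, 15, -2.8, 2, 0.7),
               4 * stem_volume(12, 15, -2.8, 2, 0.7))
  expect_error(stem_volume(0, 10, -3, 1.9, 0.9), "d")
  expect_error(stem_volume(10, -1, -3, 1.9, 0.9), "h")
})

test_that("stem volume is strictly increasing in d and h when b, c > 0", {
  set.seed(11)
  for (i in 1:25) {
    a <- runif(1, -4.5, -2); b <- runif(1, 1.5, 2.2); c <- runif(1, 0.6, 1.1)
    d <- runif(1, 5, 120); h <- runif(1, 2, 40)
    expect_gt(stem_volume(d * 1.01, h, a, b, c), stem_volume(d, h, a, b, c))
    expect_gt(stem_volume(d, h * 1.01, a, b, c), stem_volume(d, h, a, b, c))
  }
})

test_that("taper profile is nonincreasing with zero diameter at the tip", {
  expect_equal(taper_relative_diameter(1), 0)
  expect_equal(taper_relative_diameter(0.5), 0.5) # parabolic: 1 - z
  v <- taper_relative_diameter(c(0, 0.5, 0.9))
  expect_true(all(diff(v) <= 0))
  expect_error(taper_relative_diameter(1.2), "rel_height")
  expect_error(taper_relative_diameter(-0.1), "rel_height")
})

test_that("broken-stem volume matches the closed-form partial integral", {
  sp <- fixture_species()[1, ]
  d <- 28; h <- 18
  v_full <- stem_volume(d, h, sp$a, sp$b, sp$c)
  for (cut in c(0.5, 2, 9, 13.7, 17.9)) {
    expect_equal(
      broken_stem_volume(d, h, cut, sp$a, sp$b, sp$c),
      oracle_partial_volume(v_full, h, 0.15, cut),
      tolerance = 1e-9)
  }
  # monotonically increasing in cut height, bounded by the full stem
  cuts <- seq(0.2, h, length.out = 20)
  vols <- vapply(cuts, function(cc)
    broken_stem_volume(d, h, cc, sp$a, sp$b, sp$c), numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < v_full))
})

test_that("cutting at the tip recovers the full stem minus the stump segment", {
  sp <- fixture_species()[2, ]
  for (h in c(4, 11, 26)) {
    d <- 20
    v_full <- stem_volume(d, h, sp$a, sp$b, sp$c)
    v_above_stump <- broken_stem_volume(d, h, h, sp$a, sp$b, sp$c)
    stump_segment <- oracle_partial_volume(v_full, h, 0, 0.15)
    expect_equal(v_above_stump + stump_segment, v_full,
                 tolerance = 1e-9)
  }
  expect_warning(
    expect_equal(broken_stem_volume(25, 15, 0.1, -3, 1.9, 0.9), 0),
    "stump height")
})

test_that("stem biomass is volume times wood density", {
  expect_equal(stem_biomass(1, 500), 500)
  expect_equal(stem_biomass(0, 640), 0)
  expect_equal(stem_biomass(0.8514, 640), 544.896)
  expect_error(stem_biomass(-0.1, 500), "volume")
})

test_that("component policy controls total tree biomass by status", {
  expect_equal(total_tree_biomass(100, 0.4, 0.1, "live"), 150)
  expect_equal(total_tree_biomass(100, 0.4, 0.1, "dead"), 140)
  expect_equal(total_tree_biomass(100, 0.4, 0.1, "broken"), 100)
  expect_equal(total_tree_biomass(100, 0.4, 0.1, "stump"), 100)
  expect_equal(total_tree_biomass(250, 0, 0, "live"), 250)
  # a custom policy can include foliage on dead trees
  pol <- default_component_policy()
  pol$dead <- c("branch", "foliage")
  expect_equal(total_tree_biomass(100, 0.4, 0.1, "dead", policy = pol), 150)
  # total is never below stem, for any status and ratio draw
  set.seed(21)
  for (i in 1:20) {
    bs <- runif(1, 0, 2000)
    st <- sample(c("live", "dead", "broken", "stump"), 1)
    expect_gte(total_tree_biomass(bs, runif(1, 0, 1), runif(1, 0, 0.3), st),
               bs)
  }
})

test_that("species table reading validates schema with line context", {
  path <- withr::local_tempfile(fileext = ".csv")
  sp <- fixture_species()
  utils::write.csv(sp, path, row.names = FALSE, quote = FALSE)
  back <- read_species_table(path)
  expect_equal(back$density, sp$density)
  # a nonpositive density is rejected, naming the data line
  bad <- sp
  bad$density[2] <- -5
  utils::write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_species_table(path), "line\\(s\\) 3")
  utils::write.csv(sp[, -2], path, row.names = FALSE, quote = FALSE)
  expect_error(read_species_table(path), "missing column")
})
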