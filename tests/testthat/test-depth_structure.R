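test_that("depth binning pools transects and normalizes by summed length", {
  obs <- data.frame(
    site = "s1",
    depth = c(12, 15, 15),
    transect_id = c("t1", "t2", "t2"),
    transect_length = c(30, 60, 60),
    species = c("X", "X", "Y"),
    count = c(3, 6, 12))
  comm <- bin_depths(obs, width = 10)
  # depth 12 and 15 share bin [10, 20); effort = 30 + 60
  expect_equal(nrow(comm$abundance), 1)
  expect_equal(comm$info$depth_lower, 10)
  expect_equal(unname(comm$abundance[1, "X"]), (3 + 6) / 90)
  expect_equal(unname(comm$abundance[1, "Y"]), 12 / 90)
  expect_error(bin_depths(transform(obs, depth = c(-1, 15, 15))), "negative")
})

test_that("bin edges are half-open and empty bins are absent", {
  obs <- data.frame(site = "s1", depth = c(10, 19.9, 30),
                    transect_id = c("t1", "t1", "t2"),
                    transect_length = 50, species = c("A", "B", "A"),
                    count = 1)
  comm <- bin_depths(obs, width = 10)
  expect_equal(sort(unique(comm$info$depth_lower)), c(10, 30))
})

test_that("zone assignment respects site overrides and range checks", {
  sch <- zone_scheme(site_breaks = list(
    roatan = c(altiphotic = 0, upper_mesophotic = 30, lower_mesophotic = 90,
               upper_rariphotic = 130, lower_rariphotic = 200,
               below_rariphotic = 300)))
  expect_equal(assign_zone(sch, c(5, 45, 135, 250, 400)),
               c("altiphotic", "upper_mesophotic", "upper_rariphotic",
                 "lower_rariphotic", "below_rariphotic"))
  expect_equal(assign_zone(sch, 35, site = "roatan"), "upper_mesophotic")
  expect_equal(assign_zone(sch, 35, site = "curacao"), "altiphotic")
  expect_error(zone_scheme(c(a = 10, b = 5)), "increasing")
})

test_that("the 75% rule picks the shortest contiguous qualifying run", {
  zl <- c("altiphotic", "mesophotic", "rariphotic")
  # 75% in one zone -> specialist
  a <- assign_affinity(stats::setNames(c(0, 0.80, 0.20), zl))
  expect_equal(a$label, "mesophotic")
  # straddling two zones -> hyphenated pair
  b <- assign_affinity(stats::setNames(c(0.40, 0.40, 0.20), zl))
  expect_equal(b$label, "altiphotic-mesophotic")
  expect_equal(b$zones, zl[1:2])
  # single zone holds everything
  expect_equal(assign_affinity(stats::setNames(c(0, 0, 1), zl))$label,
               "rariphotic")
  # three zones needed -> generalist
  g <- assign_affinity(stats::setNames(c(0.3, 0.3, 0.4), zl))
  expect_equal(g$label, "generalist")
  expect_length(g$zones, 3)
  # ties on run length resolved by larger share, then shallower
  t1 <- assign_affinity(stats::setNames(c(0.10, 0.76, 0.14), zl))
  expect_equal(t1$label, "mesophotic")
  expect_error(assign_affinity(stats::setNames(c(0.5, 0.4, 0.2), zl)),
               "sum to 1")
  expect_error(assign_affinity(stats::setNames(numeric(3), zl)), "empty")
})

test_that("zone profiles and affinities cover every species exactly once", {
  gen <- generate_communities(synthetic_config(n_species = 40, n_sites = 2),
                              seed = 3)
  comm <- bin_depths(gen$observations, effort = gen$effort)
  shares <- species_zone_profiles(comm, zone_scheme())
  expect_equal(unname(rowSums(shares)), rep(1, nrow(shares)),
               tolerance = 1e-12)
  aff <- depth_affinities(shares)
  expect_setequal(aff$species, colnames(comm$abundance))
  expect_false(anyDuplicated(aff$species) > 0)
  # labels invariant to scaling all abundances
  comm2 <- comm
  comm2$abundance <- comm2$abundance * 7
  aff2 <- depth_affinities(species_zone_profiles(comm2, zone_scheme()))
  expect_equal(aff2$affinity, aff$affinity)
})

test_that("zone hulls are nested within the pooled hull", {
  gen <- generate_communities(synthetic_config(n_species = 60, n_sites = 2),
                              seed = 8)
  tt <- trait_table(gen$traits, taxonomy_cols = c("genus", "family"))
  btm <- expand_traits(tt)
  comm <- bin_depths(gen$observations, effort = gen$effort)
  obs_sp <- colnames(comm$abundance)
  ts <- build_trait_space(bathyfd:::btm_subset(btm, obs_sp))
  zs <- zone_trait_summary(ts$space, comm, zone_scheme())
  expect_true(all(zs$summary$area <= zs$pooled_area + 1e-12))
  expect_true(all(zs$summary$area_fraction <= 1 + 1e-12))
  # a zone containing every species fills the pooled hull exactly
  one_zone <- zone_scheme(breaks = c(everything = 0))
  zs1 <- zone_trait_summary(ts$space, comm, one_zone)
  expect_equal(zs1$summary$area_fraction, 1)
})

test_that("affinity hulls are checked against their zone hulls", {
  gen <- generate_communities(synthetic_config(n_species = 60, n_sites = 2),
                              seed = 12)
  tt <- trait_table(gen$traits, taxonomy_cols = c("genus", "family"))
  btm <- expand_traits(tt)
  comm <- bin_depths(gen$observations, effort = gen$effort)
  obs_sp <- colnames(comm$abundance)
  ts <- build_trait_space(bathyfd:::btm_subset(btm, obs_sp))
  aff <- depth_affinities(species_zone_profiles(comm, zone_scheme()))
  asum <- affinity_trait_summary(ts$space, aff, comm, zone_scheme())
  # an affinity group is a subset of the species observed in its zones,
  # so its hull area cannot exceed the zone hull area
  expect_true(all(asum$summary$area <= asum$summary$zone_area + 1e-12))
  expect_true(all(asum$summary$contained_in_zone_hull |
                    asum$summary$n_species < 3))
})
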