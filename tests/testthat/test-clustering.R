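two_block_profiles <- function(seed = 1, n_per = 6, p = 10) {
  set.seed(seed)
  # two groups of bins using disjoint category sets
  a <- cbind(matrix(runif(n_per * p / 2, 1, 2), n_per),
             matrix(0, n_per, p / 2))
  b <- cbind(matrix(0, n_per, p / 2),
             matrix(runif(n_per * p / 2, 1, 2), n_per))
  x <- rbind(a, b)
  rownames(x) <- paste0("bin", seq_len(2 * n_per))
  x
}

test_that("trait-frequency profiles are abundance-weighted category shares", {
  df <- data.frame(species = c("A", "B"), t1 = c("x", "y"), t2 = c("u", "u"))
  m <- expand_traits(trait_table(df))
  comm <- structure(list(
    abundance = matrix(c(2, 0, 1, 1), 2, 2, byrow = TRUE,
                       dimnames = list(c("b1", "b2"), c("A", "B"))),
    info = data.frame(community_id = c("b1", "b2"), site = "pooled",
                      depth_lower = c(0, 10), depth_mid = c(5, 15)),
    width = 10), class = "depth_communities")
  prof <- trait_frequency_profiles(comm, m)
  # single-species bin -> its one-hot pattern
  expect_equal(unname(prof["b1", ]), c(1, 0, 1))
  # two equal-abundance species differing in one trait -> 0.5 there
  expect_equal(unname(prof["b2", ]), c(0.5, 0.5, 1))
})

test_that("default trait schema yields 32 categories", {
  schema <- default_trait_schema()
  expect_equal(sum(lengths(schema)), 32)
  gen <- generate_communities(synthetic_config(n_species = 20, n_sites = 1),
                              seed = 1)
  m <- expand_traits(trait_table(gen$traits,
                                 schema = attr(gen$traits, "schema"),
                                 taxonomy_cols = c("genus", "family")))
  expect_equal(ncol(m), 32)
})

test_that("Bray-Curtis matches the formula oracle and a reference implementation", {
  set.seed(4)
  x <- matrix(rexp(6 * 7), 6, 7, dimnames = list(paste0("r", 1:6), NULL))
  bc <- bray_curtis(x)
  expect_equal(bc, oracle_bray_curtis(x), tolerance = 1e-12)
  expect_equal(unname(bc), unname(as.matrix(vegan::vegdist(x))),
               tolerance = 1e-12)
  # identical rows -> 0; disjoint supports -> 1
  y <- rbind(c(1, 2, 0, 0), c(1, 2, 0, 0), c(0, 0, 3, 1))
  bcy <- bray_curtis(y)
  expect_equal(bcy[1, 2], 0)
  expect_equal(bcy[1, 3], 1)
  # scaling a row leaves its zero/identity structure but BC is not scale-free
  # per row; scaling ALL rows by one constant changes nothing
  expect_equal(bray_curtis(x * 3), bc)
  expect_error(bray_curtis(rbind(x, 0)), "all-zero")
})

test_that("Ward heights reproduce the Lance-Williams recursion", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 3), n)
    dm <- as.matrix(dist(pts))
    hc <- ward_dendrogram(dm)
    expect_equal(sort(hc$height), sort(oracle_ward_heights(dm)),
                 tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
  # n = 2: a single merge at the pairwise distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  hc2 <- ward_dendrogram(d2)
  expect_equal(hc2$height, 3)
})

test_that("SIMPROF keeps homogeneous data together and splits clear blocks", {
  # identical rows -> a single cluster with pi = 0
  x <- matrix(rep(c(1, 2, 3, 4), each = 8), 8, 4)
  x <- x + 0 # numeric
  rownames(x) <- paste0("b", 1:8)
  # identical rows make Bray-Curtis all zero; hclust handles zero heights
  res <- simprof(x, alpha = 0.05, n_expected = 99, n_null = 99, seed = 1)
  expect_equal(max(res$partition), 1)
  expect_equal(res$tests$pi[1], 0)

  y <- two_block_profiles(seed = 2)
  res2 <- simprof(y, alpha = 0.05, n_expected = 199, n_null = 199, seed = 5)
  expect_equal(max(res2$partition), 2)
  expect_equal(length(unique(res2$partition[1:6])), 1)
  expect_equal(length(unique(res2$partition[7:12])), 1)
})

test_that("SIMPROF partition is invariant to row order at a fixed seed", {
  y <- two_block_profiles(seed = 3)
  res <- simprof(y, alpha = 0.05, n_expected = 99, n_null = 99, seed = 11)
  set.seed(42)
  perm <- sample(nrow(y))
  res_p <- simprof(y[perm, ], alpha = 0.05, n_expected = 99, n_null = 99,
                   seed = 11)
  # same grouping of the same labels
  for (cl in unique(res$partition)) {
    labs <- names(res$partition)[res$partition == cl]
    expect_length(unique(res_p$partition[labs]), 1)
  }
})

test_that("smaller alpha never yields a finer SIMPROF partition", {
  y <- two_block_profiles(seed = 6) +
    matrix(runif(120, 0, 0.5), 12, 10)
  res_tight <- simprof(y, alpha = 0.005, n_expected = 199, n_null = 199,
                       seed = 3)
  res_loose <- simprof(y, alpha = 0.5, n_expected = 199, n_null = 199,
                       seed = 3)
  expect_lte(max(res_tight$partition), max(res_loose$partition))
})

test_that("alpha below the permutation resolution behaves like the limit", {
  y <- two_block_profiles(seed = 9)
  res <- simprof(y, alpha = 1e-7, n_expected = 99, n_null = 99, seed = 2)
  expect_equal(res$alpha_effective, 1 / 100)
  expect_equal(max(res$partition), 2)
  expect_error(simprof(y, alpha = 0, seed = 1), "alpha")
})

test_that("deepest split depth is located only for depth-structured branches", {
  y <- two_block_profiles(seed = 10)
  depths <- seq(0, 110, by = 10)
  res <- simprof(y, alpha = 0.05, n_expected = 199, n_null = 199, seed = 7)
  expect_equal(deepest_split_depth(res, depths), 60)
})

test_that("PERMANOVA separates clear groups and stays null-calibrated", {
  y <- two_block_profiles(seed = 13)
  fac <- data.frame(group = rep(c("top", "bottom"), each = 6))
  res <- permanova_profiles(bray_curtis(y), fac, n_perm = 199, seed = 1)
  expect_lte(res$p[res$term == "group"], 0.01)
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_equal(sum(res$r2[res$term != "Total"]), 1)

  # identical group structure -> roughly uniform p under the null
  set.seed(20)
  ps <- replicate(30, {
    x <- matrix(rexp(12 * 6), 12, 6)
    f <- data.frame(g = rep(c("a", "b"), each = 6))
    permanova_profiles(bray_curtis(x), f, n_perm = 99,
                       seed = sample.int(1e6, 1))$p[1]
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps <= 0.05), 0.35)
})

test_that("dendrograms export to Newick and read back", {
  y <- two_block_profiles(seed = 15)
  hc <- ward_dendrogram(bray_curtis(y))
  tmp <- tempfile(fileext = ".nwk")
  write_newick(hc, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, rownames(y))
})
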