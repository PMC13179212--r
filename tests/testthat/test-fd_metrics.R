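make_space <- function(coords) {
  structure(list(coordinates = coords,
                 eigenvalues = rep(1, ncol(coords)),
                 variance_fractions = rep(1 / ncol(coords), ncol(coords)),
                 cailliez_constant = 0),
            class = "trait_space")
}

test_that("CWM follows the square-root-weighted proportion formula", {
  df <- data.frame(species = c("A", "B"), t1 = c("x", "y"))
  m <- expand_traits(trait_table(df))
  # species A (a=4, carries x) + species B (a=1, does not) -> CWM_x = 2/3
  v <- cwm(c(A = 4, B = 1), m)
  expect_equal(unname(v["t1::x"]), 2 / 3)
  expect_equal(unname(v["t1::y"]), 1 / 3)
  # single-species community -> its own binary row
  expect_equal(unname(cwm(c(A = 7), m)), unname(unclass(m)["A", ]))
  # all species carry a category -> CWM 1
  df2 <- data.frame(species = c("A", "B"), t1 = c("x", "x"))
  m2 <- expand_traits(trait_table(df2))
  expect_equal(unname(cwm(c(A = 2, B = 5), m2)["t1::x"]), 1)
  expect_error(cwm(numeric(0), m), "empty")
})

test_that("CWM stays in [0, 1] and trait blocks sum within bounds", {
  for (seed in 1:5) {
    m <- random_btm(9, seed)
    ab <- stats::setNames(runif(9, 0.1, 5), rownames(m))
    v <- cwm(ab, m)
    expect_true(all(v >= 0 & v <= 1))
    for (tr in unique(attr(m, "trait"))) {
      s <- sum(v[attr(m, "trait") == tr])
      expect_gte(s, 1 - 1e-12)
      expect_lte(s, sum(attr(m, "trait") == tr) + 1e-12)
    }
  }
})

test_that("functional richness is the convex-hull area on two axes", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  rownames(sq) <- letters[1:4]
  sp <- make_space(sq)
  expect_equal(functional_richness(sp, letters[1:4]), 1)
  # adding an interior point leaves the hull unchanged
  sq5 <- rbind(sq, e = c(0.5, 0.5))
  expect_equal(functional_richness(make_space(sq5), letters[1:5]), 1)
  # degenerate (collinear) -> 0 with warning
  line <- matrix(c(0, 0, 1, 1, 2, 2), 3, 2, byrow = TRUE)
  rownames(line) <- letters[1:3]
  expect_warning(a <- functional_richness(make_space(line), letters[1:3]))
  expect_equal(a, 0)
})

test_that("hull areas match the gift-wrapping oracle on random points", {
  for (seed in 1:20) {
    set.seed(seed)
    xy <- matrix(rnorm(40), 20, 2)
    rownames(xy) <- sprintf("s%02d", 1:20)
    expect_equal(functional_richness(make_space(xy), rownames(xy)),
                 oracle_hull_area(xy), tolerance = 1e-10)
  }
})

test_that("functional richness is monotone under species addition", {
  set.seed(5)
  xy <- matrix(rnorm(30), 15, 2)
  rownames(xy) <- sprintf("s%02d", 1:15)
  sp <- make_space(xy)
  a_sub <- functional_richness(sp, rownames(xy)[1:8])
  a_all <- functional_richness(sp, rownames(xy))
  expect_gte(a_all, a_sub)
})

test_that("functional evenness hits its analytic limits and oracle", {
  # equally spaced on a line, equal abundances -> FEve = 1
  line <- cbind(0:4, 0)
  rownames(line) <- letters[1:5]
  ab <- stats::setNames(rep(2, 5), letters[1:5])
  expect_equal(functional_evenness(make_space(line), ab), 1)
  # 3 species at 0, 1, 10 with equal abundances: direct formula
  pts <- cbind(c(0, 1, 10), 0)
  rownames(pts) <- letters[1:3]
  ab3 <- stats::setNames(rep(1, 3), letters[1:3])
  # MST edges 0-1 (d=1) and 1-10 (d=9); equal weights -> PEW = (0.1, 0.9)
  expect_equal(functional_evenness(make_space(pts), ab3),
               (min(0.1, 0.5) + min(0.9, 0.5) - 0.5) / (1 - 0.5))
  # scale invariance
  expect_equal(functional_evenness(make_space(pts * 100), ab3),
               functional_evenness(make_space(pts), ab3))
  # undefined below 3 species
  expect_warning(v <- functional_evenness(make_space(pts[1:2, ]), ab3[1:2]))
  expect_true(is.na(v))
})

test_that("functional dispersion limits and oracle agreement", {
  pts <- rbind(a = c(0, 0), b = c(3, 4))
  sp <- make_space(pts)
  expect_equal(functional_dispersion(sp, c(a = 1)), 0)
  # two equal species at distance 5 -> 5/2
  expect_equal(functional_dispersion(sp, c(a = 2, b = 2)), 2.5)
})

test_that("Rao, Simpson and redundancy limits", {
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  ab <- c(a = 1, b = 2, c = 3)
  r0 <- rao_simpson_redundancy(d0, ab)
  expect_equal(r0$rao_q, 0)
  expect_equal(r0$redundancy, r0$simpson)
  d1 <- 1 - diag(3)
  dimnames(d1) <- dimnames(d0)
  r1 <- rao_simpson_redundancy(d1, ab)
  expect_equal(r1$rao_q, r1$simpson)
  expect_equal(r1$redundancy, 0)
  d_bad <- d1 * 2
  expect_error(rao_simpson_redundancy(d_bad, ab), "\\[0, 1\\]")
})

test_that("weighted metrics are invariant to species ordering", {
  m <- random_btm(8, 2)
  set.seed(2)
  coords <- matrix(rnorm(24), 8, 3)
  rownames(coords) <- rownames(m)
  sp <- make_space(coords)
  ab <- stats::setNames(runif(8, 0.5, 4), rownames(m))
  g <- gower_dist(m)
  perm <- sample(8)
  expect_equal(functional_dispersion(sp, ab[perm]),
               functional_dispersion(sp, ab))
  expect_equal(functional_evenness(sp, ab[perm]),
               functional_evenness(sp, ab))
  r1 <- rao_simpson_redundancy(g, ab)
  r2 <- rao_simpson_redundancy(g, ab[perm])
  expect_equal(r1, r2)
  expect_equal(cwm(ab[perm], m), cwm(ab, m))
})

test_that("Rao's Q is invariant to splitting a species into identical copies", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))
  base <- rao_simpson_redundancy(d, c(a = 4, b = 1), sqrt_transform = FALSE)
  # split a into two identical copies with d = 0 between them
  d3 <- matrix(c(0, 0, 0.4, 0, 0, 0.4, 0.4, 0.4, 0), 3, 3,
               dimnames = list(c("a1", "a2", "b"), c("a1", "a2", "b")))
  dup <- rao_simpson_redundancy(d3, c(a1 = 2, a2 = 2, b = 1),
                                sqrt_transform = FALSE)
  expect_equal(dup$rao_q, base$rao_q)
})

test_that("rarefaction matches exhaustive subset enumeration", {
  set.seed(9)
  x <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8,
              dimnames = list(paste0("u", 1:5), paste0("s", 1:8)))
  x[1, ] <- c(1, 1, 0, 0, 0, 0, 0, 0) # ensure non-degenerate
  exact <- rarefaction(x, method = "exact")
  expect_equal(exact$mean, oracle_rarefaction_exact(x), tolerance = 1e-12)
  mc <- rarefaction(x, method = "montecarlo", n_draws = 3000, seed = 4)
  expect_equal(mc$mean, exact$mean, tolerance = 0.05)
  # endpoints are deterministic
  expect_equal(mc$mean[5], exact$mean[5])
})

test_that("rarefaction limit cases: one unit and identical units", {
  one <- matrix(c(1, 0, 1), 1, 3)
  r1 <- rarefaction(one)
  expect_equal(r1$size, 1)
  expect_equal(r1$mean, 2)
  same <- matrix(rep(c(1, 1, 0, 1), 4), 4, 4, byrow = TRUE)
  rs <- rarefaction(same, method = "exact")
  expect_equal(rs$mean, rep(3, 4))
})

test_that("rarefaction collapses taxa to entities via groups", {
  x <- matrix(c(1, 1, 0,
                0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("u1", "u2"), c("s1", "s2", "s3")))
  groups <- c(s1 = "E1", s2 = "E1", s3 = "E2")
  r <- rarefaction(x, groups = groups, method = "exact")
  # u1 holds E1 only; u2 holds E1 and E2
  expect_equal(r$mean[1], mean(c(1, 2)))
  expect_equal(r$mean[2], 2)
})
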