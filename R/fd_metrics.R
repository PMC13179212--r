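# Community-level functional diversity: community-weighted means, convex-hull
# richness, minimum-spanning-tree evenness, dispersion, Rao quadratic entropy
# and Simpson-minus-Rao redundancy, plus sample-based rarefaction.

# -- small planar-geometry helpers (2-D hulls) -------------------------------

convex_hull <- function(xy) {
  xy <- xy[!duplicated(xy), , drop = FALSE]
  if (nrow(xy) < 3) return(xy)
  h <- grDevices::chull(xy)
  xy[h, , drop = FALSE]
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  nxt <- c(2:n, 1)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

hull_area <- function(xy) polygon_area(convex_hull(xy))

points_in_hull <- function(pts, poly, tol = 1e-9) {
  if (nrow(poly) < 3) {
    # degenerate hull: containment only if points coincide with its span
    return(vapply(seq_len(nrow(pts)), function(i) {
      any(apply(poly, 1, function(v) all(abs(v - pts[i, ]) <= tol)))
    }, logical(1)))
  }
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  ex <- poly[nxt, 1] - poly[, 1]
  ey <- poly[nxt, 2] - poly[, 2]
  # chull vertices come out clockwise; orient via signed area
  x <- poly[, 1]; y <- poly[, 2]
  orient <- sign(sum(x * y[nxt] - x[nxt] * y))
  scale_ref <- max(abs(poly)) + 1
  vapply(seq_len(nrow(pts)), function(i) {
    cr <- ex * (pts[i, 2] - poly[, 2]) - ey * (pts[i, 1] - poly[, 1])
    all(orient * cr >= -tol * scale_ref)
  }, logical(1))
}

# retain class/attributes when row-subsetting a binary trait matrix
btm_subset <- function(matrix, rows) {
  structure(unclass(matrix)[rows, , drop = FALSE],
            trait = attr(matrix, "trait"),
            category = attr(matrix, "category"),
            weights = attr(matrix, "weights"),
            class = class(matrix))
}

abundance_weights <- function(abundances, sqrt_transform) {
  stopifnot(all(abundances >= 0))
  if (all(abundances == 0)) stop("community has no abundance", call. = FALSE)
  w <- if (sqrt_transform) sqrt(abundances) else abundances
  w / sum(w)
}

# -- metrics -----------------------------------------------------------------

#' Community-weighted means of binary trait categories
#'
#' For a binary category, the CWM is the proportion of the (square-root
#' transformed, by default) community abundance carried by species displaying
#' that category: `CWM_k = sum_s sqrt(a_s) x_sk / sum_s sqrt(a_s)`, bounded in
#' `[0, 1]`. The square-root transform damps extremely abundant species
#' without over-weighting rare ones.
#'
#' @param abundances named non-negative numeric vector (species -> abundance).
#' @param matrix a `binary_trait_matrix` covering those species.
#' @param sqrt_transform apply the square-root transform (default `TRUE`).
#' @return Named numeric vector, one CWM per trait category.
#' @export
cwm <- function(abundances, matrix, sqrt_transform = TRUE) {
  if (!length(abundances)) stop("empty community", call. = FALSE)
  sp <- names(abundances)
  if (is.null(sp) || !all(sp %in% rownames(matrix))) {
    stop("all community species must be rows of the trait matrix",
         call. = FALSE)
  }
  w <- abundance_weights(abundances, sqrt_transform)
  drop(w %*% unclass(matrix)[sp, , drop = FALSE])
}

#' Functional richness (2-D convex-hull area)
#'
#' Area of the convex hull of the community's species on the selected trait
#' space axes (first two by default). Abundance plays no role. Fewer than
#' three distinct points, or collinear points, give area 0 with a warning.
#'
#' @param space a `trait_space`.
#' @param species character vector of species present.
#' @param axes length-2 integer vector of axis indices.
#' @return Hull area in squared trait-space units.
#' @export
functional_richness <- function(space, species, axes = c(1, 2)) {
  stopifnot(inherits(space, "trait_space"), length(axes) == 2)
  xy <- space_coords(space, species, axes)
  xy <- xy[!duplicated(xy), , drop = FALSE]
  a <- hull_area(xy)
  if (a == 0) {
    warning("degenerate community (fewer than 3 distinct points or ",
            "collinear); functional richness is 0")
  }
  a
}

space_coords <- function(space, species, axes = NULL) {
  missing <- setdiff(species, rownames(space$coordinates))
  if (length(missing)) {
    stop("species not in trait space: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(axes)) axes <- seq_len(ncol(space$coordinates))
  if (max(axes) > ncol(space$coordinates)) {
    stop("requested axes exceed the trait space dimension", call. = FALSE)
  }
  space$coordinates[species, axes, drop = FALSE]
}

#' Functional evenness (regularity along the minimum spanning tree)
#'
#' Villeger et al. (2008): build the minimum spanning tree over the
#' community's species in trait space; each edge between species i and j gets
#' weight `EW = dist(i, j) / (w_i + w_j)` with `w` the relative abundances;
#' after normalizing to `PEW = EW / sum(EW)`,
#' `FEve = (sum min(PEW, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`.
#' Equal abundances on equally spaced species give FEve = 1.
#'
#' @param space a `trait_space`.
#' @param abundances named non-negative numeric vector of the community.
#' @param axes axis indices (default: all retained axes).
#' @param sqrt_transform square-root transform abundances before normalizing.
#' @return FEve in `(0, 1]`, or `NA` with a warning when fewer than 3 species.
#' @export
functional_evenness <- function(space, abundances, axes = NULL,
                                sqrt_transform = TRUE) {
  s <- length(abundances)
  if (s < 3) {
    warning("functional evenness undefined for fewer than 3 species")
    return(NA_real_)
  }
  coords <- space_coords(space, names(abundances), axes)
  w <- abundance_weights(abundances, sqrt_transform)
  tr <- vegan::spantree(stats::dist(coords))
  i <- 2:s
  j <- tr$kid
  ew <- tr$dist / (w[i] + w[j])
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional dispersion (abundance-weighted mean distance to centroid)
#'
#' Laliberte & Legendre (2010): distance of each species to the
#' abundance-weighted centroid of the community in trait space, averaged with
#' the same abundance weights.
#'
#' @inheritParams functional_evenness
#' @return FDis >= 0 (0 for a single species).
#' @export
functional_dispersion <- function(space, abundances, axes = NULL,
                                  sqrt_transform = TRUE) {
  coords <- space_coords(space, names(abundances), axes)
  w <- abundance_weights(abundances, sqrt_transform)
  centroid <- drop(w %*% coords)
  dists <- sqrt(rowSums((coords - matrix(centroid, nrow(coords),
                                         ncol(coords), byrow = TRUE))^2))
  sum(w * dists)
}

#' Rao quadratic entropy, Simpson diversity and functional redundancy
#'
#' Ricotta et al. (2016) decomposition: with relative abundances `p` and
#' pairwise trait dissimilarities `d` in `[0, 1]`, Rao's
#' `Q = sum_ij d_ij p_i p_j` is the trait-aware diversity, Simpson's
#' `D = 1 - sum p_i^2` the taxonomic diversity, and redundancy `R = D - Q`
#' measures how much taxonomic diversity is functionally duplicated.
#' Requires the uncorrected Gower matrix: additive-constant corrected
#' distances exceed 1 and break the decomposition.
#'
#' @param d species x species dissimilarity matrix in `[0, 1]` with labels.
#' @param abundances named non-negative numeric vector of the community.
#' @param sqrt_transform square-root transform abundances before normalizing.
#' @return Named list with `rao_q`, `simpson`, `redundancy`.
#' @export
rao_simpson_redundancy <- function(d, abundances, sqrt_transform = TRUE) {
  sp <- names(abundances)
  if (is.null(sp) || !all(sp %in% rownames(d))) {
    stop("all community species must be labelled in the distance matrix",
         call. = FALSE)
  }
  dd <- d[sp, sp, drop = FALSE]
  if (any(dd < 0) || any(dd > 1 + 1e-12)) {
    stop("redundancy requires dissimilarities in [0, 1] ",
         "(use the uncorrected Gower matrix)", call. = FALSE)
  }
  p <- abundance_weights(abundances, sqrt_transform)
  q <- drop(p %*% dd %*% p)
  simpson <- 1 - sum(p^2)
  list(rao_q = q, simpson = simpson, redundancy = simpson - q)
}

#' Sample-based rarefaction of species or entity richness
#'
#' Expected richness as a function of the number of sampling units (transects
#' or depth bins) accumulated, either by Monte-Carlo resampling of unit
#' subsets or by the exact hypergeometric formula
#' `E[S_k] = sum_s (1 - C(n - m_s, k) / C(n, k))` where `m_s` is the number of
#' units containing taxon `s`.
#'
#' @param x units x taxa matrix; any positive value counts as an occurrence.
#' @param groups optional named vector mapping taxa (columns) to groups, e.g.
#'   functional entities; occurrences are collapsed by group before rarefying.
#' @param method `"montecarlo"` (default) or `"exact"`.
#' @param n_draws Monte-Carlo draws per subset size.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return data.frame with columns `size`, `mean`, `sd` (`sd` is `NA` for the
#'   exact method).
#' @export
rarefaction <- function(x, groups = NULL, method = c("montecarlo", "exact"),
                        n_draws = 200, seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(x) > 0
  if (!is.null(groups)) {
    if (is.null(colnames(x)) || !all(colnames(x) %in% names(groups))) {
      stop("`groups` must name every column of `x`", call. = FALSE)
    }
    g <- groups[colnames(x)]
    x <- t(rowsum(t(x + 0), group = g)) > 0
  }
  n <- nrow(x)
  if (n == 1) {
    return(data.frame(size = 1, mean = sum(colSums(x) > 0), sd = 0))
  }
  m_s <- colSums(x)
  m_s <- m_s[m_s > 0]
  if (method == "exact") {
    means <- vapply(seq_len(n), function(k) {
      sum(1 - exp(lchoose(n - m_s, k) - lchoose(n, k)))
    }, numeric(1))
    return(data.frame(size = seq_len(n), mean = means, sd = NA_real_))
  }
  set.seed(seed)
  out <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    rich <- vapply(seq_len(n_draws), function(b) {
      idx <- sample.int(n, k)
      sum(colSums(x[idx, , drop = FALSE]) > 0)
    }, numeric(1))
    out[k, ] <- c(mean(rich), stats::sd(rich))
  }
  data.frame(size = seq_len(n), mean = out[, 1], sd = out[, 2])
}

#' Per-community functional diversity metrics
#'
#' Builds one pooled trait space over all species observed across the
#' communities, then computes species and entity richness, FRic (first two
#' axes by default), FEve and FDis (all retained axes), Rao's Q, Simpson
#' diversity and redundancy for every community.
#'
#' @param communities a `depth_communities` object from [bin_depths()].
#' @param matrix a `binary_trait_matrix` covering every observed species.
#' @param axes_fric axes used for the convex hull.
#' @param sqrt_transform square-root transform abundances for the weighted
#'   metrics.
#' @return data.frame: one row per community with its metadata and metrics.
#' @export
community_metrics <- function(communities, matrix, axes_fric = c(1, 2),
                              sqrt_transform = TRUE) {
  ab <- communities$abundance
  sp <- colnames(ab)
  missing <- setdiff(sp, rownames(matrix))
  if (length(missing)) {
    stop("observed species missing from the trait matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  btm <- btm_subset(matrix, sp)
  ts <- build_trait_space(btm)
  ents <- derive_entities(btm)
  info <- communities$info
  res <- lapply(seq_len(nrow(ab)), function(i) {
    a <- ab[i, ]
    a <- a[a > 0]
    spp <- names(a)
    rsr <- rao_simpson_redundancy(ts$gower, a, sqrt_transform)
    fric <- if (length(spp) >= 3) {
      suppressWarnings(functional_richness(ts$space, spp, axes_fric))
    } else 0
    feve <- suppressWarnings(
      functional_evenness(ts$space, a, sqrt_transform = sqrt_transform))
    data.frame(
      species_richness = length(spp),
      entity_richness = length(unique(ents$entity[spp])),
      fric = fric,
      feve = feve,
      fdis = functional_dispersion(ts$space, a,
                                   sqrt_transform = sqrt_transform),
      rao_q = rsr$rao_q,
      simpson = rsr$simpson,
      redundancy = rsr$redundancy)
  })
  cbind(info, do.call(rbind, res))
}

#' Community-weighted means for every community
#'
#' @inheritParams community_metrics
#' @return communities x categories matrix of CWM values in `[0, 1]`.
#' @export
community_cwm <- function(communities, matrix, sqrt_transform = TRUE) {
  ab <- communities$abundance
  out <- t(apply(ab, 1, function(a) {
    a <- a[a > 0]
    cwm(a, matrix, sqrt_transform)
  }))
  rownames(out) <- communities$info$community_id
  out
}
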