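# Depth binning of transect observations, depth-zone schemes, the 75%
# abundance-share depth-affinity classifier, and per-zone / per-affinity trait
# space summaries.

#' Bin transect observations into per-site depth-bin communities
#'
#' Observations are pooled into half-open depth bins `[d, d + width)` per
#' site. Within a bin, counts are summed over transects and divided by the
#' summed transect length, giving densities (individuals per metre of
#' transect) that are comparable across bins with unequal effort.
#'
#' @param observations data.frame with columns `site`, `depth` (m),
#'   `transect_id`, `transect_length` (m), `species`, `count`.
#' @param width bin width in metres (default 10).
#' @param effort optional data.frame (`site`, `depth`, `transect_id`,
#'   `transect_length`) listing all transects including those with no fish;
#'   defaults to the transects present in `observations`.
#' @return Object of class `depth_communities`: list with `abundance`
#'   (community x species density matrix), `info` (data.frame `community_id`,
#'   `site`, `depth_lower`, `depth_mid`) and `width`.
#' @export
bin_depths <- function(observations, width = 10, effort = NULL) {
  req <- c("site", "depth", "transect_id", "transect_length", "species",
           "count")
  missing_col <- setdiff(req, names(observations))
  if (length(missing_col)) {
    stop("observations lack column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  if (any(observations$depth < 0)) {
    stop("negative depths are not allowed", call. = FALSE)
  }
  obs <- observations
  obs$bin <- floor(obs$depth / width) * width
  obs$comm <- paste(obs$site, obs$bin, sep = "_d")

  if (is.null(effort)) {
    eff_rows <- obs[!duplicated(obs[c("comm", "transect_id")]),
                    c("comm", "transect_length")]
  } else {
    effort$bin <- floor(effort$depth / width) * width
    effort$comm <- paste(effort$site, effort$bin, sep = "_d")
    eff_rows <- effort[!duplicated(effort[c("comm", "transect_id")]),
                       c("comm", "transect_length")]
  }
  eff <- tapply(eff_rows$transect_length, eff_rows$comm, sum)

  counts <- tapply(obs$count, list(obs$comm, obs$species), sum,
                   default = 0)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  dens <- counts / as.numeric(eff[rownames(counts)])

  meta <- obs[!duplicated(obs$comm), c("comm", "site", "bin")]
  meta <- meta[match(rownames(dens), meta$comm), ]
  info <- data.frame(community_id = meta$comm, site = meta$site,
                     depth_lower = meta$bin, depth_mid = meta$bin + width / 2,
                     stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(info$site, info$depth_lower)
  structure(list(abundance = dens[ord, , drop = FALSE], info = info[ord, ],
                 width = width),
            class = "depth_communities")
}

#' @export
print.depth_communities <- function(x, ...) {
  cat("Depth communities:", nrow(x$abundance), "site x bin communities,",
      ncol(x$abundance), "species,", x$width, "m bins\n")
  invisible(x)
}

#' Pool communities across sites per depth bin
#'
#' Sums species densities over sites sharing a depth bin, yielding one
#' community per bin (the input to the trait-profile dendrogram).
#'
#' @param communities a `depth_communities` object.
#' @return A `depth_communities` object with one row per depth bin and
#'   `site = "pooled"`.
#' @export
pool_sites <- function(communities) {
  ab <- communities$abundance
  bins <- communities$info$depth_lower
  pooled <- rowsum(ab, group = bins)
  lower <- as.numeric(rownames(pooled))
  ord <- order(lower)
  pooled <- pooled[ord, , drop = FALSE]
  lower <- lower[ord]
  info <- data.frame(community_id = paste0("pooled_d", lower),
                     site = "pooled", depth_lower = lower,
                     depth_mid = lower + communities$width / 2,
                     stringsAsFactors = FALSE)
  rownames(pooled) <- info$community_id
  structure(list(abundance = pooled, info = info, width = communities$width),
            class = "depth_communities")
}

#' Depth-zone scheme
#'
#' Ordered, contiguous, half-open depth zones `[lower_i, lower_{i+1})`, the
#' last zone extending to infinity. The default reflects the depth limits of
#' taxonomically distinct Caribbean reef-fish communities: altiphotic
#' (< 40 m), upper mesophotic (40-90), lower mesophotic (90-130), upper
#' rariphotic (130-200), lower rariphotic (200-300) and below-rariphotic
#' (> 300 m). Site-specific overrides replace the default wholesale for that
#' site.
#'
#' @param breaks named increasing numeric vector of zone lower limits (m).
#' @param site_breaks optional named list `site -> breaks vector` of
#'   overrides.
#' @return Object of class `zone_scheme`.
#' @export
zone_scheme <- function(breaks = c(altiphotic = 0, upper_mesophotic = 40,
                                   lower_mesophotic = 90,
                                   upper_rariphotic = 130,
                                   lower_rariphotic = 200,
                                   below_rariphotic = 300),
                        site_breaks = NULL) {
  check_breaks <- function(b) {
    if (is.null(names(b)) || any(!nzchar(names(b)))) {
      stop("zone breaks must be named by zone", call. = FALSE)
    }
    if (is.unsorted(b, strictly = TRUE)) {
      stop("zone lower limits must be strictly increasing", call. = FALSE)
    }
    b
  }
  check_breaks(breaks)
  if (!is.null(site_breaks)) lapply(site_breaks, check_breaks)
  structure(list(default = breaks, site = site_breaks,
                 zones = names(breaks)),
            class = "zone_scheme")
}

#' Assign depths to zones
#'
#' @param scheme a [zone_scheme()].
#' @param depth numeric vector of depths (m).
#' @param site optional site name (scalar or vector) selecting site-specific
#'   limits.
#' @return Character vector of zone names (ordered-factor levels available via
#'   `scheme$zones`).
#' @export
assign_zone <- function(scheme, depth, site = NULL) {
  stopifnot(inherits(scheme, "zone_scheme"))
  pick <- function(s) {
    if (!is.null(s) && !is.null(scheme$site) && s %in% names(scheme$site)) {
      scheme$site[[s]]
    } else scheme$default
  }
  if (is.null(site) || length(unique(site)) <= 1) {
    b <- pick(if (is.null(site)) NULL else site[1])
    if (any(depth < b[1])) {
      stop("depth shallower than the scheme's range", call. = FALSE)
    }
    return(names(b)[findInterval(depth, b)])
  }
  mapply(function(d, s) {
    b <- pick(s)
    if (d < b[1]) stop("depth shallower than the scheme's range",
                       call. = FALSE)
    names(b)[findInterval(d, b)]
  }, depth, site, USE.NAMES = FALSE)
}

#' Per-species depth-zone abundance profiles
#'
#' For every species, the share of its abundance falling in each depth zone.
#' By default a zone's abundance is the species' mean density over the bins it
#' occupies within that zone, so that wide zones (spanning many bins) do not
#' dominate the profile; `stat = "sum"` uses raw summed densities instead.
#'
#' @param communities a `depth_communities` object.
#' @param scheme a [zone_scheme()].
#' @param stat `"mean"` (default) or `"sum"`.
#' @return species x zone matrix of shares (rows sum to 1); the unnormalized
#'   values are kept in attribute `raw`.
#' @export
species_zone_profiles <- function(communities, scheme,
                                  stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  ab <- communities$abundance
  zones <- assign_zone(scheme, communities$info$depth_mid,
                       communities$info$site)
  zl <- scheme$zones
  raw <- sapply(zl, function(z) {
    rows <- which(zones == z)
    if (!length(rows)) return(numeric(ncol(ab)))
    sub <- ab[rows, , drop = FALSE]
    if (stat == "sum") {
      colSums(sub)
    } else {
      occ <- colSums(sub > 0)
      tot <- colSums(sub)
      ifelse(occ > 0, tot / pmax(occ, 1), 0)
    }
  })
  rownames(raw) <- colnames(ab)
  tot <- rowSums(raw)
  if (any(tot == 0)) {
    stop("species with no abundance in any zone: ",
         paste(utils::head(rownames(raw)[tot == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  shares <- raw / tot
  attr(shares, "raw") <- raw
  shares
}

#' Classify a species' depth affinity from zone abundance shares
#'
#' A species' depth affinity is the shortest contiguous run of depth zones
#' capturing at least `threshold` (75% by default) of its abundance. Among
#' runs of equal length, the one with the higher total share wins; remaining
#' ties go to the shallower run. One zone gives a specialist label, two
#' adjacent zones a hyphenated generalist label, and three or more zones the
#' label `"generalist"`.
#'
#' @param shares named numeric vector of zone shares in shallow-to-deep order,
#'   summing to 1 (within 1e-9).
#' @param threshold abundance share defining the affinity (default 0.75).
#' @return list with `label`, `zones` (character vector of the run) and
#'   `share` (total share captured).
#' @export
assign_affinity <- function(shares, threshold = 0.75) {
  if (!length(shares) || all(shares == 0)) {
    stop("empty zone profile", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("zone shares must sum to 1", call. = FALSE)
  }
  k <- length(shares)
  zl <- names(shares)
  for (len in seq_len(k)) {
    starts <- seq_len(k - len + 1)
    sums <- vapply(starts, function(s) sum(shares[s:(s + len - 1)]),
                   numeric(1))
    ok <- which(sums >= threshold - 1e-12)
    if (length(ok)) {
      best <- ok[order(-sums[ok], starts[ok])][1]
      run <- zl[starts[best]:(starts[best] + len - 1)]
      label <- if (len == 1) {
        run
      } else if (len == 2) {
        paste(run, collapse = "-")
      } else "generalist"
      return(list(label = label, zones = run, share = sums[best]))
    }
  }
  stop("no contiguous run reaches the threshold (shares may be invalid)",
       call. = FALSE)
}

#' Depth affinities for all species
#'
#' @param profiles species x zone share matrix from
#'   [species_zone_profiles()].
#' @param threshold abundance share defining the affinity (default 0.75).
#' @return data.frame with columns `species`, `affinity`, `share`, plus a
#'   list-column `zones`.
#' @export
depth_affinities <- function(profiles, threshold = 0.75) {
  res <- lapply(seq_len(nrow(profiles)), function(i) {
    assign_affinity(profiles[i, ], threshold)
  })
  out <- data.frame(species = rownames(profiles),
                    affinity = vapply(res, `[[`, character(1), "label"),
                    share = vapply(res, `[[`, numeric(1), "share"),
                    stringsAsFactors = FALSE)
  out$zones <- lapply(res, `[[`, "zones")
  out
}

pooled_species_abundance <- function(communities, rows = NULL) {
  ab <- communities$abundance
  if (!is.null(rows)) ab <- ab[rows, , drop = FALSE]
  colSums(ab)
}

hull_summary_row <- function(space, species, weights, axes, pooled_area) {
  poly <- if (length(species)) {
    convex_hull(space_coords(space, species, axes))
  } else matrix(numeric(0), 0, 2)
  area <- polygon_area(poly)
  centroid <- if (length(species)) {
    w <- weights / sum(weights)
    drop(w %*% space_coords(space, species, axes))
  } else c(NA_real_, NA_real_)
  list(polygon = poly, area = area, centroid = centroid,
       fraction = if (pooled_area > 0) area / pooled_area else NA_real_)
}

#' Trait-space occupancy of each depth zone
#'
#' For every depth zone, the convex hull (on the chosen axes) of the species
#' observed in that zone's communities, its area, its share of the pooled
#' hull area, and the abundance-weighted trait centroid.
#'
#' @param space a `trait_space` over the observed species.
#' @param communities a `depth_communities` object.
#' @param scheme a [zone_scheme()].
#' @param axes length-2 axis selection for the hulls.
#' @param sqrt_transform square-root transform abundances for the centroid.
#' @return list with `summary` (data.frame: zone, n_species, area,
#'   area_fraction, centroid_1, centroid_2), `polygons` (named list),
#'   `pooled_polygon` and `pooled_area`.
#' @export
zone_trait_summary <- function(space, communities, scheme, axes = c(1, 2),
                               sqrt_transform = TRUE) {
  zones <- assign_zone(scheme, communities$info$depth_mid,
                       communities$info$site)
  all_ab <- pooled_species_abundance(communities)
  all_sp <- names(all_ab)[all_ab > 0]
  pooled_polygon <- convex_hull(space_coords(space, all_sp, axes))
  pooled_area <- polygon_area(pooled_polygon)
  rows <- lapply(scheme$zones, function(z) {
    zab <- pooled_species_abundance(communities, which(zones == z))
    sp <- names(zab)[zab > 0]
    w <- if (sqrt_transform) sqrt(zab[sp]) else zab[sp]
    hull_summary_row(space, sp, w, axes, pooled_area)
  })
  names(rows) <- scheme$zones
  summary <- data.frame(
    zone = scheme$zones,
    n_species = vapply(scheme$zones, function(z) {
      zab <- pooled_species_abundance(communities, which(zones == z))
      sum(zab > 0)
    }, integer(1)),
    area = vapply(rows, `[[`, numeric(1), "area"),
    area_fraction = vapply(rows, `[[`, numeric(1), "fraction"),
    centroid_1 = vapply(rows, function(r) r$centroid[1], numeric(1)),
    centroid_2 = vapply(rows, function(r) r$centroid[2], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, polygons = lapply(rows, `[[`, "polygon"),
       pooled_polygon = pooled_polygon, pooled_area = pooled_area)
}

#' Trait-space occupancy of depth-affinity groups
#'
#' For every depth-affinity group, the convex hull of its member species, its
#' area, the abundance-weighted centroid, and a containment check against the
#' hull of the communities observed in the group's corresponding depth
#' zone(s).
#'
#' @param space a `trait_space`.
#' @param affinities data.frame from [depth_affinities()].
#' @param communities a `depth_communities` object.
#' @param scheme a [zone_scheme()].
#' @param axes length-2 axis selection.
#' @param sqrt_transform square-root transform abundances for centroids.
#' @return list with `summary` (data.frame: affinity, n_species, area,
#'   zone_area, area_fraction_of_zone, contained_in_zone_hull) and `polygons`.
#' @export
affinity_trait_summary <- function(space, affinities, communities, scheme,
                                   axes = c(1, 2), sqrt_transform = TRUE) {
  zones <- assign_zone(scheme, communities$info$depth_mid,
                       communities$info$site)
  all_ab <- pooled_species_abundance(communities)
  labels <- unique(affinities$affinity)
  rows <- lapply(labels, function(lab) {
    sub <- affinities[affinities$affinity == lab, ]
    sp <- sub$species
    run <- unique(unlist(sub$zones))
    zab <- pooled_species_abundance(communities, which(zones %in% run))
    zone_sp <- names(zab)[zab > 0]
    zone_poly <- if (length(zone_sp)) {
      convex_hull(space_coords(space, zone_sp, axes))
    } else matrix(numeric(0), 0, 2)
    w <- all_ab[sp]
    if (sqrt_transform) w <- sqrt(w)
    if (all(w == 0)) w <- rep(1, length(sp))
    r <- hull_summary_row(space, sp, w, axes, polygon_area(zone_poly))
    pts <- space_coords(space, sp, axes)
    contained <- nrow(zone_poly) >= 3 && all(points_in_hull(pts, zone_poly))
    c(r, list(zone_area = polygon_area(zone_poly), contained = contained,
              n_species = length(sp)))
  })
  names(rows) <- labels
  summary <- data.frame(
    affinity = labels,
    n_species = vapply(rows, `[[`, integer(1), "n_species"),
    area = vapply(rows, `[[`, numeric(1), "area"),
    zone_area = vapply(rows, `[[`, numeric(1), "zone_area"),
    area_fraction_of_zone = vapply(rows, `[[`, numeric(1), "fraction"),
    contained_in_zone_hull = vapply(rows, `[[`, logical(1), "contained"),
    centroid_1 = vapply(rows, function(r) r$centroid[1], numeric(1)),
    centroid_2 = vapply(rows, function(r) r$centroid[2], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, polygons = lapply(rows, `[[`, "polygon"))
}
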