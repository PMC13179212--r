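# Synthetic depth-structured reef-fish communities with known ground truth.
# Species follow Gaussian depth-response curves confined to pool segments
# separated by community-break depths; trait assignment and abundance are
# filtered against depth windows, emulating environmental filtering; counts
# come from Poisson sampling of transects.

#' Default categorical trait schema (6 traits, 32 categories)
#'
#' Mirrors the structure of trait sets used for reef fishes: body size (5
#' classes), diet (9 trophic guilds), position in the water column (4),
#' gregariousness (5), mobility (4) and reproduction (5).
#'
#' @return Named list `trait -> character vector of categories`.
#' @export
default_trait_schema <- function() {
  list(
    size = c("very_small", "small", "medium", "large", "very_large"),
    diet = c("herbivore_micro", "herbivore_macro", "planktivore",
             "invertivore_mobile", "invertivore_sessile", "piscivore",
             "corallivore", "detritivore", "cleaner"),
    position = c("bottom", "near_bottom", "mid_water", "near_surface"),
    gregariousness = c("solitary", "pairs", "small_school", "medium_school",
                       "large_school"),
    mobility = c("sedentary", "reef_mobile", "between_reef",
                 "vertical_migrant"),
    reproduction = c("pelagic_eggs", "benthic_eggs", "brooder", "live_bearer",
                     "parental_care"))
}

#' Default depth filters on trait categories
#'
#' Each filter gives the depth (m) beyond which the category is progressively
#' selected against, and an exponential decay rate per metre. Filters act
#' twice: on trait assignment (a species peaking below the window is unlikely
#' to carry the category) and as abundance attenuation beyond the window.
#' Defaults emulate reef patterns: herbivores fading below the mesophotic,
#' corallivores/detritivores/cleaners restricted to the upper slope, shallow
#' water-column and schooling strategies thinning out at depth.
#'
#' @return Named list `category -> list(max_depth, decay)`.
#' @export
default_depth_filters <- function() {
  f <- function(max_depth, decay = 0.05) list(max_depth = max_depth,
                                              decay = decay)
  list(
    herbivore_micro = f(130), herbivore_macro = f(130),
    corallivore = f(90), detritivore = f(90), cleaner = f(90),
    near_surface = f(130), mid_water = f(130),
    large_school = f(130), medium_school = f(200),
    between_reef = f(200), vertical_migrant = f(200))
}

#' Configuration for the synthetic community generator
#'
#' @param n_sites number of survey sites (islands).
#' @param depth_range surveyed depth range in metres.
#' @param bin_width depth-bin width (m).
#' @param n_species size of the regional species pool.
#' @param schema trait schema (see [default_trait_schema()]).
#' @param filters depth filters (see [default_depth_filters()]).
#' @param filter_strength multiplier on all filter decay rates; 0 switches
#'   environmental filtering off.
#' @param break_depths depths (m) at which the species pool turns over;
#'   species are confined to the segment holding their peak depth.
#' @param n_transects transects per site and depth bin.
#' @param transect_length transect length (m).
#' @param site_sd log-normal sd of multiplicative site-by-species effects.
#' @param detection_beta shape parameters of the Beta distribution of
#'   per-species detection probability.
#' @param p_multi probability that a species carries a second category on one
#'   of the multi-valued traits (diet, position, gregariousness).
#' @param response_shape `"plateau"` (default): every species occupies its
#'   whole pool segment at constant expected density, with filters evaluated
#'   at the segment midpoint, so depth bins within a segment are exchangeable
#'   replicates and the community breaks are the only depth structure
#'   (a hard pool turnover). `"gaussian"`: the graded model, with density
#'   `A_s exp(-(d - mu_s)^2 / (2 sigma_s^2))` truncated at the segment edges,
#'   assignment filters evaluated at the peak depth `mu_s` and abundance
#'   attenuation varying with observation depth.
#' @param sigma_meanlog,sigma_sdlog log-normal parameters of the depth-range
#'   breadth `sigma_s` (m; gaussian shape only).
#' @param amp_meanlog,amp_sdlog log-normal parameters of the peak density
#'   `A_s` (individuals per metre of transect).
#' @param noise Poisson observation noise; `FALSE` returns expected counts.
#' @param scheme [zone_scheme()] used for ground-truth depth affinities.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 4, depth_range = c(0, 450),
                             bin_width = 10, n_species = 250,
                             schema = default_trait_schema(),
                             filters = default_depth_filters(),
                             filter_strength = 1, break_depths = 200,
                             response_shape = c("plateau", "gaussian"),
                             n_transects = 2, transect_length = 120,
                             site_sd = 0.25, detection_beta = c(17, 3),
                             p_multi = 0.15,
                             sigma_meanlog = log(70), sigma_sdlog = 0.3,
                             amp_meanlog = log(0.04), amp_sdlog = 1,
                             noise = TRUE, scheme = zone_scheme()) {
  response_shape <- match.arg(response_shape)
  stopifnot(length(depth_range) == 2, depth_range[1] < depth_range[2],
            bin_width > 0, n_species >= 3, n_sites >= 1,
            filter_strength >= 0)
  all_cats <- unlist(schema, use.names = FALSE)
  bad <- setdiff(names(filters), all_cats)
  if (length(bad)) {
    stop("filters name unknown categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  infeasible <- names(filters)[vapply(filters, function(f) {
    f$max_depth < depth_range[1]
  }, logical(1))]
  if (length(infeasible)) {
    stop("infeasible filters (window ends above the surveyed range): ",
         paste(infeasible, collapse = ", "), call. = FALSE)
  }
  if (length(break_depths) &&
      (any(break_depths <= depth_range[1]) ||
       any(break_depths >= depth_range[2]))) {
    stop("break depths must lie strictly inside the depth range",
         call. = FALSE)
  }
  structure(list(n_sites = n_sites, depth_range = depth_range,
                 bin_width = bin_width, n_species = n_species,
                 schema = schema, filters = filters,
                 filter_strength = filter_strength,
                 break_depths = sort(break_depths),
                 response_shape = response_shape,
                 n_transects = n_transects,
                 transect_length = transect_length, site_sd = site_sd,
                 detection_beta = detection_beta, p_multi = p_multi,
                 sigma_meanlog = sigma_meanlog, sigma_sdlog = sigma_sdlog,
                 amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
                 noise = noise, scheme = scheme),
            class = "synthetic_config")
}

filter_weight <- function(depth, category, filters, strength) {
  f <- filters[[category]]
  if (is.null(f)) return(rep(1, length(depth)))
  exp(-strength * f$decay * pmax(0, depth - f$max_depth))
}

#' Generate a synthetic multi-site survey with ground truth
#'
#' Draws a species pool with trait assignments filtered by depth, depth
#' response curves (plateau or Gaussian, see [synthetic_config()]) truncated
#' at the configured community-break depths, multiplicative site effects and
#' per-species detection, then Poisson transect counts. The returned ground truth records the break depths, the
#' expected (noise-free) per-bin densities, depth affinities derived from
#' those expected densities, and expected pooled trait-frequency profiles.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `traits` (data.frame ready for [trait_table()]),
#'   `observations`, `effort` (data.frames), and `ground_truth`.
#' @export
generate_communities <- function(config, seed) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_species
  rng <- config$depth_range
  width <- config$bin_width
  bins <- seq(rng[1], rng[2] - width, by = width)
  mids <- bins + width / 2
  species <- sprintf("sp%03d", seq_len(n))

  # pool segments between break depths; species allocated by segment width
  edges <- c(rng[1], config$break_depths, rng[2])
  n_seg <- length(edges) - 1
  seg_w <- diff(edges)
  alloc <- floor(n * seg_w / sum(seg_w))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  segment <- rep(seq_len(n_seg), alloc)

  mu <- stats::runif(n, edges[segment], edges[segment + 1])
  sigma <- stats::rlnorm(n, config$sigma_meanlog, config$sigma_sdlog)
  amp <- stats::rlnorm(n, config$amp_meanlog, config$amp_sdlog)
  detection <- stats::rbeta(n, config$detection_beta[1],
                            config$detection_beta[2])

  # depth at which filters act on a species: its peak depth under the graded
  # model, the segment midpoint under the plateau (hard-turnover) model so
  # that all species of one pool are exchangeable
  d_ref <- if (config$response_shape == "plateau") {
    (edges[segment] + edges[segment + 1]) / 2
  } else mu

  # trait assignment, weighted against categories filtered at the species'
  # reference depth
  schema <- config$schema
  multi_traits <- intersect(c("diet", "position", "gregariousness"),
                            names(schema))
  assign_one <- function(mu_s) {
    out <- lapply(names(schema), function(tr) {
      cats <- schema[[tr]]
      w <- vapply(cats, function(cc) {
        filter_weight(mu_s, cc, config$filters, config$filter_strength)
      }, numeric(1))
      sample(cats, 1, prob = w)
    })
    names(out) <- names(schema)
    if (length(multi_traits) && stats::runif(1) < config$p_multi) {
      tr <- if (length(multi_traits) == 1) multi_traits else
        sample(multi_traits, 1)
      cats <- setdiff(schema[[tr]], out[[tr]])
      w <- vapply(cats, function(cc) {
        filter_weight(mu_s, cc, config$filters, config$filter_strength)
      }, numeric(1))
      out[[tr]] <- c(out[[tr]], sample(cats, 1, prob = w))
    }
    out
  }
  assignments <- lapply(d_ref, assign_one)

  n_fam <- max(8L, n %/% 10L)
  family <- paste0("fam", sprintf("%02d", sample.int(n_fam, n,
                                                     replace = TRUE)))
  genus <- paste0(family, "_g", sample.int(3L, n, replace = TRUE))

  traits_df <- data.frame(species = species, genus = genus, family = family,
                          stringsAsFactors = FALSE)
  for (tr in names(schema)) {
    traits_df[[tr]] <- vapply(assignments, function(a) {
      paste(a[[tr]], collapse = ";")
    }, character(1))
  }
  # keep the declared category sets with the table: rare categories may be
  # absent from a small species pool
  attr(traits_df, "schema") <- schema

  # expected density per species x bin (before site effect and detection)
  in_segment <- outer(segment, findInterval(mids, edges,
                                            rightmost.closed = TRUE), `==`)
  shape <- if (config$response_shape == "gaussian") {
    exp(-outer(mu, mids, `-`)^2 / (2 * sigma^2))
  } else {
    matrix(1, n, length(mids))
  }
  atten <- t(vapply(seq_len(n), function(s) {
    depths <- if (config$response_shape == "plateau") {
      rep(d_ref[s], length(mids))
    } else mids
    w <- rep(1, length(mids))
    for (tr in names(schema)) {
      for (cc in assignments[[s]][[tr]]) {
        w <- w * filter_weight(depths, cc, config$filters,
                               config$filter_strength)
      }
    }
    w
  }, numeric(length(mids))))
  dens <- amp * shape * in_segment * atten
  rownames(dens) <- species
  colnames(dens) <- as.character(bins)

  sites <- paste0("site", seq_len(config$n_sites))
  site_eff <- matrix(stats::rlnorm(config$n_sites * n, 0, config$site_sd),
                     config$n_sites, n, dimnames = list(sites, species))

  obs <- vector("list", config$n_sites * config$n_transects)
  eff <- vector("list", config$n_sites * config$n_transects)
  k <- 0
  for (si in seq_len(config$n_sites)) {
    for (tr_i in seq_len(config$n_transects)) {
      k <- k + 1
      tid <- paste0(sites[si], "_t", tr_i)
      lam <- dens * detection * site_eff[si, ] *
        config$transect_length
      counts <- if (config$noise) {
        matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam))
      } else lam
      pos <- which(counts > 0, arr.ind = TRUE)
      obs[[k]] <- data.frame(
        site = sites[si], depth = mids[pos[, 2]],
        transect_id = paste0(tid, "_d", bins[pos[, 2]]),
        transect_length = config$transect_length,
        species = species[pos[, 1]], count = counts[pos],
        stringsAsFactors = FALSE)
      eff[[k]] <- data.frame(
        site = sites[si], depth = mids,
        transect_id = paste0(tid, "_d", bins),
        transect_length = config$transect_length,
        stringsAsFactors = FALSE)
    }
  }
  observations <- do.call(rbind, obs)
  effort <- do.call(rbind, eff)

  # ground truth from the expected densities
  occupied <- colSums(dens) > 0
  true_comms <- structure(list(
    abundance = t(dens[, occupied, drop = FALSE]),
    info = data.frame(community_id = paste0("true_d", bins[occupied]),
                      site = "true", depth_lower = bins[occupied],
                      depth_mid = mids[occupied], stringsAsFactors = FALSE),
    width = width), class = "depth_communities")
  rownames(true_comms$abundance) <- true_comms$info$community_id
  present <- colSums(true_comms$abundance) > 0
  true_comms$abundance <- true_comms$abundance[, present, drop = FALSE]
  shares <- species_zone_profiles(true_comms, config$scheme)
  true_aff <- depth_affinities(shares)

  mult <- detection * colSums(site_eff)
  pooled_dens <- dens * mult
  params <- data.frame(species = species, segment = segment, mu = mu,
                       sigma = sigma, amplitude = amp,
                       detection = detection, stringsAsFactors = FALSE)

  list(traits = traits_df, observations = observations, effort = effort,
       ground_truth = list(break_depths = config$break_depths,
                           affinities = true_aff,
                           zone_shares = shares,
                           expected_density = dens,
                           pooled_expected_density = pooled_dens,
                           species_params = params,
                           scheme = config$scheme),
       config = config, seed = seed)
}

#' Tiny deterministic fixture dataset
#'
#' Eight species, two traits (diet with 3 categories, position with 2), one
#' site, three 10-m depth bins with hand-set counts. Every downstream value is
#' small enough to verify by hand.
#'
#' @return list with `traits`, `observations` and `effort` data.frames.
#' @export
fixture_small <- function() {
  traits <- data.frame(
    species = paste0("sp", 1:8),
    genus = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g4"),
    family = c("f1", "f1", "f1", "f2", "f2", "f2", "f3", "f3"),
    diet = c("plank", "plank", "pisc", "invert", "invert;plank", "pisc",
             "plank", "invert"),
    position = c("bottom", "bottom", "midwater", "bottom", "midwater",
                 "bottom", "bottom", "midwater"),
    stringsAsFactors = FALSE)
  observations <- data.frame(
    site = "siteA",
    depth = c(5, 5, 5, 5, 15, 15, 15, 25, 25, 25),
    transect_id = paste0("t", c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)),
    transect_length = 30,
    species = c("sp1", "sp2", "sp3", "sp4", "sp3", "sp5", "sp6", "sp6",
                "sp7", "sp8"),
    count = c(4, 1, 2, 3, 1, 5, 2, 3, 6, 2),
    stringsAsFactors = FALSE)
  effort <- data.frame(site = "siteA", depth = c(5, 15, 25),
                       transect_id = c("t1", "t2", "t3"),
                       transect_length = 30, stringsAsFactors = FALSE)
  list(traits = traits, observations = observations, effort = effort)
}
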