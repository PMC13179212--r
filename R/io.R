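# CSV readers/writers for trait tables, observations, distance matrices and
# trait spaces; Newick export of dendrograms; configuration handling and the
# end-to-end pipeline.

#' Read a species-by-trait CSV into a trait table
#'
#' One row per species, one column per trait; multi-valued cells separated by
#' `delim`. Columns named in `taxonomy_cols` (present or not) are treated as
#' taxonomy rather than traits.
#'
#' @param path CSV file path.
#' @param delim delimiter inside multi-valued cells.
#' @param species_col species id column name.
#' @param taxonomy_cols candidate taxonomy column names.
#' @param schema optional declared category sets (see [trait_table()]).
#' @return A `trait_table`.
#' @export
read_trait_table <- function(path, delim = ";", species_col = "species",
                             taxonomy_cols = c("genus", "family"),
                             schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tax <- intersect(taxonomy_cols, names(df))
  trait_table(df, schema = schema, delim = delim, species_col = species_col,
              taxonomy_cols = if (length(tax)) tax else NULL)
}

#' Read long-format fish observations
#'
#' Required columns: `site`, `depth`, `transect_id`, `transect_length`,
#' `species`, `count`. Malformed rows (non-numeric depth/length/count,
#' negative values) are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param trait_table optional [trait_table()]; observed species absent from
#'   it are handled per `unknown_species`.
#' @param unknown_species `"error"` (default) or `"drop"` (with a warning).
#' @return data.frame of validated observations.
#' @export
read_observations <- function(path, trait_table = NULL,
                              unknown_species = c("error", "drop")) {
  unknown_species <- match.arg(unknown_species)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site", "depth", "transect_id", "transect_length", "species",
           "count")
  missing_col <- setdiff(req, names(df))
  if (length(missing_col)) {
    stop("observations file lacks column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  for (col in c("depth", "transect_length", "count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      stop("invalid '", col, "' at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    }
    df[[col]] <- v
  }
  if (!is.null(trait_table)) {
    unknown <- setdiff(unique(df$species), trait_table$species)
    if (length(unknown)) {
      if (unknown_species == "error") {
        stop("observed species missing from the trait table: ",
             paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
      }
      warning("dropping ", length(unknown),
              " species absent from the trait table")
      df <- df[!df$species %in% unknown, ]
    }
  }
  df
}

#' Write a binary trait matrix as CSV
#'
#' Layout: two header rows (trait, category), one weights row, then one row
#' per species. [read_binary_matrix()] inverts it.
#'
#' @param matrix a `binary_trait_matrix`.
#' @param path output CSV path.
#' @export
write_binary_matrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tr <- attr(matrix, "trait")
  ct <- attr(matrix, "category")
  w <- attr(matrix, "weights")
  writeLines(paste(c("trait", tr), collapse = ","), con)
  writeLines(paste(c("category", ct), collapse = ","), con)
  writeLines(paste(c("weight", format(w, digits = 17)), collapse = ","), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(c(rownames(matrix)[i], matrix[i, ]), collapse = ","),
               con)
  }
  invisible(path)
}

#' Read a binary trait matrix written by [write_binary_matrix()]
#'
#' @param path CSV path.
#' @return A `binary_trait_matrix`.
#' @export
read_binary_matrix <- function(path) {
  lines <- readLines(path)
  parse_row <- function(l) strsplit(l, ",", fixed = TRUE)[[1]]
  tr <- parse_row(lines[1])[-1]
  ct <- parse_row(lines[2])[-1]
  w <- as.numeric(parse_row(lines[3])[-1])
  body <- lapply(lines[-(1:3)], parse_row)
  species <- vapply(body, `[`, character(1), 1)
  m <- t(vapply(body, function(r) as.numeric(r[-1]), numeric(length(tr))))
  dimnames(m) <- list(species, paste(tr, ct, sep = "::"))
  structure(m, trait = tr, category = ct, weights = w,
            class = c("binary_trait_matrix", "matrix", "array"))
}

#' Read/write labelled square distance matrices
#'
#' @param d labelled symmetric matrix.
#' @param path CSV path.
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Export a trait space as coordinates CSV plus JSON sidecar
#'
#' The sidecar stores eigenvalues, variance fractions and the Cailliez
#' constant.
#'
#' @param space a `trait_space`.
#' @param prefix output path prefix (writes `<prefix>_coordinates.csv` and
#'   `<prefix>_space.json`).
#' @export
write_trait_space <- function(space, prefix) {
  utils::write.csv(as.data.frame(space$coordinates),
                   paste0(prefix, "_coordinates.csv"), row.names = TRUE)
  jsonlite::write_json(
    list(eigenvalues = space$eigenvalues,
         variance_fractions = space$variance_fractions,
         cailliez_constant = space$cailliez_constant),
    paste0(prefix, "_space.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths follow the merge heights of the `hclust` tree.
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

default_pipeline_config <- function() {
  list(delim = ";", exclude_traits = "diel_activity", bin_width = 10,
       axes_fric = c(1, 2), sqrt_transform = TRUE, affinity_threshold = 0.75,
       simprof_alpha = 1e-7, n_expected = 1000, n_null = 999, n_perm = 999,
       span = 0.75, seed = 1)
}

#' Run the full depth/functional-diversity pipeline
#'
#' Reads (or accepts in-memory) traits and observations, encodes traits,
#' builds the pooled trait space, computes per-community metrics and CWMs,
#' classifies depth affinities, clusters trait-frequency profiles with SIMPROF
#' and PERMANOVA, fits depth trends, and (optionally) writes all results
#' under `out_dir` together with a machine-readable run log.
#'
#' @param traits a `trait_table`, a data.frame for [trait_table()], or a CSV
#'   path.
#' @param observations a data.frame or CSV path of observations.
#' @param config named list overriding the defaults: `delim`,
#'   `exclude_traits`, `bin_width`, `axes_fric`, `sqrt_transform`,
#'   `affinity_threshold`, `simprof_alpha`, `n_expected`, `n_null`, `n_perm`,
#'   `span`, `seed`; or a YAML file path with those keys.
#' @param scheme a [zone_scheme()].
#' @param effort optional transect-effort data.frame (see [bin_depths()]).
#' @param out_dir optional output directory; created if missing.
#' @return list with `matrix`, `entities`, `space` (result of
#'   [build_trait_space()]), `communities`, `metrics`, `cwm`, `affinities`,
#'   `zone_summary`, `profiles`, `simprof`, `permanova`, `trends`, `log`.
#' @export
run_pipeline <- function(traits, observations, config = list(),
                         scheme = zone_scheme(), effort = NULL,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)

  if (is.character(traits)) traits <- read_trait_table(traits,
                                                       delim = cfg$delim)
  if (is.data.frame(traits)) {
    tax <- intersect(c("genus", "family"), names(traits))
    traits <- trait_table(traits, delim = cfg$delim,
                          schema = attr(traits, "schema", exact = TRUE),
                          taxonomy_cols = if (length(tax)) tax else NULL)
  }
  if (is.character(observations)) {
    observations <- read_observations(observations, trait_table = traits)
  }

  use_traits <- setdiff(names(traits$schema), cfg$exclude_traits)
  btm <- expand_traits(traits, use_traits)
  entities <- derive_entities(btm)

  communities <- bin_depths(observations, width = cfg$bin_width,
                            effort = effort)
  obs_species <- colnames(communities$abundance)
  btm_obs <- btm_subset(btm, intersect(rownames(btm), obs_species))
  ts <- build_trait_space(btm_obs)

  metrics <- community_metrics(communities, btm_obs,
                               axes_fric = cfg$axes_fric,
                               sqrt_transform = cfg$sqrt_transform)
  cwm_mat <- community_cwm(communities, btm_obs, cfg$sqrt_transform)

  shares <- species_zone_profiles(communities, scheme)
  affinities <- depth_affinities(shares, threshold = cfg$affinity_threshold)
  zones <- zone_trait_summary(ts$space, communities, scheme,
                              axes = cfg$axes_fric,
                              sqrt_transform = cfg$sqrt_transform)

  pooled <- pool_sites(communities)
  profiles <- trait_frequency_profiles(pooled, btm_obs)
  sim <- simprof(profiles, alpha = cfg$simprof_alpha,
                 n_expected = cfg$n_expected, n_null = cfg$n_null,
                 seed = cfg$seed)
  zone_factor <- assign_zone(scheme, communities$info$depth_mid,
                             communities$info$site)
  prof_site <- trait_frequency_profiles(communities, btm_obs)
  factors <- data.frame(zone = zone_factor, site = communities$info$site)
  factors <- factors[, vapply(factors, function(f) length(unique(f)) > 1,
                              logical(1)), drop = FALSE]
  perm <- if (ncol(factors)) {
    permanova_profiles(bray_curtis(prof_site), factors,
                       n_perm = cfg$n_perm, seed = cfg$seed)
  } else NULL

  trends <- list()
  for (m in c("fric", "fdis", "feve", "redundancy")) {
    trends[[m]] <- metric_depth_trends(metrics, m, span = cfg$span,
                                       seed = cfg$seed)
  }

  log <- list(package_version = as.character(utils::packageVersion("bathyfd")),
              r_version = R.version.string,
              seed = cfg$seed,
              n_species = length(obs_species),
              n_entities = length(entities$members),
              n_communities = nrow(communities$abundance),
              config_hash = config_hash(cfg),
              timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(matrix = btm_obs, entities = entities, space = ts,
              communities = communities, metrics = metrics, cwm = cwm_mat,
              affinities = affinities, zone_summary = zones,
              profiles = profiles, simprof = sim, permanova = perm,
              trends = trends, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_binary_matrix(result$matrix, p("binary_traits.csv"))
  write_trait_space(result$space$space, p("trait"))
  write_distance_csv(result$space$gower, p("gower.csv"))
  utils::write.csv(result$metrics, p("community_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$cwm), p("cwm.csv"), row.names = TRUE)
  aff <- result$affinities
  aff$zones <- vapply(aff$zones, paste, character(1), collapse = "|")
  utils::write.csv(aff, p("affinities.csv"), row.names = FALSE)
  utils::write.csv(result$zone_summary$summary, p("zone_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(community = names(result$simprof$partition),
                              cluster = result$simprof$partition),
                   p("simprof_partition.csv"), row.names = FALSE)
  utils::write.csv(result$simprof$tests, p("simprof_tests.csv"),
                   row.names = FALSE)
  write_newick(result$simprof$hc, p("dendrogram.nwk"))
  if (!is.null(result$permanova)) {
    utils::write.csv(result$permanova, p("permanova.csv"), row.names = FALSE)
  }
  trend_summary <- do.call(rbind, lapply(names(result$trends), function(m) {
    t <- result$trends[[m]]$pooled
    data.frame(metric = m, r_squared = t$r_squared, p_value = t$p_value)
  }))
  utils::write.csv(trend_summary, p("trend_summary.csv"), row.names = FALSE)
  jsonlite::write_json(result$log, p("run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
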