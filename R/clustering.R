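# Trait-frequency profiles per depth bin, Bray-Curtis dissimilarity, Ward
# dendrograms, SIMPROF significance tests and PERMANOVA.

#' Abundance-weighted trait-category frequencies per community
#'
#' For every community (depth bin), the frequency of each trait category among
#' all individuals: `f_bk = sum_s a_sb x_sk / sum_s a_sb` with raw (untrans-
#' formed) abundances. Clustering these profiles compares communities by trait
#' composition rather than species composition.
#'
#' @param communities a `depth_communities` object, typically site-pooled via
#'   [pool_sites()].
#' @param matrix a `binary_trait_matrix` covering the observed species.
#' @return communities x categories numeric matrix.
#' @export
trait_frequency_profiles <- function(communities, matrix) {
  ab <- communities$abundance
  if (!nrow(ab)) stop("no communities", call. = FALSE)
  sp <- colnames(ab)
  missing <- setdiff(sp, rownames(matrix))
  if (length(missing)) {
    stop("species missing from the trait matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  x <- unclass(matrix)[sp, , drop = FALSE]
  prof <- (ab %*% x) / rowSums(ab)
  rownames(prof) <- communities$info$community_id
  prof
}

# lower-triangle Bray-Curtis, ordered like stats::dist
bray_curtis_lower <- function(x) {
  num <- as.vector(stats::dist(x, method = "manhattan"))
  rs <- rowSums(x)
  n <- nrow(x)
  i <- sequence(seq(n - 1, 1)) + rep(seq_len(n - 1), seq(n - 1, 1))
  j <- rep(seq_len(n - 1), seq(n - 1, 1))
  num / (rs[i] + rs[j])
}

#' Bray-Curtis dissimilarity between profile rows
#'
#' `BC(u, v) = sum |u_k - v_k| / sum (u_k + v_k)`, in `[0, 1]` for
#' non-negative profiles; sensitive to both which categories are present and
#' their relative abundance.
#'
#' @param profiles non-negative numeric matrix (rows = communities).
#' @return symmetric labelled dissimilarity matrix.
#' @export
bray_curtis <- function(profiles) {
  if (any(profiles < 0)) stop("profiles must be non-negative", call. = FALSE)
  if (any(rowSums(profiles) == 0)) {
    stop("all-zero profile row(s): Bray-Curtis undefined", call. = FALSE)
  }
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  d[lower.tri(d)] <- bray_curtis_lower(profiles)
  d + t(d)
}

#' Ward minimum-variance dendrogram
#'
#' Agglomerative clustering with the Ward.D2 criterion (squared
#' dissimilarities in the Lance-Williams update), which merges the pair of
#' clusters whose fusion least increases within-cluster variance. Ties are
#' resolved deterministically by the lowest-index pair.
#'
#' @param d symmetric dissimilarity matrix or `dist` object.
#' @return An `hclust` object.
#' @export
ward_dendrogram <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  stats::hclust(d, method = "ward.D2")
}

permute_columns <- function(x) {
  m <- nrow(x)
  p <- ncol(x)
  idx <- vapply(seq_len(p), function(j) sample.int(m), integer(m))
  matrix(x[idx + rep((seq_len(p) - 1L) * m, each = m)], m, p)
}

# One similarity-profile test (Clarke et al. 2008). Similarities are
# 1 - Bray-Curtis; the null permutes each column independently across the
# node's rows.
simprof_test <- function(x, n_expected, n_null) {
  obs <- sort(1 - bray_curtis_lower(x))
  expected <- matrix(0, length(obs), n_expected)
  for (b in seq_len(n_expected)) {
    expected[, b] <- sort(1 - bray_curtis_lower(permute_columns(x)))
  }
  mean_prof <- rowMeans(expected)
  pi_obs <- sum(abs(obs - mean_prof))
  pi_null <- numeric(n_null)
  for (b in seq_len(n_null)) {
    prof <- sort(1 - bray_curtis_lower(permute_columns(x)))
    pi_null[b] <- sum(abs(prof - mean_prof))
  }
  p <- (1 + sum(pi_null >= pi_obs)) / (1 + n_null)
  list(pi = pi_obs, p = p)
}

#' SIMPROF: similarity-profile significance of hierarchical clusters
#'
#' Descends the dendrogram from the root, testing at each node whether the
#' ordered between-object similarity profile departs from the profile
#' expected when every trait category is independently permuted across the
#' node's communities (Clarke et al. 2008). The test statistic is
#' `pi = sum_r |s_(r) - sbar_(r)|`; its null distribution comes from further
#' permutations. Descent stops at nodes whose profile is compatible with
#' homogeneity, and the leaves below each stopping point form one cluster.
#'
#' The permutation p-value `p = (1 + #(pi_null >= pi_obs)) / (1 + n_null)`
#' cannot fall below `1 / (1 + n_null)`; an `alpha` smaller than that
#' resolution (e.g. the conventional 1e-7 with 999 permutations) therefore
#' behaves like the resolution limit: a node is split only when the observed
#' statistic exceeds every null draw.
#'
#' @param profiles community x category matrix (e.g. from
#'   [trait_frequency_profiles()]).
#' @param hc optional precomputed `hclust` tree on the Bray-Curtis
#'   dissimilarities of `profiles`; built with [ward_dendrogram()] if `NULL`.
#' @param alpha significance level for descending (default 1e-7; see above).
#' @param n_expected permutations used to form the mean expected profile.
#' @param n_null permutations used for the null distribution of `pi`.
#' @param seed integer seed (required: the test is stochastic).
#' @return Object of class `simprof_result`: list with `partition` (named
#'   integer, community -> cluster id, numbered along the dendrogram order),
#'   `tests` (data.frame per tested node), `hc`, `alpha` and
#'   `alpha_effective`.
#' @export
simprof <- function(profiles, hc = NULL, alpha = 1e-7, n_expected = 1000,
                    n_null = 999, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  if (is.null(hc)) hc <- ward_dendrogram(bray_curtis(profiles))
  n <- nrow(profiles)
  alpha_eff <- max(alpha, 1 / (1 + n_null))

  # leaves under each internal node
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members[[k]] <- unlist(lapply(hc$merge[k, ], function(v) {
      if (v < 0) -v else members[[v]]
    }))
  }

  tests <- list()
  clusters <- list()
  recurse <- function(node) {
    if (node < 0) {
      clusters[[length(clusters) + 1]] <<- -node
      return(invisible())
    }
    rows <- members[[node]]
    res <- simprof_test(profiles[rows, , drop = FALSE], n_expected, n_null)
    tests[[length(tests) + 1]] <<- data.frame(
      node = node, size = length(rows), pi = res$pi, p = res$p,
      significant = res$p <= alpha_eff)
    if (res$p <= alpha_eff) {
      recurse(hc$merge[node, 1])
      recurse(hc$merge[node, 2])
    } else {
      clusters[[length(clusters) + 1]] <<- rows
    }
  }
  recurse(nrow(hc$merge))

  partition <- integer(n)
  # number clusters along the dendrogram leaf order for readability
  first_leaf <- vapply(clusters, function(rows) {
    min(match(rows, hc$order))
  }, numeric(1))
  for (ci in seq_along(clusters)) {
    partition[clusters[[order(first_leaf)[ci]]]] <- ci
  }
  names(partition) <- rownames(profiles)
  structure(list(partition = partition,
                 tests = do.call(rbind, tests),
                 hc = hc, alpha = alpha, alpha_effective = alpha_eff),
            class = "simprof_result")
}

#' @export
print.simprof_result <- function(x, ...) {
  cat("SIMPROF:", max(x$partition), "significant cluster(s) over",
      length(x$partition), "communities (alpha =",
      format(x$alpha, scientific = TRUE), ")\n")
  invisible(x)
}

#' Depth of the deepest significant branching event
#'
#' A branching event in the dendrogram has a depth location only when it
#' separates the node's communities into two contiguous depth blocks (one
#' entirely shallower than the other); the split depth is then the bin edge
#' between the blocks. Significant splits whose children interleave in depth
#' (no depth structure) carry no location and are ignored. Returns the
#' deepest located significant split, or `NA` when none exists.
#'
#' @param result a `simprof_result`.
#' @param depth_lower numeric vector of bin lower edges, aligned with the
#'   profile rows.
#' @return Depth in metres of the deepest significant depth-structured split.
#' @export
deepest_split_depth <- function(result, depth_lower) {
  hc <- result$hc
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    members[[k]] <- unlist(lapply(hc$merge[k, ], function(v) {
      if (v < 0) -v else members[[v]]
    }))
  }
  leaves <- function(v) if (v < 0) -v else members[[v]]
  sig_nodes <- result$tests$node[result$tests$significant]
  depths <- vapply(sig_nodes, function(node) {
    a <- depth_lower[leaves(hc$merge[node, 1])]
    b <- depth_lower[leaves(hc$merge[node, 2])]
    if (max(a) < min(b)) return(min(b))
    if (max(b) < min(a)) return(min(a))
    NA_real_
  }, numeric(1))
  if (all(is.na(depths))) return(NA_real_)
  max(depths, na.rm = TRUE)
}

#' PERMANOVA of trait profiles against depth zone and site
#'
#' Permutational multivariate analysis of variance partitioning the squared
#' dissimilarities among factor levels (wrapper around [vegan::adonis2()]).
#'
#' @param d dissimilarity matrix or `dist` object.
#' @param factors data.frame of grouping factors (e.g. `zone`, `site`), rows
#'   aligned with `d`.
#' @param n_perm number of free row permutations.
#' @param seed integer seed.
#' @param by passed to [vegan::adonis2()] (`"terms"` by default).
#' @return data.frame with one row per term: `term`, `df`, `ss`, `r2`,
#'   `pseudo_f`, `p`.
#' @export
permanova_profiles <- function(d, factors, n_perm = 999, seed = 1,
                               by = "terms") {
  if (is.matrix(d)) d <- stats::as.dist(d)
  stopifnot(is.data.frame(factors))
  singletons <- vapply(factors, function(f) any(table(f) < 2), logical(1))
  if (any(singletons)) {
    warning("factor level(s) with a single member: ",
            paste(names(factors)[singletons], collapse = ", "))
  }
  set.seed(seed)
  fit <- vegan::adonis2(d ~ ., data = factors, permutations = n_perm,
                        by = by)
  data.frame(term = rownames(fit), df = fit$Df, ss = fit$SumOfSqs,
             r2 = fit$R2, pseudo_f = fit$F, p = fit$`Pr(>F)`,
             row.names = NULL, stringsAsFactors = FALSE)
}
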