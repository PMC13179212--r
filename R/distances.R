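# Weighted Gower dissimilarity, Cailliez additive-constant correction, and
# principal coordinates (metric MDS) embedding of trait distances.

check_distance_matrix <- function(d, tol = 1e-12) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(d - t(d))) > tol) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  invisible(d)
}

#' Weighted Gower dissimilarity between binary trait profiles
#'
#' For 0/1 trait columns with positive column weights `w_k` (here the inverse
#' of the number of categories in the column's trait), the Gower dissimilarity
#' is the weighted mean mismatch
#' `d(i,j) = sum_k w_k |x_ik - x_jk| / sum_k w_k`, bounded in `[0, 1]`.
#'
#' @param matrix a `binary_trait_matrix` from [expand_traits()], or any
#'   numeric matrix in `[0, 1]` with a `weights` attribute (defaults to equal
#'   weights when absent).
#' @return Symmetric species x species matrix of class `matrix` with zero
#'   diagonal and values in `[0, 1]`.
#' @export
gower_dist <- function(matrix) {
  if (ncol(matrix) == 0) stop("trait matrix has no columns", call. = FALSE)
  w <- attr(matrix, "weights")
  if (is.null(w)) w <- rep(1, ncol(matrix))
  stopifnot(all(w > 0), length(w) == ncol(matrix))
  x <- unclass(matrix)
  scaled <- sweep(x, 2, w, `*`)
  d <- as.matrix(stats::dist(scaled, method = "manhattan")) / sum(w)
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' Cailliez additive-constant correction
#'
#' Finds the smallest constant `c` such that adding `c` to every off-diagonal
#' dissimilarity yields a matrix embeddable in Euclidean space, as the largest
#' real eigenvalue of the standard 2n x 2n block matrix built from the
#' double-centered `-D^2/2` and `-D/2`. Already-Euclidean input returns
#' `c = 0`.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param tol relative tolerance for declaring the input Euclidean.
#' @return list with `distances` (corrected matrix, zero diagonal) and
#'   `constant`.
#' @references Cailliez, F. (1983) The analytical solution of the additive
#'   constant problem. Psychometrika 48, 305-308.
#' @export
cailliez_correct <- function(d, tol = 1e-10) {
  check_distance_matrix(d)
  n <- nrow(d)
  jc <- diag(n) - 1 / n
  delta1 <- -0.5 * jc %*% (d * d) %*% jc
  ev1 <- eigen((delta1 + t(delta1)) / 2, symmetric = TRUE,
               only.values = TRUE)$values
  scale_ref <- max(abs(ev1), 1)
  if (min(ev1) >= -tol * scale_ref) {
    return(list(distances = d, constant = 0))
  }
  delta2 <- -0.5 * jc %*% d %*% jc
  big <- rbind(cbind(matrix(0, n, n), 2 * delta1),
               cbind(-diag(n), -4 * delta2))
  ev <- eigen(big, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-8 * max(abs(ev), 1)])
  cc <- max(re, 0)
  dc <- d + cc
  diag(dc) <- 0
  list(distances = dc, constant = cc)
}

#' Principal coordinates analysis of a (Euclidean) distance matrix
#'
#' Double-centers `-D^2/2`, eigendecomposes, and scales eigenvectors by the
#' square roots of their eigenvalues. Axes are ordered by decreasing
#' eigenvalue; only eigenvalues above `tol_factor * max(eigenvalue)` yield
#' coordinates. Per-axis variance fractions are taken relative to the sum of
#' positive eigenvalues. For reproducibility across linear-algebra backends,
#' each axis is reflected so that its largest-magnitude coordinate is
#' positive.
#'
#' @param d symmetric distance matrix (Cailliez-corrected upstream when the
#'   raw dissimilarity is non-Euclidean).
#' @param tol_factor relative eigenvalue cutoff for retaining axes.
#' @return Object of class `trait_space`: list with `coordinates` (species x
#'   axis matrix), `eigenvalues` (all, decreasing), `variance_fractions`
#'   (per retained axis), and `cailliez_constant` (0 unless set by
#'   [build_trait_space()]).
#' @export
pcoa_space <- function(d, tol_factor = 1e-8) {
  check_distance_matrix(d, tol = 1e-8)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 species for a trait space", call. = FALSE)
  jc <- diag(n) - 1 / n
  b <- -0.5 * jc %*% (d * d) %*% jc
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  lam <- e$values
  if (max(lam) <= .Machine$double.eps * n) {
    stop("degenerate distance matrix: all points coincide", call. = FALSE)
  }
  keep <- which(lam > tol_factor * max(lam))
  coords <- e$vectors[, keep, drop = FALSE] *
    rep(sqrt(lam[keep]), each = n)
  for (a in seq_along(keep)) {
    j <- which.max(abs(coords[, a]))
    if (coords[j, a] < 0) coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCoA", seq_along(keep))
  pos <- lam[lam > 0]
  structure(list(coordinates = coords,
                 eigenvalues = lam,
                 variance_fractions = lam[keep] / sum(pos),
                 cailliez_constant = 0),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait space:", nrow(x$coordinates), "species,",
      ncol(x$coordinates), "axes\n")
  vf <- round(100 * x$variance_fractions[seq_len(min(
    2, length(x$variance_fractions)))], 1)
  cat("  first axes capture", paste0(vf, "%", collapse = " + "),
      "of trait variation\n")
  if (x$cailliez_constant > 0) {
    cat("  Cailliez constant:", signif(x$cailliez_constant, 4), "\n")
  }
  invisible(x)
}

#' Build a trait space from a binary trait matrix
#'
#' Convenience pipeline: weighted Gower dissimilarity, Cailliez correction,
#' then principal coordinates. The uncorrected Gower matrix is kept because
#' the Rao/Simpson redundancy decomposition requires distances in `[0, 1]`.
#'
#' @param matrix a `binary_trait_matrix`.
#' @param tol_factor passed to [pcoa_space()].
#' @return list with `space` (a `trait_space`), `gower` (uncorrected matrix),
#'   `corrected` (Cailliez-corrected matrix) and `cailliez_constant`.
#' @export
build_trait_space <- function(matrix, tol_factor = 1e-8) {
  g <- gower_dist(matrix)
  cc <- cailliez_correct(g)
  sp <- pcoa_space(cc$distances, tol_factor = tol_factor)
  sp$cailliez_constant <- cc$constant
  list(space = sp, gower = g, corrected = cc$distances,
       cailliez_constant = cc$constant)
}
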