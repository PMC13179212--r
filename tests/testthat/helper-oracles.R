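# Independent brute-force oracles: naive double loops, gift-wrapping hull,
# Prim's MST, Lance-Williams recursion, bisection Cailliez, exhaustive
# rarefaction. Deliberately slow and simple; they never share code with the
# package implementations they check.

oracle_gower <- function(x, w) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(w * abs(x[i, ] - x[j, ])) / sum(w)
    }
  }
  d
}

oracle_bray_curtis <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
    }
  }
  d
}

# gift-wrapping (Jarvis march) + shoelace
oracle_hull_area <- function(xy) {
  xy <- xy[!duplicated(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- order(xy[, 2], xy[, 1])[1]
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (p in seq_len(n)) {
      if (p == cur) next
      cr <- cross(xy[cur, ], xy[cand, ], xy[p, ])
      if (cr < 0 ||
          (cr == 0 && sum((xy[p, ] - xy[cur, ])^2) >
           sum((xy[cand, ] - xy[cur, ])^2))) {
        cand <- p
      }
    }
    cur <- cand
    if (cur == start) break
  }
  v <- xy[hull, , drop = FALSE]
  m <- nrow(v)
  if (m < 3) return(0)
  nxt <- c(2:m, 1)
  abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
}

oracle_prim_mst <- function(dm) {
  n <- nrow(dm)
  intree <- 1L
  edges <- matrix(0L, 0, 2)
  while (length(intree) < n) {
    out <- setdiff(seq_len(n), intree)
    sub <- dm[intree, out, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    edges <- rbind(edges, c(intree[k[1]], out[k[2]]))
    intree <- c(intree, out[k[2]])
  }
  edges
}

oracle_feve <- function(coords, ab, sqrt_transform = TRUE) {
  s <- length(ab)
  w <- if (sqrt_transform) sqrt(ab) else ab
  w <- w / sum(w)
  dm <- as.matrix(dist(coords))
  edges <- oracle_prim_mst(dm)
  ew <- apply(edges, 1, function(e) dm[e[1], e[2]] / (w[e[1]] + w[e[2]]))
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  unname((sum(pmin(pew, thr)) - thr) / (1 - thr))
}

oracle_fdis <- function(coords, ab, sqrt_transform = TRUE) {
  w <- if (sqrt_transform) sqrt(ab) else ab
  w <- w / sum(w)
  centroid <- colSums(coords * w)
  total <- 0
  for (i in seq_len(nrow(coords))) {
    total <- total + w[i] * sqrt(sum((coords[i, ] - centroid)^2))
  }
  unname(total)
}

oracle_rao <- function(d, ab, sqrt_transform = TRUE) {
  p <- if (sqrt_transform) sqrt(ab) else ab
  p <- p / sum(p)
  q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) q <- q + d[i, j] * p[i] * p[j]
  }
  simpson <- 1 - sum(p^2)
  list(rao_q = unname(q), simpson = unname(simpson),
       redundancy = unname(simpson - q))
}

# Lance-Williams recursion for the Ward.D2 criterion
oracle_ward_heights <- function(dm) {
  n <- nrow(dm)
  size <- rep(1, n)
  act <- seq_len(n)
  heights <- numeric(0)
  while (length(act) > 1) {
    best <- c(Inf, 0, 0)
    for (ai in seq_along(act)) {
      for (aj in seq_along(act)) {
        if (aj <= ai) next
        dd <- dm[act[ai], act[aj]]
        if (dd < best[1]) best <- c(dd, act[ai], act[aj])
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    for (l in act) {
      if (l == i || l == j) next
      dm[i, l] <- dm[l, i] <- sqrt(
        ((size[i] + size[l]) * dm[i, l]^2 +
         (size[j] + size[l]) * dm[j, l]^2 -
         size[l] * dm[i, j]^2) / (size[i] + size[j] + size[l]))
    }
    size[i] <- size[i] + size[j]
    act <- setdiff(act, j)
  }
  heights
}

# smallest additive constant by bisection on the double-centered spectrum
oracle_cailliez_bisect <- function(d, tol = 1e-10) {
  n <- nrow(d)
  jc <- diag(n) - 1 / n
  min_eig <- function(cc) {
    dd <- d + cc
    diag(dd) <- 0
    b <- -0.5 * jc %*% (dd * dd) %*% jc
    ev <- eigen((b + t(b)) / 2, symmetric = TRUE, only.values = TRUE)$values
    min(ev) / max(abs(ev), 1)
  }
  if (min_eig(0) >= -1e-9) return(0)
  lo <- 0
  hi <- 2 * max(d)
  while (min_eig(hi) < -1e-9) hi <- 2 * hi
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (min_eig(mid) < -1e-9) lo <- mid else hi <- mid
  }
  hi
}

oracle_rarefaction_exact <- function(x) {
  x <- as.matrix(x) > 0
  n <- nrow(x)
  vapply(seq_len(n), function(k) {
    subsets <- utils::combn(n, k)
    mean(apply(subsets, 2, function(idx) {
      sum(colSums(x[idx, , drop = FALSE]) > 0)
    }))
  }, numeric(1))
}

# random fuzzy-coded binary trait matrix; the generating trait_table is kept
# in attribute "table"
random_btm <- function(n_species, seed) {
  set.seed(seed)
  schema <- list(t1 = paste0("a", 1:3), t2 = paste0("b", 1:2),
                 t3 = paste0("c", 1:4))
  df <- data.frame(species = sprintf("s%02d", seq_len(n_species)))
  for (tr in names(schema)) {
    df[[tr]] <- vapply(seq_len(n_species), function(i) {
      k <- sample(c(1, 1, 1, 2), 1)
      paste(sample(schema[[tr]], k), collapse = ";")
    }, character(1))
  }
  tt <- trait_table(df, schema = schema)
  m <- expand_traits(tt)
  attr(m, "table") <- tt
  m
}

toy_trait_df <- function() {
  data.frame(
    species = c("sp1", "sp2", "sp3"),
    t1 = c("x", "y", "z"),
    t2 = c("u", "v", "u"),
    stringsAsFactors = FALSE)
}
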