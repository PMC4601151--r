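#' Square-root Jensen-Shannon distance between two profiles
#'
#' JSD(p, q) = KL(p||m)/2 + KL(q||m)/2 with m = (p+q)/2, natural log and
#' the convention 0 log 0 = 0 (no pseudocounts). The square root of the
#' divergence is a metric; profiles with disjoint supports attain its
#' maximum sqrt(log 2).
#'
#' @param p,q non-negative vectors of equal length summing to 1
#'   (renormalized with a warning otherwise).
#' @return sqrt of the Jensen-Shannon divergence (nats).
#' @export
jsd_sqrt <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles must have equal length")
  stopifnot(all(p >= 0), all(q >= 0))
  norm <- function(v, which) {
    s <- sum(v)
    if (s <= 0) stop("all-zero profile")
    if (abs(s - 1) > 1e-8) {
      warning(which, " does not sum to 1; renormalizing")
      v <- v / s
    }
    v
  }
  p <- norm(p, "p"); q <- norm(q, "q")
  m <- (p + q) / 2
  kl <- function(a, b) {
    ok <- a > 0
    sum(a[ok] * log(a[ok] / b[ok]))
  }
  d <- kl(p, m) / 2 + kl(q, m) / 2
  sqrt(max(d, 0))
}

#' Pairwise sqrt-Jensen-Shannon distance matrix
#'
#' @param profiles samples x taxa matrix of relative abundances.
#' @return symmetric distance matrix (class matrix) with zero diagonal.
#' @export
jsd_dist <- function(profiles) {
  profiles <- as.matrix(profiles)
  profiles <- profiles / rowSums(profiles)
  n <- nrow(profiles)
  d <- matrix(0, n, n, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- jsd_sqrt(profiles[i, ], profiles[j, ])
    }
  }
  d
}

#' Partitioning around medoids on a distance matrix
#'
#' Thin wrapper over [cluster::pam()] run in dissimilarity mode (BUILD
#' initialization followed by SWAP to a local optimum of the total
#' distance to medoids). Deterministic for a given distance matrix.
#'
#' @param dist square symmetric distance matrix.
#' @param k number of clusters, 2 <= k < n.
#' @return list with `assignments` (integer per sample), `medoids`
#'   (indices), `objective` (total distance to assigned medoid).
#' @export
pam_cluster <- function(dist, k) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k < 2L || k >= n)
    stop("k must satisfy 2 <= k < n")
  fit <- cluster::pam(stats::as.dist(dist), k = k, diss = TRUE)
  med <- as.integer(fit$id.med)
  list(assignments = as.integer(fit$clustering),
       medoids = med,
       objective = sum(dist[cbind(seq_len(n),
                                  med[fit$clustering])]))
}

#' Silhouette widths of a clustering
#'
#' s(i) = (b - a) / max(a, b) with a the mean distance to the own cluster
#' and b the smallest mean distance to another cluster; samples in
#' singleton clusters get s = 0 (standard convention).
#'
#' @param dist square distance matrix.
#' @param assignments integer cluster labels.
#' @return list with `widths` (per sample) and `mean`.
#' @export
silhouette_widths <- function(dist, assignments) {
  dist <- as.matrix(dist)
  if (length(unique(assignments)) < 2L)
    stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(as.integer(assignments),
                             dmatrix = dist)
  widths <- sil[, "sil_width"]
  list(widths = as.numeric(widths), mean = mean(widths))
}

#' Calinski-Harabasz index
#'
#' CH = [B/(k-1)] / [W/(n-k)] with B and W the between- and within-cluster
#' sums of squares of the supplied coordinates (here: PCoA coordinates,
#' since the clustering distance is non-Euclidean).
#'
#' @param coords samples x axes coordinate matrix.
#' @param assignments integer cluster labels.
#' @return CH index (numeric).
#' @export
calinski_harabasz <- function(coords, assignments) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- length(unique(assignments))
  if (k < 2L || k >= n)
    stop("CH requires 2 <= k < n")
  grand <- colMeans(coords)
  W <- 0; B <- 0
  for (g in unique(assignments)) {
    ix <- which(assignments == g)
    cen <- colMeans(coords[ix, , drop = FALSE])
    W <- W + sum(sweep(coords[ix, , drop = FALSE], 2L, cen)^2)
    B <- B + length(ix) * sum((cen - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: double-centering of -D^2/2 followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues, sorted in decreasing order. Negative
#' eigenvalues (possible for non-Euclidean distances) are reported and
#' their axes dropped.
#'
#' @param dist square symmetric distance matrix.
#' @return list with `points` (samples x positive axes), `eigenvalues`
#'   (all, sorted decreasing), `negative_eigenvalues`.
#' @export
pcoa <- function(dist) {
  dist <- as.matrix(dist)
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  n <- nrow(dist)
  # warning about non-positive eigenvalues is expected for non-Euclidean input
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dist), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  pts <- fit$points[, seq_along(pos), drop = FALSE]
  rownames(pts) <- rownames(dist)
  list(points = pts,
       eigenvalues = eig,
       negative_eigenvalues = eig[eig < -tol])
}

#' Choose the number of clusters
#'
#' Runs PAM over `k_range` and scores each k by mean silhouette width and
#' by the Calinski-Harabasz index on PCoA coordinates. The two criteria
#' often disagree on weakly structured data; when even the best mean
#' silhouette stays below `sil_threshold` the verdict is that there is no
#' strong clustering.
#'
#' @param dist square distance matrix.
#' @param k_range integer vector of candidate k (default 2:10, truncated
#'   to k < n).
#' @param coords optional PCoA coordinates (computed if missing).
#' @param sil_threshold weak-clustering threshold on the best mean
#'   silhouette (default 0.25; configurable, not a universal constant).
#' @return list with `table` (k, mean_silhouette, ch), `best_silhouette_k`,
#'   `best_ch_k`, `agreement`, `weak_clustering`, `single_k` flag.
#' @export
choose_k <- function(dist, k_range = 2:10, coords = NULL,
                     sil_threshold = 0.25) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  k_range <- k_range[k_range >= 2L & k_range < n]
  if (!length(k_range)) stop("k_range contains no feasible k")
  if (is.null(coords)) coords <- pcoa(dist)$points
  rows <- lapply(k_range, function(k) {
    cl <- pam_cluster(dist, k)
    data.frame(k = k,
               mean_silhouette =
                 silhouette_widths(dist, cl$assignments)$mean,
               ch = calinski_harabasz(coords, cl$assignments))
  })
  tab <- do.call(rbind, rows)
  bs <- tab$k[which.max(tab$mean_silhouette)]
  bc <- tab$k[which.max(tab$ch)]
  list(table = tab,
       best_silhouette_k = bs,
       best_ch_k = bc,
       agreement = bs == bc,
       weak_clustering = max(tab$mean_silhouette) < sil_threshold,
       single_k = length(k_range) == 1L)
}

#' Wald-Wolfowitz runs test on a binary label sequence
#'
#' Tests randomness of the ordering of a two-valued sequence via the
#' number of runs R. For n <= 20 the exact run-count distribution
#' (hypergeometric-type closed form) is used; otherwise the normal
#' approximation with continuity correction. A small lower-tail p
#' indicates temporal clustering (fewer runs than expected).
#'
#' @param labels vector with exactly two distinct values, in chronological
#'   order.
#' @return list of class `runs_test_result`: `n`, `n0`, `n1`, `n_runs`,
#'   `expected_runs`, `variance`, `z`, `p_clustered` (lower tail),
#'   `p_dispersed` (upper tail), `p_two_sided`, `method`.
#' @export
runs_test <- function(labels) {
  labels <- labels[!is.na(labels)]
  vals <- unique(labels)
  if (length(vals) != 2L)
    stop("runs test needs a sequence with exactly 2 distinct values")
  x <- as.integer(labels == vals[2L])
  n <- length(x)
  n1 <- sum(x); n0 <- n - n1
  R <- 1L + sum(x[-1L] != x[-n])
  mu <- 1 + 2 * n0 * n1 / n
  v <- 2 * n0 * n1 * (2 * n0 * n1 - n) / (n^2 * (n - 1))
  if (n <= 20L) {
    pmf <- runs_pmf(n0, n1)
    p_lo <- sum(pmf[seq_len(R)])
    p_hi <- sum(pmf[R:length(pmf)])
    method <- "exact"
    z <- if (v > 0) (R - mu) / sqrt(v) else NA_real_
  } else {
    sdv <- sqrt(v)
    z <- (R - mu) / sdv
    p_lo <- stats::pnorm((R - mu + 0.5) / sdv)
    p_hi <- stats::pnorm((R - mu - 0.5) / sdv, lower.tail = FALSE)
    method <- "normal_approx"
  }
  structure(list(n = n, n0 = n0, n1 = n1, n_runs = R,
                 expected_runs = mu, variance = v, z = z,
                 p_clustered = min(1, p_lo),
                 p_dispersed = min(1, p_hi),
                 p_two_sided = min(1, 2 * min(p_lo, p_hi)),
                 method = method),
            class = "runs_test_result")
}

#' Exact run-count distribution
#'
#' P(R = r) for the number of runs in a random arrangement of n0 zeros and
#' n1 ones: for even r = 2k, 2 C(n0-1, k-1) C(n1-1, k-1) / C(n, n0); for
#' odd r = 2k+1, [C(n0-1, k-1) C(n1-1, k) + C(n0-1, k) C(n1-1, k-1)] /
#' C(n, n0).
#'
#' @param n0,n1 counts of the two values.
#' @return numeric vector p of length n0+n1 with p[r] = P(R = r) (p[1] = 0).
#' @export
runs_pmf <- function(n0, n1) {
  n <- n0 + n1
  denom <- choose(n, n0)
  p <- numeric(n)
  for (r in 2:n) {
    if (r %% 2L == 0L) {
      k <- r %/% 2L
      p[r] <- 2 * choose(n0 - 1, k - 1) * choose(n1 - 1, k - 1) / denom
    } else {
      k <- (r - 1L) %/% 2L
      p[r] <- (choose(n0 - 1, k - 1) * choose(n1 - 1, k) +
                 choose(n0 - 1, k) * choose(n1 - 1, k - 1)) / denom
    }
  }
  p
}

#' Default enterotyping configuration
#' @return list with `k_range`, `sil_threshold` and `driver_genera` (the
#'   genus groups classically separating enterotypes).
#' @export
enterotype_config <- function(k_range = 2:10, sil_threshold = 0.25,
                              driver_genera = c("Bacteroides", "Prevotella",
                                                "Ruminococcus", "Blautia")) {
  list(k_range = k_range, sil_threshold = sil_threshold,
       driver_genera = driver_genera)
}

#' Full temporal enterotyping pipeline
#'
#' From genus-level relative abundance profiles: sqrt-Jensen-Shannon
#' distances, cluster-number selection (silhouette primary,
#' Calinski-Harabasz secondary), PAM assignment at the silhouette-optimal
#' k, PCoA for visualization, the per-day enterotype label series, a runs
#' test for temporal clustering of the labels when two enterotypes are
#' found, and mean abundances of the classic driver genera per enterotype.
#' On weakly structured data (best silhouette below threshold) no
#' switching analysis is reported.
#'
#' @param table a `processed_table`.
#' @param config see [enterotype_config()].
#' @return list of class `enterotype_result`: `dist`, `selection`,
#'   `k`, `assignments`, `pcoa`, `label_series` (day-ordered), `runs`
#'   (NULL unless two clusters and strong structure), `driver_summary`,
#'   `weak_clustering`.
#' @export
enterotype_pipeline <- function(table, config = enterotype_config()) {
  stopifnot(inherits(table, "processed_table"))
  d <- jsd_dist(table$rel_abund)
  pc <- pcoa(d)
  sel <- choose_k(d, k_range = config$k_range, coords = pc$points,
                  sil_threshold = config$sil_threshold)
  k <- sel$best_silhouette_k
  cl <- pam_cluster(d, k)
  ord <- order(table$sample_day)
  series <- data.frame(day = table$sample_day[ord],
                       sample_id = table$sample_ids[ord],
                       enterotype = cl$assignments[ord])
  runs <- NULL
  if (!sel$weak_clustering && k == 2L)
    runs <- runs_test(series$enterotype)
  drivers <- intersect(config$driver_genera, table$taxa_ids)
  driver_summary <- if (length(drivers)) {
    do.call(rbind, lapply(sort(unique(cl$assignments)), function(g) {
      ix <- which(cl$assignments == g)
      data.frame(enterotype = g, n_samples = length(ix),
                 t(colMeans(table$rel_abund[ix, drivers, drop = FALSE])),
                 check.names = FALSE)
    }))
  } else NULL
  structure(list(dist = d, selection = sel, k = k,
                 assignments = cl$assignments, medoids = cl$medoids,
                 pcoa = pc, label_series = series, runs = runs,
                 driver_summary = driver_summary,
                 weak_clustering = sel$weak_clustering),
            class = "enterotype_result")
}

#' @export
print.enterotype_result <- function(x, ...) {
  cat(sprintf("enterotype_result: k = %d (%s), mean silhouette %.3f\n",
              x$k,
              if (x$weak_clustering) "weak clustering" else "supported",
              max(x$selection$table$mean_silhouette)))
  if (!is.null(x$runs))
    cat(sprintf("  temporal clustering: %d runs, p = %.4g\n",
                x$runs$n_runs, x$runs$p_clustered))
  invisible(x)
}
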