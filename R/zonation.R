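#' Partitioning-around-medoids clustering of cell score vectors
#'
#' k-medoids (BUILD + SWAP, Euclidean distance) on the top principal-component
#' scores of the transformed genomic surface. The deterministic BUILD + SWAP
#' run is compared against `n_restarts - 1` seeded random-initialization +
#' SWAP runs and the lowest-cost solution kept. The within-cluster variation
#' is reported scale-free: `W = mean distance to assigned medoid / RMS
#' distance of all points to the global (1-medoid) center`.
#'
#' @param points Numeric matrix or tibble of points by coordinates (e.g. the
#'   `PC1..PC3` columns of [pca_scores()] output).
#' @param k Number of clusters (`1 <= k <= n`).
#' @param seed Seed for the random restarts.
#' @param n_restarts Total candidate runs (default 5; the first is the
#'   deterministic BUILD + SWAP run).
#' @param medoids Optional integer vector of row indices used as a
#'   warm-start initialization (additional candidate run).
#' @return List with `assignment` (integer vector), `medoids` (row indices),
#'   `cost` (sum of point-to-medoid distances), `W` (normalized
#'   within-cluster variation) and `k`.
#' @export
pam_cluster <- function(points, k, seed = 1, n_restarts = 5, medoids = NULL) {
  M <- as.matrix(points)
  n <- nrow(M)
  if (k > n) stop("k exceeds the number of points", call. = FALSE)
  if (any(!is.finite(M))) stop("points must be finite", call. = FALSE)
  if (k == n) {
    return(list(assignment = seq_len(n), medoids = seq_len(n), cost = 0,
                W = 0, k = k))
  }
  runs <- list(cluster::pam(M, k, metric = "euclidean", do.swap = TRUE,
                            keep.diss = FALSE, keep.data = FALSE))
  if (n_restarts > 1) {
    set.seed(derive_seed(seed, sprintf("pam_restarts_k%d", k)))
    for (r in seq_len(n_restarts - 1)) {
      init <- sample.int(n, k)
      runs[[length(runs) + 1]] <-
        cluster::pam(M, k, metric = "euclidean", medoids = init,
                     do.swap = TRUE, keep.diss = FALSE, keep.data = FALSE)
    }
  }
  if (!is.null(medoids)) {
    runs[[length(runs) + 1]] <-
      cluster::pam(M, k, metric = "euclidean", medoids = medoids,
                   do.swap = TRUE, keep.diss = FALSE, keep.data = FALSE)
  }
  costs <- vapply(runs, function(r) sum(pam_point_costs(M, r$id.med)),
                  numeric(1))
  best <- runs[[which.min(costs)]]
  cost <- min(costs)
  list(assignment = as.integer(best$clustering),
       medoids = as.integer(best$id.med), cost = cost,
       W = (cost / n) / rms_scale(M), k = k)
}

# distance of each point to its nearest medoid
pam_point_costs <- function(M, med_idx) {
  d2 <- vapply(med_idx, function(m) rowSums(sweep(M, 2, M[m, ])^2),
               numeric(nrow(M)))
  sqrt(apply(as.matrix(d2), 1, min))
}

# RMS distance of points to the global 1-medoid center (scale denominator)
rms_scale <- function(M) {
  ctr <- cluster::pam(M, 1, metric = "euclidean", do.swap = TRUE,
                      keep.diss = FALSE, keep.data = FALSE)$id.med
  sqrt(mean(rowSums(sweep(M, 2, M[ctr, ])^2)))
}

#' Scan cluster numbers and record within-cluster variation
#'
#' Runs [pam_cluster()] for every k in `k_range` (k = 1 is always computed
#' internally so the reduction at k = 2 is defined) and records W(k) and its
#' reduction r(k) = W(k-1) - W(k). Each k is additionally warm-started from
#' the k-1 medoids plus the point farthest from them, which guarantees W(k)
#' is non-increasing (an extra medoid cannot raise the cost and SWAP only
#' lowers it).
#'
#' For tractability on large grids, PAM runs on a seeded random subsample of
#' at most `max_points` cells; every point is then assigned to its nearest
#' medoid.
#'
#' @param points Points-by-coordinates matrix or tibble (see [pam_cluster()]).
#' @param k_range Integer vector of cluster numbers (default `2:16`).
#' @param seed Seed for restarts and subsampling.
#' @param n_restarts Candidate runs per k (see [pam_cluster()]).
#' @param max_points Subsample ceiling (default 20000).
#' @return A `cluster_scan` object: tibble `scan` (k, W, reduction), list
#'   `fits` (per-k pam results on the subsample), `subsample` (row indices),
#'   `points`, `seed`.
#' @export
cluster_scan <- function(points, k_range = 2:16, seed = 1, n_restarts = 5,
                         max_points = 20000) {
  M <- as.matrix(points)
  n <- nrow(M)
  if (any(k_range < 1) || any(k_range > n)) {
    stop("k_range outside [1, n_points]", call. = FALSE)
  }
  sub <- seq_len(n)
  if (n > max_points) {
    set.seed(derive_seed(seed, "cluster_scan_subsample"))
    sub <- sort(sample.int(n, max_points))
  }
  S <- M[sub, , drop = FALSE]
  ks <- sort(unique(c(1L, as.integer(k_range))))
  fits <- list()
  W <- stats::setNames(numeric(length(ks)), ks)
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    warm <- NULL
    if (!is.null(prev) && length(prev$medoids) == k - 1) {
      costs <- pam_point_costs(S, prev$medoids)
      far <- which.max(costs)
      warm <- unique(c(prev$medoids, far))
      if (length(warm) < k) warm <- NULL
    }
    fit <- pam_cluster(S, k, seed = seed, n_restarts = n_restarts,
                       medoids = warm)
    # keep the warm-started solution if the fresh one is worse (monotone W)
    if (!is.null(prev) && fit$W > W[i - 1] + 1e-12) {
      fit <- pam_cluster(S, k, seed = seed, n_restarts = 1, medoids = warm)
    }
    fits[[as.character(k)]] <- fit
    W[i] <- fit$W
    prev <- fit
  }
  scan <- tibble::tibble(
    k = ks, W = as.numeric(W),
    reduction = c(NA_real_, pmax(-diff(as.numeric(W)), 0)))
  scan <- scan[scan$k %in% k_range | scan$k == 1, ]
  structure(list(scan = scan[scan$k %in% k_range, ],
                 scan_full = scan, fits = fits, subsample = sub,
                 points = M, seed = seed),
            class = "cluster_scan")
}

#' @export
print.cluster_scan <- function(x, ...) {
  rng <- range(x$scan$k)
  cat(sprintf("<cluster_scan> k = %d..%d; W: %.4f -> %.4f\n", rng[1], rng[2],
              x$scan$W[1], x$scan$W[nrow(x$scan)]))
  invisible(x)
}

#' @export
tidy.cluster_scan <- function(x, ...) x$scan

#' Select the operational number of zones from a cluster scan
#'
#' Implements the elbow rule "adding one more cluster explains substantially
#' less within-cluster variation than adding previous clusters did": the
#' chosen k is the smallest scanned k whose next reduction satisfies
#' `r(k+1) < theta * median(r(2..k))`. If no k qualifies, the maximum scanned
#' k is returned with a `no_elbow` flag. The full decision trace is returned
#' so the rule can be audited or overridden.
#'
#' @param scan A `cluster_scan` (needs at least 3 scanned k values).
#' @param theta Fraction of the median prior reduction that counts as
#'   "substantially less" (default 0.5).
#' @return List with `k`, `no_elbow`, `theta` and a `trace` tibble
#'   (k, next_reduction, median_prior, threshold, triggered).
#' @export
select_k <- function(scan, theta = 0.5) {
  stopifnot(inherits(scan, "cluster_scan"))
  full <- scan$scan_full
  ks <- full$k[full$k >= 2]
  r <- stats::setNames(full$reduction[match(ks, full$k)], ks)
  if (length(ks) < 3) stop("scan needs at least 3 k values", call. = FALSE)
  cand <- ks[-length(ks)]
  trace <- purrr::map_dfr(cand, function(k) {
    prior <- r[as.character(ks[ks >= 2 & ks <= k])]
    nxt <- r[as.character(k + 1)]
    med <- stats::median(prior)
    tibble::tibble(k = k, next_reduction = as.numeric(nxt),
                   median_prior = med, threshold = theta * med,
                   triggered = isTRUE(nxt < theta * med))
  })
  hit <- which(trace$triggered)
  if (length(hit) == 0) {
    gf_log("select_k: no elbow at theta = %g; returning k_max = %d", theta,
           max(ks))
    return(list(k = max(ks), no_elbow = TRUE, theta = theta, trace = trace))
  }
  list(k = trace$k[hit[1]], no_elbow = FALSE, theta = theta, trace = trace)
}

#' Build a zone map from cluster assignments
#'
#' Every masked-in grid cell is assigned to its nearest medoid (ties broken
#' by the lowest zone id) and zone ids are relabeled 1..k by descending zone
#' area for stable presentation.
#'
#' @param scan A `cluster_scan` built from the grid's score columns.
#' @param grid The `genomic_grid` (with `x`, `y`) the scan points came from,
#'   one row per scan point.
#' @param k Number of zones (e.g. `select_k(scan)$k`).
#' @return A [zone_map()].
#' @export
make_zone_map <- function(scan, grid, k) {
  stopifnot(inherits(scan, "cluster_scan"))
  fit <- scan$fits[[as.character(k)]]
  if (is.null(fit)) stop(sprintf("k = %d was not scanned", k), call. = FALSE)
  M <- scan$points
  if (nrow(M) != nrow(grid)) {
    stop("scan points and grid geometry are misaligned", call. = FALSE)
  }
  med_rows <- scan$subsample[fit$medoids]
  d2 <- vapply(med_rows, function(m) rowSums(sweep(M, 2, M[m, ])^2),
               numeric(nrow(M)))
  assign <- apply(as.matrix(d2), 1, which.min)  # which.min takes lowest index on ties
  sizes <- tabulate(assign, nbins = k)
  relabel <- integer(k)
  relabel[order(-sizes, seq_len(k))] <- seq_len(k)
  zone_map(tibble::tibble(x = grid$x, y = grid$y,
                          zone = relabel[assign]),
           cellsize = grid_cellsize(grid), crs = attr(grid, "crs"),
           provenance = sprintf("gfzone PAM k=%d seed=%d", k, scan$seed))
}
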