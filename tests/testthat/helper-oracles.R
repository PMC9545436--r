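# Independent oracles and small fixture builders used across the suite.

# quiet package logging during tests
options(gfzone.verbose = FALSE)

# A climate tibble of n rows with the 20 canonical columns drawn iid uniform
# over each variable's plausible range (no inter-variable correlation), so
# importance attribution tests are not confounded by correlated decoys.
iid_climate <- function(n, seed = 1) {
  set.seed(seed)
  cv <- climate_variables()
  out <- tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)))
  for (i in seq_len(nrow(cv))) {
    out[[cv$variable[i]]] <- stats::runif(n, cv$lo[i], cv$hi[i])
  }
  out
}

# Weir & Cockerham (1984) multi-population theta for biallelic dosages,
# written directly from the variance-component formulas as an independent
# estimator of FST on simulated data.
wc_fst <- function(dosages, pops) {
  pops <- as.factor(pops)
  r <- nlevels(pops)
  num <- 0; den <- 0
  for (j in seq_len(ncol(dosages))) {
    d <- dosages[, j]
    ok <- !is.na(d)
    dj <- d[ok]; pj <- pops[ok]
    n_i <- tapply(rep(1, length(dj)), pj, sum)
    if (any(is.na(n_i)) || length(n_i) < 2) next
    p_i <- tapply(dj, pj, function(x) sum(x) / (2 * length(x)))
    h_i <- tapply(dj, pj, function(x) mean(x == 1))
    n_bar <- mean(n_i)
    p_bar <- sum(n_i * p_i) / (r * n_bar)
    if (p_bar <= 0 || p_bar >= 1) next
    s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n_i * h_i) / (r * n_bar)
    n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
         h_bar * (2 * n_bar - 1) / (4 * n_bar))
    cc <- h_bar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force turnover oracle: the weighted tally of split improvements at
# split values <= x, summed in ascending-value order.
split_tally <- function(values, weights, x) {
  o <- order(values)
  values <- values[o]; weights <- weights[o]
  vapply(x, function(xx) sum(weights[values <= xx]), numeric(1))
}

# Exhaustive k-medoids: enumerate every medoid subset of size k and return the
# minimum total point-to-medoid distance. Feasible for n <= 14.
exhaustive_pam_cost <- function(M, k) {
  M <- as.matrix(M)
  D <- as.matrix(stats::dist(M))
  combos <- utils::combn(nrow(M), k)
  min(apply(combos, 2, function(med) sum(apply(D[, med, drop = FALSE], 1, min))))
}

# Hand application of the elbow rule: smallest k with
# r(k+1) < theta * median(r(2..k)); NA if never triggered.
elbow_oracle <- function(r, ks, theta = 0.5) {
  for (k in ks[-length(ks)]) {
    prior <- r[as.character(2:k)]
    if (isTRUE(r[[as.character(k + 1)]] < theta * stats::median(prior))) {
      return(k)
    }
  }
  NA_integer_
}

# Construct a cluster_scan object from a given W(k) sequence (k = 1..length),
# so the k-selection rule can be tested on constructed reduction profiles.
fake_scan <- function(W) {
  ks <- seq_along(W)
  scan <- tibble::tibble(k = ks, W = W,
                         reduction = c(NA_real_, pmax(-diff(W), 0)))
  structure(list(scan = scan[scan$k >= 2, ], scan_full = scan,
                 fits = list(), subsample = integer(0),
                 points = matrix(numeric(0), 0, 0), seed = 1L),
            class = "cluster_scan")
}

# Six well-separated Gaussian blobs in 3D (pairwise center distance >= 8 sd).
six_blobs <- function(n_per = 100, sd = 1, seed = 42) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0),
                   c(0, 0, 10), c(10, 10, 0), c(0, 10, 10))
  pts <- do.call(rbind, lapply(seq_len(6), function(i) {
    matrix(stats::rnorm(n_per * 3, sd = sd), ncol = 3) +
      matrix(centers[i, ], n_per, 3, byrow = TRUE)
  }))
  list(points = pts, labels = rep(seq_len(6), each = n_per), centers = centers)
}

# A small zone map on an nx x ny unit grid (cellsize in metres).
toy_zone_map <- function(zones, nx, ny, cellsize = 800, provenance = "toy") {
  cells <- expand.grid(x = (seq_len(nx) - 0.5) * cellsize,
                       y = (seq_len(ny) - 0.5) * cellsize)
  zone_map(tibble::tibble(x = cells$x, y = cells$y, zone = as.integer(zones)),
           cellsize = cellsize, provenance = provenance)
}
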