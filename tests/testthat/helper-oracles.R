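# Independent reference implementations used to cross-check the package's
# primitives. These deliberately use naive algorithms.

# Quadratic-time Needleman-Wunsch score (no traceback), pure R.
nw_score_oracle <- function(ref, read, wildcard, match = 1, mismatch = -1,
                            gap = -2) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(read, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  H[1, ] <- (0:m) * gap
  H[, 1] <- (0:n) * gap
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j] || (wildcard[i] && b[j] %in% c("C", "T")))
        match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
    }
  }
  H[n + 1, m + 1]
}

# Brute-force minimum enclosing circle over all pairs and triples of the
# convex hull of the point set.
mec_oracle <- function(pts) {
  if (nrow(pts) > 2) {
    pts <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  }
  n <- nrow(pts)
  covers <- function(ctr, r) {
    all(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <= r + 1e-7)
  }
  best <- NULL
  consider <- function(ctr, r) {
    if (covers(ctr, r) && (is.null(best) || r < best$radius)) {
      best <<- list(center = ctr, radius = r)
    }
  }
  if (n == 1) return(list(center = pts[1, ], radius = 0))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    consider(ctr, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  }
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      p <- pts[i, ]; q <- pts[j, ]; r <- pts[k, ]
      d <- 2 * (p[1] * (q[2] - r[2]) + q[1] * (r[2] - p[2]) + r[1] * (p[2] - q[2]))
      if (abs(d) < 1e-9) next
      ux <- (sum(p^2) * (q[2] - r[2]) + sum(q^2) * (r[2] - p[2]) +
             sum(r^2) * (p[2] - q[2])) / d
      uy <- (sum(p^2) * (r[1] - q[1]) + sum(q^2) * (p[1] - r[1]) +
             sum(r^2) * (q[1] - p[1])) / d
      consider(c(ux, uy), sqrt(sum((p - c(ux, uy))^2)))
    }
  }
  best
}

# Maximum Feret diameter by all-pairs distance over boundary pixel centers.
feret_oracle <- function(mask) {
  pts <- methylmorph:::boundary_points(mask)
  if (nrow(pts) < 2) return(0)
  max(stats::dist(pts))
}

# Closed-form OLS slope/intercept/p via the normal equations + t CDF.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Random connected blob mask (<= 64 x 64) for oracle comparisons.
random_small_mask <- function(seed) {
  shapes <- c("circle", "ellipse", "square", "perturbed_blob")
  withr::with_seed(seed, {
    shape <- sample(shapes, 1)
    switch(shape,
      circle = generate_tumor_mask("circle", size_px = 64,
                                   r = runif(1, 8, 27)),
      ellipse = generate_tumor_mask("ellipse", size_px = 64,
                                    a = runif(1, 10, 27), b = runif(1, 5, 20)),
      square = generate_tumor_mask("square", size_px = 64,
                                   side = runif(1, 10, 40)),
      perturbed_blob = generate_tumor_mask("perturbed_blob", size_px = 64,
                                           r = runif(1, 8, 20),
                                           perturbation = runif(1, 0, 0.3),
                                           seed = seed + 1000))
  })
}
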