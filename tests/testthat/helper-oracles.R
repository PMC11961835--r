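# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops and dense-grid sweeps only.

# First-order features by an explicit all-voxel loop.
oracle_first_order <- function(volume, mask) {
  d <- dim(volume$voxels)
  suv_max <- -Inf; total <- 0; count <- 0
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask$voxels[i, j, k]) {
      v <- volume$voxels[i, j, k]
      if (v > suv_max) suv_max <- v
      total <- total + v
      count <- count + 1
    }
  }
  mtv <- count * prod(volume$spacing) / 1000
  list(suv_max = suv_max, suv_mean = total / count, mtv_ml = mtv,
       tlg = (total / count) * mtv)
}

# Bin centres computed independently of the package's discretise().
oracle_bin_centres <- function(suvs, width = 0.3, anchor = 0) {
  anchor + (floor((suvs - anchor) / width) + 0.5) * width
}

# Fraction of ROI volume with (binned) uptake >= x * max, swept on a dense
# grid and integrated by the midpoint rule.
oracle_csh_auc <- function(suvs, width = 0.3, anchor = 0, ngrid = 1e5) {
  centres <- oracle_bin_centres(suvs, width, anchor)
  m <- max(centres)
  xs <- (seq_len(ngrid) - 0.5) / ngrid
  sc <- sort(centres)
  # count of centres >= t via binary search on the sorted values
  y <- vapply(xs, function(x) {
    t <- x * m
    lo <- findInterval(t - 1e-12, sc)
    (length(sc) - lo) / length(sc)
  }, numeric(1))
  mean(y)
}

# Fraction of voxels at or above one absolute threshold (for curve checks).
oracle_frac_at <- function(suvs, level, width = 0.3, anchor = 0) {
  centres <- oracle_bin_centres(suvs, width, anchor)
  mean(centres >= level - 1e-12)
}

# Kaplan-Meier by explicit risk-set enumeration.
oracle_km <- function(times, events) {
  ut <- sort(unique(times))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    t <- ut[i]
    at_risk <- 0; d <- 0
    for (j in seq_along(times)) {
      if (times[j] >= t) at_risk <- at_risk + 1
      if (times[j] == t && events[j] == 1) d <- d + 1
    }
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# Two-group log-rank chi-square by explicit O/E table enumeration.
oracle_logrank2 <- function(times, events, group) {
  gl <- sort(unique(group))
  stopifnot(length(gl) == 2)
  ev_times <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & group == gl[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == gl[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (abs(O1 - E1) < 1e-12) return(0)
  (O1 - E1)^2 / V
}

# A random blob-shaped phantom for property tests: lognormal-ish SUVs on a
# random ellipsoidal mask.
random_phantom <- function(seed, shape = c(12, 14, 10), spacing = c(2, 2, 3)) {
  cshpet:::with_seed(seed, {
    vals <- array(exp(rnorm(prod(shape), log(4), 0.5)), dim = shape)
    centre <- shape / 2 + runif(3, -1, 1)
    semi <- runif(3, 2.5, shape / 2 - 0.5)
    idx <- arrayInd(seq_len(prod(shape)), shape)
    inside <- rowSums(sweep(idx, 2, centre, "-")^2 / rep(semi^2,
                                                         each = nrow(idx)))
    msk <- array(inside <= 1, dim = shape)
    if (!any(msk)) msk[ceiling(shape[1] / 2), ceiling(shape[2] / 2),
                       ceiling(shape[3] / 2)] <- TRUE
    v <- suv_volume(vals, spacing = spacing)
    list(volume = v, mask = roi_mask(msk, reference = v))
  })
}
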