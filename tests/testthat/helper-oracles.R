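# Independent brute-force oracles and tiny fixtures. Everything here is
# deliberately written as plain nested-loop R, independent of the package's
# compiled builders.

# discretized ROI directly from an integer level array (0 = outside ROI)
make_droi <- function(levels, spacing = c(1, 1, 1), bin_width = 1) {
  levels <- array(as.integer(levels), dim(as.array(levels)))
  if (length(dim(levels)) == 2L) dim(levels) <- c(dim(levels), 1L)
  structure(list(levels = levels, n_levels = max(levels), bin_width = bin_width,
                 anchor = 0, voxel_volume = prod(spacing), spacing = spacing),
            class = "discretized_roi")
}

# random small ROI: levels 1..ng on a dx x dy x dz grid with a random
# in-ROI pattern (every level guaranteed present at least once)
random_droi <- function(dmax = 6, ngmax = 6) {
  nd <- c(sample(2:dmax, 1), sample(2:dmax, 1), sample(2:dmax, 1))
  ng <- sample(2:ngmax, 1)
  lev <- array(sample(0:ng, prod(nd), replace = TRUE), nd)
  if (sum(lev > 0) < 2) lev[1:2] <- c(1L, 1L)
  present <- sort(unique(lev[lev > 0]))
  # remap so levels are exactly 1..length(present)
  lev[lev > 0] <- match(lev[lev > 0], present)
  make_droi(lev)
}

in_bounds <- function(v, nd) all(v >= 1) && all(v <= nd)

# exhaustive pair-count GLCM for one direction
oracle_glcm_dir <- function(lev, dir, ng) {
  nd <- dim(lev)
  M <- matrix(0L, ng, ng)
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    p <- c(x, y, z) + dir
    if (!in_bounds(p, nd)) next
    b <- lev[p[1], p[2], p[3]]
    if (b == 0) next
    M[a, b] <- M[a, b] + 1L
    M[b, a] <- M[b, a] + 1L
  }
  M
}

# exhaustive run scanner: walks every maximal same-level segment
oracle_glrlm_dir <- function(lev, dir, ng) {
  nd <- dim(lev)
  runs <- list()
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - dir
    if (in_bounds(prev, nd) && lev[prev[1], prev[2], prev[3]] == a) next
    len <- 1
    cur <- c(x, y, z) + dir
    while (in_bounds(cur, nd) && lev[cur[1], cur[2], cur[3]] == a) {
      len <- len + 1
      cur <- cur + dir
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  rmax <- max(vapply(runs, `[`, numeric(1), 2))
  M <- matrix(0L, ng, rmax)
  for (r in runs) M[r[1], r[2]] <- M[r[1], r[2]] + 1L
  M
}

# flood-fill zone finder (26-connectivity)
oracle_glszm <- function(lev, ng) {
  nd <- dim(lev)
  seen <- array(FALSE, nd)
  zones <- list()
  nbors <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbors <- nbors[rowSums(abs(nbors)) > 0, ]
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    if (lev[x, y, z] == 0 || seen[x, y, z]) next
    a <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (k in 1:nrow(nbors)) {
        p <- v + nbors[k, ]
        if (in_bounds(p, nd) && !seen[p[1], p[2], p[3]] &&
            lev[p[1], p[2], p[3]] == a) {
          seen[p[1], p[2], p[3]] <- TRUE
          queue[[length(queue) + 1]] <- p
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  smax <- max(vapply(zones, `[`, numeric(1), 2))
  M <- matrix(0L, ng, smax)
  for (zn in zones) M[zn[1], zn[2]] <- M[zn[1], zn[2]] + 1L
  M
}

# neighbor scans for GLDM (alpha = 0) and NGTDM
oracle_gldm <- function(lev, ng) {
  nd <- dim(lev)
  M <- matrix(0L, ng, 27)
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    dep <- 0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (in_bounds(p, nd) && lev[p[1], p[2], p[3]] == a) dep <- dep + 1
    }
    M[a, dep + 1] <- M[a, dep + 1] + 1L
  }
  M
}

oracle_ngtdm <- function(lev, ng) {
  nd <- dim(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in 1:nd[1]) for (y in 1:nd[2]) for (z in 1:nd[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    vals <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      p <- c(x + dx, y + dy, z + dz)
      if (in_bounds(p, nd) && lev[p[1], p[2], p[3]] > 0)
        vals <- c(vals, lev[p[1], p[2], p[3]])
    }
    if (length(vals) > 0) {
      n_i[a] <- n_i[a] + 1
      s_i[a] <- s_i[a] + abs(a - mean(vals))
    }
  }
  list(n = n_i, s = s_i)
}

# two-way ANOVA mean squares via stats::aov, then the absolute-agreement
# single-rater ICC substituted by hand
oracle_icc_a1 <- function(M) {
  n <- nrow(M); k <- ncol(M)
  df <- data.frame(y = as.vector(M),
                   subj = factor(rep(1:n, k)),
                   rater = factor(rep(1:k, each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# rmcorr via an explicit ANCOVA design matrix and sequential sums of squares
oracle_rmcorr <- function(x, y, subject) {
  fit <- stats::lm(y ~ factor(subject) + x)
  tab <- stats::anova(fit)
  ss_x <- tab["x", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  b <- stats::coef(fit)[["x"]]
  list(r = sign(b) * sqrt(ss_x / (ss_x + ss_err)),
       df = tab["Residuals", "Df"],
       p = tab["x", "Pr(>F)"])
}

# small, fast cohort spec for pipeline tests
toy_spec <- function(n = 2, seed = 11)
  cohort_spec(n_subjects = n, seed = seed, lesion_diameter_mm = c(18, 26),
              inplane_pixel_mm = c(1.0, 1.27))
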