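# Brute-force oracles, written as naive per-voxel loops so they stay
# independent of the vectorized/graph-based implementations they check.

# All 26 neighbor offsets as a list.
oracle_offsets26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx || dy || dz) out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

in_bounds <- function(p, d) all(p >= 1L) && all(p <= d)

# Ordered-pair co-occurrence counts for one offset, then symmetrized.
oracle_glcm <- function(gray, ng, off) {
  d <- dim(gray)
  C <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    g1 <- gray[x, y, z]
    if (is.na(g1)) next
    q <- c(x, y, z) + off
    if (!in_bounds(q, d)) next
    g2 <- gray[q[1], q[2], q[3]]
    if (is.na(g2)) next
    C[g1, g2] <- C[g1, g2] + 1
  }
  C <- C + t(C)
  if (sum(C) > 0) C / sum(C) else C
}

# Flood-fill zone inventory (26-connectivity, equal level).
oracle_zones <- function(gray) {
  d <- dim(gray)
  seen <- array(FALSE, d)
  offs <- oracle_offsets26()
  zones <- list()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (is.na(gray[x, y, z]) || seen[x, y, z]) next
    lev <- gray[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in offs) {
        q <- p + o
        if (in_bounds(q, d) && !seen[q[1], q[2], q[3]] &&
            !is.na(gray[q[1], q[2], q[3]]) &&
            gray[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = lev, size = size)
  }
  df <- as.data.frame(do.call(rbind, zones))
  df[order(df$level, df$size), , drop = FALSE]
}

# Per-voxel dependence counts (Chebyshev delta = 1, tolerance alpha).
# Voxels visited in column-major (linear index) order.
oracle_gldm <- function(gray, alpha = 0) {
  d <- dim(gray)
  offs <- oracle_offsets26()
  out <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    g1 <- gray[x, y, z]
    if (is.na(g1)) next
    dep <- 0L
    for (o in offs) {
      q <- c(x, y, z) + o
      if (in_bounds(q, d) && !is.na(gray[q[1], q[2], q[3]]) &&
          abs(gray[q[1], q[2], q[3]] - g1) <= alpha) {
        dep <- dep + 1L
      }
    }
    out[[length(out) + 1L]] <- c(level = g1, dependence = dep)
  }
  as.data.frame(do.call(rbind, out))
}

# Per-level n, p, s table (voxels with no in-ROI neighbor excluded).
oracle_ngtdm <- function(gray) {
  d <- dim(gray)
  offs <- oracle_offsets26()
  lev <- c(); diffs <- c()
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    g1 <- gray[x, y, z]
    if (is.na(g1)) next
    nb <- c()
    for (o in offs) {
      q <- c(x, y, z) + o
      if (in_bounds(q, d) && !is.na(gray[q[1], q[2], q[3]])) {
        nb <- c(nb, gray[q[1], q[2], q[3]])
      }
    }
    if (!length(nb)) next
    lev <- c(lev, g1)
    diffs <- c(diffs, abs(g1 - mean(nb)))
  }
  levels <- sort(unique(lev))
  out <- data.frame(
    level = levels,
    n = vapply(levels, function(l) sum(lev == l), numeric(1)),
    s = vapply(levels, function(l) sum(diffs[lev == l]), numeric(1)))
  out$nvp <- rep(length(lev), nrow(out))
  out
}

# Random small discretized test array with an irregular ROI.
random_gray <- function(seed, max_dim = c(5L, 5L, 3L), ng = 4L,
                        p_roi = 0.75) {
  set.seed(seed)
  d <- c(sample(2:max_dim[1], 1), sample(2:max_dim[2], 1),
         sample(1:max_dim[3], 1))
  g <- array(sample.int(ng, prod(d), replace = TRUE), d)
  roi <- array(runif(prod(d)) < p_roi, d)
  if (!any(roi)) roi[1, 1, 1] <- TRUE
  g[!roi] <- NA_integer_
  g
}

# Small synthetic cohort shared by slower tests (built once per session).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 8L, image_shape = c(20L, 20L, 14L),
                        roi_radius_by_label = c(4, 6), seed = 424L)
      gen <- generate_genomic_cohort(cfg)
      imgs <- generate_image_cohort(cfg, gen$truth$cic)
      cache <<- list(config = cfg, genomic = gen, images = imgs)
    }
    cache
  }
})
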