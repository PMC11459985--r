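# Independent brute-force oracles for the texture-matrix builders.
# Everything here is written with explicit nested loops and flood fills,
# sharing no code with the package implementation.

# All 26 neighbour offsets as a plain list.
oracle_offsets26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (dx || dy || dz) out[[length(out) + 1L]] <- c(dx, dy, dz)
  out
}

# The 13 unique directions: keep one of each +/- pair.
oracle_offsets13 <- function() {
  out <- list()
  for (o in oracle_offsets26()) {
    if (o[3] > 0 || (o[3] == 0 && o[2] > 0) ||
        (o[3] == 0 && o[2] == 0 && o[1] > 0))
      out[[length(out) + 1L]] <- o
  }
  out
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# Symmetric co-occurrence counts by explicit pair enumeration.
oracle_glcm <- function(lev, ng, distance = 1L) {
  d <- dim(lev)
  m <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (o in oracle_offsets26()) {
      q <- c(x, y, z) + o * distance
      if (!in_grid(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (is.na(b)) next
      m[a, b] <- m[a, b] + 1
    }
  }
  m
}

# Run-length counts by walking each line voxel by voxel.
oracle_glrlm <- function(lev, ng) {
  d <- dim(lev)
  runs <- list()
  for (o in oracle_offsets13()) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      a <- lev[x, y, z]
      if (is.na(a)) next
      prev <- c(x, y, z) - o
      if (in_grid(prev, d)) {
        pv <- lev[prev[1], prev[2], prev[3]]
        if (!is.na(pv) && pv == a) next  # not a run start
      }
      len <- 1L
      cur <- c(x, y, z) + o
      while (in_grid(cur, d)) {
        v <- lev[cur[1], cur[2], cur[3]]
        if (is.na(v) || v != a) break
        len <- len + 1L
        cur <- cur + o
      }
      runs[[length(runs) + 1L]] <- c(a, len)
    }
  }
  lmax <- max(vapply(runs, `[`, 0, 2))
  m <- matrix(0, ng, lmax)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

# 26-connected zones by stack-based flood fill.
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    g <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    members <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members[[length(members) + 1L]] <- p
      for (o in oracle_offsets26()) {
        q <- p + o
        if (!in_grid(q, d)) next
        if (seen[q[1], q[2], q[3]]) next
        v <- lev[q[1], q[2], q[3]]
        if (is.na(v) || v != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
    zones[[length(zones) + 1L]] <- list(level = g, members = members)
  }
  zones
}

oracle_glszm <- function(lev, ng) {
  zones <- oracle_zones(lev)
  smax <- max(vapply(zones, function(z) length(z$members), 0L))
  m <- matrix(0, ng, smax)
  for (z in zones) {
    s <- length(z$members)
    m[z$level, s] <- m[z$level, s] + 1
  }
  m
}

# Free-space city-block distance of a voxel to the nearest out-of-mask
# voxel, the grid being surrounded by out-of-mask space.
oracle_border_distance <- function(p, lev) {
  d <- dim(lev)
  best <- Inf
  # distance to the virtual outside beyond each face
  best <- min(best, p[1], d[1] + 1 - p[1], p[2], d[2] + 1 - p[2],
              p[3], d[3] + 1 - p[3])
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lev[x, y, z]))
      best <- min(best, abs(x - p[1]) + abs(y - p[2]) + abs(z - p[3]))
  }
  best
}

oracle_gldzm <- function(lev, ng) {
  zones <- oracle_zones(lev)
  recs <- lapply(zones, function(z) {
    dmin <- Inf
    for (p in z$members)
      dmin <- min(dmin, oracle_border_distance(p, lev))
    c(z$level, max(1, dmin))
  })
  dmax <- max(vapply(recs, `[`, 0, 2))
  m <- matrix(0, ng, dmax)
  for (r in recs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

# Neighbourhood grey-tone difference table by explicit neighbour loops.
oracle_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  n_i <- rep(0, ng)
  s_i <- rep(0, ng)
  nvc <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (o in oracle_offsets26()) {
      q <- c(x, y, z) + o
      if (!in_grid(q, d)) next
      v <- lev[q[1], q[2], q[3]]
      if (!is.na(v)) nb <- c(nb, v)
    }
    if (length(nb) == 0) next
    nvc <- nvc + 1
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, s = s_i, nvc = nvc)
}

# Random test ROI: levels in 1..ng with a random out-of-mask pattern,
# wrapped in the package's volume/mask containers.
random_droi <- function(dim3 = c(4, 4, 4), ng = 4, p_mask = 0.8,
                        seed = 1) {
  set.seed(seed)
  vals <- array(sample.int(ng, prod(dim3), replace = TRUE), dim = dim3)
  msk <- array(stats::runif(prod(dim3)) < p_mask, dim = dim3)
  if (sum(msk) < 2) msk[1:2] <- TRUE
  vol <- structure(list(data = array(as.numeric(vals), dim3), spacing = 1,
                        origin = c(0, 0, 0)), class = "activity_volume")
  mask <- structure(list(data = msk, spacing = 1, origin = c(0, 0, 0),
                         voxel_count = sum(msk)), class = "roi_mask")
  # identity discretization: values are already levels 1..ng
  droi <- discretize_fbn(vol, mask, ng = ng)
  lev <- array(NA_integer_, dim3)
  lev[msk] <- vals[msk]
  droi$levels <- lev  # exact levels, bypassing min-max rebinning
  droi
}

# Build a discretized ROI directly from a level array (NA = out of mask).
droi_from_levels <- function(lev, ng) {
  msk <- !is.na(lev)
  mask <- structure(list(data = msk, spacing = 1, origin = c(0, 0, 0),
                         voxel_count = sum(msk)), class = "roi_mask")
  structure(list(levels = lev, ng = as.integer(ng), mask = mask,
                 degenerate = length(unique(lev[msk])) < 2),
            class = "discretized_roi")
}

# Tiny volume/mask pair from a numeric array (all voxels in-mask).
tiny_volume <- function(a, spacing = 1) {
  structure(list(data = a, spacing = spacing, origin = c(0, 0, 0)),
            class = "activity_volume")
}

tiny_mask <- function(d, spacing = 1, data = NULL) {
  if (is.null(data)) data <- array(TRUE, d)
  structure(list(data = data, spacing = spacing, origin = c(0, 0, 0),
                 voxel_count = sum(data)), class = "roi_mask")
}
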