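# ---- shared fixtures -------------------------------------------------------

# small clinical-geometry phantom (fast); full-size cohort phantoms are built
# only in the acceptance tests
small_phantom <- function(seed = 3, cmb_list = NULL, noise_sigma = 5,
                          bias_amplitude = 0, grid_shape = c(72, 72, 11)) {
  if (is.null(cmb_list)) {
    # one 6 mm lesion placed relative to the brain ellipsoid so the same
    # helper works across grid sizes; grids too small to hold a brain get
    # no lesion
    geom <- midas:::phantom_geometry(phantom_spec(grid_shape = grid_shape,
                                                  seed = seed))
    cmb_list <- if (min(geom$brain) > 8)
      list(list(centre_mm = c(0.45, 0.3, 0) * geom$csf_inner,
                diameter_mm = min(6, max(2, geom$brain[1] / 2)),
                intensity_fraction = 0.3, region = "lobar"))
    else list()
  }
  make_phantom(phantom_spec(grid_shape = grid_shape,
                            cmb_list = cmb_list, noise_sigma = noise_sigma,
                            bias_amplitude = bias_amplitude, seed = seed))
}

# mid-size phantom used for parameter-recovery checks (less partial volume)
recovery_phantom <- function(seed = 11, noise_sigma = 5,
                             bias_amplitude = 0) {
  make_phantom(phantom_spec(grid_shape = c(120, 120, 17),
                            noise_sigma = noise_sigma,
                            bias_amplitude = bias_amplitude, seed = seed))
}

random_volume <- function(dim = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  volume3d(array(runif(prod(dim)), dim), spacing = spacing)
}

# ---- independent oracles ---------------------------------------------------

# queue-based flood fill, deliberately naive
floodfill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    if (connectivity == 6 && abs(a) + abs(b) + abs(c) != 1) next
    offs[[length(offs) + 1]] <- c(a, b, c)
  }
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      k <- (v - 1) %/% (d[1] * d[2])
      j <- ((v - 1) %/% d[1]) %% d[2]
      i <- (v - 1) %% d[1]
      for (o in offs) {
        ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        w <- 1 + ii + d[1] * (jj + d[2] * kk)
        if (mask[w] != 0 && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# partition of foreground voxels into label groups, order-insensitive
partition_of <- function(lab) {
  unname(lapply(split(which(lab > 0), lab[lab > 0]), sort))
}
canonical_partition <- function(p) p[order(vapply(p, min, numeric(1)))]

# ICC(2,1) through R's two-way ANOVA decomposition
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# exhaustive one-to-one assignment: max matches, then min total distance
exhaustive_match <- function(A, R, tol) {
  na <- nrow(A); nr <- nrow(R)
  if (na == 0 || nr == 0) return(list(TP = 0))
  D <- as.matrix(dist(rbind(A, R)))[seq_len(na), na + seq_len(nr),
                                    drop = FALSE]
  best <- list(TP = 0, cost = Inf)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (sa in subsets(seq_len(na))) {
    if (!length(sa)) next
    for (sr in subsets(seq_len(nr))) {
      if (length(sr) != length(sa)) next
      for (p in perms(sr)) {
        ds <- D[cbind(sa, p)]
        if (all(ds <= tol)) {
          cand <- list(TP = length(sa), cost = sum(ds))
          if (cand$TP > best$TP ||
              (cand$TP == best$TP && cand$cost < best$cost)) best <- cand
        }
      }
    }
  }
  best
}
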