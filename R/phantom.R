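#' Specification of a synthetic T2* head phantom
#'
#' Describes a seedable synthetic GRE T2*-weighted head volume with known
#' ground truth, emulating a standard clinical acquisition: anisotropic
#' voxels of 0.938 x 0.938 mm in-plane and 6.5 mm slice spacing (5 mm
#' excitation plus 1.5 mm gap, modelled as a single 6.5 mm cell). The head is
#' a set of nested ellipsoids (scalp shell, dark skull shell, subarachnoid
#' CSF rim, brain parenchyma, ventricular CSF), with T2* intensities ordered
#' as on clinical images: CSF bright, parenchyma intermediate, skull and
#' microbleeds dark.
#'
#' @param grid_shape voxel counts per axis. The default (154, 154, 22) gives
#'   a ~144 mm field of view that resamples to roughly a 96^3 working grid at
#'   1.5 mm.
#' @param voxel_size_mm voxel dimensions in mm.
#' @param tissue_means named mean T2* intensity (arbitrary units) per
#'   generative class.
#' @param noise_sigma additive Gaussian noise standard deviation (a.u.).
#' @param bias_amplitude maximum deviation of the multiplicative bias field
#'   from 1 (0 disables it).
#' @param cmb_list list of microbleeds, each a list with elements
#'   `centre_mm` (length-3, world mm), `diameter_mm` (in the 2-10 mm rating
#'   range), `intensity_fraction` (residual signal fraction, < 0.5) and
#'   optionally `region` ("lobar", "deep" or "infratentorial").
#' @param mimic_list list of artefact primitives; each a list with `type`
#'   one of `"edge_band"` (inferior air-bone susceptibility band),
#'   `"vessel"` (dark tube; fields `start_mm`, `end_mm`, `radius_mm`) or
#'   `"macrobleed"` (dark blob; fields `centre_mm`, `diameter_mm` > 10).
#' @param seed integer RNG seed; equal seeds give bit-identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(154, 154, 22),
                         voxel_size_mm = c(0.938, 0.938, 6.5),
                         tissue_means = c(GWM = 100, CSF = 180, skull = 30,
                                          scalp = 140, other = 5),
                         noise_sigma = 5, bias_amplitude = 0.1,
                         cmb_list = list(), mimic_list = list(), seed = 1L) {
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be strictly positive")
  need <- c("GWM", "CSF", "skull", "scalp", "other")
  if (!all(need %in% names(tissue_means)))
    stop("tissue_means must name classes: ", paste(need, collapse = ", "))
  for (cmb in cmb_list) {
    if (is.null(cmb$centre_mm) || is.null(cmb$diameter_mm))
      stop("each cmb_list entry needs centre_mm and diameter_mm")
    if (cmb$diameter_mm < 2 || cmb$diameter_mm > 10)
      stop("CMB diameter must lie in the 2-10 mm rating range, got ",
           cmb$diameter_mm)
    f <- if (is.null(cmb$intensity_fraction)) 0.3 else cmb$intensity_fraction
    if (f <= 0 || f >= 0.5)
      stop("CMB intensity_fraction must lie in (0, 0.5), got ", f)
  }
  if (noise_sigma < 0 || bias_amplitude < 0)
    stop("noise_sigma and bias_amplitude must be non-negative")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 tissue_means = tissue_means, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude, cmb_list = cmb_list,
                 mimic_list = mimic_list, seed = as.integer(seed)),
            class = "phantom_spec")
}

# head geometry in world mm for a given spec: nested ellipsoid semi-axes,
# all centred on the world origin
phantom_geometry <- function(spec) {
  fov <- spec$grid_shape * spec$voxel_size_mm
  scalp <- 0.45 * fov
  skull <- scalp - 4.5
  brain <- skull - 5.5
  csf_inner <- brain - 3.5
  list(fov = fov, scalp = scalp, skull = skull, brain = brain,
       csf_inner = csf_inner,
       ventricle = c(0.10, 0.13, 0.09) * fov,
       ventricle_centre = c(0, 0, 2),
       deep = c(0.17, 0.20, 0.16) * fov,
       infratentorial_z = -0.22 * fov[3])
}

# integer generative class codes
PHANTOM_CLASSES <- c(other = 0L, GWM = 1L, CSF = 2L, CMB = 3L, skull = 4L,
                     scalp = 5L)

# region codes used by the pipeline's per-region summaries
#' Region label codes
#'
#' Named integer codes used in region label volumes: none = 0, lobar = 1,
#' deep = 2, infratentorial = 3.
#' @export
MIDAS_REGIONS <- c(none = 0L, lobar = 1L, deep = 2L, infratentorial = 3L)

in_ellipsoid <- function(xyz, semi, centre = c(0, 0, 0)) {
  ((xyz[, 1] - centre[1]) / semi[1])^2 +
    ((xyz[, 2] - centre[2]) / semi[2])^2 +
    ((xyz[, 3] - centre[3]) / semi[3])^2 <= 1
}

empty_phantom_volume <- function(spec) {
  d <- spec$grid_shape
  aff <- diag(c(spec$voxel_size_mm, 1))
  aff[1:3, 4] <- -spec$voxel_size_mm * (d - 1) / 2
  volume3d(array(0, d), affine = aff, description = "phantom")
}

# fractional sphere occupancy of each voxel it touches, by sub-voxel
# supersampling on the anisotropic grid; returns linear indices + fractions
sphere_occupancy <- function(vol, centre_mm, diameter_mm) {
  r <- diameter_mm / 2
  d <- dim(vol$data)
  sp <- vol$spacing
  c_vox <- world_to_voxel(vol, matrix(centre_mm, 1))[1, ]
  lo <- pmax(floor(c_vox - r / sp - 1), 0)
  hi <- pmin(ceiling(c_vox + r / sp + 1), d - 1)
  if (any(lo > hi)) return(list(index = integer(0), occ = numeric(0)))
  ii <- seq(lo[1], hi[1]); jj <- seq(lo[2], hi[2]); kk <- seq(lo[3], hi[3])
  ijk <- as.matrix(expand.grid(ii, jj, kk))
  xyz <- voxel_to_world(vol, ijk)
  nsub <- pmax(2L, as.integer(ceiling(sp / 0.4)))
  occ <- numeric(nrow(ijk))
  offs <- lapply(1:3, function(a)
    (seq_len(nsub[a]) - (nsub[a] + 1) / 2) / nsub[a] * sp[a])
  for (ox in offs[[1]]) for (oy in offs[[2]]) for (oz in offs[[3]]) {
    d2 <- (xyz[, 1] + ox - centre_mm[1])^2 +
      (xyz[, 2] + oy - centre_mm[2])^2 +
      (xyz[, 3] + oz - centre_mm[3])^2
    occ <- occ + (d2 <= r * r)
  }
  occ <- occ / prod(nsub)
  keep <- occ > 0
  index <- 1 + ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
  list(index = as.integer(index[keep]), occ = occ[keep])
}

#' Insert a spherical hypointense lesion
#'
#' Multiplies voxel intensities inside a sphere toward
#' `intensity_fraction` of their current value, weighted by each voxel's
#' fractional sphere occupancy (partial volume on the anisotropic grid):
#' `v' = v * (1 - occ * (1 - intensity_fraction))`.
#'
#' @param vol a [volume3d].
#' @param centre_mm lesion centre in world mm.
#' @param diameter_mm lesion diameter in mm (> 0).
#' @param intensity_fraction residual signal fraction in (0, 1); 1 leaves
#'   the volume unchanged.
#' @return The modified [volume3d], with attribute `occupancy` (a list with
#'   voxel `index` and fractional `occ`).
#' @export
insert_cmb <- function(vol, centre_mm, diameter_mm, intensity_fraction) {
  stopifnot(inherits(vol, "volume3d"))
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  if (intensity_fraction <= 0 || intensity_fraction > 1)
    stop("intensity_fraction must lie in (0, 1]")
  so <- sphere_occupancy(vol, centre_mm, diameter_mm)
  vol$data[so$index] <- vol$data[so$index] *
    (1 - so$occ * (1 - intensity_fraction))
  attr(vol, "occupancy") <- so
  vol
}

#' Apply a smooth multiplicative bias field
#'
#' Multiplies the volume by `exp(f)` where `f` is a random low-order 3D
#' polynomial in scaled world coordinates, mean-centred over `mask` (so the
#' mean log-field is zero there) and scaled so that the maximum absolute
#' deviation of the field from 1 equals `amplitude`.
#'
#' @param vol a [volume3d].
#' @param amplitude max of `|field - 1|` (>= 0; 0 returns the input).
#' @param seed integer seed for the polynomial coefficients.
#' @param degree polynomial degree (default 2).
#' @param mask optional logical/0-1 array over which the log-field is centred
#'   (default: whole volume).
#' @return List with `volume` (biased) and `field` (the true field, a
#'   [volume3d]) for recovery tests.
#' @export
apply_bias_field <- function(vol, amplitude, seed = 1L, degree = 2L,
                             mask = NULL) {
  stopifnot(inherits(vol, "volume3d"), amplitude >= 0)
  if (amplitude == 0)
    return(list(volume = vol,
                field = volume3d(array(1, dim(vol$data)),
                                 affine = vol$affine)))
  xyz <- voxel_grid_world(vol)
  X <- poly_basis_3d(xyz, degree, scale_to = apply(xyz, 2, range))
  X <- X[, -1, drop = FALSE]  # drop intercept; centring handles the mean
  set.seed(seed)
  f <- as.vector(X %*% stats::rnorm(ncol(X)))
  msk <- if (is.null(mask)) rep(TRUE, length(f)) else as.logical(mask)
  f <- f - mean(f[msk])
  g <- function(s) max(abs(exp(s * f) - 1)) - amplitude
  s <- stats::uniroot(g, c(0, 10 / max(abs(f))), tol = 1e-12)$root
  field <- array(exp(s * f), dim(vol$data))
  out <- vol
  out$data <- vol$data * field
  list(volume = out, field = volume3d(field, affine = vol$affine,
                                      description = "bias field"))
}

# 3D polynomial basis up to total degree `degree` on coordinates scaled to
# [-1, 1] per axis; includes the intercept column
poly_basis_3d <- function(xyz, degree, scale_to = NULL) {
  if (is.null(scale_to)) scale_to <- apply(xyz, 2, range)
  u <- sapply(1:3, function(a) {
    r <- scale_to[, a]
    if (diff(r) < 1e-9) return(rep(0, nrow(xyz)))
    2 * (xyz[, a] - r[1]) / diff(r) - 1
  })
  cols <- list()
  for (px in 0:degree) for (py in 0:(degree - px))
    for (pz in 0:(degree - px - py))
      cols[[length(cols) + 1]] <- u[, 1]^px * u[, 2]^py * u[, 3]^pz
  X <- do.call(cbind, cols)
  attr(X, "scale_to") <- scale_to
  X
}

apply_mimics <- function(data, xyz, geom, mimic_list) {
  for (m in mimic_list) {
    if (m$type == "edge_band") {
      w <- if (is.null(m$width_mm)) 4 else m$width_mm
      rad2 <- (xyz[, 1] / geom$brain[1])^2 + (xyz[, 2] / geom$brain[2])^2 +
        (xyz[, 3] / geom$brain[3])^2
      inner <- (xyz[, 1] / (geom$brain[1] - w))^2 +
        (xyz[, 2] / (geom$brain[2] - w))^2 +
        (xyz[, 3] / (geom$brain[3] - w))^2
      sel <- rad2 <= 1 & inner > 1 & xyz[, 3] < geom$infratentorial_z
      data[sel] <- data[sel] * 0.3
    } else if (m$type == "vessel") {
      a <- m$start_mm; b <- m$end_mm
      r <- if (is.null(m$radius_mm)) 1.5 else m$radius_mm
      ab <- b - a
      L2 <- sum(ab^2)
      t <- pmin(pmax(((xyz[, 1] - a[1]) * ab[1] + (xyz[, 2] - a[2]) * ab[2] +
                        (xyz[, 3] - a[3]) * ab[3]) / L2, 0), 1)
      d2 <- (xyz[, 1] - (a[1] + t * ab[1]))^2 +
        (xyz[, 2] - (a[2] + t * ab[2]))^2 +
        (xyz[, 3] - (a[3] + t * ab[3]))^2
      sel <- d2 <= r * r
      data[sel] <- data[sel] * 0.35
    } else if (m$type == "macrobleed") {
      d <- if (is.null(m$diameter_mm)) 12 else m$diameter_mm
      # handled as a big hypointense sphere (above the CMB size range)
      sel <- (xyz[, 1] - m$centre_mm[1])^2 + (xyz[, 2] - m$centre_mm[2])^2 +
        (xyz[, 3] - m$centre_mm[3])^2 <= (d / 2)^2
      data[sel] <- data[sel] * 0.3
    } else stop("unknown mimic type: ", m$type)
  }
  data
}

#' Generate a synthetic T2* head phantom with ground truth
#'
#' Builds the nested-ellipsoid head described by the spec, assigns per-class
#' mean intensities, inserts lesion mimics and microbleeds with partial
#' volume on the anisotropic grid, applies a smooth multiplicative bias
#' field and additive Gaussian noise. Deterministic given `spec$seed`.
#'
#' A lesion voxel enters the ground-truth mask when its sphere occupancy is
#' at least 0.5 (i.e. its partial-volumed amplitude reaches half the local
#' contrast); lesions with no such voxel are recorded as sub-voxel.
#'
#' @param spec a [phantom_spec].
#' @return List of class `midas_phantom` with elements `volume` (the T2*
#'   [volume3d]) and `truth`: `cmb_mask` (binary [volume3d]), `lesions`
#'   (data frame: id, centre, diameter, mask volume, region, subvoxel flag),
#'   `labels` (generative class volume, codes in `PHANTOM_CLASSES` order:
#'   other 0, GWM 1, CSF 2, CMB 3, skull 4, scalp 5), `regions` (region
#'   label volume per [MIDAS_REGIONS]), `bias` (true field or NULL) and
#'   `brain_mask`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  vol <- empty_phantom_volume(spec)
  d <- dim(vol$data)
  xyz <- voxel_grid_world(vol)

  in_scalp <- in_ellipsoid(xyz, geom$scalp)
  in_skull <- in_ellipsoid(xyz, geom$skull)
  in_brain <- in_ellipsoid(xyz, geom$brain)
  in_inner <- in_ellipsoid(xyz, geom$csf_inner)
  in_vent <- in_ellipsoid(xyz, geom$ventricle, geom$ventricle_centre)

  labels <- integer(prod(d))            # other = 0
  labels[in_scalp] <- PHANTOM_CLASSES[["scalp"]]
  labels[in_skull] <- PHANTOM_CLASSES[["skull"]]
  labels[in_brain] <- PHANTOM_CLASSES[["CSF"]]   # subarachnoid rim
  labels[in_inner] <- PHANTOM_CLASSES[["GWM"]]
  labels[in_vent & in_brain] <- PHANTOM_CLASSES[["CSF"]]

  regions <- integer(prod(d))
  in_deep <- in_ellipsoid(xyz, geom$deep)
  regions[in_brain] <- MIDAS_REGIONS[["lobar"]]
  regions[in_brain & in_deep] <- MIDAS_REGIONS[["deep"]]
  regions[in_brain & xyz[, 3] < geom$infratentorial_z] <-
    MIDAS_REGIONS[["infratentorial"]]

  means <- spec$tissue_means
  intens <- c(means[["other"]], means[["GWM"]], means[["CSF"]],
              means[["GWM"]], means[["skull"]], means[["scalp"]])
  data <- intens[labels + 1L]

  data <- apply_mimics(data, xyz, geom, spec$mimic_list)
  vol$data <- array(data, d)

  cmb_mask <- array(0L, d)
  lesions <- list()
  vv <- voxel_volume_mm3(vol)
  for (i in seq_along(spec$cmb_list)) {
    cmb <- spec$cmb_list[[i]]
    if (!in_ellipsoid(matrix(cmb$centre_mm, 1), geom$brain))
      stop(sprintf(paste0("CMB %d centre (%.1f, %.1f, %.1f) lies outside ",
                          "the brain ellipsoid (semi-axes %.1f, %.1f, %.1f)"),
                   i, cmb$centre_mm[1], cmb$centre_mm[2], cmb$centre_mm[3],
                   geom$brain[1], geom$brain[2], geom$brain[3]))
    frac <- if (is.null(cmb$intensity_fraction)) 0.3
            else cmb$intensity_fraction
    vol <- insert_cmb(vol, cmb$centre_mm, cmb$diameter_mm, frac)
    so <- attr(vol, "occupancy")
    core <- so$index[so$occ >= 0.5]
    cmb_mask[core] <- 1L
    labels[core] <- PHANTOM_CLASSES[["CMB"]]
    lesions[[i]] <- data.frame(
      id = i, x = cmb$centre_mm[1], y = cmb$centre_mm[2],
      z = cmb$centre_mm[3], diameter_mm = cmb$diameter_mm,
      intensity_fraction = frac, n_voxels = length(core),
      volume_mm3 = length(core) * vv,
      region = if (is.null(cmb$region)) "lobar" else cmb$region,
      subvoxel = length(core) == 0)
  }
  attr(vol, "occupancy") <- NULL

  bias <- NULL
  if (spec$bias_amplitude > 0) {
    bf <- apply_bias_field(vol, spec$bias_amplitude,
                           seed = spec$seed + 1000L,
                           mask = array(in_brain, d))
    vol <- bf$volume
    bias <- bf$field
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    vol$data <- vol$data + array(stats::rnorm(prod(d), 0, spec$noise_sigma),
                                 d)
    vol$data[vol$data < 0] <- 0
  }

  truth <- list(
    cmb_mask = volume3d(cmb_mask, affine = vol$affine,
                        description = "CMB ground truth"),
    lesions = if (length(lesions)) do.call(rbind, lesions) else
      data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                 z = numeric(0), diameter_mm = numeric(0),
                 intensity_fraction = numeric(0), n_voxels = integer(0),
                 volume_mm3 = numeric(0), region = character(0),
                 subvoxel = logical(0)),
    labels = volume3d(array(labels, d), affine = vol$affine,
                      description = "generative labels"),
    regions = volume3d(array(regions, d), affine = vol$affine,
                       description = "region labels"),
    brain_mask = volume3d(array(as.integer(in_brain), d),
                          affine = vol$affine, description = "brain mask"),
    bias = bias, geometry = geom, spec = spec)
  structure(list(volume = vol, truth = truth), class = "midas_phantom")
}

#' Random multi-microbleed phantom specification
#'
#' Samples a phantom bearing several lobar microbleeds at random positions:
#' lesion count uniform in `n_cmb_range`, diameters uniform in
#' `diameter_range`, centres rejection-sampled inside the lobar parenchyma
#' with a safety margin from CSF spaces and from each other.
#'
#' @param seed integer seed (drives both placement and the phantom's own
#'   noise/bias seeds).
#' @param n_cmb_range integer range of lesion counts (default 2 to 5).
#' @param diameter_range lesion diameter range in mm (default 4 to 8).
#' @param intensity_fraction residual signal fraction (default 0.3).
#' @param noise_sigma,bias_amplitude passed to [phantom_spec()].
#' @param ... further arguments to [phantom_spec()].
#' @return A [phantom_spec].
#' @export
random_cmb_phantom_spec <- function(seed, n_cmb_range = c(2L, 5L),
                                    diameter_range = c(4, 8),
                                    intensity_fraction = 0.3,
                                    noise_sigma = 5, bias_amplitude = 0.1,
                                    ...) {
  base <- phantom_spec(noise_sigma = noise_sigma,
                       bias_amplitude = bias_amplitude, seed = seed, ...)
  geom <- phantom_geometry(base)
  set.seed(seed)
  n <- sample(seq(n_cmb_range[1], n_cmb_range[2]), 1)
  cmbs <- list()
  tries <- 0
  while (length(cmbs) < n && tries < 5000) {
    tries <- tries + 1
    diam <- stats::runif(1, diameter_range[1], diameter_range[2])
    r <- diam / 2
    p <- stats::runif(3, -1, 1) * (geom$csf_inner - r - 2)
    # lobar parenchyma only: away from ventricles, deep nuclei and the
    # infratentorial compartment, with clearance from the CSF rim
    if (in_ellipsoid(matrix(p, 1), geom$ventricle + r + 3,
                     geom$ventricle_centre)) next
    if (in_ellipsoid(matrix(p, 1), geom$deep + r + 2)) next
    if (!in_ellipsoid(matrix(p, 1), geom$csf_inner - r - 2)) next
    if (p[3] < geom$infratentorial_z + r + 2) next
    ok <- TRUE
    for (c0 in cmbs) {
      if (sqrt(sum((p - c0$centre_mm)^2)) <
          (diam + c0$diameter_mm) / 2 + 6) { ok <- FALSE; break }
    }
    if (!ok) next
    cmbs[[length(cmbs) + 1]] <- list(centre_mm = p, diameter_mm = diam,
                                     intensity_fraction = intensity_fraction,
                                     region = "lobar")
  }
  if (length(cmbs) < n)
    stop("could not place ", n, " lesions; relax the margins")
  base$cmb_list <- cmbs
  base
}
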