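#' 3D image volume with world geometry
#'
#' `volume3d` is the package's basic container: a 3D numeric array plus the
#' voxel spacing and a 4x4 voxel-to-world affine (RAS+ millimetres, 0-based
#' voxel indices). All centroids and volumes reported downstream are in world
#' units (mm, cm^3).
#'
#' @param data numeric 3D array.
#' @param spacing voxel size in mm, length 3. Ignored when `affine` is given
#'   (spacing is then derived from the affine's column norms).
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal affine with
#'   the world origin at the volume centre.
#' @param description free-text tag carried through processing.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL,
                     description = "") {
  if (length(dim(data)) != 3L)
    stop("volume3d requires a 3D array, got ", length(dim(data)),
         " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be strictly positive")
  if (is.null(affine)) {
    d <- dim(data)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- -spacing * (d - 1) / 2
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(data = data, spacing = spacing, affine = affine,
                 description = description),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d: %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              if (nzchar(x$description)) paste0(" [", x$description, "]")
              else ""))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Volume of one voxel
#'
#' @param vol a `volume3d`.
#' @return Voxel volume in mm^3 (`voxel_volume_mm3`) or cm^3
#'   (`voxel_volume_cm3`).
#' @export
voxel_volume_mm3 <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  abs(det(vol$affine[1:3, 1:3]))
}

#' @rdname voxel_volume_mm3
#' @export
voxel_volume_cm3 <- function(vol) voxel_volume_mm3(vol) / 1000

#' Voxel/world coordinate conversion
#'
#' Voxel indices are 0-based; world coordinates are RAS+ mm.
#'
#' @param vol a `volume3d`.
#' @param ijk n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of converted coordinates.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- rbind(t(matrix(as.numeric(ijk), ncol = 3)), 1)
  t(vol$affine %*% ijk)[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- rbind(t(matrix(as.numeric(xyz), ncol = 3)), 1)
  t(solve(vol$affine) %*% xyz)[, 1:3, drop = FALSE]
}

# world coordinates of every voxel centre, as an n x 3 matrix (column-major
# voxel order, matching as.vector(vol$data))
voxel_grid_world <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

same_grid <- function(a, b, tol = 1e-4) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Read a NIfTI-1 volume
#'
#' Accepts `.nii` and `.nii.gz`. The sform is preferred when set, otherwise
#' the qform. 4D (or higher) images and non-finite voxels are rejected.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  aff <- unname(RNifti::xform(img, useQuaternionFirst = FALSE))
  data <- as.array(img)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("non-finite voxel values in ", path)
  volume3d(data, affine = aff, description = basename(path))
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  aff <- structure(vol$affine, code = 2L)
  RNifti::`sform<-`(img, aff) -> img
  RNifti::`qform<-`(img, aff) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Trilinear / nearest-neighbour sampling of a 3D array at fractional 0-based
# voxel coordinates. Coordinates are clamped to the array (edge padding).
interp3 <- function(arr, coords, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(arr)
  x <- pmin(pmax(coords[, 1], 0), d[1] - 1)
  y <- pmin(pmax(coords[, 2], 0), d[2] - 1)
  z <- pmin(pmax(coords[, 3], 0), d[3] - 1)
  if (method == "nearest") {
    idx <- 1 + round(x) + d[1] * (round(y) + d[2] * round(z))
    return(arr[idx])
  }
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  x0 <- pmin(x0, d[1] - 2); y0 <- pmin(y0, d[2] - 2); z0 <- pmin(z0, d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  base <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  out <- arr[base] * (1 - fx) * (1 - fy) * (1 - fz)
  out <- out + arr[base + sx] * fx * (1 - fy) * (1 - fz)
  out <- out + arr[base + sy] * (1 - fx) * fy * (1 - fz)
  out <- out + arr[base + sx + sy] * fx * fy * (1 - fz)
  out <- out + arr[base + sz] * (1 - fx) * (1 - fy) * fz
  out <- out + arr[base + sx + sz] * fx * (1 - fy) * fz
  out <- out + arr[base + sy + sz] * (1 - fx) * fy * fz
  out <- out + arr[base + sx + sy + sz] * fx * fy * fz
  out
}

#' Resample one volume onto the grid of another
#'
#' Samples `vol` at the voxel centres of `target` (optionally through a
#' world-to-world transform), with trilinear interpolation for intensities or
#' nearest-neighbour for masks/labels.
#'
#' @param vol source [volume3d].
#' @param target [volume3d] defining the output grid.
#' @param method `"linear"` or `"nearest"`.
#' @param transform optional 4x4 world-to-world matrix mapping source world
#'   coordinates into target world coordinates (e.g. from
#'   [align_to_template()]).
#' @return A [volume3d] on `target`'s grid.
#' @export
resample_to_grid <- function(vol, target, method = c("linear", "nearest"),
                             transform = NULL) {
  method <- match.arg(method)
  d <- dim(target$data)
  M <- solve(vol$affine)
  if (!is.null(transform)) M <- M %*% solve(transform)
  M <- M %*% target$affine
  ijk <- cbind(rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
               rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]), 1)
  src <- ijk %*% t(M)
  out <- interp3(vol$data, src[, 1:3, drop = FALSE], method)
  volume3d(array(out, d), affine = target$affine,
           description = vol$description)
}

#' Resample a volume to an isotropic grid
#'
#' Builds an axis-aligned (in the volume's own voxel axes) grid at the
#' requested isotropic spacing covering the same world bounding box, and
#' interpolates the data onto it. Use `order = "nearest"` for masks and label
#' volumes.
#'
#' @param vol a [volume3d].
#' @param spacing target isotropic spacing in mm (default 1.5, the pipeline's
#'   working resolution).
#' @param order `"linear"` (intensities) or `"nearest"` (masks).
#' @return A [volume3d] at `spacing` mm isotropic.
#' @export
resample_isotropic <- function(vol, spacing = 1.5,
                               order = c("linear", "nearest")) {
  order <- match.arg(order)
  stopifnot(spacing > 0)
  d <- dim(vol$data)
  sp <- vol$spacing
  U <- sweep(vol$affine[1:3, 1:3], 2, sp, "/")
  nd <- pmax(2L, as.integer(ceiling(d * sp / spacing)))
  naff <- diag(4)
  naff[1:3, 1:3] <- U * spacing
  # keep the leading edge of the field of view fixed
  naff[1:3, 4] <- vol$affine[1:3, 4] + U %*% ((spacing - sp) / 2)
  target <- volume3d(array(0, nd), affine = naff)
  out <- resample_to_grid(vol, target, method = order)
  out$description <- vol$description
  out
}

# separable Gaussian smoothing, FWHM in mm (per-axis sigma derived from the
# voxel spacing); kernel truncated at 3 sigma
smooth_gaussian <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume3d"))
  if (all(fwhm_mm <= 0)) return(vol)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  sig_vox <- (fwhm_mm / 2.354820045) / vol$spacing
  arr <- vol$data
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (s < 1e-3) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, nrow = da[1])
    n1 <- da[1]
    acc <- matrix(0, n1, ncol(m))
    for (o in -r:r) {
      rows <- pmin(pmax(seq_len(n1) + o, 1L), n1)  # replicate edges
      acc <- acc + k[o + r + 1] * m[rows, , drop = FALSE]
    }
    arr <- aperm(array(acc, da), order(perm))
  }
  volume3d(arr, affine = vol$affine, description = vol$description)
}

# ---- affine alignment ------------------------------------------------------

# 12-parameter affine about a world centre: p = (tx ty tz, rx ry rz [deg],
# log-scales, shears)
affine_from_params <- function(p, centre = c(0, 0, 0)) {
  p <- c(p, rep(0, 12 - length(p)))
  t <- p[1:3]; r <- p[4:6] * pi / 180; s <- exp(p[7:9]); k <- p[10:12]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])),
              c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0),
              c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0),
              c(0, 0, 1))
  Sh <- rbind(c(1, k[1], k[2]), c(0, 1, k[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% Sh %*% diag(s)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- t + centre - A %*% centre
  M
}

nmi_metric <- function(sub_samp, tmpl_samp, bins = 32) {
  ok <- is.finite(sub_samp) & is.finite(tmpl_samp)
  a <- sub_samp[ok]; b <- tmpl_samp[ok]
  if (length(a) < 100) return(0)
  cut1 <- pmin(1L + as.integer((a - min(a)) / diff(range(a)) * bins * 0.9999),
               bins)
  cut2 <- pmin(1L + as.integer((b - min(b)) / diff(range(b)) * bins * 0.9999),
               bins)
  joint <- tabulate(cut1 + bins * (cut2 - 1L), nbins = bins * bins)
  pj <- joint / sum(joint)
  px <- rowSums(matrix(pj, bins)); py <- colSums(matrix(pj, bins))
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(px) + H(py)) / H(pj)
}

#' Affine alignment of a subject volume to a template
#'
#' Estimates a 12-parameter world-to-world affine (translations, rotations,
#' scales, shears) maximising normalised mutual information between the
#' subject, resampled into the template grid, and the template. Optimisation
#' is staged (translation, then rigid, then full affine) with Nelder-Mead.
#'
#' @param subject,template [volume3d] objects containing a head.
#' @param bins number of intensity bins for the joint histogram.
#' @param max_samples cap on the number of template voxels used for the
#'   metric (the grid is strided down to stay under it).
#' @return 4x4 matrix mapping subject world coordinates to template world
#'   coordinates, with attributes `metric` (final NMI) and `parameters`.
#'   Apply with `resample_to_grid(subject, template, transform = .)`.
#' @export
align_to_template <- function(subject, template, bins = 32,
                              max_samples = 40000) {
  stopifnot(inherits(subject, "volume3d"), inherits(template, "volume3d"))
  d <- dim(template$data)
  stride <- max(1L, as.integer(ceiling((prod(d) / max_samples)^(1 / 3))))
  idx <- list(seq(1, d[1], stride), seq(1, d[2], stride), seq(1, d[3], stride))
  ijk <- as.matrix(expand.grid(idx[[1]] - 1, idx[[2]] - 1, idx[[3]] - 1))
  tmpl_samp <- template$data[as.matrix(expand.grid(idx[[1]], idx[[2]],
                                                   idx[[3]]))]
  world_t <- voxel_to_world(template, ijk)
  centre <- colMeans(world_t)
  Ainv <- solve(subject$affine)

  eval_metric <- function(p) {
    M <- affine_from_params(p, centre)
    w <- cbind(world_t, 1) %*% t(solve(M))  # template world -> subject world
    v <- cbind(w[, 1:3], 1) %*% t(Ainv)
    sub_samp <- interp3(subject$data, v[, 1:3, drop = FALSE], "linear")
    # drop samples outside the subject volume
    ds <- dim(subject$data)
    inside <- v[, 1] > 0 & v[, 1] < ds[1] - 1 & v[, 2] > 0 &
      v[, 2] < ds[2] - 1 & v[, 3] > 0 & v[, 3] < ds[3] - 1
    sub_samp[!inside] <- NA_real_
    -nmi_metric(sub_samp, tmpl_samp, bins)
  }

  p <- rep(0, 12)
  # coarse axis-wise searches (translations in mm, then rotations in
  # degrees) to land inside the capture range before simplex refinement
  for (ax in 1:3) {
    cand <- seq(-15, 15, by = 5)
    vals <- vapply(cand, function(tt) {
      q <- p; q[ax] <- q[ax] + tt; eval_metric(q)
    }, numeric(1))
    p[ax] <- p[ax] + cand[which.min(vals)]
  }
  for (ax in 4:6) {
    cand <- seq(-10, 10, by = 2.5)
    vals <- vapply(cand, function(rr) {
      q <- p; q[ax] <- q[ax] + rr; eval_metric(q)
    }, numeric(1))
    p[ax] <- p[ax] + cand[which.min(vals)]
  }
  # staged Nelder-Mead: large simplex steps first (the metric is noisy at
  # sub-voxel scale), then a fine pass
  scales <- c(rep(1, 3), rep(1, 3), rep(0.01, 3), rep(0.01, 3))
  for (np in c(3, 6, 12)) {
    for (fac in c(4, 0.5)) {
      o <- stats::optim(p[1:np],
                        function(q) eval_metric(c(q, p[-seq_len(np)])),
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-8,
                                       parscale = fac * scales[1:np]))
      p[1:np] <- o$par
    }
  }
  final <- eval_metric(p)
  if (!is.finite(final) || final >= -1.0001)
    stop("affine alignment failed to find overlap; final NMI = ", -final)
  M <- affine_from_params(p, centre)
  attr(M, "metric") <- -final
  attr(M, "parameters") <- p
  M
}
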