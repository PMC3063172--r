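MIDAS_TISSUE_CLASSES <- c("GWM", "CSF", "CMB", "skull", "scalp", "other")

#' Six-class tissue prior set
#'
#' Container for the spatial priors driving the segmentation: combined
#' grey+white matter (GWM), CSF, the microbleed "extra" class (CMB), the
#' dark peri-cerebral "skull" class, scalp, and background ("other"). Values
#' sum to 1 at every voxel; the CMB prior is zero outside the brain mask. A
#' small probability floor is applied inside each class's anatomical support
#' so the EM never takes log(0) there, while hard zeros outside the support
#' stay exact.
#'
#' @name tissue_prior_set
NULL

new_prior_set <- function(maps, brain_mask, floor) {
  structure(list(maps = maps, brain_mask = brain_mask, floor = floor),
            class = "tissue_prior_set")
}

#' @export
print.tissue_prior_set <- function(x, ...) {
  cat(sprintf("tissue_prior_set: %s on a %s grid, floor %g\n",
              paste(names(x$maps), collapse = ", "),
              paste(dim(x$maps[[1]]$data), collapse = "x"), x$floor))
  invisible(x)
}

# per-voxel probability matrix (n x K) in class order
prior_matrix <- function(priors) {
  vapply(priors$maps, function(m) as.vector(m$data),
         numeric(length(priors$maps[[1]]$data)))
}

#' Build the six-class prior set
#'
#' GM and WM are merged into one GWM class (T2* barely distinguishes them);
#' the microbleed class gets a flat empirical prior (`cmb_prior_value`
#' inside the brain mask, zero outside — maximal spatial uncertainty about
#' lesion locations); "other" is the complement of the supplied tissues.
#' All six maps are then renormalised to sum to 1 per voxel, with the
#' probability floor applied inside each class's support.
#'
#' @param gm,wm,csf,skull,scalp [volume3d] probability maps in `[0, 1]`, all
#'   on the same grid.
#' @param brain_mask binary [volume3d]; support of the flat CMB prior.
#' @param cmb_prior_value flat in-brain CMB prior before renormalisation
#'   (default 0.1).
#' @param floor probability floor inside class supports (default 1e-6).
#' @return A `tissue_prior_set`.
#' @export
build_prior_set <- function(gm, wm, csf, skull, scalp, brain_mask,
                            cmb_prior_value = 0.1, floor = 1e-6) {
  vols <- list(gm = gm, wm = wm, csf = csf, skull = skull, scalp = scalp,
               brain_mask = brain_mask)
  for (nm in names(vols)) {
    v <- vols[[nm]]
    stopifnot(inherits(v, "volume3d"))
    if (!same_grid(v, gm)) stop("misaligned grid: ", nm)
    if (min(v$data) < 0) stop("negative values in ", nm)
  }
  if (max(gm$data + wm$data) > 1 + 1e-6 || max(csf$data) > 1 + 1e-6)
    stop("tissue probabilities must lie in [0, 1]")
  bm <- brain_mask$data > 0.5
  P <- cbind(GWM = as.vector(gm$data + wm$data),
             CSF = as.vector(csf$data),
             CMB = ifelse(as.vector(bm), cmb_prior_value, 0),
             skull = as.vector(skull$data),
             scalp = as.vector(scalp$data))
  other <- pmax(0, 1 - rowSums(P[, c("GWM", "CSF", "skull", "scalp")]))
  P <- cbind(P, other = other)
  P <- apply_floor_renormalise(P, floor)
  maps <- lapply(colnames(P), function(k)
    volume3d(array(P[, k], dim(gm$data)), affine = gm$affine,
             description = paste("prior:", k)))
  names(maps) <- colnames(P)
  new_prior_set(maps, volume3d(array(as.integer(bm), dim(gm$data)),
                               affine = gm$affine), floor)
}

# floor inside supports (value > 0), then renormalise rows to sum 1
apply_floor_renormalise <- function(P, floor) {
  P[P > 0 & P < floor] <- floor
  sweep(P, 1, rowSums(P), "/")
}

#' Priors from a generative label volume
#'
#' Builds a plausible prior set from an integer tissue label volume (codes as
#' in `make_phantom()`'s ground truth: other 0, GWM 1, CSF 2, CMB 3, skull 4,
#' scalp 5) by one-hot encoding each anatomical class and smoothing with a
#' Gaussian kernel, emulating what population-average template priors look
#' like. Microbleed label voxels count as parenchyma (priors must not know
#' the lesions).
#'
#' @param labels integer [volume3d] of generative classes.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @param cmb_prior_value,floor passed to [build_prior_set()].
#' @return A `tissue_prior_set` on the label grid.
#' @export
priors_from_labels <- function(labels, fwhm_mm = 8, cmb_prior_value = 0.1,
                               floor = 1e-6) {
  stopifnot(inherits(labels, "volume3d"))
  lab <- labels$data
  onehot <- function(codes) {
    v <- volume3d(array(as.numeric(lab %in% codes), dim(lab)),
                  affine = labels$affine)
    smooth_gaussian(v, fwhm_mm)
  }
  gwm <- onehot(c(1L, 3L))   # parenchyma incl. any lesion voxels
  csf <- onehot(2L)
  skull <- onehot(4L)
  scalp <- onehot(5L)
  zero <- volume3d(array(0, dim(lab)), affine = labels$affine)
  brain <- volume3d(array(as.integer(lab %in% c(1L, 2L, 3L)), dim(lab)),
                    affine = labels$affine)
  build_prior_set(gm = gwm, wm = zero, csf = csf, skull = skull,
                  scalp = scalp, brain_mask = brain,
                  cmb_prior_value = cmb_prior_value, floor = floor)
}

#' Replace the microbleed prior with a cleaned subject-specific map
#'
#' Second-iteration prior update: the CMB class is replaced by the cleaned
#' candidate map (probabilistic, in `[0, 1]`); the other five classes are
#' left unchanged and the set is renormalised per voxel. Voxels where the
#' cleaned map is zero get a hard-zero CMB prior, so the second pass can
#' only become more specific — it cannot invent candidate territory.
#'
#' @param priors a `tissue_prior_set`.
#' @param cleaned_cmb_map [volume3d] with values in `[0, 1]`, zero outside
#'   the brain.
#' @return A refined `tissue_prior_set`.
#' @export
refine_cmb_prior <- function(priors, cleaned_cmb_map) {
  stopifnot(inherits(priors, "tissue_prior_set"),
            inherits(cleaned_cmb_map, "volume3d"))
  if (!same_grid(priors$maps$CMB, cleaned_cmb_map))
    stop("cleaned map is not on the prior grid")
  cl <- as.vector(cleaned_cmb_map$data)
  if (min(cl) < -1e-9 || max(cl) > 1 + 1e-9)
    stop("cleaned map values must lie in [0, 1]")
  cl <- pmin(pmax(cl, 0), 1)
  P <- prior_matrix(priors)
  # renormalise the five untouched classes into the mass left by the new CMB
  rest <- P[, setdiff(colnames(P), "CMB"), drop = FALSE]
  rest <- sweep(rest, 1, pmax(rowSums(rest), 1e-12), "/") * (1 - cl)
  Pn <- cbind(rest, CMB = cl)[, colnames(P)]
  pos <- Pn[, "CMB"] > 0
  Pn[pos, ] <- apply_floor_renormalise(Pn[pos, , drop = FALSE], priors$floor)
  maps <- lapply(colnames(Pn), function(k)
    volume3d(array(Pn[, k], dim(cleaned_cmb_map$data)),
             affine = cleaned_cmb_map$affine,
             description = paste("refined prior:", k)))
  names(maps) <- colnames(Pn)
  new_prior_set(maps, priors$brain_mask, priors$floor)
}

#' Validate a prior set against its invariants
#'
#' Checks per-voxel sums, value ranges, grid alignment and the confinement
#' of the CMB prior to the brain mask.
#'
#' @param priors a `tissue_prior_set`.
#' @param tol tolerance on per-voxel sums.
#' @return Data frame with one row per invariant (`invariant`, `pass`,
#'   `detail`).
#' @export
validate_priors <- function(priors, tol = 1e-6) {
  P <- prior_matrix(priors)
  sums <- rowSums(P)
  checks <- list(
    c("per-voxel sum = 1",
      max(abs(sums - 1)) <= tol,
      sprintf("max |sum - 1| = %.3g", max(abs(sums - 1)))),
    c("values in [0, 1]",
      min(P) >= 0 && max(P) <= 1 + tol,
      sprintf("range [%.3g, %.3g]", min(P), max(P))),
    c("CMB prior zero outside brain",
      all(P[as.vector(priors$brain_mask$data) == 0, "CMB"] == 0),
      "hard zeros outside brain mask"),
    c("aligned grids",
      all(vapply(priors$maps, function(m)
        same_grid(m, priors$maps[[1]]), logical(1))),
      "all six maps plus brain mask on one grid"))
  data.frame(invariant = vapply(checks, `[`, "", 1),
             pass = as.logical(vapply(checks, `[`, "", 2)),
             detail = vapply(checks, `[`, "", 3))
}

# resample every prior map onto a target grid: probabilities linearly with
# per-voxel renormalisation, the brain mask nearest-neighbour
resample_priors <- function(priors, target) {
  maps <- lapply(priors$maps, resample_to_grid, target = target,
                 method = "linear")
  P <- vapply(maps, function(m) pmax(as.vector(m$data), 0),
              numeric(length(target$data)))
  P <- sweep(P, 1, pmax(rowSums(P), 1e-12), "/")
  maps <- lapply(colnames(P), function(k)
    volume3d(array(P[, k], dim(target$data)), affine = target$affine,
             description = paste("prior:", k)))
  names(maps) <- colnames(P)
  bm <- resample_to_grid(priors$brain_mask, target, method = "nearest")
  bm$data <- array(as.integer(bm$data > 0.5), dim(bm$data))
  new_prior_set(maps, bm, priors$floor)
}

#' Read/write a prior set as a directory of NIfTI files
#'
#' The directory holds one `.nii.gz` per class plus `brain_mask.nii.gz` and
#' a `manifest.json` naming the classes and the floor.
#'
#' @param priors a `tissue_prior_set`.
#' @param dir directory path.
#' @return `read_prior_set` returns a `tissue_prior_set`; `write_prior_set`
#'   returns `dir` invisibly.
#' @export
write_prior_set <- function(priors, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in names(priors$maps))
    write_volume(priors$maps[[k]], file.path(dir, paste0(k, ".nii.gz")))
  write_volume(priors$brain_mask, file.path(dir, "brain_mask.nii.gz"))
  jsonlite::write_json(list(classes = names(priors$maps),
                            floor = priors$floor),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_prior_set
#' @export
read_prior_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  maps <- lapply(man$classes, function(k)
    read_volume(file.path(dir, paste0(k, ".nii.gz"))))
  names(maps) <- man$classes
  bm <- read_volume(file.path(dir, "brain_mask.nii.gz"))
  new_prior_set(maps, bm, man$floor)
}
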