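#' Connected candidate components
#'
#' A `cmb_component_set` holds the connected candidate lesions of one
#' volume: per component the voxel set (linear indices), voxel count,
#' world-space volume and centroid, peak posterior, bounding box, and — once
#' a filter removes it — exactly one discard reason out of `too_large`,
#' `too_small`, `skull`, `csf_neighbour`, `artefact_mask`. The filtering
#' cascade is audit-complete: every candidate ends up either kept or
#' discarded with one reason.
#'
#' @name cmb_component_set
NULL

DISCARD_REASONS <- c("too_large", "too_small", "skull", "csf_neighbour",
                     "artefact_mask", "manual")

new_component_set <- function(components, dim, affine) {
  structure(list(components = components, dim = dim, affine = affine,
                 voxel_volume_cm3 =
                   abs(det(affine[1:3, 1:3])) / 1000),
            class = "cmb_component_set")
}

measure_component <- function(idx, set, posterior = NULL) {
  d <- set$dim
  i0 <- (idx - 1) %% d[1]
  j0 <- ((idx - 1) %/% d[1]) %% d[2]
  k0 <- (idx - 1) %/% (d[1] * d[2])
  ijk <- cbind(i0, j0, k0)
  world <- cbind(ijk, 1) %*% t(set$affine)
  list(voxels = as.integer(idx), n = length(idx),
       volume_cm3 = length(idx) * set$voxel_volume_cm3,
       centroid_mm = colMeans(world[, 1:3, drop = FALSE]),
       bbox = rbind(apply(ijk, 2, min), apply(ijk, 2, max)),
       peak_posterior = if (is.null(posterior)) NA_real_ else
         max(posterior[idx]))
}

#' Label connected components of a binary mask
#'
#' Maximal connected components under 6- or 26-connectivity (default 26:
#' candidate hypointensities touching only diagonally across thick slices
#' are one lesion). Volumes and centroids are computed in world units.
#'
#' @param mask binary [volume3d] (or logical/0-1 array with attribute-free
#'   geometry taken from `reference`).
#' @param connectivity 6 or 26.
#' @param posterior optional [volume3d] whose values provide each
#'   component's peak posterior.
#' @return A `cmb_component_set`; all components start with status "kept".
#' @export
label_components <- function(mask, connectivity = 26L, posterior = NULL) {
  stopifnot(inherits(mask, "volume3d"))
  d <- dim(mask$data)
  lab <- label_components_cpp(as.integer(as.vector(mask$data) != 0),
                              as.integer(d), as.integer(connectivity))
  set <- new_component_set(list(), d, mask$affine)
  pv <- if (is.null(posterior)) NULL else as.vector(posterior$data)
  nlab <- if (length(lab)) max(lab) else 0L
  if (nlab > 0) {
    idx_by_lab <- split(seq_along(lab)[lab > 0], lab[lab > 0])
    set$components <- lapply(seq_len(nlab), function(l) {
      comp <- measure_component(idx_by_lab[[as.character(l)]], set, pv)
      comp$id <- as.character(l)
      comp$status <- "kept"
      comp$discard_reason <- NA_character_
      comp
    })
  }
  set
}

#' Binarise a posterior map
#'
#' Voxels at or above the threshold are included (inclusive comparison).
#'
#' @param cmb_posterior [volume3d] with values in `[0, 1]`.
#' @param threshold probability threshold (default 0.2, the first-pass
#'   binarisation level).
#' @return Binary [volume3d].
#' @export
binarise_posterior <- function(cmb_posterior, threshold = 0.2) {
  stopifnot(inherits(cmb_posterior, "volume3d"))
  v <- cmb_posterior$data
  if (min(v) < 0 || max(v) > 1 + 1e-9)
    stop("posterior values must lie in [0, 1]")
  volume3d(array(as.integer(v >= threshold), dim(v)),
           affine = cmb_posterior$affine,
           description = "binarised CMB posterior")
}

#' @export
as.data.frame.cmb_component_set <- function(x, ...) {
  if (!length(x$components))
    return(data.frame(id = character(0), n_voxels = integer(0),
                      volume_cm3 = numeric(0), x = numeric(0),
                      y = numeric(0), z = numeric(0),
                      peak_posterior = numeric(0), region = character(0),
                      status = character(0), discard_reason = character(0)))
  do.call(rbind, lapply(x$components, function(cp)
    data.frame(id = cp$id, n_voxels = cp$n, volume_cm3 = cp$volume_cm3,
               x = cp$centroid_mm[1], y = cp$centroid_mm[2],
               z = cp$centroid_mm[3], peak_posterior = cp$peak_posterior,
               region = if (is.null(cp$region)) NA_character_ else cp$region,
               status = cp$status, discard_reason = cp$discard_reason,
               row.names = NULL)))
}

#' @export
print.cmb_component_set <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("cmb_component_set: %d components (%d kept)\n",
              nrow(df), sum(df$status == "kept")))
  if (nrow(df)) print(df, row.names = FALSE)
  invisible(x)
}

kept <- function(set) Filter(function(cp) cp$status == "kept",
                             set$components)

discard_component <- function(cp, reason) {
  cp$status <- "discarded"
  cp$discard_reason <- reason
  cp
}

#' Size filtering of candidate components (granulometry)
#'
#' Components larger than `max_volume_cm3` (strictly) are discarded as
#' macrobleed-sized (`too_large`); components with fewer than `min_voxels`
#' voxels are discarded as single-voxel noise (`too_small`).
#'
#' @param set a `cmb_component_set`.
#' @param min_voxels minimum voxel count (default 2).
#' @param max_volume_cm3 maximum volume in cm^3 (default 0.675).
#' @return The set with discard reasons applied.
#' @export
filter_by_size <- function(set, min_voxels = 2L, max_volume_cm3 = 0.675) {
  set$components <- lapply(set$components, function(cp) {
    if (cp$status != "kept") return(cp)
    if (cp$volume_cm3 > max_volume_cm3) return(discard_component(cp,
                                                                 "too_large"))
    if (cp$n < min_voxels) return(discard_component(cp, "too_small"))
    cp
  })
  set
}

# remove a voxel set from all kept components; emptied components get
# `reason`; partially clipped components are re-labelled (they may split)
# and re-measured
remove_voxels_from_components <- function(set, removal_idx, reason,
                                          connectivity = 26L,
                                          posterior = NULL) {
  if (!length(removal_idx)) return(set)
  removal <- logical(prod(set$dim))
  removal[removal_idx] <- TRUE
  pv <- if (is.null(posterior)) NULL else as.vector(posterior$data)
  out <- list()
  for (cp in set$components) {
    if (cp$status != "kept") { out[[length(out) + 1]] <- cp; next }
    hit <- removal[cp$voxels]
    if (!any(hit)) { out[[length(out) + 1]] <- cp; next }
    if (all(hit)) {
      out[[length(out) + 1]] <- discard_component(cp, reason)
      next
    }
    remain <- cp$voxels[!hit]
    sub <- logical(prod(set$dim))
    sub[remain] <- TRUE
    lab <- label_components_cpp(as.integer(sub), as.integer(set$dim),
                                as.integer(connectivity))
    pieces <- split(which(lab > 0), lab[lab > 0])
    for (p in seq_along(pieces)) {
      np <- measure_component(pieces[[p]], set, pv)
      np$id <- if (length(pieces) == 1) cp$id else
        paste0(cp$id, letters[p])
      np$status <- "kept"
      np$discard_reason <- NA_character_
      out[[length(out) + 1]] <- np
    }
  }
  set$components <- out
  set
}

#' Mask out the skull class
#'
#' Voxels whose "skull" posterior reaches the threshold are removed from all
#' candidate components (the dark peri-cerebral rim mimics microbleed
#' intensities); components emptied by the mask are discarded with reason
#' `skull`, partially overlapping components keep their remainder,
#' re-labelled and re-measured.
#'
#' @param set a `cmb_component_set`.
#' @param skull_posterior [volume3d] on the same grid.
#' @param threshold masking threshold (default 0.5, inclusive).
#' @param connectivity used when re-labelling clipped remainders.
#' @param posterior optional CMB posterior for re-measured peaks.
#' @return The filtered set.
#' @export
mask_skull <- function(set, skull_posterior, threshold = 0.5,
                       connectivity = 26L, posterior = NULL) {
  stopifnot(all(dim(skull_posterior$data) == set$dim))
  removal <- which(as.vector(skull_posterior$data) >= threshold)
  remove_voxels_from_components(set, removal, "skull", connectivity,
                                posterior)
}

#' Exclude CSF voxels and their nearest neighbours
#'
#' Voxels with CSF posterior strictly above the threshold, together with
#' their nearest neighbours (one dilation step, 6-connected by default),
#' are removed from all candidate components; hypointensities inside or
#' bordering CSF spaces (vessels in sulci, ventricle rims) are not
#' microbleed candidates. Emptied components get reason `csf_neighbour`.
#'
#' @param set a `cmb_component_set`.
#' @param csf_posterior [volume3d] on the same grid.
#' @param threshold CSF probability threshold (default 0.5, strict).
#' @param neighbour_connectivity 6 or 26 for the dilation (default 6).
#' @param connectivity used when re-labelling clipped remainders.
#' @param posterior optional CMB posterior for re-measured peaks.
#' @return The filtered set.
#' @export
exclude_csf_neighbours <- function(set, csf_posterior, threshold = 0.5,
                                   neighbour_connectivity = 6L,
                                   connectivity = 26L, posterior = NULL) {
  stopifnot(all(dim(csf_posterior$data) == set$dim))
  csf <- array(as.vector(csf_posterior$data) > threshold, set$dim)
  removal <- which(dilate_mask(csf, neighbour_connectivity))
  remove_voxels_from_components(set, removal, "csf_neighbour", connectivity,
                                posterior)
}

# one-step binary dilation by shifting along neighbour offsets
dilate_mask <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  out <- mask
  offs <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    if (connectivity == 6L && abs(a) + abs(b) + abs(c) != 1) next
    offs[[length(offs) + 1]] <- c(a, b, c)
  }
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  for (o in offs) {
    sx <- ix - o[1]; sy <- iy - o[2]; sz <- iz - o[3]
    vx <- sx >= 1 & sx <= d[1]; vy <- sy >= 1 & sy <= d[2]
    vz <- sz >= 1 & sz <= d[3]
    out[ix[vx], iy[vy], iz[vz]] <-
      out[ix[vx], iy[vy], iz[vz]] | mask[sx[vx], sy[vy], sz[vz]]
  }
  out
}

#' Discard components overlapping the artefact mask
#'
#' A component sharing at least one voxel with the control-derived artefact
#' mask is discarded whole (reason `artefact_mask`): the masked territory
#' marks recurrent false-positive locations such as air-bone interfaces.
#'
#' @param set a `cmb_component_set`.
#' @param mask an `artefact_mask` (or binary [volume3d]) in working space.
#' @return The filtered set.
#' @export
apply_artefact_mask <- function(set, mask) {
  m <- if (inherits(mask, "artefact_mask")) mask$mask else mask
  stopifnot(all(dim(m$data) == set$dim))
  mv <- as.vector(m$data) != 0
  set$components <- lapply(set$components, function(cp) {
    if (cp$status != "kept") return(cp)
    if (any(mv[cp$voxels])) discard_component(cp, "artefact_mask") else cp
  })
  set
}

#' Manually discard or restore components by id
#'
#' Represents the rapid manual editing step: listed component ids are
#' discarded (reason `manual`) or restored to "kept".
#'
#' @param set a `cmb_component_set`.
#' @param discard_ids,restore_ids character vectors of component ids.
#' @return The edited set.
#' @export
edit_components <- function(set, discard_ids = character(0),
                            restore_ids = character(0)) {
  set$components <- lapply(set$components, function(cp) {
    if (cp$id %in% discard_ids && cp$status == "kept")
      return(discard_component(cp, "manual"))
    if (cp$id %in% restore_ids && cp$status == "discarded") {
      cp$status <- "kept"
      cp$discard_reason <- NA_character_
    }
    cp
  })
  set
}

#' Render kept components as a map
#'
#' @param set a `cmb_component_set`.
#' @param posterior optional [volume3d]; kept voxels take its values
#'   (probabilistic map), otherwise 1 (binary map).
#' @return A [volume3d].
#' @export
components_to_map <- function(set, posterior = NULL) {
  arr <- array(0, set$dim)
  pv <- if (is.null(posterior)) NULL else as.vector(posterior$data)
  for (cp in kept(set))
    arr[cp$voxels] <- if (is.null(pv)) 1 else pv[cp$voxels]
  volume3d(arr, affine = set$affine, description = "cleaned CMB map")
}

#' First-pass refinement cascade
#'
#' The fixed clean-up order applied to the first-pass CMB posterior:
#' binarise (>= 0.2), label components, size filter, skull masking,
#' CSF-neighbour exclusion, artefact-mask overlap discard.
#'
#' @param cmb_posterior,skull_posterior,csf_posterior first-pass posterior
#'   maps ([volume3d], same grid).
#' @param artefact_mask optional `artefact_mask` or binary [volume3d].
#' @param config a [midas_config()].
#' @return List with `components` (audit-complete `cmb_component_set`) and
#'   `cleaned_map` (posterior values on surviving voxels, zero elsewhere).
#' @export
refine_candidates <- function(cmb_posterior, skull_posterior, csf_posterior,
                              artefact_mask = NULL,
                              config = midas_config()) {
  set <- label_components(binarise_posterior(cmb_posterior,
                                             config$binarise_threshold),
                          config$connectivity, posterior = cmb_posterior)
  set <- filter_by_size(set, config$min_voxels, config$max_volume_cm3)
  set <- mask_skull(set, skull_posterior, config$skull_threshold,
                    config$connectivity, posterior = cmb_posterior)
  set <- exclude_csf_neighbours(set, csf_posterior, config$csf_threshold,
                                config$neighbour_connectivity,
                                config$connectivity,
                                posterior = cmb_posterior)
  if (!is.null(artefact_mask)) set <- apply_artefact_mask(set, artefact_mask)
  list(components = set,
       cleaned_map = components_to_map(set, posterior = cmb_posterior))
}

#' Build the control-derived artefact mask
#'
#' Runs the full two-pass detection pipeline on each control volume (all
#' filters except the artefact-mask step itself) and unions the surviving
#' candidate voxels into one map: territory where healthy controls produce
#' detections marks recurrent mimics (air-bone interfaces, flow voids) to
#' be discarded in patients.
#'
#' @param control_volumes list of [volume3d] control T2* volumes (aligned
#'   to the template/working space).
#' @param priors a `tissue_prior_set`.
#' @param config a [midas_config()].
#' @param control_ids optional character ids recorded as provenance.
#' @return An `artefact_mask`: binary [volume3d] (working grid) +
#'   provenance.
#' @export
build_artefact_mask <- function(control_volumes, priors,
                                config = midas_config(),
                                control_ids = NULL) {
  if (is.null(control_ids))
    control_ids <- paste0("control", seq_along(control_volumes))
  acc <- NULL
  used <- character(0)
  for (i in seq_along(control_volumes)) {
    rep <- run_midas(control_volumes[[i]], priors, artefact_mask = NULL,
                     region_labels = NULL, config = config,
                     subject_id = control_ids[i])
    m <- rep$cmb_map
    if (is.null(acc)) acc <- array(0L, dim(m$data))
    acc <- acc | (m$data > 0)
    used <- c(used, control_ids[i])
  }
  if (is.null(acc))
    stop("at least one control volume is required")
  grid <- control_volumes[[1]]
  # mask lives on the working grid of the pipeline
  ref <- run_grid(grid, config)
  structure(list(mask = volume3d(array(as.integer(acc), dim(acc)),
                                 affine = ref$affine,
                                 description = "artefact mask"),
                 provenance = used),
            class = "artefact_mask")
}

#' @export
print.artefact_mask <- function(x, ...) {
  cat(sprintf("artefact_mask: %d voxels from %d controls\n",
              sum(x$mask$data), length(x$provenance)))
  invisible(x)
}
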