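# the working grid a volume is segmented on
run_grid <- function(vol, config) {
  resample_isotropic(vol, config$working_spacing, order = "linear")
}

#' Run the full two-pass microbleed detection pipeline
#'
#' Per-subject orchestration: (1) resample the T2* volume and priors to the
#' isotropic working grid; (2) first segmentation pass with the flat
#' in-brain CMB prior ([fit_constrained_mixture()]); (3) morphological
#' refinement cascade on the first-pass CMB posterior
#' ([refine_candidates()]); (4) replace the CMB prior by the cleaned
#' subject-specific map ([refine_cmb_prior()]); (5) second segmentation
#' pass (warm-started from the first); (6) threshold the second-pass CMB
#' posterior at the final level (0.5), re-label and re-apply the size
#' bounds; (7) per-region counts at the surviving centroids.
#'
#' @param t2star subject T2* [volume3d] (aligned to the prior space, or
#'   supply `transform`).
#' @param priors a `tissue_prior_set`.
#' @param artefact_mask optional `artefact_mask` or binary [volume3d] (in
#'   prior/template space or already on the working grid).
#' @param region_labels optional integer [volume3d] with codes per
#'   [MIDAS_REGIONS] (0 none, 1 lobar, 2 deep, 3 infratentorial).
#' @param config a [midas_config()].
#' @param subject_id identifier recorded in the report.
#' @param transform optional 4x4 world affine mapping subject world into
#'   prior/template world (from [align_to_template()]).
#' @return A `midas_report`: surviving components, per-region counts,
#'   audit-complete discard table, both fitted models, the cleaned prior
#'   map, the final binary CMB map, the config snapshot and runtime.
#' @export
run_midas <- function(t2star, priors, artefact_mask = NULL,
                      region_labels = NULL, config = midas_config(),
                      subject_id = "subject", transform = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stopifnot(inherits(t2star, "volume3d"),
            inherits(priors, "tissue_prior_set"))
  if (!is.null(transform))
    t2star <- resample_to_grid(t2star, priors$maps[[1]], method = "linear",
                               transform = transform)
  wvol <- run_grid(t2star, config)
  wpriors <- resample_priors(priors, wvol)
  if (sum(wpriors$brain_mask$data) < 100)
    stop("empty or near-empty brain mask on the working grid [stage: ",
         "resampling]")
  wregions <- if (is.null(region_labels)) NULL else {
    r <- resample_to_grid(region_labels, wvol, method = "nearest")
    r$data <- array(as.integer(round(r$data)), dim(r$data))
    r
  }
  wartefact <- if (is.null(artefact_mask)) NULL else {
    m <- if (inherits(artefact_mask, "artefact_mask")) artefact_mask$mask
         else artefact_mask
    if (!same_grid(m, wvol)) {
      m <- resample_to_grid(m, wvol, method = "nearest")
      m$data <- array(as.integer(m$data > 0.5), dim(m$data))
    }
    m
  }

  fit1 <- fit_constrained_mixture(wvol, wpriors, config)
  if (isTRUE(fit1$model$collapsed[["GWM"]]))
    stop("degenerate first-pass fit: GWM class collapsed [stage: pass 1]")

  ref <- refine_candidates(fit1$posteriors$CMB, fit1$posteriors$skull,
                           fit1$posteriors$CSF, wartefact, config)
  priors2 <- refine_cmb_prior(wpriors, ref$cleaned_map)
  fit2 <- fit_constrained_mixture(wvol, priors2, config,
                                  init_model = fit1$model,
                                  reinit_classes = "CMB",
                                  constrained_variance = TRUE)

  final_mask <- binarise_posterior(fit2$posteriors$CMB,
                                   config$final_threshold)
  survivors <- label_components(final_mask, config$connectivity,
                                posterior = fit2$posteriors$CMB)
  survivors <- filter_by_size(survivors, config$min_voxels,
                              config$max_volume_cm3)

  survivors <- assign_regions(survivors, wregions)
  cmb_map <- components_to_map(survivors)
  counts <- region_counts(survivors)

  report <- structure(list(
    subject_id = subject_id,
    survivors = as.data.frame(survivors),
    components = survivors,
    pass1_components = ref$components,
    discards = {
      d1 <- as.data.frame(ref$components)
      d1$pass <- rep(1L, nrow(d1))
      d2 <- as.data.frame(survivors)
      d2$pass <- rep(2L, nrow(d2))
      rbind(d1, d2)
    },
    counts = counts,
    multi_cmb = counts[["lobar"]] >= 2,
    cleaned_map = ref$cleaned_map,
    cmb_map = cmb_map,
    posteriors = fit2$posteriors,
    models = list(pass1 = fit1$model, pass2 = fit2$model),
    bias = fit2$bias,
    config = config,
    working_grid = list(dim = dim(wvol$data), affine = wvol$affine),
    runtime_s = proc.time()[["elapsed"]] - t0),
    class = "midas_report")
  report$discards <- report$discards[report$discards$status == "discarded", ]
  report$survivors <- report$survivors[report$survivors$status == "kept", ]
  report
}

assign_regions <- function(set, region_labels) {
  set$components <- lapply(set$components, function(cp) {
    if (is.null(region_labels)) { cp$region <- "lobar"; return(cp) }
    v <- world_to_voxel(region_labels, matrix(cp$centroid_mm, 1))[1, ]
    d <- dim(region_labels$data)
    v <- pmin(pmax(round(v), 0), d - 1)
    code <- region_labels$data[1 + v[1] + d[1] * (v[2] + d[2] * v[3])]
    cp$region <- names(MIDAS_REGIONS)[match(code, MIDAS_REGIONS)]
    if (is.na(cp$region) || cp$region == "none") {
      if (cp$status == "kept")
        warning("component ", cp$id, " centroid outside labelled brain")
      cp$region <- "none"
    }
    cp
  })
  set
}

region_counts <- function(set) {
  regs <- vapply(kept(set), function(cp)
    if (is.null(cp$region)) "lobar" else cp$region, character(1))
  c(lobar = sum(regs == "lobar"), deep = sum(regs == "deep"),
    infratentorial = sum(regs == "infratentorial"),
    none = sum(regs == "none"))
}

#' Per-region counts of surviving components
#'
#' Each surviving component is assigned the region of its centroid voxel in
#' the label volume; returns lobar / deep / infratentorial counts and the
#' multiple-lesion flag (two or more lobar microbleeds).
#'
#' @param report a `midas_report`.
#' @param region_labels integer [volume3d] of region codes
#'   ([MIDAS_REGIONS]); defaults to the labels used at run time.
#' @return List with `counts` (named integer vector) and `multi_cmb`.
#' @export
summarise_by_region <- function(report, region_labels = NULL) {
  set <- report$components
  if (!is.null(region_labels)) set <- assign_regions(set, region_labels)
  counts <- region_counts(set)
  list(counts = counts, multi_cmb = counts[["lobar"]] >= 2)
}

#' @export
print.midas_report <- function(x, ...) {
  cat(sprintf("midas_report [%s]: %d surviving components ", x$subject_id,
              nrow(x$survivors)))
  cat(sprintf("(lobar %d, deep %d, infratentorial %d); %d discarded\n",
              x$counts[["lobar"]], x$counts[["deep"]],
              x$counts[["infratentorial"]], nrow(x$discards)))
  cat(sprintf("  multi-lobar: %s; runtime %.1f s\n",
              x$multi_cmb, x$runtime_s))
  invisible(x)
}

#' Write a detection report to disk
#'
#' Writes `report.json` (subject, counts, survivors, discards, config,
#' model summaries), `components.tsv`, the final binary map
#' `cmb_map.nii.gz`, the cleaned first-pass map, and the six posterior
#' maps under `posteriors/`.
#'
#' @param report a `midas_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  c1 <- as.data.frame(report$pass1_components)
  c1$pass <- rep(1L, nrow(c1))
  c2 <- as.data.frame(report$components)
  c2$pass <- rep(2L, nrow(c2))
  comp <- rbind(c1, c2)
  utils::write.table(comp, file.path(dir, "components.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    subject_id = report$subject_id,
    counts = as.list(report$counts),
    multi_cmb = report$multi_cmb,
    survivors = report$survivors,
    discards = report$discards,
    config = unclass(report$config),
    models = lapply(report$models, function(m)
      list(comps = m$comps[c("class", "w", "mu", "s2")],
           gwm_mean = m$gwm_mean, converged = m$converged)),
    runtime_s = report$runtime_s),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_volume(report$cmb_map, file.path(dir, "cmb_map.nii.gz"))
  write_volume(report$cleaned_map, file.path(dir, "cleaned_pass1.nii.gz"))
  pdir <- file.path(dir, "posteriors")
  dir.create(pdir, showWarnings = FALSE)
  for (k in names(report$posteriors))
    write_volume(report$posteriors[[k]],
                 file.path(pdir, paste0(k, ".nii.gz")))
  invisible(dir)
}
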