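mask_vol <- function(arr, spacing = c(1.5, 1.5, 1.5)) {
  volume3d(array(as.numeric(arr), dim(arr)), spacing = spacing)
}

test_that("binarisation matches the elementwise oracle and is inclusive", {
  set.seed(21)
  p <- volume3d(array(runif(512), c(8, 8, 8)))
  b <- binarise_posterior(p, 0.2)
  expect_identical(b$data, array(as.integer(p$data >= 0.2), dim(p$data)))

  zero <- volume3d(array(0, c(4, 4, 4)))
  expect_equal(sum(binarise_posterior(zero)$data), 0)
  one <- zero; one$data[2, 3, 1] <- 0.9
  expect_equal(sum(binarise_posterior(one)$data), 1)
  # exact threshold value is included
  at <- zero; at$data[1, 1, 1] <- 0.2
  expect_equal(sum(binarise_posterior(at, 0.2)$data), 1)
  bad <- zero; bad$data[1, 1, 1] <- 1.4
  expect_error(binarise_posterior(bad), "\\[0, 1\\]")
})

test_that("connected components agree with a flood-fill oracle at both connectivities", {
  # corner-touching pair: one component at 26-connectivity, two at 6
  arr <- array(0, c(4, 4, 4))
  arr[1, 1, 1] <- 1; arr[2, 2, 2] <- 1
  expect_length(label_components(mask_vol(arr), 26)$components, 1)
  expect_length(label_components(mask_vol(arr), 6)$components, 2)

  for (seed in 1:4) {
    set.seed(seed)
    m <- array(rbinom(9 * 9 * 6, 1, 0.25), c(9, 9, 6))
    for (conn in c(6, 26)) {
      got <- label_components(mask_vol(m), conn)
      oracle <- floodfill_labels(m, conn)
      got_part <- canonical_partition(lapply(got$components,
                                             function(cp) sort(cp$voxels)))
      expect_identical(got_part,
                       canonical_partition(partition_of(oracle)))
    }
  }
})

test_that("component measurements are in world units", {
  arr <- array(0, c(10, 10, 4))
  arr[3:4, 5, 2] <- 1
  v <- mask_vol(arr, spacing = c(1.5, 1.5, 1.5))
  set <- label_components(v)
  cp <- set$components[[1]]
  expect_equal(cp$n, 2)
  expect_equal(cp$volume_cm3, 2 * 1.5^3 / 1000)
  expect_equal(cp$centroid_mm,
               colMeans(voxel_to_world(v, rbind(c(2, 4, 1), c(3, 4, 1)))))
})

test_that("size filtering applies the printed bounds with the stated strictness", {
  arr <- array(0, c(40, 40, 12))
  arr[1, 1, 1] <- 1                       # 1 voxel = 0.003375 cm^3
  arr[5:14, 5, 5] <- 1                    # 10 voxels = 0.034 cm^3
  arr[20:33, 20:33, 8] <- 1               # 196 voxels = 0.66 cm^3 (kept)
  v <- mask_vol(arr)
  set <- filter_by_size(label_components(v))
  df <- as.data.frame(set)
  expect_equal(df$discard_reason[df$n_voxels == 1], "too_small")
  expect_equal(df$status[df$n_voxels == 10], "kept")
  expect_equal(df$status[df$n_voxels == 196], "kept")

  # strictly above 0.675 cm^3 is discarded: 0.70 cm^3 = 208 voxels
  arr2 <- array(0, c(40, 40, 12))
  arr2[1:13, 1:16, 3] <- 1
  set2 <- filter_by_size(label_components(mask_vol(arr2)))
  df2 <- as.data.frame(set2)
  expect_equal(df2$n_voxels, 208)
  expect_gt(df2$volume_cm3, 0.675)
  expect_equal(df2$discard_reason, "too_large")
})

test_that("skull masking discards, preserves or clips components appropriately", {
  arr <- array(0, c(12, 12, 6))
  arr[2:3, 2, 2] <- 1      # fully in skull
  arr[6:7, 6, 3] <- 1      # disjoint from skull
  arr[9:10, 9, 4] <- 1     # half-overlapping
  skull <- array(0, c(12, 12, 6))
  skull[2:3, 2, 2] <- 0.9
  skull[9, 9, 4] <- 0.9
  v <- mask_vol(arr)
  set <- mask_skull(label_components(v), mask_vol(skull))
  df <- as.data.frame(set)
  expect_equal(sum(df$discard_reason == "skull", na.rm = TRUE), 1)
  kept <- df[df$status == "kept", ]
  expect_setequal(kept$n_voxels, c(2, 1))  # survivor re-measured
})

test_that("CSF-neighbour exclusion equals the dilate-then-subtract oracle", {
  set.seed(31)
  d <- c(10, 10, 6)
  cand <- array(rbinom(prod(d), 1, 0.3), d)
  csf <- array(runif(prod(d)), d)
  set <- exclude_csf_neighbours(label_components(mask_vol(cand)),
                                mask_vol(csf), threshold = 0.5,
                                neighbour_connectivity = 6)
  surv <- sort(unlist(lapply(midas:::kept(set), `[[`, "voxels")))

  # oracle: brute-force 6-neighbourhood dilation of csf > 0.5, subtracted
  high <- csf > 0.5
  dil <- high
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1),
                 c(0,0,-1))) {
    idx <- which(high, arr.ind = TRUE)
    shifted <- sweep(idx, 2, o, "+")
    ok <- shifted[, 1] >= 1 & shifted[, 1] <= d[1] &
      shifted[, 2] >= 1 & shifted[, 2] <= d[2] &
      shifted[, 3] >= 1 & shifted[, 3] <= d[3]
    dil[shifted[ok, , drop = FALSE]] <- TRUE
  }
  expect_identical(surv, sort(which(cand == 1 & !dil)))

  # below-threshold CSF leaves components untouched
  low <- mask_vol(array(0.4, d))
  set2 <- exclude_csf_neighbours(label_components(mask_vol(cand)), low)
  expect_identical(sort(unlist(lapply(midas:::kept(set2), `[[`, "voxels"))),
                   sort(which(cand == 1)))
})

test_that("artefact-mask overlap discards whole components; monotone in the mask", {
  arr <- array(0, c(12, 12, 6))
  arr[2:4, 2, 2] <- 1
  arr[8:9, 8, 4] <- 1
  v <- mask_vol(arr)
  m1 <- array(0L, c(12, 12, 6)); m1[2, 2, 2] <- 1L  # one-voxel overlap
  set <- apply_artefact_mask(label_components(v), mask_vol(m1))
  df <- as.data.frame(set)
  expect_equal(df$discard_reason[df$n_voxels == 3], "artefact_mask")
  expect_equal(df$status[df$n_voxels == 2], "kept")

  empty <- mask_vol(array(0L, c(12, 12, 6)))
  set0 <- apply_artefact_mask(label_components(v), empty)
  expect_true(all(as.data.frame(set0)$status == "kept"))

  # enlarging the mask never increases survivors
  m2 <- m1; m2[8, 8, 4] <- 1L
  n1 <- sum(as.data.frame(apply_artefact_mask(label_components(v),
                                              mask_vol(m1)))$status == "kept")
  n2 <- sum(as.data.frame(apply_artefact_mask(label_components(v),
                                              mask_vol(m2)))$status == "kept")
  expect_lte(n2, n1)
})

test_that("the refinement cascade is audit-complete with one reason per discard", {
  ph <- small_phantom(seed = 17)
  pr <- priors_from_labels(ph$truth$labels)
  w <- resample_isotropic(ph$volume, 1.5)
  wp <- midas:::resample_priors(pr, w)
  fit <- fit_constrained_mixture(w, wp)
  ref <- refine_candidates(fit$posteriors$CMB, fit$posteriors$skull,
                           fit$posteriors$CSF, config = midas_config())
  df <- as.data.frame(ref$components)
  expect_true(all(df$status %in% c("kept", "discarded")))
  expect_true(all(is.na(df$discard_reason[df$status == "kept"])))
  expect_true(all(df$discard_reason[df$status == "discarded"] %in%
                    midas:::DISCARD_REASONS))
  # cleaned map support is exactly the kept voxels
  expect_equal(sort(which(ref$cleaned_map$data > 0)),
               sort(unlist(lapply(midas:::kept(ref$components),
                                  `[[`, "voxels"))))
  # no kept component violates the size bounds
  expect_true(all(df$n_voxels[df$status == "kept"] >= 2))
  expect_true(all(df$volume_cm3[df$status == "kept"] <= 0.675))
})

test_that("manual editing discards and restores by component id", {
  arr <- array(0, c(8, 8, 4))
  arr[2:3, 2, 2] <- 1
  arr[6:7, 6, 3] <- 1
  set <- label_components(mask_vol(arr))
  ids <- vapply(set$components, `[[`, "", "id")
  ed <- edit_components(set, discard_ids = ids[1])
  df <- as.data.frame(ed)
  expect_equal(df$discard_reason[df$id == ids[1]], "manual")
  back <- edit_components(ed, restore_ids = ids[1])
  expect_true(all(as.data.frame(back)$status == "kept"))
})
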