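test_that("phantom generation is deterministic and validates its spec", {
  spec <- phantom_spec(grid_shape = c(36, 36, 8), seed = 7,
                       cmb_list = list(list(centre_mm = c(3, 2, 0),
                                            diameter_mm = 5)))
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$cmb_mask$data, b$truth$cmb_mask$data)

  expect_error(phantom_spec(cmb_list = list(list(centre_mm = c(0, 0, 0),
                                                 diameter_mm = 12))),
               "2-10 mm")
  expect_error(phantom_spec(cmb_list = list(list(centre_mm = c(0, 0, 0),
                                                 diameter_mm = 5,
                                                 intensity_fraction = 0.7))),
               "0.5")
  expect_error(phantom_spec(voxel_size_mm = c(1, 0, 1)), "positive")
  # a centre outside the brain ellipsoid is rejected with a diagnostic
  bad <- phantom_spec(grid_shape = c(36, 36, 8),
                      cmb_list = list(list(centre_mm = c(500, 0, 0),
                                           diameter_mm = 5)))
  expect_error(make_phantom(bad), "outside the brain")
})

test_that("noiseless unbiased phantom reproduces the generative means with the expected intensity ordering", {
  spec <- phantom_spec(grid_shape = c(48, 48, 10), noise_sigma = 0,
                       bias_amplitude = 0, seed = 1)
  ph <- make_phantom(spec)
  lab <- ph$truth$labels$data
  v <- ph$volume$data
  for (cl in c("GWM", "CSF", "skull", "scalp", "other")) {
    code <- midas:::PHANTOM_CLASSES[[cl]]
    expect_equal(unique(as.vector(v[lab == code])),
                 unname(spec$tissue_means[[cl]]), tolerance = 1e-12)
  }

  # histogram ordering backing the segmentation constraints:
  # CSF > GWM > 2 * CMB. Checked on a near-isotropic grid; on 6.5 mm
  # slices, partial volume legitimately dilutes small lesions.
  spec2 <- phantom_spec(grid_shape = c(64, 64, 64),
                        voxel_size_mm = c(1.5, 1.5, 1.5),
                        noise_sigma = 0, bias_amplitude = 0, seed = 1,
                        cmb_list = list(list(centre_mm = c(20, 10, 0),
                                             diameter_mm = 8,
                                             intensity_fraction = 0.3)))
  ph2 <- make_phantom(spec2)
  lab2 <- ph2$truth$labels$data
  m <- function(code) mean(ph2$volume$data[lab2 == code])
  expect_gt(m(2), m(1))            # CSF brighter than parenchyma
  expect_gt(m(1), 2 * m(3))        # parenchyma more than twice CMB level
})

test_that("lesion rasterisation respects partial volume on the anisotropic grid", {
  # 6 mm sphere centred on a slice plane (z = 3.25 on the default grid):
  # mask volume within 25% of pi d^3 / 6 = 113 mm^3
  spec <- phantom_spec(cmb_list = list(list(centre_mm = c(0, 0, 3.25),
                                            diameter_mm = 6,
                                            intensity_fraction = 0.3)),
                       noise_sigma = 0, bias_amplitude = 0, seed = 1)
  ph <- make_phantom(spec)
  les <- ph$truth$lesions
  expect_equal(nrow(les), 1L)
  expect_false(les$subvoxel)
  expect_lt(abs(les$volume_mm3 - 113.1) / 113.1, 0.25)
  # ground-truth consistency: recorded volume = mask voxels x voxel volume
  expect_equal(les$volume_mm3,
               sum(ph$truth$cmb_mask$data) * voxel_volume_mm3(ph$volume))
})

test_that("insert_cmb honours identity, sub-voxel and voxelisation contracts", {
  v <- volume3d(array(100, c(30, 30, 30)), spacing = c(1, 1, 1))

  expect_error(insert_cmb(v, c(0, 0, 0), -1, 0.3), "positive")
  same <- insert_cmb(v, c(0, 0, 0), 6, 1)
  expect_equal(same$data, v$data)

  # sub-voxel sphere at a voxel centre touches at most that voxel
  ctr <- midas:::voxel_grid_world(v)[1 + 15 + 30 * (15 + 30 * 15), ]
  tiny <- insert_cmb(v, ctr, 0.8, 0.3)
  expect_lte(sum(tiny$data != v$data), 1)

  # 8 mm sphere on the unit grid: voxels at >= half occupancy match the
  # brute-force count of voxel centres inside the sphere (about 268)
  out <- insert_cmb(v, ctr, 8, 0.3)
  occ <- attr(out, "occupancy")
  n_core <- sum(occ$occ >= 0.5)
  xyz <- midas:::voxel_grid_world(v)
  oracle <- sum(colSums((t(xyz) - ctr)^2) <= 16)
  expect_lt(abs(n_core - oracle) / oracle, 0.1)
  expect_lt(abs(n_core - 268) / 268, 0.1)
})

test_that("bias field meets its scaling and centring contracts", {
  v <- volume3d(array(100, c(24, 24, 12)), spacing = c(2, 2, 4))
  null <- apply_bias_field(v, 0, seed = 5)
  expect_equal(null$volume$data, v$data)

  bf <- apply_bias_field(v, 0.2, seed = 5)
  expect_equal(max(abs(bf$field$data - 1)), 0.2, tolerance = 1e-6)
  expect_equal(mean(log(bf$field$data)), 0, tolerance = 1e-10)
  expect_equal(bf$volume$data / v$data, bf$field$data, tolerance = 1e-12)

  # determinism of the field given the seed
  bf2 <- apply_bias_field(v, 0.2, seed = 5)
  expect_identical(bf$field$data, bf2$field$data)
})

test_that("mimic primitives create dark structures where specified", {
  spec <- phantom_spec(grid_shape = c(48, 48, 10), noise_sigma = 0,
                       bias_amplitude = 0, seed = 2,
                       mimic_list = list(
                         list(type = "edge_band", width_mm = 4),
                         list(type = "vessel", start_mm = c(-10, 0, 0),
                              end_mm = c(10, 0, 0), radius_mm = 1.2),
                         list(type = "macrobleed", centre_mm = c(0, 8, 0),
                              diameter_mm = 12)))
  ph <- make_phantom(spec)
  clean <- make_phantom(phantom_spec(grid_shape = c(48, 48, 10),
                                     noise_sigma = 0, bias_amplitude = 0,
                                     seed = 2))
  expect_gt(sum(ph$volume$data < clean$volume$data), 0)
  expect_error(make_phantom(phantom_spec(grid_shape = c(48, 48, 10),
                                         mimic_list = list(list(type = "x")))),
               "unknown mimic")
})

test_that("random lobar cohorts place lesions in the lobar compartment, reproducibly", {
  spec <- random_cmb_phantom_spec(seed = 4, grid_shape = c(120, 120, 17))
  spec_b <- random_cmb_phantom_spec(seed = 4, grid_shape = c(120, 120, 17))
  expect_identical(spec$cmb_list, spec_b$cmb_list)
  expect_gte(length(spec$cmb_list), 2)
  expect_lte(length(spec$cmb_list), 5)
  ph <- make_phantom(spec)
  reg <- ph$truth$regions
  for (cmb in spec$cmb_list) {
    expect_gte(cmb$diameter_mm, 4)
    vx <- round(world_to_voxel(reg, matrix(cmb$centre_mm, 1))[1, ])
    code <- reg$data[1 + vx[1] + dim(reg$data)[1] *
                       (vx[2] + dim(reg$data)[2] * vx[3])]
    expect_equal(unname(code), unname(MIDAS_REGIONS[["lobar"]]))
  }
})
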