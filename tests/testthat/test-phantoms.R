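test_that("box voxelisation produces the exact grid and rejects misfits", {
  ph <- voxelise_box(c(64, 64, 52), c(0.2, 0.2, 0.5))
  expect_equal(ph$dim, c(320L, 320L, 104L))
  expect_equal(prod(ph$dim), 10649600)
  expect_gt(prod(ph$dim), 1e7)
  expect_equal(voxelise_box(c(1, 1, 1), c(1, 1, 1))$dim, c(1L, 1L, 1L))
  expect_error(voxelise_box(c(63.5, 64, 52), c(0.2, 0.2, 0.5)), "exactly")
})

test_that("chamber array arithmetic matches its stated layout", {
  d <- chamber_depths(0.5, 1.0, 40)
  expect_length(d, 40)
  expect_equal(max(d), 39.5)
  expect_equal(chamber_depths(0.5, 1.0, 1), 0.5)
  d11 <- chamber_depths(0.5, 1.0, 11)
  expect_length(d11, 11)
  expect_equal(max(d11), 10.5)
  expect_error(chamber_depths(0.5, -1, 4), "positive")
  expect_equal(chamber_volume(0.38, 1.21), 0.54, tolerance = 0.02)
  expect_equal(chamber_volume(0.38, 1.21), pi * 0.38^2 * 1.21)
  expect_equal(chamber_volume(1, 0), 0)
  expect_equal(chamber_volume(1, 1), pi)
})

test_that("solid-box chambers are a non-perturbing fraction of the water", {
  ph <- solid_box_phantom()
  vol_ch <- ph$chambers$count * chamber_volume(ph$chambers$radius,
                                               ph$chambers$height)
  expect_lt(vol_ch / prod(ph$inner), 1e-3)
})

test_that("voxel phantom files round-trip and unmapped ids are named", {
  ph <- synthetic_head_phantom(seed = 3)
  g <- tempfile(fileext = ".vox"); m <- tempfile(fileext = ".map")
  write_voxel_phantom(ph, g, m)
  ph2 <- load_voxel_phantom(g, m)
  expect_identical(ph2$ids, ph$ids)
  expect_identical(ph2$dim, ph$dim)
  expect_equal(ph2$voxel_size, ph$voxel_size, tolerance = 1e-9)
  bad <- ph; bad$ids[[1]] <- 999L
  g2 <- tempfile(fileext = ".vox")
  write_voxel_phantom(bad, g2)
  expect_error(load_voxel_phantom(g2, m), "999")
  expect_error(load_voxel_phantom(tempfile()), "not found")
  # loaded phantom resolves against the packaged 30-tissue material table
  mats <- unique(material_ids(ph2))
  db <- load_materials()
  expect_true(all(mats %in% db$ids))
})

test_that("upper crop keeps the top slices and adjusts the origin", {
  ph <- voxelise_box(c(4, 4, 33.7), c(1, 1, 0.1))
  ph$ids <- as.integer(seq_along(ph$ids) %% 7 + 1)
  cr <- crop_upper(ph, 87)
  expect_equal(cr$dim[3], 87L)
  expect_equal(prod(cr$dim), 4 * 4 * 87)
  expect_equal(cr$origin[3], ph$origin[3] + (337 - 87) * 0.1)
  a <- array(ph$ids, ph$dim)
  expect_equal(array(cr$ids, cr$dim), a[, , 251:337])
  expect_identical(crop_upper(ph, ph$dim[3])$ids, ph$ids)
  expect_error(crop_upper(ph, 0), "positive")
  expect_error(crop_upper(ph, 400), "exceeds")
})

test_that("synthetic head phantom satisfies its construction contract", {
  ph <- synthetic_head_phantom(seed = 1)
  expect_identical(ph$ids, synthetic_head_phantom(seed = 1)$ids)  # deterministic
  a <- array(ph$ids, ph$dim)
  # outermost non-vacuum voxel along sampled grid lines is skin (organ 101)
  set.seed(99)
  check_line <- function(v) {
    nz <- which(v != 0)
    length(nz) == 0 || (v[nz[1]] == 101 && v[nz[length(nz)]] == 101)
  }
  for (r in 1:200) {
    j <- sample(ph$dim[2], 1); k <- sample(ph$dim[3], 1)
    expect_true(check_line(a[, j, k]))
    i <- sample(ph$dim[1], 1)
    expect_true(check_line(a[i, , k]))
    expect_true(check_line(a[i, j, ]))
  }
  # six nonempty, pairwise disjoint salivary-gland ROI masks
  expect_named(ph$rois, c("parotid_r", "parotid_l", "submandibular_r",
                          "submandibular_l", "sublingual_r", "sublingual_l"))
  expect_true(all(vapply(ph$rois, length, integer(1)) > 0))
  expect_false(any(duplicated(unlist(ph$rois))))
  # trachea voxels are air with density below 0.01 g/cm3
  trachea <- material_ids(ph)[ph$ids == 108L]
  expect_true(all(trachea == 5L))
  expect_lt(get_material(load_materials(), 5L)$density, 0.01)
  # a representative anatomy uses at least 10 of the 30 tissue materials
  expect_gte(length(setdiff(unique(material_ids(ph)), 0L)), 10)
  expect_error(synthetic_head_phantom(shape = c(10, 10, 10)), "too small")
})
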