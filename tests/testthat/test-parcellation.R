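solid_mask <- function(grid = c(16L, 16L, 16L)) {
  binary_mask(array(TRUE, grid), make_affine(c(1, 1, 1), grid))
}

test_that("symmetrize_mask is idempotent on symmetric input and unions sides", {
  m <- solid_mask()
  sym <- symmetrize_mask(m)
  expect_identical(sym$data, m$data)

  # voxel present only on the right appears bilaterally under the union rule
  arr <- array(FALSE, c(16, 16, 16))
  arr[12, 8, 8] <- TRUE
  one <- binary_mask(arr, m$affine)
  sym1 <- symmetrize_mask(one)
  expect_true(sym1$data[12, 8, 8] && sym1$data[5, 8, 8])
  expect_equal(sum(sym1$data), 2)
  # intersection rule removes one-sided voxels
  expect_equal(sum(symmetrize_mask(one, "intersection")$data), 0)
})

test_that("the four combine cases match the chosen union/intersection rules", {
  arr <- array(FALSE, c(4, 1, 1))
  # columns 1..4 have world x = -1.5, -0.5, +0.5, +1.5; pairs (1,4), (2,3)
  arr[1, 1, 1] <- TRUE  # left only of pair (1,4)
  arr[2, 1, 1] <- TRUE  # left of pair (2,3)
  arr[3, 1, 1] <- TRUE  # right of pair (2,3): both present
  m <- binary_mask(arr, make_affine(c(1, 1, 1), c(4L, 1L, 1L)))
  u <- symmetrize_mask(m, "union")$data
  expect_equal(as.vector(u), c(TRUE, TRUE, TRUE, TRUE))
  i <- symmetrize_mask(m, "intersection")$data
  expect_equal(as.vector(i), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("empty and non-alignable masks are rejected", {
  expect_error(symmetrize_mask(binary_mask(array(FALSE, c(4, 4, 4)),
                                           make_affine(c(1, 1, 1), c(4L, 4L, 4L)))),
               "nonempty")
  A <- make_affine(c(1, 1, 1), c(4L, 4L, 4L))
  A[1, 4] <- 0   # grid no longer centered on the midplane
  expect_error(symmetrize_mask(binary_mask(array(TRUE, c(4, 4, 4)), A)),
               "resample")
})

test_that("random partition tiles the hemisphere with connected near-equal ROIs", {
  sym <- symmetrize_mask(solid_mask())
  lab <- random_partition(sym, "right", 8L, seed = 4)
  sizes <- table(lab$data[lab$data > 0])
  expect_equal(length(sizes), 8)
  expect_equal(sum(sizes), 8 * 16 * 16)   # hemisphere = half the 16^3 block
  expect_lte(max(sizes) / min(sizes), 2)
  # no labels outside the hemisphere mask
  xw <- lab$affine[1, 1] * (seq_len(16) - 1) + lab$affine[1, 4]
  expect_true(all(lab$data[xw < 0, , ] == 0))
  # each ROI is 6-connected
  for (r in 1:8) {
    vox <- which(lab$data == r)
    comp <- local({
      inset <- array(FALSE, dim(lab$data)); inset[vox] <- TRUE
      seen <- array(FALSE, dim(lab$data))
      queue <- vox[1]; seen[vox[1]] <- TRUE; cnt <- 0
      dims <- dim(lab$data)
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]; cnt <- cnt + 1
        nb <- hemiconn:::neighbors6(cur, dims)
        nb <- nb[inset[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      cnt
    })
    expect_equal(comp, length(vox))
  }
})

test_that("n_rois = voxel count yields singleton ROIs; undersized masks error", {
  arr <- array(FALSE, c(8, 4, 4))
  arr[6:7, 1:2, 1:2] <- TRUE
  m <- binary_mask(arr, make_affine(c(1, 1, 1), c(8L, 4L, 4L)))
  lab <- random_partition(m, "right", sum(arr), seed = 1)
  expect_true(all(table(lab$data[lab$data > 0]) == 1))
  expect_error(random_partition(m, "right", sum(arr) + 1L, seed = 1),
               "fewer than n_rois")
})

test_that("partition is deterministic in the seed", {
  sym <- symmetrize_mask(solid_mask(c(12L, 12L, 12L)))
  a <- random_partition(sym, "right", 6L, seed = 11)
  b <- random_partition(sym, "right", 6L, seed = 11)
  expect_identical(a$data, b$data)
  c <- random_partition(sym, "right", 6L, seed = 12)
  expect_false(identical(a$data, c$data))
})

test_that("fragmented hemisphere with more components than ROIs errors", {
  arr <- array(FALSE, c(10, 5, 5))
  arr[7, 1, 1] <- TRUE; arr[9, 3, 3] <- TRUE; arr[7, 5, 5] <- TRUE
  m <- binary_mask(arr, make_affine(c(1, 1, 1), c(10L, 5L, 5L)))
  expect_error(random_partition(m, "right", 2L, seed = 1),
               "components.*component sizes")
})

test_that("mirrored template has exact homologous correspondence", {
  sym <- symmetrize_mask(solid_mask())
  lab <- random_partition(sym, "right", 8L, seed = 5)
  bil <- mirror_parcellation(lab)
  expect_equal(nrow(bil$homologs), 8)
  expect_setequal(unique(as.vector(bil$data[bil$data > 0])), 1:16)
  # left labels are the exact x-flip of right labels under the homolog map
  flipped <- bil$data[16:1, , ]
  relabelled <- ifelse(flipped > 8, flipped - 8L,
                       ifelse(flipped > 0, flipped + 8L, 0L))
  expect_identical(array(as.integer(relabelled), dim(bil$data)), bil$data)
  # centroid mirror symmetry in world coordinates
  for (r in c(1L, 5L)) {
    cr <- colMeans(hemiconn:::world_from_voxel(
      bil$affine, which(bil$data == r, arr.ind = TRUE)))
    cl <- colMeans(hemiconn:::world_from_voxel(
      bil$affine, which(bil$data == r + 8L, arr.ind = TRUE)))
    expect_equal(cr[1], -cl[1], tolerance = 1e-10)
    expect_equal(cr[2:3], cl[2:3], tolerance = 1e-10)
  }
})

test_that("labels straddling the midplane are rejected when mirroring", {
  grid <- c(16L, 8L, 8L)
  arr <- array(0L, grid)
  arr[9:12, , ] <- 1L   # world x in [0.5, 3.5]: fine
  ok <- label_volume(arr, make_affine(c(1, 1, 1), grid), 1L, "right")
  expect_silent(mirror_parcellation(ok))
  arr[5, , ] <- 1L      # world x = -3.5: straddles
  bad <- label_volume(arr, make_affine(c(1, 1, 1), grid), 1L, "right")
  expect_error(mirror_parcellation(bad), "straddling.*1")
})
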