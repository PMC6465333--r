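disc_image <- function(ny, nx, centres, radius, value = 200) {
  img <- matrix(0, ny, nx)
  for (c in centres) {
    d2 <- (row(img) - c[1])^2 + (col(img) - c[2])^2
    img[d2 <= radius^2] <- value
  }
  img
}

test_that("focus projection picks the only informative plane", {
  arr <- array(0, dim = c(32, 32, 4))
  arr[, , 3] <- matrix(runif(32 * 32) * 100, 32)
  fp <- focus_projection(arr, window = 5L)
  expect_equal(fp$projection, arr[, , 3])
  expect_true(all(fp$zmap == 2L))
  expect_identical(fp$global_focus, 2L)
})

test_that("focus projection resolves laterally split sharpness", {
  set.seed(1)
  arr <- array(0, dim = c(24, 40, 2))
  arr[, 1:20, 1] <- matrix(runif(24 * 20) * 100, 24)   # sharp left, plane 0
  arr[, 21:40, 2] <- matrix(runif(24 * 20) * 100, 24)  # sharp right, plane 1
  fp <- focus_projection(arr, window = 5L)
  # away from the seam the chosen plane follows the texture
  expect_true(all(fp$zmap[, 1:15] == 0L))
  expect_true(all(fp$zmap[, 26:40] == 1L))
})

test_that("constant stacks project to a constant with the lowest-z tie-break", {
  arr <- array(7, dim = c(16, 16, 3))
  fp <- focus_projection(arr, window = 5L)
  expect_true(all(fp$projection == 7))
  expect_true(all(fp$zmap == 0L))
  expect_warning(focus_projection(array(1, dim = c(8, 8, 1))),
                 "single-plane")
})

test_that("nucleus segmentation counts discs correctly", {
  one <- disc_image(64, 64, list(c(32, 32)), 10)
  expect_equal(max(segment_nuclei(one)), 1L)
  two <- disc_image(96, 96, list(c(30, 30), c(64, 64)), 11)
  expect_equal(max(segment_nuclei(two)), 2L)
  # overlapping discs, centres 1.5 radii apart, split by the watershed
  r <- 12
  touching <- disc_image(72, 72, list(c(36, 28), c(36, 28 + 1.5 * r)), r)
  expect_equal(max(segment_nuclei(touching)), 2L)
  expect_error(segment_nuclei(matrix(5, 32, 32)), "no foreground")
})

test_that("seeded cell segmentation partitions the foreground between nuclei", {
  # one nucleus in one bright cell
  cell <- disc_image(64, 64, list(c(32, 32)), 20, value = 60)
  nuc <- matrix(0L, 64, 64); nuc[(row(nuc) - 32)^2 + (col(nuc) - 32)^2 <= 36] <- 1L
  cells <- segment_cells(cell, nuc)
  expect_setequal(setdiff(unique(as.vector(cells)), 0L), 1L)
  expect_true(all(cells[nuc == 1L] == 1L))

  # two nuclei inside one connected blob: partitioned, labels preserved
  blob <- disc_image(64, 100, list(c(32, 35), c(32, 65)), 22, value = 60)
  nuc2 <- matrix(0L, 64, 100)
  nuc2[(row(nuc2) - 32)^2 + (col(nuc2) - 35)^2 <= 25] <- 1L
  nuc2[(row(nuc2) - 32)^2 + (col(nuc2) - 65)^2 <= 25] <- 2L
  cells2 <- segment_cells(blob, nuc2)
  expect_setequal(setdiff(unique(as.vector(cells2)), 0L), c(1L, 2L))
  expect_true(all(cells2[nuc2 == 1L] == 1L))
  expect_true(all(cells2[nuc2 == 2L] == 2L))
  # no seed is ever merged away and each cell contains its nucleus
  expect_gt(sum(cells2 == 1L), sum(nuc2 == 1L))
  expect_gt(sum(cells2 == 2L), sum(nuc2 == 2L))
})

test_that("cell and nucleus counts are recovered on rendered scenes", {
  p <- scene_params(shape = c(z = 6L, y = 220L, x = 220L), n_cells = 4L,
                    cell_radius = 30, nucleus_radius = 11,
                    spots_per_cell = 25L, n_channels = 1L,
                    camera_noise_sd = 10, seed = 77L)
  sc <- simulate_scene(p)
  st <- render_stacks(sc, channels = c("dapi", "fish_a"))
  nuclei <- segment_nuclei(mean_projection(st$dapi), min_area = 40L)
  cells <- segment_cells(mean_projection(st$fish_a), nuclei)
  expect_equal(max(nuclei), 4L)
  expect_equal(length(setdiff(unique(as.vector(cells)), 0L)), 4L)
  expect_true(all(mask_jaccard(cells, sc$geometry$cells) >= 0.9))
})

test_that("load_geometry matches labels by overlap and is idempotent", {
  # nucleus disc inside larger cell disc -> annulus cytoplasm
  cellm <- matrix(0L, 48, 48); nucm <- matrix(0L, 48, 48)
  cellm[(row(cellm) - 24)^2 + (col(cellm) - 24)^2 <= 15^2] <- 3L
  nucm[(row(nucm) - 24)^2 + (col(nucm) - 24)^2 <= 6^2] <- 9L
  g <- load_geometry(cellm, nucm)
  expect_identical(g$report$label, 1L)
  expect_identical(g$report$orig_cell_label, 3L)
  expect_identical(g$report$orig_nucleus_label, 9L)
  expect_true(g$report$analysable)
  expect_equal(sum(cytoplasm_mask(g, 1L)),
               sum(cellm == 3L) - sum(nucm == 9L))
  # idempotence
  g2 <- load_geometry(g$cells, g$nuclei)
  expect_identical(g2$cells, g$cells)
  expect_identical(g2$nuclei, g$nuclei)

  # identical masks: empty cytoplasm flagged non-analysable
  gdeg <- load_geometry(cellm, cellm)
  expect_false(gdeg$report$analysable)
  expect_length(gdeg$labels, 0L)

  # two cells with nuclei labelled in swapped order are relabelled to match
  cells2 <- matrix(0L, 40, 80)
  cells2[10:30, 10:30] <- 1L; cells2[10:30, 50:70] <- 2L
  nucs2 <- matrix(0L, 40, 80)
  nucs2[18:24, 18:24] <- 2L; nucs2[18:24, 58:64] <- 1L
  gs <- load_geometry(cells2, nucs2)
  expect_equal(sort(gs$report$label), c(1L, 2L))
  for (l in gs$report$label)
    expect_true(all(gs$cells[gs$nuclei == l] == l))

  # a nucleus with no overlapping cell is rejected and reported
  orphan <- matrix(0L, 40, 80); orphan[2:6, 2:6] <- 5L
  gr <- load_geometry(cells2, orphan)
  expect_identical(attr(gr, "rejected")$label[1], 5L)
})
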