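test_that("a scene without spots still carries valid masks", {
  sc <- simulate_scene(small_scene_params(spots_per_cell = 0L, n_channels = 2L))
  expect_s3_class(sc$geometry, "cell_geometry")
  expect_length(sc$geometry$labels, 1L)
  expect_identical(n_spots(sc$spots$fish_a), 0L)
  expect_identical(n_spots(sc$spots$fish_b), 0L)
})

test_that("rho = 1 with zero jitter pairs every channel-b spot at distance 0", {
  p <- scene_params(shape = c(z = 6L, y = 96L, x = 96L), n_cells = 2L,
                    cell_radius = 16, nucleus_radius = 6,
                    spots_per_cell = 50L, rho = 1, jitter_sd_nm = 0,
                    seed = 7L)
  sc <- simulate_scene(p)
  a <- sc$spots$fish_a$spots
  b <- sc$spots$fish_b$spots
  expect_false(anyNA(b$partner))
  d <- sqrt((a$x_nm[b$partner] - b$x_nm)^2 +
            (a$y_nm[b$partner] - b$y_nm)^2 +
            (a$z_nm[b$partner] - b$z_nm)^2)
  expect_equal(max(d), 0)
  # every channel-a spot is used exactly once as a partner
  expect_setequal(b$partner, seq_len(nrow(a)))
})

test_that("the partnered count is exactly round(rho * n) and jitter is bounded", {
  p <- scene_params(shape = c(z = 6L, y = 96L, x = 96L), n_cells = 2L,
                    cell_radius = 16, nucleus_radius = 6,
                    spots_per_cell = 50L, rho = 0.4, jitter_sd_nm = 20,
                    seed = 11L)
  sc <- simulate_scene(p)
  b <- sc$spots$fish_b$spots
  expect_identical(sum(!is.na(b$partner)), 2L * 20L)  # 2 cells * round(.4*50)
  a <- sc$spots$fish_a$spots
  idx <- which(!is.na(b$partner))
  for (ax in c("x_nm", "y_nm", "z_nm"))
    expect_true(all(abs(a[[ax]][b$partner[idx]] - b[[ax]][idx]) <= 3 * 20 + 1e-9))
})

test_that("every simulated spot lies inside the cytoplasm of its cell", {
  sc <- simulate_scene(small_scene_params(n_channels = 2L, rho = 0.5,
                                          seed = 3L))
  for (ch in names(sc$spots)) {
    df <- sc$spots[[ch]]$spots
    iy <- floor(df$y_nm / sc$params$voxel_xy) + 1
    ix <- floor(df$x_nm / sc$params$voxel_xy) + 1
    cyto <- cytoplasm_mask(sc$geometry, 1L)
    expect_true(all(cyto[cbind(iy, ix)]), label = paste("channel", ch))
  }
})

test_that("scenes and stacks are bit-identical under the same seed", {
  p <- small_scene_params(n_channels = 2L, seed = 42L)
  s1 <- simulate_scene(p); s2 <- simulate_scene(p)
  expect_identical(s1$spots$fish_a$spots, s2$spots$fish_a$spots)
  expect_identical(s1$geometry$cells, s2$geometry$cells)
  r1 <- render_stacks(s1); r2 <- render_stacks(s2)
  for (ch in names(r1)) expect_identical(r1[[ch]]$data, r2[[ch]]$data)
})

test_that("impossible cell packings are rejected with a placement error", {
  expect_error(
    simulate_scene(scene_params(shape = c(z = 6L, y = 64L, x = 64L),
                                n_cells = 20L, cell_radius = 14,
                                nucleus_radius = 5, spots_per_cell = 0L)),
    "non-overlapping cells")
  expect_error(scene_params(cell_radius = 10, nucleus_radius = 9),
               "nucleus_radius")
  expect_error(scene_params(rho = 1.2))
})

test_that("rendered FISH channels follow the scene ground truth exactly when noise-free", {
  # no spots: zero outside cells, flat background inside
  sc0 <- simulate_scene(small_scene_params(spots_per_cell = 0L,
                                           camera_noise_sd = 0,
                                           fish_background = 8))
  st0 <- render_stacks(sc0, channels = "fish_a")$fish_a
  outside <- !array(rep(sc0$geometry$cells > 0, 6), dim = dim(st0$data))
  expect_true(all(st0$data[outside] == 0))
  expect_true(all(st0$data[!outside] == 8))

  # one spot at a voxel centre peaks at exactly its amplitude
  p <- small_scene_params(spots_per_cell = 1L, camera_noise_sd = 0,
                          fish_background = 0, spot_amplitude = 120,
                          seed = 5L)
  sc1 <- simulate_scene(p)
  # move the true spot onto an exact voxel centre
  ctr <- floor(c(sc1$spots$fish_a$spots$y_nm / 70,
                 sc1$spots$fish_a$spots$x_nm / 70,
                 sc1$spots$fish_a$spots$z_nm / 300)) + 0.5
  sc1$spots$fish_a$spots$y_nm <- ctr[1] * 70
  sc1$spots$fish_a$spots$x_nm <- ctr[2] * 70
  sc1$spots$fish_a$spots$z_nm <- ctr[3] * 300
  st1 <- render_stacks(sc1, channels = "fish_a")$fish_a
  expect_equal(max(st1$data), 120)
  expect_equal(which(st1$data == 120),
               (ctr[3] - 0.5) * 48 * 48 + (ctr[2] - 0.5) * 48 + ctr[1] + 0.5)
})

test_that("the noise-free IF channel reads r x background at every RNA position", {
  sc <- simulate_scene(small_scene_params(r = 2, if_noise_sd = 0, seed = 9L))
  st <- render_stacks(sc, channels = "if")[["if"]]
  df <- sc$spots$fish_a$spots
  at <- st$data[cbind(floor(df$y_nm / 70) + 1, floor(df$x_nm / 70) + 1,
                      floor(df$z_nm / 300) + 1)]
  expect_true(all(at == 2 * sc$params$if_background))
  # and the bulk cytoplasm stays at background
  cyto3d <- array(rep(cytoplasm_mask(sc$geometry, 1L), 6),
                  dim = dim(st$data))
  expect_equal(stats::median(st$data[cyto3d]), sc$params$if_background)
})

test_that("clipping is reported when amplitudes exceed the bit depth", {
  p <- small_scene_params(spots_per_cell = 5L, spot_amplitude = 400,
                          camera_noise_sd = 0, seed = 2L)
  sc <- simulate_scene(p)
  expect_warning(st <- render_stacks(sc, channels = "fish_a"),
                 "clipped")
  expect_gt(attr(st, "report")$clipped[["fish_a"]], 0)
  expect_true(all(st$fish_a$data <= 255))
})

test_that("ground truth written to disk round-trips through the readers", {
  sc <- simulate_scene(small_scene_params(n_channels = 2L, seed = 13L))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir)
  expect_identical(read_label_mask(paths[["cells"]]), sc$geometry$cells)
  expect_identical(read_label_mask(paths[["nuclei"]]), sc$geometry$nuclei)
  truth <- read_spots(paths[["spots"]], channel = "fish_a")
  expect_equal(truth$spots$x_nm, sc$spots$fish_a$spots$x_nm)
})
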