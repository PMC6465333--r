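test_that("identical clouds match themselves at zero cost", {
  set.seed(1)
  A <- random_cloud(12)
  m <- match_clouds(A, A, d_max = 300)
  expect_identical(nrow(m$pairs), 12L)
  expect_equal(m$total_cost, 0)
  expect_equal(m$pairs$a, m$pairs$b)
  expect_length(m$unmatched_a, 0L)
})

test_that("the global optimum beats the greedy pairing on the textbook case", {
  A <- cbind(x_nm = c(0, 4), y_nm = c(0, 0), z_nm = c(0, 0))
  B <- cbind(x_nm = c(1, -2), y_nm = c(0, 0), z_nm = c(0, 0))
  m <- match_clouds(A, B, d_max = 10)
  expect_equal(m$total_cost, 5)               # (A1-B2) + (A2-B1) = 2 + 3
  expect_identical(m$pairs$b[m$pairs$a == 1], 2L)
  expect_identical(m$pairs$b[m$pairs$a == 2], 1L)
  g <- match_clouds_greedy(A, B, d_max = 10)
  expect_equal(g$total_cost, 7)               # (A1-B1) + (A2-B2) = 1 + 6
  expect_lt(m$total_cost, g$total_cost)
})

test_that("matching agrees with exhaustive enumeration on random small clouds", {
  set.seed(42)
  for (i in 1:120) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    A <- random_cloud(na, extent = c(900, 900, 600))
    B <- random_cloud(nb, extent = c(900, 900, 600))
    d_max <- runif(1, 100, 700)
    m <- match_clouds(A, B, d_max)
    o <- oracle_gated_match(A, B, d_max)
    expect_equal(match_objective(m), o$objective, tolerance = 1e-8)
    expect_identical(nrow(m$pairs), o$n_pairs)
    expect_true(all(m$pairs$distance <= d_max))
    # greedy never does better
    g <- match_clouds_greedy(A, B, d_max)
    expect_lte(match_objective(m), match_objective(g) + 1e-8)
  }
})

test_that("the match bookkeeping is internally consistent and symmetric", {
  set.seed(5)
  A <- random_cloud(20); B <- random_cloud(15)
  m <- match_clouds(A, B, d_max = 400)
  expect_identical(nrow(m$pairs) + length(m$unmatched_a), 20L)
  expect_identical(nrow(m$pairs) + length(m$unmatched_b), 15L)
  expect_false(anyDuplicated(m$pairs$a) > 0)
  expect_false(anyDuplicated(m$pairs$b) > 0)
  swapped <- match_clouds(B, A, d_max = 400)
  expect_equal(swapped$total_cost, m$total_cost)
  expect_identical(nrow(swapped$pairs), nrow(m$pairs))
})

test_that("the co-localized fraction follows its definition and the gate", {
  set.seed(9)
  A <- random_cloud(10)
  m_all <- match_clouds(A, A, d_max = 100)
  expect_equal(coloc_fraction(m_all, "a"), 1.0)

  B <- A + 5000                                # far away: nothing matches
  m_none <- match_clouds(A, B, d_max = 100)
  expect_equal(nrow(m_none$pairs), 0L)

  # 4 of 10 reference spots displaced within the gate, rest far away
  B2 <- A + 5000
  B2[1:4, ] <- A[1:4, ] + matrix(c(30, 20, 10), 4, 3, byrow = TRUE)
  m4 <- match_clouds(A, B2, d_max = 150)
  expect_equal(coloc_fraction(m4, "a"), 0.4)

  # monotone in d_max
  C <- random_cloud(25); Dc <- random_cloud(25)
  fr <- vapply(c(50, 150, 300, 600, 1200),
               function(d) coloc_fraction(match_clouds(C, Dc, d), "a"),
               numeric(1))
  expect_true(all(diff(fr) >= 0))

  empty <- match_clouds(matrix(numeric(0), 0, 3,
                               dimnames = list(NULL, c("x_nm", "y_nm", "z_nm"))),
                        Dc, 300)
  expect_identical(nrow(empty$pairs), 0L)
  expect_error(coloc_fraction(empty, "a"), "empty")
})

test_that("simulated scenes recover the co-localized fraction", {
  # two rho values here; the full grid runs in the acceptance suite
  for (rho in c(0.2, 0.9)) {
    fr <- vapply(1:8, function(k) {
      sc <- simulate_scene(scene_params(
        shape = c(z = 10L, y = 110L, x = 110L), n_cells = 1L,
        cell_radius = 30, nucleus_radius = 10, spots_per_cell = 20L,
        rho = rho, jitter_sd_nm = 20, seed = 700 + k + round(100 * rho)))
      coloc_fraction(match_clouds(sc$spots$fish_a, sc$spots$fish_b, 150), "b")
    }, numeric(1))
    expect_lt(abs(mean(fr) - rho), 0.05)
  }
})

test_that("the randomization null separates real from absent co-localization", {
  build <- function(rho, seed) simulate_scene(scene_params(
    shape = c(z = 10L, y = 110L, x = 110L), n_cells = 1L, cell_radius = 30,
    nucleus_radius = 10, spots_per_cell = 20L, rho = rho,
    jitter_sd_nm = 20, seed = seed))
  sc1 <- build(0.5, 81L)
  n1 <- randomization_null(sc1$spots$fish_a, sc1$spots$fish_b, sc1$geometry,
                           1L, d_max = 150, n_perm = 199L, seed = 4L)
  expect_lte(n1$p.value, 0.01)

  sc0 <- build(0, 82L)
  n0 <- randomization_null(sc0$spots$fish_a, sc0$spots$fish_b, sc0$geometry,
                           1L, d_max = 150, n_perm = 199L, seed = 4L)
  expect_gt(n0$p.value, 0.05)
  # observed fraction sits inside the central mass of its own null
  expect_gte(n0$observed, stats::quantile(n0$null, 0.025) - 1e-9)
  expect_lte(n0$observed, stats::quantile(n0$null, 0.975) + 1e-9)

  # zero observed co-localization can never look significant
  far_b <- spot_set(data.frame(x_nm = 1e6 + runif(5) * 100,
                               y_nm = 1e6 + runif(5) * 100,
                               z_nm = runif(5) * 100, intensity = 1))
  nz <- randomization_null(sc0$spots$fish_a, far_b, sc0$geometry, 1L,
                           d_max = 150, n_perm = 199L, seed = 4L)
  expect_equal(nz$p.value, 1)
})
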