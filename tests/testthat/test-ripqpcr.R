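test_that("percent_input reproduces the published formula exactly", {
  expect_equal(percent_input(26.644, 20.000), 100)
  expect_equal(percent_input(20, 20), 100 * 2^-6.644)
  # the printed constant 6.644 slightly overshoots log2(100) = 6.6439, so
  # equal input and IP Cp read out just under 1% input
  expect_equal(percent_input(20, 20), 0.99990, tolerance = 1e-5)
  expect_equal(percent_input(18.000, 14.356), 12.5)
  expect_true(is.na(percent_input(NA, 20)))
})

test_that("percent_input responds to Cp shifts like template doublings", {
  base <- percent_input(25, 20)
  expect_equal(percent_input(25, 19), 2 * base)   # brighter IP doubles
  expect_equal(percent_input(25, 21), base / 2)
  expect_equal(percent_input(26, 20), 2 * base)   # more input doubles too
  # strict monotonicity
  expect_true(all(diff(percent_input(25, seq(24, 16))) > 0))
  expect_true(all(diff(percent_input(seq(20, 28), 20)) > 0))
})

test_that("fold enrichment handles single- and double-delta forms", {
  expect_equal(as.numeric(fold_enrichment(22, 22)), 1.0)
  expect_true(attr(fold_enrichment(22, 22), "single_delta"))
  expect_equal(as.numeric(fold_enrichment(25, 28)), 8.0)
  fe <- fold_enrichment(22, 25, 20, 21)
  expect_equal(as.numeric(fe), 4.0)
  expect_false(attr(fe, "single_delta"))
  expect_error(fold_enrichment(22, 25, cp_input_ip = 20), "both")
})

test_that("relative statistics follow their ratio definitions", {
  expect_equal(relative_fold_enrichment(8, 2), 4.0)
  expect_equal(relative_fold_enrichment(3, 3), 1.0)
  expect_error(relative_fold_enrichment(8, 0), "> 0")

  expect_equal(relative_expression(20, 20, 20, 20), 1.0)
  expect_equal(relative_expression(25, 20, 23, 20), 0.25)  # dCp 5 vs 3
})

test_that("a simulated 50% knockdown reads out as 0.5", {
  mk <- function(ab) simulate_cp_table(cp_sim_params(
    abundances = c(target = ab, ref = 1), cp_noise_sd = 0,
    bio_reps = 1L, tech_reps = 1L, include_minus_rt = FALSE, seed = 2L))
  t1 <- mk(0.5); t2 <- mk(1.0)
  cp <- function(tab, g) tab$cp[tab$gene == g & tab$role == "input"]
  expect_equal(relative_expression(cp(t1, "target"), cp(t1, "ref"),
                                   cp(t2, "target"), cp(t2, "ref")), 0.5)
})

test_that("relative fold enrichment recovers the simulated efficiency ratio", {
  p <- cp_sim_params(abundances = c(taf8 = 1, taf10 = 4),
                     efficiency_ip = c(taf8 = 0.2, taf10 = 0.05),
                     efficiency_mock = 0.002, cp_noise_sd = 0,
                     bio_reps = 2L, tech_reps = 2L, seed = 3L)
  agg <- aggregate_replicates(simulate_cp_table(p),
                              "relative_fold_enrichment",
                              genes = "taf8", reference_gene = "taf10")
  expect_equal(agg$summary$value, 0.2 / 0.05)
})

test_that("-RT QC applies the 10-cycle rule", {
  tab <- as_cp_table(data.frame(
    gene = rep(c("g1", "g2", "g3"), each = 2),
    role = "ip",
    rt = rep(c("plus", "minus"), 3),
    bio_rep = 1L, tech_rep = 1L,
    cp = c(20, 35, 20, 27, 20, NA)))
  qc <- rt_minus_qc(tab)
  expect_identical(qc$pass[qc$gene == "g1"], TRUE)    # gap 15
  expect_identical(qc$pass[qc$gene == "g2"], FALSE)   # gap 7
  expect_identical(qc$pass[qc$gene == "g3"], TRUE)    # never amplified
  expect_warning(rt_minus_qc(tab[tab$rt == "plus", ]), "QC skipped")
})

test_that("failing -RT combinations are excluded from aggregation", {
  tab <- as_cp_table(data.frame(
    gene = "g1",
    role = rep(c("input", "ip"), each = 2),
    rt = rep(c("plus", "minus"), 2),
    bio_rep = 1L, tech_rep = 1L,
    cp = c(24, 40, 20, 22)))       # ip fails the -RT gap
  agg <- aggregate_replicates(tab, "percent_input")
  expect_identical(agg$summary$flag, "missing role")
  agg2 <- aggregate_replicates(tab, "percent_input", apply_qc = FALSE)
  expect_false(is.na(agg2$summary$value))
})

test_that("replicate aggregation is tech-then-bio and row-order invariant", {
  tab <- as_cp_table(data.frame(
    gene = "g",
    role = rep(c("input", "ip"), each = 4),
    rt = "plus",
    bio_rep = rep(c(1L, 1L, 2L, 2L), 2),
    tech_rep = rep(c(1L, 2L), 4),
    cp = c(25.0, 25.2, 25.1, 24.9, 20.0, 20.2, 21.1, 20.9)))
  agg <- aggregate_replicates(tab, "percent_input", apply_qc = FALSE)
  by_hand <- c(percent_input(25.1, 20.1), percent_input(25.0, 21.0))
  expect_equal(agg$replicates$value, by_hand)
  expect_equal(agg$summary$value, mean(by_hand))
  expect_equal(agg$summary$sd, stats::sd(by_hand))

  shuffled <- tab[c(5, 2, 8, 1, 6, 3, 7, 4), ]
  agg2 <- aggregate_replicates(as_cp_table(shuffled), "percent_input",
                               apply_qc = FALSE)
  expect_equal(agg2$summary, agg$summary)

  # single biological replicate: SD reported as missing
  single <- as_cp_table(tab[tab$bio_rep == 1L, ])
  agg3 <- aggregate_replicates(single, "percent_input", apply_qc = FALSE)
  expect_true(is.na(agg3$summary$sd))
  expect_identical(agg3$summary$n_bio, 1L)

  # identical replicates: SD exactly zero
  dup <- tab; dup$cp <- rep(c(25, 20), each = 4)
  agg4 <- aggregate_replicates(as_cp_table(dup), "percent_input",
                               apply_qc = FALSE)
  expect_equal(agg4$summary$sd, 0)
})

test_that("cp tables validate their schema and round-trip through CSV", {
  expect_error(as_cp_table(data.frame(gene = "g")), "columns")
  bad_role <- data.frame(gene = "g", role = "pulldown", rt = "plus",
                         bio_rep = 1, tech_rep = 1, cp = 20)
  expect_error(as_cp_table(bad_role), "role")
  dup <- data.frame(gene = "g", role = "ip", rt = "plus",
                    bio_rep = 1, tech_rep = 1, cp = c(20, 21))
  expect_error(as_cp_table(dup), "duplicate")

  tab <- simulate_cp_table(cp_sim_params(seed = 6L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cp_table(tab, f)
  back <- read_cp_table(f)
  expect_equal(back$cp, tab$cp)
  expect_identical(back$gene, tab$gene)
})
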