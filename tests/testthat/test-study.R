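# sweep bookkeeping, summaries, and the exact Wilcoxon signed-rank test

test_that("exact Wilcoxon matches hand-computable all-positive cases", {
  # n = 7, all differences positive: W = 28, two-sided p = 2/2^7
  p7 <- wilcoxon_signed_rank(c(2, 3, 5, 4, 6, 8, 7), rep(1, 7))
  expect_equal(p7$p_value, 0.015625)
  expect_identical(sprintf("%.3f", p7$p_value), "0.016")
  # n = 5 all positive: 2/2^5
  expect_equal(wilcoxon_signed_rank(1:5, rep(0, 5))$p_value, 0.0625)
})

test_that("identical samples give p = 1 with a warning", {
  x <- c(1, 2, 3)
  expect_warning(res <- wilcoxon_signed_rank(x, x), "zero")
  expect_equal(res$p_value, 1)
})

test_that("exact distribution agrees with brute-force enumeration", {
  set.seed(7)
  for (n in c(3, 5, 8, 10)) {
    for (rep in 1:3) {
      x <- sample(-6:9, n, replace = TRUE)
      y <- sample(-3:6, n, replace = TRUE)
      expect_equal(wilcoxon_signed_rank(x, y)$p_value,
                   wilcoxon_brute_force(x, y),
                   tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("exact path agrees with stats::wilcox.test when tie-free", {
  set.seed(21)
  for (n in c(6, 9, 12)) {
    # distinct magnitudes so no midranks arise
    d <- sample(1:20, n) * sample(c(-1, 1), n, replace = TRUE)
    ours <- wilcoxon_signed_rank(d)$p_value
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("normal approximation is close to the exact tail for larger n", {
  set.seed(5)
  d <- stats::rnorm(30, mean = 0.4)
  approx <- wilcoxon_signed_rank(d)$p_value          # n = 30 -> approx
  exact <- wilcoxon_signed_rank(d, exact_max = 40)$p_value
  expect_equal(approx, exact, tolerance = 0.15 * max(exact, 1e-4))
})

test_that("summaries follow the sample conventions", {
  recs <- tibble::tibble(
    case_id = c("a", "b"), loc_id = c("a", "b"), band = "custom",
    x = 0, y = 0, z = 0, k = 15,
    surface_kpa = c(6, 8), lesion_kpa = c(10, 12), rmpa = c(1.1, 1.2),
    plate_force_n = c(20, 22), n_covered = 10L,
    lesion_tile_i = 1L, lesion_tile_j = 1L, disc_coverage = 1,
    error = NA_character_)
  s <- summarize_sweep(recs)
  expect_equal(s$surface_mean, 7)
  expect_equal(s$surface_sd, sqrt(2))   # (n - 1) convention
  expect_equal(s$lesion_min, 10)
  expect_equal(s$lesion_max, 12)
  # single record: degenerate range, sd 0
  s1 <- summarize_sweep(recs[1, ])
  expect_equal(s1$surface_sd, 0)
  expect_equal(s1$surface_min, s1$surface_max)
})

test_that("formatted table prints mean±sd and 3-decimal p-values", {
  res <- cupA_sweep()
  tab <- format_stress_table(summarize_sweep(res))
  expect_identical(names(tab),
                   c("lesion_stiffness", "surface_kpa", "lesion_kpa",
                     "p_value"))
  expect_match(tab$surface_kpa[1], "^\\d+\\.\\d{2}±\\d+\\.\\d{2}$")
  expect_match(tab$p_value[1], "^0\\.\\d{3}$")
})

test_that("sweep over a single location and stiffness yields one record", {
  cfg <- sweep_config("A", voxel_mm = 6, k = 30,
                      locations = data.frame(x = 0, y = 37.5, z = 15),
                      n_increments = 3)
  res <- run_sweep(cfg)
  expect_identical(nrow(res$records), 1L)
  expect_true(is.na(res$records$error))
  expect_gt(res$records$lesion_kpa, 0)
})

test_that("sweep results are deterministic and summary-consistent", {
  res <- cupA_sweep()
  expect_identical(nrow(res$records), 21L)
  expect_identical(anyDuplicated(res$records$case_id), 0L)
  s <- summarize_sweep(res)
  # summary is recomputable from records
  k15 <- res$records[res$records$k == 15, ]
  expect_equal(s$surface_mean[s$k == 15], mean(k15$surface_kpa))
  expect_equal(s$lesion_sd[s$k == 15], stats::sd(k15$lesion_kpa))
  # identical config twice -> bit-identical records
  cfg <- sweep_config("A", voxel_mm = 4, k = 30,
                      locations = data.frame(x = 0, y = 30, z = 15),
                      n_increments = 5)
  again <- run_sweep(cfg)$records
  expect_identical(run_sweep(cfg)$records$surface_kpa, again$surface_kpa)
  # a cold stand-alone solve agrees with the warm-started sweep record
  # (path independence of the linear contact solution)
  cs <- res$records[res$records$case_id == "A_deep_x+000_y030_z15_k30", ]
  expect_equal(again$surface_kpa, cs$surface_kpa, tolerance = 1e-9)
  expect_equal(again$lesion_kpa, cs$lesion_kpa, tolerance = 1e-9)
  expect_equal(again$rmpa, cs$rmpa, tolerance = 1e-9)
})

test_that("sweeps persist and resume from the records file", {
  dir <- withr::local_tempdir()
  cfg <- sweep_config("A", voxel_mm = 6, k = c(15, 30),
                      locations = data.frame(x = c(-10, 10), y = 37.5,
                                             z = 15),
                      n_increments = 3, out_dir = dir)
  res1 <- run_sweep(cfg)
  expect_true(file.exists(file.path(dir, "records.csv")))
  expect_identical(nrow(res1$records), 4L)
  # resuming re-reads rather than recomputing
  res2 <- run_sweep(cfg)
  expect_equal(as.data.frame(res2$records[, c("case_id", "surface_kpa")]),
               as.data.frame(res1$records[, c("case_id", "surface_kpa")]))
})

test_that("location profiles are ordered and carry all stiffness levels", {
  res <- cupA_sweep()
  prof <- stress_vs_location_profiles(res)
  expect_identical(nrow(prof), 21L)
  sh <- prof[prof$band == "shallow" & prof$k == 50, ]
  expect_identical(sh$x, sort(sh$x))
  # lesion stress does not decrease with k at any fixed location for >= 90%
  # of locations
  recs <- res$records
  ok <- sapply(unique(recs$loc_id), function(l) {
    v <- recs[recs$loc_id == l, ]
    all(diff(v$lesion_kpa[order(v$k)]) > -1e-9)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("surface stress varies little across lesion locations", {
  res <- cupA_sweep()
  s <- summarize_sweep(res)
  expect_true(all(s$surface_sd / s$surface_mean < 0.02))
})
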