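test_that("the default study design has the documented layout", {
  sim <- simulate_study(seed = 5)
  expect_s3_class(sim, "degor_sim")
  expect_equal(nrow(sim), 1000)
  expect_equal(ncol(sim), 4 + 60)  # gene, de, delta, mu + 30 + 30 expressions
  expect_equal(sum(sim$de), 100)
  expect_equal(unname(table(sim$delta[sim$de == 1])), c(34L, 33L, 33L),
               ignore_attr = TRUE)  # even split, remainder to the smallest
  expect_equal(sort(unique(sim$delta)), c(0, 1.5, 2, 3))
  expect_equal(abs(sim$mu), sim$delta)
  expect_identical(sim, simulate_study(seed = 5))
  expect_false(identical(sim$delta, simulate_study(seed = 6)$delta))
})

test_that("explicit per-delta counts and degenerate designs are honoured", {
  sim <- simulate_study(seed = 1, delta_counts = c(33, 32, 35))
  expect_equal(unname(table(sim$delta[sim$de == 1])), c(33L, 32L, 35L),
               ignore_attr = TRUE)
  expect_error(simulate_study(delta_counts = c(1, 1, 1)), "sum to n_de")
  expect_error(simulate_study(n_genes = 10, n_de = 11), "between 0 and n_genes")
  expect_error(simulate_study(s1 = 2), "at least 3 samples")

  none <- simulate_study(n_genes = 40, n_de = 0, s1 = 5, s2 = 5, seed = 2)
  expect_equal(sum(none$de), 0)
  expect_true(all(none$delta == 0))
})

test_that("DE genes shift condition 2 by mu within normal-theory error", {
  sim <- simulate_study(seed = 7)
  mats <- study_matrices(sim)
  idx <- which(sim$delta == 3)
  diffs <- rowMeans(mats$cond2[idx, ]) - rowMeans(mats$cond1[idx, ])
  expect_true(all(abs(diffs - sim$mu[idx]) < 3 * sqrt(2 / 30)))
  null_idx <- which(sim$de == 0)
  null_diffs <- rowMeans(mats$cond2[null_idx, ]) - rowMeans(mats$cond1[null_idx, ])
  expect_lt(mean(abs(null_diffs)), 3 * sqrt(2 / 30))
})

test_that("the flat study file round-trips through write and read", {
  sim <- simulate_study(n_genes = 25, n_de = 6, s1 = 5, s2 = 7, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_study(sim, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_length(header, 1 + 2 + 5 + 7)  # label + flag + delta + expressions
  back <- read_study(path, s1 = 5)
  expect_equal(back$de, sim$de)
  expect_equal(back$delta, sim$delta)
  expect_equal(study_matrices(back), study_matrices(sim))
})

test_that("detection accounting matches hand-computed confusion counts", {
  sim <- simulate_study(n_genes = 30, n_de = 4, s1 = 5, s2 = 5, seed = 9)
  de_genes <- sim$gene[sim$de == 1]
  fake <- structure(list(genes = tibble::tibble(
    gene = c(de_genes[1:2], setdiff(sim$gene, de_genes)[1]),
    or = c(9, 8, 3), fp = c(0, 1, 4), dfp = c(0, 0.5, 7),
    strong = c(TRUE, FALSE, FALSE), relaxed = c(TRUE, TRUE, FALSE),
    cluster = c(1L, 1L, 2L)
  )), class = "degor_fit")
  det <- detection_table(sim, fake, "relaxed")
  expect_equal(det$totals$tp, 2)
  expect_equal(det$totals$fp, 0)
  expect_equal(det$totals$fn, 2)
  det_s <- detection_table(sim, fake, "strong")
  expect_equal(det_s$totals$tp, 1)
  expect_equal(det_s$totals$fn, 3)

  none <- structure(list(genes = fake$genes[0, ]), class = "degor_fit")
  det0 <- detection_table(sim, none)
  expect_equal(unlist(det0$totals[, 1:3]), c(tp = 0, fp = 0, fn = 4))

  bad <- structure(list(genes = tibble::tibble(
    gene = "nope", or = 1, fp = 0, dfp = 0,
    strong = FALSE, relaxed = FALSE, cluster = 1L
  )), class = "degor_fit")
  expect_error(detection_table(sim, bad), "labels do not match")
})

test_that("detection rate does not decrease with effect size", {
  # average over repetitions of a scaled-down study: misses concentrate at
  # the smallest shift
  set.seed(81)
  rates <- matrix(0, 12, 3)
  for (r in 1:12) {
    sim <- simulate_study(n_genes = 150, n_de = 15, s1 = 10, s2 = 10, seed = 100 + r)
    fit <- suppressWarnings(find_degs(sim, B = 25, seed = 100 + r))
    hits <- sim$gene[sim$de == 1] %in% fit$genes$gene[fit$genes$relaxed]
    rates[r, ] <- vapply(c(1.5, 2, 3), function(d) {
      mean(hits[sim$delta[sim$de == 1] == d])
    }, 0)
  }
  avg <- colMeans(rates)
  expect_lte(avg[1], avg[2] + 0.1)
  expect_lte(avg[2], avg[3] + 0.1)
  expect_gte(avg[3], 0.75)
})
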