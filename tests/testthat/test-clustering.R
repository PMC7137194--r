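test_that("strong and relaxed selection rules use the stated boundaries", {
  flags <- strong_relaxed_flags(c(0, 0.5, 2, 3), expected = 2)
  expect_equal(flags$strong, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flags$relaxed, c(TRUE, TRUE, FALSE, FALSE))  # strict at 2
  expect_error(strong_relaxed_flags(numeric(0), 1), "no scores")

  set.seed(71)
  for (i in 1:50) {
    fp <- round(runif(20, 0, 10), 1)
    fl <- strong_relaxed_flags(fp, runif(1, 0, 10))
    expect_true(all(fl$relaxed[fl$strong]))  # strong subset of relaxed
  }
})

test_that("PAM recovers separated blobs and attains the exhaustive optimum", {
  blob1 <- matrix(rep(c(0, 0, 0), each = 3), 3) + 0.01 * (1:3)
  blob2 <- matrix(rep(c(10, 10, 10), each = 3), 3) + 0.01 * (1:3)
  pts <- rbind(blob1, blob2)
  fit <- pam_cluster(pts, 2)
  expect_equal(fit$assignment[1:3], rep(fit$assignment[1], 3))
  expect_equal(fit$assignment[4:6], rep(fit$assignment[4], 3))
  expect_false(fit$assignment[1] == fit$assignment[4])
  expect_equal(fit$cost, oracle_pam_best_cost(pts, 2))

  expect_error(pam_cluster(rand_points(4, 2), 4), "k must satisfy")
})

test_that("PAM terminates at a swap-local optimum no worse than BUILD", {
  set.seed(72)
  for (i in 1:30) {
    m <- sample(5:8, 1)
    k <- sample(2:3, 1)
    x <- rand_points(m, 2)
    got <- pam_cluster(x, k)
    expect_gte(got$cost, oracle_pam_best_cost(x, k) - 1e-12)
    expect_lte(got$cost, got$build_cost + 1e-12)
    # no single medoid <-> non-medoid exchange lowers the cost
    dm <- as.matrix(dist(x))
    cost_of <- function(med) sum(apply(dm[, med, drop = FALSE], 1, min))
    for (out in got$medoids) {
      for (inn in setdiff(seq_len(m), got$medoids)) {
        expect_gte(cost_of(c(setdiff(got$medoids, out), inn)), got$cost - 1e-9)
      }
    }
  }
})

test_that("PAM edge cases: k = m - 1 and duplicated point sets", {
  set.seed(73)
  x <- rand_points(5, 2)
  fit <- pam_cluster(x, 4)
  dm <- as.matrix(dist(x))
  non_medoid <- setdiff(1:5, fit$medoids)
  expect_equal(fit$cost, min(dm[non_medoid, fit$medoids]))

  y <- rand_points(4, 2, sd = 3)
  single <- pam_cluster(y, 2)
  doubled <- pam_cluster(rbind(y, y), 2)
  expect_equal(doubled$cost, 2 * single$cost, tolerance = 1e-12)
})

test_that("mean silhouette matches the direct-formula oracle", {
  set.seed(74)
  for (i in 1:50) {
    x <- rand_points(sample(6:12, 1), 2)
    assignment <- sample(1:3, nrow(x), replace = TRUE)
    if (length(unique(assignment)) < 2) next
    expect_equal(mean_silhouette(x, assignment), oracle_silhouette(x, assignment),
                 tolerance = 1e-12)
  }
  expect_error(mean_silhouette(rand_points(5, 2), rep(1, 5)), "two clusters")
})

test_that("silhouette limits: perfect separation near 1, symmetry at 0", {
  tight <- rbind(rand_points(5, 2, sd = 0.01),
                 rand_points(5, 2, sd = 0.01) + 100)
  expect_gt(mean_silhouette(tight, rep(1:2, each = 5)), 0.99)

  # regular tetrahedron: all pairwise distances equal, any 2+2 split gives 0
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(mean_silhouette(tet, c(1, 1, 2, 2)), 0)
})

test_that("silhouette-based k selection finds planted structure", {
  set.seed(75)
  blobs <- rbind(rand_points(10, 3, sd = 0.1),
                 rand_points(10, 3, sd = 0.1) + 8,
                 rand_points(10, 3, sd = 0.1) - 8)
  expect_equal(choose_k(blobs, numclustoseek = 6)$k, 3)
  expect_equal(choose_k(blobs, numclustoseek = 2)$k, 2)
  expect_error(choose_k(blobs[1:3, ], 5), "too few")
})

test_that("cluster numbering follows decreasing mean OR and summaries partition", {
  set.seed(76)
  scores <- tibble::tibble(
    gene = paste0("g", 1:30),
    or = c(rnorm(10, 50, 1), rnorm(10, 10, 1), rnorm(10, 2, 0.1)),
    fp = c(rep(0, 10), rep(2, 10), rep(8, 10)) + runif(30, 0, 0.1),
    dfp = c(rep(0, 10), rep(1, 10), rep(30, 10)) + runif(30, 0, 0.1)
  )
  cl <- cluster_scores(scores, k = 3)
  scores$cluster <- cl$cluster
  summ <- summarize_clusters(scores)
  expect_equal(summ$cluster, 1:3)
  expect_equal(sum(summ$n_genes), 30)
  expect_false(is.unsorted(rev(summ$or_mean)))  # decreasing mean OR
  expect_equal(scores$cluster[1], 1L)           # highest-OR gene in cluster 1

  # invariance to input order
  perm <- sample(30)
  cl2 <- cluster_scores(scores[perm, c("gene", "or", "fp", "dfp")], k = 3)
  expect_equal(cl2$cluster, cl$cluster[perm])

  # identical index vectors within groups: zero dispersion per cluster
  dup <- tibble::tibble(gene = paste0("d", 1:8),
                        or = rep(c(5, 1), each = 4),
                        fp = rep(c(0, 4), each = 4),
                        dfp = rep(c(0, 9), each = 4))
  cld <- cluster_scores(dup, k = 2)
  dup$cluster <- cld$cluster
  sd_cols <- summarize_clusters(dup)[, c("or_sd", "fp_sd", "dfp_sd")]
  expect_true(all(as.matrix(sd_cols) == 0))
})
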