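make_meta <- function(subjects, timepoints) {
  meta <- expand.grid(subject_id = subjects, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$subject_id, meta$timepoint, sep = "_")
  meta
}

test_that("delta-CLR subtracts each subject's day-0 row", {
  meta <- make_meta(c("A", "B"), c("d0", "h0"))
  clr <- rbind(c(1, -1, 0), c(2, 0, -2), c(1.5, -0.5, -1), c(2.5, 0.5, -3))
  rownames(clr) <- meta$sample_id
  dl <- delta_clr(clr, meta, baseline = "d0")
  expect_equal(unname(dl["A_d0", ]), c(0, 0, 0))
  expect_equal(unname(dl["B_d0", ]), c(0, 0, 0))
  expect_equal(unname(dl["A_h0", ]), c(0.5, 0.5, -1))
  expect_equal(unname(dl["B_h0", ]), c(0.5, 0.5, -1))
  # adding a constant vector to one subject's samples cancels in the delta
  clr2 <- clr; clr2[meta$subject_id == "A", ] <- clr2[meta$subject_id == "A", ] + 5
  expect_equal(delta_clr(clr2, meta), dl)
  expect_error(delta_clr(clr, meta, baseline = "d99"), "absent")
  # subject without baseline is dropped with a warning
  keep <- meta$sample_id != "A_d0"
  expect_warning(dl2 <- delta_clr(clr[keep, ], meta[keep, ]), "A")
  expect_equal(rownames(dl2), c("B_d0", "B_h0"))
})

test_that("feature dissimilarities match hand-computed rank correlations", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10), c = c(5, 4, 3, 2, 1),
             d = c(1, 3, 2, 5, 4))
  d <- as.matrix(feature_dissimilarity(x, "spearman"))
  expect_equal(d["a", "b"], 0)                     # perfectly correlated
  expect_equal(d["a", "c"], 2)                     # perfectly anticorrelated
  # brute-force oracle: 1 - Pearson correlation of the rank vectors
  rho_ad <- cor(rank(x[, "a"]), rank(x[, "d"]))
  expect_equal(d["a", "d"], 1 - rho_ad, tolerance = 1e-12)
  expect_true(all(abs(diag(d)) < 1e-12))
  expect_error(feature_dissimilarity(cbind(x, e = rep(1, 5)), "spearman"), "e")
  de <- as.matrix(feature_dissimilarity(x, "aitchison_euclidean"))
  expect_equal(dim(de), c(5L, 5L))                  # euclidean kind clusters rows
  expect_equal(de[1, 2], sqrt(sum((x[1, ] - x[2, ])^2)), tolerance = 1e-12)
})

test_that("k-medoids cost matches exhaustive medoid search on n = 8", {
  set.seed(1)
  x <- matrix(rnorm(16), 8, 2)
  dm <- as.matrix(dist(x))
  for (k in 2:3) {
    sol <- cluster_kmedoids(dm, k, seed = 1)
    best <- min(apply(combn(8, k), 2, function(med)
      sum(apply(dm[, med, drop = FALSE], 1, min))))
    expect_equal(sol$cost, best, tolerance = 1e-12)
  }
})

test_that("k-medoids agrees with cluster::pam and handles edge cases", {
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2)
  dm <- dist(x)
  sol <- cluster_kmedoids(dm, 3, seed = 1)
  ref <- cluster::pam(dm, 3)
  # both reach the same (locally optimal) objective on this easy geometry
  expect_equal(sol$cost, unname(ref$objective["swap"]) * 20, tolerance = 1e-8)
  expect_equal(rand_index(sol$clustering, ref$clustering), 1)
  all_own <- cluster_kmedoids(dm, 20)
  expect_equal(all_own$cost, 0)
  expect_equal(length(unique(all_own$clustering)), 20L)
  expect_error(cluster_kmedoids(dm, 21), "k must be")
  # two well-separated pairs are grouped as pairs
  y <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  s2 <- cluster_kmedoids(dist(y), 2, seed = 1)
  expect_equal(unname(s2$clustering[1]), unname(s2$clustering[2]))
  expect_equal(unname(s2$clustering[3]), unname(s2$clustering[4]))
  expect_false(s2$clustering[[1]] == s2$clustering[[3]])
})

test_that("gap statistic is reproducible and monotone in within-dispersion", {
  set.seed(3)
  x <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
             matrix(rnorm(20, 4, 0.3), 10, 2))
  g1 <- gap_statistic(x, "aitchison_euclidean", k_max = 4, B = 20, seed = 5)
  g2 <- gap_statistic(x, "aitchison_euclidean", k_max = 4, B = 20, seed = 5)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$chosen_k, g2$chosen_k)
  expect_true(all(diff(g1$table$logW) <= 1e-9))
  expect_equal(g1$chosen_k, 2L)
})

test_that("gap statistic finds planted blob structure at a fixed seed", {
  set.seed(4)
  blobs <- do.call(rbind, lapply(c(0, 5, 10), function(c0)
    matrix(rnorm(20, c0, 0.1), 10, 2)))
  g <- gap_statistic(blobs, "aitchison_euclidean", k_max = 6, B = 30, seed = 1)
  expect_equal(g$chosen_k, 3L)
  single <- matrix(runif(60), 30, 2)
  g1 <- gap_statistic(single, "aitchison_euclidean", k_max = 5, B = 30, seed = 1)
  expect_equal(g1$chosen_k, 1L)
  ident <- matrix(1, 6, 3)
  expect_warning(gi <- gap_statistic(ident, "aitchison_euclidean", k_max = 3, B = 10),
                 "identical")
  expect_equal(gi$chosen_k, 1L)
})

test_that("cluster occupancy fractions sum to one per arm x timepoint", {
  meta <- make_meta(c("A", "B", "C", "D"), c("d0", "h0"))
  meta$treatment <- rep(c("CON", "CON", "SCFP", "SCFP"), 2)
  cl <- structure(list(clustering = setNames(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L),
                                             meta$sample_id)),
                  class = "cluster_solution")
  occ <- cluster_occupancy(cl, meta)
  sums <- tapply(occ$fraction, paste(occ$treatment, occ$timepoint), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  con_d0 <- occ[occ$treatment == "CON" & occ$timepoint == "d0" & occ$cluster == "1", ]
  expect_equal(con_d0$fraction, 1)
  # single cluster: every fraction is 1
  one <- structure(list(clustering = setNames(rep(1L, 8), meta$sample_id)),
                   class = "cluster_solution")
  occ1 <- cluster_occupancy(one, meta)
  expect_true(all(occ1$fraction == 1))
})
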