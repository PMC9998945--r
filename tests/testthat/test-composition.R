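test_that("zero imputation reproduces the multiplicative replacement formula", {
  m <- matrix(c(2, 3, 5,
                0, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  out <- impute_zeros(m)  # uniform prior t = 1/3, s = 3
  expect_equal(unname(out["s1", ]), c(0.2, 0.3, 0.5))           # no zeros: plain closure
  expect_equal(unname(out["s2", ]), c(1 / 13, 6 / 13, 6 / 13))  # r = (1/3 * 3)/(10 + 3)
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
})

test_that("imputation preserves ratios among observed parts and rejects empty samples", {
  set.seed(4)
  m <- matrix(rpois(60, 3), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  m[1, ] <- pmax(m[1, ], 1)
  out <- impute_zeros(m)
  expect_true(all(out > 0))
  expect_equal(unname(rowSums(out)), rep(1, 6), tolerance = 1e-12)
  for (r in 1:6) {
    nz <- which(m[r, ] > 0)
    if (length(nz) > 1)
      expect_equal(out[r, nz] / out[r, nz[1]], m[r, nz] / m[r, nz[1]],
                   tolerance = 1e-12)
  }
  m[2, ] <- 0
  expect_error(impute_zeros(m), "s2")
})

test_that("CLR matches hand-computed values and is scale invariant", {
  u <- matrix(0.25, 1, 4)
  expect_equal(as.vector(clr_transform(u)), rep(0, 4))
  x <- matrix(c(1, exp(1), exp(2)) / sum(c(1, exp(1), exp(2))), 1, 3)
  expect_equal(as.vector(clr_transform(x)), c(-1, 0, 1), tolerance = 1e-12)
  comp <- random_compositions(20, 8, seed = 2)
  expect_equal(clr_transform(comp), clr_transform(2 * comp), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(clr_transform(comp)))), 1e-9)
  expect_error(clr_transform(matrix(c(0, 1, 1), 1, 3)), "impute")
})

test_that("Aitchison distances are Euclidean on CLR rows and satisfy metric axioms", {
  clr <- rbind(a = c(-1, 0, 1), b = c(1, 0, -1))
  d <- as.matrix(aitchison_dist(clr))
  expect_equal(d["a", "b"], sqrt(8), tolerance = 1e-12)
  expect_equal(d["a", "a"], 0)
  D <- as.matrix(aitchison_dist(clr_transform(random_compositions(50, 6, seed = 7))))
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D[upper.tri(D)] > 0))
  for (i in 1:48) for (j in (i + 1):49) for (k in (j + 1):50)
    expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
})

test_that("Aitchison distances are invariant to per-sample count rescaling", {
  set.seed(9)
  counts <- matrix(rpois(50, 20) + 1, 5, 10)
  rownames(counts) <- paste0("s", 1:5); colnames(counts) <- paste0("t", 1:10)
  scaled <- counts * c(1L, 2L, 5L, 10L, 3L)
  d1 <- aitchison_dist(clr_transform(impute_zeros(counts)))
  d2 <- aitchison_dist(clr_transform(impute_zeros(scaled)))
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)
})

test_that("prevalence/abundance filter matches brute-force evaluation on a toy table", {
  counts <- rbind(
    # 4 pre samples                       4 post samples
    c(5, 0, 100, 1, 0), c(3, 0, 200, 1, 0), c(4, 9, 150, 0, 0), c(6, 0, 120, 1, 0),
    c(0, 8, 180, 1, 4), c(0, 7, 160, 1, 5), c(0, 9, 140, 1, 6), c(1, 6, 170, 0, 3))
  rownames(counts) <- paste0("s", 1:8)
  colnames(counts) <- paste0("t", 1:5)
  phase <- rep(c("pre", "post"), each = 4)
  ts <- prevalence_abundance_filter(counts, phase, prevalence = 0.75,
                                    min_relabund = 0.01)
  # independent brute-force oracle over both criteria per taxon per phase
  oracle <- function(rows) {
    sub <- counts[rows, ]
    rel <- sub / rowSums(sub)
    names(which(colMeans(sub > 0) >= 0.75 & colMeans(rel) > 0.01))
  }
  expect_setequal(ts$pre_set, oracle(1:4))
  expect_setequal(ts$post_set, oracle(5:8))
  expect_setequal(ts$superset, union(oracle(1:4), oracle(5:8)))
  # taxon present in only 2 of 4 pre samples cannot pass pre prevalence
  expect_false("t2" %in% ts$pre_set)
  # union semantics: pre-only and post-only taxa both appear in the superset
  expect_true("t1" %in% ts$pre_set && !("t1" %in% ts$post_set))
  expect_true("t5" %in% ts$post_set && !("t5" %in% ts$pre_set))
  expect_true(all(c("t1", "t5") %in% ts$superset))
})

test_that("filter is invariant to sample and taxon order and validates phases", {
  set.seed(3)
  counts <- matrix(rpois(80, 4), 8, 10,
                   dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  phase <- rep(c("pre", "post"), 4)
  ts1 <- prevalence_abundance_filter(counts, phase, prevalence = 0.5,
                                     min_relabund = 0.01)
  ro <- sample(8); co <- sample(10)
  ts2 <- prevalence_abundance_filter(counts[ro, co], phase[ro], prevalence = 0.5,
                                     min_relabund = 0.01)
  expect_setequal(ts1$superset, ts2$superset)
  expect_setequal(ts1$pre_set, ts2$pre_set)
  expect_error(prevalence_abundance_filter(counts, rep("weird", 8)), "unknown phase")
  expect_error(prevalence_abundance_filter(counts, rep("pre", 8)), "both")
})

test_that("rarefaction conserves depth and matches the hypergeometric mean", {
  counts <- matrix(c(100, 200, 300, 400,
                     50, 50, 50, 50), 2, 4, byrow = TRUE,
                   dimnames = list(c("a", "b"), paste0("t", 1:4)))
  r <- rarefy_counts(counts, depth = 200, seed = 1)
  expect_true(all(rowSums(r) == 200))
  # depth equal to the sample total leaves counts unchanged
  expect_equal(unname(rarefy_counts(counts, depth = 200, seed = 1)["b", ]),
               unname(counts["b", ]))
  # Monte-Carlo mean of the rarefied count equals depth * proportion
  one <- matrix(c(100, 200, 300, 400), 2, 4, byrow = TRUE,
                dimnames = list(c("x", "y"), paste0("t", 1:4)))
  acc <- numeric(4)
  for (i in 1:1000) acc <- acc + rarefy_counts(one, depth = 100, seed = i)["x", ]
  expect_equal(unname(acc / 1000), 100 * c(100, 200, 300, 400) / 1000,
               tolerance = 0.05)
  expect_error(rarefy_counts(counts, depth = 0), "positive")
  expect_warning(rarefy_counts(counts, depth = 300, seed = 1), "dropping")
})
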