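test_that("pairwise correlations cover every unordered pair exactly once", {
  set.seed(1)
  x <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  tbl <- pairwise_correlations(x)
  expect_equal(nrow(tbl), choose(10, 2))
  expect_true(all(tbl$feature_a != tbl$feature_b))
  key <- paste(pmin(tbl$feature_a, tbl$feature_b), pmax(tbl$feature_a, tbl$feature_b))
  expect_equal(anyDuplicated(key), 0L)
  expect_error(pairwise_correlations(x[1:4, ]), "at least 5")
})

test_that("a perfectly monotone pair has rho = tau = 1", {
  x <- cbind(a = 1:10, b = (1:10)^3)
  tbl <- pairwise_correlations(cbind(x, c = rnorm(10)))
  row <- tbl[tbl$feature_a == "a" & tbl$feature_b == "b", ]
  expect_equal(row$rho, 1)
  expect_equal(row$tau, 1)
  expect_lt(row$p_spearman, 1e-6)
  expect_lt(row$p_kendall, 0.001)
})

test_that("analytic p-values match cor.test approximations without ties", {
  set.seed(2)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tbl <- pairwise_correlations(x)
  for (r in seq_len(nrow(tbl))) {
    i <- tbl$feature_a[r]; j <- tbl$feature_b[r]
    expect_equal(tbl$p_pearson[r],
                 cor.test(x[, i], x[, j])$p.value, tolerance = 1e-10)
    expect_equal(tbl$p_spearman[r],
                 cor.test(x[, i], x[, j], method = "spearman", exact = FALSE)$p.value,
                 tolerance = 1e-10)
    expect_equal(tbl$p_kendall[r],
                 cor.test(x[, i], x[, j], method = "kendall", exact = FALSE)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("constant features are excluded with a warning naming them", {
  set.seed(3)
  x <- cbind(matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4))),
             flat = rep(2, 10))
  expect_warning(tbl <- pairwise_correlations(x), "flat")
  expect_false(any(c(tbl$feature_a, tbl$feature_b) == "flat"))
})

test_that("consensus support rule keeps only sign-consistent multi-measure edges", {
  tbl <- data.frame(
    feature_a = c("a", "a", "b"), feature_b = c("b", "c", "c"),
    r_pearson = c(0.9, 0.8, -0.9), p_pearson = c(1e-6, 1e-6, 1e-6),
    rho = c(0.9, 0.1, 0.85), p_spearman = c(1e-5, 0.9, 1e-5),
    tau = c(0.8, 0.05, 0.7), p_kendall = c(1e-4, 0.95, 1e-4)
  )
  edges <- consensus_edges(tbl, alpha = 0.05, min_support = 2)
  # a-b: three agreeing positive measures -> kept, sign +
  ab <- edges[edges$feature_a == "a" & edges$feature_b == "b", ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$sign, "+")
  expect_equal(ab$support, 3)
  # a-c: Pearson only -> support 1, discarded
  expect_false(any(edges$feature_a == "a" & edges$feature_b == "c"))
  # b-c: Pearson negative vs Spearman/Kendall positive -> sign conflict, discarded
  expect_false(any(edges$feature_a == "b" & edges$feature_b == "c"))
  expect_error(consensus_edges(tbl, min_support = 4), "exceeds")
})

test_that("raising min_support never adds edges", {
  set.seed(4)
  x <- matrix(rnorm(25 * 12), 25, 12)
  x[, 2] <- x[, 1] + rnorm(25, 0, 0.3)
  x[, 4] <- -x[, 3] + rnorm(25, 0, 0.3)
  colnames(x) <- paste0("f", 1:12)
  tbl <- pairwise_correlations(x)
  e1 <- consensus_edges(tbl, min_support = 1)
  e2 <- consensus_edges(tbl, min_support = 2)
  e3 <- consensus_edges(tbl, min_support = 3)
  key <- function(e) paste(e$feature_a, e$feature_b)
  expect_true(all(key(e2) %in% key(e1)))
  expect_true(all(key(e3) %in% key(e2)))
})

test_that("on rank-transformed data Pearson and Spearman support coincide", {
  set.seed(5)
  x <- matrix(rnorm(20 * 8), 20, 8, dimnames = list(NULL, paste0("f", 1:8)))
  ranks <- apply(x, 2, rank)
  tbl <- pairwise_correlations(ranks)
  expect_equal(tbl$r_pearson, tbl$rho, tolerance = 1e-12)
  expect_equal(tbl$p_pearson, tbl$p_spearman, tolerance = 1e-12)
})

test_that("edge sets are invariant to sample and feature ordering", {
  set.seed(6)
  x <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("f", 1:8)))
  x[, 2] <- x[, 1] + rnorm(30, 0, 0.2)
  e1 <- consensus_edges(pairwise_correlations(x))
  e2 <- consensus_edges(pairwise_correlations(x[sample(30), sample(8)]))
  key <- function(e) sort(paste(pmin(e$feature_a, e$feature_b),
                                pmax(e$feature_a, e$feature_b), e$sign))
  expect_identical(key(e1), key(e2))
})

test_that("network summaries count signs and handle empty edge lists", {
  edges <- data.frame(feature_a = letters[1:4], feature_b = letters[5:8],
                      sign = c("+", "+", "+", "-"))
  s <- network_summary(edges)
  expect_equal(s$n_edges, 4)
  expect_equal(s$percent_positive, 75)
  empty <- edges[0, ]
  s0 <- network_summary(empty)
  expect_equal(s0$n_edges, 0)
  expect_true(is.na(s0$percent_positive))
})

test_that("planted correlation structure is recovered with the planted sign balance", {
  set.seed(7)
  n <- 30; m <- 30
  x <- matrix(rnorm(n * m, 0, 0.5), n, m, dimnames = list(NULL, paste0("f", 1:m)))
  pairs <- cbind(seq(1, 23, 2), seq(2, 24, 2))
  loading <- c(rep(1.2, 10), rep(-1.2, 2))
  for (q in seq_len(12)) {
    z <- rnorm(n)
    x[, pairs[q, 1]] <- x[, pairs[q, 1]] + abs(loading[q]) * z
    x[, pairs[q, 2]] <- x[, pairs[q, 2]] + loading[q] * z
  }
  edges <- consensus_edges(pairwise_correlations(x))
  s <- network_summary(edges)
  expect_gt(s$n_edges, 6)
  expect_lt(abs(s$percent_positive - 100 * 10 / 12), 15)
})
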