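test_that("Shannon index matches closed forms", {
  m <- rbind(u = c(5, 5, 5, 5), s = c(9, 0, 0, 0), t = c(1, 1, 2, 0))
  H <- shannon_index(m)
  expect_equal(unname(H["u"]), log(4), tolerance = 1e-12)
  expect_equal(unname(H["s"]), 0)
  expect_equal(unname(H["t"]), -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(unname(H["t"]), 1.0397, tolerance = 1e-4)
  expect_error(shannon_index(rbind(c(1, 1), c(0, 0))), "empty")
})

test_that("Shannon agrees with the vegan implementation on random tables", {
  set.seed(8)
  m <- matrix(rpois(200, 10), 20, 10)
  rownames(m) <- paste0("s", 1:20)
  expect_equal(unname(shannon_index(m)), unname(vegan::diversity(m, "shannon")),
               tolerance = 1e-12)
})

test_that("balanced mixed-model fixed effects agree with OLS", {
  st <- generate_study(tiny_config(), seed = 3)
  set.seed(3)
  H <- rnorm(nrow(st$metadata), 2, 0.2)
  names(H) <- st$metadata$sample_id
  fit <- fit_alpha_model(H, st$metadata)
  ols <- lm(H ~ treatment * time, data = fit$data)
  expect_equal(unname(fit$fixef), unname(coef(ols)), tolerance = 1e-6)
  expect_gte(fit$subject_sd, 0)
})

test_that("a planted timepoint shift is recovered within its confidence interval", {
  st <- generate_study(sim_config(), seed = 4)
  meta <- st$metadata
  set.seed(4)
  H <- 2 + 0.5 * (meta$timepoint == "h0") +
    rnorm(20, 0, 0.2)[match(meta$subject_id, unique(meta$subject_id))] +
    rnorm(nrow(meta), 0, 0.15)
  names(H) <- meta$sample_id
  fit <- fit_alpha_model(H, meta)
  est <- fit$fixef[["timeh0"]]
  se <- sqrt(diag(as.matrix(vcov(fit$model))))[["timeh0"]]
  expect_gt(0.5, est - 2 * se)
  expect_lt(0.5, est + 2 * se)
})

test_that("subject variance component is recovered on average", {
  ests <- replicate(20, NA_real_)
  meta <- generate_study(sim_config(), seed = 1)$metadata
  subjects <- unique(meta$subject_id)
  for (i in seq_len(20)) {
    set.seed(200 + i)
    H <- 2 + rnorm(20, 0, 0.3)[match(meta$subject_id, subjects)] +
      rnorm(nrow(meta), 0, 0.2)
    names(H) <- meta$sample_id
    ests[i] <- fit_alpha_model(H, meta)$subject_sd
  }
  expect_gt(mean(ests), 0.15)
  expect_lt(mean(ests), 0.45)
})

test_that("contrast bookkeeping: 21 within-arm pairs per arm, Bonferroni per family", {
  st <- generate_study(sim_config(), seed = 5)
  set.seed(5)
  H <- rnorm(nrow(st$metadata), 2, 0.3)
  names(H) <- st$metadata$sample_id
  fit <- fit_alpha_model(H, st$metadata)
  cw <- alpha_contrasts(fit, "within_group_pairwise")
  expect_equal(nrow(cw), 42L)
  expect_equal(as.vector(table(cw$group)), c(21L, 21L))
  expect_equal(cw$p_adj, pmin(1, cw$p_raw * 21), tolerance = 1e-12)
  expect_true(all(cw$p_adj >= cw$p_raw & cw$p_adj <= 1))
  cb <- alpha_contrasts(fit, "between_group_per_timepoint")
  expect_equal(nrow(cb), 7L)
  expect_equal(cb$p_adj, pmin(1, cb$p_raw * 1), tolerance = 1e-12)  # one test per timepoint family
  cbp <- alpha_contrasts(fit, "between_group_per_timepoint", family = "pooled")
  expect_equal(cbp$p_adj, pmin(1, cbp$p_raw * 7), tolerance = 1e-12)
  expect_error(alpha_contrasts(fit, "no_such_scheme"))
})

test_that("null alpha model does not over-reject the treatment effect", {
  meta <- generate_study(sim_config(), seed = 1)$metadata
  subjects <- unique(meta$subject_id)
  rej <- 0; n_sim <- 60
  for (i in seq_len(n_sim)) {
    set.seed(1000 + i)
    H <- 2 + rnorm(20, 0, 0.2)[match(meta$subject_id, subjects)] +
      rnorm(nrow(meta), 0, 0.2)
    names(H) <- meta$sample_id
    fit <- fit_alpha_model(H, meta)
    a <- stats::anova(fit$model)
    rej <- rej + (a["treatment", "Pr(>F)"] < 0.05)
  }
  expect_lte(rej / n_sim, 0.15)
})

test_that("PCA ordination is an exact decomposition with ordered variance", {
  set.seed(6)
  clr <- clr_transform(random_compositions(15, 8, seed = 6))
  ord <- pca_ordination(clr)
  expect_true(all(diff(ord$var_explained) <= 1e-12))
  expect_lte(sum(ord$var_explained), 1 + 1e-9)
  recon <- ord$scores %*% t(ord$loadings)
  centered <- sweep(clr, 2, ord$center)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # duplicate samples get identical scores
  clr2 <- rbind(clr, clr[1, , drop = FALSE])
  ord2 <- pca_ordination(clr2)
  expect_equal(ord2$scores[1, ], ord2$scores[16, ], tolerance = 1e-10)
})

test_that("PC1 separates well-separated synthetic clusters", {
  set.seed(7)
  lam <- rbind(matrix(rnorm(10 * 6, 0, 0.2), 10, 6),
               matrix(rnorm(10 * 6, 0, 0.2) + rep(c(3, -3), each = 3 * 10), 10, 6))
  clr <- lam - rowMeans(lam)
  ord <- pca_ordination(clr)
  labels <- rep(c("a", "b"), each = 10)
  expect_gt(silhouette_1d(ord$scores[, 1], labels), 0.5)
})
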