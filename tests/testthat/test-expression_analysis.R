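count_fixture <- function(counts, types = NULL) {
  ids <- sprintf("g%03d", seq_len(nrow(counts)))
  rownames(counts) <- ids
  if (is.null(types)) types <- rep("protein_coding", nrow(counts))
  expression_data(counts, data.frame(gene_id = ids, symbol = ids,
                                     gene_type = types))
}

test_that("gene filtering enforces the mean-count and gene-type rules", {
  cts <- rbind(rep(2, 10),          # mean 2 < 3: removed
               rep(3, 10),          # mean 3: kept (cut is 'less than three')
               rep(50, 10),         # miRNA: removed despite high counts
               rep(10, 10))
  d <- count_fixture(cts, types = c("protein_coding", "protein_coding",
                                    "miRNA", "lncRNA"))
  f <- filter_genes(d)
  expect_equal(rownames(f$counts), c("g002", "g004"))
  expect_equal(attr(f, "removed"), c(low_expression = 1, gene_type = 1))
  only_low <- count_fixture(matrix(1, 2, 5))
  expect_error(filter_genes(only_low), "no genes")
})

test_that("median-of-ratios normalisation equalises scaled samples", {
  set.seed(3)
  base <- matrix(rnbinom(200 * 2, mu = 50, size = 5), 200, 2)
  cts <- cbind(A = base[, 1], B = 2 * base[, 1], C = base[, 2])
  d <- count_fixture(cts)
  v <- vst_normalize(d)
  expect_equal(v$size_factors[["B"]] / v$size_factors[["A"]], 2, tolerance = 1e-9)
  expect_equal(v$mat[, "A"], v$mat[, "B"], tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero count maps to 0; transform is monotone within a sample
  cts2 <- cbind(s = c(0, 1, 5, 100, 20, 7))
  d2 <- count_fixture(cts2)
  v2 <- vst_normalize(d2)
  expect_equal(unname(v2$mat[1, 1]), 0)
  expect_equal(order(v2$mat[, 1]), order(cts2[, 1]))
})

test_that("NB regression recovers planted slopes with good power", {
  set.seed(17)
  n <- 120; ng <- 300
  cgc <- rnorm(n, sd = 3)
  mu0 <- 2^runif(ng, 4, 8)
  slope <- c(rep(1, 100), rep(0, ng - 100))
  mu <- outer(mu0, rep(1, n)) * 2^outer(slope, cgc)
  cts <- matrix(rnbinom(ng * n, mu = mu, size = 10), ng, n)
  colnames(cts) <- sprintf("s%03d", 1:n)
  d <- count_fixture(cts)
  res <- fit_dgr(d, cgc, size_factors = rep(1, n))
  expect_gt(mean(res$significant[1:100]), 0.8)
  expect_lt(mean(res$significant[101:ng]), 0.02)
  expect_equal(res$wald_z, res$lfc / res$se, tolerance = 1e-12)
  ok <- !is.na(res$p)
  expect_true(all(res$fdr[ok] >= res$p[ok] - 1e-12))
})

test_that("NB slope approaches the Poisson slope as dispersion vanishes", {
  set.seed(23)
  n <- 150
  cgc <- rnorm(n, sd = 2)
  mu <- 100 * 2^(0.4 * cgc)
  y <- rpois(n, mu)   # dispersion -> 0 limit
  d <- count_fixture(matrix(y, 1, n, dimnames = list(NULL, sprintf("s%03d", 1:n))))
  res <- fit_dgr(d, cgc, size_factors = rep(1, n))
  pois <- glm(y ~ cgc, family = poisson())
  expect_equal(res$lfc[1], unname(coef(pois)["cgc"]) / log(2), tolerance = 1e-3)
})

test_that("recursive clustering recovers planted blocks and drops small ones", {
  bl <- block_expression(c(60, 55, 50, 40, 20), n_samples = 80, seed = 12)
  mods <- recursive_cluster(bl$mat, min_cluster = 31)
  expect_equal(length(mods$modules), 4)
  expect_equal(length(mods$dropped), 20)
  found <- rep(names(mods$modules), lengths(mods$modules))
  names(found) <- unlist(mods$modules)
  keep <- names(bl$labels)[bl$labels != 5]
  expect_gt(adjusted_rand(bl$labels[keep], found[keep]), 0.95)
  expect_error(recursive_cluster(bl$mat[1:10, ], min_cluster = 31), "too few")
})

test_that("a perfect block correlation structure is a fixed point", {
  bl <- block_expression(c(30, 30), n_samples = 50, noise_sd = 1e-4, seed = 2)
  cc <- cor(t(bl$mat))
  cc2 <- cor(cc)
  within <- bl$labels[row(cc)] == bl$labels[col(cc)]
  expect_true(all(cc2[within] > 0.999))
  expect_true(all(cc2[!within] < 0))
})

test_that("cluster labels are deterministic given lfc and sizes", {
  bl <- block_expression(c(60, 55, 50), n_samples = 80, seed = 7)
  lfc <- setNames(c(rep(-1, 60), rep(0.5, 55), rep(0.8, 50)), rownames(bl$mat))
  mods <- recursive_cluster(bl$mat, lfc = lfc, min_cluster = 31)
  expect_lt(mods$mean_lfc[["C0"]], 0)
  sizes <- lengths(mods$modules)[-1]
  expect_true(all(diff(sizes) <= 0))  # C1.. by descending size
  # permutation invariance of the partition
  perm <- sample(nrow(bl$mat))
  mods_p <- recursive_cluster(bl$mat[perm, ], lfc = lfc, min_cluster = 31)
  for (m in names(mods$modules))
    expect_setequal(mods_p$modules[[m]], mods$modules[[m]])
})

test_that("signature scores track a planted gradient after orientation", {
  set.seed(9)
  n <- 70
  grad <- sort(rnorm(n))
  mat <- matrix(rnorm(40 * n, sd = 0.5), 40, n,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:n)))
  mat[1:25, ] <- mat[1:25, ] + outer(runif(25, 0.8, 1.2), grad)
  mods <- list(M = rownames(mat)[1:25])
  ss <- signature_scores(mat, mods)
  expect_gt(cor(ss$scores[, "M"], grad, method = "spearman"), 0.9)
  # duplicating every gene leaves scores unchanged up to scale
  dup <- rbind(mat[1:25, ], mat[1:25, ])
  rownames(dup) <- sprintf("d%02d", 1:50)
  ss2 <- signature_scores(dup, list(M = rownames(dup)))
  expect_gt(abs(cor(ss$scores[, "M"], ss2$scores[, "M"])), 0.999)
  expect_error(signature_scores(matrix(1, 3, 5, dimnames = list(letters[1:3], NULL)),
                                list(M = letters[1:3])), "zero variance")
})

test_that("z-statistic concordance behaves under null and shared signal", {
  idm <- data.frame(gene = sprintf("g%03d", 1:100), wald_z = rnorm(100))
  same <- concordance_z(structure(idm, class = c("dgr_result", "data.frame")),
                        data.frame(gene = idm$gene, t_mod = idm$wald_z))
  expect_equal(same$rho, 1)
  set.seed(11)
  z1 <- rnorm(1000); z2 <- rnorm(1000)
  ind <- concordance_z(
    structure(data.frame(gene = as.character(1:1000), wald_z = z1),
              class = c("dgr_result", "data.frame")),
    data.frame(gene = as.character(1:1000), t_mod = z2))
  expect_lt(abs(ind$rho), 0.1)
  shared <- sqrt(0.5) * z1 + sqrt(0.5) * rnorm(1000)
  dep <- concordance_z(
    structure(data.frame(gene = as.character(1:1000), wald_z = z1),
              class = c("dgr_result", "data.frame")),
    data.frame(gene = as.character(1:1000), t_mod = shared))
  expect_gt(dep$rho, 0.3)
  expect_lt(dep$p, 1e-6)
  expect_error(concordance_z(
    structure(data.frame(gene = "a", wald_z = 1),
              class = c("dgr_result", "data.frame")),
    data.frame(gene = "a", t_mod = 1)), "10 shared")
})

test_that("top-variance PCA finds a planted secondary malignancy axis", {
  set.seed(19)
  n <- 90
  purity <- rnorm(n, sd = 3)     # dominant axis
  malig <- rnorm(n, sd = 1.5)    # orthogonal secondary axis
  mat <- rbind(outer(runif(60, 0.8, 1.2), purity),
               outer(runif(40, 0.8, 1.2), malig)) +
    matrix(rnorm(100 * n, sd = 0.3), 100, n)
  rownames(mat) <- sprintf("f%03d", 1:100)
  res <- pca_top_features(mat, n_top = 100, covariate = malig)
  expect_gt(abs(res$cor_covariate[["PC2"]]), 0.5)
  expect_equal(length(res$selected), 100)
  # selection invariant to sample order
  perm <- sample(n)
  res_p <- pca_top_features(mat[, perm], n_top = 50)
  expect_setequal(res_p$selected, pca_top_features(mat, n_top = 50)$selected)
  # n_top = all features reproduces full PCA variances
  full <- prcomp(t(mat), center = TRUE)
  expect_equal(res$var_explained, full$sdev^2 / sum(full$sdev^2),
               tolerance = 1e-9)
  expect_error(pca_top_features(mat, n_top = 101), "exceeds")
})
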