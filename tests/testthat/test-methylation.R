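test_that("beta/M transforms are the exact logit pair", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)                      # log2(4)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b), tolerance = 1e-12)

  ann <- data.frame(probe_id = "p1", chrom = "chr1", pos = 1,
                    cpg_context = "Island", gene_region = "Body",
                    gene_symbols = "G1")
  d <- methylation_data(matrix(0.8, 1, 2, dimnames = list("p1", c("a", "b"))),
                        ann, scale = "beta")
  m <- beta_m_transform(d, "to_m")
  expect_identical(m$scale, "M")
  expect_equal(unname(m$mat[1, 1]), 2)
  expect_error(beta_m_transform(m, "to_m"), "already")
  back <- beta_m_transform(m, "to_beta")
  expect_equal(back$mat, d$mat, tolerance = 1e-12)
})

test_that("probe filtering removes sex chromosomes and unannotated probes", {
  ann <- data.frame(probe_id = paste0("p", 1:4),
                    chrom = c("chrX", "chr1", "chrY", "chr2"),
                    pos = 1:4, cpg_context = "OpenSea", gene_region = "Body",
                    gene_symbols = c("A", "", "B", "C"))
  mat <- matrix(0.5, 4, 3, dimnames = list(ann$probe_id, c("s1", "s2", "s3")))
  f <- filter_probes(methylation_data(mat, ann, "beta"))
  expect_equal(rownames(f$mat), "p4")
  expect_equal(attr(f, "removed"), c(sex_chromosome = 2, no_gene_annotation = 1))
})

test_that("moderated regression recovers planted slopes and controls nulls", {
  set.seed(21)
  n <- 100; np <- 400
  cgc <- rnorm(n, sd = 3)
  mat <- matrix(rnorm(np * n, sd = 0.5), np, n,
                dimnames = list(sprintf("p%03d", 1:np), sprintf("s%03d", 1:n)))
  planted <- 1:20
  mat[planted, ] <- mat[planted, ] + outer(rep(1, 20), cgc)  # slope +1
  mat[np, ] <- 7                                             # constant probe
  res <- fit_dmp(mat, cgc)
  expect_true(all(res$significant[planted]))
  expect_true(all(res$direction[planted] == "hyper"))
  expect_true(is.na(res$p[np]))
  expect_false(res$significant[np])
  # slope estimates unbiased: planted slopes within 3 SE
  expect_true(all(abs(res$lfc[planted] - 1) < 3 * res$se[planted]))
  # null probes essentially never called
  nulls <- setdiff(seq_len(np - 1), planted)
  expect_lt(mean(res$significant[nulls]), 0.01)
  # BH: fdr >= p elementwise, fdr monotone in p
  ok <- !is.na(res$p)
  expect_true(all(res$fdr[ok] >= res$p[ok] - 1e-12))
  o <- order(res$p[ok])
  expect_true(all(diff(res$fdr[ok][o]) >= -1e-12))
})

test_that("moderation limits reduce to pooled and ordinary t", {
  set.seed(8)
  n <- 20; np <- 50
  cgc <- rnorm(n)
  mat <- matrix(rnorm(np * n, sd = rep(runif(np, 0.3, 2), n)), np, n,
                dimnames = list(sprintf("p%02d", 1:np), NULL))
  inf_fit <- fit_dmp(mat, cgc, prior_df = Inf)
  expect_equal(length(unique(round(inf_fit$se, 12))), 1)  # pooled variance
  zero_fit <- fit_dmp(mat, cgc, prior_df = 0)
  lm_t <- apply(mat, 1, function(y) summary(lm(y ~ cgc))$coefficients["cgc", "t value"])
  expect_equal(unname(zero_fit$t_mod), unname(lm_t), tolerance = 1e-8)
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(13)
  n <- 40; np <- 300
  cgc <- rnorm(n)
  mat <- matrix(rnorm(np * n, sd = rep(runif(np, 0.4, 1.6), n)), np, n,
                dimnames = list(sprintf("p%03d", 1:np), NULL))
  mine <- fit_dmp(mat, cgc)
  design <- cbind(Intercept = 1, cgc = cgc)
  ref <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(attr(mine, "moderation")$d0, ref$df.prior, tolerance = 1e-3)
  expect_equal(unname(mine$t_mod), unname(ref$t[, "cgc"]), tolerance = 1e-6)
  expect_equal(unname(mine$p), unname(ref$p.value[, "cgc"]), tolerance = 1e-6)
})

test_that("context enrichment matches the exact hypergeometric", {
  # all hyper on islands, all hypo outside: p = 2 / C(20, 10)
  ann <- data.frame(probe_id = paste0("p", 1:20),
                    cpg_context = rep(c("Island", "OpenSea"), each = 10),
                    gene_region = "Body")
  dmp <- data.frame(probe = paste0("p", 1:20), lfc = rep(c(1, -1), each = 10),
                    se = 0.1, t_mod = rep(c(10, -10), each = 10), df_total = 10,
                    p = 1e-6, fdr = 1e-5,
                    direction = rep(c("hyper", "hypo"), each = 10),
                    significant = TRUE, stringsAsFactors = FALSE)
  class(dmp) <- c("dmp_result", "data.frame")
  enr <- context_enrichment(dmp, ann)
  isl <- enr[enr$class == "Island", ]
  expect_equal(isl$p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(isl$hyper_in, 10); expect_equal(isl$hypo_in, 0)

  # identical context proportions: p = 1
  ann2 <- ann; ann2$cpg_context <- rep(c("Island", "OpenSea"), 10)
  enr2 <- context_enrichment(dmp, ann2)
  expect_true(all(enr2$p == 1))

  none <- dmp; none$significant <- FALSE
  expect_error(context_enrichment(none, ann), "no significant")
})

test_that("gene-level aggregation takes medians over annotated probes", {
  ann <- data.frame(probe_id = paste0("p", 1:4), chrom = "chr1", pos = 1:4,
                    cpg_context = "Island", gene_region = "Body",
                    gene_symbols = c("A", "A", "A;B", "C"))
  mat <- matrix(c(1, 2, 4, 9), 4, 1, dimnames = list(ann$probe_id, "s1"))
  d <- methylation_data(mat, ann, scale = "M")
  g <- aggregate_gene_m(d)
  expect_equal(g["A", "s1"], 2)      # median of {1, 2, 4}
  expect_equal(g["B", "s1"], 4)      # shared probe contributes to both genes
  expect_equal(g["C", "s1"], 9)      # single-probe gene
})

test_that("methylation signature separates planted sample clusters", {
  set.seed(5)
  n <- 60; np <- 40
  grp <- rep(c(0, 1), each = n / 2)
  mat <- matrix(rnorm(np * n, sd = 0.4), np, n,
                dimnames = list(sprintf("p%02d", 1:np), sprintf("s%02d", 1:n)))
  mat <- mat + outer(rep(2, np), grp)   # cluster 1 shifted up
  ann <- data.frame(probe_id = rownames(mat), chrom = "chr1", pos = 1:np,
                    cpg_context = "Island", gene_region = "Body",
                    gene_symbols = "G")
  d <- methylation_data(mat, ann, scale = "M")
  sig <- methylation_signature(d, rownames(mat))
  expect_equal(unname(sig$risk_group), factor(ifelse(grp == 1, "high", "low"),
                                              levels = c("low", "high")))
  expect_gt(cor(sig$pc1, sig$median_m, method = "spearman"), 0)

  const <- methylation_data(matrix(1.5, 3, 4, dimnames = list(letters[1:3], NULL)),
                            data.frame(probe_id = letters[1:3], chrom = "chr1",
                                       pos = 1:3, cpg_context = "Island",
                                       gene_region = "Body", gene_symbols = "G"),
                            scale = "M")
  expect_error(methylation_signature(const, letters[1:3]), "zero variance")
  expect_error(methylation_signature(d, c("nope1", "nope2")), "disjoint")
})
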