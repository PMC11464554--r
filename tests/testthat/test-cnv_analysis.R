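make_track <- function(values, chrom = "chr1", width = 50000) {
  nb <- nrow(values)
  bins <- data.frame(chrom = rep(chrom, length.out = nb),
                     start = (seq_len(nb) - 1) * width,
                     end = seq_len(nb) * width)
  # separate chromosomes restart coordinates; simple case: one chromosome
  cnv_bin_track(bins, values)
}

test_that("event calling applies thresholds with HD/amp precedence", {
  v <- matrix(c(0.2, -0.5, 0.05, 0.4, -0.12, 0), 6, 1,
              dimnames = list(NULL, "s"))
  lab <- call_bin_events(make_track(v))
  expect_equal(unname(lab[, 1]),
               c("gain", "HD", "neutral", "amp", "loss", "neutral"))
  # exactly one label per cell; HD values also satisfy the loss threshold
  expect_false(anyNA(lab))
  thr <- cnv_thresholds()
  expect_true(all(v[lab == "HD", 1] <= thr$loss))
  expect_error(cnv_thresholds(hd = 0.2), "hd < loss")
})

test_that("CNV load sums flagged bin widths in Mb with a strict 350 cut", {
  v8 <- matrix(0.2, 8, 1, dimnames = list(NULL, "s"))
  load8 <- compute_cnv_load(make_track(v8))
  expect_equal(load8$load_mb, 0.4)
  expect_false(load8$high_load)

  v7001 <- matrix(0.2, 7001, 1, dimnames = list(NULL, "s"))
  big <- compute_cnv_load(make_track(v7001))
  expect_equal(big$load_mb, 350.05)
  expect_true(big$high_load)
  # exactly at the cut: not high load (strict >)
  v7000 <- matrix(0.2, 7000, 1, dimnames = list(NULL, "s"))
  expect_false(compute_cnv_load(make_track(v7000))$high_load)

  neutral <- matrix(0.05, 5, 1, dimnames = list(NULL, "s"))
  expect_equal(compute_cnv_load(make_track(neutral))$load_mb, 0)
})

test_that("load is invariant to bin order and sums over chromosomes", {
  set.seed(2)
  v <- matrix(rnorm(40, sd = 0.2), 40, 2, dimnames = list(NULL, c("a", "b")))
  bins <- data.frame(chrom = rep(c("chr1", "chr2"), each = 20),
                     start = rep((0:19) * 50000, 2),
                     end = rep((1:20) * 50000, 2))
  tr <- cnv_bin_track(bins, v)
  whole <- compute_cnv_load(tr)
  perm <- sample(40)
  tr_p <- cnv_bin_track(bins[perm, ], v[perm, , drop = FALSE])
  expect_equal(compute_cnv_load(tr_p)$load_mb, whole$load_mb)
  per_chr <- vapply(c("chr1", "chr2"), function(ch) {
    idx <- bins$chrom == ch
    compute_cnv_load(cnv_bin_track(bins[idx, ], v[idx, , drop = FALSE]))$load_mb
  }, numeric(2))
  expect_equal(rowSums(per_chr), whole$load_mb)
})

test_that("bin association matches the exact rank-sum p", {
  # carriers {5,6,7} vs non-carriers {0,1,2,3}: exact two-sided p = 2/35
  cgc <- c(5, 6, 7, 0, 1, 2, 3)
  v <- matrix(c(rep(-0.6, 3), rep(0, 4)), nrow = 1,
              dimnames = list(NULL, paste0("s", 1:7)))
  res <- scan_bin_association(make_track(v), cgc, mode = "hd")
  expect_equal(res$p[1], 2 / 35, tolerance = 1e-9)
  expect_equal(res$n_event[1], 3)
  expect_equal(res$signed_logp[1], log10(res$p[1]))
  expect_equal(abs(res$signed_logp[1]), -log10(res$p[1]))
})

test_that("rank test agrees with brute-force enumeration for small groups", {
  set.seed(31)
  for (m in 3:6) for (n in 3:6) {
    vals <- sample(100, m + n)  # untied
    a <- vals[seq_len(m)]; b <- vals[-seq_len(m)]
    expect_equal(suppressWarnings(wilcox.test(a, b)$p.value),
                 exact_ranksum_p(a, b), tolerance = 1e-12,
                 info = paste("m =", m, "n =", n))
  }
})

test_that("untestable bins get NA and stay out of the FDR family", {
  set.seed(6)
  v <- rbind(c(-0.6, -0.6, -0.6, 0, 0, 0, 0, 0),
             rep(0, 8),                      # zero carriers
             c(-0.6, rep(0, 7)))             # one carrier < min_group
  colnames(v) <- paste0("s", 1:8)
  res <- scan_bin_association(make_track(v), rnorm(8), mode = "hd")
  expect_true(is.na(res$p[2]) && is.na(res$p[3]))
  expect_true(is.na(res$fdr[2]))
  expect_equal(res$fdr[1], res$p[1])  # single-member FDR family
  all_na <- make_track(matrix(0, 3, 8, dimnames = list(NULL, paste0("s", 1:8))))
  expect_error(scan_bin_association(all_na, rnorm(8), mode = "hd"),
               "no bin testable")
})

test_that("the planted HD locus carries the genome-wide minimum FDR", {
  cfg <- tiny_config(seed = 77, n_bins = 500)
  cal <- generate_calibrated_scores(cfg$n_samples, cfg$seed)
  cnv <- generate_cnv(cal$latent, cfg)
  cgc <- compute_cgc(cal$scores)
  res <- scan_bin_association(cnv$track, cgc, mode = "hd")
  expect_true(which.min(res$fdr) %in% cnv$truth$hd_bins)
  amp <- scan_bin_association(cnv$track, cgc, mode = "amp")
  expect_true(which.min(amp$fdr) %in% cnv$truth$amp_bins)
  # gains reported as -log10(p): positive sign
  expect_true(all(amp$signed_logp[!is.na(amp$p)] >= 0))
})

test_that("gene-interval convenience calls find overlapping events", {
  v <- matrix(c(-0.6, 0, 0.5, 0), 4, 1, dimnames = list(NULL, "s1"))
  tr <- make_track(v, chrom = "chr9")
  hd <- gene_event_status(tr, "9", 10000, 60000, mode = "hd")
  expect_true(hd[["s1"]])
  amp <- gene_event_status(tr, "chr9", 100000, 160000, mode = "amp")
  expect_true(amp[["s1"]])
  expect_error(gene_event_status(tr, "chr1", 0, 1000, mode = "hd"), "no bins")
})
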