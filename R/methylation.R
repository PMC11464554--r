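#' Methylation data container
#'
#' Bundles a probes x samples matrix with its probe annotation and an
#' explicit scale flag. Beta values are the methylated fraction
#' `meth / (meth + unmeth)` in `[0, 1]`; M-values are their log2-odds
#' (logit base 2), which are closer to homoscedastic and are the scale on
#' which all regression modelling here is done.
#'
#' @param mat numeric matrix, probes x samples, with probe row names.
#' @param annotation data frame keyed by probe (row names or column
#'   `probe_id`) with columns `chrom`, `pos`, `cpg_context`
#'   (Island / N_Shore / S_Shore / N_Shelf / S_Shelf / OpenSea),
#'   `gene_region`, and `gene_symbols` (semicolon-separated, possibly empty).
#' @param scale `"beta"` or `"M"`.
#' @return a `methylation_data` object.
#' @export
methylation_data <- function(mat, annotation, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("matrix must have probe row names")
  if ("probe_id" %in% names(annotation)) rownames(annotation) <- annotation$probe_id
  if (!all(rownames(mat) %in% rownames(annotation)))
    stop("annotation missing for some probes")
  annotation <- annotation[rownames(mat), , drop = FALSE]
  if (scale == "beta" && any(mat < 0 | mat > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  structure(list(mat = mat, annotation = annotation, scale = scale),
            class = "methylation_data")
}

#' @export
print.methylation_data <- function(x, ...) {
  cat("<methylation_data> ", nrow(x$mat), " probes x ", ncol(x$mat),
      " samples, scale = ", x$scale, "\n", sep = "")
  invisible(x)
}

#' Beta/M transforms
#'
#' `beta_to_m()` is the logit (base 2) transform `M = log2(beta/(1-beta))`
#' after clamping beta into `[eps, 1-eps]`; `m_to_beta()` inverts it.
#' `beta_m_transform()` applies either to a [methylation_data()] container
#' and updates the scale flag, refusing to transform data already on the
#' target scale.
#'
#' @param beta,m numeric vectors or matrices.
#' @param eps clamping bound for beta.
#' @return transformed values; for `beta_m_transform()`, a new container.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' @rdname beta_to_m
#' @param data a `methylation_data` object.
#' @param direction `"to_m"` or `"to_beta"`.
#' @export
beta_m_transform <- function(data, direction = c("to_m", "to_beta"), eps = 1e-6) {
  direction <- match.arg(direction)
  stopifnot(inherits(data, "methylation_data"))
  if (direction == "to_m") {
    if (data$scale == "M") stop("data already on M scale")
    data$mat <- beta_to_m(data$mat, eps)
    data$scale <- "M"
  } else {
    if (data$scale == "beta") stop("data already on beta scale")
    data$mat <- m_to_beta(data$mat)
    data$scale <- "beta"
  }
  data
}

#' Filter probes for differential methylation analysis
#'
#' Removes probes on the sex chromosomes (chrX/chrY) and probes lacking any
#' RefGene gene annotation, the two exclusion rules applied before probe-wise
#' regression. Counts of each removal are attached as attribute `"removed"`.
#'
#' @param data a [methylation_data()] object.
#' @return the filtered container.
#' @export
filter_probes <- function(data) {
  stopifnot(inherits(data, "methylation_data"))
  ann <- data$annotation
  chrom <- normalize_chrom(ann$chrom)
  sex <- chrom %in% c("chrX", "chrY")
  genes <- as.character(ann$gene_symbols)
  unannot <- is.na(genes) | trimws(genes) == ""
  keep <- !sex & !unannot
  data$mat <- data$mat[keep, , drop = FALSE]
  data$annotation <- ann[keep, , drop = FALSE]
  attr(data, "removed") <- c(sex_chromosome = sum(sex),
                             no_gene_annotation = sum(unannot & !sex))
  data
}

# Invert trigamma by Newton iteration (monotone decreasing on (0, Inf)).
# Used to moment-match the scaled inverse chi-square prior on residual
# variances; returns Inf when y <= 0 (no excess dispersion of log-variances).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

# Empirical-Bayes squeeze of per-feature residual variances toward a common
# prior, by moment matching on log variances: fits a scaled F prior with
# d0 prior df and s0^2 prior variance.
squeeze_variances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  excess <- stats::var(e) - trigamma(df / 2)
  if (is.finite(excess) && excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  post <- s2
  post[ok] <- if (is.finite(d0)) (d0 * s0_sq + df * s2[ok]) / (d0 + df) else s0_sq
  list(d0 = d0, s0_sq = s0_sq, s2_post = post)
}

#' Moderated per-probe regression of M-values on the CGC
#'
#' Fits, for every probe, an ordinary least-squares regression of the
#' M-value on an intercept plus the CGC (plus optional covariates), then
#' shrinks the residual variances toward a common prior by empirical-Bayes
#' moment matching on log variances (prior df via trigamma inversion). The
#' moderated t uses the posterior variance with `df_residual + d0` degrees
#' of freedom. The reported `lfc` is the M-value slope per CGC unit — the
#' fold-change convention of moderated-regression software when the model
#' term is continuous.
#'
#' @param data a [methylation_data()] object on the M scale.
#' @param cgc numeric CGC per sample, aligned with the matrix columns (or a
#'   `cgc_result` whose `sample_id` matches the column names).
#' @param lfc_cut,fdr_cut significance thresholds: a probe is called
#'   differentially methylated when `|lfc| > lfc_cut` and `fdr < fdr_cut`.
#' @param covariates optional numeric matrix of additional per-sample
#'   covariates.
#' @param prior_df `"estimate"` (default), or a number forcing the prior df:
#'   `0` gives the ordinary per-probe t, `Inf` the pooled-variance t.
#' @return a `dmp_result` data frame (probe, lfc, se, t_mod, df_total, p,
#'   fdr, direction, significant) with the moderation parameters in
#'   attribute `"moderation"` and the thresholds in attribute `"cuts"`.
#'   Zero-variance probes get NA statistics and are excluded from the FDR
#'   family.
#' @export
fit_dmp <- function(data, cgc, lfc_cut = 0.5, fdr_cut = 0.01,
                    covariates = NULL, prior_df = "estimate") {
  if (inherits(data, "methylation_data")) {
    if (data$scale != "M") stop("fit_dmp requires M-scale data; use beta_m_transform()")
    mat <- data$mat
  } else mat <- as.matrix(data)
  if (is.data.frame(cgc) && "cgc" %in% names(cgc)) {
    cgc <- stats::setNames(cgc$cgc, cgc$sample_id)[colnames(mat)]
  }
  n <- ncol(mat)
  if (n < 3) stop("need at least 3 samples")
  if (stats::sd(cgc) == 0) stop("CGC does not vary across samples")
  X <- cbind(intercept = 1, cgc = cgc)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  p <- ncol(X)
  df_res <- n - p
  qr_x <- qr(X)
  coefs <- t(qr.coef(qr_x, t(mat)))          # probes x p
  fits <- t(qr.fitted(qr_x, t(mat)))
  res <- mat - fits
  s2 <- rowSums(res^2) / df_res
  XtXinv <- chol2inv(qr.R(qr_x))
  unscaled <- sqrt(XtXinv[2, 2])             # sd multiplier for the cgc slope
  zero_var <- s2 < .Machine$double.eps * max(s2, 1)
  s2[zero_var] <- NA_real_

  if (identical(prior_df, "estimate")) {
    sq <- squeeze_variances(s2, df_res)
  } else {
    d0 <- as.numeric(prior_df)
    pooled <- mean(s2, na.rm = TRUE)
    s2_post <- if (is.infinite(d0)) rep(pooled, length(s2))
               else if (d0 == 0) s2
               else (d0 * pooled + df_res * s2) / (d0 + df_res)
    s2_post[is.na(s2)] <- NA_real_
    sq <- list(d0 = d0, s0_sq = pooled, s2_post = s2_post)
  }
  se <- unscaled * sqrt(sq$s2_post)
  lfc <- coefs[, 2]
  t_mod <- lfc / se
  df_total <- df_res + sq$d0
  df_t <- if (is.finite(df_total)) df_total else 1e6
  pval <- 2 * stats::pt(-abs(t_mod), df = df_t)
  pval[zero_var] <- NA_real_
  fdr <- rep(NA_real_, length(pval))
  tested <- !is.na(pval)
  fdr[tested] <- stats::p.adjust(pval[tested], method = "BH")
  out <- data.frame(probe = rownames(mat), lfc = lfc, se = se, t_mod = t_mod,
                    df_total = df_total, p = pval, fdr = fdr,
                    direction = ifelse(lfc >= 0, "hyper", "hypo"),
                    significant = !is.na(fdr) & abs(lfc) > lfc_cut & fdr < fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "moderation") <- list(d0 = sq$d0, s0_sq = sq$s0_sq, df_residual = df_res)
  attr(out, "cuts") <- c(lfc = lfc_cut, fdr = fdr_cut)
  class(out) <- c("dmp_result", "data.frame")
  out
}

#' @export
print.dmp_result <- function(x, ...) {
  mod <- attr(x, "moderation")
  cat("<dmp_result> ", nrow(x), " probes, ", sum(x$significant), " significant (",
      sum(x$significant & x$direction == "hyper"), " hyper / ",
      sum(x$significant & x$direction == "hypo"), " hypo); d0 = ",
      signif(mod$d0, 4), "\n", sep = "")
  invisible(x)
}

#' CpG-context enrichment of hyper- vs hypomethylated probes
#'
#' For each annotation class (CpG context by default, optionally gene
#' region), tests whether significantly hypermethylated probes fall in the
#' class more often than hypomethylated ones, with a two-sided Fisher exact
#' test on the 2x2 table (hyper/hypo x in-class/not). The context
#' distribution of all tested probes is returned as the genome-wide
#' reference.
#'
#' @param dmp a `dmp_result` from [fit_dmp()].
#' @param annotation probe annotation data frame (rows keyed by probe id or
#'   with a `probe_id` column).
#' @param what annotation column to test, `"cpg_context"` or `"gene_region"`.
#' @return a data frame with one row per class: counts, odds ratio, p,
#'   and the reference fraction among all tested probes.
#' @export
context_enrichment <- function(dmp, annotation, what = c("cpg_context", "gene_region")) {
  what <- match.arg(what)
  stopifnot(inherits(dmp, "dmp_result"))
  if ("probe_id" %in% names(annotation)) rownames(annotation) <- annotation$probe_id
  sig <- dmp[dmp$significant, ]
  if (!nrow(sig)) stop("no significant probes: cannot test enrichment")
  ctx_sig <- as.character(annotation[sig$probe, what])
  ctx_all <- as.character(annotation[dmp$probe[!is.na(dmp$p)], what])
  classes <- sort(unique(ctx_all))
  hyper <- sig$direction == "hyper"
  rows <- lapply(classes, function(cl) {
    inc <- ctx_sig == cl
    tab <- matrix(c(sum(hyper & inc), sum(hyper & !inc),
                    sum(!hyper & inc), sum(!hyper & !inc)),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(class = cl,
               hyper_in = tab[1, 1], hyper_out = tab[1, 2],
               hypo_in = tab[2, 1], hypo_out = tab[2, 2],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               reference_fraction = mean(ctx_all == cl),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate probe M-values to gene level
#'
#' Each probe contributes to every gene in its (semicolon-separated) gene
#' annotation; the gene-level value per sample is the median M over all
#' contributing probes.
#'
#' @param data a [methylation_data()] object on the M scale.
#' @return genes x samples numeric matrix.
#' @export
aggregate_gene_m <- function(data) {
  stopifnot(inherits(data, "methylation_data"))
  if (data$scale != "M") stop("aggregate_gene_m requires M-scale data")
  genes <- strsplit(as.character(data$annotation$gene_symbols), ";", fixed = TRUE)
  genes <- lapply(genes, function(g) unique(trimws(g[trimws(g) != ""])))
  probe_idx <- rep(seq_along(genes), lengths(genes))
  gene_of <- unlist(genes)
  if (!length(gene_of)) stop("no gene annotations present")
  by_gene <- split(probe_idx, gene_of)
  out <- matrix(NA_real_, length(by_gene), ncol(data$mat),
                dimnames = list(names(by_gene), colnames(data$mat)))
  for (k in seq_along(by_gene)) {
    sub <- data$mat[by_gene[[k]], , drop = FALSE]
    out[k, ] <- apply(sub, 2, stats::median)
  }
  out
}

#' Methylation signature score over a probe set
#'
#' Two per-sample summaries of a probe set (typically the CGC-hypermethylated
#' probes): (a) the median M-value, used for correlation analyses, and
#' (b) the first principal component of the per-probe standardised
#' submatrix, sign-oriented to correlate positively with (a). The risk group
#' (the "hypermethylation phenotype") is high iff the oriented PC1 score is
#' positive.
#'
#' @param data a [methylation_data()] object on the M scale.
#' @param probe_set character vector of probe ids.
#' @return list with `median_m`, `pc1` (oriented), `risk_group`
#'   (factor low/high), `orientation` (+1/-1) and `var_explained`.
#' @export
methylation_signature <- function(data, probe_set) {
  stopifnot(inherits(data, "methylation_data"))
  if (data$scale != "M") stop("methylation_signature requires M-scale data")
  probe_set <- intersect(probe_set, rownames(data$mat))
  if (!length(probe_set)) stop("probe_set is disjoint from the matrix")
  sub <- data$mat[probe_set, , drop = FALSE]
  med <- apply(sub, 2, stats::median)
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stop("zero variance: probe set is constant across samples")
  subz <- (sub[sds > 0, , drop = FALSE] - rowMeans(sub[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  pc <- stats::prcomp(t(subz), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  orientation <- if (stats::cor(score, med) < 0) -1 else 1
  score <- orientation * score
  list(median_m = med, pc1 = score,
       risk_group = factor(ifelse(score > 0, "high", "low"), levels = c("low", "high")),
       orientation = orientation,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}
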