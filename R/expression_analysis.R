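#' Expression count data container
#'
#' @param counts non-negative integer matrix, genes x samples, with gene row
#'   names.
#' @param annotation data frame keyed by gene (row names or column
#'   `gene_id`) with at least `gene_type`; `symbol` optional.
#' @return an `expression_data` object.
#' @export
expression_data <- function(counts, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene row names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if ("gene_id" %in% names(annotation)) rownames(annotation) <- annotation$gene_id
  if (!all(rownames(counts) %in% rownames(annotation)))
    stop("annotation missing for some genes")
  annotation <- annotation[rownames(counts), , drop = FALSE]
  structure(list(counts = counts, annotation = annotation),
            class = "expression_data")
}

#' @export
print.expression_data <- function(x, ...) {
  cat("<expression_data> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

#' Filter genes by expression level and gene type
#'
#' Keeps genes with an average read count of at least `min_mean` across
#' samples and a gene type among `types` (protein-coding and lncRNA by
#' default).
#'
#' @param data an [expression_data()] object.
#' @param min_mean minimum mean raw count.
#' @param types retained gene types.
#' @return the filtered container; removal counts in attribute `"removed"`.
#' @export
filter_genes <- function(data, min_mean = 3,
                         types = c("protein_coding", "lncRNA")) {
  stopifnot(inherits(data, "expression_data"))
  low <- rowMeans(data$counts) < min_mean
  badtype <- !(data$annotation$gene_type %in% types)
  keep <- !low & !badtype
  if (!any(keep)) stop("no genes pass the expression/type filter")
  out <- expression_data(data$counts[keep, , drop = FALSE],
                         data$annotation[keep, , drop = FALSE])
  attr(out, "removed") <- c(low_expression = sum(low), gene_type = sum(badtype & !low))
  out
}

#' Variance-stabilising normalisation of counts
#'
#' Median-of-ratios size factors (each sample's median ratio to the per-gene
#' geometric mean, computed over genes with no zero count), followed by the
#' started-log transform `log2(count / size_factor + 1)`. The log2 scale
#' stabilises the variance of the NB counts well enough for the downstream
#' correlation, clustering and PCA steps, which are robust to the exact
#' variance-stabilising curve.
#'
#' @param data an [expression_data()] object (after [filter_genes()]).
#' @return list with `mat` (normalised genes x samples matrix) and
#'   `size_factors`.
#' @export
vst_normalize <- function(data) {
  stopifnot(inherits(data, "expression_data"))
  counts <- data$counts
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warning("every gene contains a zero; using positive counts only for the reference")
    loggeo <- apply(counts, 1, function(r) mean(log(r[r > 0])))
    ref_ok <- is.finite(loggeo)
  } else {
    loggeo <- rowMeans(log(counts + (counts == 0)))  # only used where all_pos
    ref_ok <- all_pos
  }
  sf <- apply(counts, 2, function(col) {
    exp(stats::median((log(col) - loggeo)[ref_ok & col > 0]))
  })
  mat <- log2(sweep(counts, 2, sf, "/") + 1)
  list(mat = mat, size_factors = sf)
}

#' Negative-binomial differential gene regression on the CGC
#'
#' Per gene, fits a negative-binomial log-linear model of the raw count on
#' the CGC as continuous condition, with the log size factor as offset and
#' gene-wise dispersion estimated by maximum likelihood. The Wald statistic
#' `z = lfc / se` is reported on the log2 scale with a two-sided normal p
#' and BH FDR; a gene is called differentially expressed when
#' `|lfc| > lfc_cut` and `fdr < fdr_cut`. Genes whose fit does not converge
#' are flagged with NA statistics and excluded from the FDR family.
#'
#' @param data a filtered [expression_data()] object.
#' @param cgc numeric CGC per sample aligned with the count columns, or a
#'   `cgc_result` matched by sample id.
#' @param lfc_cut,fdr_cut significance thresholds.
#' @param size_factors optional precomputed size factors; defaults to
#'   [vst_normalize()]'s median-of-ratios factors.
#' @return a `dgr_result` data frame: gene, lfc, se, wald_z, p, fdr,
#'   dispersion, converged, significant.
#' @export
fit_dgr <- function(data, cgc, lfc_cut = 0.5, fdr_cut = 0.01, size_factors = NULL) {
  stopifnot(inherits(data, "expression_data"))
  counts <- data$counts
  if (is.data.frame(cgc) && "cgc" %in% names(cgc))
    cgc <- stats::setNames(cgc$cgc, cgc$sample_id)[colnames(counts)]
  if (is.null(size_factors)) size_factors <- vst_normalize(data)$size_factors
  off <- log(size_factors)
  ng <- nrow(counts)
  lfc <- se <- disp <- rep(NA_real_, ng)
  conv <- logical(ng)
  for (i in seq_len(ng)) {
    y <- counts[i, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ cgc + offset(off))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && !is.na(stats::coef(fit)["cgc"])) {
      sm <- summary(fit)$coefficients
      lfc[i] <- sm["cgc", "Estimate"] / log(2)
      se[i] <- sm["cgc", "Std. Error"] / log(2)
      disp[i] <- 1 / fit$theta
      conv[i] <- TRUE
    }
  }
  wald_z <- lfc / se
  p <- 2 * stats::pnorm(-abs(wald_z))
  fdr <- rep(NA_real_, ng)
  tested <- !is.na(p)
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  out <- data.frame(gene = rownames(counts), lfc = lfc, se = se, wald_z = wald_z,
                    p = p, fdr = fdr, dispersion = disp, converged = conv,
                    significant = !is.na(fdr) & abs(lfc) > lfc_cut & fdr < fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cuts") <- c(lfc = lfc_cut, fdr = fdr_cut)
  class(out) <- c("dgr_result", "data.frame")
  out
}

#' @export
print.dgr_result <- function(x, ...) {
  cat("<dgr_result> ", nrow(x), " genes, ", sum(x$significant), " significant (",
      sum(x$significant & x$lfc > 0), " up / ",
      sum(x$significant & x$lfc < 0), " down)\n", sep = "")
  invisible(x)
}

# Mean silhouette width of a partition against a distance matrix.
mean_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(labels, d)
  mean(sil[, "sil_width"])
}

#' Recursive correlation clustering of genes into modules
#'
#' Builds the gene-gene Pearson correlation matrix across samples, then the
#' correlation of its columns ("correlation of correlation", which sharpens
#' block structure), and cuts a Ward-linkage tree on the distance
#' `1 - corr-of-corr`. The number of clusters is chosen by maximal mean
#' silhouette width over `k_range`; clusters of `min_cluster - 1` genes or
#' fewer are excluded. Surviving modules are labelled C0, C1, ... : when
#' per-gene `lfc` values are supplied, C0 is the module with the most
#' negative mean lfc and the remaining modules are numbered by descending
#' size; otherwise all modules are numbered by descending size from C0.
#'
#' @param mat normalised expression matrix (genes x samples) restricted to
#'   the genes to cluster (typically the significant DGR genes).
#' @param lfc optional named per-gene regression slopes used for labelling.
#' @param min_cluster minimum module size to survive (default 51, i.e.
#'   modules of 50 genes or fewer are dropped).
#' @param k_range candidate numbers of clusters.
#' @param recursion_depth number of corr-of-corr passes (default 1).
#' @param linkage agglomeration method for [stats::hclust()].
#' @return a `gene_modules` object: list with `modules` (named list of gene
#'   vectors), `mean_lfc`, `k`, `silhouette`, `dropped` (genes in dropped
#'   clusters) and `membership` (full pre-drop partition).
#' @export
recursive_cluster <- function(mat, lfc = NULL, min_cluster = 51, k_range = 2:10,
                              recursion_depth = 1, linkage = "ward.D2") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 * min_cluster)
    stop("too few genes to cluster (need at least ", 2 * min_cluster, ")")
  cc <- stats::cor(t(mat))
  for (i in seq_len(recursion_depth)) cc <- stats::cor(cc)
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = linkage)
  k_range <- k_range[k_range < nrow(mat)]
  sil <- vapply(k_range, function(k) mean_silhouette(stats::cutree(hc, k), d),
                numeric(1))
  k <- k_range[which.max(sil)]
  part <- stats::cutree(hc, k)
  sizes <- table(part)
  keep_cl <- names(sizes)[sizes >= min_cluster]
  dropped <- names(part)[!part %in% as.integer(keep_cl)]
  mods <- lapply(keep_cl, function(cl) names(part)[part == as.integer(cl)])
  if (!length(mods)) stop("all clusters fall at or below the size cut")
  mean_lfc <- if (!is.null(lfc)) {
    vapply(mods, function(g) mean(lfc[g], na.rm = TRUE), numeric(1))
  } else rep(NA_real_, length(mods))
  sz <- lengths(mods)
  if (!is.null(lfc)) {
    c0 <- which.min(mean_lfc)
    rest <- setdiff(order(sz, decreasing = TRUE), c0)
    ord <- c(c0, rest)
  } else ord <- order(sz, decreasing = TRUE)
  mods <- mods[ord]; mean_lfc <- mean_lfc[ord]
  names(mods) <- paste0("C", seq_along(mods) - 1L)
  names(mean_lfc) <- names(mods)
  structure(list(modules = mods, mean_lfc = mean_lfc, k = k,
                 silhouette = max(sil), dropped = dropped, membership = part),
            class = "gene_modules")
}

#' @export
print.gene_modules <- function(x, ...) {
  cat("<gene_modules> k = ", x$k, " (mean silhouette ", signif(x$silhouette, 3),
      "); ", length(x$dropped), " genes in dropped clusters\n", sep = "")
  for (m in names(x$modules))
    cat(sprintf("  %s: %d genes (mean lfc %.3g)\n", m, length(x$modules[[m]]),
                x$mean_lfc[m]))
  invisible(x)
}

#' Per-sample module signature scores
#'
#' For each gene module, the signature score is the first principal
#' component of the per-gene z-scored module submatrix across samples,
#' sign-oriented so that the score correlates positively with the mean
#' z-scored module expression. The orientation makes scores reproducible
#' across runs (PCA signs are otherwise arbitrary) and makes "score > 0"
#' interpretable as above-average module expression.
#'
#' @param mat normalised expression matrix (genes x samples).
#' @param modules a `gene_modules` object or a named list of gene vectors.
#' @return a `signature_scores` object: list with `scores` (samples x
#'   modules matrix), `orientation` and `var_explained`.
#' @export
signature_scores <- function(mat, modules) {
  if (inherits(modules, "gene_modules")) modules <- modules$modules
  mat <- as.matrix(mat)
  scores <- matrix(NA_real_, ncol(mat), length(modules),
                   dimnames = list(colnames(mat), names(modules)))
  orient <- var_exp <- stats::setNames(numeric(length(modules)), names(modules))
  for (m in names(modules)) {
    genes <- intersect(modules[[m]], rownames(mat))
    if (!length(genes)) stop("module ", m, " is disjoint from the matrix")
    sub <- mat[genes, , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (all(sds == 0)) stop("zero variance: module ", m, " is constant")
    subz <- (sub[sds > 0, , drop = FALSE] - rowMeans(sub[sds > 0, , drop = FALSE])) /
      sds[sds > 0]
    pc <- stats::prcomp(t(subz), center = FALSE, scale. = FALSE)
    sc <- pc$x[, 1]
    o <- if (stats::cor(sc, colMeans(subz)) < 0) -1 else 1
    scores[, m] <- o * sc
    orient[m] <- o
    var_exp[m] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  structure(list(scores = scores, orientation = orient, var_explained = var_exp),
            class = "signature_scores")
}

#' @export
print.signature_scores <- function(x, ...) {
  cat("<signature_scores> ", nrow(x$scores), " samples x ", ncol(x$scores),
      " modules; PC1 variance explained: ",
      paste(sprintf("%s %.0f%%", colnames(x$scores), 100 * x$var_explained),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Concordance of expression and methylation regression statistics
#'
#' Joins per-gene Wald statistics from the expression regression with
#' per-gene moderated statistics from the gene-level methylation regression
#' (both `slope / se`) and reports their Spearman correlation.
#'
#' @param dgr a `dgr_result` from [fit_dgr()].
#' @param dmp_gene a gene-level `dmp_result` (from [fit_dmp()] on the
#'   [aggregate_gene_m()] matrix) or any data frame with columns `probe` (or
#'   `gene`) and a z-statistic column `t_mod` (or `wald_z`).
#' @return list with `table` (gene, z_expression, z_methylation), `rho`,
#'   `p`.
#' @export
concordance_z <- function(dgr, dmp_gene) {
  gene_col <- if ("gene" %in% names(dmp_gene)) "gene" else "probe"
  z_col <- if ("wald_z" %in% names(dmp_gene)) "wald_z" else "t_mod"
  tab <- merge(data.frame(gene = dgr$gene, z_expression = dgr$wald_z),
               data.frame(gene = dmp_gene[[gene_col]],
                          z_methylation = dmp_gene[[z_col]]),
               by = "gene")
  tab <- tab[stats::complete.cases(tab), ]
  if (nrow(tab) < 10) stop("fewer than 10 shared genes")
  ct <- suppressWarnings(
    stats::cor.test(tab$z_expression, tab$z_methylation, method = "spearman"))
  list(table = tab, rho = unname(ct$estimate), p = ct$p.value)
}

#' PCA on the most variable features
#'
#' Ranks features by variance, keeps the top `n_top`, and runs centred
#' (unscaled) PCA over samples. Optionally reports the Spearman correlation
#' of each PC with a supplied per-sample covariate (e.g. the CGC).
#'
#' @param mat features x samples numeric matrix.
#' @param n_top number of features to keep.
#' @param covariate optional per-sample numeric covariate.
#' @param n_loadings how many top-|loading| features to report per PC.
#' @return list with `scores` (samples x PCs), `loadings`, `var_explained`,
#'   `top_features` (per PC), `selected` (the retained feature ids) and,
#'   if a covariate was given, `cor_covariate` (Spearman rho per PC).
#' @export
pca_top_features <- function(mat, n_top, covariate = NULL, n_loadings = 50) {
  mat <- as.matrix(mat)
  if (n_top > nrow(mat)) stop("n_top exceeds the number of features")
  vars <- apply(mat, 1, stats::var)
  sel <- rownames(mat)[order(vars, decreasing = TRUE)[seq_len(n_top)]]
  pc <- stats::prcomp(t(mat[sel, , drop = FALSE]), center = TRUE, scale. = FALSE)
  top_feats <- apply(pc$rotation, 2, function(l)
    rownames(pc$rotation)[order(abs(l), decreasing = TRUE)[seq_len(min(n_loadings, length(l)))]],
    simplify = FALSE)
  out <- list(scores = pc$x, loadings = pc$rotation,
              var_explained = pc$sdev^2 / sum(pc$sdev^2),
              top_features = top_feats, selected = sel)
  if (!is.null(covariate)) {
    out$cor_covariate <- apply(pc$x, 2, function(s)
      suppressWarnings(stats::cor(s, covariate, method = "spearman")))
  }
  out
}
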