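#' Build a binned control-gene enrichment scorer
#'
#' Ranks all genes by mean expression across nuclei and partitions them into
#' `n_bins` contiguous rank bins of (near-)equal size; bin sizes differ by
#' at most one. Ties in mean expression are broken by gene id so that the
#' binning is stable across runs and nuclei orderings.
#'
#' @param expression genes x nuclei matrix of normalised expression values
#'   with gene row names.
#' @param n_bins number of expression bins.
#' @param controls_per_gene control genes drawn per query gene when scoring.
#' @param seed integer seed controlling the control-gene draws.
#' @return an `enrichment_scorer` object.
#' @export
build_scorer <- function(expression, n_bins = 30, controls_per_gene = 100, seed = 1) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression))) stop("expression must have gene row names")
  if (nrow(expression) < n_bins)
    stop("fewer genes (", nrow(expression), ") than bins (", n_bins, ")")
  means <- rowMeans(expression)
  ord <- order(means, rownames(expression))
  sizes <- rep(nrow(expression) %/% n_bins, n_bins)
  extra <- nrow(expression) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(nrow(expression))
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  names(bin) <- rownames(expression)
  structure(list(expression = expression, bins = bin, n_bins = n_bins,
                 controls_per_gene = controls_per_gene, seed = seed),
            class = "enrichment_scorer")
}

#' @export
print.enrichment_scorer <- function(x, ...) {
  cat("<enrichment_scorer> ", nrow(x$expression), " genes x ",
      ncol(x$expression), " nuclei; ", x$n_bins, " bins, ",
      x$controls_per_gene, " controls/gene\n", sep = "")
  invisible(x)
}

#' Per-nucleus enrichment score of a gene set
#'
#' For a gene set G, a reference multiset R is built by drawing
#' `controls_per_gene` genes from each query gene's expression bin (the gene
#' itself excluded; drawn without replacement when the bin is large enough,
#' with replacement otherwise), so that |R| = `controls_per_gene` x |G|.
#' The enrichment score of a nucleus is the difference in average
#' expression between G and R in that nucleus. Draws are seeded from the
#' scorer, so scores are reproducible.
#'
#' @param scorer an [build_scorer()] object.
#' @param genes character vector: the gene set G.
#' @return list with `scores` (named per-nucleus vector), `reference`
#'   (the control multiset) and `genes` (the query genes used).
#' @export
score_gene_set <- function(scorer, genes) {
  stopifnot(inherits(scorer, "enrichment_scorer"))
  genes <- intersect(unique(genes), rownames(scorer$expression))
  if (!length(genes)) stop("gene set is empty or disjoint from the matrix")
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(scorer$seed)
  by_bin <- split(names(scorer$bins), scorer$bins)
  ref <- unlist(lapply(genes, function(g) {
    pool <- setdiff(by_bin[[as.character(scorer$bins[g])]], g)
    sample(pool, scorer$controls_per_gene,
           replace = length(pool) < scorer$controls_per_gene)
  }), use.names = FALSE)
  sc <- colMeans(scorer$expression[genes, , drop = FALSE]) -
    colMeans(scorer$expression[ref, , drop = FALSE])
  list(scores = sc, reference = ref, genes = genes)
}
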