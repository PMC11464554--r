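#' Copy-number calling thresholds
#'
#' Log2-intensity cut-offs for per-bin event calling: gain/loss at +-0.10,
#' amplification at +0.35, homozygous deletion (HD) at -0.415, and the
#' 350 Mb cut above which a sample is categorised as having a high CNV load.
#'
#' @param gain,loss,amp,hd log2-intensity thresholds (hd < loss < 0 < gain < amp).
#' @param load_mb_cut CNV-load cut in megabases (strict ">").
#' @return a `cnv_thresholds` object.
#' @export
cnv_thresholds <- function(gain = 0.10, loss = -0.10, amp = 0.35, hd = -0.415,
                           load_mb_cut = 350) {
  if (!(hd < loss && loss < 0 && 0 < gain && gain < amp))
    stop("thresholds must satisfy hd < loss < 0 < gain < amp")
  structure(list(gain = gain, loss = loss, amp = amp, hd = hd,
                 load_mb_cut = load_mb_cut), class = "cnv_thresholds")
}

#' Call per-bin copy-number events
#'
#' Labels every (bin, sample) cell as one of HD / loss / neutral / gain /
#' amp: HD iff value <= hd threshold, else loss iff <= loss; amp iff
#' value >= amp threshold, else gain iff >= gain; neutral otherwise. NA
#' values yield NA labels.
#'
#' @param track a [cnv_bin_track()].
#' @param thresholds a [cnv_thresholds()] object.
#' @return character matrix (bins x samples) of labels.
#' @export
call_bin_events <- function(track, thresholds = cnv_thresholds()) {
  stopifnot(inherits(track, "cnv_bin_track"), inherits(thresholds, "cnv_thresholds"))
  v <- track$values
  lab <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  lab[!is.na(v)] <- "neutral"
  lab[!is.na(v) & v >= thresholds$gain] <- "gain"
  lab[!is.na(v) & v >= thresholds$amp] <- "amp"
  lab[!is.na(v) & v <= thresholds$loss] <- "loss"
  lab[!is.na(v) & v <= thresholds$hd] <- "HD"
  lab
}

#' Per-sample CNV load
#'
#' The CNV load is the total genomic extent (in Mb) of bins carrying any
#' non-neutral event (loss, gain, HD or amplification); samples exceeding
#' `load_mb_cut` (strictly) are categorised as high-load.
#'
#' @param track a [cnv_bin_track()].
#' @param thresholds a [cnv_thresholds()] object.
#' @return data frame: sample_id, load_mb, high_load.
#' @export
compute_cnv_load <- function(track, thresholds = cnv_thresholds()) {
  lab <- call_bin_events(track, thresholds)
  widths <- track$bins$end - track$bins$start
  flagged <- !is.na(lab) & lab != "neutral"
  load_mb <- colSums(flagged * widths) / 1e6
  data.frame(sample_id = colnames(track$values), load_mb = load_mb,
             high_load = load_mb > thresholds$load_mb_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan bins for association between event status and the CGC
#'
#' For every genomic bin, compares the CGC of event carriers against
#' non-carriers with a two-sided Mann-Whitney rank-sum test (exact when both
#' groups are small and untied, normal approximation with tie correction
#' otherwise). Events are amplifications (value >= amp threshold) in mode
#' `"amp"` and homozygous deletions (value <= hd threshold) in mode `"hd"`;
#' the two modes are scanned independently. Bins where either group has
#' fewer than `min_group` samples are untestable (NA) and excluded from the
#' BH FDR family. `signed_logp` follows the reporting convention
#' log10(p) for losses and -log10(p) for gains.
#'
#' @param track a [cnv_bin_track()].
#' @param cgc numeric CGC per sample aligned with the track columns, or a
#'   `cgc_result` matched by sample id.
#' @param mode `"amp"` or `"hd"`.
#' @param thresholds a [cnv_thresholds()] object.
#' @param min_group minimum carriers and non-carriers for a testable bin.
#' @return a `bin_association` data frame: bin coordinates, n_event,
#'   n_no_event, p, fdr, signed_logp.
#' @export
scan_bin_association <- function(track, cgc, mode = c("amp", "hd"),
                                 thresholds = cnv_thresholds(), min_group = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "cnv_bin_track"))
  if (is.data.frame(cgc) && "cgc" %in% names(cgc))
    cgc <- stats::setNames(cgc$cgc, cgc$sample_id)[colnames(track$values)]
  if (length(cgc) != ncol(track$values))
    stop("cgc must provide one value per track sample")
  v <- track$values
  carrier <- if (mode == "amp") v >= thresholds$amp else v <= thresholds$hd
  nb <- nrow(v)
  p <- rep(NA_real_, nb)
  n_event <- integer(nb); n_no <- integer(nb)
  for (i in seq_len(nb)) {
    ev <- carrier[i, ] & !is.na(carrier[i, ])
    ok <- !is.na(v[i, ]) & !is.na(cgc)
    a <- cgc[ev & ok]; b <- cgc[!ev & ok]
    n_event[i] <- length(a); n_no[i] <- length(b)
    if (length(a) >= min_group && length(b) >= min_group)
      p[i] <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  fdr <- rep(NA_real_, nb)
  tested <- !is.na(p)
  if (!any(tested)) stop("no bin testable: every bin has a group below min_group")
  fdr[tested] <- stats::p.adjust(p[tested], method = "BH")
  sign_dir <- if (mode == "hd") 1 else -1      # losses: log10(p); gains: -log10(p)
  out <- data.frame(track$bins,
                    n_event = n_event, n_no_event = n_no,
                    p = p, fdr = fdr, signed_logp = sign_dir * log10(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("bin_association", "data.frame")
  out
}

#' Event status of bins overlapping a gene interval
#'
#' Convenience wrapper for gene-level calls (e.g. CDKN2A/B HD, CDK4
#' amplification): a sample carries the event iff any bin overlapping the
#' interval carries it.
#'
#' @param track a [cnv_bin_track()].
#' @param chrom,start,end gene interval (0-based half-open, any chromosome
#'   naming convention).
#' @param mode `"amp"` or `"hd"`.
#' @param thresholds a [cnv_thresholds()] object.
#' @return named logical vector per sample.
#' @export
gene_event_status <- function(track, chrom, start, end, mode = c("amp", "hd"),
                              thresholds = cnv_thresholds()) {
  mode <- match.arg(mode)
  chrom <- normalize_chrom(chrom)
  hit <- track$bins$chrom == chrom & track$bins$start < end & track$bins$end > start
  if (!any(hit)) stop("no bins overlap ", chrom, ":", start, "-", end)
  v <- track$values[hit, , drop = FALSE]
  carrier <- if (mode == "amp") v >= thresholds$amp else v <= thresholds$hd
  apply(carrier, 2, any, na.rm = TRUE)
}
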