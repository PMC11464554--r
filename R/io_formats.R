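#' Normalise chromosome names to the "chr"-prefixed convention
#'
#' Accepts bare ("9", "X") or prefixed ("chr9") names and returns the
#' "chr"-prefixed form; sex chromosomes become "chrX"/"chrY". Used by every
#' reader so that joins across tables never fail on naming convention.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalised names.
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x[x %in% c("x", "X")] <- "X"
  x[x %in% c("y", "Y")] <- "Y"
  paste0("chr", x)
}

#' Read a calibrated classifier score table
#'
#' Reads the per-sample calibrated class-probability CSV emitted by the
#' CNS-tumour methylation classifier (one row per sample, one numeric column
#' per methylation class). The two astrocytoma grading classes
#' `A_IDH_HG` and `A_IDH_LG` must be present; all other class columns are
#' preserved untouched.
#'
#' @param path path to a CSV file. The sample identifier is taken from a
#'   column named `sample_id` (or `sample`), otherwise from the first column.
#' @param hg_col,lg_col names of the high-/low-grade calibrated score columns.
#'   Exposed because the exact header of the classifier export can vary
#'   between report versions.
#' @return a `calibrated_scores` data frame: `sample_id` plus one numeric
#'   column per class.
#' @export
read_calibrated_scores <- function(path, hg_col = "A_IDH_HG", lg_col = "A_IDH_LG") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  id_col <- intersect(c("sample_id", "sample"), names(df))
  id_col <- if (length(id_col)) id_col[1] else names(df)[1]
  ids <- as.character(df[[id_col]])
  score_cols <- setdiff(names(df), id_col)
  for (cls in c(hg_col, lg_col)) {
    if (!cls %in% score_cols)
      stop("calibrated score table lacks required class column '", cls, "'")
  }
  for (cls in score_cols) {
    v <- suppressWarnings(as.numeric(df[[cls]]))
    bad <- which(is.na(v) & !is.na(df[[cls]]) & df[[cls]] != "NA" & df[[cls]] != "")
    if (length(bad))
      stop("non-numeric score in column '", cls, "' at row ", bad[1])
    df[[cls]] <- v
  }
  out <- data.frame(sample_id = ids, df[score_cols],
                    check.names = FALSE, stringsAsFactors = FALSE)
  validate_calibrated_scores(out, hg_col = hg_col, lg_col = lg_col)
}

#' @rdname read_calibrated_scores
#' @param x a data frame with `sample_id` and numeric class-score columns.
#' @export
validate_calibrated_scores <- function(x, hg_col = "A_IDH_HG", lg_col = "A_IDH_LG") {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  for (cls in c(hg_col, lg_col))
    if (!cls %in% names(x))
      stop("calibrated score table lacks required class column '", cls, "'")
  num <- setdiff(names(x), "sample_id")
  for (cls in num) {
    v <- x[[cls]]
    if (!is.numeric(v)) stop("score column '", cls, "' is not numeric")
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("scores in column '", cls, "' outside [0, 1]")
  }
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id in calibrated score table")
  class(x) <- c("calibrated_scores", "data.frame")
  x
}

#' @rdname read_calibrated_scores
#' @export
write_calibrated_scores <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read per-bin copy-number log2-intensity tracks
#'
#' Reads one or more tab-separated IGV-dialect bin tracks (columns
#' chromosome, start, end, feature, then one numeric column per sample) and
#' merges them over the union of samples. All files must share the same bin
#' grid; bins are 0-based half-open and kept in file order. Chromosome names
#' are normalised via [normalize_chrom()].
#'
#' @param paths character vector of file paths.
#' @return a `cnv_bin_track`: list with `bins` (data frame chrom/start/end)
#'   and `values` (bins x samples numeric matrix).
#' @export
read_cnv_bins_igv <- function(paths) {
  tracks <- lapply(paths, function(p) {
    df <- utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 5)
      stop("malformed bins.igv file '", p, "': fewer than 5 columns")
    bins <- data.frame(chrom = normalize_chrom(df[[1]]),
                       start = as.numeric(df[[2]]),
                       end   = as.numeric(df[[3]]),
                       stringsAsFactors = FALSE)
    bad <- which(is.na(bins$start) | is.na(bins$end))
    if (length(bad))
      stop("malformed row in '", p, "' at line ", bad[1] + 1L)
    vals <- as.matrix(df[, -(1:4), drop = FALSE])
    storage.mode(vals) <- "double"
    list(bins = bins, values = vals)
  })
  ref <- tracks[[1]]$bins
  for (i in seq_along(tracks)[-1]) {
    b <- tracks[[i]]$bins
    if (nrow(b) != nrow(ref))
      stop("bin grid mismatch: '", paths[i], "' has ", nrow(b),
           " bins, expected ", nrow(ref))
    mism <- which(b$chrom != ref$chrom | b$start != ref$start | b$end != ref$end)
    if (length(mism))
      stop("bin grid mismatch in '", paths[i], "' at bin ", mism[1], " (",
           b$chrom[mism[1]], ":", b$start[mism[1]], "-", b$end[mism[1]], ")")
  }
  values <- do.call(cbind, lapply(tracks, `[[`, "values"))
  cnv_bin_track(ref, values)
}

#' @rdname read_cnv_bins_igv
#' @param bins data frame with columns chrom, start, end.
#' @param values numeric matrix, one row per bin, one column per sample.
#' @export
cnv_bin_track <- function(bins, values) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  values <- as.matrix(values)
  if (nrow(values) != nrow(bins))
    stop("values must have one row per bin")
  if (any(bins$end <= bins$start))
    stop("every bin must satisfy end > start")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping bins on ", ch)
  }
  structure(list(bins = bins, values = values), class = "cnv_bin_track")
}

#' @rdname read_cnv_bins_igv
#' @param x a `cnv_bin_track`.
#' @param path output path.
#' @export
write_cnv_bins_igv <- function(x, path) {
  stopifnot(inherits(x, "cnv_bin_track"))
  df <- data.frame(chromosome = x$bins$chrom, start = x$bins$start,
                   end = x$bins$end, feature = "bin",
                   x$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.cnv_bin_track <- function(x, ...) {
  cat("<cnv_bin_track> ", nrow(x$bins), " bins x ", ncol(x$values),
      " samples (", length(unique(x$bins$chrom)), " chromosomes)\n", sep = "")
  invisible(x)
}

#' Read a feature-by-sample matrix with a matching annotation table
#'
#' Both inputs are TSV; the first column of each is the feature identifier.
#' Features are restricted to those present in both tables and returned in
#' annotation order (deterministic regardless of matrix row order).
#'
#' @param path TSV matrix, features x samples, first column = feature id.
#' @param annotation_path TSV annotation keyed by feature id (first column).
#' @return list with `matrix`, `annotation` and `n_dropped` (features present
#'   in the matrix but absent from the annotation, or vice versa).
#' @export
read_annotated_matrix <- function(path, annotation_path) {
  m <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann <- utils::read.delim(annotation_path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(m[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in matrix: '", ids[duplicated(ids)][1], "'")
  aid <- as.character(ann[[1]])
  if (anyDuplicated(aid))
    stop("duplicate feature id in annotation: '", aid[duplicated(aid)][1], "'")
  keep <- aid[aid %in% ids]
  if (!length(keep))
    stop("no overlapping features between matrix and annotation")
  mat <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat <- mat[keep, , drop = FALSE]
  ann2 <- ann[match(keep, aid), , drop = FALSE]
  rownames(ann2) <- keep
  n_dropped <- (length(ids) - length(keep)) + (length(aid) - length(keep))
  list(matrix = mat, annotation = ann2, n_dropped = n_dropped)
}

#' @rdname read_annotated_matrix
#' @param mat numeric matrix with feature row names.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a clinical/survival table
#'
#' TSV with at least `sample_id`, `os_time` (years) and `os_event` (0/1);
#' remaining columns are carried along as covariates.
#'
#' @param path TSV path.
#' @return a validated `clinical_table` data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param x data frame to validate.
#' @export
validate_clinical <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(x$os_time < 0, na.rm = TRUE)) stop("os_time must be >= 0")
  if (!all(x$os_event %in% c(0, 1, NA))) stop("os_event must be 0/1")
  class(x) <- c("clinical_table", "data.frame")
  x
}

#' @rdname read_clinical
#' @export
write_clinical <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
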