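#' Compute the continuous grading coefficient (CGC)
#'
#' The CGC is the natural log-ratio of the calibrated classifier
#' probabilities for the high-grade versus low-grade IDH-mutant astrocytoma
#' methylation classes:
#' \deqn{CGC = \ln(\mathrm{cal}_{HG} / \mathrm{cal}_{LG})}
#' Calibrated scores are clamped into `[clamp_eps, 1 - clamp_eps]` before the
#' ratio so that scores of exactly 0 or 1 yield finite coefficients.
#'
#' @param scores a `calibrated_scores` table (see [read_calibrated_scores()]).
#' @param clamp_eps clamping bound, in (0, 0.5).
#' @param hg_col,lg_col column names of the high-/low-grade calibrated scores.
#' @return a `cgc_result` data frame: `sample_id`, `cgc`, `subgroup` (NA
#'   until [assign_subgroups()] is applied).
#' @seealso [derive_cutoffs()], [assign_subgroups()]
#' @export
compute_cgc <- function(scores, clamp_eps = 1e-6,
                        hg_col = "A_IDH_HG", lg_col = "A_IDH_LG") {
  stopifnot(is.data.frame(scores), clamp_eps > 0, clamp_eps < 0.5)
  for (cls in c(hg_col, lg_col))
    if (!cls %in% names(scores))
      stop("scores table lacks class column '", cls, "'")
  hg <- scores[[hg_col]]
  lg <- scores[[lg_col]]
  miss <- which(is.na(hg) | is.na(lg))
  if (length(miss))
    stop("missing class score for sample '", scores$sample_id[miss[1]], "'")
  clamp <- function(x) pmin(pmax(x, clamp_eps), 1 - clamp_eps)
  out <- data.frame(sample_id = scores$sample_id,
                    cgc = log(clamp(hg) / clamp(lg)),
                    subgroup = factor(NA, levels = c("low", "medium", "high")),
                    stringsAsFactors = FALSE)
  class(out) <- c("cgc_result", "data.frame")
  out
}

#' Published default CGC cut-offs
#'
#' Subgroup boundaries for the CGC: low below -4.5, high above +4.5, medium
#' in between (boundaries inclusive to medium). These are the cohort-derived
#' values shipped as the default so that derived cut-offs never silently
#' replace them.
#'
#' @param low_cut,high_cut boundaries on the CGC scale.
#' @param central_mass fraction of the total cumulative rate of change of the
#'   calibrated high-grade score assigned to the medium interval.
#' @param provenance `"published-default"` or `"derived"`.
#' @return a `cgc_cutoffs` object.
#' @export
cgc_cutoffs <- function(low_cut = -4.5, high_cut = 4.5, central_mass = 0.95,
                        provenance = "published-default") {
  stopifnot(low_cut < high_cut, central_mass > 0, central_mass < 1)
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 central_mass = central_mass, provenance = provenance),
            class = "cgc_cutoffs")
}

#' @export
print.cgc_cutoffs <- function(x, ...) {
  cat(sprintf("CGC cut-offs [%s]: low < %.4g, medium [%.4g, %.4g], high > %.4g (central mass %.1f%%)\n",
              x$provenance, x$low_cut, x$low_cut, x$high_cut, x$high_cut,
              100 * x$central_mass))
  invisible(x)
}

#' Derive CGC subgroup cut-points from the calibrated-score curve
#'
#' Reconstructs the unsupervised cut-point procedure: the calibrated
#' high-grade score is a monotone function of the CGC, and the medium-grade
#' interval is chosen to contain `central_mass` (default 95%) of the total
#' cumulative rate of change of that score per unit CGC.
#'
#' The monotone curve `f(cgc)` is estimated by isotonic regression of
#' `cal_hg` on `cgc`, interpolated piecewise-linearly onto a uniform grid of
#' `grid_size` points. Since the integral of the rate f' is f itself, the
#' normalised cumulative rate is `F(x) = (f(x) - f(min)) / (f(max) - f(min))`;
#' the low cut-off is the smallest grid point with
#' `F >= (1 - central_mass)/2` and the high cut-off the smallest with
#' `F >= 1 - (1 - central_mass)/2`, so the medium interval carries exactly
#' the central mass (up to grid resolution).
#'
#' @param cgc numeric vector of CGC values.
#' @param cal_hg paired calibrated high-grade scores, in `[0, 1]`.
#' @param central_mass central fraction of the cumulative rate, in (0, 1).
#' @param grid_size number of uniform grid points.
#' @return a `cgc_cutoffs` object with provenance `"derived"`; the fitted
#'   grid (`grid`, `f`, `F`) is attached as attribute `"curve"`.
#' @export
derive_cutoffs <- function(cgc, cal_hg, central_mass = 0.95, grid_size = 1001) {
  stopifnot(length(cgc) == length(cal_hg), central_mass > 0, central_mass < 1,
            grid_size >= 10)
  ok <- is.finite(cgc) & is.finite(cal_hg)
  cgc <- cgc[ok]; cal_hg <- cal_hg[ok]
  if (length(cgc) < 20)
    stop("need at least 20 paired observations to derive cut-offs")
  if (any(cal_hg < 0 | cal_hg > 1))
    stop("cal_hg must lie in [0, 1]")
  # average replicated x before PAVA so interpolation is single-valued
  ux <- sort(unique(cgc))
  uy <- vapply(split(cal_hg, factor(match(cgc, ux), levels = seq_along(ux))),
               mean, numeric(1))
  iso <- stats::isoreg(ux, uy)
  grid <- seq(min(ux), max(ux), length.out = grid_size)
  f <- if (length(ux) == 1) rep(iso$yf, grid_size) else
    stats::approx(ux, iso$yf, xout = grid, rule = 2)$y
  total <- f[grid_size] - f[1]
  if (total <= 0)
    stop("degenerate calibration curve: calibrated score does not increase over the CGC range")
  Fcum <- (f - f[1]) / total
  tail_mass <- (1 - central_mass) / 2
  low_cut <- grid[which(Fcum >= tail_mass)[1]]
  high_cut <- grid[which(Fcum >= 1 - tail_mass)[1]]
  out <- cgc_cutoffs(low_cut, high_cut, central_mass, provenance = "derived")
  attr(out, "curve") <- list(grid = grid, f = f, F = Fcum)
  out
}

#' Assign CGC subgroups
#'
#' Labels each sample low / medium / high relative to a [cgc_cutoffs()]
#' object: low iff cgc < low_cut, high iff cgc > high_cut, medium otherwise
#' (both boundaries belong to medium).
#'
#' @param cgc a `cgc_result` data frame from [compute_cgc()], or a numeric
#'   vector of CGC values.
#' @param cutoffs a `cgc_cutoffs` object; defaults to the published pair.
#' @return the input with `subgroup` filled (a factor low/medium/high), or a
#'   factor if `cgc` was a bare vector.
#' @export
assign_subgroups <- function(cgc, cutoffs = cgc_cutoffs()) {
  stopifnot(inherits(cutoffs, "cgc_cutoffs"))
  vals <- if (is.data.frame(cgc)) cgc$cgc else cgc
  if (any(!is.finite(vals)))
    stop("CGC values must be finite")
  sub <- factor(ifelse(vals < cutoffs$low_cut, "low",
                ifelse(vals > cutoffs$high_cut, "high", "medium")),
                levels = c("low", "medium", "high"))
  if (is.data.frame(cgc)) {
    cgc$subgroup <- sub
    attr(cgc, "cutoffs") <- cutoffs
    cgc
  } else sub
}

#' @export
print.cgc_result <- function(x, ...) {
  cat("<cgc_result> ", nrow(x), " samples; CGC range [",
      sprintf("%.3g", min(x$cgc)), ", ", sprintf("%.3g", max(x$cgc)), "]\n", sep = "")
  if (!all(is.na(x$subgroup)))
    print(table(x$subgroup))
  invisible(x)
}
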