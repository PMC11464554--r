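#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. The defaults emulate the
#' statistical structure the grading analysis assumes: a bimodal latent
#' malignancy gradient, a sigmoidal calibrated high-grade score, ~8% of
#' probes differentially methylated (99% hypomethylating in the open sea,
#' 1% hypermethylating on CpG islands), four NB-count gene modules (one
#' down-, three up-regulated with malignancy, sized as the reported C0-C3
#' clusters), a focal homozygous deletion on chr9 and a focal amplification
#' on chr12 whose carrier probability rises with malignancy, proportional-
#' hazards survival with ~40% censoring, and a small single-nucleus matrix
#' with one population enriched for the cycling (C1) module.
#'
#' @param n_samples,n_probes,n_genes,n_bins,n_nuclei cohort dimensions.
#' @param seed integer seed; each sub-generator draws from its own stream
#'   derived from it, so the cohort is byte-identical under a fixed seed.
#' @param malignancy_spread half-distance between the two latent Gaussian
#'   modes (low-grade at -spread, high-grade at +spread, unit SD each).
#' @param calibration_slope steepness of the default logistic calibration
#'   `P(high grade) = plogis(calibration_slope * latent)`; the default (2)
#'   gives a saturating calibrated-score curve with the CGC spanning
#'   roughly +-9, comfortably inside the clamp bound of the log-odds
#'   transform so the CGC remains a linear readout of the gradient.
#' @param calibration_noise_sd logit-scale noise on the calibrated score.
#' @param other_class_mass probability mass assigned to non-astrocytoma
#'   classifier classes.
#' @param frac_affected_probes fraction of probes with a planted
#'   methylation slope; `frac_hyper` of those hypermethylate (islands), the
#'   rest hypomethylate (open sea).
#' @param hypo_slope,hyper_slope planted M-value slopes per CGC unit (the
#'   CGC-scale gradient is `calibration_slope * latent`).
#' @param meth_noise_sd residual SD of M-values.
#' @param module_sizes,module_slopes named (C0..C3) module gene counts and
#'   planted log2 count slopes per CGC unit.
#' @param module_factor_sd SD (log2 units) of the per-module latent factor
#'   shared by a module's genes on top of the malignancy gradient
#'   (co-regulation orthogonal to the gradient). Larger values make the
#'   modules more separable by correlation clustering but push the counts
#'   away from the negative-binomial sampling model; the default keeps the
#'   NB Wald standard errors calibrated.
#' @param nb_dispersion NB dispersion (1/size) of the counts.
#' @param hd_depth,amp_depth log2 shift of the planted focal events.
#' @param hd_locus_bins,amp_locus_bins width of the planted loci, in bins.
#' @param event_logit_base,event_logit_slope carrier probability of the
#'   planted events is `plogis(base + slope * latent)`.
#' @param cnv_noise_sd per-bin log2 noise SD.
#' @param sporadic_rate,sporadic_len,sporadic_mag Poisson rate, mean length
#'   (bins) and |log2| magnitude of malignancy-independent background
#'   gain/loss segments.
#' @param base_median_os median overall survival (years) of the low
#'   subgroup; `subgroup_log_hr` is the planted log hazard ratio per CGC
#'   subgroup step (low -> medium -> high).
#' @param censor_frac target censoring fraction.
#' @param snrna_c1_shift expression shift of C1 genes in the cycling
#'   nucleus population.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 200, n_probes = 5000, n_genes = 2000,
                          n_bins = 2000, n_nuclei = 300, seed = 1,
                          malignancy_spread = 2,
                          calibration_slope = 2,
                          calibration_noise_sd = 0,
                          other_class_mass = 0.02,
                          frac_affected_probes = 0.08,
                          frac_hyper = 0.01,
                          hypo_slope = -0.8, hyper_slope = 0.8,
                          meth_noise_sd = 0.5,
                          module_sizes = c(C0 = 149, C1 = 175, C2 = 176, C3 = 97),
                          module_slopes = c(C0 = -0.7, C1 = 0.7, C2 = 0.8, C3 = 0.9),
                          module_factor_sd = 1.5,
                          nb_dispersion = 0.1,
                          hd_depth = -0.8, amp_depth = 0.6,
                          hd_locus_bins = 20, amp_locus_bins = 20,
                          event_logit_base = -0.5, event_logit_slope = 0.8,
                          cnv_noise_sd = 0.08,
                          sporadic_rate = 2, sporadic_len = 10, sporadic_mag = 0.22,
                          base_median_os = 8, subgroup_log_hr = log(2),
                          censor_frac = 0.4,
                          snrna_c1_shift = 1.5) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_samples, cfg$n_probes, cfg$n_genes, cfg$n_bins, cfg$n_nuclei)
  if (any(counts < 1)) stop("all cohort dimensions must be >= 1")
  fracs <- c(cfg$frac_affected_probes, cfg$frac_hyper, cfg$censor_frac,
             cfg$other_class_mass)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("module sizes exceed n_genes")
  if (!identical(names(cfg$module_sizes), names(cfg$module_slopes)))
    stop("module_sizes and module_slopes must share names")
  structure(cfg, class = "cohort_config")
}

#' Generate a calibrated classifier score table
#'
#' Draws latent malignancy from a two-component Gaussian mixture (so the
#' low- and high-grade modes the classifier implies are both populated) and
#' maps it through a monotone calibration curve (default logistic) to the
#' calibrated high-grade probability; logit-scale noise emulates
#' calibration error. The remaining probability mass (minus a small
#' "other classes" share) goes to the low-grade class, so the CGC computed
#' downstream is a noisy monotone transform of the latent value.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param calibration monotone non-decreasing function latent -> P(high
#'   grade); checked on a grid, non-monotone specs are rejected. Default:
#'   logistic with steepness `cal_slope`.
#' @param cal_slope steepness of the default logistic calibration.
#' @param spread,noise_sd,other_mass see [cohort_config()].
#' @return list with `scores` (a `calibrated_scores` table) and `latent`
#'   (named numeric vector, the ground truth).
#' @export
generate_calibrated_scores <- function(n, seed, calibration = NULL,
                                       cal_slope = 2, spread = 2, noise_sd = 0,
                                       other_mass = 0.02) {
  if (is.null(calibration))
    calibration <- function(x) stats::plogis(cal_slope * x)
  set.seed(seed)
  comp <- stats::rbinom(n, 1, 0.5)
  latent <- stats::rnorm(n, mean = ifelse(comp == 1, spread, -spread), sd = 1)
  grid <- seq(min(latent), max(latent), length.out = 201)
  pg <- calibration(grid)
  if (any(diff(pg) < -1e-12)) stop("calibration curve is not monotone non-decreasing")
  p <- calibration(latent)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  if (noise_sd > 0)
    p <- stats::plogis(stats::qlogis(p) + stats::rnorm(n, sd = noise_sd))
  ids <- sprintf("S%04d", seq_len(n))
  scores <- data.frame(sample_id = ids,
                       A_IDH_HG = p * (1 - other_mass),
                       A_IDH_LG = (1 - p) * (1 - other_mass),
                       O_IDH = rep(other_mass / 2, n),
                       OLIGOSARC_IDH = rep(other_mass / 2, n),
                       stringsAsFactors = FALSE)
  scores <- validate_calibrated_scores(scores)
  names(latent) <- ids
  list(scores = scores, latent = latent)
}

# Gene universe shared between methylation and expression generators.
gene_universe <- function(n_genes) sprintf("GENE%05d", seq_len(n_genes))

#' Generate synthetic expression counts with planted gene modules
#'
#' NB-distributed counts whose log2 mean shifts linearly with the latent
#' malignancy for genes in the planted modules; module genes are correlated
#' through the shared latent gradient, which is what the recursive
#' correlation clustering later recovers. A tenth of genes are lowly
#' expressed and a twentieth carry a non-retained gene type, so the
#' filtering rules have work to do.
#'
#' @param latent named latent-malignancy vector (defines the samples).
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return list with `data` (an [expression_data()]), `truth` (gene_id,
#'   module, slope) and `size_factors` used in generation.
#' @export
generate_expression <- function(latent, config = cohort_config(), seed = config$seed + 1L) {
  set.seed(seed)
  ng <- config$n_genes; n <- length(latent)
  ids <- gene_universe(ng)
  gene_type <- sample(c("protein_coding", "lncRNA", "miRNA"), ng,
                      replace = TRUE, prob = c(0.85, 0.10, 0.05))
  mu <- 2^stats::rnorm(ng, mean = 5, sd = 1.5)
  low <- sample(ng, round(0.1 * ng))
  mu[low] <- stats::runif(length(low), 0.2, 2)
  slope <- rep(0, ng)
  module <- rep(NA_character_, ng)
  eligible <- which(gene_type %in% c("protein_coding", "lncRNA") & mu >= 8)
  if (length(eligible) < sum(config$module_sizes))
    stop("not enough well-expressed genes to place the modules")
  pool <- sample(eligible)
  at <- 0
  for (m in names(config$module_sizes)) {
    idx <- pool[at + seq_len(config$module_sizes[[m]])]
    at <- at + config$module_sizes[[m]]
    module[idx] <- m
    slope[idx] <- config$module_slopes[[m]]
  }
  sf <- exp(stats::rnorm(n, sd = 0.2))
  g <- config$calibration_slope * latent    # latent gradient in CGC units
  logmu <- outer(log2(mu), rep(1, n)) + outer(slope, g)
  for (m in names(config$module_sizes)) {
    # co-regulation orthogonal to the malignancy gradient, so the planted
    # per-CGC-unit slopes stay identifiable
    f_m <- stats::rnorm(n, sd = config$module_factor_sd)
    f_m <- stats::residuals(stats::lm(f_m ~ g))
    idx <- which(!is.na(module) & module == m)
    logmu[idx, ] <- logmu[idx, ] + rep(f_m, each = length(idx))
  }
  mumat <- 2^logmu * rep(sf, each = ng)
  counts <- matrix(stats::rnbinom(ng * n, mu = mumat, size = 1 / config$nb_dispersion),
                   ng, n, dimnames = list(ids, names(latent)))
  ann <- data.frame(gene_id = ids, symbol = ids, gene_type = gene_type,
                    stringsAsFactors = FALSE)
  list(data = expression_data(counts, ann),
       truth = data.frame(gene_id = ids, module = module, slope = slope,
                          base_mean = mu, stringsAsFactors = FALSE),
       size_factors = sf)
}

#' Generate synthetic methylation betas with planted context structure
#'
#' Probes get a CpG context (EPIC-like proportions), a chromosome (a small
#' share on chrX/chrY) and gene annotations from the shared gene universe;
#' 5% carry no gene annotation. Of the affected probes, `frac_hyper`
#' (default 1%) hypermethylate and sit on CpG islands — annotated to the C2
#' module genes so the methylation/expression concordance has shared signal
#' — and the rest hypomethylate in the open sea, mirroring the global
#' demethylation with focal island hypermethylation that accompanies
#' malignant progression. M-values are Gaussian around a context baseline
#' plus `slope * latent`; betas are their inverse-logit, hence in (0, 1).
#'
#' @inheritParams generate_expression
#' @param expr_truth the `truth` table from [generate_expression()] (used
#'   to annotate hypermethylated probes with C2 genes); optional.
#' @return list with `data` (a [methylation_data()] on the beta scale) and
#'   `truth` (probe_id, context, slope).
#' @export
generate_methylation <- function(latent, config = cohort_config(),
                                 seed = config$seed + 2L, expr_truth = NULL) {
  set.seed(seed)
  np <- config$n_probes; n <- length(latent)
  ids <- sprintf("cg%07d", seq_len(np))
  ctx <- sample(c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea"),
                np, replace = TRUE, prob = c(0.31, 0.12, 0.11, 0.05, 0.05, 0.36))
  chrom <- sample(paste0("chr", 1:22), np, replace = TRUE)
  sex <- sample(np, round(0.03 * np))
  chrom[sex] <- sample(c("chrX", "chrY"), length(sex), replace = TRUE)
  genes <- gene_universe(config$n_genes)
  gene_symbols <- vapply(seq_len(np), function(i) {
    k <- sample(1:2, 1, prob = c(0.8, 0.2))
    paste(sample(genes, k), collapse = ";")
  }, character(1))
  gene_symbols[sample(np, round(0.05 * np))] <- ""
  region <- sample(c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR"),
                   np, replace = TRUE, prob = c(0.1, 0.1, 0.08, 0.07, 0.5, 0.15))
  base <- c(Island = -3, N_Shore = -1, S_Shore = -1,
            N_Shelf = 0.5, S_Shelf = 0.5, OpenSea = 1.5)[ctx] +
    stats::rnorm(np, sd = 0.7)

  plantable <- chrom %in% paste0("chr", 1:22) & gene_symbols != ""
  n_aff <- round(config$frac_affected_probes * np)
  n_hyper <- max(1L, round(config$frac_hyper * n_aff))
  hyper_idx <- sample(which(plantable & ctx == "Island"), n_hyper)
  hypo_idx <- sample(setdiff(which(plantable & ctx == "OpenSea"), hyper_idx),
                     n_aff - n_hyper)
  slope <- rep(0, np)
  slope[hyper_idx] <- config$hyper_slope
  slope[hypo_idx] <- config$hypo_slope
  if (!is.null(expr_truth)) {
    c2 <- expr_truth$gene_id[!is.na(expr_truth$module) & expr_truth$module == "C2"]
    if (length(c2))
      gene_symbols[hyper_idx] <- sample(c2, length(hyper_idx), replace = TRUE)
  }
  g <- config$calibration_slope * latent    # latent gradient in CGC units
  m <- outer(base, rep(1, n)) + outer(slope, g) +
    matrix(stats::rnorm(np * n, sd = config$meth_noise_sd), np, n)
  beta <- m_to_beta(m)
  dimnames(beta) <- list(ids, names(latent))
  ann <- data.frame(probe_id = ids, chrom = chrom,
                    pos = sample.int(2e8, np, replace = TRUE),
                    cpg_context = ctx, gene_region = region,
                    gene_symbols = gene_symbols, stringsAsFactors = FALSE)
  list(data = methylation_data(beta, ann, scale = "beta"),
       truth = data.frame(probe_id = ids, context = ctx, slope = slope,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic CNV bin track with planted focal events
#'
#' A 50,000-bp bin grid over chr1-chr22 with Gaussian log2 noise, sporadic
#' malignancy-independent gain/loss segments below the amp/HD thresholds,
#' and two planted focal events whose carrier probability increases with
#' latent malignancy: a homozygous deletion on chr9 (CDKN2A/B-like) and an
#' amplification on chr12 (CDK4-like).
#'
#' @inheritParams generate_expression
#' @return list with `track` (a [cnv_bin_track()]) and `truth` (planted bin
#'   indices, depths and per-sample carrier status).
#' @export
generate_cnv <- function(latent, config = cohort_config(), seed = config$seed + 3L) {
  set.seed(seed)
  nb <- config$n_bins; n <- length(latent)
  per_chr <- diff(round(seq(0, nb, length.out = 23)))
  chrom <- rep(paste0("chr", 1:22), per_chr)
  start <- unlist(lapply(per_chr, function(k) (seq_len(k) - 1) * 50000))
  bins <- data.frame(chrom = chrom, start = start, end = start + 50000,
                     stringsAsFactors = FALSE)
  values <- matrix(stats::rnorm(nb * n, sd = config$cnv_noise_sd), nb, n,
                   dimnames = list(NULL, names(latent)))
  # sporadic background segments (gain/loss range, never amp/HD)
  for (j in seq_len(n)) {
    for (s in seq_len(stats::rpois(1, config$sporadic_rate))) {
      len <- 1 + stats::rgeom(1, 1 / config$sporadic_len)
      st <- sample(nb - len, 1)
      values[st:(st + len - 1), j] <- values[st:(st + len - 1), j] +
        sample(c(-1, 1), 1) * config$sporadic_mag
    }
  }
  place_locus <- function(chr, width) {
    idx <- which(bins$chrom == chr)
    st <- idx[1] + (length(idx) - width) %/% 2
    st:(st + width - 1)
  }
  hd_bins <- place_locus("chr9", config$hd_locus_bins)
  amp_bins <- place_locus("chr12", config$amp_locus_bins)
  p_event <- stats::plogis(config$event_logit_base + config$event_logit_slope * latent)
  hd_carrier <- stats::rbinom(n, 1, p_event) == 1
  amp_carrier <- stats::rbinom(n, 1, p_event) == 1
  values[hd_bins, hd_carrier] <- values[hd_bins, hd_carrier] + config$hd_depth
  values[amp_bins, amp_carrier] <- values[amp_bins, amp_carrier] + config$amp_depth
  list(track = cnv_bin_track(bins, values),
       truth = list(hd_bins = hd_bins, amp_bins = amp_bins,
                    hd_depth = config$hd_depth, amp_depth = config$amp_depth,
                    hd_carrier = stats::setNames(hd_carrier, names(latent)),
                    amp_carrier = stats::setNames(amp_carrier, names(latent))))
}

#' Generate synthetic survival data under proportional hazards
#'
#' Exponential event times whose log hazard increases by `subgroup_log_hr`
#' per CGC subgroup step (low -> medium -> high, subgroups from the
#' published cut-offs), with independent exponential censoring whose rate
#' is tuned to the target censoring fraction. Clinical covariates (age,
#' sex, CDKN2A/B HD from the CNV truth, necrosis/MVP and treatment arm)
#' are included so multivariable models can be exercised.
#'
#' @inheritParams generate_expression
#' @param cgc a `cgc_result` for the same samples (used for the subgroup
#'   step).
#' @param cnv_truth optional `truth` element of [generate_cnv()].
#' @return list with `clinical` (a `clinical_table`) and `truth`
#'   (per-sample subgroup step, rates, planted log HR).
#' @export
generate_survival <- function(latent, cgc, config = cohort_config(),
                              seed = config$seed + 4L, cnv_truth = NULL) {
  set.seed(seed)
  n <- length(latent)
  sub <- assign_subgroups(cgc)$subgroup
  step <- as.integer(sub) - 1L
  rate <- log(2) / config$base_median_os * exp(config$subgroup_log_hr * step)
  t_event <- stats::rexp(n, rate)
  # with exponential censoring, P(censored | rate_i) = rc / (rc + rate_i);
  # solve for rc so the cohort-average censoring hits the target exactly
  cens_rate <- stats::uniroot(
    function(log_rc) mean(exp(log_rc) / (exp(log_rc) + rate)) - config$censor_frac,
    interval = log(c(1e-8, 1e4) * mean(rate)), tol = 1e-10)$root
  cens_rate <- exp(cens_rate)
  t_cens <- stats::rexp(n, cens_rate)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  hd <- if (!is.null(cnv_truth)) as.integer(cnv_truth$hd_carrier)
        else stats::rbinom(n, 1, 0.2)
  clinical <- data.frame(
    sample_id = names(latent),
    os_time = os_time, os_event = os_event,
    age = round(pmax(18, stats::rnorm(n, 40, 12))),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cdkn2ab_hd = hd,
    necrosis_mvp = stats::rbinom(n, 1, stats::plogis(-1 + 0.5 * latent)),
    treatment_rt_tmz = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE)
  list(clinical = validate_clinical(clinical),
       truth = list(step = stats::setNames(step, names(latent)),
                    log_hr_per_step = config$subgroup_log_hr,
                    event_rate = rate, censor_rate = cens_rate))
}

#' Generate a synthetic single-nucleus expression matrix
#'
#' Normalised (real-valued) expression for a subset of the gene universe
#' across five labelled nucleus populations; the cycling-tumour population
#' over-expresses the C1 module genes by `snrna_c1_shift`, so enrichment
#' scoring can recover it.
#'
#' @inheritParams generate_expression
#' @param expr_truth `truth` table from [generate_expression()].
#' @return list with `mat` (genes x nuclei), `cell_type` (factor per
#'   nucleus) and `truth` (the enriched population and gene set).
#' @export
generate_snrna <- function(config = cohort_config(), expr_truth,
                           seed = config$seed + 5L) {
  set.seed(seed)
  nn <- config$n_nuclei
  c1 <- expr_truth$gene_id[!is.na(expr_truth$module) & expr_truth$module == "C1"]
  genes <- union(c1, sample(expr_truth$gene_id, min(1500, nrow(expr_truth))))
  types <- c("astro_like", "cycling_tumour", "oligo_like", "neuron", "endothelial")
  cell_type <- factor(sample(types, nn, replace = TRUE,
                             prob = c(0.35, 0.2, 0.2, 0.15, 0.1)), levels = types)
  base <- stats::rnorm(length(genes), mean = 2, sd = 1)
  mat <- matrix(stats::rnorm(length(genes) * nn, mean = base, sd = 0.4),
                length(genes), nn, dimnames = list(genes, sprintf("N%04d", seq_len(nn))))
  mat[c1, cell_type == "cycling_tumour"] <-
    mat[c1, cell_type == "cycling_tumour"] + config$snrna_c1_shift
  list(mat = mat, cell_type = cell_type,
       truth = list(enriched_type = "cycling_tumour", gene_set = c1))
}

#' Generate a full synthetic cohort
#'
#' Runs every sub-generator from its own seed stream (derived from
#' `config$seed` by fixed offsets, so the cohort is invariant to the order
#' in which components are consumed) and bundles the tables with a
#' ground-truth ledger sufficient to score recovery of every planted
#' effect.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: `latent`, `scores`, `cgc`,
#'   `methylation`, `expression`, `cnv`, `clinical`, `snrna`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cal <- generate_calibrated_scores(config$n_samples, config$seed,
                                    cal_slope = config$calibration_slope,
                                    spread = config$malignancy_spread,
                                    noise_sd = config$calibration_noise_sd,
                                    other_mass = config$other_class_mass)
  expr <- generate_expression(cal$latent, config)
  meth <- generate_methylation(cal$latent, config, expr_truth = expr$truth)
  cnv <- generate_cnv(cal$latent, config)
  cgc <- compute_cgc(cal$scores)
  surv <- generate_survival(cal$latent, cgc, config, cnv_truth = cnv$truth)
  sn <- generate_snrna(config, expr$truth)
  structure(list(
    latent = cal$latent, scores = cal$scores,
    cgc = assign_subgroups(cgc),
    methylation = meth$data, expression = expr$data, cnv = cnv$track,
    clinical = surv$clinical,
    snrna = sn[c("mat", "cell_type")],
    truth = list(latent = cal$latent, probes = meth$truth, genes = expr$truth,
                 cnv = cnv$truth, survival = surv$truth, snrna = sn$truth,
                 config = config)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$latent), " samples: ",
      nrow(x$methylation$mat), " probes, ", nrow(x$expression$counts),
      " genes, ", nrow(x$cnv$bins), " CNV bins, ", ncol(x$snrna$mat),
      " nuclei\n", sep = "")
  print(table(x$cgc$subgroup))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's file dialects
#'
#' Emits the calibrated-score CSV, beta-matrix and probe-annotation TSVs,
#' count-matrix and gene-annotation TSVs, bins.igv track, clinical TSV and
#' a `truth.tsv` per planted-feature table.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calibrated_scores(cohort$scores, file.path(dir, "scores_cal.csv"))
  write_matrix_tsv(cohort$methylation$mat, file.path(dir, "betas.tsv"), "probe_id")
  utils::write.table(cohort$methylation$annotation, file.path(dir, "probe_annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  write_matrix_tsv(cohort$expression$counts, file.path(dir, "counts.tsv"), "gene_id")
  utils::write.table(cohort$expression$annotation, file.path(dir, "gene_annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  write_cnv_bins_igv(cohort$cnv, file.path(dir, "cnv.bins.igv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$truth$probes, file.path(dir, "truth_probes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  utils::write.table(cohort$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
  invisible(dir)
}
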