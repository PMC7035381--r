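#' Configuration for the end-to-end analysis
#'
#' @param protocol `"facs"` (full-length; gene-total filter, spike-ins
#'   expected) or `"droplet"` (UMI; per-cell quality filter)
#' @param min_gene_total,min_cell_count FACS filter thresholds
#' @param min_total_reads,min_genes droplet filter thresholds
#' @param intermittency_cutoff threshold on I for calling a gene
#'   intermittent (default `log(5)`, i.e. p < 0.2)
#' @param c_threshold magnitude threshold on C for the sign balance
#' @param epsilon tolerance around -1 for the K exclusivity call
#' @param max_pairs cap on surveyed gene pairs per tissue
#' @param tail_cutoff_quantile quantile of A_bar used as the tail-fit
#'   cutoff (default 0.5)
#' @param seed integer seed used for every stochastic step
#' @return list of class `analysis_config`
#' @export
analysis_config <- function(protocol = c("facs", "droplet"),
                            min_gene_total = 500, min_cell_count = 10,
                            min_total_reads = 1000, min_genes = 500,
                            intermittency_cutoff = log(5),
                            c_threshold = 0.1, epsilon = 0.05,
                            max_pairs = 2e5, tail_cutoff_quantile = 0.5,
                            seed = 1L) {
  protocol <- match.arg(protocol)
  if (min(min_gene_total, min_cell_count, min_total_reads, min_genes) < 0)
    stop("thresholds must be non-negative")
  structure(list(protocol = protocol, min_gene_total = min_gene_total,
                 min_cell_count = min_cell_count,
                 min_total_reads = min_total_reads, min_genes = min_genes,
                 intermittency_cutoff = intermittency_cutoff,
                 c_threshold = c_threshold, epsilon = epsilon,
                 max_pairs = max_pairs,
                 tail_cutoff_quantile = tail_cutoff_quantile,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full intermittency analysis
#'
#' Orchestrates the stages: protocol-specific quality filter, per-(gene,
#' tissue) parameter estimation, tissue averaging and cross-tissue
#' dispersion, spike-in log-variability diagnostics (when spike-ins are
#' present), the gene-pair correlation survey with the exclusivity and
#' sign-balance summaries, per-tissue A and I densities, the activity
#' tail fit, and the A_bar-I_bar correlation.  The summary carries a
#' verdict on which explanation of rarely observed genes the data
#' support: `"differentiation-consistent"` when a substantial share of
#' pairs sit at K = -1 (mutually exclusive expression),
#' `"intermittency-consistent"` when significant correlations are
#' predominantly positive with almost no exclusive pairs, and
#' `"indeterminate"` otherwise.
#'
#' @param x a CountMatrix
#' @param config an [analysis_config()]
#' @return list of class `analysis_bundle` with elements `filtered`,
#'   `stats`, `gene_summary`, `dispersion`, `spikein_report` (or NULL),
#'   `pairs`, `correlation_summary`, `pdf_A`, `pdf_I`, `tail_fit` (or
#'   NULL), `c_AI` (or NA), `summary`, `config`
#' @export
run_analysis <- function(x, config = analysis_config()) {
  stopifnot(inherits(x, "CountMatrix"), inherits(config, "analysis_config"))
  filtered <- switch(config$protocol,
    facs = filter_facs(x, config$min_gene_total, config$min_cell_count),
    droplet = filter_droplet(x, config$min_total_reads, config$min_genes))
  if (nrow(filtered$counts) == 0 || ncol(filtered$counts) == 0)
    stop("analysis stage 'filter': no cells or genes survive")
  stats <- gene_tissue_stats(filtered,
                             intermittency_cutoff = config$intermittency_cutoff)
  if (nrow(stats) == 0) stop("analysis stage 'estimate': empty statistics")
  gs <- tissue_summary(stats)
  disp <- dispersion_variances(gs)
  spikein_report <- NULL
  if (any(filtered$genes$is_spikein) &&
      all(cell_totals(filtered, include_spikeins = FALSE) > 0)) {
    spikein_report <- spikein_log_variability(filtered)
  }
  pairs <- correlation_survey(filtered, max_pairs = config$max_pairs,
                              seed = config$seed)
  corr <- exclusivity_fraction(pairs, epsilon = config$epsilon,
                               c_threshold = config$c_threshold)
  pdf_A <- pdf_by_tissue(stats, "A")
  pdf_I <- pdf_by_tissue(stats, "I")
  tail_fit <- NULL
  cutoff <- stats::quantile(gs$summary$A_bar, config$tail_cutoff_quantile)
  if (sum(gs$summary$A_bar > cutoff) >= 50)
    tail_fit <- fit_tail_exponent(gs$summary$A_bar, cutoff)
  c_AI <- tryCatch(activity_intermittency_correlation(gs),
                   error = function(e) NA_real_)
  intermittent_frac <- tapply(stats$intermittent, stats$tissue, mean)
  verdict <- if (corr$fraction_exclusive >= 0.25) {
    "differentiation-consistent"
  } else if (!is.na(corr$positive_fraction) &&
             corr$positive_fraction >= 0.75 &&
             corr$fraction_exclusive < 0.05) {
    "intermittency-consistent"
  } else "indeterminate"
  summary <- list(var_dA = disp$var_dA, var_dI = disp$var_dI,
                  dispersion_ratio = disp$ratio,
                  intermittent_fraction = intermittent_frac,
                  fraction_exclusive = corr$fraction_exclusive,
                  positive_fraction = corr$positive_fraction,
                  pos_neg_ratio = corr$pos_neg_ratio,
                  tail_slope = if (is.null(tail_fit)) NA_real_
                               else tail_fit$tail_slope,
                  c_AI = c_AI, verdict = verdict)
  structure(list(filtered = filtered, stats = stats, gene_summary = gs,
                 dispersion = disp, spikein_report = spikein_report,
                 pairs = pairs, correlation_summary = corr,
                 pdf_A = pdf_A, pdf_I = pdf_I, tail_fit = tail_fit,
                 c_AI = c_AI, summary = summary, config = config),
            class = "analysis_bundle")
}

#' @export
print.analysis_bundle <- function(x, ...) {
  s <- x$summary
  cat("analysis_bundle\n")
  cat(sprintf("  Var(dA) = %.4g, Var(dI) = %.4g (ratio %.3g)\n",
              s$var_dA, s$var_dI, s$dispersion_ratio))
  cat(sprintf("  exclusive-pair fraction = %.3g, positive fraction = %.3g\n",
              s$fraction_exclusive,
              ifelse(is.na(s$positive_fraction), NaN, s$positive_fraction)))
  if (!is.na(s$tail_slope))
    cat(sprintf("  activity tail slope = %.3g\n", s$tail_slope))
  cat(sprintf("  C(A_bar, I_bar) = %.3g\n  verdict: %s\n", s$c_AI, s$verdict))
  invisible(x)
}

#' Write an analysis bundle as plain-text tables
#'
#' Every numeric product of [run_analysis()] is exported as a
#' tab-delimited table (statistics, summaries, deltas, pair survey,
#' densities, heatmap grid) plus a `summary.tsv` of the headline scalars,
#' so reruns can be diffed without rendering anything.
#'
#' @param bundle an `analysis_bundle`
#' @param dir output directory (created if missing)
#' @return invisibly, the paths written
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "analysis_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wt(bundle$stats, "gene_tissue_stats.tsv"),
    wt(bundle$gene_summary$summary, "gene_summary.tsv"),
    wt(bundle$gene_summary$deltas, "tissue_deltas.tsv"),
    wt(bundle$pairs, "pair_correlations.tsv"),
    wt(bundle$pdf_A, "pdf_A.tsv"),
    wt(bundle$pdf_I, "pdf_I.tsv"),
    wt(as.data.frame(bundle$dispersion$heatmap$counts),
       "dispersion_heatmap.tsv"))
  if (!is.null(bundle$spikein_report))
    paths <- c(paths, wt(bundle$spikein_report, "spikein_variability.tsv"))
  s <- bundle$summary
  flat <- data.frame(
    quantity = c("var_dA", "var_dI", "dispersion_ratio",
                 "fraction_exclusive", "positive_fraction", "tail_slope",
                 "c_AI", "verdict"),
    value = c(s$var_dA, s$var_dI, s$dispersion_ratio, s$fraction_exclusive,
              s$positive_fraction, s$tail_slope, s$c_AI, s$verdict))
  paths <- c(paths, wt(flat, "summary.tsv"))
  invisible(paths)
}
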