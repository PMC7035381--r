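#' Per-tissue probability density histograms
#'
#' Histograms of a per-(gene, tissue) variable (activity A or
#' intermittency I), one per tissue, on common bin edges and normalized
#' to unit area so tissues of different gene counts are comparable.
#'
#' @param stats a table from [gene_tissue_stats()] (optionally passed
#'   through [equalize_tissue_activity()] first)
#' @param variable column to histogram, `"A"` or `"I"`
#' @param n_bins number of uniform bins over the pooled range (default 50)
#' @return data.frame (`tissue`, `bin_left`, `bin_right`, `count`,
#'   `density`); per tissue the densities integrate to 1
#' @export
pdf_by_tissue <- function(stats, variable = c("A", "I"), n_bins = 50) {
  variable <- match.arg(variable)
  v <- stats[[variable]]
  if (length(v) == 0) stop("empty statistics table")
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  width <- diff(edges)[1]
  out <- lapply(split(v, stats$tissue), function(vt) {
    if (length(vt) == 0) stop("empty tissue")
    b <- pmin(pmax(findInterval(vt, edges, rightmost.closed = TRUE), 1L), n_bins)
    cnt <- tabulate(b, nbins = n_bins)
    data.frame(bin_left = edges[-length(edges)], bin_right = edges[-1],
               count = cnt, density = cnt / (sum(cnt) * width))
  })
  res <- do.call(rbind, Map(function(df, t) cbind(tissue = t, df),
                            out, names(out)))
  rownames(res) <- NULL
  res
}

#' Exponential tail fit of tissue-averaged activity
#'
#' The upper tail of the distribution of the tissue-averaged activity
#' A_bar is modelled as exp(-lambda * A_bar); by the change of variables
#' alpha = exp(A), this is equivalent to a power-law tail
#' P(alpha) ~ alpha^-(lambda + 1), and the exponential-rate MLE on the
#' exceedances (A_bar - cutoff) is exactly the Hill estimator for the
#' power-law exponent.  The maximum-likelihood route is used (rather than
#' regression on a log-binned histogram) because it is the statistically
#' defensible default; `method = "regression"` fits a line to the log of
#' a binned density for figure-style replication.
#'
#' @param a_bar numeric vector of tissue-averaged activities (log scale);
#'   to fit raw alpha values pass `log(alpha)`
#' @param lower_cutoff tail threshold on A_bar; only values strictly
#'   above it enter the fit
#' @param method `"mle"` (default) or `"regression"`
#' @param n_bins bins for the regression method
#' @param min_tail_points minimum exceedances required (default 50)
#' @return list of class `tail_fit`: `tail_slope` (the exponential rate),
#'   `implied_alpha_exponent` (= tail_slope + 1), `se`, `lower_cutoff`,
#'   `n_tail`, `method`
#' @export
fit_tail_exponent <- function(a_bar, lower_cutoff,
                              method = c("mle", "regression"),
                              n_bins = 30, min_tail_points = 50) {
  method <- match.arg(method)
  if (lower_cutoff >= max(a_bar))
    stop("lower cutoff is outside the data support")
  exceed <- a_bar[a_bar > lower_cutoff] - lower_cutoff
  n <- length(exceed)
  if (n < min_tail_points)
    stop("too few tail points above the cutoff (", n, ")")
  if (mean(exceed) == 0) stop("degenerate tail (all values at the cutoff)")
  if (method == "mle") {
    slope <- 1 / mean(exceed)
    se <- slope / sqrt(n)
  } else {
    edges <- seq(0, max(exceed), length.out = n_bins + 1)
    b <- pmin(pmax(findInterval(exceed, edges, rightmost.closed = TRUE), 1L),
              n_bins)
    cnt <- tabulate(b, nbins = n_bins)
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    keep <- cnt > 0
    fit <- stats::lm(log(cnt[keep] / (n * diff(edges)[1])) ~ mid[keep])
    slope <- -unname(stats::coef(fit)[2])
    se <- unname(summary(fit)$coefficients[2, 2])
  }
  structure(list(tail_slope = slope, implied_alpha_exponent = slope + 1,
                 se = se, lower_cutoff = lower_cutoff, n_tail = n,
                 method = method),
            class = "tail_fit")
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf(
    "tail_fit (%s): rate %.4g (se %.2g) on %d points above %.3g -> P(alpha) ~ alpha^-%.4g\n",
    x$method, x$tail_slope, x$se, x$n_tail, x$lower_cutoff,
    x$implied_alpha_exponent))
  invisible(x)
}

#' Correlation between mean activity and mean intermittency
#'
#' Pearson correlation of A_bar against I_bar across genes.  A value near
#' zero supports activity being an intrinsic gene property not tied to
#' how intermittently the gene is expressed; a weak negative value means
#' rarely active genes tend to have slightly lower peak activity.
#'
#' @param gs a `gene_summary` from [tissue_summary()], or a data.frame
#'   with `A_bar` and `I_bar` columns
#' @return the correlation coefficient
#' @export
activity_intermittency_correlation <- function(gs) {
  df <- if (inherits(gs, "gene_summary")) gs$summary else gs
  if (nrow(df) < 3) stop("need at least 3 genes")
  if (stats::sd(df$A_bar) == 0 || stats::sd(df$I_bar) == 0)
    stop("degenerate variance")
  stats::cor(df$A_bar, df$I_bar)
}
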