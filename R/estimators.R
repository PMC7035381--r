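#' Mean and variance of a count vector
#'
#' Population convention: `mu = mean(M)`, `sigma2 = mean(M^2) - mu^2`,
#' i.e. the 1/N variance.  These are the raw moments from which the
#' activation probability and peak activity are constructed.
#'
#' @param counts non-empty vector of non-negative integer counts
#'   (one gene, one tissue; one entry per cell)
#' @param var_method `"population"` (1/N, the default) or `"sample"`
#'   (1/(N-1))
#' @return named numeric vector `c(mu, sigma2)`
#' @export
moments <- function(counts, var_method = c("population", "sample")) {
  var_method <- match.arg(var_method)
  if (length(counts) == 0) stop("empty count vector")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- length(counts)
  mu <- sum(counts) / n
  s2 <- sum(counts^2) / n - mu^2
  s2 <- max(s2, 0)                       # guard tiny negative round-off
  if (var_method == "sample" && n > 1) s2 <- s2 * n / (n - 1)
  c(mu = mu, sigma2 = s2)
}

#' Activation-probability estimator p = mu^2 / sigma^2
#'
#' Under a two-point on/off model in which a gene is active with
#' probability p and yields a count alpha when active, `mu = alpha * p`
#' and `sigma2 = p * (1 - p) * alpha^2`, so `mu^2 / sigma2 = p / (1 - p)`,
#' which approaches p for rare activation (p << 1).  Ratios exceeding 1
#' (sub-Poissonian, near-constant genes, e.g. ideal spike-ins) are clipped
#' to 1 so that the intermittency I = -ln(p) stays non-negative; `mu = 0`
#' yields p = 0.  Both situations are degenerate in the sense of
#' [is_degenerate()].
#'
#' @param mu,sigma2 non-negative moments as returned by [moments()]
#' @return activation probability estimate in \[0, 1\] (vectorized)
#' @export
estimate_p <- function(mu, sigma2) {
  if (any(mu < 0) || any(sigma2 < 0)) stop("moments must be non-negative")
  p <- ifelse(mu == 0, 0,
              ifelse(sigma2 == 0, 1, pmin(mu^2 / sigma2, 1)))
  as.numeric(p)
}

#' Peak-activity estimator alpha = sigma^2 / mu
#'
#' The estimated typical count while the gene is on; under the two-point
#' model it equals `alpha * (1 - p)`.  For a constant nonzero gene
#' (sigma2 = 0) the peak level is the constant itself, `alpha = mu`.
#'
#' @inheritParams estimate_p
#' @return peak activity estimate (vectorized); error if any `mu` is zero
#' @export
estimate_alpha <- function(mu, sigma2) {
  if (any(mu < 0) || any(sigma2 < 0)) stop("moments must be non-negative")
  if (any(mu == 0)) stop("peak activity is undefined for mu = 0")
  as.numeric(ifelse(sigma2 == 0, mu, sigma2 / mu))
}

#' Flag degenerate moment pairs
#'
#' Degenerate means the moment-ratio estimators are pinned rather than
#' informative: an all-zero gene (mu = 0), a constant gene (sigma2 = 0),
#' or a sub-Poissonian gene whose raw ratio mu^2/sigma2 exceeds 1 and was
#' clipped.  The identity `p * alpha = mu` holds exactly on all
#' non-degenerate pairs.
#'
#' @inheritParams estimate_p
#' @return logical vector
#' @export
is_degenerate <- function(mu, sigma2) {
  mu == 0 | sigma2 == 0 | mu^2 > sigma2
}

#' Logarithmic gene variables: intermittency and activity
#'
#' `I = -ln(p)` (non-negative because p <= 1) and `A = ln(alpha)`.  Both
#' raw parameters span decades; the logarithmic variables keep statistics
#' from being dominated by the largest values.
#'
#' @param p activation probability in (0, 1]
#' @param alpha positive peak activity
#' @return data.frame with columns `I` and `A`
#' @export
to_log <- function(p, alpha) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  if (any(alpha <= 0)) stop("alpha must be positive")
  data.frame(I = pmax(-log(p), 0), A = log(alpha))
}

#' Intermittency classification
#'
#' A gene is regarded as intermittent when I > ln(5) strictly, i.e. when
#' its estimated activation probability is below 0.2.  The cutoff is
#' calibrated on spike-in sequences, which are present in every cell and
#' should ideally have I = 0: few high-concentration spike-ins exceed
#' ln(5).
#'
#' @param I non-negative intermittency value(s)
#' @param cutoff classification threshold, default `log(5)`
#' @return logical vector
#' @export
classify_intermittent <- function(I, cutoff = log(5)) {
  I > cutoff
}

col_sq_sums <- function(m) {
  sq <- m
  sq@x <- sq@x^2
  Matrix::colSums(sq)
}

#' Per-gene, per-tissue parameter table
#'
#' For every (gene, tissue) combination in which the gene has at least one
#' nonzero count, computes the count moments and the derived parameters
#' p, alpha, A, I, plus the intermittency and degeneracy flags.  All-zero
#' combinations are excluded (a gene absent from a tissue carries no
#' information there, and I would be infinite).
#'
#' @param x a CountMatrix, normally already quality-filtered
#' @param include_spikeins also report spike-in genes (default `FALSE`)
#' @param var_method variance convention, see [moments()]
#' @param intermittency_cutoff threshold for [classify_intermittent()]
#' @return data.frame with columns `gene_id`, `tissue`, `n_cells`, `mu`,
#'   `sigma2`, `p`, `alpha`, `A`, `I`, `intermittent`, `degenerate`
#' @export
gene_tissue_stats <- function(x, include_spikeins = FALSE,
                              var_method = c("population", "sample"),
                              intermittency_cutoff = log(5)) {
  stopifnot(inherits(x, "CountMatrix"))
  var_method <- match.arg(var_method)
  gsel <- if (include_spikeins) seq_len(ncol(x$counts)) else which(!x$genes$is_spikein)
  tissues <- unique(x$cells$tissue)
  res <- vector("list", length(tissues))
  for (t in seq_along(tissues)) {
    rows <- which(x$cells$tissue == tissues[t])
    n <- length(rows)
    m <- x$counts[rows, gsel, drop = FALSE]
    mu <- Matrix::colSums(m) / n
    s2 <- pmax(col_sq_sums(m) / n - mu^2, 0)
    if (var_method == "sample" && n > 1) s2 <- s2 * n / (n - 1)
    present <- mu > 0
    mu <- mu[present]; s2 <- s2[present]
    p <- estimate_p(mu, s2)
    a <- estimate_alpha(mu, s2)
    la <- to_log(p, a)
    res[[t]] <- data.frame(
      gene_id = x$genes$gene_id[gsel][present],
      tissue = tissues[t],
      n_cells = n,
      mu = mu, sigma2 = s2, p = p, alpha = a,
      A = la$A, I = la$I,
      intermittent = classify_intermittent(la$I, intermittency_cutoff),
      degenerate = is_degenerate(mu, s2),
      row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tissue-averaged parameters and per-tissue deviations
#'
#' For each gene, the activity and intermittency are averaged across
#' tissues with a simple (unweighted) mean, giving `A_bar` and `I_bar`;
#' per-tissue deviations `dA = A - A_bar` and `dI = I - I_bar` quantify
#' how much each parameter moves between tissues.  Degenerate entries are
#' excluded, since their clipped p carries no intermittency information.
#'
#' @param stats a table from [gene_tissue_stats()]
#' @param drop_degenerate exclude degenerate (gene, tissue) entries
#'   (default `TRUE`)
#' @return list of class `gene_summary` with elements `summary` (per gene:
#'   `gene_id`, `A_bar`, `I_bar`, `n_tissues`) and `deltas` (per gene and
#'   tissue: `gene_id`, `tissue`, `dA`, `dI`)
#' @export
tissue_summary <- function(stats, drop_degenerate = TRUE) {
  if (drop_degenerate) stats <- stats[!stats$degenerate, , drop = FALSE]
  if (nrow(stats) == 0) stop("no usable (gene, tissue) entries")
  g <- factor(stats$gene_id, levels = unique(stats$gene_id))
  A_bar <- tapply(stats$A, g, mean)
  I_bar <- tapply(stats$I, g, mean)
  n_tis <- tapply(stats$A, g, length)
  summary <- data.frame(gene_id = levels(g),
                        A_bar = as.numeric(A_bar),
                        I_bar = as.numeric(I_bar),
                        n_tissues = as.integer(n_tis),
                        row.names = NULL)
  idx <- match(stats$gene_id, summary$gene_id)
  deltas <- data.frame(gene_id = stats$gene_id,
                       tissue = stats$tissue,
                       dA = stats$A - summary$A_bar[idx],
                       dI = stats$I - summary$I_bar[idx],
                       row.names = NULL)
  structure(list(summary = summary, deltas = deltas), class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("gene_summary: %d genes over up to %d tissues\n",
              nrow(x$summary), max(x$summary$n_tissues)))
  invisible(x)
}

#' Cross-tissue dispersion of activity and intermittency
#'
#' Pools the per-tissue deviations dA and dI over all (gene, tissue)
#' points and reports their population variances, together with a 20 x 20
#' two-dimensional histogram of (dI, dA) pairs — the heatmap view of how
#' much each parameter disperses across tissues.  A small
#' `Var(dA)/Var(dI)` ratio is the signature of peak activity being a
#' persistent, tissue-independent property of a gene while the expression
#' probability is tissue-modulated.
#'
#' @param gs a `gene_summary` from [tissue_summary()]
#' @param n_bins histogram lattice size per axis (default 20)
#' @return list with `var_dA`, `var_dI`, `ratio` (= var_dA/var_dI, NA when
#'   var_dI is 0) and `heatmap` (list: `counts` n_bins x n_bins matrix,
#'   `dI_edges`, `dA_edges`)
#' @export
dispersion_variances <- function(gs, n_bins = 20) {
  stopifnot(inherits(gs, "gene_summary"))
  dA <- gs$deltas$dA
  dI <- gs$deltas$dI
  pvar <- function(v) mean(v^2) - mean(v)^2
  var_dA <- pvar(dA)
  var_dI <- pvar(dI)
  rng <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    r
  }
  eI <- seq(rng(dI)[1], rng(dI)[2], length.out = n_bins + 1)
  eA <- seq(rng(dA)[1], rng(dA)[2], length.out = n_bins + 1)
  bi <- pmin(pmax(findInterval(dI, eI, rightmost.closed = TRUE), 1L), n_bins)
  ba <- pmin(pmax(findInterval(dA, eA, rightmost.closed = TRUE), 1L), n_bins)
  counts <- matrix(tabulate((ba - 1L) * n_bins + bi, nbins = n_bins^2),
                   n_bins, n_bins)
  list(var_dA = var_dA, var_dI = var_dI,
       ratio = if (var_dI > 0) var_dA / var_dI else NA_real_,
       heatmap = list(counts = counts, dI_edges = eI, dA_edges = eA))
}
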