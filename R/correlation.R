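#' Correlation statistics for one gene pair
#'
#' `C` is the Pearson-type coefficient built from population moments,
#' `C = (<Mi Mj> - mu_i mu_j) / (sigma_i sigma_j)`, and `K` rescales it by
#' `sigma_i sigma_j / (mu_i mu_j)`, i.e. `K = (<Mi Mj> - mu_i mu_j) /
#' (mu_i mu_j)`.  K is the exclusivity statistic: whenever two genes are
#' never expressed in the same cell the cross moment `<Mi Mj>` is zero and
#' K equals -1 exactly, whatever the expression levels — the fingerprint
#' of genes confined to disjoint rare cell types.
#'
#' @param counts_i,counts_j aligned count vectors (same cells, length
#'   >= 2); both genes must have positive mean and variance
#' @return list of class `pair_correlation` with elements `C` and `K`
#' @export
pair_correlation <- function(counts_i, counts_j) {
  n <- length(counts_i)
  if (n != length(counts_j)) stop("count vectors must be aligned")
  if (n < 2) stop("need at least two cells")
  mi <- mean(counts_i); mj <- mean(counts_j)
  vi <- mean(counts_i^2) - mi^2
  vj <- mean(counts_j^2) - mj^2
  if (mi == 0 || mj == 0) stop("both genes must have positive mean")
  if (vi <= 0 || vj <= 0) stop("both genes must have positive variance")
  cross <- mean(counts_i * counts_j) - mi * mj
  C <- cross / sqrt(vi * vj)
  structure(list(C = C, K = cross / (mi * mj)), class = "pair_correlation")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf("pair_correlation: C = %.6g, K = %.6g\n", x$C, x$K))
  invisible(x)
}

#' Survey C and K over gene pairs of one tissue
#'
#' Computes the pair statistics for every pair of eligible genes
#' (non-degenerate in the tissue: positive mean and variance, spike-ins
#' excluded) or, above `max_pairs`, for a seeded random subsample of
#' pairs — subsampling preserves the sign-split distributions that the
#' case A / case B discrimination rests on.
#'
#' @param x a CountMatrix (normally quality-filtered)
#' @param tissue tissue label to survey (default: first tissue present)
#' @param genes optional character vector restricting the gene universe
#' @param max_pairs cap on the number of pairs (default `Inf`)
#' @param seed seed for pair subsampling
#' @return data.frame (`gene_i`, `gene_j`, `tissue`, `C`, `K`), one row
#'   per pair
#' @export
correlation_survey <- function(x, tissue = NULL, genes = NULL,
                               max_pairs = Inf, seed = 1L) {
  stopifnot(inherits(x, "CountMatrix"))
  if (is.null(tissue)) tissue <- x$cells$tissue[1]
  rows <- which(x$cells$tissue == tissue)
  if (length(rows) < 2) stop("tissue has fewer than 2 cells")
  gsel <- which(!x$genes$is_spikein)
  if (!is.null(genes)) gsel <- gsel[x$genes$gene_id[gsel] %in% genes]
  m <- x$counts[rows, gsel, drop = FALSE]
  n <- nrow(m)
  mu <- Matrix::colSums(m) / n
  s2 <- pmax(col_sq_sums(m) / n - mu^2, 0)
  ok <- mu > 0 & s2 > 0
  if (sum(ok) < 2) stop("fewer than 2 eligible genes")
  m <- m[, ok, drop = FALSE]
  ids <- x$genes$gene_id[gsel][ok]
  mu <- mu[ok]; s2 <- s2[ok]
  G <- length(ids)
  pairs <- utils::combn(G, 2)
  if (ncol(pairs) > max_pairs) {
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  # cross moments for all needed pairs in one sparse product
  cp <- as.matrix(Matrix::crossprod(m)) / n
  i <- pairs[1, ]; j <- pairs[2, ]
  cross <- cp[cbind(i, j)] - mu[i] * mu[j]
  data.frame(gene_i = ids[i], gene_j = ids[j], tissue = tissue,
             C = cross / sqrt(s2[i] * s2[j]),
             K = cross / (mu[i] * mu[j]),
             row.names = NULL)
}

#' Log-binned sign-split histogram of correlation magnitudes
#'
#' Bins `|value|` logarithmically, separately for positive and negative
#' values, the form in which the preponderance of positive over negative
#' coefficients among the larger magnitudes is visible.
#'
#' @param values numeric vector of C or K values
#' @param n_bins number of logarithmic bins (default 40)
#' @param floor magnitudes below this are pooled into the first bin
#'   (default 1e-4)
#' @return data.frame (`sign`, `bin_left`, `bin_right`, `count`,
#'   `density`)
#' @export
correlation_histogram <- function(values, n_bins = 40, floor = 1e-4) {
  values <- values[is.finite(values) & values != 0]
  if (length(values) == 0) stop("no nonzero values")
  top <- max(abs(values))
  if (top <= floor) top <- floor * 10
  edges <- exp(seq(log(floor), log(top), length.out = n_bins + 1))
  one_branch <- function(v, lab) {
    if (length(v) == 0) return(NULL)
    a <- pmax(abs(v), floor)
    b <- pmin(pmax(findInterval(a, edges, rightmost.closed = TRUE), 1L), n_bins)
    cnt <- tabulate(b, nbins = n_bins)
    width <- diff(edges)
    data.frame(sign = lab, bin_left = edges[-length(edges)],
               bin_right = edges[-1], count = cnt,
               density = cnt / (sum(cnt) * width))
  }
  out <- rbind(one_branch(values[values > 0], "positive"),
               one_branch(values[values < 0], "negative"))
  rownames(out) <- NULL
  out
}

#' Exclusivity fraction and correlation sign balance
#'
#' Two summaries of a pair survey that together discriminate the
#' competing explanations of rarely observed genes.  The exclusivity
#' fraction is the share of pairs with K within `epsilon` of -1 (genes
#' never co-expressed, as disjoint rare cell types would force); the sign
#' balance is the fraction of positive coefficients among the pairs with
#' `|C| > c_threshold` (temporal co-activation yields predominantly
#' positive correlations).
#'
#' @param pairs data.frame from [correlation_survey()] (or any frame with
#'   `C` and `K` columns)
#' @param epsilon tolerance around -1 for "exclusive" (default 0.05)
#' @param c_threshold magnitude threshold defining "significant" C
#'   (default 0.1)
#' @return list: `fraction_exclusive`, `n_pairs`, `n_significant`,
#'   `positive_fraction` (among significant; NA if none),
#'   `pos_neg_ratio` (positive:negative counts among significant; Inf if
#'   no negatives)
#' @export
exclusivity_fraction <- function(pairs, epsilon = 0.05, c_threshold = 0.1) {
  if (nrow(pairs) == 0) stop("empty pair list")
  frac <- mean(abs(pairs$K + 1) <= epsilon)
  sig <- pairs$C[abs(pairs$C) > c_threshold]
  npos <- sum(sig > 0); nneg <- sum(sig < 0)
  list(fraction_exclusive = frac,
       n_pairs = nrow(pairs),
       n_significant = length(sig),
       positive_fraction = if (length(sig)) npos / length(sig) else NA_real_,
       pos_neg_ratio = if (nneg > 0) npos / nneg
                       else if (npos > 0) Inf else NA_real_)
}
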