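#' Normalize counts to per-cell fractions
#'
#' Replaces each count by its fraction of the cell's total, M' = M / sum(M).
#' By default the denominator is the endogenous total only (spike-ins,
#' being exogenous additions, are not part of a cell's transcriptome);
#' endogenous entries of a cell then sum to 1.  Cells with zero total are
#' an error and must be removed upstream.
#'
#' @param x a CountMatrix
#' @param include_spikeins include spike-in counts in the per-cell
#'   denominator
#' @return list of class `normalized_matrix`: `norm` (sparse cells x genes
#'   fractions), `totals` (the denominators), `source` (the input)
#' @export
normalize_counts <- function(x, include_spikeins = FALSE) {
  stopifnot(inherits(x, "CountMatrix"))
  tot <- cell_totals(x, include_spikeins = include_spikeins)
  if (any(tot == 0)) stop("cells with zero total count must be excluded upstream")
  norm <- x$counts / tot      # recycles per row (cells)
  structure(list(norm = norm, totals = tot, source = x),
            class = "normalized_matrix")
}

log_var_positive <- function(v) {
  v <- v[v > 0]
  if (length(v) == 0) return(NA_real_)
  lv <- log(v)
  mean(lv^2) - mean(lv)^2
}

#' Spike-in variability of log raw vs. log normalized counts
#'
#' A spike-in is present in every cell at the same concentration, so the
#' fluctuation of ln(count) measures the technical (fractional) error.
#' If most of the cell-to-cell variation in total counts were technical,
#' normalizing would reduce that fluctuation; if the totals' variation is
#' real (biological), dividing a constant-concentration sequence by a
#' fluctuating total *injects* variability, and Var(ln M') exceeds
#' Var(ln M).  The comparison therefore decides whether total-count
#' normalization is appropriate.  Variances are over cells with a nonzero
#' count (population convention); optionally, cells in the lower quartile
#' of total count — whose tiny denominators drive the effect — are
#' excluded first.
#'
#' @param x a CountMatrix containing spike-ins
#' @param exclude_lower_quartile drop cells in the lower quartile of total
#'   count (all genes, raw) before computing
#' @param include_spikeins_in_total pass-through to [normalize_counts()]
#' @return data.frame, one row per spike-in (`sequence_id`,
#'   `concentration`, `var_log_raw`, `var_log_norm`, `n_cells_used`), with
#'   attributes `mean_var_log_raw`, `mean_var_log_norm` and `ratio`
#'   (their quotient)
#' @export
spikein_log_variability <- function(x, exclude_lower_quartile = FALSE,
                                    include_spikeins_in_total = FALSE) {
  stopifnot(inherits(x, "CountMatrix"))
  sp <- which(x$genes$is_spikein)
  if (length(sp) == 0) stop("no spike-ins present")
  if (exclude_lower_quartile) {
    tot_all <- cell_totals(x, include_spikeins = TRUE)
    keep <- which(tot_all > stats::quantile(tot_all, 0.25))
    x <- subset_countmatrix(x, cells = keep)
  }
  nm <- normalize_counts(x, include_spikeins = include_spikeins_in_total)
  res <- data.frame(sequence_id = x$genes$gene_id[sp],
                    concentration = x$genes$concentration[sp],
                    var_log_raw = NA_real_, var_log_norm = NA_real_,
                    n_cells_used = NA_integer_)
  for (i in seq_along(sp)) {
    raw <- as.numeric(x$counts[, sp[i]])
    res$var_log_raw[i] <- log_var_positive(raw)
    res$var_log_norm[i] <- log_var_positive(as.numeric(nm$norm[, sp[i]]))
    res$n_cells_used[i] <- sum(raw > 0)
  }
  ok <- !is.na(res$var_log_raw)
  attr(res, "mean_var_log_raw") <- mean(res$var_log_raw[ok])
  attr(res, "mean_var_log_norm") <- mean(res$var_log_norm[ok])
  attr(res, "ratio") <-
    if (any(ok) && mean(res$var_log_raw[ok]) > 0)
      mean(res$var_log_norm[ok]) / mean(res$var_log_raw[ok]) else NA_real_
  res
}

#' Equalize mean activity across tissues
#'
#' Shifts each tissue's activity values A additively so that every
#' tissue's mean A equals the pooled mean — multiplicative rescaling of
#' alpha, accounting for tissues whose cells have systematically
#' different total mRNA content.  Within-tissue variances of A are
#' untouched (a pure shift).
#'
#' @param stats a table from [gene_tissue_stats()]
#' @return the table with `A` adjusted (and `alpha` updated to `exp(A)`);
#'   per-tissue shifts are recorded in the `tissue_shifts` attribute
#' @export
equalize_tissue_activity <- function(stats) {
  grand <- mean(stats$A)
  tm <- tapply(stats$A, stats$tissue, mean)
  shift <- grand - tm
  stats$A <- as.numeric(stats$A + shift[as.character(stats$tissue)])
  stats$alpha <- exp(stats$A)
  attr(stats, "tissue_shifts") <- shift
  stats
}
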