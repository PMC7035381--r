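# Shared helpers: tiny CountMatrix builder and Monte-Carlo error estimators.

toy_cm <- function(m, tissue = "t1", spikein = NULL) {
  n_cells <- nrow(m)
  n_genes <- ncol(m)
  if (is.null(spikein)) spikein <- rep(FALSE, n_genes)
  tissue <- rep_len(tissue, n_cells)
  CountMatrix(m,
              cells = data.frame(cell_id = paste0("c", seq_len(n_cells)),
                                 tissue = tissue),
              genes = data.frame(gene_id = paste0("g", seq_len(n_genes)),
                                 is_spikein = spikein))
}

# Standard error of a plug-in statistic by batch means: split the sample
# into B batches, apply the statistic per batch; for asymptotically linear
# statistics SE(full) ~= sd(batch values) / sqrt(B).
batch_se <- function(x, stat, n_batches = 10) {
  b <- rep(seq_len(n_batches), length.out = length(x))
  vals <- vapply(split(x, b), stat, numeric(1))
  stats::sd(vals) / sqrt(n_batches)
}

# SE of the sample mean and of the population-convention sample variance.
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
se_var <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  sqrt(max(m4 - m2^2, 0) / n)
}
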