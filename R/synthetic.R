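#' Specify intermittently transcribed genes
#'
#' Builds the gene table consumed by [gen_intermittent_counts()].  Each
#' gene is active in any given cell with probability `p` and, when active,
#' produces a count with mean `alpha`.  Genes sharing a `program` label use
#' a common per-cell activation draw, modelling co-regulated gene sets that
#' switch on and off together.
#'
#' @param gene_id character vector of identifiers
#' @param p activation probabilities in (0, 1], recycled
#' @param alpha positive mean active-state counts, recycled
#' @param program optional program labels (`NA` = independent), recycled
#' @return data.frame with one row per gene
#' @export
intermittent_genes <- function(gene_id, p, alpha, program = NA) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  if (any(alpha <= 0)) stop("alpha must be positive")
  data.frame(gene_id = gene_id, p = p, alpha = alpha, program = program,
             stringsAsFactors = FALSE)
}

lognormal_scales <- function(n, sdlog) {
  if (sdlog == 0) rep(1, n) else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

active_counts <- function(n_active, level, mode) {
  level <- rep_len(level, n_active)
  if (mode == "fixed") as.integer(round(level))
  else stats::rpois(n_active, level)
}

build_cm <- function(counts, tissue_of_cell, gene_df, seed, ground_truth) {
  n_cells <- nrow(counts)
  cells <- data.frame(cell_id = sprintf("cell%06d", seq_len(n_cells)),
                      tissue = tissue_of_cell, stringsAsFactors = FALSE)
  cm <- CountMatrix(counts, cells, gene_df)
  attr(cm, "ground_truth") <- ground_truth
  attr(cm, "seed") <- seed
  cm
}

#' Generate counts under temporal intermittency (case B)
#'
#' Every cell of every tissue can express every gene: gene g is active in
#' a cell with probability `p` (optionally overridden per tissue), and an
#' active cell yields a count with mean `alpha`, either exactly
#' `round(alpha)` (`mode = "fixed"`, the two-point model underlying the
#' moment-ratio estimators) or Poisson with mean `alpha`
#' (`mode = "poisson"`, the default, allowing within-state fluctuation).
#' Inactive cells yield 0.  An optional lognormal per-cell scale factor
#' (`cell_size_dispersion`, the sdlog) modulates the active-state mean,
#' emulating cell-to-cell differences in total mRNA content.
#'
#' @param genes gene table from [intermittent_genes()]
#' @param n_cells named integer vector: cells per tissue (names are tissue
#'   labels); an unnamed scalar means one tissue called `"tissue1"`
#' @param p_overrides optional data.frame (`gene_id`, `tissue`, `p`) of
#'   tissue-specific activation probabilities
#' @param cell_size_dispersion sdlog of the per-cell lognormal scale
#'   factor (0 = none)
#' @param mode `"poisson"` (default) or `"fixed"` active-state count model
#' @param seed integer RNG seed, recorded in the output
#' @return a [CountMatrix()] with a `ground_truth` attribute: data.frame
#'   (`gene_id`, `tissue`, `p_true`, `alpha_true`)
#' @export
gen_intermittent_counts <- function(genes, n_cells, p_overrides = NULL,
                                    cell_size_dispersion = 0,
                                    mode = c("poisson", "fixed"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  if (!is.data.frame(genes) || nrow(genes) == 0) stop("empty gene specification")
  if (any(n_cells <= 0)) stop("n_cells must be positive")
  if (cell_size_dispersion < 0) stop("cell_size_dispersion must be non-negative")
  if (is.null(names(n_cells))) {
    if (length(n_cells) != 1) stop("n_cells must be named by tissue")
    names(n_cells) <- "tissue1"
  }
  set.seed(seed)
  prog <- as.character(genes$program)
  prog[is.na(genes$program)] <- paste0(".solo", seq_len(nrow(genes)))[is.na(genes$program)]
  prog_id <- match(prog, unique(prog))
  blocks <- vector("list", length(n_cells))
  truth <- vector("list", length(n_cells))
  for (t in seq_along(n_cells)) {
    tissue <- names(n_cells)[t]
    n <- n_cells[[t]]
    p <- genes$p
    if (!is.null(p_overrides)) {
      ov <- p_overrides[p_overrides$tissue == tissue, , drop = FALSE]
      idx <- match(ov$gene_id, genes$gene_id)
      p[idx[!is.na(idx)]] <- ov$p[!is.na(idx)]
    }
    if (any(p <= 0 | p > 1)) stop("override probabilities must lie in (0, 1]")
    u <- matrix(stats::runif(n * max(prog_id)), n, max(prog_id))
    scales <- lognormal_scales(n, cell_size_dispersion)
    cols <- vector("list", nrow(genes))
    for (g in seq_len(nrow(genes))) {
      on <- which(u[, prog_id[g]] < p[g])
      v <- integer(n)
      if (length(on))
        v[on] <- active_counts(length(on), genes$alpha[g] * scales[on], mode)
      cols[[g]] <- v
    }
    blocks[[t]] <- do.call(cbind, cols)
    truth[[t]] <- data.frame(gene_id = genes$gene_id, tissue = tissue,
                             p_true = p, alpha_true = genes$alpha,
                             stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  gene_df <- data.frame(gene_id = genes$gene_id, is_spikein = FALSE,
                        concentration = NA_real_, stringsAsFactors = FALSE)
  build_cm(counts, rep(names(n_cells), n_cells), gene_df, seed,
           do.call(rbind, truth))
}

#' Multi-tissue intermittency study conditions
#'
#' Convenience wrapper composing [intermittent_genes()] and
#' [gen_intermittent_counts()] into the canonical persistence setting:
#' every gene keeps one peak activity alpha across all tissues, drawn
#' from a Pareto (power-law) tail, while its activation probability p is
#' redrawn log-uniformly for every tissue.  This is the configuration in
#' which activity is a persistent gene property and expression differences
#' between tissues are carried entirely by intermittency.
#'
#' @param n_genes number of genes (default 150)
#' @param n_tissues number of tissues (default 8)
#' @param n_cells cells per tissue (default 400)
#' @param alpha_exponent power-law exponent of the alpha distribution,
#'   P(alpha) ~ alpha^-alpha_exponent (default 2.35)
#' @param alpha_min lower bound of the alpha support (default 20)
#' @param p_range range of the log-uniform per-(gene, tissue) activation
#'   probability (default `c(0.02, 0.5)`)
#' @param mode active-state count model, see [gen_intermittent_counts()]
#' @param seed integer RNG seed
#' @return a [CountMatrix()] with ground truth, as from
#'   [gen_intermittent_counts()]
#' @export
gen_multi_tissue_counts <- function(n_genes = 150, n_tissues = 8,
                                    n_cells = 400, alpha_exponent = 2.35,
                                    alpha_min = 20, p_range = c(0.02, 0.5),
                                    mode = c("poisson", "fixed"), seed = 1L) {
  if (alpha_exponent <= 1) stop("alpha_exponent must exceed 1")
  set.seed(seed)
  alpha <- alpha_min * stats::runif(n_genes)^(-1 / (alpha_exponent - 1))
  genes <- intermittent_genes(sprintf("gene%04d", seq_len(n_genes)),
                              p = 0.1, alpha = alpha)
  tissues <- sprintf("tissue%02d", seq_len(n_tissues))
  ov <- expand.grid(gene_id = genes$gene_id, tissue = tissues,
                    stringsAsFactors = FALSE)
  lr <- log(p_range)
  ov$p <- exp(stats::runif(nrow(ov), lr[1], lr[2]))
  gen_intermittent_counts(genes, stats::setNames(rep(n_cells, n_tissues),
                                                 tissues),
                          p_overrides = ov, mode = match.arg(mode),
                          seed = seed + 1L)
}

#' Specify rare-cell-type (differentiation) expression
#'
#' Builds the specification for [gen_differentiated_counts()]: a set of
#' disjoint cell types with given frequencies, each continuously
#' expressing its own exclusive gene set at a given level.
#'
#' @param type_freq named numeric vector of cell-type frequencies, summing
#'   to 1
#' @param gene_type named character vector mapping each gene id to exactly
#'   one cell type
#' @param level named numeric vector of expression levels per gene (mean
#'   count in cells of the gene's own type), recycled by gene
#' @return list of class `differentiation_spec`
#' @export
differentiation_spec <- function(type_freq, gene_type, level) {
  if (abs(sum(type_freq) - 1) > 1e-8) stop("type frequencies must sum to 1")
  if (!all(gene_type %in% names(type_freq)))
    stop("every gene must map to a declared cell type")
  level <- rep_len(level, length(gene_type))
  names(level) <- names(gene_type)
  structure(list(type_freq = type_freq, gene_type = gene_type, level = level),
            class = "differentiation_spec")
}

#' Generate counts under rare-cell-type expression (case A)
#'
#' Each cell is assigned one cell type by the specified frequencies; a
#' gene has nonzero counts only in cells of its own type, where it is
#' expressed continuously (every such cell draws a count, `"fixed"` =
#' exactly `round(level)`, `"poisson"` = Poisson with that mean).  For
#' genes of different types the product of counts is zero in every cell,
#' which forces the rescaled correlation K to equal -1 exactly — the
#' algebraic signature this generator exists to produce.
#'
#' @param spec a [differentiation_spec()]
#' @param n_cells number of cells
#' @param mode `"poisson"` (default) or `"fixed"`
#' @param seed integer RNG seed
#' @return a [CountMatrix()] (single tissue `"tissue1"`); the
#'   `ground_truth` attribute holds the per-cell types and the gene-type map
#' @export
gen_differentiated_counts <- function(spec, n_cells, mode = c("poisson", "fixed"),
                                      seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "differentiation_spec"))
  if (n_cells <= 0) stop("n_cells must be positive")
  set.seed(seed)
  types <- sample(names(spec$type_freq), n_cells, replace = TRUE,
                  prob = spec$type_freq)
  gids <- names(spec$gene_type)
  counts <- matrix(0L, n_cells, length(gids))
  for (g in seq_along(gids)) {
    own <- which(types == spec$gene_type[[g]])
    if (length(own))
      counts[own, g] <- active_counts(length(own), spec$level[[g]], mode)
  }
  gene_df <- data.frame(gene_id = gids, is_spikein = FALSE,
                        concentration = NA_real_, stringsAsFactors = FALSE)
  build_cm(counts, rep("tissue1", n_cells), gene_df, seed,
           list(cell_type = types, gene_type = spec$gene_type))
}

#' Generate stationary telegraph-model counts
#'
#' Samples exact stationary counts of the two-state transcription model by
#' its Poisson-Beta representation: the Poisson rate is `M0 = k_tr/k_deg`
#' times a Beta(`k_on/k_deg`, `k_off/k_deg`) promoter-occupancy variable.
#' This is the stationary law itself, so no burn-in is involved and the
#' sample moments converge to the closed-form stationary mean and variance
#' of [stationary_moments()].
#'
#' @param params a [telegraph_params()] or a list of them (one gene each)
#' @param n_cells number of cells
#' @param seed integer RNG seed
#' @return a [CountMatrix()] (single tissue); `ground_truth` holds the
#'   rates and derived (p0, M0) per gene
#' @export
gen_telegraph_counts <- function(params, n_cells, seed = 1L) {
  if (inherits(params, "telegraph_params")) params <- list(params)
  if (length(params) == 0) stop("empty parameter list")
  if (n_cells <= 0) stop("n_cells must be positive")
  set.seed(seed)
  cols <- vector("list", length(params))
  truth <- vector("list", length(params))
  for (g in seq_along(params)) {
    tp <- params[[g]]
    stopifnot(inherits(tp, "telegraph_params"))
    if (tp$k_tr == 0) {
      cols[[g]] <- integer(n_cells)
    } else if (tp$k_off == 0) {
      cols[[g]] <- stats::rpois(n_cells, tp$M0)   # promoter always active
    } else {
      occ <- stats::rbeta(n_cells, tp$k_on / tp$k_deg, tp$k_off / tp$k_deg)
      cols[[g]] <- stats::rpois(n_cells, tp$M0 * occ)
    }
    truth[[g]] <- data.frame(gene_id = sprintf("tele%03d", g),
                             k_on = tp$k_on, k_off = tp$k_off,
                             k_tr = tp$k_tr, k_deg = tp$k_deg,
                             p0 = tp$p0, M0 = tp$M0)
  }
  gene_df <- data.frame(gene_id = sprintf("tele%03d", seq_along(params)),
                        is_spikein = FALSE, concentration = NA_real_,
                        stringsAsFactors = FALSE)
  build_cm(do.call(cbind, cols), rep("tissue1", n_cells), gene_df, seed,
           do.call(rbind, truth))
}

#' Specify an ERCC-style spike-in panel
#'
#' @param sequence_id identifiers (conventionally `ERCC-000xx`)
#' @param concentration known concentrations in amol/ul, positive,
#'   recycled
#' @param capture_efficiency expected counts per unit concentration,
#'   positive, recycled
#' @param noise_sd sdlog of per-entry lognormal technical noise,
#'   non-negative, recycled
#' @return data.frame with one row per spike-in sequence
#' @export
spikein_panel <- function(sequence_id, concentration,
                          capture_efficiency = 1, noise_sd = 0) {
  if (any(concentration <= 0)) stop("concentrations must be positive")
  if (any(capture_efficiency <= 0)) stop("capture efficiency must be positive")
  if (any(noise_sd < 0)) stop("noise scale must be non-negative")
  data.frame(sequence_id = sequence_id, concentration = concentration,
             capture_efficiency = capture_efficiency, noise_sd = noise_sd,
             stringsAsFactors = FALSE)
}

#' Generate spike-in counts, optionally alongside biological genes
#'
#' Spike-ins are added to every cell at the same concentration, so their
#' expected count is `concentration * capture_efficiency`, independent of
#' the cell's biological mRNA content; lognormal technical noise
#' (`noise_sd`, per entry) and a per-cell technical scale factor
#' (`cell_scale_variation`, sdlog, shared by all sequences of a cell)
#' perturb it multiplicatively, and the result is rounded, so a noise-free
#' panel gives identical counts in every cell.  Optional biological filler
#' genes (`bio_genes`) carry an additional per-cell *biological* lognormal
#' size factor (`bio_cell_sd`) that spike-ins do not share — this is the
#' configuration that makes total-count normalization inject the
#' biological totals' variability into the constant-concentration
#' spike-ins.
#'
#' @param panel a [spikein_panel()]
#' @param n_cells number of cells
#' @param cell_scale_variation sdlog of the per-cell technical scale
#'   factor applied to all sequences (0 = none)
#' @param bio_genes optional data.frame (`gene_id`, `mean`) of endogenous
#'   filler genes, Poisson-expressed around `mean` times the cell's
#'   biological size factor
#' @param bio_cell_sd sdlog of the per-cell biological size factor
#'   applied to filler genes only
#' @param seed integer RNG seed
#' @return a [CountMatrix()] (single tissue) with spike-ins flagged and
#'   concentrations recorded
#' @export
gen_spikein_counts <- function(panel, n_cells, cell_scale_variation = 0,
                               bio_genes = NULL, bio_cell_sd = 0, seed = 1L) {
  if (!is.data.frame(panel) || nrow(panel) == 0) stop("empty spike-in panel")
  if (n_cells <= 0) stop("n_cells must be positive")
  if (cell_scale_variation < 0 || bio_cell_sd < 0)
    stop("noise parameters must be non-negative")
  set.seed(seed)
  tech <- lognormal_scales(n_cells, cell_scale_variation)
  spike_cols <- vector("list", nrow(panel))
  for (s in seq_len(nrow(panel))) {
    base <- panel$concentration[s] * panel$capture_efficiency[s]
    noise <- lognormal_scales(n_cells, panel$noise_sd[s])
    spike_cols[[s]] <- as.integer(round(base * tech * noise))
  }
  counts <- do.call(cbind, spike_cols)
  gene_df <- data.frame(gene_id = panel$sequence_id, is_spikein = TRUE,
                        concentration = panel$concentration,
                        stringsAsFactors = FALSE)
  if (!is.null(bio_genes)) {
    biosize <- lognormal_scales(n_cells, bio_cell_sd)
    bio_cols <- vapply(bio_genes$mean,
                       function(m) stats::rpois(n_cells, m * biosize * tech),
                       integer(n_cells))
    counts <- cbind(counts, bio_cols)
    gene_df <- rbind(gene_df,
                     data.frame(gene_id = bio_genes$gene_id, is_spikein = FALSE,
                                concentration = NA_real_,
                                stringsAsFactors = FALSE))
  }
  build_cm(counts, rep("tissue1", n_cells), gene_df, seed,
           list(panel = panel, cell_scale_variation = cell_scale_variation,
                bio_cell_sd = bio_cell_sd))
}
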