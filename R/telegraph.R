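#' Telegraph-model kinetic parameters
#'
#' The two-state model of transcription: the promoter switches inactive ->
#' active at rate `k_on` and active -> inactive at rate `k_off`;
#' transcripts are produced at rate `k_tr` while active and degraded at
#' rate `k_deg` (all rates per unit time, in the same units).  Derived
#' quantities: `p0 = k_on / (k_on + k_off)`, the stationary probability of
#' the active promoter state, and `M0 = k_tr / k_deg`, the mean count the
#' gene would reach if always active.
#'
#' @param k_on,k_off,k_tr,k_deg non-negative rates; `k_on + k_off` and
#'   `k_deg` must be positive
#' @return list of class `telegraph_params` with the rates and derived
#'   `p0`, `M0`
#' @export
telegraph_params <- function(k_on, k_off, k_tr, k_deg) {
  if (any(c(k_on, k_off, k_tr, k_deg) < 0)) stop("rates must be non-negative")
  if (k_on + k_off <= 0) stop("k_on + k_off must be positive")
  if (k_deg <= 0) stop("k_deg must be positive")
  structure(list(k_on = k_on, k_off = k_off, k_tr = k_tr, k_deg = k_deg,
                 p0 = k_on / (k_on + k_off), M0 = k_tr / k_deg),
            class = "telegraph_params")
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf(
    "telegraph_params: k_on=%g k_off=%g k_tr=%g k_deg=%g (p0=%.4g, M0=%.4g)\n",
    x$k_on, x$k_off, x$k_tr, x$k_deg, x$p0, x$M0))
  invisible(x)
}

#' Stationary mean and variance of the telegraph model
#'
#' Closed-form moments of the stationary transcript count:
#' `mean = p0 * M0` and
#' `var = p0*M0 + p0*(1 - p0)*M0^2 * k_deg / (k_on + k_off + k_deg)` —
#' Poissonian shot noise plus the excess variance contributed by promoter
#' switching.  In the always-active limit (`k_off = 0`) the second term
#' vanishes and the count is Poisson with mean `M0`.
#'
#' @param params a [telegraph_params()]
#' @return named numeric vector `c(mean, variance)`
#' @export
stationary_moments <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  m <- params$p0 * params$M0
  v <- m + params$p0 * (1 - params$p0) * params$M0^2 *
    params$k_deg / (params$k_on + params$k_off + params$k_deg)
  c(mean = m, variance = v)
}

#' Moment-ratio parameters implied by telegraph kinetics
#'
#' Substituting the stationary moments into the estimators
#' p = mu^2/sigma^2 and alpha = sigma^2/mu gives, for M0 >> 1,
#' \deqn{p = \frac{p_0}{1-p_0}\,\frac{k_{deg}+k_{on}+k_{off}}{k_{deg}},
#'   \qquad
#'   \alpha = M_0 (1-p_0)\,\frac{k_{deg}}{k_{deg}+k_{on}+k_{off}},}
#' whose product is exactly `p0 * M0`, the stationary mean.  When
#' `p0 << 1` and switching is slow relative to degradation
#' (`k_deg >> k_on + k_off`), p and alpha reduce to the mechanistic
#' parameters p0 and M0 — the identification limit in which the
#' mechanism-agnostic moment ratios read off the promoter kinetics.
#'
#' @param params a [telegraph_params()]
#' @return named numeric vector `c(p, alpha)`
#' @export
predict_p_alpha <- function(params) {
  stopifnot(inherits(params, "telegraph_params"))
  if (params$p0 == 1)
    stop("p is undefined at p0 = 1 (always-active promoter)")
  if (params$M0 <= 10)
    warning("predict_p_alpha assumes M0 >> 1; M0 = ", signif(params$M0, 3))
  ksum <- params$k_deg + params$k_on + params$k_off
  p <- params$p0 / (1 - params$p0) * ksum / params$k_deg
  alpha <- params$M0 * (1 - params$p0) * params$k_deg / ksum
  c(p = p, alpha = alpha)
}

#' Simulate-and-estimate check of the identification limit
#'
#' For each parameter set in the grid, draws `n_cells` stationary counts
#' ([gen_telegraph_counts()]), runs the moment-ratio estimators, and
#' compares the estimates against both the asymptotic predictions of
#' [predict_p_alpha()] and the mechanistic (p0, M0).  Relative errors are
#' reported so the regime in which the moment ratios identify the
#' promoter kinetics (p0 small, degradation fast relative to switching)
#' can be verified empirically.
#'
#' @param grid list of [telegraph_params()]
#' @param n_cells cells per parameter set
#' @param seed integer RNG seed
#' @return data.frame, one row per grid point: rates, p0, M0, predicted
#'   (p_pred, alpha_pred), estimated (p_hat, alpha_hat), sample mean,
#'   relative errors of the estimates against p0/M0 and the predictions
#' @export
verify_identification <- function(grid, n_cells = 1e5, seed = 1L) {
  if (inherits(grid, "telegraph_params")) grid <- list(grid)
  rows <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    tp <- grid[[g]]
    cm <- gen_telegraph_counts(tp, n_cells, seed = seed + g - 1L)
    v <- as.numeric(cm$counts[, 1])
    mom <- moments(v)
    # raw moment ratios (no clipping): this is a theory check, and outside
    # the identification limit the ratio legitimately exceeds 1
    p_hat <- mom[["mu"]]^2 / mom[["sigma2"]]
    a_hat <- mom[["sigma2"]] / mom[["mu"]]
    pred <- suppressWarnings(predict_p_alpha(tp))
    rows[[g]] <- data.frame(
      k_on = tp$k_on, k_off = tp$k_off, k_tr = tp$k_tr, k_deg = tp$k_deg,
      p0 = tp$p0, M0 = tp$M0,
      p_pred = pred[["p"]], alpha_pred = pred[["alpha"]],
      p_hat = p_hat, alpha_hat = a_hat,
      sample_mean = mom[["mu"]],
      rel_err_p0 = abs(p_hat - tp$p0) / tp$p0,
      rel_err_M0 = abs(a_hat - tp$M0) / tp$M0,
      rel_err_p_pred = abs(p_hat - pred[["p"]]) / pred[["p"]],
      rel_err_alpha_pred = abs(a_hat - pred[["alpha"]]) / pred[["alpha"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
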