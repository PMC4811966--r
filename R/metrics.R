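#' Benjamini-Yekutieli FDR adjustment and rejection decisions
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' raw p-values are inflated by `m * c(m) / rank` with the harmonic
#' correction `c(m) = sum_{i<=m} 1/i`, enforced monotone and capped at 1
#' (as in `p.adjust(method = "BY")`).
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param alpha Rejection level on the adjusted scale.
#' @return List with `adjusted` p-values and logical `reject` flags; empty
#'   input yields empty output.
#' @export
by_fdr_adjust <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BY")
  list(adjusted = adj, reject = !is.na(adj) & adj < alpha)
}

#' Average power and type I error from per-replicate decisions
#'
#' Per-SNP rejection frequencies over converged replicates, averaged over
#' the causal SNPs (power) and over the null SNPs (type I error).
#'
#' @param decisions Logical matrix, replicates in rows, SNPs in columns;
#'   include only converged replicates.
#' @param causal_idx Indices of the truly associated SNPs.
#' @return List with `power`, `type1`, `per_snp` rejection rates, and
#'   `n_replicates` (the denominator).
#' @export
power_type1 <- function(decisions, causal_idx) {
  decisions <- as.matrix(decisions)
  if (!nrow(decisions)) stop("no converged replicates: power/type I undefined")
  k <- ncol(decisions)
  per_snp <- colMeans(decisions)
  is_causal <- seq_len(k) %in% causal_idx
  list(power = if (any(is_causal)) mean(per_snp[is_causal]) else NA_real_,
       type1 = if (any(!is_causal)) mean(per_snp[!is_causal]) else NA_real_,
       per_snp = per_snp, n_replicates = nrow(decisions))
}

#' Selection sensitivity and specificity across replicates
#'
#' Sensitivity is the mean fraction of truly non-zero coefficients selected;
#' specificity the mean fraction of truly zero coefficients excluded.
#'
#' @param supports List of integer support sets (one per converged
#'   replicate) or a logical selection matrix (replicates x variables).
#' @param causal_idx Indices of the truly non-zero coefficients.
#' @param k Total number of candidate variables (required for list input).
#' @return List with `sensitivity`, `specificity`, `n_replicates`.
#' @export
sensitivity_specificity <- function(supports, causal_idx, k = NULL) {
  if (is.list(supports)) {
    if (is.null(k)) stop("k is required when supports is a list")
    sel <- t(vapply(supports, function(s) seq_len(k) %in% s, logical(k)))
  } else {
    sel <- as.matrix(supports)
    k <- ncol(sel)
  }
  if (!nrow(sel)) stop("no converged replicates: sensitivity/specificity undefined")
  is_causal <- seq_len(k) %in% causal_idx
  sens <- if (any(is_causal)) mean(rowMeans(sel[, is_causal, drop = FALSE])) else NA_real_
  spec <- if (any(!is_causal)) mean(1 - rowMeans(sel[, !is_causal, drop = FALSE])) else NA_real_
  list(sensitivity = sens, specificity = spec, n_replicates = nrow(sel))
}

#' Mean squared error of coefficient estimates across replicates
#'
#' For per-replicate estimates `b_s` of a true vector `b`, computes the
#' squared Euclidean distance `(b_s - b)'(b_s - b)` per replicate and
#' aggregates. The default `scale = "per_parameter"` averages over
#' replicates and divides by `length(b)` -- the scale on which the
#' published simulation tables report MSEs. `"mean"` averages the squared
#' distances without the dimension divisor and `"sum"` totals them.
#'
#' @param estimates Matrix of estimates (replicates x coefficients), only
#'   converged replicates.
#' @param truth True coefficient vector (count-model coefficients including
#'   the intercept).
#' @param scale `"per_parameter"` (default), `"mean"`, or `"sum"`.
#' @return List with `mse`, per-replicate squared errors `sq_err` (on the
#'   chosen coefficient scale before replicate aggregation), `mc_se` (the
#'   Monte-Carlo standard error of `mse`), and `n_replicates`.
#' @export
mse <- function(estimates, truth, scale = c("per_parameter", "mean", "sum")) {
  scale <- match.arg(scale)
  estimates <- as.matrix(estimates)
  if (!nrow(estimates)) stop("no converged replicates: MSE undefined")
  if (ncol(estimates) != length(truth)) stop("estimates do not conform to truth")
  sq <- rowSums(sweep(estimates, 2L, truth)^2)
  if (scale == "per_parameter") sq <- sq / length(truth)
  val <- if (scale == "sum") sum(sq) else mean(sq)
  mc <- if (scale == "sum") stats::sd(sq) * sqrt(nrow(estimates))
        else stats::sd(sq) / sqrt(nrow(estimates))
  list(mse = val, sq_err = sq, mc_se = mc, n_replicates = nrow(estimates))
}

#' Non-convergence proportion per method
#'
#' @param converged Logical vector of per-replicate convergence flags, or a
#'   data frame with columns `method` and `converged`.
#' @return Percentage(s) of non-converged replicates (0-100).
#' @export
nonconvergence_rate <- function(converged) {
  if (is.data.frame(converged)) {
    stopifnot(all(c("method", "converged") %in% names(converged)))
    return(vapply(split(converged$converged, converged$method),
                  function(x) 100 * mean(!x), 0))
  }
  if (!length(converged)) stop("at least one replicate is required")
  100 * mean(!converged)
}
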