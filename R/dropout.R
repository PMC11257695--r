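# Gene-wise probabilistic dropout model: the probability that a transcript
# present at log pseudocount x is observed as zero decays exponentially with
# x, P(x_obs = 0 | x) = beta_g * exp(-lambda_g * x), clipped to 1. Dropout
# counts across cells then follow a Poisson-binomial distribution.

#' Dropout decay rate from the non-zero mean
#'
#' Sets the half-life of the exponential dropout decay to the gene's
#' empirical non-zero mean: \eqn{\lambda_g = \ln(2) / \hat\mu_{NZ}(g)}, so
#' the dropout probability at \eqn{x = \hat\mu_{NZ}} is \eqn{\beta_g / 2}.
#'
#' @param mean_nz Mean of the gene's non-zero log pseudocounts (> 0).
#' @return The decay rate \eqn{\lambda_g} (vectorised over `mean_nz`).
#' @examples
#' dropout_rate_param(log(2))  # 1
#' @export
dropout_rate_param <- function(mean_nz) {
  if (any(!is.finite(mean_nz)) || any(mean_nz <= 0))
    abort("`mean_nz` must be positive; genes without positive support are discarded upstream")
  log(2) / mean_nz
}

#' Dropout normalisation constant targeting a reference rate
#'
#' Closed-form minimiser of the quadratic deviation between the expected
#' dropout rate of a sampled batch (the Poisson-binomial mean) and the target
#' rate: \eqn{\beta = n \tau^{ref} / \sum_c e^{-\lambda x_c}}, computed from
#' the batch's sampled prior pseudocounts.
#'
#' @param x_sample Sampled prior log pseudocounts of one gene (length >= 1).
#' @param lambda Decay rate \eqn{\lambda_g} (> 0).
#' @param tau_ref Target dropout rate in `[0, 1]`.
#' @return The normalisation constant \eqn{\beta_g \ge 0}.
#' @export
dropout_norm_constant <- function(x_sample, lambda, tau_ref) {
  if (!length(x_sample)) abort("`x_sample` must be non-empty")
  if (lambda <= 0) abort("`lambda` must be positive")
  if (tau_ref < 0 || tau_ref > 1) abort("`tau_ref` must be in [0, 1]")
  length(x_sample) * tau_ref / sum(exp(-lambda * x_sample))
}

#' Pointwise dropout probability
#'
#' \eqn{p = \min(1, \beta e^{-\lambda x})}; non-increasing in `x`. The raw
#' exponential can exceed 1 at small `x` for large \eqn{\beta}; probabilities
#' are clipped (see [expected_dropout_rate()] for the induced shortfall).
#'
#' @param x Log pseudocount(s), >= 0.
#' @param lambda Decay rate (> 0).
#' @param beta Normalisation constant (>= 0).
#' @return Probabilities in `[0, 1]`, vectorised over `x`.
#' @export
dropout_probability <- function(x, lambda, beta) {
  if (any(x < 0)) abort("`x` must be >= 0")
  pmin(1, beta * exp(-lambda * x))
}

#' Expected dropout rate of a batch
#'
#' Poisson-binomial mean of the dropout count divided by the batch size:
#' \eqn{E[\tau] = n^{-1} \sum_c \min(1, \beta e^{-\lambda x_c})}. Equals
#' `tau_ref` exactly when `beta` comes from [dropout_norm_constant()] and no
#' probability is clipped; under clipping it falls short of `tau_ref`.
#'
#' @inheritParams dropout_norm_constant
#' @param beta Normalisation constant.
#' @return The expected dropout rate.
#' @export
expected_dropout_rate <- function(x_sample, lambda, beta) {
  mean(dropout_probability(x_sample, lambda, beta))
}

#' Simulate dropout events on an expression matrix
#'
#' Sets each entry independently to zero with probability
#' \eqn{\min(1, \beta_g e^{-\lambda_g x})}. Values are never increased and
#' existing zeros stay zero (they carry the maximal dropout probability
#' \eqn{\min(1, \beta_g)} but a dropped zero is still zero). Per-gene random
#' substreams are derived from `seed` and the gene name, so results do not
#' depend on gene column order.
#'
#' @param expr Expression tibble (cell id column + gene columns).
#' @param params Tibble with columns `gene`, `lambda`, `beta` covering every
#'   gene of `expr`.
#' @param seed Optional integer seed.
#' @return A tibble of the same shape as `expr` with simulated dropouts.
#' @export
simulate_dropout <- function(expr, params, seed = NULL) {
  validate_expression(expr, "expr")
  genes <- gene_ids(expr)
  missing <- setdiff(genes, params$gene)
  if (length(missing))
    abort(sprintf("missing dropout params for gene(s): %s", paste(missing, collapse = ", ")))
  out <- expr
  for (g in genes) {
    i <- match(g, params$gene)
    p <- dropout_probability(expr[[g]], params$lambda[i], params$beta[i])
    drop <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, paste0("dropout:", g)),
                      rbinom(length(p), 1L, p) == 1L)
    out[[g]] <- ifelse(drop, 0, expr[[g]])
  }
  out
}

# Poisson-binomial sd of the realised dropout *rate* for one gene.
poisson_binomial_rate_sd <- function(p) sqrt(sum(p * (1 - p))) / length(p)
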