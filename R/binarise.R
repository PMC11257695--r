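#' Binarisation configuration
#'
#' @param theta Bimodal posterior confidence threshold, `0.5 < theta <= 1`
#'   (default 0.95). Lower values binarise more observations of bimodal genes.
#' @param q Margin quantile for unimodal genes, in `(0, 0.5)` (default 0.05):
#'   with `alpha = 0` roughly a fraction `2q` of observations is binarised.
#' @param alpha Non-negative IQR multiplier widening the unimodal fences
#'   (default 0; Tukey's classical fences use 1.5 with q = 0.25).
#' @param z Label assigned to zeros of zero-inflated genes:
#'   `"undetermined"` (default; dropout of unknown cause) or `"zero"`
#'   (treated as biological absence).
#' @param keep_discarded Keep discarded genes as all-undetermined columns
#'   instead of removing them (default `FALSE`).
#' @return A list of class `binarisation_config`.
#' @export
binarisation_config <- function(theta = 0.95, q = 0.05, alpha = 0,
                                z = c("undetermined", "zero"),
                                keep_discarded = FALSE) {
  z <- match.arg(z)
  stopifnot(theta > 0.5, theta <= 1, q > 0, q < 0.5, alpha >= 0)
  structure(list(theta = theta, q = q, alpha = alpha, z = z,
                 keep_discarded = isTRUE(keep_discarded)),
            class = "binarisation_config")
}

as_fit_list <- function(fit) {
  if (is.data.frame(fit)) fit <- as.list(fit[1L, ])
  needed <- c("phi1", "mu1", "sigma1", "phi2", "mu2", "sigma2")
  if (!all(needed %in% names(fit)) || anyNA(unlist(fit[needed])))
    abort("`fit` must carry phi1, mu1, sigma1, phi2, mu2, sigma2")
  fit[needed]
}

#' Posterior component probabilities of a two-component mixture
#'
#' \eqn{p(C_i | x) = \phi_i N(x | \mu_i, \sigma_i^2) / \sum_j \phi_j
#' N(x | \mu_j, \sigma_j^2)}, evaluated in log space for stability. The two
#' probabilities sum to one; \eqn{C_2} is the high-mean (active) component.
#'
#' @param x Numeric vector of log pseudocounts.
#' @param fit Bimodal fit: list or one-row tibble with `phi1`, `mu1`,
#'   `sigma1`, `phi2`, `mu2`, `sigma2`.
#' @return A tibble with columns `p1` and `p2`.
#' @export
posterior_components <- function(x, fit) {
  f <- as_fit_list(fit)
  l1 <- log(f$phi1) + dnorm(x, f$mu1, f$sigma1, log = TRUE)
  l2 <- log(f$phi2) + dnorm(x, f$mu2, f$sigma2, log = TRUE)
  p2 <- 1 / (1 + exp(l1 - l2))
  tibble::tibble(p1 = 1 - p2, p2 = p2)
}

#' Category-wise binarisation rules
#'
#' Three-valued coarse-graining of a single gene's values; `NA` encodes
#' undetermined. Bimodal genes: 0/1 when the posterior probability of the
#' low/high component reaches `theta` (at most one branch can fire since
#' `theta > 0.5`). Unimodal genes: Tukey-fence rule, 0 below
#' \eqn{Q(q) - \alpha\,IQR} and 1 above \eqn{Q(1-q) + \alpha\,IQR}, with
#' type-7 quantiles of the gene's non-zero reference values. Zero-inflated
#' genes: 1 when positive, otherwise the configured zero label.
#'
#' @param x Numeric vector of log pseudocounts.
#' @param fit Gene fit (one-row tibble or list): mixture parameters for
#'   `binarise_bimodal()`, `quantiles` grid plus `iqr` for
#'   `binarise_unimodal()`.
#' @param theta,q,alpha See [binarisation_config()].
#' @param z `"undetermined"` or `"zero"`.
#' @return Numeric vector of 0, 1 and `NA`.
#' @export
binarise_bimodal <- function(x, fit, theta = 0.95) {
  stopifnot(theta > 0.5, theta <= 1)
  post <- posterior_components(x, fit)
  ifelse(post$p1 >= theta, 0, ifelse(post$p2 >= theta, 1, NA_real_))
}

profile_quantile <- function(fit, q) {
  qs <- if (is.data.frame(fit)) fit$quantiles[[1L]] else fit$quantiles
  if (is.null(qs)) abort("`fit` carries no quantile table")
  approx(profile_quantile_probs(), qs, xout = q, rule = 2)$y
}

#' @rdname binarise_bimodal
#' @export
binarise_unimodal <- function(x, fit, q = 0.05, alpha = 0) {
  stopifnot(q > 0, q < 0.5, alpha >= 0)
  iqr <- if (is.data.frame(fit)) fit$iqr else fit$iqr
  lower <- profile_quantile(fit, q) - alpha * iqr
  upper <- profile_quantile(fit, 1 - q) + alpha * iqr
  ifelse(x < lower, 0, ifelse(x > upper, 1, NA_real_))
}

#' @rdname binarise_bimodal
#' @export
binarise_zero_inflated <- function(x, z = c("undetermined", "zero")) {
  z <- match.arg(z)
  if (any(x < 0)) abort("`x` must be >= 0")
  ifelse(x > 0, 1, if (z == "zero") 0 else NA_real_)
}

#' Binarise an expression matrix against learnt profiles
#'
#' Applies each gene's category rule (see [binarise_bimodal()]). Genes
#' discarded at learning time are removed from the output (or kept as
#' all-undetermined columns with `keep_discarded`); genes absent from the
#' profiles are an error. Binarisation is deterministic.
#'
#' @param expr Expression tibble; every gene column must be present in
#'   `profiles`. The query matrix must use the same normalisation as the
#'   reference the profiles were learnt from.
#' @param profiles A `reference_profiles` object.
#' @param config A [binarisation_config()].
#' @return A binary tibble (0 / 1 / `NA`); dropped genes are recorded in the
#'   `"discarded"` attribute.
#' @examples
#' spec <- fixture_spec(n_per_category = 2, n_cells = 200)
#' ref <- generate_reference_fixture(spec, seed = 1)
#' prof <- learn_reference(ref$expr)
#' head(binarise(ref$expr, prof))
#' @export
binarise <- function(expr, profiles, config = binarisation_config()) {
  validate_expression(expr, "expr")
  stopifnot(inherits(profiles, "reference_profiles"))
  p <- profiles$profiles
  genes <- gene_ids(expr)
  missing <- setdiff(genes, p$gene)
  if (length(missing))
    abort(sprintf("gene(s) absent from profiles: %s", paste(missing, collapse = ", ")))
  out <- expr[, 1L, drop = FALSE]
  dropped <- character()
  for (g in genes) {
    row <- p[match(g, p$gene), ]
    vals <- switch(row$category,
      discarded = {
        dropped <- c(dropped, g)
        if (config$keep_discarded) rep(NA_real_, nrow(expr)) else NULL
      },
      bimodal = binarise_bimodal(expr[[g]], row, config$theta),
      zero_inflated = binarise_zero_inflated(expr[[g]], config$z),
      unimodal = binarise_unimodal(expr[[g]], row, config$q, config$alpha))
    if (!is.null(vals)) out[[g]] <- vals
  }
  if (length(dropped))
    inform(sprintf("%d discarded gene(s) %s: %s", length(dropped),
                   if (config$keep_discarded) "kept as undetermined" else "removed",
                   paste(dropped, collapse = ", ")))
  attr(out, "discarded") <- dropped
  out
}

#' Probability mass binarised for one bimodal gene
#'
#' Numerically integrates the fitted mixture density over the region where
#' the posterior rule fires (either component's posterior above `theta`).
#' Used as the per-gene estimate of the determined fraction of bimodal genes.
#'
#' @param fit Bimodal fit (see [posterior_components()]).
#' @param theta Confidence threshold.
#' @param n_grid Number of integration grid points (default 4001).
#' @return The determined probability mass, in `[0, 1]`.
#' @export
bimodal_determined_mass <- function(fit, theta = 0.95, n_grid = 4001L) {
  f <- as_fit_list(fit)
  xs <- seq(f$mu1 - 8 * f$sigma1, f$mu2 + 8 * f$sigma2, length.out = n_grid)
  dens <- f$phi1 * dnorm(xs, f$mu1, f$sigma1) + f$phi2 * dnorm(xs, f$mu2, f$sigma2)
  post <- posterior_components(xs, f)
  fire <- post$p1 >= theta | post$p2 >= theta
  sum((dens * fire)[-1L] * diff(xs))
}

#' Approximate overall binarised fraction
#'
#' Closed-form estimate of the proportion of observations binarised to 0 or
#' 1: \eqn{\xi(1-\tau) + \beta p^{\star} + \eta\, 2q}, with \eqn{\xi, \beta,
#' \eta} the proportions of zero-inflated, bimodal and unimodal genes among
#' the non-discarded genes, \eqn{\tau} the average dropout rate of the
#' zero-inflated genes, and \eqn{p^{\star}} the average determined mass of
#' the bimodal fits (estimated by [bimodal_determined_mass()] when not
#' supplied). The zero-inflated term assumes the default undetermined zero
#' label; with `z = "zero"` those genes are fully determined and the first
#' term becomes \eqn{\xi}.
#'
#' @param profiles A `reference_profiles` object.
#' @param config A [binarisation_config()].
#' @param p_star Optional determined fraction for bimodal genes.
#' @return A single number in `[0, 1]`.
#' @export
expected_binarised_fraction <- function(profiles, config = binarisation_config(),
                                        p_star = NULL) {
  p <- profiles$profiles
  kept <- p[p$category != "discarded", ]
  if (!nrow(kept)) return(0)
  xi <- mean(kept$category == "zero_inflated")
  bb <- mean(kept$category == "bimodal")
  eta <- mean(kept$category == "unimodal")
  stopifnot(abs(xi + bb + eta - 1) < 1e-12)
  tau <- if (any(kept$category == "zero_inflated"))
    mean(kept$dropout_rate[kept$category == "zero_inflated"]) else 0
  if (is.null(p_star)) {
    bi <- kept[kept$category == "bimodal", ]
    p_star <- if (nrow(bi))
      mean(purrr::map_dbl(seq_len(nrow(bi)),
                          function(i) bimodal_determined_mass(bi[i, ], config$theta)))
      else 0
  }
  zi_term <- if (config$z == "zero") xi else xi * (1 - tau)
  zi_term + bb * p_star + eta * 2 * config$q
}

#' Resolve undetermined binary calls deterministically
#'
#' Fills `NA` entries of a binarised matrix by each gene's rule midpoint so
#' the result is strictly binary and can seed Boolean-state sampling:
#' unimodal genes split at the median of the non-zero reference values,
#' bimodal genes at the posterior 0.5 crossing (equivalently, the larger
#' posterior), zero-inflated zeros become 0. Discarded genes cannot be
#' resolved and must not be present.
#'
#' @param binary Binary tibble from [binarise()].
#' @param expr The expression tibble that was binarised (same shape).
#' @param profiles The `reference_profiles` used.
#' @return A strictly binary tibble.
#' @export
resolve_undetermined <- function(binary, expr, profiles) {
  validate_binary(binary)
  p <- profiles$profiles
  out <- binary
  for (g in gene_ids(binary)) {
    idx <- which(is.na(binary[[g]]))
    if (!length(idx)) next
    row <- p[match(g, p$gene), ]
    if (is.na(row$gene[1L]) || row$category == "discarded")
      abort(sprintf("cannot resolve gene %s (missing or discarded profile)", g))
    x <- expr[[g]][idx]
    out[[g]][idx] <- switch(row$category,
      bimodal = as.numeric(posterior_components(x, row)$p2 > 0.5),
      unimodal = as.numeric(x > row$median_nz),
      zero_inflated = as.numeric(x > 0))
  }
  validate_states(out)
  out
}
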