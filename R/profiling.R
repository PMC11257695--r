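#' Classifier configuration
#'
#' Tuning parameters of the per-gene distribution classification cascade.
#'
#' @param dropout_discard_threshold Genes with a zero fraction above this are
#'   discarded (default 0.95; 0.99 is a common permissive alternative).
#' @param amplitude_divisor Genes with amplitude (max - min log pseudocount)
#'   below `median amplitude / amplitude_divisor` are discarded (default 10).
#' @param dip_alpha Significance level of the dip test of unimodality on
#'   non-zero values (default 0.05).
#' @param bi_threshold Bimodality-index cut-off (default 1.5).
#' @param zero_peak_frac A gene is zero-inflated when its overall density peak
#'   lies within this fraction of its amplitude above the minimum (default 0.1).
#' @param min_nonzero Minimum number of non-zero observations required to fit
#'   and test a gene; genes below it are discarded (default 10).
#' @param seed Optional integer seed recorded with the profiles.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(dropout_discard_threshold = 0.95,
                              amplitude_divisor = 10,
                              dip_alpha = 0.05,
                              bi_threshold = 1.5,
                              zero_peak_frac = 0.1,
                              min_nonzero = 10,
                              seed = NULL) {
  stopifnot(dropout_discard_threshold > 0, dropout_discard_threshold <= 1,
            amplitude_divisor > 0, dip_alpha > 0, dip_alpha < 1,
            bi_threshold >= 0, zero_peak_frac > 0, zero_peak_frac < 1,
            min_nonzero >= 2)
  structure(list(dropout_discard_threshold = dropout_discard_threshold,
                 amplitude_divisor = amplitude_divisor,
                 dip_alpha = dip_alpha,
                 bi_threshold = bi_threshold,
                 zero_peak_frac = zero_peak_frac,
                 min_nonzero = as.integer(min_nonzero),
                 seed = seed),
            class = "classifier_config")
}

#' Bimodality index
#'
#' Separation statistic \eqn{\delta \sqrt{p(1-p)}} with
#' \eqn{\delta = (\mu_2 - \mu_1)/\sigma} from a provisional equal-variance
#' two-component Gaussian mixture fit, where `p` is the proportion of the
#' first component. Larger values indicate better-separated modes; 1.5 is a
#' conventional cut-off.
#'
#' @param x Numeric vector (typically non-zero log pseudocounts).
#' @return A single non-negative number, or `NA` when the provisional fit fails.
#' @export
bimodality_index <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4L || length(unique(x)) < 3L) return(NA_real_)
  fit <- suppressWarnings(
    try(mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE), silent = TRUE))
  if (inherits(fit, "try-error") || is.null(fit)) return(NA_real_)
  mu <- fit$parameters$mean
  p <- fit$parameters$pro[which.min(mu)]
  sigma <- sqrt(fit$parameters$variance$sigmasq[1L])
  if (sigma <= 0) return(Inf)
  abs(diff(range(mu))) / sigma * sqrt(p * (1 - p))
}

#' Per-gene summary statistics
#'
#' Computes the statistics the classification cascade is based on. Dropout
#' rate and amplitude are computed over all values; the `_nz` moments, the
#' dip test and the bimodality index over strictly positive values (dropout
#' would otherwise deflate means and inflate variances); the density peak
#' (Gaussian kernel, Silverman bandwidth) over the full distribution.
#' Statistics whose support is smaller than `min_nonzero` are returned as `NA`.
#'
#' @param values Numeric vector of log pseudocounts (length >= 1, all >= 0).
#' @param min_nonzero Minimum non-zero support for the dip test and
#'   bimodality index (default 10).
#' @return A one-row tibble.
#' @export
gene_stats <- function(values, min_nonzero = 10) {
  if (length(values) < 1L) abort("`values` must have length >= 1")
  if (anyNA(values) || any(values < 0)) abort("`values` must be non-negative and non-missing")
  n <- length(values)
  nz <- values[values > 0]
  n_nonzero <- length(nz)
  peak <- if (length(unique(values)) >= 2L) {
    d <- density(values, bw = "nrd0")
    d$x[which.max(d$y)]
  } else values[1L]
  enough <- n_nonzero >= min_nonzero
  full_m <- raw_moments(values)   # full-data population moments (node matching)
  tibble::tibble(
    n = n,
    mean_all = full_m[["mean"]],
    var_all = full_m[["variance"]],
    skewness_all = full_m[["skewness"]],
    kurtosis_all = full_m[["kurtosis"]],
    n_nonzero = n_nonzero,
    dropout_rate = (n - n_nonzero) / n,
    amplitude = max(values) - min(values),
    min_value = min(values),
    mean_nz = if (n_nonzero >= 1L) mean(nz) else NA_real_,
    var_nz = if (n_nonzero >= 2L) var(nz) else NA_real_,
    median_nz = if (n_nonzero >= 1L) median(nz) else NA_real_,
    skewness_nz = if (n_nonzero >= 3L) e1071::skewness(nz, type = 1) else NA_real_,
    kurtosis_nz = if (n_nonzero >= 4L) e1071::kurtosis(nz, type = 1) else NA_real_,
    dip_pvalue = if (enough) dip_test(nz)$p.value else NA_real_,
    bimodality_index = if (enough) bimodality_index(nz) else NA_real_,
    density_peak = peak
  )
}

#' Classify a gene's distribution
#'
#' Fixed-order cascade: (1) discard genes with excessive dropout,
#' insufficient dynamic range relative to the matrix-wide median amplitude,
#' or too few non-zero observations; (2) bimodal when the dip test rejects
#' unimodality and the bimodality index exceeds its threshold; (3)
#' zero-inflated when the overall density peak sits in the low band of the
#' gene's range; (4) unimodal otherwise.
#'
#' @param stats One-row tibble from [gene_stats()].
#' @param median_amplitude Median amplitude over all genes of the matrix.
#' @param config A [classifier_config()].
#' @return One of `"discarded"`, `"bimodal"`, `"zero_inflated"`, `"unimodal"`.
#' @export
classify_gene <- function(stats, median_amplitude, config = classifier_config()) {
  if (stats$dropout_rate > config$dropout_discard_threshold ||
      stats$amplitude < median_amplitude / config$amplitude_divisor ||
      stats$n_nonzero < config$min_nonzero)
    return("discarded")
  if (!is.na(stats$dip_pvalue) && !is.na(stats$bimodality_index) &&
      stats$dip_pvalue < config$dip_alpha &&
      stats$bimodality_index > config$bi_threshold)
    return("bimodal")
  if (stats$density_peak <= stats$min_value + config$zero_peak_frac * stats$amplitude)
    return("zero_inflated")
  "unimodal"
}

discard_reason <- function(stats, median_amplitude, config) {
  if (stats$dropout_rate > config$dropout_discard_threshold)
    sprintf("dropout rate %.3f > %.2f", stats$dropout_rate, config$dropout_discard_threshold)
  else if (stats$amplitude < median_amplitude / config$amplitude_divisor)
    sprintf("amplitude %.3f < median amplitude / %g", stats$amplitude, config$amplitude_divisor)
  else if (stats$n_nonzero < config$min_nonzero)
    sprintf("only %d non-zero observations (< %d)", stats$n_nonzero, config$min_nonzero)
  else NA_character_
}

# Quantile grid stored with unimodal fits; includes the default margin
# quantiles 0.05/0.95 exactly.
profile_quantile_probs <- function() seq(0, 1, by = 0.005)

fit_gmm2 <- function(x, model = "V") {
  fit <- suppressWarnings(
    try(mclust::Mclust(x, G = 2, modelNames = model, verbose = FALSE), silent = TRUE))
  if (inherits(fit, "try-error") || is.null(fit)) return(NULL)
  mu <- as.numeric(fit$parameters$mean)
  sig2 <- fit$parameters$variance$sigmasq
  if (length(sig2) == 1L) sig2 <- rep(sig2, 2L)
  if (any(!is.finite(sig2)) || any(sig2 <= 1e-12)) return(NULL)
  ord <- order(mu)  # relabel so mu2 > mu1
  list(phi1 = fit$parameters$pro[ord[1L]], phi2 = fit$parameters$pro[ord[2L]],
       mu1 = mu[ord[1L]], mu2 = mu[ord[2L]],
       sigma1 = sqrt(sig2[ord[1L]]), sigma2 = sqrt(sig2[ord[2L]]))
}

empty_fit_cols <- function() {
  tibble::tibble(fit_type = NA_character_, zero_inflated = NA,
                 phi1 = NA_real_, mu1 = NA_real_, sigma1 = NA_real_,
                 phi2 = NA_real_, mu2 = NA_real_, sigma2 = NA_real_,
                 mu = NA_real_, sigma = NA_real_, iqr = NA_real_,
                 quantiles = list(NULL),
                 lambda = NA_real_, tau_ref = NA_real_)
}

#' Fit the parametric profile of a classified gene
#'
#' Bimodal genes get a two-component Gaussian mixture (components relabelled
#' so that \eqn{\mu_2 > \mu_1}), unimodal genes a non-zero mean/sd plus an
#' empirical quantile table (type-7), both on non-zero values. Zero-inflated
#' genes have their non-zero sub-distribution re-tested for bimodality with
#' the same criteria and are fitted as the corresponding sub-case, flagged
#' `zero_inflated = TRUE`. Dropout parameters \eqn{\lambda_g = \ln 2 /
#' \hat\mu_{NZ}} and \eqn{\tau^{ref}_g} (zero fraction) are attached for
#' every non-discarded gene.
#'
#' @param values Numeric vector of log pseudocounts for one gene.
#' @param category Category from [classify_gene()].
#' @param config A [classifier_config()].
#' @return A one-row tibble of fit columns (`fit_type`, mixture or
#'   unimodal parameters, `quantiles` list column, `lambda`, `tau_ref`).
#' @export
fit_profile <- function(values, category = c("unimodal", "bimodal", "zero_inflated", "discarded"),
                        config = classifier_config()) {
  category <- match.arg(category)
  out <- empty_fit_cols()
  if (category == "discarded") return(out)
  nz <- values[values > 0]
  if (length(nz) < config$min_nonzero)
    abort(sprintf("cannot fit a profile on %d non-zero observations (min_nonzero = %d)",
                  length(nz), config$min_nonzero))
  fit_type <- switch(category,
    bimodal = "bimodal",
    unimodal = "unimodal",
    zero_inflated = {
      dp <- dip_test(nz)$p.value
      bi <- bimodality_index(nz)
      if (!is.na(dp) && !is.na(bi) && dp < config$dip_alpha && bi > config$bi_threshold)
        "bimodal" else "unimodal"
    })
  out$zero_inflated <- category == "zero_inflated"
  out$fit_type <- fit_type
  if (fit_type == "bimodal") {
    g <- fit_gmm2(nz, "V") %||% fit_gmm2(nz, "E")
    if (is.null(g))
      abort("degenerate two-component mixture fit (collapsing variance)")
    out[names(g)] <- g
  } else {
    qs <- quantile(nz, probs = profile_quantile_probs(), type = 7, names = FALSE)
    out$mu <- mean(nz)
    out$sigma <- if (length(nz) >= 2L) sd(nz) else 0
    out$iqr <- unname(quantile(nz, 0.75, type = 7) - quantile(nz, 0.25, type = 7))
    out$quantiles <- list(qs)
  }
  out$lambda <- dropout_rate_param(mean(nz))
  out$tau_ref <- mean(values == 0)
  out
}

#' Learn per-gene reference profiles from an expression matrix
#'
#' Runs the full learning pass over a reference log-pseudocount matrix:
#' per-gene statistics, category classification, parametric fit and dropout
#' parameters. The reference is assumed to be pre-filtered to highly variable
#' genes (plus any markers of interest); this is documented, not enforced.
#' The result is deterministic for a given matrix and configuration.
#'
#' @param expr Expression tibble (cell id column + numeric gene columns).
#' @param config A [classifier_config()].
#' @return A `reference_profiles` object; see [tidy.reference_profiles()] and
#'   [glance.reference_profiles()].
#' @examples
#' spec <- fixture_spec(n_per_category = 3, n_cells = 300)
#' ref <- generate_reference_fixture(spec, seed = 1)
#' prof <- learn_reference(ref$expr)
#' glance(prof)
#' @export
learn_reference <- function(expr, config = classifier_config()) {
  validate_expression(expr, "expr")
  genes <- gene_ids(expr)
  if (!length(genes)) abort("`expr` has no gene columns")
  stats <- purrr::map(genes, function(g) gene_stats(expr[[g]], config$min_nonzero))
  med_amp <- median(purrr::map_dbl(stats, "amplitude"))
  rows <- purrr::map2(genes, stats, function(g, st) {
    category <- classify_gene(st, med_amp, config)
    fit <- tryCatch(fit_profile(expr[[g]], category, config),
                    error = function(e) abort(sprintf("gene %s: %s", g, conditionMessage(e))))
    dplyr::bind_cols(tibble::tibble(gene = g, category = category), fit, st,
                     tibble::tibble(discard_reason = discard_reason(st, med_amp, config)))
  })
  profiles <- dplyr::bind_rows(rows)
  structure(list(profiles = profiles,
                 config = config,
                 n_cells = nrow(expr),
                 median_amplitude = med_amp),
            class = "reference_profiles")
}

#' @export
print.reference_profiles <- function(x, ...) {
  counts <- table(factor(x$profiles$category,
                         levels = c("unimodal", "bimodal", "zero_inflated", "discarded")))
  cat(sprintf("<reference_profiles: %d genes learnt from %d cells>\n",
              nrow(x$profiles), x$n_cells))
  cat(sprintf("  unimodal %d | bimodal %d | zero-inflated %d | discarded %d\n",
              counts[["unimodal"]], counts[["bimodal"]],
              counts[["zero_inflated"]], counts[["discarded"]]))
  invisible(x)
}

#' Tidy and summarise learnt reference profiles
#'
#' `tidy()` returns the per-gene profile table (category, fit parameters,
#' dropout parameters and classification statistics); `glance()` a one-row
#' summary with category counts.
#'
#' @param x A `reference_profiles` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy reference_profiles
#' @export
tidy.reference_profiles <- function(x, ...) x$profiles

#' @rdname tidy.reference_profiles
#' @method glance reference_profiles
#' @export
glance.reference_profiles <- function(x, ...) {
  p <- x$profiles
  tibble::tibble(
    n_genes = nrow(p),
    n_cells = x$n_cells,
    n_unimodal = sum(p$category == "unimodal"),
    n_bimodal = sum(p$category == "bimodal"),
    n_zero_inflated = sum(p$category == "zero_inflated"),
    n_discarded = sum(p$category == "discarded"),
    median_amplitude = x$median_amplitude,
    mean_dropout = mean(p$dropout_rate)
  )
}

profile_row <- function(profiles, gene) {
  p <- profiles$profiles
  i <- match(gene, p$gene)
  if (is.na(i)) abort(sprintf("gene %s not present in profiles", gene))
  p[i, ]
}

#' Serialise reference profiles to / from JSON
#'
#' One record per gene carrying category, fit and dropout parameters and the
#' classification statistics; round-trips losslessly (full precision).
#'
#' @param profiles A `reference_profiles` object.
#' @param path Output (input) file path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()` a
#'   `reference_profiles` object.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "reference_profiles"))
  p <- profiles$profiles
  genes <- purrr::map(seq_len(nrow(p)), function(i) {
    rec <- as.list(p[i, setdiff(names(p), "quantiles")])
    rec$quantiles <- p$quantiles[[i]]
    rec
  })
  payload <- list(format = "boolexpr_profiles", version = 1L,
                  columns = names(p),
                  n_cells = profiles$n_cells,
                  median_amplitude = profiles$median_amplitude,
                  config = unclass(profiles$config),
                  quantile_probs = profile_quantile_probs(),
                  genes = genes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(payload$format, "boolexpr_profiles"))
    abort(sprintf("'%s' is not a profiles file", path))
  rows <- purrr::map(payload$genes, function(rec) {
    qs <- rec$quantiles
    rec$quantiles <- NULL
    rec <- purrr::map(rec, function(v) if (is.null(v)) NA else v)
    row <- tibble::as_tibble(rec)
    row$quantiles <- list(if (length(qs)) as.numeric(qs) else NULL)
    row
  })
  cfg <- payload$config
  config <- classifier_config(cfg$dropout_discard_threshold, cfg$amplitude_divisor,
                              cfg$dip_alpha, cfg$bi_threshold, cfg$zero_peak_frac,
                              cfg$min_nonzero, cfg$seed)
  profiles <- dplyr::bind_rows(rows)
  profiles$discard_reason <- as.character(profiles$discard_reason)
  if (!is.null(payload$columns)) profiles <- profiles[, unlist(payload$columns)]
  structure(list(profiles = profiles,
                 config = config,
                 n_cells = payload$n_cells,
                 median_amplitude = payload$median_amplitude),
            class = "reference_profiles")
}
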