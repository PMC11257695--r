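#' Generation configuration
#'
#' @param n_samples_per_state Synthetic cells generated per Boolean state row
#'   (default 10).
#' @param dropout_mode `"learned"` (exponential-decay model with the learnt
#'   \eqn{\lambda_g}, \eqn{\beta_g} recomputed per batch to target
#'   \eqn{\tau^{ref}_g}), `"none"` (no simulated dropout; zeros only arise
#'   from negative clipping) or `"user_rates"` (same decay shape, \eqn{\beta}
#'   retargeted to user-specified per-gene rates).
#' @param user_rates Named numeric vector or tibble (`gene`, `rate`) of
#'   target dropout rates in `[0, 1]`; required iff
#'   `dropout_mode = "user_rates"`.
#' @param seed Optional integer seed; per-gene substreams are derived from it
#'   so results do not depend on gene order.
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(n_samples_per_state = 10L,
                              dropout_mode = c("learned", "none", "user_rates"),
                              user_rates = NULL, seed = NULL) {
  dropout_mode <- match.arg(dropout_mode)
  stopifnot(n_samples_per_state >= 1)
  if (dropout_mode == "user_rates") {
    if (is.data.frame(user_rates)) user_rates <- setNames(user_rates$rate, user_rates$gene)
    if (is.null(user_rates) || is.null(names(user_rates)))
      abort("`user_rates` (named gene -> rate) is required with dropout_mode = \"user_rates\"")
    if (any(user_rates < 0 | user_rates > 1)) abort("`user_rates` must lie in [0, 1]")
  } else if (!is.null(user_rates)) {
    abort("`user_rates` is only meaningful with dropout_mode = \"user_rates\"")
  }
  structure(list(n_samples_per_state = as.integer(n_samples_per_state),
                 dropout_mode = dropout_mode, user_rates = user_rates, seed = seed),
            class = "generation_config")
}

#' Biased sampling from learnt fits
#'
#' Draws synthetic log pseudocounts biased by a Boolean activation state.
#' Unimodal genes sample from the half-normal around the non-zero mean:
#' \eqn{\mu + |N(0, \sigma^2)|} when active, \eqn{\mu - |N(0, \sigma^2)|}
#' when inactive. Bimodal genes sample from the component matching the
#' state: \eqn{N(\mu_2, \sigma_2^2)} when active, \eqn{N(\mu_1, \sigma_1^2)}
#' when inactive. Draws are later clipped at zero by the generator.
#'
#' @param state 0 (inactive) or 1 (active).
#' @param fit Gene fit (one-row tibble or list): `mu`, `sigma` for
#'   `sample_unimodal()`; mixture parameters for `sample_bimodal()`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_unimodal <- function(state, fit, n) {
  stopifnot(state %in% c(0, 1), n >= 1)
  mu <- if (is.data.frame(fit)) fit$mu else fit$mu
  sigma <- if (is.data.frame(fit)) fit$sigma else fit$sigma
  half <- abs(rnorm(n, 0, sigma))
  if (state == 1) mu + half else mu - half
}

#' @rdname sample_unimodal
#' @export
sample_bimodal <- function(state, fit, n) {
  stopifnot(state %in% c(0, 1), n >= 1)
  f <- as_fit_list(fit)
  if (state == 1) rnorm(n, f$mu2, f$sigma2) else rnorm(n, f$mu1, f$sigma1)
}

#' Clip values at zero
#'
#' Element-wise `max(x, 0)`: the Gaussian fits give positive probability to
#' negative pseudocounts, which are corrected to 0 (and therefore appear as
#' additional zeros even without dropout simulation).
#'
#' @param x Numeric vector.
#' @return `x` with negative entries replaced by 0.
#' @export
clip_nonnegative <- function(x) pmax(x, 0)

#' Generate synthetic expression data from Boolean states
#'
#' For every row of `states`, draws `n_samples_per_state` synthetic cells per
#' gene by biased sampling from the mapped gene's learnt fit (zero-inflated
#' genes sample through their non-zero sub-fit), clips negatives to zero,
#' then simulates dropout according to the configuration: the learnt decay
#' rate \eqn{\lambda_g} with \eqn{\beta_g} recomputed on the generated batch
#' to target the reference (or user-specified) dropout rate.
#'
#' @param states Strictly binary tibble (state id column + node columns);
#'   undetermined entries are rejected (see [resolve_undetermined()]).
#' @param profiles A `reference_profiles` object.
#' @param mapping Optional tibble (`node`, `gene`) assigning each Boolean
#'   node to a distinct non-discarded gene (e.g. from [match_genes()]).
#'   Defaults to the identity mapping (nodes are gene names of the
#'   reference).
#' @param config A [generation_config()].
#' @return An expression tibble with one row per synthetic cell (cell ids are
#'   `<state id>_<replicate>` and the `"source_state"` attribute repeats the
#'   source Boolean state row per cell); gene columns are named by the mapped
#'   genes.
#' @examples
#' spec <- fixture_spec(n_per_category = 2, n_cells = 300)
#' ref <- generate_reference_fixture(spec, seed = 1)
#' prof <- learn_reference(ref$expr)
#' genes <- tidy(prof)$gene[tidy(prof)$category != "discarded"]
#' states <- tibble::tibble(state = "all_on")
#' states[genes] <- 1
#' synth <- generate_from_states(states, prof,
#'                               config = generation_config(5, seed = 1))
#' @export
generate_from_states <- function(states, profiles, mapping = NULL,
                                 config = generation_config()) {
  validate_states(states)
  stopifnot(inherits(profiles, "reference_profiles"))
  p <- profiles$profiles
  nodes <- gene_ids(states)
  if (is.null(mapping)) mapping <- tibble::tibble(node = nodes, gene = nodes)
  unmapped <- setdiff(nodes, mapping$node)
  if (length(unmapped))
    abort(sprintf("unmapped node(s): %s", paste(unmapped, collapse = ", ")))
  mapping <- mapping[match(nodes, mapping$node), ]
  if (anyDuplicated(mapping$gene)) abort("`mapping` must be injective (one gene per node)")
  missing <- setdiff(mapping$gene, p$gene)
  if (length(missing))
    abort(sprintf("mapped gene(s) absent from profiles: %s", paste(missing, collapse = ", ")))
  cats <- p$category[match(mapping$gene, p$gene)]
  if (any(cats == "discarded"))
    abort(sprintf("discarded gene(s) in mapping: %s",
                  paste(mapping$gene[cats == "discarded"], collapse = ", ")))

  k <- config$n_samples_per_state
  n_states <- nrow(states)
  n_cells <- n_states * k
  state_ids <- as.character(states[[1L]])
  source_state <- rep(state_ids, each = k)
  out <- tibble::tibble(
    cell = paste0(source_state, "_", rep(seq_len(k), times = n_states)))

  for (j in seq_along(nodes)) {
    node <- nodes[j]; gene <- mapping$gene[j]
    row <- p[match(gene, p$gene), ]
    seed_g <- if (is.null(config$seed)) NULL else derive_seed(config$seed, paste0("gen:", gene))
    vals <- with_seed(seed_g, {
      draws <- numeric(n_cells)
      st <- rep(as.numeric(states[[node]]), each = k)
      for (s in c(0, 1)) {
        idx <- which(st == s)
        if (!length(idx)) next
        draws[idx] <- if (row$fit_type == "bimodal")
          sample_bimodal(s, row, length(idx)) else sample_unimodal(s, row, length(idx))
      }
      draws <- clip_nonnegative(draws)
      if (config$dropout_mode != "none") {
        target <- if (config$dropout_mode == "learned") row$tau_ref
          else {
            if (!gene %in% names(config$user_rates) && !node %in% names(config$user_rates))
              abort(sprintf("no user dropout rate for gene %s", gene))
            unname(config$user_rates[[if (gene %in% names(config$user_rates)) gene else node]])
          }
        beta <- dropout_norm_constant(draws, row$lambda, target)
        pr <- dropout_probability(draws, row$lambda, beta)
        draws[rbinom(n_cells, 1L, pr) == 1L] <- 0
      }
      draws
    })
    out[[gene]] <- vals
  }
  attr(out, "source_state") <- source_state
  out
}
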