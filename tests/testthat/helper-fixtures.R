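# Shared fixtures and independent oracles. The standard fixture (10 genes per
# category, 2000 cells, seed 1) and its learnt profiles are computed once per
# test run and reused across files.

.fx <- new.env(parent = emptyenv())

std_fixture <- function() {
  if (is.null(.fx$ref)) {
    spec <- fixture_spec(n_per_category = 10, n_cells = 2000, seed = 1)
    .fx$ref <- generate_reference_fixture(spec, seed = 1)
  }
  .fx$ref
}

std_profiles <- function() {
  if (is.null(.fx$prof)) .fx$prof <- learn_reference(std_fixture()$expr)
  .fx$prof
}

small_fixture <- function() {
  if (is.null(.fx$small)) {
    spec <- fixture_spec(n_per_category = 4, n_cells = 400, seed = 2)
    .fx$small <- generate_reference_fixture(spec, seed = 2)
  }
  .fx$small
}

small_profiles <- function() {
  if (is.null(.fx$small_prof)) .fx$small_prof <- learn_reference(small_fixture()$expr)
  .fx$small_prof
}

# Random Boolean network from explicit truth tables (function-valued rules).
random_truth_network <- function(n, seed) {
  withr::with_seed(seed, {
    tts <- lapply(seq_len(n), function(i) sample(c(0, 1), 2^n, replace = TRUE))
  })
  rules <- lapply(seq_len(n), function(i) {
    tt <- tts[[i]]
    function(x) tt[sum(x * 2^(seq_along(x) - 1)) + 1]
  })
  names(rules) <- paste0("n", seq_len(n))
  boolean_network(rules)
}

all_configs <- function(nodes) {
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), length(nodes))))
  colnames(m) <- nodes
  m
}

# Brute-force influence-graph oracle: independent double loop over node pairs
# and configurations, straight from the definition.
oracle_influence <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  cfgs <- all_configs(nodes)
  edges <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      pos <- FALSE; neg <- FALSE
      for (r in seq_len(nrow(cfgs))) {
        x <- cfgs[r, ]
        if (x[j] != 0) next
        y <- x; y[j] <- 1
        f0 <- bn_evaluate(net, x)[i]
        f1 <- bn_evaluate(net, y)[i]
        if (f0 < f1) pos <- TRUE
        if (f0 > f1) neg <- TRUE
      }
      if (pos) edges[[length(edges) + 1]] <-
          data.frame(from = nodes[j], to = nodes[i], sign = "+")
      if (neg) edges[[length(edges) + 1]] <-
          data.frame(from = nodes[j], to = nodes[i], sign = "-")
    }
  }
  if (!length(edges)) return(data.frame(from = character(), to = character(),
                                        sign = character()))
  out <- do.call(rbind, edges)
  out[order(out$from, out$to, out$sign), ]
}

edge_key <- function(df) sort(paste(df$from, df$to, df$sign))

# Trace validator: checks the update-mode invariant of an emitted trace.
expect_valid_trace <- function(net, trace) {
  mode <- attr(trace, "update_mode")
  m <- as.matrix(trace[, -1])
  for (r in seq_len(nrow(m) - 1)) {
    x <- m[r, ]; y <- m[r + 1, ]
    if (mode == "synchronous") {
      expect_equal(unname(y), unname(bn_evaluate(net, x)))
    } else {
      diff_nodes <- which(x != y)
      expect_length(diff_nodes, 1)
      expect_equal(unname(y[diff_nodes]),
                   unname(bn_evaluate(net, x)[diff_nodes]))
    }
  }
  invisible(trace)
}
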