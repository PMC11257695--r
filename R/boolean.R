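# Boolean network representation, dynamics, influence graphs, and the
# scaled-moment matching of Boolean nodes to reference genes.

bn_token_re <- "^[A-Za-z_][A-Za-z0-9_.]*$"

compile_rule <- function(expr_text, nodes, where = "") {
  cleaned <- gsub("[!&|()]", " ", expr_text)
  toks <- strsplit(trimws(cleaned), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks)]
  bad <- toks[!(toks %in% c("0", "1")) & !grepl(bn_token_re, toks)]
  if (length(bad))
    abort(sprintf("invalid token(s)%s: %s", where, paste(bad, collapse = ", ")))
  undef <- setdiff(toks[grepl(bn_token_re, toks)], nodes)
  if (length(undef))
    abort(sprintf("undefined node reference(s)%s: %s", where, paste(undef, collapse = ", ")))
  parsed <- tryCatch(str2lang(expr_text),
                     error = function(e) abort(sprintf("syntax error%s: %s", where, expr_text)))
  parsed
}

#' Construct a Boolean network
#'
#' A Boolean network maps binary configurations to binary configurations; each
#' node carries an update function over the node states. Rules are Boolean
#' expressions over node names with `!`, `&`, `|`, parentheses and the
#' constants 0/1 (BoolNet-style syntax), or arbitrary R functions taking a
#' named 0/1 vector.
#'
#' @param rules Named list (or character vector) of rule expressions, or of
#'   functions `function(x) -> 0/1`; names are the node ids.
#' @return A `boolean_network` object.
#' @examples
#' net <- boolean_network(c(A = "!B", B = "!A"))
#' bn_is_stable(net, c(A = 1, B = 0))
#' @export
boolean_network <- function(rules) {
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes))) abort("`rules` must be named by node id")
  check_unique(nodes, "node ids")
  bad <- nodes[!grepl(bn_token_re, nodes)]
  if (length(bad)) abort(sprintf("invalid node id(s): %s", paste(bad, collapse = ", ")))
  exprs <- vector("list", length(nodes)); names(exprs) <- nodes
  fns <- vector("list", length(nodes)); names(fns) <- nodes
  for (nd in nodes) {
    r <- rules[[nd]]
    if (is.function(r)) {
      fns[[nd]] <- r
    } else {
      e <- compile_rule(as.character(r), nodes, sprintf(" in rule for %s", nd))
      exprs[[nd]] <- as.character(r)
      fns[[nd]] <- local({
        expr <- e
        function(x) as.numeric(as.logical(eval(expr, envir = as.list(x != 0))))
      })
    }
  }
  structure(list(nodes = nodes, exprs = exprs, fns = fns), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("<boolean_network: %d nodes: %s>\n", length(x$nodes),
              paste(x$nodes, collapse = ", ")))
  invisible(x)
}

#' Parse / write BoolNet-format network text
#'
#' The BoolNet text format has a `targets, factors` header followed by one
#' `node, expression` line per node. `parse_boolnet()` accepts the text as a
#' character vector of lines (or a single string); `read_boolnet()` reads a
#' file; `write_boolnet()` is the exact inverse on parsed networks.
#'
#' @param text Character vector of lines or single string.
#' @param path File path.
#' @param net A `boolean_network` built from expression rules.
#' @return A `boolean_network`; the writer returns `path` invisibly.
#' @export
parse_boolnet <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("empty network text")
  if (!grepl("^targets[[:space:]]*,[[:space:]]*factors$", lines[1L], ignore.case = TRUE))
    abort("missing 'targets, factors' header")
  body <- lines[-1L]
  parts <- regmatches(body, regexpr(",", body), invert = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    abort(sprintf("syntax error at line %d: expected 'target, expression'", bad[1L] + 1L))
  rules <- setNames(trimws(vapply(parts, `[`, "", 2L)),
                    trimws(vapply(parts, `[`, "", 1L)))
  boolean_network(as.list(rules))
}

#' @rdname parse_boolnet
#' @export
read_boolnet <- function(path) parse_boolnet(readLines(path))

#' @rdname parse_boolnet
#' @export
write_boolnet <- function(net, path) {
  stopifnot(inherits(net, "boolean_network"))
  if (any(vapply(net$exprs, is.null, TRUE)))
    abort("network has function-valued rules without expression text; cannot serialise")
  writeLines(c("targets, factors",
               sprintf("%s, %s", net$nodes, unlist(net$exprs))), path)
  invisible(path)
}

as_config <- function(net, x) {
  if (is.null(names(x))) names(x) <- net$nodes
  if (!setequal(names(x), net$nodes) || length(x) != length(net$nodes))
    abort("configuration must assign exactly the network's nodes")
  x <- x[net$nodes]
  if (anyNA(x) || !all(x %in% c(0, 1))) abort("configuration entries must be 0 or 1")
  x
}

#' Evaluate a Boolean network on a configuration
#'
#' Applies every node's update function to the configuration `x`, returning
#' the successor configuration `f(x)`.
#'
#' @param net A `boolean_network`.
#' @param x Named (or node-ordered) 0/1 vector.
#' @return Named 0/1 numeric vector.
#' @export
bn_evaluate <- function(net, x) {
  x <- as_config(net, x)
  vapply(net$nodes, function(nd) as.numeric(net$fns[[nd]](x)), 0)
}

#' Test whether a configuration is a stable state
#'
#' A configuration is stable (a fixed point) when `f(x) = x`.
#'
#' @inheritParams bn_evaluate
#' @return `TRUE` or `FALSE`.
#' @export
bn_is_stable <- function(net, x) {
  x <- as_config(net, x)
  all(bn_evaluate(net, x) == x)
}

trace_tbl <- function(net, configs, mode) {
  m <- do.call(rbind, configs)
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, state = sprintf("t%d", seq_len(nrow(m)) - 1L),
                            .before = 1L)
  attr(out, "update_mode") <- mode
  out
}

#' Fully asynchronous random walk
#'
#' From `x0`, repeatedly picks uniformly at random one node whose update
#' function disagrees with its current state and flips it, so that any two
#' successive configurations differ on exactly one node `i` with
#' \eqn{x_i^{m+1} = f_i(x^m)}. Terminates at a stable state or after
#' `max_steps` flips.
#'
#' @param net A `boolean_network`.
#' @param x0 Initial configuration (named 0/1 vector).
#' @param max_steps Maximum number of flips (default 1000).
#' @param seed Optional integer seed.
#' @return A trace tibble (`state` id column `t0`, `t1`, ... plus node
#'   columns) with attribute `update_mode = "asynchronous"`.
#' @examples
#' star <- read_boolnet(system.file("extdata", "star.bnet", package = "boolexpr"))
#' x0 <- setNames(c(1, rep(0, 8)), star$nodes)
#' bn_async_walk(star, x0, seed = 1)
#' @export
bn_async_walk <- function(net, x0, max_steps = 1000L, seed = NULL) {
  x <- as_config(net, x0)
  stopifnot(max_steps >= 0)
  with_seed(seed, {
    configs <- list(x)
    for (step in seq_len(max_steps)) {
      fx <- bn_evaluate(net, x)
      unstable <- which(fx != x)
      if (!length(unstable)) break
      i <- if (length(unstable) == 1L) unstable else sample(unstable, 1L)
      x[i] <- fx[i]
      configs[[length(configs) + 1L]] <- x
    }
    trace_tbl(net, configs, "asynchronous")
  })
}

#' Synchronous trace
#'
#' Deterministic iteration \eqn{x^{m+1} = f(x^m)} for `k` steps.
#'
#' @inheritParams bn_async_walk
#' @param k Number of update steps (>= 1).
#' @return A trace tibble of `k + 1` configurations with attribute
#'   `update_mode = "synchronous"`.
#' @export
bn_sync_trace <- function(net, x0, k) {
  x <- as_config(net, x0)
  stopifnot(k >= 1)
  configs <- vector("list", k + 1L)
  configs[[1L]] <- x
  for (m in seq_len(k)) {
    x <- bn_evaluate(net, x)
    configs[[m + 1L]] <- x
  }
  trace_tbl(net, configs, "synchronous")
}

#' Signed influence graph of a Boolean network
#'
#' Exhaustively enumerates configurations: there is a positive edge
#' `j -> i` iff flipping node `j` from 0 to 1 increases \eqn{f_i} in some
#' configuration, and a negative edge iff it decreases it in some
#' configuration. Both signs may coexist (non-monotone dependence). Guarded
#' to networks of at most 20 nodes (the enumeration is exponential).
#'
#' @param net A `boolean_network`.
#' @return A tibble with columns `from`, `to`, `sign` (`"+"` or `"-"`).
#' @export
influence_graph <- function(net) {
  n <- length(net$nodes)
  if (n > 20L) abort("influence_graph() enumerates all configurations; n must be <= 20")
  combs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  colnames(combs) <- net$nodes
  edges <- list()
  for (j in seq_len(n)) {
    base <- combs[combs[, j] == 0, , drop = FALSE]
    pos <- neg <- rep(FALSE, n)
    for (r in seq_len(nrow(base))) {
      x0 <- base[r, ]
      x1 <- x0; x1[j] <- 1
      f0 <- bn_evaluate(net, x0)
      f1 <- bn_evaluate(net, x1)
      pos <- pos | (f0 < f1)
      neg <- neg | (f0 > f1)
    }
    for (i in which(pos))
      edges[[length(edges) + 1L]] <- tibble::tibble(from = net$nodes[j],
                                                    to = net$nodes[i], sign = "+")
    for (i in which(neg))
      edges[[length(edges) + 1L]] <- tibble::tibble(from = net$nodes[j],
                                                    to = net$nodes[i], sign = "-")
  }
  if (!length(edges))
    return(tibble::tibble(from = character(), to = character(), sign = character()))
  dplyr::arrange(dplyr::bind_rows(edges), .data$from, .data$to, .data$sign)
}

# Population (biased) moments; skewness / excess kurtosis imputed as 0 for
# degenerate (zero-variance) vectors.
raw_moments <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0))
  c(mean = m, variance = m2,
    skewness = mean((x - m)^3) / m2^1.5,
    kurtosis = mean((x - m)^4) / m2^2 - 3)
}

#' Scaled first four moments
#'
#' Computes mean, variance, skewness and excess kurtosis (population
#' formulae; identical for Boolean and real vectors, with degenerate
#' skewness/kurtosis imputed as 0) and min-max scales them with a scaler
#' fitted on the reference genes' moments, so heterogeneous moment ranges
#' share a common footing.
#'
#' @param x Numeric or 0/1 vector (length >= 2).
#' @param scaler A scaler from [moment_scaler()], or `NULL` for raw moments.
#' @return A named numeric vector of the four (scaled) moments.
#' @export
scaled_moments <- function(x, scaler = NULL) {
  if (length(x) < 2L) abort("`x` must have length >= 2")
  m <- raw_moments(x)
  if (is.null(scaler)) return(m)
  (m - scaler$min) / ifelse(scaler$max > scaler$min, scaler$max - scaler$min, 1)
}

#' Min-max moment scaler fitted on reference gene moments
#'
#' @param moments Matrix or data frame with columns `mean`, `variance`,
#'   `skewness`, `kurtosis` (one row per reference gene).
#' @return A `moment_scaler` list with `min` and `max` per moment; reference
#'   minima map to 0 and maxima to 1 under [scaled_moments()].
#' @export
moment_scaler <- function(moments) {
  m <- as.matrix(moments[, c("mean", "variance", "skewness", "kurtosis")])
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max)),
            class = "moment_scaler")
}

knn_majority <- function(d, labels, k) {
  ord <- order(d, seq_along(d))   # deterministic tie-break by reference order
  nb <- ord[seq_len(k)]
  tab <- table(labels[nb])
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) return(winners)
  labels[nb][labels[nb] %in% winners][1L]  # tie: label of the nearest
}

scaled_moments_vec <- function(m, scaler) {
  (m - scaler$min) / ifelse(scaler$max > scaler$min, scaler$max - scaler$min, 1)
}

# Scale the reference frame and the node frame each by its own min-max
# scaler, so that Boolean moments (mean in [0, 1], variance <= 0.25) and
# pseudocount moments share a common footing: what matters is each node's /
# gene's relative position within its own frame. Node moments whose range is
# degenerate (e.g. a single node) fall back to the reference scaler for that
# moment.
two_frame_scaled <- function(ref_m, node_m) {
  sc_ref <- moment_scaler(ref_m)
  sc_node <- moment_scaler(node_m)
  degen <- sc_node$max <= sc_node$min
  sc_node$min[degen] <- sc_ref$min[degen]
  sc_node$max[degen] <- sc_ref$max[degen]
  list(ref = t(apply(ref_m, 1L, scaled_moments_vec, scaler = sc_ref)),
       node = t(apply(node_m, 1L, scaled_moments_vec, scaler = sc_node)))
}

#' Classify Boolean nodes by k-nearest reference genes
#'
#' Euclidean k-nearest-neighbour vote in scaled-moment space, trained on the
#' reference genes' scaled moments labelled with their distribution
#' categories. Each frame (reference genes, Boolean nodes) is min-max scaled
#' by its own moment ranges so the heterogeneous scales of Boolean and
#' pseudocount moments become comparable; degenerate node ranges fall back to
#' the reference scaler. Ties are broken deterministically (distance, then
#' reference order; split votes go to the nearest tied label).
#'
#' @param node_moments Matrix/data frame of node moments (rows = nodes,
#'   columns `mean`, `variance`, `skewness`, `kurtosis`), unscaled.
#' @param ref_moments Same for reference genes.
#' @param ref_labels Character vector of gene categories (`"unimodal"`,
#'   `"bimodal"`, `"zero_inflated"`).
#' @param k Number of neighbours (default 5).
#' @return Character vector of predicted categories, one per node row.
#' @export
classify_nodes <- function(node_moments, ref_moments, ref_labels, k = 5L) {
  rm_ <- as.matrix(ref_moments[, c("mean", "variance", "skewness", "kurtosis")])
  if (k < 1L || k > nrow(rm_)) abort("`k` must be between 1 and the number of reference genes")
  nm <- as.matrix(node_moments[, c("mean", "variance", "skewness", "kurtosis"), drop = FALSE])
  fr <- two_frame_scaled(rm_, nm)
  vapply(seq_len(nrow(nm)), function(i) {
    d <- sqrt(rowSums((fr$ref - matrix(fr$node[i, ], nrow(fr$ref), 4L, byrow = TRUE))^2))
    knn_majority(d, ref_labels, k)
  }, "")
}

#' Match Boolean nodes to reference genes
#'
#' Classifies each node of a Boolean state matrix by [classify_nodes()] and
#' then, within each category, assigns nodes to distinct reference genes of
#' that category greedily in order of ascending nearest-gene distance in
#' scaled-moment space (ties broken lexicographically by node id then gene
#' id). The mapping is injective: no gene represents two nodes.
#'
#' @param states Strictly binary state tibble (id column + node columns).
#' @param profiles A `reference_profiles` object.
#' @param k Neighbours for the category vote (default 5).
#' @return A tibble with columns `node`, `gene`, `category`, `distance`,
#'   usable as the `mapping` of [generate_from_states()].
#' @export
match_genes <- function(states, profiles, k = 5L) {
  validate_states(states)
  p <- profiles$profiles
  kept <- p[p$category != "discarded", ]
  if (!nrow(kept)) abort("profiles contain no usable genes")
  ref_m <- cbind(mean = kept$mean_all, variance = kept$var_all,
                 skewness = kept$skewness_all, kurtosis = kept$kurtosis_all)
  rownames(ref_m) <- kept$gene
  nodes <- gene_ids(states)
  node_m <- t(vapply(nodes, function(nd) raw_moments(as.numeric(states[[nd]])),
                     numeric(4L)))
  colnames(node_m) <- c("mean", "variance", "skewness", "kurtosis")
  cats <- classify_nodes(node_m, ref_m, kept$category, k)

  fr <- two_frame_scaled(ref_m, node_m)
  ref_sc <- fr$ref
  rownames(ref_sc) <- kept$gene
  node_sc <- fr$node
  rownames(node_sc) <- nodes
  out <- list()
  for (cat in unique(cats)) {
    nds <- nodes[cats == cat]
    pool <- kept$gene[kept$category == cat]
    if (length(nds) > length(pool))
      abort(sprintf("category %s exhausted: %d node(s) but only %d reference gene(s)",
                    cat, length(nds), length(pool)))
    nds <- sort(nds)
    repeat {
      un <- setdiff(nds, vapply(out, function(r) r$node, ""))
      if (!length(un)) break
      best <- NULL
      for (nd in un) {
        d <- sqrt(rowSums((ref_sc[pool, , drop = FALSE] -
                             matrix(node_sc[nd, ], length(pool), 4L, byrow = TRUE))^2))
        o <- order(d, pool)
        cand <- list(node = nd, gene = pool[o[1L]], category = cat, distance = d[o[1L]])
        if (is.null(best) || cand$distance < best$distance ||
            (cand$distance == best$distance &&
             (cand$node < best$node || (cand$node == best$node && cand$gene < best$gene))))
          best <- cand
      }
      out[[length(out) + 1L]] <- best
      pool <- setdiff(pool, best$gene)
    }
  }
  res <- dplyr::bind_rows(out)
  res[match(nodes, res$node), ]
}
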