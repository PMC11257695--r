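test_that("BoolNet text parses, evaluates and round-trips", {
  net <- parse_boolnet(c("targets, factors", "A, B", "B, !A"))
  expect_equal(unname(bn_evaluate(net, c(A = 0, B = 1))), c(1, 1))
  expect_equal(unname(bn_evaluate(net, c(A = 1, B = 0))), c(0, 0))
  const <- parse_boolnet(c("targets, factors", "A, 1"))
  expect_equal(unname(bn_evaluate(const, c(A = 0))), 1)
  star_path <- system.file("extdata", "star.bnet", package = "boolexpr")
  star <- read_boolnet(star_path)
  tmp <- withr::local_tempfile(fileext = ".bnet")
  write_boolnet(star, tmp)
  star2 <- parse_boolnet(readLines(tmp))
  expect_equal(star2$nodes, star$nodes)
  expect_equal(star2$exprs, star$exprs)
  expect_error(parse_boolnet(c("targets, factors", "A, B & C")), "undefined")
  expect_error(parse_boolnet(c("A, B")), "header")
})

test_that("expression rules agree with an exhaustive truth-table oracle", {
  net <- parse_boolnet(c("targets, factors",
                         "a, b | !c", "b, a & c", "c, !a"))
  cfgs <- all_configs(net$nodes)
  for (r in seq_len(nrow(cfgs))) {
    x <- cfgs[r, ]
    expected <- c(as.numeric(x["b"] | !x["c"]),
                  as.numeric(x["a"] & x["c"]),
                  as.numeric(!x["a"]))
    expect_equal(unname(bn_evaluate(net, x)), expected)
  }
})

test_that("stable states are exactly the fixed points", {
  star <- read_boolnet(system.file("extdata", "star.bnet", package = "boolexpr"))
  all_on <- setNames(rep(1, length(star$nodes)), star$nodes)
  expect_true(bn_is_stable(star, all_on))
  neg <- boolean_network(c(A = "!A"))
  expect_false(bn_is_stable(neg, c(A = 0)))
  expect_false(bn_is_stable(neg, c(A = 1)))
  # agreement with exhaustive enumeration on random 3-node networks
  for (s in 1:20) {
    net <- random_truth_network(3, seed = s)
    cfgs <- all_configs(net$nodes)
    for (r in seq_len(nrow(cfgs))) {
      x <- cfgs[r, ]
      expect_equal(bn_is_stable(net, x), all(bn_evaluate(net, x) == x))
    }
  }
})

test_that("asynchronous walks satisfy the one-flip invariant and stop at fixed points", {
  star <- read_boolnet(system.file("extdata", "star.bnet", package = "boolexpr"))
  all_on <- setNames(rep(1, length(star$nodes)), star$nodes)
  expect_equal(nrow(bn_async_walk(star, all_on, seed = 1)), 1)  # already stable
  x0 <- setNames(c(1, rep(0, 8)), star$nodes)
  tr <- bn_async_walk(star, x0, seed = 5)
  expect_valid_trace(star, tr)
  expect_equal(nrow(tr), 9)  # 8 genes activate one per step
  counts <- rowSums(tr[, -1])
  expect_false(is.unsorted(counts))                        # monotone activation
  expect_true(bn_is_stable(star, unlist(tr[nrow(tr), -1])))
})

test_that("asynchronous walks stay within the reachable set", {
  net <- random_truth_network(3, seed = 99)
  # brute-force BFS over the fully asynchronous transition relation
  key <- function(x) paste(x, collapse = "")
  frontier <- list(c(n1 = 0, n2 = 1, n3 = 0))
  reach <- key(frontier[[1]])
  while (length(frontier)) {
    x <- frontier[[1]]; frontier <- frontier[-1]
    fx <- bn_evaluate(net, x)
    for (i in which(fx != x)) {
      y <- x; y[i] <- fx[i]
      if (!key(y) %in% reach) {
        reach <- c(reach, key(y)); frontier <- c(frontier, list(y))
      }
    }
  }
  visited <- character()
  for (s in 1:200) {
    tr <- bn_async_walk(net, c(n1 = 0, n2 = 1, n3 = 0), max_steps = 30, seed = s)
    expect_valid_trace(net, tr)
    visited <- union(visited, apply(tr[, -1], 1, paste, collapse = ""))
  }
  expect_true(all(visited %in% reach))
})

test_that("synchronous traces iterate the global map", {
  swap <- boolean_network(c(A = "B", B = "A"))
  tr <- bn_sync_trace(swap, c(A = 0, B = 1), k = 4)
  expect_valid_trace(swap, tr)
  expect_equal(unname(as.matrix(tr[, -1])[, 1]), c(0, 1, 0, 1, 0))  # period-2 cycle
  fixed <- bn_sync_trace(swap, c(A = 1, B = 1), k = 3)
  expect_true(all(as.matrix(fixed[, -1]) == 1))
  # agreement with iterated evaluation
  net <- random_truth_network(3, seed = 7)
  x <- c(n1 = 1, n2 = 0, n3 = 1)
  tr2 <- bn_sync_trace(net, x, k = 5)
  for (r in 2:6) {
    x <- bn_evaluate(net, x)
    expect_equal(unname(unlist(tr2[r, -1])), unname(x))
  }
})

test_that("influence graphs capture signed and non-monotone dependencies", {
  cp <- boolean_network(c(A = "B", B = "B"))
  g <- influence_graph(cp)
  expect_equal(g[g$to == "A", ]$from, "B")
  expect_equal(g[g$to == "A", ]$sign, "+")
  ng <- influence_graph(boolean_network(c(A = "!B", B = "B")))
  expect_equal(ng[ng$to == "A", ]$sign, "-")
  xor <- boolean_network(c(A = "(B & !C) | (!B & C)", B = "B", C = "C"))
  gx <- influence_graph(xor)
  expect_setequal(gx[gx$from == "B" & gx$to == "A", ]$sign, c("+", "-"))
  expect_setequal(gx[gx$from == "C" & gx$to == "A", ]$sign, c("+", "-"))
})

test_that("influence graphs match the brute-force oracle on random networks", {
  for (s in 1:40) {
    n <- 2 + s %% 2
    net <- random_truth_network(n, seed = 1000 + s)
    expect_equal(edge_key(influence_graph(net)), edge_key(oracle_influence(net)))
  }
})

test_that("scaled moments use population formulae with degenerate imputation", {
  m1 <- scaled_moments(rep(1, 20))
  expect_equal(unname(m1), c(1, 0, 0, 0))
  mb <- scaled_moments(rep(c(0, 1), 25))
  expect_equal(unname(mb), c(0.5, 0.25, 0, -2))  # Bernoulli(1/2) closed forms
  ref <- rbind(c(0.2, 0.1, 1, 2), c(0.8, 0.3, -1, 5))
  colnames(ref) <- c("mean", "variance", "skewness", "kurtosis")
  sc <- moment_scaler(ref)
  expect_equal(unname(boolexpr:::scaled_moments_vec(ref[1, ], sc)), c(0, 0, 1, 0))
  expect_equal(unname(boolexpr:::scaled_moments_vec(ref[2, ], sc)), c(1, 1, 0, 1))
})

test_that("node classification votes among nearest reference genes", {
  tt <- tidy(std_profiles())
  kept <- tt[tt$category != "discarded", ]
  ref_m <- data.frame(mean = kept$mean_all, variance = kept$var_all,
                      skewness = kept$skewness_all, kurtosis = kept$kurtosis_all)
  # a node identical in moments to one reference gene, k = 1 -> its label
  pred <- classify_nodes(ref_m[3, , drop = FALSE], ref_m, kept$category, k = 1)
  expect_equal(pred, kept$category[3])
  n <- 2000
  balanced <- rep(c(0, 1), n / 2)                     # varies maximally
  rare <- c(rep(0, n - 20), rep(1, 20))               # almost always inactive
  node_m <- rbind(scaled_moments(balanced), scaled_moments(rare))
  colnames(node_m) <- c("mean", "variance", "skewness", "kurtosis")
  preds <- classify_nodes(node_m, ref_m, kept$category, k = 5)
  expect_equal(preds[1], "bimodal")
  expect_equal(preds[2], "zero_inflated")
  expect_error(classify_nodes(node_m, ref_m, kept$category, k = nrow(ref_m) + 1), "k")
})

test_that("node-gene matching is injective and replays the greedy rule", {
  prof <- std_profiles()
  states <- withr::with_seed(13, {
    s <- tibble::tibble(state = sprintf("s%02d", 1:40))
    s$na <- rep(c(0, 1), 20)                # bimodal-ish
    s$nb <- rbinom(40, 1, 0.45)
    s$nc <- c(rep(1, 38), 0, 0)             # nearly always active
    s
  })
  map <- match_genes(states, prof, k = 3)
  expect_equal(nrow(map), 3)
  expect_false(anyDuplicated(map$gene) > 0)
  expect_setequal(map$node, c("na", "nb", "nc"))
  # mapped genes carry the node's predicted category and are not discarded
  tt <- tidy(prof)
  expect_true(all(tt$category[match(map$gene, tt$gene)] == map$category))
  # independent replay of the documented greedy procedure
  kept <- tt[tt$category != "discarded", ]
  ref_m <- cbind(mean = kept$mean_all, variance = kept$var_all,
                 skewness = kept$skewness_all, kurtosis = kept$kurtosis_all)
  node_m <- t(vapply(c("na", "nb", "nc"),
                     function(nd) scaled_moments(as.numeric(states[[nd]])), numeric(4)))
  colnames(node_m) <- colnames(ref_m)
  fr <- boolexpr:::two_frame_scaled(ref_m, node_m)  # shared coordinates
  rownames(fr$ref) <- kept$gene; rownames(fr$node) <- c("na", "nb", "nc")
  for (cat in unique(map$category)) {
    nodes_cat <- sort(map$node[map$category == cat])
    pool <- kept$gene[kept$category == cat]
    assigned <- character(0)
    while (length(nodes_cat)) {
      cand <- do.call(rbind, lapply(nodes_cat, function(nd) {
        d <- vapply(pool, function(g)
          sqrt(sum((fr$ref[g, ] - fr$node[nd, ])^2)), 0)
        o <- order(d, pool)
        data.frame(node = nd, gene = pool[o[1]], d = d[o[1]])
      }))
      cand <- cand[order(cand$d, cand$node, cand$gene), ]
      pick <- cand[1, ]
      expect_equal(map$gene[map$node == pick$node], pick$gene)
      assigned <- c(assigned, pick$gene)
      pool <- setdiff(pool, pick$gene)
      nodes_cat <- setdiff(nodes_cat, pick$node)
    }
  }
})

test_that("category-exhausted matching errors with counts", {
  prof <- small_profiles()
  tt <- tidy(prof)
  n_zi <- sum(tt$category == "zero_inflated")
  states <- tibble::tibble(state = sprintf("s%d", 1:50))
  for (i in seq_len(n_zi + 1))   # one more nearly-silent node than ZI genes
    states[[paste0("z", i)]] <- c(rep(0, 48), 1, 1)
  expect_error(match_genes(states, prof), "exhausted")
})
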