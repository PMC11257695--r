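test_that("fixture generation is deterministic and honours dropout targets", {
  spec <- fixture_spec(n_per_category = 3, n_cells = 500, seed = 5)
  a <- generate_reference_fixture(spec, seed = 9)
  b <- generate_reference_fixture(spec, seed = 9)
  expect_equal(a$expr, b$expr)
  expect_false(isTRUE(all.equal(a$expr, generate_reference_fixture(spec, seed = 10)$expr)))
  # a zero dropout target leaves only clipping zeros
  spec0 <- spec
  spec0$target_dropout <- 0
  clean <- generate_reference_fixture(spec0, seed = 9)
  for (i in seq_len(nrow(spec0))) {
    g <- spec0$gene[i]
    clip_mass <- if (spec0$family[i] == "mixture")
      spec0$phi1[i] * pnorm(0, spec0$mu1[i], spec0$sigma1[i]) +
        (1 - spec0$phi1[i]) * pnorm(0, spec0$mu2[i], spec0$sigma2[i])
    else pnorm(0, spec0$mu[i], spec0$sigma[i])
    expect_lt(abs(mean(clean$expr[[g]] == 0) - clip_mass),
              4 * sqrt(clip_mass * (1 - clip_mass) / 500) + 0.01)
  }
  # declared targets are realised within Poisson-binomial tolerance
  for (i in seq_len(nrow(spec))) {
    g <- spec$gene[i]
    expect_lt(abs(mean(a$expr[[g]] == 0) - spec$target_dropout[i]), 0.1)
  }
})

test_that("summary moments agree with a naive two-pass oracle", {
  expr <- withr::with_seed(17, {
    m <- matrix(pmax(rnorm(50 * 20, 2, 1.5), 0), 50, 20,
                dimnames = list(NULL, paste0("g", 1:20)))
    out <- tibble::tibble(cell = paste0("c", 1:50))
    out[colnames(m)] <- as.data.frame(m)
    out
  })
  s <- summarise_expression(expr)
  for (g in paste0("g", 1:20)) {
    x <- expr[[g]]
    mu <- sum(x) / length(x)
    m2 <- sum((x - mu)^2) / length(x)
    m3 <- sum((x - mu)^3) / length(x)
    m4 <- sum((x - mu)^4) / length(x)
    row <- s[s$gene == g, ]
    expect_equal(row$mean, mu, tolerance = 1e-10)
    expect_equal(row$variance, m2, tolerance = 1e-10)
    expect_equal(row$skewness, m3 / m2^1.5, tolerance = 1e-10)
    expect_equal(row$kurtosis, m4 / m2^2 - 3, tolerance = 1e-10)
    expect_equal(row$dropout_rate, mean(x == 0))
  }
  const <- tibble::tibble(cell = c("a", "b"), g1 = c(2, 2), g2 = c(0, 0))
  sc <- summarise_expression(const)
  expect_equal(sc$variance, c(0, 0))
  expect_equal(sc$dropout_rate, c(0, 1))
})

test_that("a summary compared with itself gives unit correlations", {
  s <- summarise_expression(small_fixture()$expr)
  cmp <- compare_summaries(s, s)
  expect_true(all(abs(cmp$stat_cor$pearson - 1) < 1e-12))
  expect_true(all(abs(cmp$stat_cor$spearman - 1) < 1e-12))
  expect_equal(cmp$agreement, 1)
  expect_error(compare_summaries(s, s[-1, ]), "same genes")
})

test_that("the full generation loop reproduces reference statistics", {
  prof <- std_profiles()
  ref <- std_fixture()
  bin <- suppressMessages(binarise(ref$expr, prof))
  kept <- names(bin)[-1]
  states <- resolve_undetermined(bin, ref$expr[, c("cell", kept)], prof)
  synth <- generate_from_states(states, prof,
                                config = generation_config(1, "learned", seed = 21))
  s_ref <- summarise_expression(ref$expr[, c("cell", kept)])
  s_syn <- summarise_expression(synth[, c("cell", kept)])
  cmp <- compare_summaries(s_ref, s_syn)
  expect_gte(cmp$stat_cor$pearson[cmp$stat_cor$statistic == "mean"], 0.9)
  expect_gte(cmp$stat_cor$spearman[cmp$stat_cor$statistic == "dropout_rate"], 0.9)
  # mean-variance and mean-dropout monotone trends are preserved
  pc <- cmp$pair_cor
  md <- pc[pc$pair == "mean-dropout_rate", ]
  expect_lt(md$ref_spearman, -0.5)
  expect_lt(md$synth_spearman, -0.5)
  # S10-style negative control: without dropout simulation the mean-dropout
  # relationship collapses
  synth0 <- generate_from_states(states, prof,
                                 config = generation_config(1, "none", seed = 22))
  s_syn0 <- summarise_expression(synth0[, c("cell", kept)])
  cmp0 <- compare_summaries(s_ref, s_syn0)
  md0 <- cmp0$pair_cor[cmp0$pair_cor$pair == "mean-dropout_rate", ]
  expect_lt(abs(md0$synth_pearson), 0.35)
})

test_that("skewed unimodal fixtures still binarise about 2q of observations", {
  spec <- fixture_spec(n_per_category = 4, n_cells = 1500,
                       unimodal_family = "lognormal", seed = 6)
  ref <- generate_reference_fixture(spec, seed = 6)
  prof <- learn_reference(ref$expr)
  tt <- tidy(prof)
  uni <- tt$gene[tt$category == "unimodal" & startsWith(tt$gene, "uni")]
  expect_gt(length(uni), 0)
  bin <- suppressMessages(binarise(ref$expr, prof))
  for (g in intersect(uni, names(bin)))
    expect_lt(abs(mean(!is.na(bin[[g]])) - 0.10), 2 / sqrt(1500) + 0.03)
})
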