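test_that("gene_stats separates full-data and non-zero statistics", {
  st <- gene_stats(c(0, 0, 2, 4))
  expect_equal(st$dropout_rate, 0.5)
  expect_equal(st$mean_nz, 3)
  expect_equal(st$amplitude, 4)
  expect_equal(st$n_nonzero, 2)
  z <- gene_stats(rep(0, 50))
  expect_equal(z$dropout_rate, 1)
  expect_equal(z$n_nonzero, 0)
  expect_equal(z$amplitude, 0)
  expect_true(is.na(z$mean_nz) && is.na(z$dip_pvalue) && is.na(z$bimodality_index))
  expect_error(gene_stats(numeric(0)), "length")
  expect_error(gene_stats(c(1, -1)), "non-negative")
})

test_that("well-separated mixtures trigger both bimodality statistics", {
  x <- withr::with_seed(5, c(rnorm(500, 2, 0.5), rnorm(500, 6, 0.5)))
  st <- gene_stats(x)
  expect_lt(st$dip_pvalue, 0.05)
  expect_gt(st$bimodality_index, 1.5)
  # oracle for the index: delta * sqrt(p (1 - p)) at the generating values
  expect_lt(abs(st$bimodality_index - (6 - 2) / 0.5 * sqrt(0.25)), 1.5)
})

test_that("classification cascade fires in its fixed order", {
  config <- classifier_config()
  high_drop <- gene_stats(c(rep(0, 96), rnorm(4, 5) + 10))   # tau = 0.96
  high_drop$n_nonzero <- 20L                                 # isolate the dropout rule
  expect_equal(classify_gene(high_drop, median_amplitude = 1, config), "discarded")
  flat <- gene_stats(withr::with_seed(1, runif(100, 2, 2.5)))  # amplitude ~ 0.5
  expect_equal(classify_gene(flat, median_amplitude = 6, config), "discarded")
  uni <- withr::with_seed(2, c(rep(0, 50), rnorm(950, 5, 1)))  # 5% zeros, peak ~ 5
  expect_equal(classify_gene(gene_stats(uni), 6, config), "unimodal")
  zi <- withr::with_seed(3, c(rep(0, 700), rnorm(300, 2, 0.5)))  # peak at 0
  expect_equal(classify_gene(gene_stats(zi), 6, config), "zero_inflated")
  bim <- withr::with_seed(4, c(rnorm(400, 1.5, 0.4), rnorm(600, 5, 0.4)))
  expect_equal(classify_gene(gene_stats(bim), 6, config), "bimodal")
})

test_that("mixture fits recover generating parameters with mu2 > mu1", {
  x <- withr::with_seed(9, c(rep(0, 100), rnorm(1000, 1, 0.3), rnorm(1000, 5, 0.3)))
  fit <- fit_profile(x, "bimodal")
  expect_lt(abs(fit$mu1 - 1), 0.1)
  expect_lt(abs(fit$mu2 - 5), 0.1)
  expect_lt(abs(fit$phi1 - 0.5), 0.05)
  expect_gt(fit$mu2, fit$mu1)
  expect_equal(fit$phi1 + fit$phi2, 1)
  # dropout parameters ride along
  nz <- x[x > 0]
  expect_equal(fit$lambda, log(2) / mean(nz))
  expect_equal(fit$tau_ref, 100 / 2100)
})

test_that("unimodal and constant fits carry quantile tables", {
  fit <- fit_profile(rep(3.5, 20), "unimodal")
  expect_equal(fit$mu, 3.5)
  expect_equal(fit$sigma, 0)
  expect_equal(fit$iqr, 0)
  x <- c(rep(0, 5), 1:100)
  ufit <- fit_profile(x, "unimodal")
  expect_equal(boolexpr:::profile_quantile(ufit, 0.05), unname(quantile(1:100, 0.05)))
  expect_equal(ufit$iqr, unname(quantile(1:100, .75) - quantile(1:100, .25)))
})

test_that("zero-inflated genes are fitted through their non-zero sub-case", {
  x <- withr::with_seed(10, c(rep(0, 700), rnorm(300, 2, 0.5)))
  fit <- fit_profile(x, "zero_inflated")
  expect_true(fit$zero_inflated)
  expect_equal(fit$fit_type, "unimodal")
  expect_lt(abs(fit$mu - 2), 0.15)
  xb <- withr::with_seed(11, c(rep(0, 600), rnorm(200, 1, 0.3), rnorm(200, 5, 0.3)))
  fitb <- fit_profile(xb, "zero_inflated")
  expect_true(fitb$zero_inflated)
  expect_equal(fitb$fit_type, "bimodal")
})

test_that("learn_reference recovers fixture categories and is deterministic", {
  prof <- std_profiles()
  truth <- std_fixture()$truth
  tt <- tidy(prof)
  expect_setequal(tt$gene, truth$gene)
  hits <- sum(tt$category[match(truth$gene, tt$gene)] == truth$category)
  expect_gte(hits, 27)  # >= 90% recovery on well-separated fixtures
  expect_equal(sum(glance(prof)[, c("n_unimodal", "n_bimodal",
                                    "n_zero_inflated", "n_discarded")]),
               nrow(tt))
  prof2 <- learn_reference(std_fixture()$expr)
  expect_equal(tidy(prof2), tt)
})

test_that("an all-zero gene is discarded with a reason", {
  expr <- small_fixture()$expr
  expr$dead <- 0
  prof <- learn_reference(expr)
  row <- tidy(prof)[tidy(prof)$gene == "dead", ]
  expect_equal(row$category, "discarded")
  expect_match(row$discard_reason, "dropout")
})

test_that("classification is invariant to cell order and duplication", {
  expr <- small_fixture()$expr
  base <- tidy(learn_reference(expr))
  shuffled <- expr[withr::with_seed(3, sample(nrow(expr))), ]
  expect_equal(tidy(learn_reference(shuffled))$category, base$category)
  doubled <- dplyr::bind_rows(expr, dplyr::mutate(expr, cell = paste0(cell, "_dup")))
  expect_equal(tidy(learn_reference(doubled))$category, base$category)
})

test_that("profiles serialise losslessly to JSON", {
  prof <- small_profiles()
  path <- withr::local_tempfile(fileext = ".json")
  write_profiles(prof, path)
  back <- read_profiles(path)
  expect_equal(tidy(back), tidy(prof))
  expect_equal(back$n_cells, prof$n_cells)
  expect_equal(unclass(back$config), unclass(prof$config))
})
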