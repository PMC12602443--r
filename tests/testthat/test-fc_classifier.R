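test_that("histogram bins floor toward minus infinity and conserve mass", {
  h <- build_histogram(c(0.00, 0.04, 0.09))
  expect_identical(nrow(h), 1L)
  expect_equal(h$bin_left, 0)
  expect_identical(h$count, 3L)

  h <- build_histogram(-0.01)
  expect_equal(h$bin_left, -0.1)
  expect_identical(h$count, 1L)

  # values that are exact bin edges up to floating error stay in their own bin
  h <- build_histogram(c(0.3, 0.1 + 0.2, -0.3))
  expect_equal(h$bin_left, c(-0.3, 0.3))
  expect_identical(h$count, c(1L, 2L))

  set.seed(13)
  for (i in 1:20) {
    x <- switch(1 + i %% 3,
                rnorm(sample(10:5000, 1), 0, runif(1, 0.1, 2)),
                rcauchy(500), runif(200, -4, 4))
    x <- c(x, NA, Inf, -Inf)
    h <- suppressMessages(build_histogram(x))
    expect_identical(sum(h$count), sum(is.finite(x)))
    expect_false(is.unsorted(h$bin_left))
    expect_identical(anyDuplicated(h$bin_left), 0L)
  }

  set.seed(99)
  x <- rnorm(10000, 0, 0.5)
  h <- build_histogram(x)
  expect_identical(sum(h$count), 10000L)
  # modal bin agrees with a brute-force floor tabulation
  oracle <- table(floor(x / 0.1 + 1e-9))
  modal <- h$bin_left[which.max(h$count)]
  expect_equal(modal,
               round(as.numeric(names(oracle)[which.max(oracle)]) * 0.1, 10))

  expect_error(build_histogram(numeric(0)), "no finite")
})

test_that("peak fits recover noiseless parameters to high precision", {
  x <- seq(-3, 3, by = 0.1)
  for (model in c("gaussian", "lorentzian")) {
    y <- if (model == "gaussian")
      200 * exp(-(x + 0.05 - 0.15)^2 / (2 * 0.6^2))
    else 200 * 0.6^2 / ((x + 0.05 - 0.15)^2 + 0.6^2)
    h <- make_hist(x, y)
    fit <- fit_distribution(h, model)
    expect_true(fit$converged)
    expect_lt(abs(fit$center - 0.15) / 0.15, 1e-6)
    expect_lt(abs(fit$width - 0.6) / 0.6, 1e-6)
    expect_lt(abs(fit$amplitude - 200) / 200, 1e-6)
    expect_lt(fit$sse, 1e-10)
  }
})

test_that("an exactly symmetric histogram fits a centered peak", {
  x <- seq(-2, 1.9, by = 0.1)  # bin centers at x + 0.05, symmetric about 0
  y <- 100 * exp(-(x + 0.05)^2 / (2 * 0.5^2))
  fit <- fit_distribution(make_hist(x, y), "gaussian")
  expect_lt(abs(fit$center), 1e-9)
})

test_that("fitted center and width recover a sampled Gaussian background", {
  set.seed(31)
  h <- build_histogram(rnorm(15000, 0.2, 0.6))
  fit <- fit_distribution(h, "gaussian")
  expect_true(fit$converged)
  expect_lt(abs(fit$center - 0.2), 0.05)
  expect_lt(abs(fit$width - 0.6), 0.06)
})

test_that("model selection prefers the generating shape and honors overrides", {
  x <- seq(-4, 4, by = 0.1)
  yg <- 300 * exp(-(x + 0.05)^2 / (2 * 0.7^2))
  yl <- 300 * 0.7^2 / ((x + 0.05)^2 + 0.7^2)
  expect_identical(select_model(make_hist(x, yg))$model, "gaussian")
  expect_identical(select_model(make_hist(x, yl))$model, "lorentzian")
  forced <- select_model(make_hist(x, yl), model = "gaussian")
  expect_identical(forced$model, "gaussian")
  expect_error(fit_distribution(make_hist(c(0, 0.1), c(1, 2)), "gaussian"),
               "at least 5")
})

test_that("gene categorization gates on padj then thresholds on the fit", {
  fit <- fixed_fit(center = 0, width = 0.5)
  de <- data.frame(
    gene_id = c("up", "inside", "ns", "down", "edge"),
    base_mean = 100, log2fc = c(log2(170), 0.3, 2.5, -3, 0.5),
    se = 0.1, p = 0.001, padj = c(1e-8, 0.001, 0.2, 1e-4, 1e-4),
    stringsAsFactors = FALSE
  )
  cls <- classify_genes(de, fit, alpha = 0.05)
  expect_identical(as.character(cls$category),
                   c("increased", "unchanged", "not_significant", "decreased",
                     "unchanged"))  # boundary equality is unchanged
  expect_identical(nrow(cls), nrow(de))
  expect_false(anyNA(cls$category))
})

test_that("shifting all log2fc shifts the center and preserves categories", {
  set.seed(77)
  lfc <- c(rnorm(4000, 0, 0.4), runif(60, 2, 6), runif(60, -6, -2))
  de <- data.frame(gene_id = sprintf("g%04d", seq_along(lfc)), base_mean = 100,
                   log2fc = lfc, se = 0.1, p = 0.001,
                   padj = rep(c(0.001, 0.5), length.out = length(lfc)),
                   stringsAsFactors = FALSE)
  fit0 <- fit_distribution(build_histogram(de$log2fc), "gaussian")
  shift <- 0.8
  de2 <- de; de2$log2fc <- de$log2fc + shift
  fit2 <- fit_distribution(build_histogram(de2$log2fc), "gaussian")
  expect_lt(abs((fit2$center - fit0$center) - shift), 0.02)
  c0 <- classify_genes(de, fit0)
  c2 <- classify_genes(de2, fit2)
  expect_gte(mean(c0$category == c2$category), 0.99)
})
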