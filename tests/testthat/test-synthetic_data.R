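small_panel <- function(n = 60L) {
  data.frame(human_symbol = sprintf("PG%03d", seq_len(n)),
             mouse_symbol = sprintf("Pg%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("simulation is a deterministic function of the seed", {
  panel <- small_panel()
  cfg <- sim_config(n_genes = 500L, seed = 11L,
                    spike_table = data.frame(gene_id = "Pg001",
                                             log2fc_cm = 4,
                                             delta_log2fc_ntci = -2))
  a <- simulate_dataset(cfg, panel)
  b <- simulate_dataset(cfg, panel)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(sim_config(n_genes = 500L, seed = 12L), panel)
  expect_false(identical(a$counts, c$counts))
})

test_that("per-gene substreams keep draws stable under gene-count changes", {
  panel <- small_panel()
  a <- simulate_dataset(sim_config(n_genes = 300L, seed = 5L), panel)
  b <- simulate_dataset(sim_config(n_genes = 400L, seed = 5L), panel)
  common <- intersect(rownames(a$counts), rownames(b$counts))
  expect_identical(a$counts[common, ], b$counts[common, ])
})

test_that("null genes hit their configured mean (law of large numbers)", {
  cfg <- sim_config(n_genes = 5L, n_reps = 100L, seed = 3L,
                    baseline_meanlog = log(100), baseline_sdlog = 0,
                    dispersion = 0.05)
  sim <- simulate_dataset(cfg)
  sf <- attr(sim$truth, "size_factors")
  norm <- sweep(sim$counts, 2L, sf, "/")
  means <- rowMeans(norm)  # 300 samples per gene, no condition effects
  expect_true(all(abs(means - 100) < 5))
})

test_that("spikes referencing unknown genes are rejected", {
  cfg <- sim_config(n_genes = 100L, spike_table = data.frame(
    gene_id = "NotAGene", log2fc_cm = 4, delta_log2fc_ntci = 0))
  expect_error(simulate_dataset(cfg, small_panel()), "unknown gene")
})

test_that("background shift is recovered from the generated fold changes", {
  cfg <- sim_config(n_genes = 10000L, seed = 19L, background_shift = 0.2,
                    background_sd = 0.1)
  sim <- simulate_dataset(cfg)
  sf <- attr(sim$truth, "size_factors")  # generator truth, not re-estimated
  norm <- sweep(sim$counts, 2L, sf, "/")
  cm <- sim$sheet$condition == "cm"
  sham <- sim$sheet$condition == "sham"
  lfc <- log2((rowMeans(norm[, cm]) + 0.5) / (rowMeans(norm[, sham]) + 0.5))
  fit <- fit_distribution(build_histogram(lfc), "gaussian")
  expect_true(fit$converged)
  expect_lt(abs(fit$center - 0.2), 0.05)
})

test_that("the preset spike table encodes the reported effect magnitudes", {
  spikes <- sepsis_panel_spikes(bundled_panel())
  il10 <- spikes[spikes$gene_id == "Il10", ]
  expect_equal(il10$log2fc_cm, log2(170))
  expect_equal(il10$delta_log2fc_ntci, -log2(6.5))
  nl <- spikes[spikes$gene_id == "Nlrp12", ]
  expect_equal(nl$log2fc_cm, -log2(40))
  expect_equal(nl$delta_log2fc_ntci, log2(4))
  expect_identical(sum(!spikes$exact), 40L)
  expect_true(all(abs(spikes$log2fc_cm[!spikes$exact]) == 4))
})

test_that("doubling every count leaves spiked-gene calls unchanged", {
  panel <- small_panel()
  spikes <- data.frame(gene_id = c("Pg001", "Pg002"),
                       log2fc_cm = c(4, -4), delta_log2fc_ntci = c(-2, 2))
  cfg <- sim_config(n_genes = 2000L, seed = 23L, spike_table = spikes)
  sim <- simulate_dataset(cfg, panel)
  run <- function(counts) {
    an <- suppressMessages(
      analyze_dataset(counts, sim$sheet, panel, reprogram_rule = "delta"))
    cls <- an$classes[["cm_vs_sham"]]
    as.character(cls$category[match(spikes$gene_id, cls$gene_id)])
  }
  doubled <- sim$counts * 2L
  storage.mode(doubled) <- "integer"
  expect_identical(run(sim$counts), c("increased", "decreased"))
  expect_identical(run(doubled), run(sim$counts))
})

test_that("a truth table with large paired effects is recovered exactly", {
  panel <- small_panel()
  spikes <- data.frame(
    gene_id = sprintf("Pg%03d", 1:16),
    log2fc_cm = c(rep(-4, 7), rep(4, 9)),
    delta_log2fc_ntci = c(rep(3, 7), rep(-3, 9)),
    exact = TRUE)
  cfg <- sim_config(n_genes = 3000L, seed = 29L, spike_table = spikes)
  res <- suppressMessages(
    recovery_experiment(cfg, panel, rule = "delta"))
  rec <- res$analysis$records
  expect_identical(sum(rec$reprogram_class == "enhanced"), 7L)
  expect_identical(sum(rec$reprogram_class == "suppressed"), 9L)
  expect_identical(res$analysis$summary$n_reprogrammed, 16L)
})
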