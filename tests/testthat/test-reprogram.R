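# Shared scaffolding: two DE tables over a 3-gene panel with known effects.
paired_fixture <- function() {
  genes <- c("Il10", "Nlrp12", "Flat1")
  lfc_cm <- c(log2(170), -log2(40), 1.2)
  lfc_nt <- c(log2(170 / 6.5), -log2(10), 1.2)
  mk <- function(lfc) data.frame(gene_id = genes, base_mean = 1000,
                                 log2fc = lfc, se = 0.1, p = 1e-6,
                                 padj = 1e-5, stringsAsFactors = FALSE)
  de_cm <- mk(lfc_cm); de_nt <- mk(lfc_nt)
  fit <- fixed_fit(0, 0.5)
  panel <- data.frame(human_symbol = toupper(genes), mouse_symbol = genes,
                      stringsAsFactors = FALSE)
  list(de_cm = de_cm, de_nt = de_nt,
       cls_cm = classify_genes(de_cm, fit), cls_nt = classify_genes(de_nt, fit),
       inter = map_orthologs(panel, genes))
}

test_that("paired contrasts reproduce the reported attenuation and reversal", {
  fx <- paired_fixture()
  rec <- pair_contrasts(fx$de_cm, fx$de_nt, fx$cls_cm, fx$cls_nt, fx$inter,
                        rule = "delta", delta = 0.5)
  il10 <- rec[rec$gene_id == "Il10", ]
  expect_equal(il10$fc_ratio, 6.5, tolerance = 1e-12)
  expect_identical(as.character(il10$reprogram_class), "suppressed")

  nlrp12 <- rec[rec$gene_id == "Nlrp12", ]
  expect_equal(nlrp12$fc_ratio, 0.25, tolerance = 1e-12)
  expect_identical(as.character(nlrp12$reprogram_class), "enhanced")

  flat <- rec[rec$gene_id == "Flat1", ]
  expect_identical(flat$delta_log2fc, 0)
  expect_identical(flat$fc_ratio, 1)
  expect_identical(as.character(flat$reprogram_class), "not_reprogrammed")

  # structural invariants
  expect_equal(rec$fc_ratio, 2^(-rec$delta_log2fc), tolerance = 1e-15)
  swapped <- pair_contrasts(fx$de_nt, fx$de_cm, fx$cls_nt, fx$cls_cm, fx$inter,
                            rule = "delta", delta = 0.5)
  expect_equal(swapped$fc_ratio, 1 / rec$fc_ratio, tolerance = 1e-12)
})

test_that("category-change rule follows the category ordering and is scale-invariant", {
  fx <- paired_fixture()
  rec <- pair_contrasts(fx$de_cm, fx$de_nt, fx$cls_cm, fx$cls_nt, fx$inter,
                        rule = "category_change")
  # Il10 stays 'increased' in both contrasts: no category change
  expect_identical(as.character(rec$reprogram_class[rec$gene_id == "Il10"]),
                   "not_reprogrammed")

  # a decreased -> unchanged transition is enhancement
  de_nt2 <- fx$de_nt
  de_nt2$log2fc[de_nt2$gene_id == "Nlrp12"] <- -0.2
  cls_nt2 <- classify_genes(de_nt2, fixed_fit(0, 0.5))
  rec2 <- pair_contrasts(fx$de_cm, de_nt2, fx$cls_cm, cls_nt2, fx$inter,
                         rule = "category_change")
  expect_identical(as.character(rec2$reprogram_class[rec2$gene_id == "Nlrp12"]),
                   "enhanced")

  # invariant to monotone rescaling of log2fc that preserves categories:
  # same categories, doubled fold changes -> same calls
  de_cm3 <- fx$de_cm; de_cm3$log2fc <- 2 * de_cm3$log2fc
  de_nt3 <- de_nt2;  de_nt3$log2fc <- 2 * de_nt3$log2fc
  cls_cm3 <- classify_genes(de_cm3, fixed_fit(0, 1.0))
  cls_nt3 <- classify_genes(de_nt3, fixed_fit(0, 1.0))
  rec3 <- pair_contrasts(de_cm3, de_nt3, cls_cm3, cls_nt3, fx$inter,
                         rule = "category_change")
  expect_identical(as.character(rec3$reprogram_class),
                   as.character(rec2$reprogram_class))
})

test_that("genes missing from one contrast are excluded with a message", {
  fx <- paired_fixture()
  de_nt <- fx$de_nt[fx$de_nt$gene_id != "Flat1", ]
  expect_message(
    rec <- pair_contrasts(fx$de_cm, de_nt, fx$cls_cm, fx$cls_nt, fx$inter,
                          rule = "delta", delta = 0.5),
    "missing from one contrast")
  expect_identical(rec$gene_id, c("Il10", "Nlrp12"))
})

test_that("summaries satisfy the count identities", {
  fx <- paired_fixture()
  rec <- pair_contrasts(fx$de_cm, fx$de_nt, fx$cls_cm, fx$cls_nt, fx$inter,
                        rule = "delta", delta = 0.5)
  s <- summarize_reprogramming(rec, fx$cls_cm, fx$inter, "spleen")
  expect_identical(s$n_reprogrammed, s$n_enhanced + s$n_suppressed)
  expect_identical(s$n_panel_significant,
                   s$n_increased + s$n_decreased + s$n_unchanged)

  s0 <- summarize_reprogramming(rec[0, ], fx$cls_cm[0, ],
                                fx$inter[0, ], "lungs")
  expect_identical(s0$n_reprogrammed, 0L)
  expect_identical(s0$n_panel_significant, 0L)
})

test_that("fold statements match the reporting style", {
  fx <- paired_fixture()
  rec <- pair_contrasts(fx$de_cm, fx$de_nt, fx$cls_cm, fx$cls_nt, fx$inter,
                        rule = "delta", delta = 0.5)
  expect_identical(fold_statement(rec[rec$gene_id == "Il10", ]),
                   "reduced 6.5-fold")
  expect_identical(fold_statement(rec[rec$gene_id == "Nlrp12", ]),
                   "reversed 4.0-fold")
  expect_identical(fold_statement(rec[rec$gene_id == "Flat1", ]),
                   "unchanged (1.0-fold)")
})
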