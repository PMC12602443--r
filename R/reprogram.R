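# Paired-contrast comparison: how the treatment (sepsis + NTCI peptide)
# contrast differs from the plain sepsis contrast for every panel gene, and
# the enhanced/suppressed "reprogramming" calls derived from it.

REPROGRAM_CLASSES <- c("enhanced", "suppressed", "not_reprogrammed")

#' Pair the sepsis and sepsis-plus-treatment contrasts per panel gene
#'
#' Builds one record per mapped panel gene present in both DE tables, carrying
#' both log2 fold changes, both categories, their difference
#' `delta_log2fc = log2fc_ntci - log2fc_cm` and the linear fold-change ratio
#' `fc_ratio = 2^(log2fc_cm - log2fc_ntci)` (how many-fold the treatment
#' attenuated the sepsis response; values < 1 mean the treatment pushed the
#' gene further in the sepsis direction or reversed a suppression).
#'
#' Two reprogramming rules are available:
#' \describe{
#'   \item{`category_change`}{parameter-free; `enhanced` when the treatment
#'     category is strictly higher in the ordering decreased < unchanged <
#'     increased than the sepsis category, `suppressed` when strictly lower.
#'     `not_significant` ranks with `unchanged`.}
#'   \item{`delta`}{`enhanced` when `delta_log2fc > delta`, `suppressed` when
#'     `delta_log2fc < -delta`, with `delta` defaulting to the fitted width of
#'     the treatment-contrast histogram; only genes significant
#'     (`padj < alpha`) in at least one contrast are eligible, so pure noise
#'     genes are never called.}
#' }
#'
#' @param de_cm,de_ntci DE tables for the sepsis and sepsis-plus-treatment
#'   contrasts.
#' @param classes_cm,classes_ntci Matching classification tables from
#'   [classify_genes()].
#' @param inter Panel intersection from [map_orthologs()].
#' @param rule `"category_change"` (default) or `"delta"`.
#' @param delta Threshold on `delta_log2fc` for the `"delta"` rule; required
#'   for that rule (use the treatment-contrast fit width).
#' @param alpha Significance gate used by the `"delta"` rule.
#' @return A data.frame with one row per panel gene present in both contrasts:
#'   `gene_id`, `log2fc_cm`, `log2fc_ntci`, `cat_cm`, `cat_ntci`,
#'   `delta_log2fc`, `fc_ratio`, `reprogram_class`.
#' @export
pair_contrasts <- function(de_cm, de_ntci, classes_cm, classes_ntci, inter,
                           rule = c("category_change", "delta"), delta = NULL,
                           alpha = 0.05) {
  rule <- match.arg(rule)
  de_cm <- validate_de_table(de_cm)
  de_ntci <- validate_de_table(de_ntci)
  panel_genes <- inter$mouse_symbol[inter$present_in_data]
  genes <- intersect(panel_genes, intersect(de_cm$gene_id, de_ntci$gene_id))
  dropped <- setdiff(panel_genes, genes)
  if (length(dropped))
    message("pair_contrasts: ", length(dropped),
            " panel gene(s) missing from one contrast, excluded")
  i_cm <- match(genes, de_cm$gene_id)
  i_nt <- match(genes, de_ntci$gene_id)
  c_cm <- as.character(classes_cm$category[match(genes, classes_cm$gene_id)])
  c_nt <- as.character(classes_ntci$category[match(genes, classes_ntci$gene_id)])
  lfc_cm <- de_cm$log2fc[i_cm]
  lfc_nt <- de_ntci$log2fc[i_nt]
  dlfc <- lfc_nt - lfc_cm
  fc_ratio <- 2^(-dlfc)

  if (rule == "category_change") {
    ord <- c(decreased = 1L, unchanged = 2L, not_significant = 2L,
             increased = 3L)
    cls <- ifelse(ord[c_nt] > ord[c_cm], "enhanced",
           ifelse(ord[c_nt] < ord[c_cm], "suppressed", "not_reprogrammed"))
  } else {
    if (is.null(delta) || !is.finite(delta) || delta <= 0)
      stop("the 'delta' rule needs a positive delta threshold ",
           "(use the treatment-contrast fit width)")
    eligible <- de_cm$padj[i_cm] < alpha | de_ntci$padj[i_nt] < alpha
    cls <- ifelse(!eligible, "not_reprogrammed",
           ifelse(dlfc > delta, "enhanced",
           ifelse(dlfc < -delta, "suppressed", "not_reprogrammed")))
  }
  cls[dlfc == 0] <- "not_reprogrammed"
  data.frame(gene_id = genes, log2fc_cm = lfc_cm, log2fc_ntci = lfc_nt,
             cat_cm = c_cm, cat_ntci = c_nt, delta_log2fc = dlfc,
             fc_ratio = fc_ratio,
             reprogram_class = factor(cls, levels = REPROGRAM_CLASSES),
             stringsAsFactors = FALSE)
}

#' Summarize the panel response and reprogramming for one organ
#'
#' @param records Output of [pair_contrasts()].
#' @param classes_cm Classification table for the sepsis contrast.
#' @param inter Panel intersection from [map_orthologs()].
#' @param organ Organ label (`"spleen"` or `"lungs"`).
#' @return A list of class `"reprogram_summary"` with the panel-significant
#'   gene count, the increased/decreased/unchanged counts among them, the
#'   enhanced/suppressed/reprogrammed counts, and percentages for each.
#' @export
summarize_reprogramming <- function(records, classes_cm, inter, organ) {
  ps <- panel_summary(inter, classes_cm)
  n_enh <- sum(records$reprogram_class == "enhanced")
  n_sup <- sum(records$reprogram_class == "suppressed")
  pctr <- function(x, n) if (n > 0) 100 * x / n else 0
  n_rec <- nrow(records)
  out <- list(
    organ = organ,
    n_panel_present = ps$n_panel_present,
    n_panel_significant = ps$n_significant,
    n_increased = unname(ps$counts["increased"]),
    n_decreased = unname(ps$counts["decreased"]),
    n_unchanged = unname(ps$counts["unchanged"]),
    pct_increased = unname(ps$percentages["increased"]),
    pct_decreased = unname(ps$percentages["decreased"]),
    pct_unchanged = unname(ps$percentages["unchanged"]),
    n_enhanced = n_enh,
    n_suppressed = n_sup,
    n_reprogrammed = n_enh + n_sup,
    pct_enhanced = pctr(n_enh, n_rec),
    pct_suppressed = pctr(n_sup, n_rec),
    pct_reprogrammed = pctr(n_enh + n_sup, n_rec)
  )
  structure(out, class = "reprogram_summary")
}

#' @export
print.reprogram_summary <- function(x, ...) {
  cat(sprintf("Panel response summary (%s)\n", x$organ))
  cat(sprintf("  significantly expressed panel genes: %d (of %d present)\n",
              x$n_panel_significant, x$n_panel_present))
  cat(sprintf("  increased %d (%.1f%%), decreased %d (%.1f%%), unchanged %d (%.1f%%)\n",
              x$n_increased, x$pct_increased, x$n_decreased, x$pct_decreased,
              x$n_unchanged, x$pct_unchanged))
  cat(sprintf("  reprogrammed by treatment: %d (enhanced %d, suppressed %d)\n",
              x$n_reprogrammed, x$n_enhanced, x$n_suppressed))
  invisible(x)
}

#' Human-readable fold-change statement for one record
#'
#' Reports treatment attenuation of a sepsis-upregulated gene as
#' `"reduced k-fold"` (k = `fc_ratio`), reversal of a sepsis-suppressed gene as
#' `"reversed k-fold"` (k = `1/fc_ratio`), deepening of a suppressed gene as
#' `"deepened k-fold"`, further induction of an upregulated gene as
#' `"enhanced k-fold"`, and a zero difference as `"unchanged (1.0-fold)"`.
#' Ratios are linear-scale, one decimal.
#'
#' @param record One row of the [pair_contrasts()] output.
#' @return A character string.
#' @export
fold_statement <- function(record) {
  stopifnot(nrow(record) == 1L)
  d <- record$delta_log2fc
  if (d == 0) return("unchanged (1.0-fold)")
  k <- function(v) sprintf("%.1f", v)
  if (record$log2fc_cm > 0 && d < 0)
    sprintf("reduced %s-fold", k(record$fc_ratio))
  else if (record$log2fc_cm < 0 && d > 0)
    sprintf("reversed %s-fold", k(1 / record$fc_ratio))
  else if (d > 0)
    sprintf("enhanced %s-fold", k(1 / record$fc_ratio))
  else
    sprintf("deepened %s-fold", k(record$fc_ratio))
}
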