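# Readers/writers for the plain-text formats every other module consumes:
# count matrices, sample sheets, gene panels, differential-expression tables
# and the YAML run configuration. All files are TSV/CSV, UTF-8, "." decimal.

CONDITION_LEVELS <- c("sham", "cm", "cm_ntci")
ORGAN_LEVELS <- c("spleen", "lungs")

#' Read a gene-level count matrix
#'
#' Parses a tab-separated file whose first column holds gene identifiers and
#' whose remaining columns are per-sample raw counts. Counts must be
#' non-negative integers; gene identifiers must be unique. Input gene order is
#' preserved.
#'
#' @param path Path to a TSV file. The header row names the samples; the first
#'   column (any header) carries gene identifiers.
#' @return An integer matrix (genes x samples) with gene identifiers as row
#'   names and sample identifiers as column names.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L)
    stop("count matrix must have a gene column plus at least one sample column")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene id in count matrix: ", dup[1L])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric count values in count matrix")
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer or negative count at gene '%s', sample '%s' (value %s)",
      genes[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]],
      format(mat[bad[1L, , drop = FALSE]])))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  validate_counts(mat)
}

#' Write a count matrix
#'
#' @param counts Integer matrix as returned by [read_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  counts
}

#' Read a sample sheet
#'
#' Comma-separated file with columns `sample_id`, `condition` and `organ`.
#' Conditions must be one of `sham`, `cm` (polymicrobial sepsis induced by a
#' cecal microbiome inoculum) or `cm_ntci` (sepsis plus the nuclear transport
#' checkpoint inhibitor peptide); organs one of `spleen`, `lungs`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `sample_id`, `condition`, `organ`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "condition", "organ")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(df$condition), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CONDITION_LEVELS, collapse = ", "), ")")
  bad <- setdiff(unique(df$organ), ORGAN_LEVELS)
  if (length(bad))
    stop("unknown organ label(s): ", paste(bad, collapse = ", "))
  df
}

#' Read an immunodeficiency gene panel
#'
#' Two-column TSV with header `human_symbol` and `mouse_symbol`. An empty
#' `mouse_symbol` marks a panel entry with no curated mouse ortholog
#' (see [map_orthologs()] for the fallback naming convention).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with character columns `human_symbol` and
#'   `mouse_symbol` ("" = unmapped).
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character")
  validate_panel(df)
}

#' @rdname read_panel
#' @param panel Panel data.frame.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_panel <- function(df) {
  need <- c("human_symbol", "mouse_symbol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("gene panel missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$human_symbol <- as.character(df$human_symbol)
  df$mouse_symbol <- as.character(df$mouse_symbol)
  df$mouse_symbol[is.na(df$mouse_symbol)] <- ""
  if (anyDuplicated(df$human_symbol))
    stop("duplicate human_symbol in gene panel: ",
         df$human_symbol[duplicated(df$human_symbol)][1L])
  nonempty <- df$mouse_symbol[df$mouse_symbol != ""]
  if (anyDuplicated(nonempty))
    stop("duplicate mouse_symbol in gene panel: ",
         nonempty[duplicated(nonempty)][1L])
  df
}

#' Read a differential-expression table
#'
#' Accepts the column convention used by standard differential-expression
#' engines: `gene`, `baseMean`, `log2FoldChange`, `pvalue`, `padj` (an optional
#' `lfcSE` is kept when present; extra columns are ignored). Rows with a
#' missing `padj` are retained with `padj = 1` and flagged in the
#' `padj_imputed` column, so the gene universe stays stable for histogram
#' construction.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `gene_id`, `base_mean`, `log2fc`, `se`
#'   (NA when absent from the file), `p`, `padj`, `padj_imputed`.
#' @export
read_de_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "baseMean", "log2FoldChange", "pvalue", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("DE table missing required column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    gene_id = as.character(df$gene),
    base_mean = as.numeric(df$baseMean),
    log2fc = as.numeric(df$log2FoldChange),
    se = if ("lfcSE" %in% names(df)) as.numeric(df$lfcSE) else NA_real_,
    p = as.numeric(df$pvalue),
    padj = as.numeric(df$padj),
    stringsAsFactors = FALSE
  )
  out$padj_imputed <- is.na(out$padj)
  if (any(out$padj_imputed)) {
    warning(sum(out$padj_imputed),
            " row(s) with missing padj retained with padj = 1")
    out$padj[out$padj_imputed] <- 1
  }
  validate_de_table(out)
}

#' Write a differential-expression table
#'
#' Writes the engine-standard column names (`gene`, `baseMean`,
#' `log2FoldChange`, `lfcSE`, `pvalue`, `padj`) so the output round-trips
#' through [read_de_table()].
#'
#' @param de DE table as returned by [de_test()] or [read_de_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  de <- validate_de_table(de)
  # full round-trip precision so a re-read table is bit-identical and the
  # external-ingestion path reproduces internal results exactly
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    gene = de$gene_id, baseMean = num(de$base_mean),
    log2FoldChange = num(de$log2fc), lfcSE = num(de$se),
    pvalue = num(de$p), padj = num(de$padj), stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_de_table <- function(de) {
  need <- c("gene_id", "base_mean", "log2fc", "p", "padj")
  miss <- setdiff(need, names(de))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene_id in DE table")
  if (any(de$base_mean < 0, na.rm = TRUE))
    stop("base_mean must be non-negative")
  rng <- function(x) any(x < 0 | x > 1, na.rm = TRUE)
  if (rng(de$p) || rng(de$padj))
    stop("p and padj must lie in [0, 1]")
  if (any(de$base_mean > 0 & !is.finite(de$log2fc)))
    stop("log2fc must be finite for genes with base_mean > 0")
  if (!"padj_imputed" %in% names(de)) de$padj_imputed <- FALSE
  de
}

#' Read a run configuration
#'
#' YAML file with keys `paths` (counts, sample_sheet, panel, optional
#' de_tables), `contrasts`, `alpha`, `bin_width`, `fit_model`,
#' `reprogram_rule`, `seed` and `output_dir`. Missing keys are filled with
#' package defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated run-configuration list (see [run_config()]).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Build a run configuration
#'
#' @param paths Named list of input paths (`counts`, `sample_sheet`, `panel`,
#'   optionally `de_cm` / `de_cm_ntci` for externally produced DE tables).
#' @param contrasts List of 2-vectors `c(treatment, reference)`; default the
#'   sepsis contrast and the sepsis-plus-treatment contrast, both against sham.
#' @param alpha Adjusted-p significance gate (default 0.05).
#' @param bin_width Histogram bin width on the log2 fold-change axis
#'   (default 0.1).
#' @param fit_model `"auto"` (pick Gaussian vs Lorentzian by residual sum of
#'   squares), `"gaussian"` or `"lorentzian"`.
#' @param reprogram_rule `"category_change"` or `"delta"` (see
#'   [pair_contrasts()]).
#' @param seed Integer seed for any randomized step.
#' @param output_dir Directory for stage outputs.
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(paths = list(), contrasts = list(c("cm", "sham"),
                                                        c("cm_ntci", "sham")),
                       alpha = 0.05, bin_width = 0.1,
                       fit_model = c("auto", "gaussian", "lorentzian"),
                       reprogram_rule = c("category_change", "delta"),
                       seed = 1L, output_dir = "reprog-out") {
  fit_model <- match.arg(fit_model)
  reprogram_rule <- match.arg(reprogram_rule)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  contrasts <- lapply(contrasts, function(ct) {
    ct <- as.character(unlist(ct))
    if (length(ct) != 2L)
      stop("each contrast must be c(treatment, reference)")
    ct
  })
  structure(list(paths = paths, contrasts = contrasts, alpha = alpha,
                 bin_width = bin_width, fit_model = fit_model,
                 reprogram_rule = reprogram_rule, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}
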