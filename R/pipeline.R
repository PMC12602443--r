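# Orchestration: run every stage on one dataset (in memory) or from a run
# configuration with a fixed on-disk artifact layout.

#' Analyze one organ dataset end to end
#'
#' Runs size-factor normalization, the NB Wald test for the sepsis
#' (`cm` vs `sham`) and treatment (`cm_ntci` vs `sham`) contrasts (or ingests
#' externally produced DE tables), fits the log2 fold-change histogram, assigns
#' gene categories, intersects with the gene panel, pairs the contrasts and
#' summarizes reprogramming.
#'
#' The histogram is built from genes with `base_mean > 0` (the expressed
#' universe); the significance gate applies only to the final categories, not
#' to the background fit.
#'
#' @param counts Integer count matrix.
#' @param sheet Sample sheet covering its columns.
#' @param panel Gene panel.
#' @param alpha Adjusted-p significance gate (default 0.05).
#' @param bin_width Histogram bin width (default 0.1).
#' @param fit_model `"auto"`, `"gaussian"` or `"lorentzian"`.
#' @param reprogram_rule `"category_change"` or `"delta"`.
#' @param de_tables Optional named list of external DE tables (names
#'   `cm_vs_sham`, `cm_ntci_vs_sham`) read with [read_de_table()]; when given,
#'   the internal DE engine is skipped.
#' @param exceptions Optional curated ortholog overrides for
#'   [map_orthologs()].
#' @return A list with elements `de`, `fits`, `classes` (named per contrast),
#'   `inter`, `records`, `summary`, and the parameters used.
#' @export
analyze_dataset <- function(counts, sheet, panel, alpha = 0.05,
                            bin_width = 0.1,
                            fit_model = c("auto", "gaussian", "lorentzian"),
                            reprogram_rule = c("category_change", "delta"),
                            de_tables = NULL, exceptions = NULL) {
  fit_model <- match.arg(fit_model)
  reprogram_rule <- match.arg(reprogram_rule)
  contrasts <- list(cm_vs_sham = c("cm", "sham"),
                    cm_ntci_vs_sham = c("cm_ntci", "sham"))
  organ <- unique(sheet$organ)
  if (length(organ) != 1L)
    stop("analyze_dataset expects a single-organ dataset; got: ",
         paste(organ, collapse = ", "))

  de <- list(); fits <- list(); classes <- list()
  sf <- NULL
  if (is.null(de_tables)) {
    counts <- validate_counts(counts)
    sf <- size_factors(counts)
  }
  for (nm in names(contrasts)) {
    de[[nm]] <- if (!is.null(de_tables)) {
      if (!nm %in% names(de_tables))
        stop("external DE table missing for contrast ", nm)
      validate_de_table(de_tables[[nm]])
    } else {
      de_test(counts, sheet, contrasts[[nm]], sf = sf)
    }
    expressed <- de[[nm]][de[[nm]]$base_mean > 0, , drop = FALSE]
    h <- build_histogram(expressed$log2fc, bin_width = bin_width)
    fits[[nm]] <- select_model(h, model = fit_model)
    message(sprintf(
      "stage classify [%s/%s]: alpha=%g bin_width=%g model=%s center=%.4f width=%.4f",
      organ, nm, alpha, bin_width, fits[[nm]]$model, fits[[nm]]$center,
      fits[[nm]]$width))
    classes[[nm]] <- classify_genes(de[[nm]], fits[[nm]], alpha = alpha)
  }

  gene_ids <- de[["cm_vs_sham"]]$gene_id
  inter <- map_orthologs(panel, gene_ids, exceptions = exceptions)
  records <- pair_contrasts(
    de[["cm_vs_sham"]], de[["cm_ntci_vs_sham"]],
    classes[["cm_vs_sham"]], classes[["cm_ntci_vs_sham"]], inter,
    rule = reprogram_rule,
    delta = if (reprogram_rule == "delta")
      fits[["cm_ntci_vs_sham"]]$width else NULL,
    alpha = alpha)
  message(sprintf("stage reprogram [%s]: rule=%s%s", organ, reprogram_rule,
                  if (reprogram_rule == "delta")
                    sprintf(" delta=%.4f", fits[["cm_ntci_vs_sham"]]$width)
                  else ""))
  summary <- summarize_reprogramming(records, classes[["cm_vs_sham"]], inter,
                                     organ)
  list(de = de, fits = fits, classes = classes, inter = inter,
       records = records, summary = summary,
       params = list(alpha = alpha, bin_width = bin_width,
                     fit_model = fit_model, reprogram_rule = reprogram_rule))
}

fit_report <- function(fit) {
  list(model = fit$model, center = fit$center, width = fit$width,
       amplitude = fit$amplitude, sse = fit$sse, converged = fit$converged)
}

write_analysis <- function(an, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(an$de)) {
    write_de_table(an$de[[nm]], file.path(dir, paste0("de_", nm, ".tsv")))
    jsonlite::write_json(fit_report(an$fits[[nm]]),
                         file.path(dir, paste0("fit_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(an$classes[[nm]],
                       file.path(dir, paste0("classes_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(an$inter, file.path(dir, "panel_intersection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(an$records, file.path(dir, "reprogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(an$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full pipeline from a run configuration
#'
#' Reads the configured inputs, splits the data by organ, analyzes every organ
#' with [analyze_dataset()] and writes per-organ artifacts (DE tables, fit
#' reports, classification tables, reprogramming table, summary JSON) under
#' `output_dir/<organ>/`.
#'
#' @param cfg A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return Named list of `"reprogram_summary"` objects, one per organ,
#'   invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$paths
  for (key in c("counts", "sample_sheet", "panel"))
    if (is.null(p[[key]]))
      stop("run configuration missing path: ", key)
  counts <- read_counts(p$counts)
  sheet <- read_sample_sheet(p$sample_sheet)
  panel <- read_panel(p$panel)
  de_tables <- NULL
  if (!is.null(p$de_cm) || !is.null(p$de_cm_ntci)) {
    if (is.null(p$de_cm) || is.null(p$de_cm_ntci))
      stop("external DE ingestion needs both de_cm and de_cm_ntci paths")
    de_tables <- list(cm_vs_sham = read_de_table(p$de_cm),
                      cm_ntci_vs_sham = read_de_table(p$de_cm_ntci))
  }
  out <- list()
  for (organ in unique(sheet$organ)) {
    sub_sheet <- sheet[sheet$organ == organ, , drop = FALSE]
    sub_counts <- counts[, sub_sheet$sample_id, drop = FALSE]
    an <- analyze_dataset(sub_counts, sub_sheet, panel, alpha = cfg$alpha,
                          bin_width = cfg$bin_width,
                          fit_model = cfg$fit_model,
                          reprogram_rule = cfg$reprogram_rule,
                          de_tables = de_tables)
    write_analysis(an, file.path(cfg$output_dir, organ))
    out[[organ]] <- an$summary
  }
  invisible(out)
}
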