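# Human immunodeficiency (IEI) gene panel: human -> mouse ortholog symbol
# mapping and intersection with classified genes.

#' Default human-to-mouse symbol convention
#'
#' Mouse gene symbols conventionally Title-case the human ALL-CAPS symbol
#' (IL10 -> Il10, CD40LG -> Cd40lg). This is a naming convention, not an
#' orthology assertion; curated mappings always take precedence.
#'
#' @param human_symbol Character vector of human gene symbols.
#' @return Character vector of convention-cased mouse symbols.
#' @export
human_to_mouse_symbol <- function(human_symbol) {
  s <- as.character(human_symbol)
  paste0(toupper(substr(s, 1L, 1L)), tolower(substr(s, 2L, nchar(s))))
}

#' Map a gene panel to mouse symbols and intersect with the data
#'
#' Resolution order per panel entry: a row in `exceptions` (curated override;
#' an empty/NA mouse symbol there marks the gene as having no mouse ortholog),
#' then the panel's own non-empty `mouse_symbol`, then the Title-case
#' convention. Mapping is deterministic and idempotent. Unmapped symbols are a
#' reported outcome, never an error.
#'
#' @param panel Gene panel (see [read_panel()]).
#' @param genes Character vector of gene identifiers present in the count
#'   matrix.
#' @param exceptions Optional data.frame with columns `human_symbol`,
#'   `mouse_symbol` overriding everything else.
#' @return A data.frame with columns `human_symbol`, `mouse_symbol`
#'   (`NA` when unmapped), `source` (`"curated"`, `"panel"`, `"convention"` or
#'   `"none"`) and `present_in_data`.
#' @export
map_orthologs <- function(panel, genes, exceptions = NULL) {
  panel <- validate_panel(panel)
  genes <- as.character(genes)
  mouse <- ifelse(panel$mouse_symbol == "", NA_character_, panel$mouse_symbol)
  source <- ifelse(is.na(mouse), "convention", "panel")
  conv <- is.na(mouse)
  mouse[conv] <- human_to_mouse_symbol(panel$human_symbol[conv])
  if (!is.null(exceptions)) {
    if (!all(c("human_symbol", "mouse_symbol") %in% names(exceptions)))
      stop("exceptions must have columns human_symbol and mouse_symbol")
    i <- match(panel$human_symbol, exceptions$human_symbol)
    hit <- !is.na(i)
    ex <- as.character(exceptions$mouse_symbol)[i[hit]]
    ex[is.na(ex)] <- ""
    mouse[hit] <- ifelse(ex == "", NA_character_, ex)
    source[hit] <- ifelse(ex == "", "none", "curated")
  }
  data.frame(human_symbol = panel$human_symbol, mouse_symbol = mouse,
             source = source,
             present_in_data = !is.na(mouse) & mouse %in% genes,
             stringsAsFactors = FALSE)
}

#' Category counts of panel genes for one contrast
#'
#' Restricts a classification table to the mapped panel genes present in the
#' data and counts the increased / decreased / unchanged categories among the
#' significantly expressed ones, with percentages of that significant panel
#' universe.
#'
#' @param inter Intersection table from [map_orthologs()].
#' @param classes Either a classification data.frame from [classify_genes()]
#'   or a named list of such data.frames, one per contrast.
#' @param contrast Contrast name to pull from `classes` when it is a list.
#' @return A list with `n_panel_present`, `n_significant`, `counts` (named
#'   integer vector over increased/decreased/unchanged) and `percentages`
#'   (same names; of the significant panel universe, summing to 100 up to
#'   rounding).
#' @export
panel_summary <- function(inter, classes, contrast = NULL) {
  if (!is.data.frame(classes)) {
    if (is.null(contrast) || !contrast %in% names(classes))
      stop("no classification available for contrast '", contrast, "'")
    classes <- classes[[contrast]]
  }
  present <- inter$mouse_symbol[inter$present_in_data]
  sub <- classes[classes$gene_id %in% present, , drop = FALSE]
  sig <- sub[sub$category != "not_significant", , drop = FALSE]
  counts <- table(factor(as.character(sig$category),
                         levels = c("increased", "decreased", "unchanged")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_sig <- sum(counts)
  pct <- if (n_sig > 0) 100 * counts / n_sig else counts * 0
  list(n_panel_present = length(unique(present)),
       n_significant = n_sig, counts = counts, percentages = pct)
}
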