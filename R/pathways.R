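#' Assemble signed disease -> gene -> disease candidate paths
#'
#' Given two sets of significant signed regulatory edges — one from the
#' source disease to genes, one from the target disease to genes — a
#' candidate cross-disease path exists for every gene present in both.
#' The path is *concordant* when the gene's regulation sign agrees
#' between the two diseases. Paths are hypothesis-generating candidate
#' routes; no causal scoring is computed, and genes lacking polarity
#' evidence belong in a side table (see [score_associations()]), not
#' here.
#'
#' @param edges_source,edges_target Tibbles with columns `disease`,
#'   `gene`, `sign` (`"positive"`/`"negative"`), and optionally `n_refs`
#'   and `q_value`. Each must already be filtered to significant
#'   associations; duplicate (disease, gene) rows are an error.
#' @return Tibble of class `cross_disease_paths`, one row per shared
#'   gene in alphabetical order: `source_disease`, `gene`,
#'   `target_disease`, `source_sign`, `target_sign`, `concordant`, plus
#'   `source_n_refs`/`source_q`/`target_n_refs`/`target_q` when present.
#' @export
#' @examples
#' dm <- tibble::tibble(disease = "DM", gene = c("APP", "CYP2C19"),
#'                      sign = c("positive", "negative"))
#' hn <- tibble::tibble(disease = "HNSCC", gene = c("APP", "CYP2C19"),
#'                      sign = c("positive", "negative"))
#' assemble_paths(dm, hn)
assemble_paths <- function(edges_source, edges_target) {
  check_edges <- function(e, which) {
    stopifnot(all(c("disease", "gene", "sign") %in% names(e)))
    if (anyDuplicated(paste(e$disease, e$gene))) {
      stop("duplicate (disease, gene) edges in ", which, " set")
    }
    e
  }
  src <- check_edges(tibble::as_tibble(edges_source), "source")
  tgt <- check_edges(tibble::as_tibble(edges_target), "target")
  if (nrow(src) == 0 || nrow(tgt) == 0) {
    out <- tibble::tibble(source_disease = character(), gene = character(),
                          target_disease = character(),
                          source_sign = character(), target_sign = character(),
                          concordant = logical())
    return(structure(out, class = c("cross_disease_paths",
                                    class(tibble::tibble()))))
  }
  src_r <- dplyr::rename(src, source_disease = "disease",
                         source_sign = "sign")
  tgt_r <- dplyr::rename(tgt, target_disease = "disease",
                         target_sign = "sign")
  opt_rename <- function(e, prefix) {
    for (col in c("n_refs", "q_value")) {
      if (col %in% names(e)) {
        names(e)[names(e) == col] <- paste0(
          prefix, if (col == "q_value") "_q" else "_n_refs")
      }
    }
    e
  }
  src_r <- opt_rename(src_r, "source")
  tgt_r <- opt_rename(tgt_r, "target")
  paths <- dplyr::inner_join(src_r, tgt_r, by = "gene") |>
    dplyr::mutate(concordant = .data$source_sign == .data$target_sign) |>
    dplyr::arrange(.data$gene)
  front <- c("source_disease", "gene", "target_disease",
             "source_sign", "target_sign", "concordant")
  paths <- dplyr::relocate(paths, dplyr::all_of(front))
  structure(paths, class = c("cross_disease_paths", class(tibble::tibble())))
}

#' Serialize a path set
#'
#' `json` emits the path rows as a JSON array; `tsv` a tab-delimited
#' table; `dot` a Graphviz digraph with two edges per path
#' (disease -> gene and gene -> disease), colored green for positive and
#' red for negative regulation. All outputs carry a hypothesis-generating
#' disclaimer: these are candidate routes, not causal claims.
#'
#' @param paths An [assemble_paths()] result.
#' @param fmt `"json"`, `"tsv"`, or `"dot"`.
#' @return A single string in the requested format.
#' @export
pathway_report <- function(paths, fmt = c("json", "tsv", "dot")) {
  fmt <- match.arg(fmt)
  note <- "hypothesis-generating candidate paths; not evidence of causality"
  if (fmt == "json") {
    jsonlite::toJSON(list(note = note,
                          paths = tibble::as_tibble(paths)),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (fmt == "tsv") {
    readr::format_tsv(tibble::as_tibble(paths))
  } else {
    col <- function(sign) if (sign == "positive") "green" else "red"
    lines <- c(sprintf("digraph cross_disease_paths {  // %s", note))
    for (i in seq_len(nrow(paths))) {
      p <- paths[i, ]
      lines <- c(lines,
        sprintf('  "%s" -> "%s" [color=%s];', p$source_disease, p$gene,
                col(p$source_sign)),
        sprintf('  "%s" -> "%s" [color=%s];', p$gene, p$target_disease,
                col(p$target_sign)))
    }
    paste(c(lines, "}"), collapse = "\n")
  }
}

#' @rdname assemble_paths
#' @param x A `cross_disease_paths` tibble.
#' @param ... Unused.
#' @method glance cross_disease_paths
#' @export
glance.cross_disease_paths <- function(x, ...) {
  tibble::tibble(n_paths = nrow(x),
                 n_concordant = sum(x$concordant),
                 n_discordant = sum(!x$concordant))
}
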