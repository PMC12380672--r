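#' Adjusted binomial p-value for a literature-derived association
#'
#' Upper-tail binomial probability `P(X >= n_pos)` with `X ~
#' Binomial(n_total, p_null)`: the chance of seeing at least the observed
#' number of positive-polarity findings among the polarity-adjusted
#' literature observations for a gene-disease pair if findings were
#' signed at the null rate. Evaluated with the stable survival function
#' (`pbinom(lower.tail = FALSE)`), never as `1 - cdf`, so small tails are
#' exact.
#'
#' The null proportion `p_null` defaults to 0.5 — polarity at chance —
#' and should be set explicitly if the curation pipeline implies a
#' different null.
#'
#' @param n_pos Observed positive-polarity count(s).
#' @param n_total Total polarity-adjusted observation count(s), >= 1.
#' @param p_null Null positive-polarity proportion in (0, 1).
#' @return Numeric p-value(s), vectorized over the inputs.
#' @export
#' @examples
#' abm_pvalue(8, 10, 0.5)   # 56/1024
abm_pvalue <- function(n_pos, n_total, p_null = 0.5) {
  stopifnot(all(n_total >= 1), all(n_pos >= 0), all(n_pos <= n_total),
            all(p_null > 0), all(p_null < 1))
  stats::pbinom(n_pos - 1, n_total, p_null, lower.tail = FALSE)
}

#' Benjamini–Hochberg q-values
#'
#' Step-up FDR adjustment: sort p ascending, take running minima of
#' `p_(j) * m / j` from the largest rank down, cap at 1, and map back to
#' the input order. Output is invariant to input permutation (up to that
#' permutation) and satisfies `q >= p` elementwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Classify the regulation sign of a gene-disease association
#'
#' Majority vote over polarity-labeled supporting references: positive if
#' positive references outnumber negative ones, negative for the reverse,
#' mixed on a tie.
#'
#' @param pos_refs,neg_refs Non-negative reference counts (vectorized).
#' @return Character vector in `{"positive", "negative", "mixed"}`.
#' @export
classify_sign <- function(pos_refs, neg_refs) {
  stopifnot(all(pos_refs >= 0), all(neg_refs >= 0))
  if (any(pos_refs + neg_refs < 1)) stop("no polarity evidence")
  dplyr::case_when(
    pos_refs > neg_refs ~ "positive",
    neg_refs > pos_refs ~ "negative",
    TRUE ~ "mixed"
  )
}

#' Score gene-disease associations and apply FDR filtering
#'
#' Computes the adjusted binomial p-value per observation, applies
#' Benjamini–Hochberg correction *within each disease* (the FDR family is
#' the set of genes tested for that disease), and flags associations with
#' `q <= q_threshold` as significant. When polarity reference counts are
#' present (`pos_refs`, `neg_refs`), the regulation sign is classified as
#' well. q-values are reported for every row — filtering is a view, not
#' destruction — but the default return keeps only significant rows.
#'
#' @param observations Tibble with columns `gene`, `disease`, `n_pos`,
#'   `n_total`, optionally `pos_refs` and `neg_refs`. One row per
#'   (gene, disease) pair.
#' @param p_null Null positive-polarity proportion (default 0.5).
#' @param q_threshold Significance threshold on q (default 0.01).
#' @param keep_all Return all rows (with a `significant` flag) instead of
#'   only the significant ones.
#' @return Tibble of class `gene_disease_associations`, ordered by
#'   disease then gene symbol: `gene`, `disease`, `n_pos`, `n_total`,
#'   `p_value`, `q_value`, `significant`, and `sign`/`n_refs` when
#'   polarity counts were supplied.
#' @export
#' @examples
#' obs <- generate_literature(n_genes = 50, frac_true = 0.2, seed = 1)
#' score_associations(obs, keep_all = TRUE)
score_associations <- function(observations, p_null = 0.5,
                               q_threshold = 0.01, keep_all = FALSE) {
  need <- c("gene", "disease", "n_pos", "n_total")
  stopifnot(all(need %in% names(observations)))
  if (nrow(observations) == 0) {
    out <- tibble::tibble(gene = character(), disease = character(),
                          n_pos = integer(), n_total = integer(),
                          p_value = numeric(), q_value = numeric(),
                          significant = logical())
    return(structure(out, class = c("gene_disease_associations",
                                    class(tibble::tibble()))))
  }
  dup <- observations |> dplyr::count(.data$gene, .data$disease) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (gene, disease) keys: ",
         paste(dup$gene, dup$disease, sep = "/", collapse = ", "))
  }
  scored <- observations |>
    dplyr::mutate(p_value = abm_pvalue(.data$n_pos, .data$n_total, p_null)) |>
    dplyr::group_by(.data$disease) |>
    dplyr::mutate(q_value = bh_fdr(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q_value <= q_threshold) |>
    dplyr::arrange(.data$disease, .data$gene)
  if (all(c("pos_refs", "neg_refs") %in% names(scored))) {
    scored <- scored |>
      dplyr::mutate(
        sign = classify_sign(.data$pos_refs, .data$neg_refs),
        n_refs = .data$pos_refs + .data$neg_refs
      )
  }
  if (!keep_all) scored <- dplyr::filter(scored, .data$significant)
  structure(scored,
            class = c("gene_disease_associations", class(tibble::tibble())))
}

#' @rdname score_associations
#' @param x A `gene_disease_associations` tibble.
#' @param ... Unused.
#' @method glance gene_disease_associations
#' @export
glance.gene_disease_associations <- function(x, ...) {
  x |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarise(n_tested = dplyr::n(),
                     n_significant = sum(.data$significant),
                     .groups = "drop")
}
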