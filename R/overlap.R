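#' Build a labeled gene set
#'
#' Gene symbols are uppercased and deduplicated so that mixed-case
#' symbols from literature sources (e.g. lncRNA names) match.
#'
#' @param label Set label.
#' @param members Character vector of gene symbols.
#' @return List of class `gene_set` with `label` and unique, uppercased
#'   `members`.
#' @export
gene_set <- function(label, members) {
  structure(list(label = label,
                 members = unique(toupper(trimws(as.character(members))))),
            class = "gene_set")
}

#' Read gene sets from GMT or one-symbol-per-line files
#'
#' GMT rows are `label <tab> description <tab> gene1 <tab> gene2 ...`;
#' plain list files hold one symbol per line and take their label from
#' the file name.
#'
#' @param path File path; `.gmt` files are parsed as GMT.
#' @return A single [gene_set()] for a plain list, or a named list of
#'   gene sets for GMT.
#' @export
read_gene_sets <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stop("malformed GMT row: ", substr(l, 1, 40))
      gene_set(f[1], f[-(1:2)])
    })
    stats::setNames(sets, vapply(sets, `[[`, "", "label"))
  } else {
    syms <- readr::read_lines(path)
    gene_set(tools::file_path_sans_ext(basename(path)), syms[nzchar(syms)])
  }
}

#' Cross-disease gene-set overlap enrichment
#'
#' Tests whether two gene sets drawn from a finite universe share more
#' members than expected by chance. The 2x2 table is `a` = overlap,
#' `b` = set A only, `c` = set B only, `d` = universe outside both;
#' `OR = ad/bc` and the p-value is the one-sided (greater) hypergeometric
#' tail by default — the enrichment convention of the reference tables —
#' with the minlike two-sided test available behind `alternative`.
#' The universe size is an explicit required argument: silently
#' substituting `|A union B|` would change `d` and with it every result.
#'
#' @param set_a,set_b Either [gene_set()] objects (overlap computed from
#'   members, which must all lie inside the declared universe when
#'   `universe` is a character vector) or integer set sizes (counts
#'   mode, with `overlap` supplied).
#' @param universe Universe size (count), or a character vector of
#'   universe gene symbols.
#' @param overlap Overlap count; only in counts mode.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return One-row tibble of class `overlap_result`: `label_a`,
#'   `label_b`, `size_a`, `size_b`, `overlap`, `universe_size`,
#'   `odds_ratio`, `p_value`, `p_display` (bounded display string for
#'   sub-denormal p).
#' @export
#' @examples
#' overlap_fisher(7403, 4954, universe = 19924, overlap = 3489)
overlap_fisher <- function(set_a, set_b, universe, overlap = NULL,
                           alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (inherits(set_a, "gene_set")) {
    universe_size <- if (is.character(universe)) {
      length(unique(toupper(universe)))
    } else universe
    if (is.character(universe)) {
      uni <- unique(toupper(universe))
      off_a <- setdiff(set_a$members, uni)
      off_b <- setdiff(set_b$members, uni)
      if (length(off_a) + length(off_b) > 0) {
        stop("genes outside the declared universe: ",
             paste(utils::head(c(off_a, off_b), 10), collapse = ", "))
      }
    }
    label_a <- set_a$label; label_b <- set_b$label
    size_a <- length(set_a$members); size_b <- length(set_b$members)
    overlap <- length(intersect(set_a$members, set_b$members))
  } else {
    stopifnot(is.numeric(set_a), is.numeric(set_b), !is.null(overlap))
    label_a <- "set_a"; label_b <- "set_b"
    size_a <- set_a; size_b <- set_b
    universe_size <- universe
  }
  if (overlap > min(size_a, size_b) || size_a > universe_size ||
      size_b > universe_size || universe_size - size_a - size_b + overlap < 0) {
    stop("inconsistent counts: overlap/set sizes incompatible with universe")
  }
  cells <- as.double(c(overlap, size_a - overlap, size_b - overlap,
                       universe_size - size_a - size_b + overlap))
  # degenerate tables (a set fully contained in the other) get OR = Inf
  # rather than an error: the enrichment direction is still well defined
  or <- if (cells[2] * cells[3] == 0) {
    if (cells[1] * cells[4] == 0) NaN else Inf
  } else {
    odds_ratio(cells, continuity = FALSE)
  }
  alt <- if (alternative == "greater") "greater" else "two_sided"
  p <- fisher_exact(cells, alternative = alt)
  structure(tibble::tibble(
    label_a = label_a, label_b = label_b,
    size_a = size_a, size_b = size_b, overlap = overlap,
    universe_size = universe_size,
    odds_ratio = or, p_value = p,
    p_display = format_pvalue_bound(p)
  ), class = c("overlap_result", class(tibble::tibble())))
}

#' Two-set Venn partition counts
#'
#' @param set_a,set_b [gene_set()] objects or character vectors of
#'   symbols (case-normalized).
#' @return Tibble with `only_a`, `only_b`, `both`.
#' @export
#' @examples
#' venn_counts(c("g1", "g2"), c("g2", "g3"))
venn_counts <- function(set_a, set_b) {
  a <- if (inherits(set_a, "gene_set")) set_a$members else unique(toupper(set_a))
  b <- if (inherits(set_b, "gene_set")) set_b$members else unique(toupper(set_b))
  both <- length(intersect(a, b))
  tibble::tibble(only_a = length(a) - both,
                 only_b = length(b) - both,
                 both = both)
}

#' @rdname overlap_fisher
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname overlap_fisher
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(
    odds_ratio = x$odds_ratio,
    p_value = x$p_value,
    expected_overlap = x$size_a * x$size_b / x$universe_size,
    observed_overlap = x$overlap
  )
}
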