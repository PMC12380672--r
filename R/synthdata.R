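# Seeded generators emulating the structure of the analysis inputs.
# Every generator takes an explicit seed and restores the caller's RNG
# state (withr::with_seed): no global RNG side effects.

.truncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic all-case clinical cohort
#'
#' Emulates the structure of a single-disease (all patients are cases)
#' surgical cohort: a fixed sex split, per-sex comorbid-exposure status
#' drawn as a binomial, truncated-normal ages, and TNM stages sampled
#' from the reference cohort's stage frequencies. Defaults reproduce the
#' reference cohort's shape: 728 patients, 692/728 male, DM probability
#' 127/692 in males and 5/36 in females, ages mean 61.1 / sd 10.4
#' truncated to the observed \[14, 91\] range.
#'
#' The number of males is `round(n_patients * sex_proportion_male)`
#' (deterministic, so published stratum sizes round-trip exactly); only
#' DM status, ages, and stages are random.
#'
#' @param n_patients Cohort size.
#' @param sex_proportion_male Proportion male.
#' @param dm_prob_by_sex Named numeric `c(male = , female = )` exposure
#'   probabilities.
#' @param age_mean,age_sd,age_range Age distribution parameters.
#' @param seed RNG seed (required).
#' @return Tibble of patient records (same columns as [read_cohort()]).
#' @export
#' @examples
#' generate_cohort(n_patients = 100, seed = 7)
generate_cohort <- function(n_patients = 728,
                            sex_proportion_male = 692 / 728,
                            dm_prob_by_sex = c(male = 127 / 692,
                                               female = 5 / 36),
                            age_mean = 61.1, age_sd = 10.4,
                            age_range = c(14, 91),
                            seed) {
  stopifnot(n_patients >= 1,
            sex_proportion_male >= 0, sex_proportion_male <= 1,
            all(dm_prob_by_sex >= 0), all(dm_prob_by_sex <= 1),
            all(c("male", "female") %in% names(dm_prob_by_sex)),
            !missing(seed))
  n_male <- round(n_patients * sex_proportion_male)
  sex <- c(rep("male", n_male), rep("female", n_patients - n_male))
  # stage sampling weights from the reference cohort's frequency table
  t_w <- c(191, 194, 239, 270)
  n_w <- c(449, 212, 152, 46, 35)
  m_w <- c(893, 1)
  withr::with_seed(seed, {
    dm <- stats::rbinom(n_patients, 1,
                        unname(dm_prob_by_sex[sex])) == 1
    age <- as.integer(round(.truncnorm(n_patients, age_mean, age_sd,
                                       age_range[1], age_range[2])))
    t_stage <- sample(1:4, n_patients, replace = TRUE, prob = t_w)
    n_stage <- sample(0:4, n_patients, replace = TRUE, prob = n_w)
    m_stage <- sample(0:1, n_patients, replace = TRUE, prob = m_w)
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      sex = sex, age = age, dm_status = dm,
      t_stage = t_stage, n_stage = n_stage, m_stage = m_stage,
      subtype = NA_character_
    )
  })
}

#' Generate a synthetic literature observation panel
#'
#' Emulates polarity-labeled literature counts per gene: each gene gets
#' a total observation count drawn uniformly from `n_total_range`; a
#' fraction `frac_true` of genes are true associations whose positive
#' counts follow `Binomial(n_total, p_true)`, the rest are nulls with
#' positive rate `p_null`. Truth labels are returned (`is_true`) so that
#' type-I error and power can be measured against the generator.
#' Polarity reference counts (`pos_refs`, `neg_refs`) are set to the
#' positive and negative finding counts.
#'
#' @param n_genes Number of genes.
#' @param frac_true Fraction of genes with a real effect.
#' @param p_null Null positive-polarity proportion (default 0.5).
#' @param p_true Positive-polarity proportion for true associations;
#'   must exceed `p_null`.
#' @param n_total_range Inclusive range for per-gene observation totals.
#' @param disease Disease label for all rows.
#' @param seed RNG seed (required).
#' @return Tibble: `gene`, `disease`, `n_pos`, `n_total`, `pos_refs`,
#'   `neg_refs`, `is_true`.
#' @export
generate_literature <- function(n_genes = 1000, frac_true = 0.1,
                                p_null = 0.5, p_true = 0.9,
                                n_total_range = c(5, 50),
                                disease = "disease", seed) {
  stopifnot(n_genes >= 1, frac_true >= 0, frac_true <= 1,
            p_null > 0, p_null < 1, p_true > p_null, p_true <= 1,
            n_total_range[1] >= 1, n_total_range[1] <= n_total_range[2],
            !missing(seed))
  n_true <- round(n_genes * frac_true)
  withr::with_seed(seed, {
    n_total <- sample(n_total_range[1]:n_total_range[2], n_genes,
                      replace = TRUE)
    is_true <- c(rep(TRUE, n_true), rep(FALSE, n_genes - n_true))
    p <- ifelse(is_true, p_true, p_null)
    n_pos <- stats::rbinom(n_genes, n_total, p)
    tibble::tibble(
      gene = sprintf("GENE%05d", seq_len(n_genes)),
      disease = disease,
      n_pos = n_pos, n_total = n_total,
      pos_refs = n_pos, neg_refs = n_total - n_pos,
      is_true = is_true
    )
  })
}

#' Generate a random directed network
#'
#' `fixed_edge_count` draws exactly `m_edges` distinct ordered pairs
#' (no self-loops) uniformly at random; `erdos_renyi` includes each
#' ordered pair independently with probability `edge_prob`.
#'
#' @param n_nodes Number of nodes (labeled `G1..Gn`).
#' @param model `"fixed_edge_count"` or `"erdos_renyi"`.
#' @param m_edges Edge count for `fixed_edge_count`.
#' @param edge_prob Edge probability for `erdos_renyi`.
#' @param seed RNG seed (required).
#' @return A [gene_network()].
#' @export
#' @examples
#' net <- generate_network(n_nodes = 9, m_edges = 29, seed = 1)
#' network_density(net)
generate_network <- function(n_nodes,
                             model = c("fixed_edge_count", "erdos_renyi"),
                             m_edges = NULL, edge_prob = NULL, seed) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 2, !missing(seed))
  nodes <- sprintf("G%d", seq_len(n_nodes))
  # all ordered non-self pairs
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  withr::with_seed(seed, {
    if (model == "fixed_edge_count") {
      stopifnot(!is.null(m_edges), m_edges <= nrow(pairs))
      idx <- sample.int(nrow(pairs), m_edges)
    } else {
      stopifnot(!is.null(edge_prob), edge_prob >= 0, edge_prob <= 1)
      idx <- which(stats::runif(nrow(pairs)) < edge_prob)
    }
    gene_network(tibble::as_tibble(pairs[sort(idx), , drop = FALSE]),
                 nodes = nodes)
  })
}

#' Generate two gene sets with controlled overlap from a finite universe
#'
#' @param universe_size Number of genes in the universe
#'   (`U00001..U<n>`).
#' @param size_a,size_b Set sizes.
#' @param forced_overlap Exact intersection size, or `NULL` for
#'   independent uniform draws.
#' @param labels Length-2 character vector of set labels.
#' @param seed RNG seed (required).
#' @return List with elements `set_a`, `set_b` ([gene_set()]s) and
#'   `universe` (character vector).
#' @export
#' @examples
#' gs <- generate_gene_sets(19924, 7403, 4954, forced_overlap = 3489,
#'                          seed = 1)
#' overlap_fisher(gs$set_a, gs$set_b, universe = gs$universe)
generate_gene_sets <- function(universe_size, size_a, size_b,
                               forced_overlap = NULL,
                               labels = c("set_a", "set_b"), seed) {
  stopifnot(size_a <= universe_size, size_b <= universe_size,
            !missing(seed))
  if (!is.null(forced_overlap)) {
    stopifnot(forced_overlap <= min(size_a, size_b),
              size_a + size_b - forced_overlap <= universe_size)
  }
  universe <- sprintf("U%05d", seq_len(universe_size))
  withr::with_seed(seed, {
    if (is.null(forced_overlap)) {
      a <- sample(universe, size_a)
      b <- sample(universe, size_b)
    } else {
      shared <- sample(universe, forced_overlap)
      rest <- setdiff(universe, shared)
      only <- sample(rest, (size_a - forced_overlap) +
                           (size_b - forced_overlap))
      a <- c(shared, only[seq_len(size_a - forced_overlap)])
      b <- c(shared, only[seq_len(size_b - forced_overlap) +
                            (size_a - forced_overlap)])
    }
    list(set_a = gene_set(labels[1], a),
         set_b = gene_set(labels[2], b),
         universe = universe)
  })
}
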