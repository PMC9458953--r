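#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * ln p_i)` over non-zero proportions of a count vector.
#' Computed in nats; the choice of base is a reporting convention only.
#'
#' @param counts Non-negative count (or abundance) vector with a positive
#'   sum.
#' @return Shannon index (nats).
#' @examples
#' shannon_index(c(10, 30, 60))
#' @export
shannon_index <- function(counts) {
  check_counts(counts)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Simpson diversity
#'
#' `1 - sum(p_i^2)`: the probability that two reads drawn at random belong
#' to different taxa.
#'
#' @inheritParams shannon_index
#' @return Simpson index in `[0, 1)`.
#' @examples
#' simpson_index(c(10, 30, 60))
#' @export
simpson_index <- function(counts) {
  check_counts(counts)
  unname(vegan::diversity(counts, index = "simpson"))
}

check_counts <- function(counts) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("Counts must be finite and non-negative.", class = "lfcr_domain_error")
  }
  if (sum(counts) <= 0) {
    abort("Counts must have a positive sum.", class = "lfcr_domain_error")
  }
  invisible(counts)
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|a_i - b_i|) / sum(a_i + b_i)` on raw counts. With equal read
#' depths (as in the synthetic tables) raw-count and proportion versions
#' coincide; set `normalise = TRUE` to compare samples of unequal depth on
#' proportions.
#'
#' @param a,b Count vectors of equal length with positive sums.
#' @param normalise Divide each vector by its total first.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(6, 2), c(2, 6))  # 0.5
#' @export
bray_curtis <- function(a, b, normalise = FALSE) {
  if (length(a) != length(b)) {
    abort("Vectors must have equal length.", class = "lfcr_shape_error")
  }
  check_counts(a); check_counts(b)
  if (normalise) {
    a <- a / sum(a); b <- b / sum(b)
  }
  as.numeric(vegan::vegdist(rbind(a, b), method = "bray"))
}

#' Alpha-diversity table for an ASV count table
#'
#' @param table ASV tibble as produced by [generate_asv_table()] (columns
#'   `asv_id`, `taxonomy`, then one count column per sample).
#' @return Long tibble `(sample, metric, value)` with Shannon and Simpson
#'   indices per sample.
#' @export
diversity_table <- function(table) {
  counts <- asv_count_matrix(table)
  tibble(
    sample = rep(colnames(counts), 2),
    metric = rep(c("shannon", "simpson"), each = ncol(counts)),
    value = c(apply(counts, 2, shannon_index), apply(counts, 2, simpson_index))
  )
}

asv_count_matrix <- function(table) {
  meta <- intersect(c("asv_id", "taxonomy"), names(table))
  if (!"asv_id" %in% meta) {
    abort("Table needs an `asv_id` column.", class = "lfcr_schema_error")
  }
  m <- as.matrix(table[setdiff(names(table), meta)])
  rownames(m) <- table$asv_id
  if (ncol(m) == 0 || nrow(m) == 0) {
    abort("Empty ASV table.", class = "lfcr_domain_error")
  }
  m
}

CANONICAL_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Aggregate an ASV table to a taxonomic rank
#'
#' Sums counts over taxa sharing the label at the requested rank of the
#' semicolon-delimited taxonomy string and converts to relative abundance;
#' taxa without a label at that rank are pooled as `"unclassified"`.
#' Columns sum to 1.
#'
#' @param table ASV count tibble (see [diversity_table()]).
#' @param rank One of domain, phylum, class, order, family, genus,
#'   species.
#' @return Tibble with `taxon` and one relative-abundance column per
#'   sample.
#' @export
aggregate_rank <- function(table, rank = "phylum") {
  rank <- match.arg(rank, CANONICAL_RANKS)
  counts <- asv_count_matrix(table)
  idx <- match(rank, CANONICAL_RANKS)
  labels <- purrr::map_chr(strsplit(table$taxonomy, ";", fixed = TRUE), function(parts) {
    lab <- if (length(parts) >= idx) trimws(parts[idx]) else ""
    if (is.na(lab) || lab == "") "unclassified" else lab
  })
  agg <- rowsum(counts, group = labels)
  rel <- sweep(agg, 2, colSums(agg), "/")
  dplyr::bind_cols(tibble(taxon = rownames(rel)), as_tibble(rel))
}

#' Relative-abundance shift between two temperatures
#'
#' For each community, the change in relative abundance of each taxon
#' between a warm and a cold condition (`delta = relabund(cold) -
#' relabund(warm)`), with a prevalence display filter: only taxa reaching
#' `min_abundance` relative abundance in at least one of the two
#' conditions are kept.
#'
#' @param table ASV count tibble with sample columns named
#'   `<community>_<temp>C`.
#' @param warm_c,cold_c The two temperatures (degC) to contrast.
#' @param rank Taxonomic rank for aggregation, or `"asv"` for no
#'   aggregation.
#' @param min_abundance Relative-abundance display filter (default 1%).
#' @return Tibble `(community, taxon, relabund_warm, relabund_cold,
#'   delta)`.
#' @export
shift_table <- function(table, warm_c = 30, cold_c = 10, rank = "asv",
                        min_abundance = 0.01) {
  rel <- if (identical(rank, "asv")) {
    counts <- asv_count_matrix(table)
    rel <- sweep(counts, 2, colSums(counts), "/")
    dplyr::bind_cols(tibble(taxon = rownames(rel)), as_tibble(rel))
  } else {
    aggregate_rank(table, rank)
  }
  sample_cols <- setdiff(names(rel), "taxon")
  communities <- unique(sub("_[0-9.]+C$", "", sample_cols))
  purrr::map_dfr(communities, function(comm) {
    w_col <- sprintf("%s_%gC", comm, warm_c)
    c_col <- sprintf("%s_%gC", comm, cold_c)
    if (!all(c(w_col, c_col) %in% sample_cols)) {
      abort(sprintf("Community %s lacks a sample at %g or %g degC.",
                    comm, warm_c, cold_c),
        class = "lfcr_missing_sample_error")
    }
    tibble(
      community = comm,
      taxon = rel$taxon,
      relabund_warm = rel[[w_col]],
      relabund_cold = rel[[c_col]]
    ) |>
      dplyr::mutate(delta = .data$relabund_cold - .data$relabund_warm) |>
      dplyr::filter(pmax(.data$relabund_warm, .data$relabund_cold) >= min_abundance)
  })
}
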