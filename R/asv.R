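#' Design for a synthetic ASV count table
#'
#' Describes a set of taxa with SILVA-style taxonomy strings, a baseline
#' log-abundance (logit) per community, and a linear temperature response
#' on the logit scale. Sample proportions at temperature `T` (degC) are
#' `softmax(baseline + sensitivity * (T - 30))`, so a positive sensitivity
#' means the taxon loses relative abundance as temperature drops below
#' 30 degC. Counts are drawn Dirichlet-multinomial: a Dirichlet sample
#' with concentration `overdispersion * proportions` followed by a
#' multinomial of `read_depth` reads.
#'
#' @param taxa Tibble with columns `asv_id`, `taxonomy` (semicolon-
#'   delimited ranks, domain to genus), one baseline column per community
#'   (`baseline_<community>`) and `sensitivity` (per degC).
#' @param communities Character vector of community (microenvironment)
#'   labels; defaults to the four sampled microenvironments: carbon fibres
#'   (CF), planktonic volume (PV), planktonic settled (PS) and the
#'   floating sulphur biofilm (FSB).
#' @param read_depth Reads per sample.
#' @param overdispersion Dirichlet concentration scalar; larger values
#'   approach pure multinomial sampling.
#' @return An `asv_design` list.
#' @export
asv_design <- function(taxa, communities = c("CF", "PV", "PS", "FSB"),
                       read_depth = 35000, overdispersion = 200) {
  if (read_depth <= 0 || overdispersion <= 0) {
    abort("`read_depth` and `overdispersion` must be positive.",
      class = "lfcr_config_error")
  }
  need <- c("asv_id", "taxonomy", "sensitivity", paste0("baseline_", communities))
  missing_cols <- setdiff(need, names(taxa))
  if (length(missing_cols)) {
    abort(paste0("`taxa` is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "lfcr_config_error")
  }
  if (nrow(taxa) < 1) {
    abort("Need at least one taxon per community.", class = "lfcr_config_error")
  }
  structure(
    list(taxa = as_tibble(taxa), communities = communities,
         read_depth = as.integer(read_depth), overdispersion = overdispersion),
    class = "asv_design"
  )
}

#' Default taxon set for the synthetic community generator
#'
#' A compact community emulating the reactor's guilds: sulphate-reducing
#' Deltaproteobacteria that decline in relative abundance with falling
#' temperature, sulphide-oxidising Alpha/Beta/Gamma/Epsilonproteobacteria
#' (Gammaproteobacteria gaining at cold), fermentative Firmicutes,
#' Bacteroidetes and Synergistetes, and a cold-tolerant *Desulfobacter*.
#'
#' @return A taxa tibble suitable for [asv_design()].
#' @export
default_asv_taxa <- function() {
  tx <- function(phylum, class, order, family, genus) {
    paste("Bacteria", phylum, class, order, family, genus, sep = ";")
  }
  taxa <- tibble(
    asv_id = sprintf("ASV%03d", 1:12),
    taxonomy = c(
      tx("Proteobacteria", "Deltaproteobacteria", "Desulfovibrionales", "Desulfovibrionaceae", "Desulfovibrio"),
      tx("Proteobacteria", "Deltaproteobacteria", "Desulfobacterales", "Desulfobacteraceae", "Desulfobacter"),
      tx("Proteobacteria", "Deltaproteobacteria", "Desulfobacterales", "Desulfobulbaceae", "Desulfobulbus"),
      tx("Proteobacteria", "Deltaproteobacteria", "Desulfovibrionales", "Desulfomicrobiaceae", "Desulfomicrobium"),
      tx("Proteobacteria", "Gammaproteobacteria", "Chromatiales", "Halothiobacillaceae", "Halothiobacillus"),
      tx("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae", "Pseudomonas"),
      tx("Proteobacteria", "Betaproteobacteria", "Hydrogenophilales", "Hydrogenophilaceae", "Thiobacillus"),
      tx("Proteobacteria", "Epsilonproteobacteria", "Campylobacterales", "Arcobacteraceae", "Arcobacter"),
      tx("Proteobacteria", "Alphaproteobacteria", "Rhodobacterales", "Rhodobacteraceae", "Rhodobacter"),
      tx("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae", "Clostridium"),
      tx("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Dysgonomonadaceae", "Proteiniphilum"),
      tx("Synergistetes", "Synergistia", "Synergistales", "Synergistaceae", "Aminobacterium")
    ),
    # warm-community log abundances per microenvironment
    baseline_CF  = c(3.0, 1.0, 2.0, 1.5, 0.5, 0.5, 1.0, 0.5, 0.5, 2.0, 1.5, 1.0),
    baseline_PV  = c(2.5, 1.0, 1.8, 1.2, 1.0, 1.0, 1.2, 1.0, 0.8, 2.2, 1.6, 1.2),
    baseline_PS  = c(2.8, 1.2, 1.9, 1.4, 0.8, 0.8, 1.1, 0.8, 0.6, 2.1, 1.5, 1.1),
    baseline_FSB = c(1.0, 0.5, 0.8, 0.6, 2.5, 2.0, 2.2, 2.4, 1.8, 1.0, 0.8, 0.6),
    # logit change per degC relative to 30 degC; positive = declines when cooled
    sensitivity = c(0.06, -0.05, 0.04, 0.05, -0.04, -0.05, -0.02, -0.04, -0.02,
                    0.01, -0.01, 0.0)
  )
  taxa
}

# Expected taxon proportions for one community at temperature temp_c.
asv_expected_proportions <- function(design, community, temp_c) {
  base <- design$taxa[[paste0("baseline_", community)]]
  logit <- base + design$taxa$sensitivity * (temp_c - 30)
  w <- exp(logit - max(logit))
  w / sum(w)
}

#' Generate a synthetic ASV count table
#'
#' One sample per (community, temperature) pair with Dirichlet-multinomial
#' counts around the design's expected proportions. Column sums equal the
#' read depth exactly.
#'
#' @param design An [asv_design()].
#' @param temperatures Temperatures (degC) at which communities were
#'   sampled.
#' @param seed Integer seed for reproducibility.
#' @return A tibble with `asv_id`, `taxonomy` and one integer count column
#'   per sample, named `<community>_<temp>C`.
#' @examples
#' tab <- generate_asv_table(asv_design(default_asv_taxa()), c(30, 10), seed = 1)
#' colSums(tab[-(1:2)])
#' @export
generate_asv_table <- function(design, temperatures = c(30, 10), seed = 1) {
  stopifnot(inherits(design, "asv_design"))
  n_taxa <- nrow(design$taxa)
  out <- design$taxa[c("asv_id", "taxonomy")]
  withr::with_seed(seed, {
    for (comm in design$communities) {
      for (temp in temperatures) {
        p <- asv_expected_proportions(design, comm, temp)
        alpha <- design$overdispersion * p
        g <- rgamma(n_taxa, shape = alpha, rate = 1)
        if (sum(g) <= 0) g <- p  # degenerate Dirichlet draw guard
        probs <- g / sum(g)
        counts <- as.integer(rmultinom(1, size = design$read_depth, prob = probs))
        out[[sprintf("%s_%gC", comm, temp)]] <- counts
      }
    }
  })
  out
}
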