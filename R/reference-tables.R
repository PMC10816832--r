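#' Reference QTN table for a maize inter-heterotic-group hybrid panel
#'
#' A curated table of 49 significant additive/dominance QTNs for ten
#' agronomic traits (GY, GM, PH, EH, ELL, ELW, ELA, RPR_TIAG, RPR_IUE, TBN)
#' mapped with the full additive-dominance-epistasis background model in a
#' Shaan A x Shaan B maize hybrid panel; columns are trait, SNP id,
#' chromosome, position, alleles, effect mode, effect estimate, -log10 p
#' and PVE (%).  Bundled as a worked input for the PVE-accounting and
#' favorable-genotype utilities.
#'
#' @return Data frame with one row per QTN.
#' @export
reference_qtn_table <- function() {
  path <- system.file("extdata", "maize_qtn_table.tsv",
                      package = "hybridGWAS", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Reference OGMS counts per mating strategy
#'
#' One-genotype-missing-site totals over a 19,461-SNP panel for the current
#' 4 x 5 core-tester mating strategy and the medians of the doubled and
#' tripled resampling strategies; input for [ogms_percent_change()].
#'
#' @return Data frame `strategy`, `statistic`, `ogms`.
#' @export
reference_ogms_counts <- function() {
  path <- system.file("extdata", "maize_ogms_counts.tsv",
                      package = "hybridGWAS", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Per-trait PVE totals of a QTN table
#'
#' Sums the per-QTN PVE column within each trait; the per-trait total is the
#' phenotypic variance jointly attributed to the trait's main-effect QTNs.
#'
#' @param qtn_table Data frame with columns `trait` and `pve` (e.g.
#'   [reference_qtn_table()]).
#' @return Data frame `trait`, `n_qtn`, `total_pve`.
#' @export
sum_qtn_pve <- function(qtn_table) {
  stopifnot(all(c("trait", "pve") %in% names(qtn_table)))
  out <- do.call(rbind, lapply(split(qtn_table, qtn_table$trait), function(d)
    data.frame(trait = d$trait[1], n_qtn = nrow(d),
               total_pve = sum(d$pve), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
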