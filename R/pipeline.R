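#' Run configuration
#'
#' Collects paths, QC thresholds, model and scan settings for the pipeline
#' entry points.  Referenced input paths must exist at validation time.
#'
#' @param genotypes Path to the parental VCF (scan stage).
#' @param design Path to the cross-design TSV.
#' @param phenotypes Path to the phenotype TSV.
#' @param out_dir Output directory.
#' @param trait Trait column to analyse (default: first trait column).
#' @param model Background model, `"KinA"` or `"KinADE"`.
#' @param maf_min,missing_max QC thresholds.
#' @param alpha_main,alpha_epi Genome-wide significance levels.
#' @param variance_fraction PCA fraction for the effective marker number.
#' @param ld_window,r2_max,pve_min Clumping/screening parameters.
#' @param candidate_n Size of the LD-pruned candidate set for the epistasis
#'   scan.
#' @param epi_types Interaction types to scan.
#' @param cv_repeats,cv_folds Cross-validation settings (0 repeats skips CV).
#' @param seed Integer seed, recorded in every output header.
#' @param sim Named list overriding [founder_panel_spec()] /
#'   [trait_architecture()] defaults for the simulate stage.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, design = NULL, phenotypes = NULL,
                       out_dir = "results", trait = NULL, model = "KinADE",
                       maf_min = 0.05, missing_max = 0.10,
                       alpha_main = 0.10, alpha_epi = 0.10,
                       variance_fraction = 0.995, ld_window = 150000,
                       r2_max = 0.2, pve_min = 1.0, candidate_n = 20,
                       epi_types = c("aa", "ad", "da", "dd"),
                       cv_repeats = 0, cv_folds = 5, seed = 1, sim = list()) {
  for (p in c(genotypes = genotypes, design = design,
              phenotypes = phenotypes)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!model %in% c("KinA", "KinADE"))
    stop("model must be KinA or KinADE")
  structure(list(genotypes = genotypes, design = design,
                 phenotypes = phenotypes, out_dir = out_dir, trait = trait,
                 model = model, maf_min = maf_min, missing_max = missing_max,
                 alpha_main = alpha_main, alpha_epi = alpha_epi,
                 variance_fraction = variance_fraction,
                 ld_window = ld_window, r2_max = r2_max, pve_min = pve_min,
                 candidate_n = candidate_n, epi_types = epi_types,
                 cv_repeats = cv_repeats, cv_folds = cv_folds,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

## Output tables carry a provenance header: package version, seed, config
## hash.
write_output_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# hybridGWAS ",
                      as.character(utils::packageVersion("hybridGWAS"))),
               paste0("# seed: ", config$seed),
               paste0("# config: ", config_hash(config))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate-stage entry point
#'
#' Generates a complete synthetic study (founders, cross design, hybrid
#' phenotypes, ground truth) and writes it as plain-text fixtures.
#'
#' @param config A [run_config()]; `config$sim` may override any
#'   [founder_panel_spec()] field plus `n_hybrids`, `heritability`,
#'   `polygenic_share`, `n_qtn_add`, `n_qtn_dom`, `n_qtn_epi`.
#' @return Invisibly, the fixture manifest.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  spec_args <- sim[names(sim) %in% names(formals(founder_panel_spec))]
  if (is.null(spec_args$seed)) spec_args$seed <- config$seed
  spec <- do.call(founder_panel_spec, spec_args)
  arch <- default_architecture(
    n_markers = spec$n_markers,
    n_add = sim$n_qtn_add %||% 5, n_dom = sim$n_qtn_dom %||% 2,
    n_epi = sim$n_qtn_epi %||% 2,
    heritability = sim$heritability %||% 0.6,
    polygenic_share = sim$polygenic_share %||% 0.3,
    seed = spec$seed)
  study <- simulate_study(spec, arch,
                          n_hybrids = sim$n_hybrids %||% NULL,
                          mode = sim$mode %||% "partial_factorial")
  manifest <- write_fixture(study, config$out_dir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default simulated trait architecture
#'
#' Draws QTN positions uniformly over the marker panel and effect sizes from
#' centred Gaussians; a convenience for the simulate stage and tests.
#'
#' @param n_markers Marker panel size.
#' @param n_add,n_dom,n_epi Numbers of additive, dominance and epistatic
#'   QTNs.
#' @param heritability,polygenic_share,seed See [trait_architecture()].
#' @return A [trait_architecture()].
#' @export
default_architecture <- function(n_markers, n_add = 5, n_dom = 2, n_epi = 2,
                                 heritability = 0.6, polygenic_share = 0.3,
                                 seed = 1) {
  set.seed(seed + 1L)
  need <- n_add + n_dom + 2 * n_epi
  if (need > n_markers) stop("not enough markers for the requested QTNs")
  picks <- sample.int(n_markers, need)
  add <- if (n_add) data.frame(marker = picks[seq_len(n_add)],
                               effect = stats::rnorm(n_add, 0, 1)) else NULL
  dom <- if (n_dom) data.frame(marker = picks[n_add + seq_len(n_dom)],
                               effect = stats::rnorm(n_dom, 0, 1)) else NULL
  epi <- NULL
  if (n_epi) {
    base <- n_add + n_dom
    epi <- data.frame(marker_i = picks[base + seq_len(n_epi)],
                      marker_j = picks[base + n_epi + seq_len(n_epi)],
                      type = sample(c("aa", "ad", "da", "dd"), n_epi,
                                    replace = TRUE),
                      effect = stats::rnorm(n_epi, 0, 1))
  }
  trait_architecture(additive = add, dominance = dom, epistasis = epi,
                     heritability = heritability,
                     polygenic_share = polygenic_share, seed = seed)
}

#' Scan-stage entry point
#'
#' Runs the full association pipeline: QC filtering, parent-level KNN
#' imputation, hybrid genotype deduction, kinship construction, effective
#' marker number and thresholds, null REML fit, main-effect scan, LD
#' clumping with PVE screening, and a pairwise epistasis scan over an
#' LD-pruned candidate set.  Writes `scan_main.tsv`, `qtn_table.tsv` and
#' `epistasis.tsv` (plus `cv_comparison.tsv` when `cv_repeats > 0`) under
#' `config$out_dir`.
#'
#' @param config A [run_config()] with `genotypes`, `design` and
#'   `phenotypes` set.
#' @return A list with every intermediate object (parents, hybrids, `y`,
#'   kinships, `me`, `thresholds`, `null`, `scan`, `qtn`, `epistasis`,
#'   optionally `cv`).
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  design_raw <- read_cross_design(config$design)
  parents <- read_vcf(config$genotypes)
  grp <- rep("none", nrow(parents$samples))
  grp[parents$samples$id %in% design_raw$parent_a] <- "A"
  grp[parents$samples$id %in% design_raw$parent_b] <- "B"
  parents <- set_sample_groups(parents,
                               stats::setNames(grp, parents$samples$id))
  design <- cross_design(design_raw$hybrid, design_raw$parent_a,
                         design_raw$parent_b, parents = parents)
  phen <- read_phenotypes(config$phenotypes)
  trait <- config$trait %||% names(phen)[2]
  if (!trait %in% names(phen)) stop("trait '", trait, "' not in phenotypes")

  parents <- qc_filter(parents, config$maf_min, config$missing_max)
  parents <- knn_impute(parents)
  hybrids <- deduce_hybrids(parents, design)

  missing_ph <- setdiff(hybrids$samples$id, phen$hybrid)
  if (length(missing_ph))
    stop("hybrids without phenotype: ", paste(missing_ph, collapse = ", "))
  phen <- phen[match(hybrids$samples$id, phen$hybrid), ]
  y <- phen[[trait]]

  K <- build_kinships(hybrids)
  me <- effective_marker_number(hybrids,
                                variance_fraction = config$variance_fraction)
  thr_main <- significance_threshold(me, config$alpha_main, "main")
  thr_epi <- significance_threshold(max(me, 2), config$alpha_epi, "pairwise")
  null <- fit_null_reml(y, K, model = config$model)
  scan <- scan_main_effects(y, hybrids, null, threshold = thr_main)
  qtn <- clump_significant(scan, hybrids, thr_main,
                           ld_window = config$ld_window,
                           r2_max = config$r2_max, pve_min = config$pve_min)
  cand <- epistasis_candidates(scan, hybrids, n = config$candidate_n,
                               ld_window = config$ld_window,
                               r2_max = config$r2_max)
  epi <- scan_epistasis(y, hybrids, null, cand, types = config$epi_types)
  epi_sig <- epi[!is.na(epi$logp) & epi$logp >= thr_epi, , drop = FALSE]

  write_output_table(scan, file.path(config$out_dir, "scan_main.tsv"), config)
  write_output_table(qtn, file.path(config$out_dir, "qtn_table.tsv"), config)
  write_output_table(epi, file.path(config$out_dir, "epistasis.tsv"), config)
  out <- list(parents = parents, design = design, hybrids = hybrids,
              y = y, trait = trait, K = K, me = me,
              thresholds = c(main = thr_main, pairwise = thr_epi),
              null = null, scan = scan, qtn = qtn, epistasis = epi,
              epistasis_significant = epi_sig, config = config)
  if (config$cv_repeats > 0) {
    out$cv <- crossvalidate_models(y, K, folds = config$cv_folds,
                                   repeats = config$cv_repeats,
                                   seed = config$seed)
    write_output_table(out$cv$summary,
                       file.path(config$out_dir, "cv_comparison.tsv"), config)
  }
  message("scan: Me = ", me, ", thresholds ", round(thr_main, 2), "/",
          round(thr_epi, 2), ", ", nrow(qtn), " QTN(s), ",
          nrow(epi_sig), " significant epistatic pair(s)",
          if (!null$converged) " [REML not converged]")
  out
}

## LD-pruned candidate set for the epistasis scan: markers ranked by main
## scan -log10 p, greedily keeping those not in LD with an already kept one.
epistasis_candidates <- function(scan, hybrids, n = 20, ld_window = 150000,
                                 r2_max = 0.2) {
  ok <- which(!is.na(scan$logp))
  ord <- ok[order(-scan$logp[ok], scan$pos[ok])]
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) >= n) break
    close_by <- kept[scan$chrom[kept] == scan$chrom[j] &
                       abs(scan$pos[kept] - scan$pos[j]) <= ld_window]
    if (length(close_by)) {
      r2 <- suppressWarnings(
        stats::cor(hybrids$calls[, j],
                   hybrids$calls[, close_by, drop = FALSE]))^2
      if (any(r2 > r2_max, na.rm = TRUE)) next
    }
    kept <- c(kept, j)
  }
  scan$marker[sort(kept)]
}

#' Insights-stage entry point
#'
#' Post-GWAS breeding analytics on a [run_scan()] result: favorable
#' genotypes and accumulation regression, per-group allele frequencies of
#' the QTNs, TOP/BOT heterozygosity and favorable-count enrichment, and
#' (when tester sets are supplied) OGMS counting plus the
#' doubled/tripled mating-strategy comparison.
#'
#' @param scan_out A [run_scan()] result.
#' @param direction Trait direction (`"higher_better"`, `"lower_better"` or
#'   a trait name known to [trait_directions()]).
#' @param fraction Tail fraction for the TOP/BOT comparison.
#' @param testers_a,testers_b Optional core tester ids for the OGMS
#'   analysis.
#' @param n_resamples Resamples for the mating-strategy comparison.
#' @return A list with `favorable`, `accumulation`, `group_freq`,
#'   `top_bottom`, and optionally `ogms` / `strategies`.
#' @export
run_insights <- function(scan_out, direction = "higher_better",
                         fraction = 0.10, testers_a = NULL, testers_b = NULL,
                         n_resamples = 50) {
  config <- scan_out$config
  if (nrow(scan_out$qtn) == 0) stop("no QTNs in scan output")
  cm <- genotype_class_means(scan_out$y, scan_out$hybrids,
                             scan_out$qtn$marker)
  fav <- favorable_genotypes(cm, direction)
  acc <- accumulation_regression(scan_out$y, scan_out$hybrids, fav)
  gf <- group_allele_frequencies(scan_out$parents, scan_out$qtn$marker)
  tb_fav <- top_bottom_enrichment(scan_out$y, acc$counts, fraction)
  het <- heterozygosity_counts(scan_out$hybrids, scan_out$qtn$marker)
  tb_het <- top_bottom_enrichment(scan_out$y, het, fraction)
  out <- list(favorable = fav, accumulation = acc, group_freq = gf,
              top_bottom = rbind(cbind(count = "favorable", tb_fav),
                                 cbind(count = "heterozygote", tb_het)))
  write_output_table(fav, file.path(config$out_dir, "favorable.tsv"), config)
  write_output_table(data.frame(slope = acc$slope, intercept = acc$intercept,
                                r_squared = acc$r_squared,
                                p_value = acc$p_value, n = acc$n),
                     file.path(config$out_dir, "accumulation.tsv"), config)
  write_output_table(gf, file.path(config$out_dir, "group_freq.tsv"), config)
  write_output_table(out$top_bottom,
                     file.path(config$out_dir, "top_bottom.tsv"), config)
  if (!is.null(testers_a) && !is.null(testers_b)) {
    out$ogms <- count_ogms(scan_out$parents, testers_a, testers_b)
    out$strategies <- compare_mating_strategies(
      scan_out$parents, testers_a, testers_b, n_resamples = n_resamples,
      seed = config$seed)
    write_output_table(out$strategies$strategies,
                       file.path(config$out_dir, "ogms_strategies.tsv"),
                       config)
    write_output_table(out$strategies$resamples,
                       file.path(config$out_dir, "ogms_resamples.tsv"),
                       config)
  }
  out
}
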