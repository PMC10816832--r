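#' Read a VCF into a marker matrix
#'
#' Loads biallelic SNP records from a VCF (v4.x) via \pkg{vcfR}.
#' Multi-allelic records are skipped with a logged count (available as
#' `attr(x, "n_multiallelic_skipped")`); missing or half-missing GT fields
#' become missing calls.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param groups Optional assignment of heterotic-group labels: a named
#'   character vector (`id -> group`) or a function of the sample ids, as in
#'   [set_sample_groups()].  Default labels every sample `"none"`.
#' @return A [marker_matrix()] (samples x markers).
#' @export
read_vcf <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error in '", path,
                                         "': ", conditionMessage(e)))
  fix <- v@fix
  gt <- v@gt
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no records: ", path)
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"]) |
    !fix[, "ALT"] %in% c("A", "C", "G", "T") |
    !fix[, "REF"] %in% c("A", "C", "G", "T")
  n_skip <- sum(multi)
  if (n_skip) message(n_skip, " non-biallelic-SNP record(s) skipped")
  fix <- fix[!multi, , drop = FALSE]
  gt <- gt[!multi, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records left in ", path)
  sample_ids <- colnames(gt)[-1]
  gt_field <- sub(":.*", "", gt[, -1, drop = FALSE])
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  calls <- t(apply(gt_field, 1, code))   # markers x samples -> transpose below
  calls <- t(matrix(as.integer(calls), nrow = nrow(gt_field)))
  rownames(calls) <- sample_ids
  mk <- fix[, "ID"]
  mk[is.na(mk) | mk == "."] <- paste0(fix[, "CHROM"], "_",
                                      fix[, "POS"])[is.na(mk) | mk == "."]
  map <- data.frame(marker = mk, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  samples <- data.frame(id = sample_ids, group = "none",
                        stringsAsFactors = FALSE)
  m <- marker_matrix(calls, map, samples)
  if (!is.null(groups)) m <- set_sample_groups(m, groups)
  message(nrow(map), " biallelic record(s), ", length(sample_ids),
          " sample(s) loaded from ", basename(path))
  attr(m, "n_multiallelic_skipped") <- n_skip
  m
}

#' Write a marker matrix as a plain-text VCF
#'
#' Minimal VCF v4.2 writer (uncompressed, GT field only).  Calls are written
#' as `0/0`, `0/1`, `1/1` or `./.`.
#'
#' @param m A [marker_matrix()].
#' @param path Output file path.
#' @export
write_vcf <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=hybridGWAS_",
                      as.character(utils::packageVersion("hybridGWAS"))),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", m$samples$id), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(m$calls), ncol(m$calls))
  obs <- !is.na(m$calls)
  gt[obs] <- gt_code[m$calls[obs] + 1L]
  lines <- vapply(seq_len(ncol(m$calls)), function(j) {
    paste(c(m$map$chrom[j], m$map$pos[j], m$map$marker[j], m$map$ref[j],
            m$map$alt[j], ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a cross-design table
#'
#' Tab-separated file with header columns `hybrid`, `parent_a`, `parent_b`.
#' Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param parents Optional parental [marker_matrix()] for id validation.
#' @return A [cross_design()].
#' @export
read_cross_design <- function(path, parents = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("hybrid", "parent_a", "parent_b")
  if (!all(need %in% names(d)))
    stop("cross-design file must have columns: ", paste(need, collapse = ", "))
  message(nrow(d), " cross-design row(s) read from ", basename(path))
  cross_design(d$hybrid, d$parent_a, d$parent_b, parents = parents)
}

#' Read a phenotype table
#'
#' Tab-separated, header row, first column the hybrid id and remaining
#' column(s) trait values.  Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A data frame with column `hybrid` and one column per trait.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("phenotype file needs an id column plus >= 1 trait")
  names(d)[1] <- "hybrid"
  message(nrow(d), " phenotype row(s), ", ncol(d) - 1,
          " trait(s) read from ", basename(path))
  d
}

#' Per-marker missingness, MAF and PIC
#'
#' MAF is computed from non-missing calls.  For a biallelic marker with
#' allele frequencies p and q, PIC = 1 - p^2 - q^2 - 2 p^2 q^2.
#'
#' @param m A [marker_matrix()].
#' @return Data frame `marker`, `missing_rate`, `maf`, `pic`.
#' @export
marker_stats <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  calls <- m$calls
  n_obs <- colSums(!is.na(calls))
  miss <- 1 - n_obs / nrow(calls)
  p <- ifelse(n_obs > 0, colSums(calls, na.rm = TRUE) / (2 * n_obs), 0)
  maf <- pmin(p, 1 - p)
  pic <- 1 - p^2 - (1 - p)^2 - 2 * p^2 * (1 - p)^2
  pic[maf == 0] <- 0
  data.frame(marker = m$map$marker, missing_rate = miss, maf = maf, pic = pic,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter markers on MAF and missingness
#'
#' Retains markers with MAF >= `maf_min` and missing rate <= `missing_max`
#' (a marker with missing rate exactly at the threshold is kept; only
#' strictly greater is removed).  Marker order is preserved.  The removal
#' tally by reason is attached as `attr(x, "removed")`.
#'
#' @param m A [marker_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param missing_max Maximum missing rate (default 0.10).
#' @return The filtered [marker_matrix()].
#' @export
qc_filter <- function(m, maf_min = 0.05, missing_max = 0.10) {
  stopifnot(inherits(m, "marker_matrix"))
  if (ncol(m$calls) == 0) stop("marker matrix is empty")
  st <- marker_stats(m)
  low_maf <- st$maf < maf_min
  high_miss <- st$missing_rate > missing_max
  keep <- !(low_maf | high_miss)
  if (!any(keep))
    warning("qc_filter removed every marker")
  out <- mm_subset(m, markers = which(keep))
  attr(out, "removed") <- list(n_low_maf = sum(low_maf),
                               n_high_missing = sum(high_miss),
                               n_removed = sum(!keep))
  out
}

#' LD-based KNN imputation of missing calls
#'
#' Fills each missing call by a weighted vote of the `k` most similar
#' samples, with similarity computed over the `window` markers flanking the
#' missing site on the same chromosome (LD-kNN genotype imputation).
#' Non-missing calls are never changed.  A marker with no observed calls at
#' all is filled with the homozygous REF genotype and logged.
#'
#' @param m A [marker_matrix()].
#' @param k Number of nearest neighbour samples (default 5).
#' @param window Number of flanking markers used for the distance
#'   (default 30).
#' @return A complete [marker_matrix()] with no missing calls.
#' @export
knn_impute <- function(m, k = 5, window = 30) {
  stopifnot(inherits(m, "marker_matrix"))
  calls <- m$calls
  if (!anyNA(calls)) return(m)
  if (nrow(calls) < k + 1) stop("need at least k+1 samples for KNN imputation")
  n_full_missing <- 0L
  for (j in which(colSums(is.na(calls)) > 0)) {
    obs_j <- !is.na(calls[, j])
    if (!any(obs_j)) {
      calls[, j] <- 0L  # fully missing marker: fall back to hom REF
      n_full_missing <- n_full_missing + 1L
      next
    }
    ## flanking window on the same chromosome (by map order)
    same_chr <- which(m$map$chrom == m$map$chrom[j])
    nb <- setdiff(same_chr[order(abs(same_chr - j))], j)
    nb <- nb[seq_len(min(window, length(nb)))]
    win <- m$calls[, nb, drop = FALSE]
    maj <- as.integer(names(which.max(table(calls[obs_j, j]))))
    cand <- which(obs_j)
    win_obs <- win[cand, , drop = FALSE]
    for (i in which(!obs_j)) {
      d <- rowMeans(abs(sweep(win_obs, 2, win[i, ], "-")), na.rm = TRUE)
      d[is.nan(d)] <- Inf
      ord <- order(d)[seq_len(min(k, length(cand)))]
      if (!any(is.finite(d[ord]))) { calls[i, j] <- maj; next }
      sel <- cand[ord]
      wts <- 1 / (d[ord] + 0.1)
      votes <- tapply(wts, calls[sel, j], sum)
      calls[i, j] <- as.integer(names(votes)[which.max(votes)])
    }
  }
  if (n_full_missing)
    message(n_full_missing, " fully missing marker(s) filled with hom REF")
  marker_matrix(calls, m$map, m$samples)
}

#' Deduce F1 hybrid genotypes from inbred parents
#'
#' For homozygous parents the hybrid genotype at a marker is fully
#' determined: both parents hom REF gives hom REF, both hom ALT gives hom
#' ALT, and differing homozygotes give a heterozygote.  A missing parental
#' call makes the hybrid call missing.  A residually heterozygous parental
#' call makes the hybrid call missing under `on_het = "missing"` (default)
#' or raises an error under `on_het = "error"`, since the deduction is only
#' defined for inbred parents.
#'
#' @param parents Parental [marker_matrix()].
#' @param design A [cross_design()].
#' @param on_het `"missing"` or `"error"`.
#' @return A hybrid [marker_matrix()] (group `"hybrid"`), markers as in
#'   `parents`.
#' @export
deduce_hybrids <- function(parents, design, on_het = c("missing", "error")) {
  stopifnot(inherits(parents, "marker_matrix"))
  on_het <- match.arg(on_het)
  ids <- parents$samples$id
  bad <- setdiff(unique(c(design$parent_a, design$parent_b)), ids)
  if (length(bad))
    stop("parent id(s) not found in parental matrix: ",
         paste(bad, collapse = ", "))
  calls <- parents$calls
  if (on_het == "error" && any(calls == 1L, na.rm = TRUE))
    stop("heterozygous parental call(s) present; parents must be inbred")
  calls[calls == 1L] <- NA_integer_   # residual heterozygosity -> missing
  gA <- calls[design$parent_a, , drop = FALSE]
  gB <- calls[design$parent_b, , drop = FALSE]
  hyb <- (gA + gB) %/% 2L
  rownames(hyb) <- design$hybrid
  marker_matrix(hyb, parents$map,
                data.frame(id = design$hybrid, group = "hybrid",
                           stringsAsFactors = FALSE))
}

#' Per-hybrid heterozygote counts
#'
#' Number of heterozygous calls per sample over a marker subset (default all
#' markers); used for heterozygosity-enrichment comparisons between
#' phenotype tails.
#'
#' @param hybrids A [marker_matrix()].
#' @param markers Optional marker ids or indices.
#' @return Named integer vector, one count per sample.
#' @export
heterozygosity_counts <- function(hybrids, markers = NULL) {
  stopifnot(inherits(hybrids, "marker_matrix"))
  if (!is.null(markers) && length(markers) == 0)
    stop("empty marker subset")
  mm <- if (is.null(markers)) hybrids else mm_subset(hybrids, markers = markers)
  cnt <- rowSums(mm$calls == 1L, na.rm = TRUE)
  stats::setNames(as.integer(cnt), mm$samples$id)
}
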