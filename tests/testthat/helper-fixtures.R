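# Shared fixture builders; everything is generated in code at test time.

# Marker matrix from a plain call matrix, auto-filling the map.
toy_mm <- function(calls, chrom = NULL, pos = NULL, group = NULL,
                   ref = NULL, alt = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  n <- nrow(calls)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) {
    pos <- integer(m)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- seq_along(idx) * 1000L
    }
  }
  ids <- rownames(calls)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  if (is.null(group)) group <- rep("none", n)
  marker_matrix(calls,
                map = data.frame(marker = sprintf("m%03d", seq_len(m)),
                                 chrom = chrom, pos = pos,
                                 ref = if (is.null(ref)) rep("A", m) else ref,
                                 alt = if (is.null(alt)) rep("T", m) else alt),
                samples = data.frame(id = ids, group = group))
}

# A small complete synthetic study reused across scan/insight tests.
small_study <- function(seed = 11, n_a = 10, n_b = 18, n_markers = 250,
                        n_hybrids = 120, h2 = 0.6, n_add = 3, n_dom = 1,
                        n_epi = 1, polygenic_share = 0.3) {
  spec <- founder_panel_spec(n_group_a = n_a, n_group_b = n_b,
                             n_markers = n_markers, seed = seed)
  arch <- default_architecture(n_markers, n_add = n_add, n_dom = n_dom,
                               n_epi = n_epi, heritability = h2,
                               polygenic_share = polygenic_share, seed = seed)
  simulate_study(spec, arch, n_hybrids = n_hybrids)
}

# Independent closed-form oracle: single-kinship REML profiled over the
# variance ratio after eigen-rotation.
reml_single_oracle <- function(y, Ka) {
  n <- length(y)
  eig <- eigen(Ka, symmetric = TRUE)
  xi <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- as.vector(crossprod(U, y))
  xs <- as.vector(crossprod(U, rep(1, n)))
  prof <- function(loglam) {
    lam <- exp(loglam)
    d <- lam * xi + 1
    xvx <- sum(xs^2 / d)
    xvy <- sum(xs * ys / d)
    ypy <- sum(ys^2 / d) - xvy^2 / xvx
    se2 <- ypy / (n - 1)
    ll <- -0.5 * (sum(log(d)) + (n - 1) * log(se2) + log(xvx) + (n - 1))
    list(ll = ll, se2 = se2, sa2 = lam * se2)
  }
  opt <- stats::optimize(function(t) -prof(t)$ll, c(-12, 12), tol = 1e-10)
  prof(opt$minimum)
}

# Hand-written 3-sample VCF with one triallelic record and missing calls.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "P3", sep = "\t"),
    paste("chr1", "100", "snpA", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "snpTri", "G", "A,C", ".", "PASS", ".", "GT",
          "0/0", "1/2", "0/1", sep = "\t"),
    paste("chr2", "150", "snpB", "C", "G", ".", "PASS", ".", "GT",
          "./.", "0/0", "1/1", sep = "\t")), path)
  path
}
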