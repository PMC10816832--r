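#' Founder panel specification
#'
#' Parameters of the synthetic founder generator.  The generator emulates two
#' diverged heterotic groups of fully homozygous inbred lines (a narrow
#' "A" pool and a genetically broader "B" pool, as in typical maize breeding
#' programs) with block-wise linkage disequilibrium.
#'
#' @param n_group_a,n_group_b Number of inbred lines per heterotic group.
#' @param n_markers Number of biallelic markers.
#' @param n_chromosomes Number of chromosomes the markers are spread over.
#' @param divergence Real in `[0,1]`; controls the separation of per-marker
#'   allele frequencies between the two groups (0 = one shared frequency
#'   distribution).
#' @param ld_block_span Haplotype-block span in basepairs; markers within a
#'   block share founder haplotype state with probability `ld_rho`, which is
#'   what gives the LD-clumping stage realistically correlated markers.
#' @param ld_rho Within-block copying probability in `[0,1)`; 0 gives
#'   mutually independent markers.
#' @param maf_floor Lower bound of the allele-frequency distribution,
#'   in (0, 0.5).
#' @param mean_spacing_bp Mean inter-marker spacing in basepairs.
#' @param seed Integer seed; the generator is a pure function of the spec.
#'
#' @return A list of class `founder_panel_spec`.
#' @export
founder_panel_spec <- function(n_group_a = 30, n_group_b = 89,
                               n_markers = 1000, n_chromosomes = 10,
                               divergence = 0.3, ld_block_span = 150000,
                               ld_rho = 0.9, maf_floor = 0.05,
                               mean_spacing_bp = 20000, seed = 1) {
  chk <- function(ok, field, msg) if (!ok) stop("invalid '", field, "': ", msg)
  chk(is.numeric(n_group_a) && n_group_a >= 1, "n_group_a", "must be >= 1")
  chk(is.numeric(n_group_b) && n_group_b >= 1, "n_group_b", "must be >= 1")
  chk(is.numeric(n_markers) && n_markers >= 1, "n_markers", "must be >= 1")
  chk(is.numeric(n_chromosomes) && n_chromosomes >= 1, "n_chromosomes",
      "must be >= 1")
  chk(is.numeric(divergence) && divergence >= 0 && divergence <= 1,
      "divergence", "must be in [0,1]")
  chk(is.numeric(ld_block_span) && ld_block_span >= 1, "ld_block_span",
      "must be positive basepairs")
  chk(is.numeric(ld_rho) && ld_rho >= 0 && ld_rho < 1, "ld_rho",
      "must be in [0,1)")
  chk(is.numeric(maf_floor) && maf_floor > 0 && maf_floor < 0.5, "maf_floor",
      "must be in (0,0.5)")
  chk(is.numeric(mean_spacing_bp) && mean_spacing_bp >= 1, "mean_spacing_bp",
      "must be positive")
  chk(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 divergence = divergence, ld_block_span = ld_block_span,
                 ld_rho = ld_rho, maf_floor = maf_floor,
                 mean_spacing_bp = mean_spacing_bp, seed = as.integer(seed)),
            class = "founder_panel_spec")
}

#' Simulate a founder panel of inbred lines
#'
#' Draws per-marker ALT-allele frequencies for the two heterotic groups from
#' Beta distributions whose means are separated proportionally to
#' `divergence` (the B group uses a lower Beta concentration, giving it the
#' wider within-group diversity observed in real breeder pools), then samples
#' fully homozygous founder genotypes.  LD is induced by sharing a per-block
#' latent uniform across markers of the same haplotype block with probability
#' `ld_rho`, which leaves marginal allele frequencies untouched.
#'
#' @param spec A [founder_panel_spec()].
#' @return A [marker_matrix()] of homozygous calls (0/2) with group labels
#'   `"A"`/`"B"` and a marker map with strictly increasing positions.
#' @export
simulate_founders <- function(spec) {
  stopifnot(inherits(spec, "founder_panel_spec"))
  set.seed(spec$seed)
  m <- spec$n_markers
  nA <- spec$n_group_a
  nB <- spec$n_group_b

  ## marker map: markers split near-evenly over chromosomes,
  ## exponential spacing
  chrom <- sort(rep_len(seq_len(spec$n_chromosomes), m))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- 1 + stats::rexp(length(idx), rate = 1 / spec$mean_spacing_bp)
    pos[idx] <- cumsum(ceiling(gaps))
  }
  alle <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))

  ## group allele-frequency means separated by divergence
  mu <- stats::runif(m, spec$maf_floor, 1 - spec$maf_floor)
  sgn <- sample(c(-1, 1), m, replace = TRUE)
  half <- spec$divergence * 0.25
  clamp <- function(x) pmin(pmax(x, spec$maf_floor), 1 - spec$maf_floor)
  muA <- clamp(mu + sgn * half)
  muB <- clamp(mu - sgn * half)
  conc_a <- 30; conc_b <- 10   # B pool drawn with wider spread
  pA <- stats::rbeta(m, muA * conc_a, (1 - muA) * conc_a)
  pB <- stats::rbeta(m, muB * conc_b, (1 - muB) * conc_b)
  pA <- clamp(pA); pB <- clamp(pB)

  ## haplotype blocks by physical span: new block when the distance from the
  ## block anchor exceeds ld_block_span
  block <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    bb <- integer(length(idx)); cur <- 1L; anchor <- pos[idx][1]
    for (j in seq_along(idx)) {
      if (pos[idx][j] - anchor > spec$ld_block_span) {
        cur <- cur + 1L; anchor <- pos[idx][j]
      }
      bb[j] <- cur
    }
    block[idx] <- bb + max(c(0L, block)) # unique across chromosomes
  }

  draw_group <- function(n, p) {
    g <- matrix(0L, n, m)
    for (b in unique(block)) {
      cols <- which(block == b)
      u_shared <- stats::runif(n)
      for (j in cols) {
        u <- ifelse(stats::runif(n) < spec$ld_rho, u_shared, stats::runif(n))
        g[, j] <- 2L * (u < p[j])
      }
    }
    g
  }
  gA <- draw_group(nA, pA)
  gB <- draw_group(nB, pB)

  ids <- c(sprintf("A%03d", seq_len(nA)), sprintf("B%03d", seq_len(nB)))
  map <- data.frame(marker = sprintf("snp%05d", seq_len(m)),
                    chrom = paste0("chr", chrom), pos = pos,
                    ref = alle[, 1], alt = alle[, 2],
                    stringsAsFactors = FALSE)
  samples <- data.frame(id = ids,
                        group = rep(c("A", "B"), c(nA, nB)),
                        stringsAsFactors = FALSE)
  marker_matrix(rbind(gA, gB), map, samples)
}

#' Simulate a cross design between two heterotic groups
#'
#' @param founders Parental [marker_matrix()] with groups `"A"` and `"B"`.
#' @param n_hybrids Number of hybrids to draw (ignored for
#'   `mode = "full_factorial"`; defaults to all available pairs otherwise).
#' @param mode `"partial_factorial"` samples unique A-by-B pairs at random;
#'   `"full_factorial"` enumerates every pair; `"tester"` restricts both
#'   sides to the named core tester lines.
#' @param testers_a,testers_b Tester ids (required for `mode = "tester"`).
#' @param seed Integer seed.
#' @return A [cross_design()] with no duplicate parent pairs.
#' @export
simulate_cross_design <- function(founders, n_hybrids = NULL,
                                  mode = c("partial_factorial",
                                           "full_factorial", "tester"),
                                  testers_a = NULL, testers_b = NULL,
                                  seed = 1) {
  stopifnot(inherits(founders, "marker_matrix"))
  mode <- match.arg(mode)
  ids_a <- founders$samples$id[founders$samples$group == "A"]
  ids_b <- founders$samples$id[founders$samples$group == "B"]
  if (mode == "tester") {
    if (is.null(testers_a) || is.null(testers_b))
      stop("tester mode requires testers_a and testers_b")
    bad <- c(setdiff(testers_a, ids_a), setdiff(testers_b, ids_b))
    if (length(bad)) stop("unknown tester id(s): ", paste(bad, collapse = ", "))
    ids_a <- testers_a; ids_b <- testers_b
  }
  pairs <- expand.grid(parent_a = ids_a, parent_b = ids_b,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_avail <- nrow(pairs)
  if (mode == "full_factorial" || is.null(n_hybrids)) {
    take <- seq_len(n_avail)
    if (!is.null(n_hybrids) && n_hybrids != n_avail && mode == "full_factorial")
      stop("full factorial of ", n_avail, " pairs; n_hybrids mismatch")
  } else {
    if (n_hybrids > n_avail)
      stop("n_hybrids (", n_hybrids, ") exceeds available A x B pairs (",
           n_avail, ")")
    set.seed(seed)
    take <- sort(sample.int(n_avail, n_hybrids))
  }
  pairs <- pairs[take, , drop = FALSE]
  cross_design(hybrid = sprintf("H%04d", seq_len(nrow(pairs))),
               parent_a = pairs$parent_a, parent_b = pairs$parent_b,
               parents = founders)
}

#' Trait architecture for phenotype simulation
#'
#' Ground truth of a simulated trait: quantitative-trait-nucleotide (QTN)
#' positions and effects for additive, dominance and epistatic terms, the
#' target narrow+non-additive (broad-sense) heritability, and the share of
#' genetic variance carried by a diffuse polygenic background.
#'
#' @param additive Data frame `marker` (index or id), `effect` (a); may be
#'   empty.
#' @param dominance Data frame `marker`, `effect` (d); may be empty.
#' @param epistasis Data frame `marker_i`, `marker_j`,
#'   `type` in `{"aa","ad","da","dd"}`, `effect`; may be empty.
#' @param heritability Target genetic variance fraction, strictly in (0,1).
#' @param polygenic_share Fraction of genetic variance from the polygenic
#'   background, in `[0,1)`.
#' @param seed Integer seed.
#' @return A list of class `trait_architecture`.
#' @export
trait_architecture <- function(additive = NULL, dominance = NULL,
                               epistasis = NULL, heritability = 0.6,
                               polygenic_share = 0.3, seed = 1) {
  empty2 <- data.frame(marker = integer(), effect = numeric())
  empty4 <- data.frame(marker_i = integer(), marker_j = integer(),
                       type = character(), effect = numeric())
  additive <- if (is.null(additive)) empty2 else as.data.frame(additive)
  dominance <- if (is.null(dominance)) empty2 else as.data.frame(dominance)
  epistasis <- if (is.null(epistasis)) empty4 else as.data.frame(epistasis)
  if (!(heritability > 0 && heritability < 1))
    stop("invalid 'heritability': must be strictly in (0,1)")
  if (!(polygenic_share >= 0 && polygenic_share < 1))
    stop("invalid 'polygenic_share': must be in [0,1)")
  if (anyDuplicated(additive$marker))
    stop("invalid 'additive': duplicate QTN markers")
  if (anyDuplicated(dominance$marker))
    stop("invalid 'dominance': duplicate QTN markers")
  if (nrow(epistasis)) {
    if (!all(epistasis$type %in% c("aa", "ad", "da", "dd")))
      stop("invalid 'epistasis': type must be aa/ad/da/dd")
    key <- paste(pmin(epistasis$marker_i, epistasis$marker_j),
                 pmax(epistasis$marker_i, epistasis$marker_j),
                 epistasis$type)
    if (anyDuplicated(key)) stop("invalid 'epistasis': duplicate pairs")
  }
  structure(list(additive = additive, dominance = dominance,
                 epistasis = epistasis, heritability = heritability,
                 polygenic_share = polygenic_share, seed = as.integer(seed)),
            class = "trait_architecture")
}

resolve_qtn_index <- function(marker, m) {
  idx <- if (is.character(marker)) match(marker, m$map$marker) else as.integer(marker)
  if (anyNA(idx) || any(idx < 1) || any(idx > ncol(m$calls)))
    stop("QTN marker index out of range")
  idx
}

#' Simulate hybrid phenotypes from a trait architecture
#'
#' The phenotype is the sum of additive terms (effects on the -1/0/1 additive
#' coding Z), dominance terms (0/1 heterozygosity coding W), epistatic terms
#' (direct products of the corresponding Z/W columns, the same coding the
#' association scan fits), a polygenic term drawn with covariance
#' proportional to the additive kinship of the hybrids, and Gaussian residual
#' noise scaled so that the realized genetic variance fraction matches the
#' target heritability.
#'
#' @param hybrids Hybrid [marker_matrix()] (no missing calls).
#' @param arch A [trait_architecture()].
#' @return A list with `phenotypes` (data frame `hybrid`, `value`) and
#'   `components` (data frame of realized variances per component plus the
#'   realized heritability).
#' @export
simulate_phenotypes <- function(hybrids, arch) {
  stopifnot(inherits(hybrids, "marker_matrix"),
            inherits(arch, "trait_architecture"))
  if (anyNA(hybrids$calls)) stop("hybrid calls must be complete")
  set.seed(arch$seed)
  n <- nrow(hybrids$calls)
  Z <- hybrids$calls - 1
  W <- (hybrids$calls == 1) * 1

  g_add <- g_dom <- g_epi <- rep(0, n)
  if (nrow(arch$additive)) {
    ia <- resolve_qtn_index(arch$additive$marker, hybrids)
    g_add <- as.vector(Z[, ia, drop = FALSE] %*% arch$additive$effect)
  }
  if (nrow(arch$dominance)) {
    id <- resolve_qtn_index(arch$dominance$marker, hybrids)
    g_dom <- as.vector(W[, id, drop = FALSE] %*% arch$dominance$effect)
  }
  if (nrow(arch$epistasis)) {
    for (r in seq_len(nrow(arch$epistasis))) {
      i <- resolve_qtn_index(arch$epistasis$marker_i[r], hybrids)
      j <- resolve_qtn_index(arch$epistasis$marker_j[r], hybrids)
      ty <- strsplit(arch$epistasis$type[r], "")[[1]]
      ci <- if (ty[1] == "a") Z[, i] else W[, i]
      cj <- if (ty[2] == "a") Z[, j] else W[, j]
      g_epi <- g_epi + arch$epistasis$effect[r] * ci * cj
    }
  }
  g_qtn <- g_add + g_dom + g_epi
  v_qtn <- stats::var(g_qtn) * (n - 1) / n

  g_poly <- rep(0, n)
  s <- arch$polygenic_share
  if (s > 0) {
    Ka <- tcrossprod(Z)
    Ka <- Ka / mean(diag(Ka))
    L <- chol(Ka + diag(1e-6, n))
    g0 <- as.vector(crossprod(L, stats::rnorm(n)))
    g0 <- g0 - mean(g0)
    v0 <- stats::var(g0) * (n - 1) / n
    v_target <- if (v_qtn > 0) v_qtn * s / (1 - s) else 1
    if (v0 > 0) g_poly <- g0 * sqrt(v_target / v0)
  }
  g <- g_qtn + g_poly
  v_g <- stats::var(g) * (n - 1) / n
  h2 <- arch$heritability
  v_e <- if (v_g > 0) v_g * (1 - h2) / h2 else 1
  e <- stats::rnorm(n, sd = sqrt(v_e))
  y <- g + e

  comp <- data.frame(
    component = c("additive", "dominance", "epistatic", "polygenic",
                  "genetic_total", "residual", "realized_h2"),
    variance = c(stats::var(g_add) * (n - 1) / n,
                 stats::var(g_dom) * (n - 1) / n,
                 stats::var(g_epi) * (n - 1) / n,
                 stats::var(g_poly) * (n - 1) / n,
                 v_g,
                 stats::var(e) * (n - 1) / n,
                 v_g / (v_g + stats::var(e) * (n - 1) / n)))
  list(phenotypes = data.frame(hybrid = hybrids$samples$id, value = y,
                               stringsAsFactors = FALSE),
       components = comp)
}

#' Simulate a complete hybrid GWAS study
#'
#' Convenience wrapper chaining [simulate_founders()],
#' [simulate_cross_design()], [deduce_hybrids()] and
#' [simulate_phenotypes()].
#'
#' @param spec A [founder_panel_spec()].
#' @param arch A [trait_architecture()].
#' @param n_hybrids,mode,testers_a,testers_b Passed to
#'   [simulate_cross_design()].
#' @return A list of class `simulated_study` with elements `founders`,
#'   `design`, `hybrids`, `phenotypes`, `truth` (architecture plus realized
#'   components).
#' @export
simulate_study <- function(spec, arch, n_hybrids = NULL,
                           mode = "partial_factorial",
                           testers_a = NULL, testers_b = NULL) {
  founders <- simulate_founders(spec)
  design <- simulate_cross_design(founders, n_hybrids = n_hybrids,
                                  mode = mode, testers_a = testers_a,
                                  testers_b = testers_b, seed = spec$seed)
  hybrids <- deduce_hybrids(founders, design)
  ph <- simulate_phenotypes(hybrids, arch)
  structure(list(founders = founders, design = design, hybrids = hybrids,
                 phenotypes = ph$phenotypes,
                 truth = list(architecture = arch,
                              components = ph$components)),
            class = "simulated_study")
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Emits the founder VCF, cross-design and phenotype tables (tab-separated)
#' and the ground-truth architecture (YAML), plus a manifest with MD5
#' checksums.  All files round-trip through the package readers.
#'
#' @param study A [simulate_study()] result.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_fixture <- function(study, directory) {
  stopifnot(inherits(study, "simulated_study"))
  ok <- dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  f_vcf <- file.path(directory, "founders.vcf")
  f_des <- file.path(directory, "design.tsv")
  f_phe <- file.path(directory, "phenotypes.tsv")
  f_tru <- file.path(directory, "truth.yml")
  write_vcf(study$founders, f_vcf)
  utils::write.table(study$design, f_des, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$phenotypes, f_phe, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_trait_architecture(study$truth$architecture, f_tru,
                           components = study$truth$components)
  files <- c(f_vcf, f_des, f_phe, f_tru)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a trait architecture to YAML
#'
#' @param arch A [trait_architecture()].
#' @param path Output file.
#' @param components Optional realized-components data frame stored alongside.
#' @export
write_trait_architecture <- function(arch, path, components = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  x <- list(heritability = arch$heritability,
            polygenic_share = arch$polygenic_share,
            seed = arch$seed,
            additive = lapply(seq_len(nrow(arch$additive)), function(i)
              list(marker = arch$additive$marker[i],
                   effect = arch$additive$effect[i])),
            dominance = lapply(seq_len(nrow(arch$dominance)), function(i)
              list(marker = arch$dominance$marker[i],
                   effect = arch$dominance$effect[i])),
            epistasis = lapply(seq_len(nrow(arch$epistasis)), function(i)
              list(marker_i = arch$epistasis$marker_i[i],
                   marker_j = arch$epistasis$marker_j[i],
                   type = arch$epistasis$type[i],
                   effect = arch$epistasis$effect[i])))
  if (!is.null(components))
    x$realized_components <- as.list(stats::setNames(components$variance,
                                                     components$component))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a trait architecture from YAML
#'
#' @param path File written by [write_trait_architecture()].
#' @return A [trait_architecture()].
#' @export
read_trait_architecture <- function(path) {
  x <- yaml::read_yaml(path)
  unroll <- function(lst, cols) {
    if (!length(lst)) return(NULL)
    do.call(rbind, lapply(lst, function(e) as.data.frame(e[cols])))
  }
  trait_architecture(
    additive = unroll(x$additive, c("marker", "effect")),
    dominance = unroll(x$dominance, c("marker", "effect")),
    epistasis = unroll(x$epistasis,
                       c("marker_i", "marker_j", "type", "effect")),
    heritability = x$heritability,
    polygenic_share = x$polygenic_share,
    seed = x$seed)
}
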