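#' Trait direction table
#'
#' Breeding-target convention: for some traits a lower phenotypic level is
#' favorable (grain moisture GM, ear height EH, tassel branch number TBN),
#' for the remaining standard maize traits a higher level is favorable.
#' Used to decide favorable genotypes per QTN; fully overridable.
#'
#' @param lower_better Character vector of trait names where lower is better.
#' @param higher_better Character vector of trait names where higher is
#'   better.
#' @return Named character vector trait -> direction.
#' @export
trait_directions <- function(lower_better = c("GM", "EH", "TBN"),
                             higher_better = c("GY", "PH", "ELL", "ELW",
                                               "ELA", "RPR_TIAG", "RPR_IUE")) {
  c(stats::setNames(rep("lower_better", length(lower_better)), lower_better),
    stats::setNames(rep("higher_better", length(higher_better)),
                    higher_better))
}

#' Per-genotype-class phenotype means
#'
#' Observed mean phenotype of each genotype class at each requested marker;
#' the usual input for deciding favorable genotypes.
#'
#' @param y Phenotype vector aligned with `hybrids`.
#' @param hybrids Hybrid [marker_matrix()].
#' @param markers Marker ids or indices.
#' @return Data frame `marker`, `class` (0/1/2), `mean`, `n`.
#' @export
genotype_class_means <- function(y, hybrids, markers) {
  stopifnot(inherits(hybrids, "marker_matrix"))
  idx <- resolve_qtn_index(markers, hybrids)
  y <- as.numeric(y)
  rows <- list()
  for (j in idx) {
    g <- hybrids$calls[, j]
    for (cl in sort(unique(g[!is.na(g)]))) {
      sel <- !is.na(g) & g == cl
      rows[[length(rows) + 1]] <- data.frame(
        marker = hybrids$map$marker[j], class = cl, mean = mean(y[sel]),
        n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Decide the favorable genotype of each QTN
#'
#' The favorable genotype class of a QTN is the class with the best
#' predicted phenotype in the trait's breeding direction: the highest class
#' mean for `higher_better` traits, the lowest for `lower_better`.  An
#' overdominant locus can therefore have the heterozygote as its favorable
#' class.
#'
#' @param class_means Data frame `marker`, `class`, `mean` as from
#'   [genotype_class_means()].
#' @param direction `"higher_better"` or `"lower_better"`, or a trait name
#'   to be looked up in `directions`.
#' @param directions Named direction table, default [trait_directions()].
#' @return Data frame of class `favorable_call`: `marker`,
#'   `favorable_class`, `direction`.
#' @export
favorable_genotypes <- function(class_means, direction,
                                directions = trait_directions()) {
  if (!direction %in% c("higher_better", "lower_better")) {
    if (!direction %in% names(directions))
      stop("no direction configured for trait '", direction, "'")
    direction <- directions[[direction]]
  }
  pick <- if (direction == "higher_better") which.max else which.min
  out <- do.call(rbind, lapply(split(class_means, class_means$marker),
                               function(d) {
    data.frame(marker = d$marker[1], favorable_class = d$class[pick(d$mean)],
               direction = direction, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("favorable_call", "data.frame")
  out
}

#' Count favorable genotypes per hybrid
#'
#' @param hybrids Hybrid [marker_matrix()].
#' @param favorable A [favorable_genotypes()] table.
#' @return Named integer vector: per hybrid, the number of QTNs at which it
#'   carries the favorable genotype class.
#' @export
favorable_counts <- function(hybrids, favorable) {
  stopifnot(inherits(hybrids, "marker_matrix"))
  idx <- resolve_qtn_index(favorable$marker, hybrids)
  cnt <- integer(nrow(hybrids$calls))
  for (r in seq_along(idx))
    cnt <- cnt + (hybrids$calls[, idx[r]] == favorable$favorable_class[r])
  stats::setNames(as.integer(cnt), hybrids$samples$id)
}

#' Favorable-genotype accumulation regression
#'
#' Ordinary linear regression of the phenotype on the per-hybrid count of
#' favorable genotypes; a significant slope in the trait's direction
#' validates the mapped QTNs.
#'
#' @param y Phenotype vector aligned with `hybrids`.
#' @param hybrids Hybrid [marker_matrix()].
#' @param favorable A [favorable_genotypes()] table.
#' @return A list of class `accumulation_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, and the per-hybrid `counts`.
#' @export
accumulation_regression <- function(y, hybrids, favorable) {
  counts <- favorable_counts(hybrids, favorable)
  y <- as.numeric(y)
  if (stats::var(counts) == 0)
    stop("degenerate regression: favorable-genotype counts have no variance")
  fit <- stats::lm(y ~ counts)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(y), counts = counts),
            class = "accumulation_fit")
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat("accumulation_fit: slope =", signif(x$slope, 4),
      " R^2 =", signif(x$r_squared, 3),
      " p =", signif(x$p_value, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Allele frequencies per heterotic group
#'
#' ALT-allele frequency of each requested marker within group A and group B
#' parents separately, plus global major/minor allele labels.
#'
#' @param parents Parental [marker_matrix()] with groups `"A"` and `"B"`.
#' @param markers Marker ids or indices (default all).
#' @return Data frame `marker`, `ref`, `alt`, `freq_alt_a`, `freq_alt_b`,
#'   `freq_alt_global`, `major_allele`, `minor_allele`.
#' @export
group_allele_frequencies <- function(parents, markers = NULL) {
  stopifnot(inherits(parents, "marker_matrix"))
  ia <- parents$samples$group == "A"
  ib <- parents$samples$group == "B"
  if (!any(ia)) stop("no genotyped group-A parents")
  if (!any(ib)) stop("no genotyped group-B parents")
  idx <- if (is.null(markers)) seq_len(ncol(parents$calls)) else
    resolve_qtn_index(markers, parents)
  freq <- function(g) {
    nobs <- sum(!is.na(g))
    if (nobs == 0) return(NA_real_)
    sum(g, na.rm = TRUE) / (2 * nobs)
  }
  fa <- apply(parents$calls[ia, idx, drop = FALSE], 2, freq)
  fb <- apply(parents$calls[ib, idx, drop = FALSE], 2, freq)
  fg <- apply(parents$calls[, idx, drop = FALSE], 2, freq)
  ref <- parents$map$ref[idx]; alt <- parents$map$alt[idx]
  major <- ifelse(fg <= 0.5, ref, alt)
  minor <- ifelse(fg <= 0.5, alt, ref)
  data.frame(marker = parents$map$marker[idx], ref = ref, alt = alt,
             freq_alt_a = unname(fa), freq_alt_b = unname(fb),
             freq_alt_global = unname(fg), major_allele = major,
             minor_allele = minor, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare favorable/heterozygote counts between phenotype tails
#'
#' Selects the top and bottom `fraction` of hybrids by phenotype and
#' compares their per-hybrid counts (favorable genotypes, heterozygotes,
#' ...) with a Wilcoxon rank-sum test.
#'
#' @param y Phenotype vector.
#' @param counts Per-hybrid count vector aligned with `y`.
#' @param fraction Tail fraction (default 0.10); must leave >= 3 hybrids per
#'   tail.
#' @return Data frame with group means, group sizes and the rank-sum
#'   p-value.
#' @export
top_bottom_enrichment <- function(y, counts, fraction = 0.10) {
  y <- as.numeric(y)
  n <- length(y)
  if (length(counts) != n) stop("counts must align with phenotypes")
  n_tail <- floor(fraction * n)
  if (n_tail < 3) stop("fraction leaves < 3 hybrids per tail")
  ord <- order(y)
  bot <- ord[seq_len(n_tail)]
  top <- ord[seq(n - n_tail + 1, n)]
  wt <- suppressWarnings(stats::wilcox.test(counts[top], counts[bot]))
  data.frame(group = c("TOP", "BOT"),
             n = c(length(top), length(bot)),
             mean_count = c(mean(counts[top]), mean(counts[bot])),
             p_value = wt$p.value, stringsAsFactors = FALSE)
}

## Achievable hybrid genotype classes at one marker given the homozygous
## parental genotype sets of each side.
achievable_classes <- function(ga, gb) {
  ga <- unique(ga[!is.na(ga) & ga != 1L])
  gb <- unique(gb[!is.na(gb) & gb != 1L])
  if (!length(ga) || !length(gb)) return(integer(0))
  unique(as.vector(outer(ga, gb, function(a, b) (a + b) %/% 2L)))
}

#' Count one-genotype-missing-sites (OGMS)
#'
#' A marker is an OGMS when the hybrid population can only contain one
#' homozygote class plus the heterozygote, which confounds additive and
#' dominance effects at that locus.  By default the achievable genotype
#' classes are enumerated from the parental tester genotypes (every A x B
#' tester pair); with a `design`, only the realized crossing pairs are
#' enumerated.  Heterozygous or missing parental calls are excluded from
#' the enumeration (parents are inbred).
#'
#' @param parents Parental [marker_matrix()].
#' @param testers_a,testers_b Tester line ids (required unless `design`
#'   given).
#' @param design Optional [cross_design()]; overrides the tester sets with
#'   the realized pairs.
#' @return A list of class `ogms_count`: `total` and logical per-marker
#'   `flags`.
#' @export
count_ogms <- function(parents, testers_a = NULL, testers_b = NULL,
                       design = NULL) {
  stopifnot(inherits(parents, "marker_matrix"))
  m <- ncol(parents$calls)
  flags <- logical(m)
  if (is.null(design)) {
    if (is.null(testers_a) || is.null(testers_b) ||
        !length(testers_a) || !length(testers_b))
      stop("empty tester set")
    ga_rows <- match(testers_a, parents$samples$id)
    gb_rows <- match(testers_b, parents$samples$id)
    if (anyNA(ga_rows) || anyNA(gb_rows)) stop("unknown tester id(s)")
    for (j in seq_len(m)) {
      cls <- achievable_classes(parents$calls[ga_rows, j],
                                parents$calls[gb_rows, j])
      flags[j] <- length(cls) == 2 && 1L %in% cls
    }
  } else {
    pa <- match(design$parent_a, parents$samples$id)
    pb <- match(design$parent_b, parents$samples$id)
    if (anyNA(pa) || anyNA(pb)) stop("design parent id(s) not in parents")
    calls <- parents$calls
    calls[calls == 1L] <- NA_integer_
    for (j in seq_len(m)) {
      hyb <- (calls[pa, j] + calls[pb, j]) %/% 2L
      cls <- unique(hyb[!is.na(hyb)])
      flags[j] <- length(cls) == 2 && 1L %in% cls
    }
  }
  structure(list(total = sum(flags),
                 flags = stats::setNames(flags, parents$map$marker)),
            class = "ogms_count")
}

#' Percent change of an OGMS count against a baseline
#'
#' `100 * (baseline - value) / baseline`: the percent decrease of the OGMS
#' burden of a mating strategy relative to the current strategy.
#'
#' @param baseline Baseline OGMS count.
#' @param value Strategy OGMS count (e.g. the median over resamples).
#' @return Percent decrease (positive = fewer OGMS than baseline).
#' @export
ogms_percent_change <- function(baseline, value) {
  if (baseline <= 0) stop("baseline OGMS count must be positive")
  100 * (baseline - value) / baseline
}

#' Compare core-tester mating strategies by OGMS burden
#'
#' Baseline: the given tester sets, fully crossed.  A strategy with
#' multiplier k draws k times as many tester lines per group from the
#' available parents but realizes only a constant hybrid budget by randomly
#' pairing subsets, so the field cost stays fixed while each locus sees more
#' parental diversity.  Per resample the multiplied tester sets are drawn,
#' a hybrid set of the budget size is sampled uniformly from their crossing
#' grid, and the OGMS count of the realized pairs is taken; the report
#' carries the per-resample distribution, the median, and the percent
#' decrease against baseline.
#'
#' @param parents Parental [marker_matrix()] with groups `"A"` and `"B"`.
#' @param testers_a,testers_b Baseline core tester ids.
#' @param multipliers Integer multipliers to evaluate (default `c(2, 3)`;
#'   a multiplier of 1 reproduces the baseline exactly).
#' @param n_resamples Resamples per strategy (default 50).
#' @param n_hybrids Constant hybrid budget (default 442, a typical breeder
#'   hybrid population; the number of distinct realized pairs is capped at
#'   the crossing-grid size, extra budget being replicate crosses that add
#'   no new genotype classes).  A budget below the multiplied grid sizes
#'   thins the realized pairs and can lose genotype classes.
#' @param seed Integer seed.
#' @return A list of class `ogms_report`: `baseline` count, `strategies`
#'   (data frame: multiplier, median OGMS, percent decrease) and `resamples`
#'   (long data frame for plotting).
#' @export
compare_mating_strategies <- function(parents, testers_a, testers_b,
                                      multipliers = c(2, 3),
                                      n_resamples = 50, n_hybrids = NULL,
                                      seed = 1) {
  stopifnot(inherits(parents, "marker_matrix"))
  ids_a <- parents$samples$id[parents$samples$group == "A"]
  ids_b <- parents$samples$id[parents$samples$group == "B"]
  nA <- length(testers_a); nB <- length(testers_b)
  budget <- if (is.null(n_hybrids)) 442 else n_hybrids
  baseline <- count_ogms(parents, testers_a, testers_b)$total
  set.seed(seed)
  strat_rows <- list(); res_rows <- list()
  for (k in multipliers) {
    if (k == 1) {
      med <- baseline
      counts <- rep(baseline, n_resamples)
    } else {
      if (k * nA > length(ids_a) || k * nB > length(ids_b))
        stop("not enough distinct parents for multiplier ", k)
      counts <- integer(n_resamples)
      for (r in seq_len(n_resamples)) {
        ta <- sample(ids_a, k * nA)
        tb <- sample(ids_b, k * nB)
        grid <- expand.grid(parent_a = ta, parent_b = tb,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        take <- sample.int(nrow(grid), min(budget, nrow(grid)))
        d <- cross_design(sprintf("H%05d", seq_along(take)),
                          grid$parent_a[take], grid$parent_b[take])
        counts[r] <- count_ogms(parents, design = d)$total
      }
      med <- stats::median(counts)
    }
    strat_rows[[length(strat_rows) + 1]] <- data.frame(
      multiplier = k, median_ogms = med,
      pct_decrease = ogms_percent_change(baseline, med))
    res_rows[[length(res_rows) + 1]] <- data.frame(
      multiplier = k, resample = seq_len(n_resamples), ogms = counts)
  }
  structure(list(baseline = baseline,
                 strategies = do.call(rbind, strat_rows),
                 resamples = do.call(rbind, res_rows)),
            class = "ogms_report")
}

#' @export
print.ogms_report <- function(x, ...) {
  cat("ogms_report: baseline =", x$baseline, "\n")
  print(x$strategies)
  invisible(x)
}

#' Restrict a cross design to named tester lines
#'
#' Keeps hybrids whose parents are both in the named tester sets; used for
#' close/far tester-subset re-scans.
#'
#' @param design A [cross_design()].
#' @param testers_a,testers_b Tester ids.
#' @return The filtered `cross_design` (zero rows with a warning when the
#'   subset is empty).
#' @export
subset_by_testers <- function(design, testers_a, testers_b) {
  keep <- design$parent_a %in% testers_a & design$parent_b %in% testers_b
  out <- design[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("tester subset matches no hybrids")
  class(out) <- c("cross_design", "data.frame")
  out
}
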