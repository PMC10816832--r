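#' Marker matrix container
#'
#' The central genotype container of the package: a samples-by-markers matrix
#' of biallelic calls coded as the count of ALT alleles (0 = homozygous REF,
#' 1 = heterozygous, 2 = homozygous ALT, `NA` = missing), together with a
#' marker map (chromosome, 1-based position, REF/ALT alleles) and a sample
#' table carrying the heterotic-group label of each line.
#'
#' @param calls Integer matrix, samples in rows and markers in columns.
#'   Row names are sample ids, column names marker ids.
#' @param map Data frame with columns `marker`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per column of `calls`, in column order.  Positions must be
#'   strictly increasing within a chromosome.
#' @param samples Data frame with columns `id` and `group`
#'   (one of `"A"`, `"B"`, `"hybrid"`, `"none"`), one row per row of `calls`.
#'
#' @return An object of class `marker_matrix` with elements `calls`, `map`
#'   and `samples`.
#' @export
marker_matrix <- function(calls, map, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_)))
    stop("calls must be 0, 1, 2 or NA")
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  need_map <- c("marker", "chrom", "pos", "ref", "alt")
  if (!all(need_map %in% names(map)))
    stop("map must have columns: ", paste(need_map, collapse = ", "))
  if (!all(c("id", "group") %in% names(samples)))
    stop("samples must have columns id, group")
  if (nrow(map) != ncol(calls))
    stop("map rows (", nrow(map), ") != marker columns (", ncol(calls), ")")
  if (nrow(samples) != nrow(calls))
    stop("sample rows (", nrow(samples), ") != call rows (", nrow(calls), ")")
  if (anyDuplicated(samples$id))
    stop("sample ids must be unique")
  if (anyDuplicated(map$marker))
    stop("marker ids must be unique")
  bad_group <- setdiff(unique(samples$group), c("A", "B", "hybrid", "none"))
  if (length(bad_group))
    stop("unknown sample group(s): ", paste(bad_group, collapse = ", "))
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  rownames(calls) <- samples$id
  colnames(calls) <- map$marker
  structure(list(calls = calls, map = map, samples = samples),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  grp <- table(x$samples$group)
  cat("marker_matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " markers\n", sep = "")
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = " "), "\n")
  cat("  chromosomes:", length(unique(x$map$chrom)),
      " missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$calls)

#' Subset a marker matrix
#'
#' @param m A [marker_matrix()].
#' @param samples Optional sample ids or logical/integer index over rows.
#' @param markers Optional marker ids or logical/integer index over columns.
#' @return A `marker_matrix` restricted to the requested rows/columns.
#' @export
mm_subset <- function(m, samples = NULL, markers = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  ri <- seq_len(nrow(m$calls))
  ci <- seq_len(ncol(m$calls))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, m$samples$id) else ri[samples]
    if (anyNA(ri)) stop("unknown sample id(s)")
  }
  if (!is.null(markers)) {
    ci <- if (is.character(markers)) match(markers, m$map$marker) else ci[markers]
    if (anyNA(ci)) stop("unknown marker id(s)")
  }
  marker_matrix(m$calls[ri, ci, drop = FALSE],
                m$map[ci, , drop = FALSE],
                m$samples[ri, , drop = FALSE])
}

#' Assign heterotic-group labels to samples
#'
#' @param m A [marker_matrix()].
#' @param groups Either a named character vector (`id -> group`) or a single
#'   function mapping sample ids to group labels.
#' @return The marker matrix with updated `samples$group`.
#' @export
set_sample_groups <- function(m, groups) {
  stopifnot(inherits(m, "marker_matrix"))
  g <- if (is.function(groups)) groups(m$samples$id) else groups[m$samples$id]
  g[is.na(g)] <- "none"
  m$samples$group <- unname(g)
  marker_matrix(m$calls, m$map, m$samples)
}

#' Cross design table
#'
#' Validates a hybrid pedigree: each row links one hybrid to its group-A
#' (female) and group-B (male) parent.
#'
#' @param hybrid,parent_a,parent_b Character vectors of equal length.
#' @param parents Optional parental [marker_matrix()]; when supplied, parent
#'   ids must resolve in it and carry the matching group label.
#' @return A data frame of class `cross_design`.
#' @export
cross_design <- function(hybrid, parent_a, parent_b, parents = NULL) {
  d <- data.frame(hybrid = as.character(hybrid),
                  parent_a = as.character(parent_a),
                  parent_b = as.character(parent_b),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$hybrid)) stop("hybrid ids must be unique")
  if (!is.null(parents)) {
    stopifnot(inherits(parents, "marker_matrix"))
    ids <- parents$samples$id
    bad <- setdiff(unique(c(d$parent_a, d$parent_b)), ids)
    if (length(bad))
      stop("parent id(s) not in parental matrix: ", paste(bad, collapse = ", "))
    grp <- stats::setNames(parents$samples$group, ids)
    if (any(grp[d$parent_a] != "A"))
      stop("parent_a entries must be group-A lines")
    if (any(grp[d$parent_b] != "B"))
      stop("parent_b entries must be group-B lines")
  }
  class(d) <- c("cross_design", "data.frame")
  d
}
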