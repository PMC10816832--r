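#' Additive design coding
#'
#' Codes each marker as -1 for the homozygous REF genotype, 0 for the
#' heterozygote and +1 for the homozygous ALT genotype.
#'
#' @param m A [marker_matrix()] with no missing calls (impute first).
#' @param center Subtract column means (off by default; the raw -1/0/1
#'   coding is the package convention).
#' @return Numeric matrix Z, samples x markers.
#' @export
additive_coding <- function(m, center = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$calls)) stop("missing calls present; impute before coding")
  Z <- m$calls - 1
  storage.mode(Z) <- "double"
  if (center) Z <- scale(Z, center = TRUE, scale = FALSE)[, , drop = FALSE]
  Z
}

#' Dominance design coding
#'
#' Codes each marker as 1 for the heterozygote and 0 for either homozygote.
#'
#' @inheritParams additive_coding
#' @return Numeric matrix W, samples x markers.
#' @export
dominance_coding <- function(m, center = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$calls)) stop("missing calls present; impute before coding")
  W <- (m$calls == 1) * 1
  storage.mode(W) <- "double"
  if (center) W <- scale(W, center = TRUE, scale = FALSE)[, , drop = FALSE]
  W
}

#' Epistatic interaction column
#'
#' The epistatic design column of a locus pair is the element-wise (direct)
#' product of the two main-effect columns chosen by the interaction type:
#' the additive coding Z for an "a" and the dominance coding W for a "d" at
#' each position of the type label.
#'
#' @param col_i,col_j Coded main-effect columns (Z or W as appropriate for
#'   `type`) of equal length.
#' @param type Interaction type, one of `"aa"`, `"ad"`, `"da"`, `"dd"`;
#'   attached to the result as an attribute.
#' @return Numeric vector `col_i * col_j` with attribute `type`.
#' @export
epistatic_column <- function(col_i, col_j, type = c("aa", "ad", "da", "dd")) {
  type <- match.arg(type)
  if (length(col_i) != length(col_j))
    stop("column length mismatch: ", length(col_i), " vs ", length(col_j))
  out <- as.numeric(col_i) * as.numeric(col_j)
  attr(out, "type") <- type
  out
}

#' Epistatic design column from genotype calls
#'
#' Convenience wrapper building the typed interaction column of two markers
#' directly from a marker matrix.
#'
#' @param m A [marker_matrix()] with no missing calls.
#' @param i,j Marker ids or indices.
#' @param type Interaction type (`"aa"`, `"ad"`, `"da"`, `"dd"`).
#' @return Numeric vector as in [epistatic_column()].
#' @export
epistatic_design <- function(m, i, j, type = c("aa", "ad", "da", "dd")) {
  type <- match.arg(type)
  ii <- resolve_qtn_index(i, m)
  jj <- resolve_qtn_index(j, m)
  ty <- strsplit(type, "")[[1]]
  g <- m$calls
  ci <- if (ty[1] == "a") g[, ii] - 1 else (g[, ii] == 1) * 1
  cj <- if (ty[2] == "a") g[, jj] - 1 else (g[, jj] == 1) * 1
  epistatic_column(ci, cj, type)
}

#' Build the six genomic kinship matrices
#'
#' The additive kinship is Ka = ZZ'/c and the dominance kinship
#' Kd = WW'/c', each scaled so the mean diagonal equals 1 (putting the
#' associated variance components on the phenotype scale).  The four
#' epistatic kinships are Hadamard (element-wise) products of the normalized
#' main kinships -- Kaa = Ka*Ka, Kad = Ka*Kd, Kda = Kd*Ka, Kdd = Kd*Kd --
#' each re-scaled to mean diagonal 1.  This is the standard genome-scale
#' construction for epistatic covariance and keeps every matrix symmetric
#' positive semi-definite.  On a panel with no heterozygotes (inbred lines)
#' the dominance-containing matrices are degenerate; they are returned as
#' zero matrices and flagged.
#'
#' @param m A [marker_matrix()] with no missing calls and at least two
#'   polymorphic markers.
#' @param center Use column-centered codings (default `FALSE`, the raw
#'   literal coding).
#' @return A list of class `kinship_set` with matrices `Ka`, `Kd`, `Kaa`,
#'   `Kad`, `Kda`, `Kdd`, normalization constants `scales`, and a logical
#'   `degenerate` flag per matrix.
#' @export
build_kinships <- function(m, center = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$calls)) stop("missing calls present; impute before kinships")
  if (nrow(unique(m$calls)) == 1)
    stop("degenerate kinship: all samples genotypically identical")
  poly <- apply(m$calls, 2, function(g) length(unique(g)) > 1)
  if (sum(poly) < 2) stop("need >= 2 polymorphic markers")
  Z <- additive_coding(m, center = center)
  W <- dominance_coding(m, center = center)
  ids <- m$samples$id
  normalize <- function(K) {
    md <- mean(diag(K))
    if (md <= .Machine$double.eps) return(list(K = K * 0, scale = NA_real_,
                                               degenerate = TRUE))
    list(K = K / md, scale = md, degenerate = FALSE)
  }
  ka <- normalize(tcrossprod(Z))
  kd <- normalize(tcrossprod(W))
  had <- function(a, b) {
    if (a$degenerate || b$degenerate)
      return(list(K = a$K * 0, scale = NA_real_, degenerate = TRUE))
    normalize(a$K * b$K)
  }
  kaa <- had(ka, ka); kad <- had(ka, kd); kda <- had(kd, ka); kdd <- had(kd, kd)
  out <- list(Ka = ka$K, Kd = kd$K, Kaa = kaa$K, Kad = kad$K, Kda = kda$K,
              Kdd = kdd$K)
  out <- lapply(out, function(K) { dimnames(K) <- list(ids, ids); K })
  structure(c(out,
              list(scales = c(Ka = ka$scale, Kd = kd$scale, Kaa = kaa$scale,
                              Kad = kad$scale, Kda = kda$scale,
                              Kdd = kdd$scale),
                   degenerate = c(Ka = ka$degenerate, Kd = kd$degenerate,
                                  Kaa = kaa$degenerate, Kad = kad$degenerate,
                                  Kda = kda$degenerate,
                                  Kdd = kdd$degenerate))),
            class = "kinship_set")
}

#' @export
print.kinship_set <- function(x, ...) {
  n <- nrow(x$Ka)
  cat("kinship_set:", n, "x", n, "\n")
  cat("  degenerate:", paste(names(which(x$degenerate)), collapse = " "),
      "\n")
  invisible(x)
}

#' Subset a kinship set to a set of samples
#'
#' @param K A [build_kinships()] result.
#' @param idx Sample indices or ids (rows = columns).
#' @param idx2 Optional second index set; when given, returns rectangular
#'   cross-blocks `K[idx, idx2]` (used for mixed-model prediction).
#' @return A `kinship_set` (square case) or plain list of matrices.
#' @export
subset_kinships <- function(K, idx, idx2 = NULL) {
  stopifnot(inherits(K, "kinship_set"))
  mats <- c("Ka", "Kd", "Kaa", "Kad", "Kda", "Kdd")
  if (is.null(idx2)) {
    out <- lapply(K[mats], function(M) M[idx, idx, drop = FALSE])
    structure(c(out, list(scales = K$scales, degenerate = K$degenerate)),
              class = "kinship_set")
  } else {
    lapply(K[mats], function(M) M[idx, idx2, drop = FALSE])
  }
}

#' Write / read a kinship matrix as TSV
#'
#' Square tab-separated matrix with sample ids as header row and first
#' column.
#'
#' @param K A symmetric matrix with dimnames.
#' @param path File path.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(id = rownames(K), K, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  K <- as.matrix(df[, -1, drop = FALSE])
  rownames(K) <- df[[1]]
  K
}
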