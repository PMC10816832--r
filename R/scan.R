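#' Effective number of independent markers
#'
#' Computes the effective marker count Me used for Bonferroni correction:
#' the smallest number of principal components of the marker correlation
#' structure whose cumulative eigenvalue share reaches `variance_fraction`.
#' Monomorphic markers carry no information and are dropped first.  When the
#' panel has more markers than samples the spectrum is computed from the
#' (samples x samples) Gram matrix, which has the same non-zero eigenvalues.
#'
#' @param m A [marker_matrix()] with no missing calls.
#' @param variance_fraction Cumulative variance target in (0, 1];
#'   1 returns the rank of the marker matrix.
#' @return Integer Me.
#' @export
effective_marker_number <- function(m, variance_fraction = 0.995) {
  stopifnot(inherits(m, "marker_matrix"))
  if (!(is.numeric(variance_fraction) && variance_fraction > 0 &&
        variance_fraction <= 1))
    stop("variance_fraction must be in (0, 1]")
  if (anyNA(m$calls)) stop("missing calls present; impute first")
  if (nrow(m$calls) < 2) stop("need >= 2 samples")
  X <- m$calls
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (ncol(X) == 0) stop("no polymorphic markers")
  Xs <- scale(X)
  n <- nrow(Xs)
  G <- if (ncol(Xs) <= n) crossprod(Xs) / (n - 1) else tcrossprod(Xs) / (n - 1)
  lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  total <- sum(lam)
  rank <- sum(lam > max(lam) * 1e-9)
  if (variance_fraction == 1) return(as.integer(rank))
  cum <- cumsum(lam) / total
  as.integer(which(cum >= variance_fraction - 1e-12)[1])
}

#' Genome-wide significance threshold on the -log10 scale
#'
#' Bonferroni threshold based on the effective marker number Me:
#' `-log10(alpha / Me)` for single-marker (main-effect) tests and
#' `-log10(alpha / (Me * (Me - 1) / 2))` for pairwise epistasis tests.
#' The returned value is unrounded; report it rounded to 2 decimals.
#'
#' @param Me Effective marker count (>= 2 for pairwise tests).
#' @param alpha Genome-wide significance level.
#' @param test `"main"` or `"pairwise"`.
#' @return The -log10 p-value threshold.
#' @export
significance_threshold <- function(Me, alpha, test = c("main", "pairwise")) {
  test <- match.arg(test)
  if (!(is.numeric(alpha) && alpha > 0 && alpha < 1))
    stop("alpha must be in (0,1)")
  if (!(is.numeric(Me) && Me >= 1)) stop("Me must be a positive count")
  if (test == "pairwise" && Me < 2)
    stop("pairwise threshold needs Me >= 2")
  n_tests <- if (test == "main") Me else Me * (Me - 1) / 2
  -log10(alpha / n_tests)
}

## Restricted log-likelihood and projection pieces at a given set of variance
## components.  Ks: list of kinship matrices (residual identity excluded).
reml_pieces <- function(theta, Ks, y, X) {
  n <- length(y)
  q <- length(Ks)
  V <- diag(theta[q + 1], n)
  for (k in seq_len(q)) V <- V + theta[k] * Ks[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  P <- Vinv - VinvX %*% solve(XtVX, t(VinvX))
  Py <- as.vector(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) +
                  as.numeric(determinant(XtVX)$modulus) +
                  sum(y * Py))
  list(ll = ll, P = P, Py = Py, V = V)
}

#' Fit the null (no-marker) mixed model by REML
#'
#' Estimates the variance components of the polygenic background model:
#' `KinA` fits an additive kinship plus residual; `KinADE` fits all six
#' kinship backgrounds (additive, dominance, and the four epistatic
#' Hadamard kinships) plus residual.  Components are estimated by
#' average-information REML with a few multiplicative EM warm-up steps,
#' step-halving, and non-negativity enforced by a small floor.  Degenerate
#' kinships (e.g. dominance terms on an all-inbred panel) are dropped and
#' reported as zero.
#'
#' @param y Phenotype vector aligned to the kinship sample order (n >= 10).
#' @param K A [build_kinships()] result.
#' @param model `"KinA"` or `"KinADE"`.
#' @param max_iter Maximum AI iterations.
#' @param tol Convergence tolerance on the restricted log-likelihood.
#' @return An object of class `null_fit`: `model`, `sigma2` (named vector
#'   incl. residual `e`), `loglik`, `converged`, `n_iter`, and the fitted
#'   covariance matrix `V`.
#' @export
fit_null_reml <- function(y, K, model = c("KinA", "KinADE"),
                          max_iter = 100, tol = 1e-6) {
  model <- match.arg(model)
  stopifnot(inherits(K, "kinship_set"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("need n >= 10 for REML")
  if (nrow(K$Ka) != n) stop("phenotype length does not match kinship order")
  comp_names <- if (model == "KinA") "a" else c("a", "d", "aa", "ad", "da", "dd")
  mat_names <- c(a = "Ka", d = "Kd", aa = "Kaa", ad = "Kad", da = "Kda",
                 dd = "Kdd")
  usable <- comp_names[!K$degenerate[mat_names[comp_names]]]
  Ks <- lapply(mat_names[usable], function(nm) K[[nm]])
  names(Ks) <- usable
  q <- length(Ks)
  if (q == 0) stop("all requested kinship components are degenerate")
  if (max(abs(K$Ka - diag(n))) < 1e-8)
    warning("degenerate model: additive kinship equals the identity; ",
            "polygenic and residual variances are not separately identifiable")
  X <- matrix(1, n, 1)
  vy <- stats::var(y)
  if (vy == 0) stop("phenotype has zero variance")
  floor_v <- 1e-8 * vy
  theta <- rep(vy / (q + 1), q + 1)
  names(theta) <- c(names(Ks), "e")

  pc <- reml_pieces(theta, Ks, y, X)
  ## multiplicative EM-style warm-up: stable but slow
  for (it in 1:3) {
    upd <- theta
    for (k in seq_len(q)) {
      u <- as.vector(Ks[[k]] %*% pc$Py)
      num <- sum(pc$Py * u); den <- sum(pc$P * Ks[[k]])
      if (den > 0 && num > 0) upd[k] <- max(theta[k] * num / den, floor_v)
    }
    num <- sum(pc$Py^2); den <- sum(diag(pc$P))
    if (den > 0 && num > 0) upd[q + 1] <- max(theta[q + 1] * num / den, floor_v)
    pc2 <- reml_pieces(upd, Ks, y, X)
    if (pc2$ll > pc$ll) { theta <- upd; pc <- pc2 }
  }

  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    ## score and average-information matrix over all q+1 components
    U <- matrix(0, n, q + 1)
    score <- numeric(q + 1)
    for (k in seq_len(q)) {
      U[, k] <- as.vector(Ks[[k]] %*% pc$Py)
      score[k] <- -0.5 * (sum(pc$P * Ks[[k]]) - sum(pc$Py * U[, k]))
    }
    U[, q + 1] <- pc$Py
    score[q + 1] <- -0.5 * (sum(diag(pc$P)) - sum(pc$Py^2))
    AI <- 0.5 * crossprod(U, pc$P %*% U)
    delta <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI)), q + 1), score),
                      error = function(e) score * 0)
    step <- 1
    accepted <- FALSE
    for (h in 1:20) {
      prop <- pmax(theta + step * delta, floor_v)
      pc2 <- reml_pieces(prop, Ks, y, X)
      if (pc2$ll >= pc$ll - 1e-10) {
        if (abs(pc2$ll - pc$ll) < tol) converged <- TRUE
        theta <- prop; pc <- pc2; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }  # no uphill step left
    if (converged) break
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations (model ",
            model, ")")
  sigma2 <- stats::setNames(numeric(length(comp_names) + 1),
                            c(comp_names, "e"))
  sigma2[names(theta)] <- theta
  sigma2[sigma2 <= 2 * floor_v] <- pmax(sigma2[sigma2 <= 2 * floor_v], 0)
  structure(list(model = model, sigma2 = sigma2, loglik = pc$ll,
                 converged = converged, n_iter = n_iter, V = pc$V,
                 components_used = names(Ks), n = n),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat("null_fit (", x$model, "), n = ", x$n, ", REML logLik = ",
      round(x$loglik, 3), if (!x$converged) "  [NOT CONVERGED]", "\n",
      sep = "")
  print(round(x$sigma2, 5))
  invisible(x)
}

## Construct a null_fit with a user-supplied covariance (used for oracle
## comparisons and for running scans without a fitted background).
#' Null model with a fixed covariance matrix
#'
#' Builds a `null_fit` whose covariance is `sigma2 * I` (or any supplied
#' matrix) without REML estimation; the scans then reduce to ordinary
#' generalized least squares with that fixed covariance.
#'
#' @param y Phenotype vector (used for its length and, by default, its
#'   variance).
#' @param V Optional covariance matrix; default `var(y) * I`.
#' @return A `null_fit` object.
#' @export
null_fit_fixed <- function(y, V = NULL) {
  n <- length(y)
  if (is.null(V)) V <- diag(stats::var(y), n)
  structure(list(model = "fixed", sigma2 = c(e = mean(diag(V))),
                 loglik = NA_real_, converged = TRUE, n_iter = 0L, V = V,
                 components_used = character(), n = n),
            class = "null_fit")
}

## GLS helper on pre-whitened data: rank-aware least squares with t-tests.
## Returns coef, se, logp (base-10), df; NA entries for aliased columns.
tfit <- function(X, y) {
  qx <- qr(X)
  r <- qx$rank
  p <- ncol(X)
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- length(y) - r
  se <- rep(NA_real_, p)
  logp <- rep(NA_real_, p)
  if (df > 0 && r > 0) {
    s2 <- sum(res^2) / df
    piv <- qx$pivot[seq_len(r)]
    R <- qr.R(qx)[seq_len(r), seq_len(r), drop = FALSE]
    xx <- chol2inv(R)
    se[piv] <- sqrt(pmax(diag(xx), 0) * s2)
    tt <- coef / se
    logp <- -stats::pt(abs(tt), df, lower.tail = FALSE, log.p = TRUE) / log(10)
    logp <- logp - log10(2)  # two-sided
  }
  list(coef = coef, se = se, logp = logp, df = df)
}

#' Scan single-marker additive and dominance effects
#'
#' P3D-style mixed-model scan: the background covariance V is taken from the
#' null fit and held fixed (up to a per-marker residual scale re-estimated
#' from the generalized-least-squares residuals, so each marker test is an
#' exact t-test with n - p degrees of freedom).  Markers with all three
#' genotype classes are fitted with the additive (Z) and dominance (W)
#' columns jointly; markers with only two observed classes get a single
#' confounded column and the `Add/Dom` mode label; monomorphic markers are
#' skipped and logged.
#'
#' @param y Phenotype vector aligned with `hybrids` sample order.
#' @param hybrids Hybrid [marker_matrix()] with no missing calls.
#' @param null A `null_fit` from [fit_null_reml()] (or [null_fit_fixed()]).
#' @param threshold Optional -log10 significance threshold; when given, mode
#'   labels are assigned via [classify_mode()].
#' @return A data frame of class `scan_result`: per marker the genotype
#'   class counts, estimates `a_hat`/`d_hat`, `-log10` p-values per testable
#'   term, the maximal `logp`, PVE (%), and mode/reason labels.  Skipped
#'   (monomorphic) marker ids are in `attr(x, "skipped")`.
#' @export
scan_main_effects <- function(y, hybrids, null, threshold = NULL) {
  stopifnot(inherits(hybrids, "marker_matrix"), inherits(null, "null_fit"))
  if (anyNA(hybrids$calls)) stop("missing hybrid calls; impute parents first")
  y <- as.numeric(y)
  n <- length(y)
  if (n != nrow(hybrids$calls)) stop("phenotype / genotype length mismatch")
  if (!null$converged)
    warning("null fit had not converged; scan uses its components anyway")
  vary <- stats::var(y)
  if (vary == 0) stop("phenotype has zero variance")
  Z <- hybrids$calls - 1
  W <- (hybrids$calls == 1) * 1
  Lt <- t(chol(null$V))
  ty <- forwardsolve(Lt, y)
  t1 <- forwardsolve(Lt, rep(1, n))
  TZ <- forwardsolve(Lt, Z)
  TW <- forwardsolve(Lt, W)

  m <- ncol(hybrids$calls)
  out <- data.frame(marker = hybrids$map$marker, chrom = hybrids$map$chrom,
                    pos = hybrids$map$pos,
                    n0 = colSums(hybrids$calls == 0L),
                    n1 = colSums(hybrids$calls == 1L),
                    n2 = colSums(hybrids$calls == 2L),
                    classes = NA_integer_, a_hat = NA_real_, d_hat = NA_real_,
                    effect = NA_real_, logp_add = NA_real_,
                    logp_dom = NA_real_, logp = NA_real_, pve = NA_real_,
                    mode = NA_character_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  skipped <- character(0)
  for (j in seq_len(m)) {
    cls <- (out$n0[j] > 0) + (out$n1[j] > 0) + (out$n2[j] > 0)
    out$classes[j] <- cls
    if (cls <= 1) { skipped <- c(skipped, out$marker[j]); next }
    if (cls == 3) {
      fit <- tfit(cbind(t1, TZ[, j], TW[, j]), ty)
      if (!anyNA(fit$coef)) {
        out$a_hat[j] <- fit$coef[2]; out$d_hat[j] <- fit$coef[3]
        out$logp_add[j] <- fit$logp[2]; out$logp_dom[j] <- fit$logp[3]
        out$logp[j] <- max(fit$logp[2:3])
        g <- Z[, j] * fit$coef[2] + W[, j] * fit$coef[3]
        out$pve[j] <- 100 * stats::var(g) / vary
        next
      }
    }
    ## two observed classes (or numerically confounded): single column
    fit <- tfit(cbind(t1, TZ[, j]), ty)
    out$effect[j] <- fit$coef[2]
    out$logp[j] <- fit$logp[2]
    out$pve[j] <- 100 * stats::var(Z[, j] * fit$coef[2]) / vary
    out$classes[j] <- 2L
  }
  if (length(skipped))
    message(length(skipped), " monomorphic marker(s) skipped")
  class(out) <- c("scan_result", "data.frame")
  attr(out, "skipped") <- skipped
  if (!is.null(threshold)) out <- classify_mode(out, threshold)
  out
}

#' Assign Add / Dom / Add-Dom mode labels
#'
#' Markers with only two observed genotype classes are labelled `Add/Dom`
#' (one homozygote is absent in the F1 population, so additive and dominance
#' effects cannot be separated).  For three-class markers the label is `Add`
#' if only the additive term passes the threshold, `Dom` if only the
#' dominance term does, `Add/Dom` if both do, and `NS` otherwise; the
#' `reason` column distinguishes the confounded case from the
#' both-significant case.  The reported `effect` is the estimate of the
#' significant term (the more significant one when both pass).
#'
#' @param result A `scan_result` from [scan_main_effects()].
#' @param threshold -log10 significance threshold for the main-effect tests.
#' @return The `scan_result` with `mode`, `reason` and `effect` filled in.
#' @export
classify_mode <- function(result, threshold) {
  stopifnot(inherits(result, "scan_result"))
  for (j in seq_len(nrow(result))) {
    if (is.na(result$classes[j]) || result$classes[j] <= 1) next
    if (result$classes[j] == 2) {
      result$mode[j] <- "Add/Dom"
      result$reason[j] <- "one_homozygote_missing"
      next
    }
    sa <- !is.na(result$logp_add[j]) && result$logp_add[j] >= threshold
    sd <- !is.na(result$logp_dom[j]) && result$logp_dom[j] >= threshold
    if (sa && sd) {
      result$mode[j] <- "Add/Dom"; result$reason[j] <- "both_significant"
      result$effect[j] <- if (result$logp_add[j] >= result$logp_dom[j])
        result$a_hat[j] else result$d_hat[j]
    } else if (sa) {
      result$mode[j] <- "Add"; result$reason[j] <- "additive_only"
      result$effect[j] <- result$a_hat[j]
    } else if (sd) {
      result$mode[j] <- "Dom"; result$reason[j] <- "dominance_only"
      result$effect[j] <- result$d_hat[j]
    } else {
      result$mode[j] <- "NS"; result$reason[j] <- "not_significant"
      result$effect[j] <- if (!is.na(result$logp_add[j]) &&
                              (is.na(result$logp_dom[j]) ||
                               result$logp_add[j] >= result$logp_dom[j]))
        result$a_hat[j] else result$d_hat[j]
    }
  }
  result
}

#' Scan pairwise epistatic effects
#'
#' For every unordered pair of candidate markers and every requested
#' interaction type, fits the two loci's estimable main-effect columns plus
#' the typed interaction column against the fixed background covariance
#' (P3D) and tests the interaction term.  Interaction columns that are
#' constant or collinear with the main effects are skipped as inestimable
#' and logged.
#'
#' @param y Phenotype vector.
#' @param hybrids Hybrid [marker_matrix()] with no missing calls.
#' @param null A `null_fit`.
#' @param candidates Marker ids or indices (>= 2).
#' @param types Subset of `c("aa","ad","da","dd")`.
#' @return A data frame of class `epistasis_result`: `marker_i`, `marker_j`
#'   (i before j in map order), `type`, `alpha_hat`, `logp`, `pve`.
#'   Skipped combinations are recorded in `attr(x, "skipped")`.
#' @export
scan_epistasis <- function(y, hybrids, null, candidates,
                           types = c("aa", "ad", "da", "dd")) {
  stopifnot(inherits(hybrids, "marker_matrix"), inherits(null, "null_fit"))
  if (anyNA(hybrids$calls)) stop("missing hybrid calls; impute parents first")
  types <- match.arg(types, several.ok = TRUE)
  idx <- resolve_qtn_index(candidates, hybrids)
  idx <- sort(unique(idx))
  if (length(idx) < 2) stop("need >= 2 candidate markers")
  y <- as.numeric(y)
  n <- length(y)
  vary <- stats::var(y)
  Z <- hybrids$calls - 1
  W <- (hybrids$calls == 1) * 1
  Lt <- t(chol(null$V))
  ty <- forwardsolve(Lt, y)
  rows <- list()
  skipped <- list()
  pairs <- utils::combn(idx, 2)
  for (pp in seq_len(ncol(pairs))) {
    i <- pairs[1, pp]; j <- pairs[2, pp]
    mains <- cbind(Z[, i], W[, i], Z[, j], W[, j])
    mains <- mains[, apply(mains, 2, stats::sd) > 0, drop = FALSE]
    for (ty_lab in types) {
      tl <- strsplit(ty_lab, "")[[1]]
      ci <- if (tl[1] == "a") Z[, i] else W[, i]
      cj <- if (tl[2] == "a") Z[, j] else W[, j]
      inter <- ci * cj
      if (stats::sd(inter) == 0) {
        skipped[[length(skipped) + 1]] <-
          data.frame(marker_i = hybrids$map$marker[i],
                     marker_j = hybrids$map$marker[j], type = ty_lab,
                     reason = "constant_interaction")
        next
      }
      Xr <- cbind(1, mains, inter)
      Tx <- forwardsolve(Lt, Xr)
      fit <- tfit(Tx, ty)
      last <- ncol(Xr)
      if (is.na(fit$coef[last])) {
        skipped[[length(skipped) + 1]] <-
          data.frame(marker_i = hybrids$map$marker[i],
                     marker_j = hybrids$map$marker[j], type = ty_lab,
                     reason = "collinear_interaction")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        marker_i = hybrids$map$marker[i], marker_j = hybrids$map$marker[j],
        type = ty_lab, alpha_hat = fit$coef[last], logp = fit$logp[last],
        pve = 100 * stats::var(inter * fit$coef[last]) / vary,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_i = character(), marker_j = character(),
               type = character(), alpha_hat = numeric(), logp = numeric(),
               pve = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("epistasis_result", "data.frame")
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "n_pairs") <- ncol(pairs)
  out
}

#' Phenotypic variance explained by a fitted effect
#'
#' PVE = 100 * var(M alpha) / var(y), using the observed genotype
#' distribution of the fitted design column(s).
#'
#' @param y Phenotype vector.
#' @param M Design column(s) (vector or matrix).
#' @param alpha Effect estimate(s), one per column of `M`.
#' @return PVE in percent.
#' @export
compute_pve <- function(y, M, alpha) {
  vy <- stats::var(as.numeric(y))
  if (is.na(vy) || vy == 0) stop("phenotype has zero variance")
  M <- as.matrix(M)
  if (ncol(M) != length(alpha)) stop("one effect per design column required")
  100 * stats::var(as.vector(M %*% alpha)) / vy
}

#' LD clumping and PVE screening of significant markers
#'
#' Among significant markers within `ld_window` basepairs of each other and
#' with pairwise r-squared above `r2_max`, keeps only the most significant
#' one (ties broken by smaller position), then drops retained markers whose
#' PVE is below `pve_min` percent.
#'
#' @param result A `scan_result`.
#' @param hybrids The hybrid [marker_matrix()] the scan was run on (for
#'   genotype correlations).
#' @param threshold -log10 significance threshold for selecting markers.
#' @param ld_window LD decay distance in basepairs (default 150000).
#' @param r2_max Markers above this r-squared are clumped (default 0.2).
#' @param pve_min Minimum PVE percent for a retained QTN (default 1.0).
#' @return The QTN table: the retained rows of `result`, ordered by
#'   chromosome and position.
#' @export
clump_significant <- function(result, hybrids, threshold,
                              ld_window = 150000, r2_max = 0.2,
                              pve_min = 1.0) {
  stopifnot(inherits(result, "scan_result"),
            inherits(hybrids, "marker_matrix"))
  sig <- result[!is.na(result$logp) & result$logp >= threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(sig)
  ord <- order(-sig$logp, sig$pos)
  sig <- sig[ord, , drop = FALSE]
  calls <- hybrids$calls[, match(sig$marker, hybrids$map$marker), drop = FALSE]
  keep <- logical(nrow(sig))
  removed <- logical(nrow(sig))
  for (i in seq_len(nrow(sig))) {
    if (removed[i]) next
    keep[i] <- TRUE
    if (i == nrow(sig)) break
    for (j in seq((i + 1), nrow(sig))) {
      if (removed[j]) next
      if (sig$chrom[j] != sig$chrom[i]) next
      if (abs(sig$pos[j] - sig$pos[i]) > ld_window) next
      r2 <- suppressWarnings(stats::cor(calls[, i], calls[, j]))^2
      if (!is.na(r2) && r2 > r2_max) removed[j] <- TRUE
    }
  }
  out <- sig[keep & !removed, , drop = FALSE]
  out <- out[!is.na(out$pve) & out$pve >= pve_min, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Cross-validated comparison of background models
#'
#' Repeated k-fold cross-validation of the KinA and KinADE background
#' models: per repeat, a random fold partition is drawn; each model is
#' fitted by REML on the training folds and the held-out phenotypes are
#' predicted by the mixed-model BLUP (cross-covariance times the inverse
#' training covariance applied to the centred training phenotypes).  The
#' predictive PVE of a repeat is 100 times the squared correlation between
#' predicted and observed phenotypes over all held-out samples.
#'
#' @param y Phenotype vector.
#' @param K A [build_kinships()] result on the full sample set.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeated partitions (default 100).
#' @param seed Integer seed; fold partitions and results are fully
#'   reproducible.
#' @param models Models to compare.
#' @param max_iter REML iteration cap per fold fit.
#' @return A list with `results` (long data frame: repeat, model,
#'   predictive PVE) and `summary` (mean and sd per model).
#' @export
crossvalidate_models <- function(y, K, folds = 5, repeats = 100, seed = 1,
                                 models = c("KinA", "KinADE"),
                                 max_iter = 40) {
  stopifnot(inherits(K, "kinship_set"))
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2 * folds) stop("folds would contain < 2 samples")
  mat_names <- c(a = "Ka", d = "Kd", aa = "Kaa", ad = "Kad", da = "Kda",
                 dd = "Kdd")
  set.seed(seed)
  res <- list()
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (model in models) {
      pred <- rep(NA_real_, n)
      for (f in seq_len(folds)) {
        test <- which(fold_id == f)
        train <- which(fold_id != f)
        Ktr <- subset_kinships(K, train)
        fit <- suppressWarnings(
          fit_null_reml(y[train], Ktr, model = model, max_iter = max_iter))
        Vtr <- fit$V
        one <- rep(1, length(train))
        Vinv_y <- solve(Vtr, y[train])
        Vinv_1 <- solve(Vtr, one)
        mu <- sum(one * Vinv_y) / sum(one * Vinv_1)
        cross <- subset_kinships(K, test, train)
        C <- matrix(0, length(test), length(train))
        for (cn in fit$components_used)
          C <- C + fit$sigma2[cn] * cross[[mat_names[cn]]]
        pred[test] <- mu + as.vector(C %*% solve(Vtr, y[train] - mu))
      }
      res[[length(res) + 1]] <- data.frame(
        rep = r, model = model,
        pve = 100 * suppressWarnings(stats::cor(pred, y))^2,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  results$pve[is.na(results$pve)] <- 0
  summary <- do.call(rbind, lapply(split(results, results$model), function(d)
    data.frame(model = d$model[1], mean_pve = mean(d$pve),
               sd_pve = stats::sd(d$pve), stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
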