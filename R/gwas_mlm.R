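#' Mean-imputed dosage matrix
#'
#' Missing calls replaced by the per-marker mean dosage; the standard
#' imputation for kinship and single-marker scans.
#' @param G A [geno_matrix()].
#' @return Numeric matrix accessions x markers.
#' @export
impute_dosage <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  M <- G$calls
  storage.mode(M) <- "double"
  cm <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx) > 0) M[idx] <- cm[idx[, 2]]
  M
}

#' VanRaden genomic relationship matrix
#'
#' `K = Z Z' / (2 * sum(p * (1 - p)))` with `Z` the mean-imputed dosage
#' matrix centered by `2p` (`p` = alt-allele frequency).  Symmetric and, up
#' to numerical noise, positive semidefinite.
#'
#' @param G A [geno_matrix()].
#' @return n x n matrix of class `matrix` with accession dimnames and an
#'   `estimator` attribute.
#' @export
kinship <- function(G) {
  M <- impute_dosage(G)
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; kinship undefined")
  M <- M[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  K <- (K + t(K)) / 2
  dimnames(K) <- list(G$accessions, G$accessions)
  attr(K, "estimator") <- "vanraden"
  K
}

#' Principal-component structure covariates
#'
#' Top principal components of the centered, mean-imputed genotype matrix,
#' the standard stand-in for a STRUCTURE-style Q matrix.  Returned with a
#' leading intercept column; components are deterministic up to sign.
#'
#' @param G A [geno_matrix()].
#' @param n_components Number of components (>= 1, < n accessions).
#' @return n x (1 + n_components) matrix, columns `intercept`, `PC1`, ...
#' @export
structure_covariates <- function(G, n_components = 3) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- nrow(G$calls)
  if (n_components <= 0) stop("n_components must be positive")
  if (n_components >= n) stop("n_components must be < n_accessions")
  M <- impute_dosage(G)
  Z <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Z, nu = n_components, nv = 0)
  Q <- cbind(1, sv$u[, seq_len(n_components), drop = FALSE] *
               rep(sv$d[seq_len(n_components)], each = n))
  colnames(Q) <- c("intercept", paste0("PC", seq_len(n_components)))
  rownames(Q) <- G$accessions
  Q
}

# REML log-likelihood machinery (EMMA-style): profile everything onto
# delta = sigma_e^2 / sigma_g^2 using the eigendecomposition of K.
.reml_pieces <- function(delta, yS, XS, S) {
  w <- 1 / (S + delta)
  XtWX <- crossprod(XS, XS * w)
  XtWy <- crossprod(XS, yS * w)
  beta <- solve(XtWX, XtWy)
  r <- yS - XS %*% beta
  rss <- sum(w * r^2)
  list(beta = beta, rss = rss, logdetV = sum(log(S + delta)),
       logdetXtWX = determinant(XtWX, logarithm = TRUE)$modulus[1])
}

.reml_loglik <- function(delta, yS, XS, S, nq, logdetXtX) {
  pc <- .reml_pieces(delta, yS, XS, S)
  sg2 <- pc$rss / nq
  -0.5 * (nq * log(2 * pi * sg2) + pc$logdetV + pc$logdetXtWX -
            logdetXtX + nq)
}

#' Fit the null mixed linear model
#'
#' REML fit of `y = Q b + u + e` with `u ~ N(0, sg2 K)` and
#' `e ~ N(0, se2 I)`, profiled onto the variance ratio
#' `delta = se2 / sg2` via the eigendecomposition of `K` and optimized by a
#' log-spaced grid search refined with Brent's method — so the returned
#' likelihood is a global optimum over the searched range
#' (`delta` in `[1e-5, 1e5]`).
#'
#' @param y Numeric phenotype vector (non-constant, no NA).
#' @param Q Fixed-effect design matrix including the intercept (defaults to
#'   an intercept-only design).
#' @param K Kinship matrix from [kinship()].
#' @return Object of class `mlm_fit`: `sigma_g2`, `sigma_e2`, `delta`, `h2`
#'   (`sg2 / (sg2 + se2)`), `loglik` (REML), `beta`, plus the cached rotation
#'   (`U`, `S`) reused by [scan_mlm()].
#' @export
fit_null_mlm <- function(y, Q = NULL, K) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("y must be finite (impute or drop NAs first)")
  if (stats::sd(y) == 0) stop("y is constant")
  n <- length(y)
  if (is.null(Q)) Q <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == n, nrow(K) == n, ncol(K) == n)
  if (qr(Q)$rank < ncol(Q)) stop("singular fixed-effect design")
  eg <- eigen(K, symmetric = TRUE)
  S <- pmax(eg$values, 0)
  U <- eg$vectors
  yS <- crossprod(U, y)
  XS <- crossprod(U, Q)
  nq <- n - ncol(Q)
  logdetXtX <- determinant(crossprod(Q), logarithm = TRUE)$modulus[1]

  grid <- 10^seq(-5, 5, length.out = 41)
  ll <- vapply(grid, .reml_loglik, numeric(1), yS = yS, XS = XS, S = S,
               nq = nq, logdetXtX = logdetXtX)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  # optimize over log-delta for numerical stability
  f_log <- function(ld) .reml_loglik(exp(ld), yS, XS, S, nq, logdetXtX)
  opt <- stats::optimize(f_log, interval = log(c(lo, hi)), maximum = TRUE,
                         tol = 1e-8)
  delta <- exp(opt$maximum)
  if (opt$objective < ll[i]) delta <- grid[i]
  pc <- .reml_pieces(delta, yS, XS, S)
  sg2 <- pc$rss / nq
  se2 <- delta * sg2
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, delta = delta,
                 h2 = sg2 / (sg2 + se2),
                 loglik = .reml_loglik(delta, yS, XS, S, nq, logdetXtX),
                 beta = stats::setNames(as.numeric(pc$beta), colnames(Q)),
                 U = U, S = S),
            class = "mlm_fit")
}

#' @export
print.mlm_fit <- function(x, ...) {
  cat(sprintf("<mlm_fit> sg2=%.4g, se2=%.4g, h2=%.3f, REML logLik=%.3f\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

# whitening transform: returns function mapping vectors/matrices into the
# space where the null covariance is the identity
.whitener <- function(fit) {
  w <- 1 / sqrt(fit$S + fit$delta)
  function(x) {
    x <- as.matrix(x)
    crossprod(fit$U, x) * w
  }
}

#' Single-locus mixed-model association scan
#'
#' Tests each marker's allele-substitution effect in the mixed model with
#' variance parameters fixed at the null fit (the P3D /
#' population-parameters-previously-determined contract): the data are
#' whitened by the null covariance and each marker is tested by ordinary
#' least squares with a two-sided t test (df = n - q - 1).  Missing calls are
#' mean-imputed; monomorphic markers are skipped; a marker collinear with the
#' covariates is reported with `beta = 0, p = 1`.  Set `p3d = FALSE` to
#' re-estimate the variance ratio per marker (exact, much slower).
#'
#' @param G A [geno_matrix()] (QC-passed).
#' @param y Phenotype vector aligned with `G$accessions`.
#' @param Q Fixed covariates incl. intercept (default intercept +
#'   [structure_covariates()] is the caller's choice; bare intercept if NULL).
#' @param K Kinship matrix; ignored if `fit` supplied.
#' @param fit Optional pre-computed [fit_null_mlm()] result.
#' @param p3d Keep null variance components fixed (default TRUE).
#' @return `data.frame` of association records: snp, chrom, pos, beta, se,
#'   p, neglog10p, pve.
#' @export
scan_mlm <- function(G, y, Q = NULL, K = NULL, fit = NULL, p3d = TRUE) {
  stopifnot(inherits(G, "geno_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  Q <- as.matrix(Q)
  if (is.null(fit)) {
    if (is.null(K)) stop("supply K or a null fit")
    fit <- fit_null_mlm(y, Q, K)
  }
  M <- impute_dosage(G)
  mono <- apply(M, 2, stats::sd) == 0
  W <- .whitener(fit)
  yt <- W(y); Xt <- W(Q)
  q <- ncol(Q)
  df <- n - q - 1
  vary <- stats::var(y)

  run_one <- function(j) {
    g <- M[, j]
    if (!p3d) {
      fj <- fit_null_mlm(y, cbind(Q, g), if (is.null(K)) NULL else K)
      Wj <- .whitener(fj); ytj <- Wj(y); Dj <- cbind(Wj(Q), Wj(g))
    } else {
      ytj <- yt; Dj <- cbind(Xt, W(g))
    }
    qr_ <- qr(Dj)
    if (qr_$rank < ncol(Dj))
      return(c(beta = 0, se = NA, p = 1))
    cf <- qr.coef(qr_, ytj)
    res <- ytj - Dj %*% cf
    s2 <- sum(res^2) / df
    XtXinv_jj <- chol2inv(qr.R(qr_))[ncol(Dj), ncol(Dj)]
    se <- sqrt(s2 * XtXinv_jj)
    tval <- cf[length(cf)] / se
    c(beta = cf[length(cf)], se = se,
      p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
  }

  use <- which(!mono)
  out <- t(vapply(use, run_one, numeric(3)))
  p <- pmax(out[, "p"], .Machine$double.xmin)
  pve <- 100 * out[, "beta"]^2 * apply(M[, use, drop = FALSE], 2, stats::var) / vary
  data.frame(snp = G$markers$id[use], chrom = G$markers$chrom[use],
             pos = G$markers$pos[use], beta = out[, "beta"],
             se = out[, "se"], p = p, neglog10p = -log10(p),
             pve = pmin(pve, 100), stringsAsFactors = FALSE)
}

#' Leave-one-chromosome-out mixed-model scan
#'
#' Runs [scan_mlm()] chromosome by chromosome with the kinship matrix
#' rebuilt from all other chromosomes (LOCO).  Including the tested marker's
#' chromosome in the kinship lets the polygenic term absorb part of the
#' marker's own effect (proximal contamination) and costs power; LOCO is the
#' standard remedy.  With a single chromosome the full-kinship scan is used
#' with a warning.
#'
#' @inheritParams scan_mlm
#' @return `data.frame` as from [scan_mlm()], in marker order.
#' @export
scan_mlm_loco <- function(G, y, Q = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  chroms <- unique(G$markers$chrom)
  if (length(chroms) < 2) {
    warning("single chromosome: LOCO impossible, using full kinship")
    return(scan_mlm(G, y, Q, K = kinship(G)))
  }
  parts <- lapply(chroms, function(ch) {
    off <- G$markers$chrom != ch
    Koff <- kinship(geno_matrix(G$calls[, off, drop = FALSE],
                                G$markers[off, , drop = FALSE]))
    on <- !off
    Gon <- geno_matrix(G$calls[, on, drop = FALSE],
                       G$markers[on, , drop = FALSE])
    scan_mlm(Gon, y, Q, K = Koff)
  })
  out <- do.call(rbind, parts)
  out[match(G$markers$id[G$markers$id %in% out$snp], out$snp), ]
}

#' Percent variance explained by one marker
#'
#' `PVE = 100 * beta^2 * Var(g) / Var(y)` with `Var(g)` the sample variance
#' of the mean-imputed dosage — one of several GAPIT-era conventions,
#' labeled as such in outputs.  Invariant to affine rescaling of `y`.
#'
#' @param beta Estimated allele-substitution effect.
#' @param g Marker dosage vector (missing allowed; mean-imputed).
#' @param y Phenotype vector.
#' @return PVE in percent, capped at 100.
#' @export
pve_of_snp <- function(beta, g, y) {
  vy <- stats::var(y, na.rm = TRUE)
  if (!is.finite(vy) || vy == 0) stop("zero trait variance")
  g <- as.numeric(g); g[is.na(g)] <- mean(g, na.rm = TRUE)
  min(100, 100 * beta^2 * stats::var(g) / vy)
}

#' Call suggestive marker-trait associations
#'
#' Keeps records with `-log10(p)` strictly above the suggestive threshold
#' (default 5, i.e. p < 1e-5).  With `peak_window` set, records are grouped
#' into peaks per chromosome (windows of that many bases) and only the
#' smallest-p record per peak is kept.
#'
#' @param records Scan output from [scan_mlm()].
#' @param threshold_neglog10p Suggestive threshold (default 5; strict `>`).
#' @param peak_window Optional window size in bases for peak grouping
#'   (e.g. 1e6); `NULL` disables grouping.
#' @return Filtered `data.frame` of records.
#' @export
suggestive_mtas <- function(records, threshold_neglog10p = 5,
                            peak_window = NULL) {
  hits <- records[records$neglog10p > threshold_neglog10p, , drop = FALSE]
  if (!is.null(peak_window) && nrow(hits) > 1) {
    keep <- logical(nrow(hits))
    for (ch in unique(hits$chrom)) {
      idx <- which(hits$chrom == ch)
      idx <- idx[order(hits$pos[idx])]
      grp <- cumsum(c(1, diff(hits$pos[idx]) > peak_window))
      for (g in unique(grp)) {
        members <- idx[grp == g]
        keep[members[which.min(hits$p[members])]] <- TRUE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Multi-locus LOD confirmation of candidate markers
#'
#' A documented stand-in for the mrMLM model family: candidates are entered
#' into a joint model on the whitened (null-covariance-corrected) data by
#' forward selection (entry while the partial F-test p-value is below
#' `enter_p`), and each candidate's LOD is the likelihood-ratio support for
#' its effect in the joint model: retained markers are scored by dropping
#' them from the joint model, unselected ones by adding them to it;
#' `LOD = n/2 * log10(RSS_reduced / RSS_full)`.  Markers with LOD strictly
#' greater than `lod_threshold` are flagged confirmed.
#'
#' @param G A [geno_matrix()].
#' @param y Phenotype vector.
#' @param Q Fixed covariates (default intercept).
#' @param K Kinship matrix (used for the null fit when `fit` missing).
#' @param candidates Marker ids to test (pre-selected, e.g. scan p < 0.01).
#' @param fit Optional [fit_null_mlm()] result.
#' @param lod_threshold Confirmation threshold (default 3; strict `>`).
#' @param enter_p Forward-selection entry p-value (default 0.01).
#' @return `data.frame`: snp, lod, retained, confirmed.
#' @export
lod_confirm <- function(G, y, Q = NULL, K = NULL, candidates, fit = NULL,
                        lod_threshold = 3, enter_p = 0.01) {
  stopifnot(inherits(G, "geno_matrix"), length(candidates) >= 1)
  y <- as.numeric(y); n <- length(y)
  if (is.null(Q)) Q <- matrix(1, n, 1)
  Q <- as.matrix(Q)
  if (is.null(fit)) {
    if (is.null(K)) stop("supply K or a null fit")
    fit <- fit_null_mlm(y, Q, K)
  }
  jidx <- match(candidates, G$markers$id)
  if (any(is.na(jidx))) stop("unknown candidate marker id")
  M <- impute_dosage(G)[, jidx, drop = FALSE]
  W <- .whitener(fit)
  yt <- W(y); Xt <- W(Q); Mt <- W(M)

  max_terms <- min(length(candidates), floor(n / 2) - ncol(Q))
  rss_of <- function(D) {
    f <- stats::.lm.fit(D, yt)
    sum(f$residuals^2)
  }
  sel <- integer(0)
  D0 <- Xt
  rss0 <- rss_of(D0)
  repeat {
    if (length(sel) >= max_terms) break
    rest <- setdiff(seq_along(jidx), sel)
    if (length(rest) == 0) break
    rss_try <- vapply(rest, function(j) rss_of(cbind(D0, Mt[, j])), numeric(1))
    b <- which.min(rss_try)
    df2 <- n - ncol(D0) - 1
    Fv <- (rss0 - rss_try[b]) / (rss_try[b] / df2)
    pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
    if (!is.finite(pv) || pv >= enter_p) break
    sel <- c(sel, rest[b])
    D0 <- cbind(D0, Mt[, rest[b]])
    rss0 <- rss_of(D0)
  }

  Dfull <- cbind(Xt, Mt[, sel, drop = FALSE])
  rss_full <- rss_of(Dfull)
  lod <- numeric(length(jidx))
  for (i in seq_along(jidx)) {
    if (i %in% sel) {
      keep <- setdiff(sel, i)
      rss_red <- rss_of(cbind(Xt, Mt[, keep, drop = FALSE]))
      lod[i] <- n / 2 * log10(rss_red / rss_full)
    } else {
      rss_aug <- rss_of(cbind(Dfull, Mt[, i]))
      lod[i] <- n / 2 * log10(rss_full / rss_aug)
    }
  }
  data.frame(snp = candidates, lod = pmax(lod, 0),
             retained = seq_along(jidx) %in% sel,
             confirmed = pmax(lod, 0) > lod_threshold,
             stringsAsFactors = FALSE)
}

#' Per-allele phenotypic effect and favorable allele
#'
#' The allele effect `a_i` is the mean phenotype over carriers of allele `i`
#' minus the overall panel mean (carriers of the reference allele have
#' dosage 0 or 1; of the alternative allele, 1 or 2).  The favorable allele
#' is the one whose effect moves the trait in its breeding-preferred
#' direction ([GQ_TRAIT_DIRECTION]): up for AC, KL, LBR, ASV, KLAC, LER, GC,
#' RS; down for KB, KBAC and PGI.
#'
#' @param g Dosage calls (0/1/2, NA allowed).
#' @param y Phenotype vector.
#' @param trait Trait name (one of [GQ_TRAITS]).
#' @param alleles Optional c(ref, alt) allele letters for labeling.
#' @return List: `effects` (named by allele), `favorable` (allele label),
#'   `favorable_effect`.
#' @export
allele_effect_ai <- function(g, y, trait, alleles = c("ref", "alt")) {
  stopifnot(trait %in% GQ_TRAITS, length(g) == length(y))
  ok <- !is.na(g) & !is.na(y)
  g <- g[ok]; y <- y[ok]
  carriers_ref <- g <= 1
  carriers_alt <- g >= 1
  if (!any(carriers_ref) || !any(carriers_alt))
    stop("marker is monomorphic among scored accessions")
  mu <- mean(y)
  a <- c(mean(y[carriers_ref]) - mu, mean(y[carriers_alt]) - mu)
  names(a) <- alleles
  dir <- GQ_TRAIT_DIRECTION[[trait]]
  fav <- which.max(dir * a)
  list(effects = a, favorable = alleles[fav], favorable_effect = a[[fav]])
}

#' Assign candidate genes to an association
#'
#' A marker inside a gene span is assigned to that gene; an intergenic
#' marker is assigned to its nearest gene on each side (two flanking
#' candidates), with distances to the gene boundaries reported.
#'
#' @param chrom,pos Marker location (1-based).
#' @param models A `gene_models` object from [read_gene_models()] or
#'   [simulate_gene_models()].
#' @return `data.frame`: gene_id, relation (`within` / `upstream` /
#'   `downstream`), distance (0 for `within`).
#' @export
assign_candidate_genes <- function(chrom, pos, models) {
  g <- models$genes[models$genes$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(g) == 0) stop("no gene models on chromosome ", chrom)
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  q <- GenomicRanges::GRanges(as.character(chrom), IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, gr)
  if (length(hit) > 0) {
    i <- S4Vectors::subjectHits(hit)
    return(data.frame(gene_id = g$gene_id[i], relation = "within",
                      distance = 0L, stringsAsFactors = FALSE))
  }
  out <- NULL
  left <- which(g$end < pos)
  if (length(left) > 0) {
    i <- left[which.max(g$end[left])]
    out <- rbind(out, data.frame(gene_id = g$gene_id[i],
                                 relation = "upstream",
                                 distance = pos - g$end[i],
                                 stringsAsFactors = FALSE))
  }
  right <- which(g$start > pos)
  if (length(right) > 0) {
    i <- right[which.min(g$start[right])]
    out <- rbind(out, data.frame(gene_id = g$gene_id[i],
                                 relation = "downstream",
                                 distance = g$start[i] - pos,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Full per-trait MTA calling
#'
#' Chains [scan_mlm()], [suggestive_mtas()], [lod_confirm()],
#' [allele_effect_ai()] and (when gene models are given)
#' [assign_candidate_genes()] into the per-trait marker-trait-association
#' table.
#'
#' @param G QC-passed [geno_matrix()].
#' @param y Phenotype vector for `trait`.
#' @param trait Trait name.
#' @param Q,K Covariates and kinship (see [scan_mlm()]).
#' @param models Optional `gene_models` for candidate-gene assignment.
#' @param threshold_neglog10p Suggestive threshold (default 5).
#' @param lod_threshold LOD confirmation threshold (default 3).
#' @param candidate_p Scan p-value bound pre-selecting LOD candidates
#'   (default 0.01).
#' @param peak_window Optional peak-grouping window (bases).
#' @param loco Scan with leave-one-chromosome-out kinship (default TRUE when
#'   the map has more than one chromosome; see [scan_mlm_loco()]).
#' @return List: `records` (full scan), `mtas` (suggestive records with lod,
#'   confirmed flag, allele effects, favorable allele, candidate genes).
#' @export
call_mtas <- function(G, y, trait, Q = NULL, K = NULL, models = NULL,
                      threshold_neglog10p = 5, lod_threshold = 3,
                      candidate_p = 0.01, peak_window = NULL, loco = TRUE) {
  if (is.null(K)) K <- kinship(G)
  fit <- fit_null_mlm(y, Q, K)
  rec <- if (loco && length(unique(G$markers$chrom)) > 1)
    scan_mlm_loco(G, y, Q) else scan_mlm(G, y, Q, fit = fit)
  mtas <- suggestive_mtas(rec, threshold_neglog10p, peak_window)
  if (nrow(mtas) == 0)
    return(list(records = rec, mtas = cbind(
      mtas, lod = numeric(0), confirmed = logical(0),
      a_ref = numeric(0), a_alt = numeric(0),
      favorable_allele = character(0), favorable_effect = numeric(0),
      genes = character(0))))
  cand <- rec$snp[rec$p < candidate_p]
  cand <- union(cand, mtas$snp)
  lodtab <- lod_confirm(G, y, Q, candidates = cand, fit = fit,
                        lod_threshold = lod_threshold)
  mtas$lod <- lodtab$lod[match(mtas$snp, lodtab$snp)]
  mtas$confirmed <- lodtab$confirmed[match(mtas$snp, lodtab$snp)]
  eff <- lapply(mtas$snp, function(s) {
    j <- match(s, G$markers$id)
    allele_effect_ai(G$calls[, j], y, trait,
                     alleles = c(G$markers$ref[j], G$markers$alt[j]))
  })
  mtas$a_ref <- vapply(eff, function(e) e$effects[[1]], numeric(1))
  mtas$a_alt <- vapply(eff, function(e) e$effects[[2]], numeric(1))
  mtas$favorable_allele <- vapply(eff, `[[`, character(1), "favorable")
  mtas$favorable_effect <- vapply(eff, `[[`, numeric(1), "favorable_effect")
  if (!is.null(models)) {
    mtas$genes <- vapply(seq_len(nrow(mtas)), function(i) {
      cg <- tryCatch(assign_candidate_genes(mtas$chrom[i], mtas$pos[i], models),
                     error = function(e) NULL)
      if (is.null(cg)) "" else paste(cg$gene_id, collapse = ",")
    }, character(1))
  }
  list(records = rec, mtas = mtas)
}
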