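#' The eleven grain-quality trait names
#'
#' Amylose content (AC, %), kernel length and breadth (KL, KB, mm),
#' length/breadth ratio (LBR), alkali spreading value (ASV, score 1-7),
#' kernel length and breadth after cooking (KLAC, KBAC, mm), linear
#' elongation ratio (LER), gel consistency (GC, mm), resistant starch
#' (RS, %) and predicted glycemic index (PGI).
#' @export
GQ_TRAITS <- c("AC", "KL", "KB", "LBR", "ASV", "KLAC", "KBAC",
               "LER", "GC", "RS", "PGI")

#' Breeding-preferred direction per trait
#'
#' `+1` means larger values are favorable (AC, KL, LBR, ASV, KLAC, LER, GC,
#' RS); `-1` means smaller values are favorable (KB, KBAC, PGI).
#' @export
GQ_TRAIT_DIRECTION <- c(AC = 1, KL = 1, KB = -1, LBR = 1, ASV = 1,
                        KLAC = 1, KBAC = -1, LER = 1, GC = 1, RS = 1,
                        PGI = -1)

#' Derived kernel ratios
#'
#' Length/breadth ratio `LBR = KL / KB` and linear elongation ratio
#' `LER = KLAC / KL` (cooked over raw kernel length), the standard
#' rice-quality definitions.
#'
#' @param KL,KB Raw kernel length and breadth in mm (> 0).
#' @param KLAC Kernel length after cooking in mm (> 0); optional — if
#'   missing, only LBR is computed.
#' @return List with numeric vectors `LBR` and (if `KLAC` given) `LER`.
#' @export
derive_ratios <- function(KL, KB, KLAC = NULL) {
  if (any(KL <= 0, na.rm = TRUE) || any(KB <= 0, na.rm = TRUE))
    stop("KL and KB must be positive")
  out <- list(LBR = KL / KB)
  if (!is.null(KLAC)) {
    if (any(KLAC <= 0, na.rm = TRUE)) stop("KLAC must be positive")
    out$LER <- KLAC / KL
  }
  out
}

#' Classify gel consistency
#'
#' Gel-flow length in mm is banded as soft (>= 61 mm), medium (41-60 mm) and
#' hard (<= 40 mm).  The nominal hard band starts at 25 mm; shorter gels
#' still classify as hard but trigger a below-scale warning, since panel
#' minima below 25 mm occur in practice.
#'
#' @param gel_length Gel length in mm (> 0), vectorized.
#' @return Factor with levels `hard`, `medium`, `soft`.
#' @export
classify_gc <- function(gel_length) {
  if (any(!is.finite(gel_length) | gel_length <= 0))
    stop("gel_length must be positive")
  if (any(gel_length < 25))
    warning("gel length below the 25 mm scale floor; classified as hard")
  cls <- ifelse(gel_length >= 61, "soft",
                ifelse(gel_length >= 41, "medium", "hard"))
  factor(cls, levels = c("hard", "medium", "soft"))
}

#' Pairwise trait correlations with significance stars
#'
#' Pairwise-complete Pearson correlations between all numeric trait columns,
#' with two-sided t-test p-values and the conventional star display
#' (`*` p < 0.05, `**` p < 0.01).  Constant columns or pairs with fewer than
#' 3 complete observations yield `NA`.
#'
#' @param pheno `data.frame` with an accession id column (ignored) and
#'   numeric trait columns.
#' @param traits Trait columns to use; defaults to all numeric columns.
#' @return List with matrices `r`, `p`, `stars` and a long-format
#'   `data.frame` `table` (trait1, trait2, r, p, stars).
#' @export
trait_correlations <- function(pheno, traits = NULL) {
  num <- vapply(pheno, is.numeric, logical(1))
  if (is.null(traits)) traits <- names(pheno)[num]
  stopifnot(all(traits %in% names(pheno)))
  X <- as.matrix(pheno[traits])
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(X[, i], X[, j])
    n <- sum(ok)
    if (n < 3 || stats::sd(X[ok, i]) == 0 || stats::sd(X[ok, j]) == 0) next
    ct <- stats::cor.test(X[ok, i], X[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  diag(stars) <- ""
  idx <- which(upper.tri(r), arr.ind = TRUE)
  tab <- data.frame(trait1 = traits[idx[, 1]], trait2 = traits[idx[, 2]],
                    r = r[idx], p = p[idx], stars = stars[idx],
                    stringsAsFactors = FALSE)
  list(r = r, p = p, stars = stars, table = tab)
}

#' Per-trait descriptive statistics
#'
#' Mean, min, max and sample standard deviation (n-1 denominator) per trait,
#' ignoring missing values.
#'
#' @param pheno `data.frame` of numeric trait columns (non-numeric columns
#'   ignored).
#' @return `data.frame` with columns trait, n, mean, min, max, sd.
#' @export
trait_descriptives <- function(pheno) {
  num <- names(pheno)[vapply(pheno, is.numeric, logical(1))]
  if (length(num) == 0) stop("no numeric trait columns")
  rows <- lapply(num, function(tr) {
    x <- pheno[[tr]]
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("trait '", tr, "' has no non-missing values")
    data.frame(trait = tr, n = length(x), mean = mean(x), min = min(x),
               max = max(x), sd = if (length(x) > 1) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a correlation table as TSV
#'
#' Long-format TSV with columns trait1, trait2, r, p, stars.
#' @param corr Result of [trait_correlations()].
#' @param path Output path.
#' @export
write_correlations_tsv <- function(corr, path) {
  data.table::fwrite(corr$table, path, sep = "\t")
  invisible(path)
}
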