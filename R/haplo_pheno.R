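#' Extract the functional variants of a gene
#'
#' Restricts a genotype matrix to the markers inside a gene span that are
#' exonic AND (nonsynonymous OR indel) — the variant set that defines
#' gene-level haplotypes — in position order.
#'
#' @param G A [geno_matrix()] whose marker table carries annotation flags.
#' @param models A `gene_models` object.
#' @param gene_id Gene to extract.
#' @return Call submatrix (accessions x flagged in-gene markers); zero
#'   columns when the gene carries no flagged variants.
#' @export
extract_gene_variants <- function(G, models, gene_id) {
  stopifnot(inherits(G, "geno_matrix"))
  g <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("gene '", gene_id, "' not in models")
  m <- G$markers
  sel <- m$chrom == g$chrom & m$pos >= g$start & m$pos <= g$end &
    m$exonic & (m$nonsyn | m$indel)
  sel[is.na(sel)] <- FALSE
  G$calls[, which(sel)[order(m$pos[sel])], drop = FALSE]
}

#' Call gene haplotypes by exact variant-pattern grouping
#'
#' Accessions sharing an identical call vector over the gene's functional
#' variants share a haplotype.  Haplotypes are labeled H1, H2, ... by
#' descending carrier count (ties broken by first occurrence).  Accessions
#' with any missing call in the submatrix are excluded (listed with reason),
#' which avoids phantom haplotypes from partial patterns.  An empty
#' submatrix assigns every accession to H1.
#'
#' @param submatrix Call matrix from [extract_gene_variants()].
#' @return Object of class `haplotype_assignment`: `haplotype` (named
#'   character, accession -> label), `patterns` (label -> call pattern
#'   string), `excluded` (data.frame accession, reason).
#' @export
call_haplotypes <- function(submatrix) {
  submatrix <- as.matrix(submatrix)
  acc <- rownames(submatrix)
  if (is.null(acc)) acc <- paste0("acc", seq_len(nrow(submatrix)))
  if (ncol(submatrix) == 0) {
    out <- list(haplotype = stats::setNames(rep("H1", length(acc)), acc),
                patterns = c(H1 = ""),
                excluded = data.frame(accession = character(0),
                                      reason = character(0)))
    class(out) <- "haplotype_assignment"
    return(out)
  }
  has_na <- rowSums(is.na(submatrix)) > 0
  excluded <- data.frame(accession = acc[has_na],
                         reason = rep("missing call", sum(has_na)),
                         stringsAsFactors = FALSE)
  keep <- !has_na
  pat <- apply(submatrix[keep, , drop = FALSE], 1, paste, collapse = "/")
  counts <- table(pat)
  # order: descending count, ties by first occurrence in the data
  first <- vapply(names(counts), function(p) which(pat == p)[1], integer(1))
  ord <- order(-as.integer(counts), first)
  labels <- stats::setNames(paste0("H", seq_along(ord)), names(counts)[ord])
  out <- list(haplotype = stats::setNames(unname(labels[pat]), acc[keep]),
              patterns = stats::setNames(names(counts)[ord], unname(labels)),
              excluded = excluded)
  class(out) <- "haplotype_assignment"
  out
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("<haplotype_assignment> %d accessions in %d haplotype(s); %d excluded\n",
              length(x$haplotype), length(x$patterns), nrow(x$excluded)))
  invisible(x)
}

#' Haplotype frequency table
#'
#' Percent frequency of each haplotype over included accessions; descending
#' frequency defines the H-numbering, so the table comes back in label
#' order.
#'
#' @param assignment A `haplotype_assignment`.
#' @return `data.frame`: haplotype, n, freq_pct.
#' @export
haplotype_frequencies <- function(assignment) {
  stopifnot(inherits(assignment, "haplotype_assignment"))
  if (length(assignment$haplotype) == 0) stop("no included accessions")
  tb <- table(assignment$haplotype)
  labs <- names(assignment$patterns)
  n <- as.integer(tb[labs])
  data.frame(haplotype = labs, n = n,
             freq_pct = 100 * n / sum(n),
             stringsAsFactors = FALSE)
}

#' Duncan's multiple range test letter display
#'
#' Groups are sorted by descending mean; the shortest significant range for
#' a span of `p` ordered means is `R_p = q(1 - alpha_p, p, df) *
#' sqrt(mse / n_h)` with Duncan's protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` (studentized-range quantile via
#' `qtukey`) and `n_h` the harmonic mean of the sizes of the groups spanned
#' (the Kramer adjustment for unequal n).  A span whose extreme means differ
#' by less than its range — or that sits inside a non-significant span — is
#' declared homogeneous; maximal homogeneous spans become the shared
#' letters.
#'
#' @param means Named vector of group means.
#' @param n Group sizes (same order/names).
#' @param mse Error mean square from the ANOVA (> 0).
#' @param df_error Error degrees of freedom (>= 1).
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` (in descending-mean order): group, mean, n, letters.
#' @export
duncan_mrt <- function(means, n, mse, df_error, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2, length(n) == k, df_error >= 1, mse > 0,
            alpha > 0, alpha < 1)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; nn <- n[ord]

  crit_range <- function(i, j) {     # span over sorted positions i..j
    p <- j - i + 1
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    nh <- p / sum(1 / nn[i:j])
    stats::qtukey(1 - alpha_p, p, df_error) * sqrt(mse / nh)
  }

  # homogeneous[i, j]: span i..j declared not significantly separated,
  # with the protection rule that spans inside a homogeneous span are
  # never declared significant
  homog <- matrix(FALSE, k, k)
  diag(homog) <- TRUE
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      inside <- FALSE
      if (span < k) {
        for (a in seq_len(k - span)) {
          b <- a + span
          if (a <= i && j <= b && homog[a, b]) { inside <- TRUE; break }
        }
      }
      homog[i, j] <- inside || (m[i] - m[j] < crit_range(i, j))
    }
  }

  # maximal homogeneous spans -> letters
  spans <- list()
  for (i in seq_len(k)) for (j in i:k) {
    if (!homog[i, j]) next
    maximal <- !(i > 1 && homog[i - 1, j]) && !(j < k && homog[i, j + 1])
    if (maximal) spans[[length(spans) + 1]] <- c(i, j)
  }
  letters_vec <- character(k)
  for (s in seq_along(spans)) {
    rng <- spans[[s]][1]:spans[[s]][2]
    letters_vec[rng] <- paste0(letters_vec[rng], letters[s])
  }
  data.frame(group = names(m), mean = unname(m), n = unname(nn),
             letters = letters_vec, stringsAsFactors = FALSE)
}

#' Haplo-pheno comparison for one gene and trait
#'
#' Joins a haplotype assignment with a phenotype column, reports per-
#' haplotype counts, frequencies and trait means, and — across haplotypes
#' carried by at least `min_n` accessions — runs a one-way ANOVA followed by
#' Duncan's multiple range test.  Haplotypes below `min_n` stay in the table
#' (with means) but never enter testing.  Accessions with a missing trait
#' value are dropped.
#'
#' @param assignment A `haplotype_assignment`.
#' @param pheno Phenotype `data.frame` with an `accession` column.
#' @param trait Trait column name.
#' @param min_n Minimum carriers for a haplotype to be tested (default 2).
#' @param alpha Significance level for Duncan's test (default 0.05).
#' @return Object of class `haplo_pheno_table`: `table` (haplotype, n,
#'   freq_pct, mean, sd, tested, letters), `anova` (F, p, df, mse), `trait`,
#'   `note` (non-NULL when testing was impossible).
#' @export
haplo_pheno_table <- function(assignment, pheno, trait, min_n = 2,
                              alpha = 0.05) {
  stopifnot(inherits(assignment, "haplotype_assignment"),
            trait %in% names(pheno), "accession" %in% names(pheno))
  hap <- assignment$haplotype
  y <- pheno[[trait]][match(names(hap), pheno$accession)]
  ok <- !is.na(y)
  hap <- hap[ok]; y <- y[ok]
  if (length(y) == 0) stop("no scored accessions shared with the phenotype table")

  freq <- haplotype_frequencies(assignment)
  agg <- data.frame(
    haplotype = freq$haplotype,
    n = vapply(freq$haplotype, function(h) sum(hap == h), integer(1)),
    freq_pct = freq$freq_pct,
    mean = vapply(freq$haplotype, function(h)
      if (any(hap == h)) mean(y[hap == h]) else NA_real_, numeric(1)),
    sd = vapply(freq$haplotype, function(h)
      if (sum(hap == h) > 1) stats::sd(y[hap == h]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  agg$tested <- agg$n >= min_n
  agg$letters <- NA_character_

  res <- list(table = agg, anova = NULL, trait = trait, alpha = alpha,
              note = NULL)
  class(res) <- "haplo_pheno_table"

  testable <- agg$haplotype[agg$tested]
  if (length(testable) < 2) {
    res$note <- "fewer than 2 haplotypes pass the min-n rule; no test run"
    return(res)
  }
  sel <- hap %in% testable
  fit <- stats::aov(y[sel] ~ factor(hap[sel]))
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2]; dfe <- an[["Df"]][2]
  res$anova <- list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                    df = an[["Df"]], mse = mse, df_error = dfe)
  if (dfe < 1 || !is.finite(mse) || mse <= 0) {
    res$note <- "degenerate ANOVA (no residual variance); letters omitted"
    return(res)
  }
  d <- duncan_mrt(stats::setNames(agg$mean[agg$tested], testable),
                  agg$n[agg$tested], mse, dfe, alpha)
  res$table$letters[match(d$group, res$table$haplotype)] <- d$letters
  res
}

#' @export
print.haplo_pheno_table <- function(x, ...) {
  cat(sprintf("<haplo_pheno_table> trait %s, %d haplotype(s)\n",
              x$trait, nrow(x$table)))
  print(x$table, row.names = FALSE)
  if (!is.null(x$anova))
    cat(sprintf("ANOVA F=%.3f, p=%.3g\n", x$anova$F, x$anova$p))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Pick the superior haplotype for a trait
#'
#' The tested haplotype whose mean is best in the trait's favorable
#' direction (maximum for AC, KL, LBR, ASV, KLAC, LER, GC, RS; minimum for
#' KB, KBAC, PGI).  Ties break toward the larger carrier count, then the
#' lower haplotype index.  If the winner shares its Duncan letter with every
#' other tested haplotype, it is flagged `separated = FALSE`.
#'
#' @param hp A [haplo_pheno_table()] result with letters.
#' @param trait Trait name (defaults to the table's trait).
#' @return List: `haplotype`, `mean`, `separated`.
#' @export
superior_haplotype <- function(hp, trait = hp$trait) {
  stopifnot(inherits(hp, "haplo_pheno_table"), trait %in% GQ_TRAITS)
  tab <- hp$table[hp$table$tested, , drop = FALSE]
  if (nrow(tab) == 0 || all(is.na(tab$letters)))
    stop("table has no Duncan letters; cannot rank haplotypes")
  dir <- GQ_TRAIT_DIRECTION[[trait]]
  score <- dir * tab$mean
  idx <- as.integer(sub("^H", "", tab$haplotype))
  best <- order(-score, -tab$n, idx)[1]
  others <- setdiff(seq_len(nrow(tab)), best)
  shares <- vapply(others, function(i) {
    any(strsplit(tab$letters[best], "")[[1]] %in%
          strsplit(tab$letters[i], "")[[1]])
  }, logical(1))
  list(haplotype = tab$haplotype[best], mean = tab$mean[best],
       separated = !(length(shares) > 0 && all(shares)))
}

#' Accessions carrying a haplotype
#'
#' Donor lookup for haplotype-based breeding: the accession ids assigned to
#' the given haplotype label.
#' @param assignment A `haplotype_assignment`.
#' @param haplotype Label, e.g. "H4".
#' @return Character vector of accession ids.
#' @export
haplotype_donors <- function(assignment, haplotype) {
  stopifnot(inherits(assignment, "haplotype_assignment"))
  names(assignment$haplotype)[assignment$haplotype == haplotype]
}
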