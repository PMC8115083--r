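#' Default trait ranges for the simulated panel
#'
#' Observed panel ranges for the nine measured traits plus cooked-kernel
#' dimensions; used by the phenotype simulator as affine-mapping targets and
#' clamps.  KLAC and KBAC ranges are nominal values typical of cooked indica
#' kernels (no panel range is published for them).
#' @export
GQ_TRAIT_RANGES <- list(
  AC   = c(12, 33),       KL   = c(4.60, 7.7),   KB  = c(1.80, 3.00),
  LBR  = c(1.58, 3.60),   ASV  = c(1, 7),        KLAC = c(6.0, 12.0),
  KBAC = c(2.0, 4.0),     LER  = c(1.02, 1.96),  GC  = c(14.50, 100),
  RS   = c(0.57, 10.00),  PGI  = c(52.91, 99.94))

#' Default subpopulation labels of the panel
#' @export
GQ_SUBPOPS <- c("aro", "aus", "admix", "ind1A", "ind1B", "ind2", "ind3", "indx")

#' Specify a planted QTL
#'
#' @param snp_index Column index (or marker id) of the causal SNP.
#' @param trait One of [GQ_TRAITS].
#' @param target_pve Percent of phenotypic variance the QTL should explain,
#'   in (0, 100); the field's reported marker effects sit in the 10-30 range.
#' @param direction `+1` or `-1`: sign of the alt-allele effect on the trait.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(snp_index, trait, target_pve = 20, direction = 1) {
  stopifnot(trait %in% GQ_TRAITS, target_pve > 0, target_pve < 100,
            direction %in% c(-1, 1))
  structure(list(snp_index = snp_index, trait = trait,
                 target_pve = target_pve, direction = direction),
            class = "qtl_spec")
}

#' Simulation configuration
#'
#' Describes the simulated panel: a structured set of inbred accessions split
#' into subpopulations whose allele frequencies diverge from a common
#' ancestral frequency (Balding-Nichols model), with planted trait QTLs, a
#' kinship-structured polygenic term, and residual noise.
#'
#' @param n_accessions Panel size (default 150).
#' @param n_subpops Number of subpopulations (default 8, labels
#'   [GQ_SUBPOPS]).
#' @param n_snps Number of simulated biallelic SNPs.
#' @param n_chrom Number of pseudo-chromosomes (default 12, the rice karyotype).
#' @param divergence Fst-like scalar in \[0, 1): expected between-subpopulation
#'   variance of allele frequency is `divergence * p * (1 - p)`.  Default 0.15,
#'   of the order of subspecies-level differentiation in rice.
#' @param maf_range Interval in (0, 0.5\] for the ancestral alt-allele
#'   frequency draw (default c(0.05, 0.5)).
#' @param missing_rate Uniform missing-call rate in \[0, 0.2\] (default 0.02).
#' @param het_rate Residual heterozygosity (default 0; inbred panel).
#' @param qtls List of [qtl_spec()] entries.
#' @param h2_poly Polygenic variance fraction in \[0, 1) (default 0.4).
#' @param noise_frac Residual variance fraction; `NULL` (default) sets it to
#'   `1 - h2_poly - sum(pve)/100`.
#' @param trait_ranges Named list of (min, max) per trait
#'   (default [GQ_TRAIT_RANGES]).
#' @param rng_seed Integer seed; fully determines all outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 150, n_subpops = 8, n_snps = 1000,
                       n_chrom = 12, divergence = 0.15,
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       het_rate = 0, qtls = list(), h2_poly = 0.4,
                       noise_frac = NULL,
                       trait_ranges = GQ_TRAIT_RANGES, rng_seed = 1L) {
  stopifnot(n_accessions >= 1, n_subpops >= 1, n_snps >= 1, n_chrom >= 1)
  if (n_subpops > n_accessions) stop("n_subpops cannot exceed n_accessions")
  if (length(maf_range) != 2 || diff(maf_range) < 0 || maf_range[1] <= 0 ||
      maf_range[2] > 0.5)
    stop("maf_range must be an interval within (0, 0.5]")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("missing_rate must be in [0, 0.2]")
  if (het_rate < 0 || het_rate > 1) stop("het_rate must be in [0, 1]")
  if (h2_poly < 0 || h2_poly >= 1) stop("h2_poly must be in [0, 1)")
  for (q in qtls) stopifnot(inherits(q, "qtl_spec"))
  for (tr in unique(vapply(qtls, `[[`, character(1), "trait"))) {
    s <- sum(vapply(qtls, function(q)
      if (q$trait == tr) q$target_pve else 0, numeric(1)))
    if (s >= 100) stop("target PVEs for trait ", tr, " sum to >= 100")
  }
  if (!is.null(noise_frac) && (noise_frac < 0 || noise_frac > 1))
    stop("noise_frac must be in [0, 1]")
  structure(list(n_accessions = n_accessions, n_subpops = n_subpops,
                 n_snps = n_snps, n_chrom = n_chrom, divergence = divergence,
                 maf_range = maf_range, missing_rate = missing_rate,
                 het_rate = het_rate, qtls = qtls, h2_poly = h2_poly,
                 noise_frac = noise_frac, trait_ranges = trait_ranges,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate structured inbred genotypes
#'
#' Ancestral alt-allele frequencies are drawn uniformly from
#' `config$maf_range`; each subpopulation's frequency is then drawn from a
#' Beta distribution with mean `p` and variance `divergence * p * (1 - p)`
#' (Balding-Nichols).  Accessions are split as evenly as possible across
#' subpopulations and genotyped as inbred lines (dosage 0 or 2; heterozygotes
#' at `het_rate` if configured).  Missing calls are masked uniformly at
#' `missing_rate`.  Markers are spread over `n_chrom` pseudo-chromosomes with
#' 1-based positions and ids `S<chrom>_<pos>`.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [geno_matrix()]), `subpops` (named factor
#'   accession -> subpopulation), `p_anc` (ancestral frequencies) and `p_sub`
#'   (subpop x marker frequency matrix).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_accessions; m <- config$n_snps; K <- config$n_subpops
  Fst <- config$divergence

  labels <- if (K <= length(GQ_SUBPOPS)) GQ_SUBPOPS[seq_len(K)] else
    paste0("pop", seq_len(K))
  sub <- factor(labels[rep(seq_len(K), length.out = n)], levels = labels)
  acc <- sprintf("acc%03d", seq_len(n))
  names(sub) <- acc

  # marker map: positions strictly increasing within pseudo-chromosomes
  chrom <- sort(rep(seq_len(config$n_chrom), length.out = m))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(3e7, k))
  }
  ids <- paste0("S", chrom, "_", pos)

  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  p_sub <- matrix(NA_real_, K, m, dimnames = list(labels, ids))
  if (Fst > 0) {
    a <- p_anc * (1 - Fst) / Fst
    b <- (1 - p_anc) * (1 - Fst) / Fst
    for (s in seq_len(K))
      p_sub[s, ] <- stats::rbeta(m, a, b)
  } else {
    p_sub[] <- rep(p_anc, each = K)
  }

  calls <- matrix(NA_integer_, n, m, dimnames = list(acc, ids))
  for (s in seq_len(K)) {
    rows <- which(as.integer(sub) == s)
    draws <- matrix(stats::rbinom(length(rows) * m, 1L, rep(p_sub[s, ],
                    each = length(rows))), length(rows), m)
    calls[rows, ] <- 2L * draws
  }
  if (config$het_rate > 0) {
    het <- matrix(stats::runif(n * m) < config$het_rate, n, m)
    calls[het] <- 1L
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    calls[miss] <- NA_integer_
  }

  markers <- data.frame(id = ids, chrom = as.character(chrom), pos = pos,
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  list(genotypes = geno_matrix(calls, markers), subpops = sub,
       p_anc = stats::setNames(p_anc, ids), p_sub = p_sub)
}

# standardized mean-imputed dosage of one marker
.std_dosage <- function(g) {
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  s <- stats::sd(g)
  if (s == 0) rep(0, length(g)) else (g - mean(g)) / s
}

#' Simulate trait phenotypes with planted QTLs
#'
#' For each trait, a standardized liability is assembled as
#' `sum_j sqrt(v_j) * x_j + sqrt(h2_poly) * u + sqrt(noise_frac) * e`,
#' where `x_j` is the standardized dosage at planted QTL `j`
#' (`v_j = target_pve / 100`), `u` is a polygenic value with covariance
#' proportional to the genomic kinship of the simulated panel, and `e` is
#' iid Gaussian noise.  The liability is affine-mapped so that the trait mean
#' sits at the range midpoint and 3 liability SDs span the half-range, then
#' clamped into the configured range; ASV is additionally rounded to its
#' 1-7 integer score.
#'
#' @param sim Result of [simulate_genotypes()] (or a bare [geno_matrix()]).
#' @param config The same [sim_config()].
#' @return List with `phenotypes` (data.frame: accession + 11 traits) and
#'   `truth` (class `sim_truth`: subpop labels, per-QTL realized PVE computed
#'   from the stored components by regression, polygenic values, component
#'   matrices and affine map per trait).
#' @export
simulate_phenotypes <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  G <- if (inherits(sim, "geno_matrix")) sim else sim$genotypes
  set.seed(config$rng_seed + 1L)
  n <- nrow(G$calls)
  for (q in config$qtls) {
    j <- if (is.character(q$snp_index)) match(q$snp_index, G$markers$id) else q$snp_index
    if (is.na(j) || j < 1 || j > ncol(G$calls))
      stop("QTL snp_index out of range: ", q$snp_index)
  }

  K <- kinship(G)
  eg <- eigen(K, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)

  pheno <- data.frame(accession = G$accessions, stringsAsFactors = FALSE)
  truth_q <- list(); comp <- list(); maps <- list()
  upoly <- matrix(NA_real_, n, length(GQ_TRAITS),
                  dimnames = list(G$accessions, GQ_TRAITS))
  for (tr in GQ_TRAITS) {
    qs <- Filter(function(q) q$trait == tr, config$qtls)
    v_q <- vapply(qs, function(q) q$target_pve / 100, numeric(1))
    vn <- if (is.null(config$noise_frac))
      max(0, 1 - config$h2_poly - sum(v_q)) else config$noise_frac
    qtl_part <- matrix(0, n, length(qs))
    if (length(qs) > 0) for (i in seq_along(qs)) {
      j <- if (is.character(qs[[i]]$snp_index))
        match(qs[[i]]$snp_index, G$markers$id) else qs[[i]]$snp_index
      qtl_part[, i] <- sqrt(v_q[i]) * qs[[i]]$direction *
        .std_dosage(G$calls[, j])
    }
    u <- as.numeric(L %*% stats::rnorm(n))
    if (stats::sd(u) > 0) u <- (u - mean(u)) / stats::sd(u)
    upoly[, tr] <- u
    e <- stats::rnorm(n)
    raw <- rowSums(qtl_part) + sqrt(config$h2_poly) * u + sqrt(vn) * e

    rng <- config$trait_ranges[[tr]]
    mid <- mean(rng); half <- diff(rng) / 2
    y <- mid + raw * half / 3
    y <- pmin(pmax(y, rng[1]), rng[2])
    if (tr == "ASV") y <- round(y)
    pheno[[tr]] <- y

    if (length(qs) > 0) {
      vr <- stats::var(raw)
      truth_q[[tr]] <- data.frame(
        trait = tr,
        snp = vapply(qs, function(q)
          if (is.character(q$snp_index)) q$snp_index else
            G$markers$id[q$snp_index], character(1)),
        target_pve = 100 * v_q,
        realized_pve = vapply(seq_along(qs), function(i)
          100 * stats::var(qtl_part[, i]) / vr, numeric(1)),
        direction = vapply(qs, `[[`, numeric(1), "direction"),
        stringsAsFactors = FALSE)
    }
    comp[[tr]] <- list(qtl = qtl_part, poly = sqrt(config$h2_poly) * u,
                       noise = sqrt(vn) * e)
    maps[[tr]] <- c(intercept = mid, slope = half / 3)
  }
  truth <- structure(
    list(subpops = if (!inherits(sim, "geno_matrix")) sim$subpops else NULL,
         qtls = if (length(truth_q)) do.call(rbind, truth_q) else
           data.frame(trait = character(0), snp = character(0),
                      target_pve = numeric(0), realized_pve = numeric(0),
                      direction = numeric(0)),
         polygenic = upoly, components = comp, affine = maps),
    class = "sim_truth")
  list(phenotypes = pheno, truth = truth)
}

#' Simulate first-order starch-hydrolysis curves
#'
#' Generates glucose time-courses on the standard sampling grid
#' (30, 60, 90, 120, 180 min) from the first-order model: the percent starch
#' hydrolyzed is `Calpha * (1 - exp(-k t))`, and the glucose reading is that
#' percent divided by 0.9 (starch -> glucose mass gain), plus additive
#' Gaussian noise truncated at zero.
#'
#' @param n Number of curves.
#' @param calpha,k Either vectors of length `n`, scalars, or `NULL` to draw
#'   `calpha ~ U(20, 100)` and `k ~ U(0.005, 0.05)`.
#' @param noise_sd SD of the additive glucose noise (default 1, glucose-percent
#'   units; 0 gives exact curves).
#' @param times Sampling grid in minutes.
#' @param include_t0 Prepend a t = 0 point with reading 0.
#' @param rng_seed Integer seed.
#' @return List with `curves` (list of [hydrolysis_curve()]) and `truth`
#'   (data.frame sample, calpha, k).
#' @export
simulate_hydrolysis_curves <- function(n, calpha = NULL, k = NULL,
                                       noise_sd = 1,
                                       times = c(30, 60, 90, 120, 180),
                                       include_t0 = FALSE, rng_seed = 1L) {
  stopifnot(n >= 1, noise_sd >= 0)
  set.seed(as.integer(rng_seed))
  if (is.null(calpha)) calpha <- stats::runif(n, 20, 100)
  if (is.null(k)) k <- stats::runif(n, 0.005, 0.05)
  calpha <- rep_len(calpha, n); k <- rep_len(k, n)
  if (any(calpha <= 0) || any(k <= 0)) stop("calpha and k must be positive")
  tt <- if (include_t0) c(0, times) else times
  ids <- sprintf("sample%03d", seq_len(n))
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    pct <- calpha[i] * (1 - exp(-k[i] * tt))
    glu <- pct / 0.9
    if (noise_sd > 0) glu <- pmax(0, glu + stats::rnorm(length(tt), 0, noise_sd))
    if (include_t0) glu[1] <- 0
    curves[[i]] <- hydrolysis_curve(ids[i], tt, glu, total_starch = 100)
  }
  list(curves = curves,
       truth = data.frame(sample = ids, calpha = calpha, k = k,
                          stringsAsFactors = FALSE))
}

#' Simulate toy gene models and annotation flags
#'
#' Places `n_genes` non-overlapping gene intervals over the simulated marker
#' map (consecutive marker blocks per chromosome, each gene spanning its
#' block with a small margin and one exon covering the span), then flags
#' in-gene markers as exonic-nonsynonymous at `flag_rate`.  The genotype
#' matrix is returned with its `gene`, `exonic` and `nonsyn` marker columns
#' filled in.
#'
#' @param G A [geno_matrix()].
#' @param n_genes Number of genes to place.
#' @param flag_rate Probability an in-gene marker is flagged
#'   nonsynonymous-exonic (default 0.3).
#' @param markers_per_gene Target number of markers per gene block (default 5).
#' @param rng_seed Integer seed.
#' @return List with `models` (a `gene_models`) and `genotypes` (annotated
#'   [geno_matrix()]).
#' @export
simulate_gene_models <- function(G, n_genes, flag_rate = 0.3,
                                 markers_per_gene = 5, rng_seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"), n_genes >= 1,
            flag_rate >= 0, flag_rate <= 1)
  set.seed(as.integer(rng_seed))
  m <- G$markers
  blocks <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    nb <- max(1, floor(length(idx) / markers_per_gene))
    sp <- if (nb == 1) list(idx) else
      split(idx, cut(seq_along(idx), nb, labels = FALSE))
    blocks <- c(blocks, sp)
  }
  if (n_genes > length(blocks))
    stop("cannot place ", n_genes, " non-overlapping genes on this map")
  use <- sort(sample.int(length(blocks), n_genes))
  genes <- exons <- NULL
  m$gene <- NA_character_; m$exonic <- FALSE; m$nonsyn <- FALSE
  for (i in seq_along(use)) {
    idx <- blocks[[use[i]]]
    ch <- m$chrom[idx[1]]
    gid <- sprintf("gene%03d", i)
    span <- c(max(1L, min(m$pos[idx]) - 100L), max(m$pos[idx]) + 100L)
    genes <- rbind(genes, data.frame(
      gene_id = gid, chrom = ch, start = span[1], end = span[2],
      strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(
      gene_id = gid, chrom = ch, start = span[1], end = span[2],
      stringsAsFactors = FALSE))
    m$gene[idx] <- gid
    flag <- stats::runif(length(idx)) < flag_rate
    m$exonic[idx] <- flag
    m$nonsyn[idx] <- flag
  }
  models <- structure(list(genes = genes, exons = exons),
                      class = "gene_models")
  list(models = models, genotypes = geno_matrix(G$calls, m))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d planted QTL(s); %s subpopulation labels\n",
              nrow(x$qtls),
              if (is.null(x$subpops)) "no" else
                length(levels(x$subpops))))
  invisible(x)
}
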