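test_that("kinship equals the hand-computed VanRaden cross-product", {
  set.seed(2)
  calls <- matrix(sample(c(0L, 2L), 5 * 8, TRUE), 5, 8)
  calls[5, ] <- calls[1, ]                    # duplicate accession
  G <- tiny_geno(calls)
  K <- kinship(G)
  # brute-force oracle
  M <- calls; storage.mode(M) <- "double"
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])
  K_oracle <- Z %*% t(Z) / (2 * sum(p[poly] * (1 - p[poly])))
  expect_equal(unname(K), unname(K_oracle), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(K))
  # identical rows: off-diagonal equals each one's diagonal
  expect_equal(K[1, 5], K[1, 1])
  expect_equal(K[1, 5], K[5, 5])
  expect_error(kinship(tiny_geno(matrix(0L, 4, 3))), "monomorphic")
})

test_that("principal components recover strong two-population structure", {
  sc <- sim_config(n_accessions = 60, n_subpops = 2, n_snps = 400,
                   divergence = 0.4, missing_rate = 0, rng_seed = 9)
  gs <- simulate_genotypes(sc)
  Q <- structure_covariates(gs$genotypes, 2)
  r <- cor(Q[, "PC1"], as.integer(gs$subpops))
  expect_gt(abs(r), 0.9)
  expect_error(structure_covariates(gs$genotypes, 0), "positive")
  expect_error(structure_covariates(gs$genotypes, 60), "n_accessions")
})

test_that("without structure the leading PC is no stronger than a permutation null", {
  sc <- sim_config(n_accessions = 60, n_subpops = 1, n_snps = 300,
                   divergence = 0, missing_rate = 0, rng_seed = 10)
  gs <- simulate_genotypes(sc)
  M <- scale(impute_dosage(gs$genotypes), scale = FALSE)
  share <- function(X) { d <- svd(X, nu = 0, nv = 0)$d; d[1]^2 / sum(d^2) }
  set.seed(10)
  Mperm <- apply(M, 2, sample)
  expect_lt(share(M) / share(Mperm), 1.3)
})

test_that("null-model REML matches a dense-matrix oracle and is optimal", {
  set.seed(3)
  panel <- sim_panel(3, n = 60, m = 200)
  K <- kinship(panel$geno$genotypes)
  y <- panel$pheno$RS
  X <- matrix(1, 60, 1)
  fit <- fit_null_mlm(y, X, K)
  # same REML log-likelihood from literal matrix algebra at the optimum
  expect_equal(fit$loglik, oracle_reml_loglik(fit$delta, y, X, K),
               tolerance = 1e-6)
  # optimum beats 50 random variance ratios
  for (d in 10^runif(50, -4, 4))
    expect_gte(fit$loglik, oracle_reml_loglik(d, y, X, K) - 1e-6)
  expect_error(fit_null_mlm(rep(1, 60), X, K), "constant")
})

test_that("with identity kinship the null model collapses to OLS", {
  set.seed(4)
  n <- 50
  y <- rnorm(n)
  Q <- cbind(1, rnorm(n))
  fit <- fit_null_mlm(y, Q, diag(n))
  ols <- lm(y ~ Q - 1)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  # total variance matches the OLS residual variance
  expect_equal(fit$sigma_g2 * (1 + fit$delta), summary(ols)$sigma^2,
               tolerance = 1e-6)
})

test_that("null-model heritability is recovered across replicates", {
  sc <- sim_config(n_accessions = 120, n_snps = 400, missing_rate = 0,
                   rng_seed = 20)
  gs <- simulate_genotypes(sc)
  K <- kinship(gs$genotypes)
  Ks <- K / mean(diag(K))           # unit-scale kinship for a clean h2
  L <- t(chol(Ks + 1e-8 * diag(120)))
  set.seed(20)
  h2hat <- replicate(60, {
    y <- sqrt(0.5) * as.numeric(L %*% rnorm(120)) + sqrt(0.5) * rnorm(120)
    fit_null_mlm(y, K = Ks)$h2
  })
  expect_lt(abs(median(h2hat) - 0.5), 0.1)
})

test_that("scan p-values equal an explicit GLS whitening computation", {
  panel <- sim_panel(30, n = 20, m = 50, qtls = list(qtl_spec(5, "RS", 25, 1)))
  G <- panel$geno$genotypes
  y <- panel$pheno$RS
  Q <- cbind(1, structure_covariates(G, 1)[, -1])
  K <- kinship(G)
  fit <- fit_null_mlm(y, Q, K)
  rec <- scan_mlm(G, y, Q, fit = fit)
  # oracle: whiten by chol(K + delta I), then ordinary regression t-tests
  W <- solve(t(chol(K + fit$delta * diag(20))))
  yw <- W %*% y; Qw <- W %*% Q
  M <- impute_dosage(G)
  for (i in seq_len(nrow(rec))) {
    g <- M[, rec$snp[i]]
    f <- lm(yw ~ cbind(Qw, W %*% g) - 1)
    p_oracle <- summary(f)$coefficients[ncol(Qw) + 1, 4]
    expect_equal(rec$p[i], p_oracle, tolerance = 1e-8)
  }
})

test_that("with identity kinship and no covariates the scan is simple regression", {
  set.seed(6)
  calls <- matrix(sample(c(0L, 2L), 40 * 30, TRUE), 40, 30)
  G <- tiny_geno(calls)
  y <- rnorm(40) + 0.5 * calls[, 3]
  rec <- scan_mlm(G, y, K = diag(40))
  for (i in sample(nrow(rec), 10)) {
    p_lm <- summary(lm(y ~ impute_dosage(G)[, rec$snp[i]]))$coefficients[2, 4]
    expect_equal(rec$p[i], p_lm, tolerance = 1e-8)
  }
})

test_that("scan p-values are invariant to accession order and trait rescaling", {
  panel <- sim_panel(31, n = 40, m = 80)
  G <- panel$geno$genotypes
  y <- panel$pheno$AC
  K <- kinship(G)
  rec1 <- scan_mlm(G, y, K = K)
  rec2 <- scan_mlm(G, 3.7 * y - 11, K = K)
  expect_equal(rec1$p, rec2$p, tolerance = 1e-6)
  expect_equal(rec1$pve, rec2$pve, tolerance = 1e-6)
  perm <- sample(40)
  Gp <- geno_matrix(G$calls[perm, ], G$markers)
  rec3 <- scan_mlm(Gp, y[perm], K = K[perm, perm])
  expect_equal(rec1$p, rec3$p, tolerance = 1e-6)
})

test_that("a marker collinear with a covariate is reported with p = 1", {
  set.seed(7)
  calls <- matrix(sample(c(0L, 2L), 30 * 5, TRUE), 30, 5)
  G <- tiny_geno(calls)
  y <- rnorm(30)
  Q <- cbind(1, calls[, 2])          # covariate duplicates marker 2
  rec <- scan_mlm(G, y, Q, K = diag(30))
  expect_equal(rec$p[rec$snp == G$markers$id[2]], 1)
  expect_equal(rec$beta[rec$snp == G$markers$id[2]], 0)
})

test_that("PVE follows its definition and invariances", {
  set.seed(8)
  g <- sample(c(0, 2), 100, TRUE)
  y <- 0.8 * g + rnorm(100)
  b <- coef(lm(y ~ g))[2]
  expect_equal(pve_of_snp(b, g, y), unname(100 * b^2 * var(g) / var(y)))
  expect_equal(pve_of_snp(0, g, y), 0)
  expect_equal(pve_of_snp(b / 5, g, y * 0.2 + 3), pve_of_snp(b, g, y))
  expect_error(pve_of_snp(1, g, rep(2, 100)), "variance")
})

test_that("suggestive threshold is strict at -log10 p = 5", {
  rec <- data.frame(snp = c("a", "b", "c"), chrom = "1", pos = c(1, 2, 3) * 1e6,
                    beta = 1, se = 1, p = c(1e-6, 1e-4, 1e-5),
                    neglog10p = c(6, 4, 5), pve = 10)
  out <- suggestive_mtas(rec)
  expect_equal(out$snp, "a")
})

test_that("peak grouping keeps the smallest p per window", {
  rec <- data.frame(snp = paste0("s", 1:4), chrom = c("1", "1", "1", "2"),
                    pos = c(1e6, 1.5e6, 9e6, 1e6), beta = 1, se = 1,
                    p = c(1e-7, 1e-9, 1e-6, 1e-8),
                    neglog10p = c(7, 9, 6, 8), pve = 10)
  out <- suggestive_mtas(rec, peak_window = 1e6)
  expect_setequal(out$snp, c("s2", "s3", "s4"))
})

test_that("single-marker LOD equals the direct likelihood-ratio identity", {
  set.seed(9)
  n <- 50
  calls <- matrix(sample(c(0L, 2L), n * 3, TRUE), n, 3)
  G <- tiny_geno(calls)
  y <- rnorm(n) + 0.7 * calls[, 1]
  res <- lod_confirm(G, y, K = diag(n), candidates = G$markers$id[1])
  # identity kinship: whitening is a scalar, so RSS ratios match plain lm
  rss0 <- sum(resid(lm(y ~ 1))^2)
  rss1 <- sum(resid(lm(y ~ calls[, 1]))^2)
  expect_equal(res$lod, n / 2 * log10(rss0 / rss1), tolerance = 1e-8)
  expect_true(res$retained)
})

test_that("allele effects follow carrier-mean-minus-grand-mean arithmetic", {
  # balanced two-class algebra: a1 = (m1 - m2) / 2 = -a2
  g <- c(0, 0, 0, 2, 2, 2)
  y <- c(10, 11, 12, 16, 17, 18)
  ae <- allele_effect_ai(g, y, "AC", alleles = c("A", "G"))
  m1 <- mean(y[1:3]); m2 <- mean(y[4:6])
  expect_equal(unname(ae$effects["A"]), (m1 - m2) / 2)
  expect_equal(unname(ae$effects["G"]), (m2 - m1) / 2)
  expect_equal(ae$favorable, "G")   # AC: increase favorable
  # 6-accession toy, unbalanced, brute-force group means
  g2 <- c(0, 0, 2, 2, 2, 2)
  y2 <- c(5, 7, 1, 2, 3, 2)
  ae2 <- allele_effect_ai(g2, y2, "PGI", alleles = c("A", "G"))
  expect_equal(unname(ae2$effects["A"]), mean(y2[1:2]) - mean(y2))
  expect_equal(unname(ae2$effects["G"]), mean(y2[3:6]) - mean(y2))
  # PGI decrease is favorable: negative-effect allele wins
  expect_equal(ae2$favorable, "G")
  expect_lt(ae2$favorable_effect, 0)
  expect_error(allele_effect_ai(rep(2, 6), y2, "PGI"), "monomorphic")
})

test_that("candidate genes: containment beats flanking; oracle agreement", {
  models <- structure(list(
    genes = data.frame(gene_id = c("g1", "g2", "g3"), chrom = "1",
                       start = c(1000L, 5000L, 9000L),
                       end = c(2000L, 6000L, 9500L), strand = "+",
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = character(0), chrom = character(0),
                       start = integer(0), end = integer(0))),
    class = "gene_models")
  inside <- assign_candidate_genes("1", 1500, models)
  expect_equal(inside$gene_id, "g1")
  expect_equal(inside$relation, "within")
  between <- assign_candidate_genes("1", 4000, models)
  expect_setequal(between$gene_id, c("g1", "g2"))
  expect_setequal(between$relation, c("upstream", "downstream"))
  expect_equal(sort(between$distance), c(1000L, 2000L))
  expect_error(assign_candidate_genes("7", 100, models), "no gene")
  # 50 random placements vs brute-force nearest-interval scan
  set.seed(10)
  for (pos in sample(1:12000, 50)) {
    got <- assign_candidate_genes("1", pos, models)
    inside <- which(models$genes$start <= pos & models$genes$end >= pos)
    if (length(inside)) {
      expect_equal(got$gene_id, models$genes$gene_id[inside])
    } else {
      exp_g <- character(0)
      left <- which(models$genes$end < pos)
      if (length(left)) exp_g <- c(exp_g, models$genes$gene_id[
        left[which.min(pos - models$genes$end[left])]])
      right <- which(models$genes$start > pos)
      if (length(right)) exp_g <- c(exp_g, models$genes$gene_id[
        right[which.min(models$genes$start[right] - pos)]])
      expect_setequal(got$gene_id, exp_g)
    }
  }
})

test_that("structure inflates a naive scan; the mixed model deflates it", {
  lambda <- function(p) median(qchisq(1 - p, 1)) / qchisq(0.5, 1)
  lam <- sapply(1:3, function(seed) {
    sc <- sim_config(n_accessions = 150, n_subpops = 3, n_snps = 800,
                     divergence = 0.3, h2_poly = 0.6, missing_rate = 0,
                     rng_seed = seed)
    gs <- simulate_genotypes(sc)
    ph <- simulate_phenotypes(gs, sc)
    G <- gs$genotypes
    y <- ph$phenotypes$GC
    naive <- scan_mlm(G, y, K = diag(150))
    corr <- scan_mlm_loco(G, y, structure_covariates(G, 3))
    c(naive = lambda(naive$p), corrected = lambda(corr$p))
  })
  expect_true(all(lam["naive", ] > 1.1))
  expect_gte(median(lam["corrected", ]), 0.9)
  expect_lte(median(lam["corrected", ]), 1.1)
})

test_that("end-to-end MTA calling recovers a strong planted QTL", {
  panel <- sim_panel(44, n = 150, m = 400,
                     qtls = list(qtl_spec(100, "RS", 25, 1)))
  G <- panel$geno$genotypes
  Q <- structure_covariates(G, 3)
  K <- kinship(G)
  res <- call_mtas(G, panel$pheno$RS, "RS", Q, K)
  expect_gt(nrow(res$mtas), 0)
  top <- res$mtas[which.max(res$mtas$neglog10p), ]
  expect_equal(top$snp, G$markers$id[100])
  expect_gt(top$lod, 3)
  expect_true(top$confirmed)
  expect_equal(top$favorable_allele, G$markers$alt[100])  # RS up, direction +
})
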