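# Shared fixtures and independent oracles used across test files.

# small deterministic genotype matrix built by hand
tiny_geno <- function(calls, chrom = NULL, pos = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = m)
  geno_matrix(calls, data.frame(
    id = paste0("S", chrom, "_", pos), chrom = chrom, pos = pos,
    ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# brute-force row grouping oracle: haplotype counts by exact string match
oracle_group_rows <- function(mat) {
  keep <- rowSums(is.na(mat)) == 0
  pat <- apply(mat[keep, , drop = FALSE], 1, paste, collapse = "/")
  sort(as.integer(table(pat)), decreasing = TRUE)
}

# independent Duncan oracle: literal textbook procedure.  Pairwise shortest
# significant ranges with protection (a pair inside a non-significant
# stretch is never significant), then greedy letter construction scanning
# means in descending order.
oracle_duncan <- function(means, n, mse, dfe, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; nn <- n[ord]
  rp <- function(p, nh) qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, dfe) *
    sqrt(mse / nh)
  # step 1: test every ordered pair by its spanned range
  sig <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    p <- j - i + 1
    nh <- p / sum(1 / nn[i:j])
    sig[i, j] <- (m[i] - m[j]) >= rp(p, nh)
  }
  # step 2: protection — clear significance inside any non-significant span
  repeat {
    changed <- FALSE
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (!sig[i, j]) {
        inner <- sig[i:j, i:j]
        if (any(inner)) { sig[i:j, i:j] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  # step 3: letters from maximal non-significant stretches (after the
  # protection pass, non-significance is interval-consistent)
  lets <- rep("", k)
  lab <- 0; last_end <- 0
  for (i in 1:k) {
    j <- i
    while (j < k && !sig[i, j + 1]) j <- j + 1
    if (j > last_end || i == 1) {
      lab <- lab + 1
      lets[i:j] <- paste0(lets[i:j], letters[lab])
      last_end <- j
    }
  }
  data.frame(group = names(m), letters = lets, stringsAsFactors = FALSE)
}

# dense REML log-likelihood by literal matrix algebra (oracle for the
# eigendecomposition-based fit)
oracle_reml_loglik <- function(delta, y, X, K) {
  n <- length(y); q <- ncol(X)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sg2 <- as.numeric(t(r) %*% Vi %*% r) / (n - q)
  as.numeric(-0.5 * ((n - q) * log(2 * pi * sg2) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus -
                       determinant(crossprod(X), logarithm = TRUE)$modulus +
                       (n - q)))
}

# quick structured simulation for GWAS-level tests
sim_panel <- function(seed, n = 150, m = 600, qtls = list(), h2 = 0.4,
                      divergence = 0.15, missing_rate = 0) {
  sc <- sim_config(n_accessions = n, n_snps = m, divergence = divergence,
                   missing_rate = missing_rate, qtls = qtls, h2_poly = h2,
                   rng_seed = seed)
  gs <- simulate_genotypes(sc)
  ph <- simulate_phenotypes(gs, sc)
  list(config = sc, geno = gs, pheno = ph$phenotypes, truth = ph$truth)
}
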