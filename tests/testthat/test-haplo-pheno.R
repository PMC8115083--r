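make_pheno <- function(acc, trait, values) {
  df <- data.frame(accession = acc, stringsAsFactors = FALSE)
  df[[trait]] <- values
  df
}

test_that("gene-variant extraction honors span and annotation flags", {
  calls <- matrix(sample(c(0L, 2L), 10 * 6, TRUE), 10, 6)
  markers <- data.frame(
    id = paste0("S1_", c(50, 150, 250, 350, 450, 550)),
    chrom = "1", pos = c(50L, 150L, 250L, 350L, 450L, 550L),
    ref = "A", alt = "G",
    exonic = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    nonsyn = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    indel = FALSE, gene = NA_character_, stringsAsFactors = FALSE)
  G <- geno_matrix(calls, markers)
  models <- structure(list(
    genes = data.frame(gene_id = "gX", chrom = "1", start = 100L, end = 500L,
                       strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "gX", chrom = "1", start = 100L, end = 500L)),
    class = "gene_models")
  sub <- extract_gene_variants(G, models, "gX")
  # 3 flagged in-span columns; flagged S1_550 is 50 bp past the span: excluded
  expect_equal(colnames(sub), paste0("S1_", c(150, 250, 450)))
  # boundary: flagged variant 1 bp outside the span is excluded
  models$genes$end <- 449L
  expect_equal(colnames(extract_gene_variants(G, models, "gX")),
               paste0("S1_", c(150, 250)))
  expect_error(extract_gene_variants(G, models, "nope"), "not in models")
})

test_that("haplotype calling groups identical rows exactly", {
  sub <- matrix(0L, 5, 2, dimnames = list(paste0("a", 1:5), c("m1", "m2")))
  asg <- call_haplotypes(sub)
  expect_equal(length(asg$patterns), 1L)
  expect_equal(unname(asg$haplotype), rep("H1", 5))
  expect_equal(haplotype_frequencies(asg)$freq_pct, 100)

  # all four patterns of 2 biallelic SNPs
  sub4 <- rbind(c(0L, 0L), c(0L, 2L), c(2L, 0L), c(2L, 2L),
                c(0L, 0L), c(0L, 0L), c(2L, 2L))
  rownames(sub4) <- paste0("x", 1:7)
  asg4 <- call_haplotypes(sub4)
  expect_equal(length(asg4$patterns), 4L)
  expect_equal(sort(as.integer(table(asg4$haplotype)), decreasing = TRUE),
               oracle_group_rows(sub4))
  expect_equal(unname(asg4$haplotype["x1"]), "H1")  # most frequent pattern
})

test_that("haplotype calling matches the string-grouping oracle on random data", {
  set.seed(12)
  for (rep in 1:20) {
    sub <- matrix(sample(c(0L, 2L, NA), 30 * 4, TRUE, c(0.5, 0.4, 0.1)), 30, 4,
                  dimnames = list(sprintf("a%02d", 1:30), paste0("m", 1:4)))
    asg <- call_haplotypes(sub)
    expect_equal(sort(as.integer(table(asg$haplotype)), decreasing = TRUE),
                 oracle_group_rows(sub))
    # missing calls excluded with reason
    expect_setequal(asg$excluded$accession,
                    rownames(sub)[rowSums(is.na(sub)) > 0])
    # relabeling accessions permutes but never changes counts
    perm <- sample(30)
    asg_p <- call_haplotypes(sub[perm, ])
    expect_equal(sort(as.integer(table(asg_p$haplotype))),
                 sort(as.integer(table(asg$haplotype))))
  }
})

test_that("labels are ordered by descending frequency from H1", {
  sub <- rbind(matrix(2L, 3, 1), matrix(0L, 10, 1))
  rownames(sub) <- paste0("a", 1:13)
  asg <- call_haplotypes(sub)
  fr <- haplotype_frequencies(asg)
  expect_equal(fr$haplotype, c("H1", "H2"))
  expect_true(all(diff(fr$freq_pct) <= 0))
  expect_equal(fr$n, c(10L, 3L))
})

test_that("frequency arithmetic reproduces the published 57.33% split", {
  sub <- matrix(0L, 150, 1, dimnames = list(sprintf("a%03d", 1:150), "m"))
  sub[87:126] <- 2L          # 40 accessions
  sub[127:150] <- 1L         # 24 accessions
  asg <- call_haplotypes(sub)
  fr <- haplotype_frequencies(asg)
  expect_equal(fr$n, c(86L, 40L, 24L))
  expect_equal(round(fr$freq_pct, 2), c(57.33, 26.67, 16.00))
  expect_equal(sum(fr$freq_pct), 100)
  # uniform split
  sub2 <- matrix(c(rep(0L, 5), rep(2L, 5)), 10, 1,
                 dimnames = list(paste0("b", 1:10), "m"))
  expect_equal(haplotype_frequencies(call_haplotypes(sub2))$freq_pct, c(50, 50))
})

test_that("Duncan letters: degenerate separations behave", {
  d_same <- duncan_mrt(c(A = 10, B = 10), n = c(8, 8), mse = 4, df_error = 14)
  expect_equal(d_same$letters, c("a", "a"))
  d_far <- duncan_mrt(c(A = 0, B = 100), n = c(10, 10), mse = 1, df_error = 18)
  expect_false(d_far$letters[1] == d_far$letters[2])
  expect_error(duncan_mrt(c(1, 2), n = c(3, 3), mse = 0, df_error = 4))
})

test_that("Duncan letters match the balanced textbook worked example", {
  # 5 treatments, n = 5 each, MSE = 8.06, df = 20 (cotton-strength design):
  # top mean separates alone; middle pair shares; bottom pair shares.
  means <- c(t15 = 9.8, t20 = 15.4, t25 = 17.6, t30 = 21.6, t35 = 10.8)
  sizes <- rep(5, 5)
  d <- duncan_mrt(means, sizes, mse = 8.06, df_error = 20)
  expect_equal(d$group, c("t30", "t25", "t20", "t35", "t15"))
  expect_equal(d$letters, c("a", "b", "b", "c", "c"))
  # and the independent oracle agrees
  o <- oracle_duncan(means, sizes, mse = 8.06, dfe = 20)
  expect_equal(d$letters, o$letters)
})

test_that("Duncan letters match the independent oracle on random designs", {
  set.seed(14)
  for (rep in 1:25) {
    k <- sample(3:7, 1)
    means <- rnorm(k, 20, 3)
    names(means) <- paste0("g", seq_len(k))
    sizes <- sample(4:20, k, TRUE)
    mse <- runif(1, 0.5, 15)
    dfe <- sum(sizes) - k
    d <- duncan_mrt(means, sizes, mse, dfe)
    o <- oracle_duncan(means, sizes, mse, dfe)
    expect_equal(d$letters, o$letters, label = paste("rep", rep))
  }
})

test_that("haplo-pheno table applies the >= 2-line rule and ANOVA", {
  set.seed(15)
  acc <- sprintf("a%02d", 1:41)
  sub <- matrix(0L, 41, 2, dimnames = list(acc, c("m1", "m2")))
  sub[21:40, 1] <- 2L
  sub[41, ] <- c(2L, 2L)     # singleton haplotype
  asg <- call_haplotypes(sub)
  y <- c(rnorm(20, 10), rnorm(20, 14), 99)
  hp <- haplo_pheno_table(asg, make_pheno(acc, "RS", y), "RS")
  expect_equal(nrow(hp$table), 3)
  singleton <- hp$table[hp$table$n == 1, ]
  expect_false(singleton$tested)          # listed but untested
  expect_equal(singleton$mean, 99)
  expect_true(is.na(singleton$letters))
  expect_true(all(!is.na(hp$table$letters[hp$table$tested])))
  expect_lt(hp$anova$p, 0.01)
  # fewer than 2 testable haplotypes -> notice, no letters
  asg1 <- call_haplotypes(matrix(0L, 5, 1, dimnames = list(acc[1:5], "m")))
  hp1 <- haplo_pheno_table(asg1, make_pheno(acc[1:5], "RS", rnorm(5)), "RS")
  expect_false(is.null(hp1$note))
})

test_that("ANOVA false-positive rate is near nominal under the null", {
  set.seed(16)
  acc <- sprintf("a%02d", 1:30)
  sub <- matrix(0L, 30, 1, dimnames = list(acc, "m"))
  sub[11:20] <- 1L; sub[21:30] <- 2L
  asg <- call_haplotypes(sub)
  hits <- replicate(400, {
    hp <- haplo_pheno_table(asg, make_pheno(acc, "RS", rnorm(30)), "RS")
    hp$anova$p < 0.05
  })
  ci <- 2.58 * sqrt(0.05 * 0.95 / 400)
  expect_gt(mean(hits), 0.05 - ci)
  expect_lt(mean(hits), 0.05 + ci)
})

test_that("a 3-SD shifted haplotype earns an exclusive top letter", {
  set.seed(17)
  acc <- sprintf("a%02d", 1:60)
  sub <- matrix(0L, 60, 2, dimnames = list(acc, c("m1", "m2")))
  sub[21:40, 1] <- 2L; sub[41:60, 2] <- 2L
  asg <- call_haplotypes(sub)
  y <- c(rnorm(20, 10), rnorm(20, 10), rnorm(20, 13))  # 3 within-group SDs
  hp <- haplo_pheno_table(asg, make_pheno(acc, "RS", y), "RS")
  top <- hp$table[which.max(hp$table$mean), ]
  others <- setdiff(hp$table$letters[hp$table$tested], top$letters)
  expect_false(any(strsplit(top$letters, "")[[1]] %in%
                     unlist(strsplit(others, ""))))
})

test_that("superior haplotype follows trait direction and published anchors", {
  # high RS is favorable: H4 (3.28) beats H1/H2/H3 as in the published table
  tab_rs <- data.frame(haplotype = paste0("H", 1:4), n = c(48, 10, 5, 48),
                       freq_pct = c(43, 9, 5, 43),
                       mean = c(3.06, 2.42, 2.85, 3.28), sd = 1,
                       tested = TRUE, letters = c("a", "c", "ab", "a"))
  hp_rs <- structure(list(table = tab_rs, anova = list(p = 0.01),
                          trait = "RS", note = NULL),
                     class = "haplo_pheno_table")
  expect_equal(superior_haplotype(hp_rs)$haplotype, "H4")
  # low PGI is favorable: 62.52 beats 71.67
  tab_pgi <- data.frame(haplotype = c("H13", "H14"), n = c(5, 7),
                        freq_pct = c(40, 60), mean = c(62.52, 71.67), sd = 1,
                        tested = TRUE, letters = c("a", "b"))
  hp_pgi <- structure(list(table = tab_pgi, anova = list(p = 0.01),
                           trait = "PGI", note = NULL),
                      class = "haplo_pheno_table")
  expect_equal(superior_haplotype(hp_pgi)$haplotype, "H13")
  # all means equal: tie breaks to larger n then lower index, not separated
  tab_tie <- data.frame(haplotype = paste0("H", 1:3), n = c(5, 9, 9),
                        freq_pct = c(20, 40, 40), mean = c(2, 2, 2), sd = 1,
                        tested = TRUE, letters = "a")
  hp_tie <- structure(list(table = tab_tie, anova = list(p = 0.9),
                           trait = "RS", note = NULL),
                      class = "haplo_pheno_table")
  sup <- superior_haplotype(hp_tie)
  expect_equal(sup$haplotype, "H2")
  expect_false(sup$separated)
})

test_that("donor lookup equals brute-force accession filtering", {
  set.seed(18)
  sub <- matrix(sample(c(0L, 2L), 40, TRUE), 40, 1,
                dimnames = list(sprintf("a%02d", 1:40), "m"))
  asg <- call_haplotypes(sub)
  for (h in names(asg$patterns))
    expect_setequal(haplotype_donors(asg, h),
                    names(asg$haplotype)[asg$haplotype == h])
})
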