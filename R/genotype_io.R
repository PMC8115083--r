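#' Genotype matrix container
#'
#' Holds biallelic genotype calls for a panel of accessions.  Calls are coded
#' as alt-allele dosage: 0 = homozygous reference, 2 = homozygous alternative,
#' 1 = heterozygous (rare in an inbred panel), `NA` = missing.  Marker
#' metadata carries 1-based positions and optional functional annotation
#' flags used by gene-level haplotype calling.
#'
#' @param calls Integer matrix, accessions x markers, values in
#'   `{0, 1, 2, NA}`; rownames are accession ids, colnames marker ids.
#' @param markers `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optional logical `exonic`, `nonsyn`, `indel` and
#'   character `gene` columns.
#' @return Object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(ncol(calls) == nrow(markers))
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(markers$id)) stop("marker ids must be unique")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("acc", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls))) stop("accession ids must be unique")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  bad <- calls[!is.na(calls)]
  if (any(!bad %in% c(0L, 1L, 2L))) stop("calls must be 0, 1, 2 or NA")
  for (fl in c("exonic", "nonsyn", "indel"))
    if (is.null(markers[[fl]])) markers[[fl]] <- FALSE
  if (is.null(markers$gene)) markers$gene <- NA_character_
  colnames(calls) <- markers$id
  structure(list(calls = calls, markers = markers,
                 accessions = rownames(calls)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d accessions x %d markers on %d chromosome(s); %.1f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$markers$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Alternative-allele frequencies of a genotype matrix
#'
#' Per-marker alt-allele frequency over non-missing calls (dosage sum over
#' 2 x calls observed).  Markers with no observed calls yield `NA`.
#' @param G A [geno_matrix()].
#' @return Named numeric vector.
#' @export
alt_freq <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  nn <- colSums(!is.na(G$calls))
  f <- colSums(G$calls, na.rm = TRUE) / (2 * nn)
  f[nn == 0] <- NA_real_
  f
}

#' Per-marker missing-call fraction
#' @param G A [geno_matrix()].
#' @return Named numeric vector in \[0, 1\].
#' @export
missing_rate <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  colMeans(is.na(G$calls))
}

#' Apply the panel SNP quality filters
#'
#' Keeps markers whose alternative-allele frequency is at least `maf_min`
#' and whose missing-call fraction is at most `missing_max` — the filters
#' that define the "3kfiltered" style SNP set.  Frequency is computed over
#' non-missing calls.  "Alternative" is taken literally; set
#' `freq = "minor"` to filter on minor-allele frequency instead.
#'
#' @param G A [geno_matrix()].
#' @param maf_min Minimum retained allele frequency (default 0.01).
#' @param missing_max Maximum retained missing fraction (default 0.2).
#' @param freq `"alt"` (default) or `"minor"`.
#' @return List with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (class `qc_report`: n_input, n_pass, n_fail_maf, n_fail_missing and the
#'   thresholds).  A marker failing both filters is attributed to the
#'   frequency rule (the first rule).
#' @export
filter_snps <- function(G, maf_min = 0.01, missing_max = 0.2,
                        freq = c("alt", "minor")) {
  freq <- match.arg(freq)
  stopifnot(inherits(G, "geno_matrix"), ncol(G$calls) > 0)
  f <- alt_freq(G)
  if (freq == "minor") f <- pmin(f, 1 - f)
  miss <- missing_rate(G)
  fail_maf <- is.na(f) | f < maf_min
  fail_miss <- !fail_maf & miss > missing_max
  keep <- !fail_maf & !fail_miss
  if (!any(keep)) warning("all markers removed by QC filters")
  out <- geno_matrix(G$calls[, keep, drop = FALSE],
                     G$markers[keep, , drop = FALSE])
  report <- structure(
    list(n_input = ncol(G$calls), n_pass = sum(keep),
         n_fail_maf = sum(fail_maf), n_fail_missing = sum(fail_miss),
         thresholds = list(maf_min = maf_min, missing_max = missing_max,
                           freq = freq)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d markers in, %d pass (%d fail freq<%g, %d fail missing>%g)\n",
              x$n_input, x$n_pass, x$n_fail_maf, x$thresholds$maf_min,
              x$n_fail_missing, x$thresholds$missing_max))
  invisible(x)
}

.gt_code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
              "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)

#' Read a genotype matrix from VCF or HapMap-style TSV
#'
#' VCF is parsed with VariantAnnotation; phased and unphased GT calls are
#' treated identically; multi-allelic sites are dropped and counted.
#' Functional annotation arrives through the INFO flags `EXONIC`, `NONSYN`,
#' `INDEL` and the string field `GENE` when present.  The HapMap-like TSV has
#' columns `rs`, `chrom`, `pos`, `alleles` (ref/alt) followed by one
#' two-letter genotype column per accession (`NN` = missing).
#'
#' @param path Input file.
#' @param format `"vcf"` or `"hapmap"`.
#' @return A [geno_matrix()]; the number of dropped multi-allelic sites is
#'   attached as attribute `n_multiallelic`.
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap")) {
  format <- match.arg(format)
  if (format == "vcf") .read_vcf(path) else .read_hapmap(path)
}

.read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- nalt != 1
  n_multi <- sum(multi)
  if (n_multi > 0) vcf <- vcf[!multi]
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  auto <- is.null(ids) | is.na(ids) | ids == "." | ids == ""
  gen_ids <- paste0("S", chrom, "_", pos)
  if (is.null(ids)) ids <- gen_ids else ids[auto] <- gen_ids[auto]
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  info <- VariantAnnotation::info(vcf)
  getflag <- function(nm) if (nm %in% names(info)) as.logical(info[[nm]]) else
    rep(FALSE, length(ids))
  gene <- if ("GENE" %in% names(info)) as.character(info$GENE) else
    rep(NA_character_, length(ids))
  markers <- data.frame(id = ids, chrom = chrom, pos = pos, ref = ref,
                        alt = alt, exonic = getflag("EXONIC"),
                        nonsyn = getflag("NONSYN"), indel = getflag("INDEL"),
                        gene = gene, stringsAsFactors = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT   # markers x accessions
  calls <- matrix(.gt_code[gt], nrow = nrow(gt))
  bad <- !is.na(gt) & gt != "./." & gt != ".|." & gt != "." & is.na(calls)
  if (any(bad))
    stop("unparseable GT value(s), e.g. '", gt[which(bad)[1]], "' at record ",
         which(rowSums(bad) > 0)[1])
  calls <- t(calls)
  rownames(calls) <- colnames(gt)
  out <- geno_matrix(calls, markers)
  attr(out, "n_multiallelic") <- n_multi
  out
}

.read_hapmap <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, sep = "\t")
  need <- c("rs", "chrom", "pos", "alleles")
  if (!all(need %in% names(df)))
    stop("hapmap TSV must have columns: ", paste(need, collapse = ", "))
  acc <- setdiff(names(df), need)
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  if (any(lengths(al) != 2)) {
    i <- which(lengths(al) != 2)[1]
    stop("malformed alleles field at line ", i + 1, ": '", df$alleles[i], "'")
  }
  ref <- vapply(al, `[`, character(1), 1)
  alt <- vapply(al, `[`, character(1), 2)
  m <- nrow(df)
  calls <- matrix(NA_integer_, length(acc), m,
                  dimnames = list(acc, df$rs))
  for (j in seq_len(m)) {
    g <- as.character(df[j, acc])
    code <- rep(NA_integer_, length(g))
    code[g == paste0(ref[j], ref[j])] <- 0L
    code[g == paste0(alt[j], alt[j])] <- 2L
    code[g %in% c(paste0(ref[j], alt[j]), paste0(alt[j], ref[j]))] <- 1L
    bad <- !(g %in% c("NN", "--")) & is.na(code)
    if (any(bad))
      stop("unparseable genotype '", g[which(bad)[1]], "' at line ", j + 1)
    calls[, j] <- code
  }
  markers <- data.frame(id = df$rs, chrom = as.character(df$chrom),
                        pos = df$pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  out <- geno_matrix(calls, markers)
  attr(out, "n_multiallelic") <- 0L
  out
}

#' Write a genotype matrix
#'
#' `write_vcf_genotypes` writes a minimal VCF v4.2 with GT calls and the
#' annotation INFO flags; `write_hapmap_genotypes` writes the HapMap-like
#' TSV.  Both round-trip through [read_genotypes()] bit-exactly.
#'
#' @param G A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  m <- G$markers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ricegq",
    vapply(unique(m$chrom), function(ch)
      sprintf("##contig=<ID=%s,length=%d>", ch,
              max(m$pos[m$chrom == ch]) + 1000L), character(1)),
    "##INFO=<ID=EXONIC,Number=0,Type=Flag,Description=\"Variant in an exon\">",
    "##INFO=<ID=NONSYN,Number=0,Type=Flag,Description=\"Nonsynonymous variant\">",
    "##INFO=<ID=INDEL,Number=0,Type=Flag,Description=\"Insertion/deletion\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Containing gene id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$accessions), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(m))) {
    info <- c(if (isTRUE(m$exonic[j])) "EXONIC",
              if (isTRUE(m$nonsyn[j])) "NONSYN",
              if (isTRUE(m$indel[j])) "INDEL",
              if (!is.na(m$gene[j])) paste0("GENE=", m$gene[j]))
    info <- if (length(info)) paste(info, collapse = ";") else "."
    g <- G$calls[, j]
    gs <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    writeLines(paste(c(m$chrom[j], m$pos[j], m$id[j], m$ref[j], m$alt[j],
                       ".", "PASS", info, "GT", gs), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf_genotypes
#' @export
write_hapmap_genotypes <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  m <- G$markers
  gmat <- vapply(seq_len(nrow(m)), function(j) {
    g <- G$calls[, j]
    out <- rep("NN", length(g))
    out[!is.na(g) & g == 0L] <- paste0(m$ref[j], m$ref[j])
    out[!is.na(g) & g == 1L] <- paste0(m$ref[j], m$alt[j])
    out[!is.na(g) & g == 2L] <- paste0(m$alt[j], m$alt[j])
    out
  }, character(nrow(G$calls)))
  df <- data.frame(rs = m$id, chrom = m$chrom, pos = m$pos,
                   alleles = paste0(m$ref, "/", m$alt),
                   t(gmat), stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df)[-(1:4)] <- G$accessions
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features (other feature types are ignored) with
#' 1-based inclusive coordinates.  Exons are linked to genes via their
#' `Parent` attribute; an exon extending outside its gene span is an error.
#'
#' @param path GFF3 file.
#' @return Object of class `gene_models`: list with `genes`
#'   (data.frame gene_id, chrom, start, end, strand) and `exons`
#'   (data.frame gene_id, chrom, start, end).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  gg <- gr[typ == "gene"]
  ee <- gr[typ == "exon"]
  if (length(gg) == 0) stop("no gene features in ", path)
  gid <- gg$ID
  if (is.null(gid) || any(is.na(gid))) stop("gene features must carry ID attributes")
  genes <- data.frame(gene_id = as.character(gid),
                      chrom = as.character(GenomicRanges::seqnames(gg)),
                      start = GenomicRanges::start(gg),
                      end = GenomicRanges::end(gg),
                      strand = as.character(GenomicRanges::strand(gg)),
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  if (length(ee) > 0) {
    par <- vapply(as.list(ee$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    exons <- data.frame(gene_id = par,
                        chrom = as.character(GenomicRanges::seqnames(ee)),
                        start = GenomicRanges::start(ee),
                        end = GenomicRanges::end(ee),
                        stringsAsFactors = FALSE)
    gi <- match(exons$gene_id, genes$gene_id)
    if (any(is.na(gi))) stop("exon with unknown Parent gene")
    if (any(exons$start < genes$start[gi] | exons$end > genes$end[gi]))
      stop("exon outside its gene span")
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Write gene models as GFF3
#' @param models A `gene_models` object.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes; e <- models$exons
  lines <- c("##gff-version 3",
             sprintf("%s\tricegq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     g$chrom, g$start, g$end, g$strand, g$gene_id))
  if (nrow(e) > 0) {
    st <- g$strand[match(e$gene_id, g$gene_id)]
    lines <- c(lines,
               sprintf("%s\tricegq\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                       e$chrom, e$start, e$end, st, e$gene_id,
                       stats::ave(seq_len(nrow(e)), e$gene_id, FUN = seq_along),
                       e$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Markers overlapping a gene (or any interval set)
#'
#' 1-based inclusive interval membership of marker positions in gene spans,
#' computed with IRanges.
#' @param G A [geno_matrix()].
#' @param models A `gene_models` object.
#' @param gene_id Gene to query.
#' @return Character vector of marker ids inside the gene span.
#' @export
markers_in_gene <- function(G, models, gene_id) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(g) == 0) stop("gene '", gene_id, "' not found")
  m <- G$markers
  sel <- m$chrom == g$chrom & m$pos >= g$start & m$pos <= g$end
  m$id[sel]
}
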