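#' Build a pipeline run configuration
#'
#' One configuration object drives all pipeline stages.  Thresholds default
#' to the published analysis settings: suggestive `-log10(p) > 5`,
#' multi-locus `LOD > 3`, SNP filters alt-frequency `>= 0.01` and
#' missingness `<= 0.2`, Duncan alpha 0.05, and the >= 2-line haplotype
#' rule.  Serialized to/from JSON (the package's documented key-value
#' config dialect).
#'
#' @param out_dir Output directory for all stage products.
#' @param seed Integer seed propagated to every stochastic stage.
#' @param sim Named list of [sim_config()] arguments (plus optional
#'   `n_genes`, `flag_rate` for the gene-model stage).
#' @param thresholds Named list overriding any of `neglog10p` (5), `lod` (3),
#'   `maf` (0.01), `missing` (0.2), `alpha` (0.05), `min_hap_n` (2),
#'   `candidate_p` (0.01).
#' @param n_pcs Number of structure covariates for the scan (default 3).
#' @param traits Traits to analyze (default all of [GQ_TRAITS]).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = list(),
                       thresholds = list(), n_pcs = 3,
                       traits = GQ_TRAITS) {
  th <- list(neglog10p = 5, lod = 3, maf = 0.01, missing = 0.2,
             alpha = 0.05, min_hap_n = 2, candidate_p = 0.01)
  th[names(thresholds)] <- thresholds
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  stopifnot(all(traits %in% GQ_TRAITS))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 thresholds = th, n_pcs = n_pcs, traits = traits),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(out_dir = cfg$out_dir %||% dirname(path),
             seed = cfg$seed %||% 1L,
             sim = as.list(cfg$sim %||% list()),
             thresholds = as.list(cfg$thresholds %||% list()),
             n_pcs = cfg$n_pcs %||% 3,
             traits = cfg$traits %||% GQ_TRAITS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

.write_manifest <- function(config, stage, files, counts) {
  man_path <- file.path(config$out_dir, "manifest.json")
  man <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = FALSE) else
      list(version = as.character(utils::packageVersion("ricegq")),
           config = unclass(config), stages = list())
  files <- files[file.exists(files)]
  man$stages[[stage]] <- list(
    counts = as.list(counts),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(man_path)
}

#' Simulate a full dataset to disk
#'
#' Runs the genotype, phenotype, gene-model and hydrolysis-curve simulators
#' under the configured seed and writes `genotypes.vcf`, `phenotypes.csv`,
#' `genes.gff3`, `curves.csv` and `truth.json` into `out_dir`.
#'
#' @param config A [run_config()] whose `sim` block holds the simulator
#'   arguments.
#' @return Named list of written file paths, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- config$sim
  n_genes <- sim_args$n_genes %||% 10
  flag_rate <- sim_args$flag_rate %||% 0.5
  sim_args$n_genes <- NULL; sim_args$flag_rate <- NULL
  if (!is.null(sim_args$qtls) && length(sim_args$qtls) > 0 &&
      !inherits(sim_args$qtls[[1]], "qtl_spec"))
    sim_args$qtls <- lapply(sim_args$qtls, function(q)
      qtl_spec(q$snp_index, q$trait, q$target_pve %||% 20, q$direction %||% 1))
  sim_args$rng_seed <- config$seed
  sc <- do.call(sim_config, sim_args)

  gs <- simulate_genotypes(sc)
  gm <- simulate_gene_models(gs$genotypes, n_genes, flag_rate,
                             rng_seed = config$seed + 2L)
  gs$genotypes <- gm$genotypes
  ph <- simulate_phenotypes(gs, sc)
  cv <- simulate_hydrolysis_curves(sc$n_accessions,
                                   rng_seed = config$seed + 3L)

  paths <- c(
    vcf = file.path(config$out_dir, "genotypes.vcf"),
    pheno = file.path(config$out_dir, "phenotypes.csv"),
    gff = file.path(config$out_dir, "genes.gff3"),
    curves = file.path(config$out_dir, "curves.csv"),
    truth = file.path(config$out_dir, "truth.json"))
  write_vcf_genotypes(gs$genotypes, paths["vcf"])
  data.table::fwrite(ph$phenotypes, paths["pheno"])
  write_gene_models(gm$models, paths["gff"])
  cdf <- do.call(rbind, lapply(cv$curves, function(cu)
    data.frame(sample = cu$sample, t(stats::setNames(cu$glucose,
      paste0("time_", cu$times))), total_starch = cu$total_starch,
      check.names = FALSE)))
  cdf$reference <- FALSE
  data.table::fwrite(cdf, paths["curves"])
  truth <- list(
    seed = config$seed,
    subpops = as.list(stats::setNames(as.character(ph$truth$subpops),
                                      names(ph$truth$subpops))),
    qtls = ph$truth$qtls,
    kinetics = cv$truth)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .write_manifest(config, "simulate", paths,
                  c(accessions = sc$n_accessions, snps = sc$n_snps,
                    genes = n_genes))
  .stage_log("simulate", sprintf("%d accessions, %d SNPs, %d genes -> %s",
                                 sc$n_accessions, sc$n_snps, n_genes,
                                 config$out_dir))
  invisible(paths)
}

#' Compute PGI/RS phenotypes from raw curves
#'
#' Reads the curve CSV (see [read_curves_csv()]), fits every sample, and
#' writes `kinetics.csv` with Calpha, k, AUC, HI, PGI and GI class per
#' sample.  The reference is the flagged curve, or a supplied reference AUC.
#'
#' @param config A [run_config()]; uses `<out_dir>/curves.csv`.
#' @param curves_path Optional explicit input path.
#' @param reference Optional reference sample id or AUC; defaults to the
#'   flagged curve, else the white-bread convention `Calpha = 100,
#'   k = 0.025`.
#' @return Path of the written CSV, invisibly.
#' @export
cmd_phenotype <- function(config, curves_path = NULL, reference = NULL) {
  stopifnot(inherits(config, "run_config"))
  curves_path <- curves_path %||% file.path(config$out_dir, "curves.csv")
  if (!file.exists(curves_path)) stop("no curve file at ", curves_path)
  cin <- read_curves_csv(curves_path)
  ref <- reference %||% cin$reference %||% auc_first_order(100, 0.025)
  res <- pgi_pipeline(cin$curves, ref)
  out <- file.path(config$out_dir, "kinetics.csv")
  data.table::fwrite(res, out)
  .write_manifest(config, "phenotype", c(kinetics = out),
                  c(samples = nrow(res)))
  .stage_log("phenotype", sprintf("%d samples fitted", nrow(res)))
  invisible(out)
}

#' Run the GWAS stage
#'
#' Reads genotypes and phenotypes from `out_dir`, applies the SNP QC
#' filters, builds kinship and principal-component covariates, and calls
#' MTAs per trait ([call_mtas()]).  Writes per-trait association TSVs
#' (`assoc_<trait>.tsv`, Manhattan-ready), a combined `mtas.tsv` and the QC
#' report.
#'
#' @param config A [run_config()].
#' @return List with `mtas` (data.frame) and `qc` report, invisibly.
#' @export
cmd_gwas <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  G <- read_genotypes(file.path(config$out_dir, "genotypes.vcf"), "vcf")
  pheno <- data.table::fread(file.path(config$out_dir, "phenotypes.csv"),
                             data.table = FALSE)
  miss_tr <- setdiff(config$traits, names(pheno))
  if (length(miss_tr) > 0)
    stop("trait(s) missing from phenotype file: ",
         paste(miss_tr, collapse = ", "))
  qc <- filter_snps(G, maf_min = th$maf, missing_max = th$missing)
  G <- qc$genotypes
  pheno <- pheno[match(G$accessions, pheno$accession), ]
  K <- kinship(G)
  Q <- structure_covariates(G, config$n_pcs)
  models <- tryCatch(read_gene_models(file.path(config$out_dir, "genes.gff3")),
                     error = function(e) NULL)

  all_mtas <- list()
  for (tr in config$traits) {
    y <- pheno[[tr]]
    res <- call_mtas(G, y, tr, Q, K, models,
                     threshold_neglog10p = th$neglog10p,
                     lod_threshold = th$lod, candidate_p = th$candidate_p)
    ap <- file.path(config$out_dir, paste0("assoc_", tr, ".tsv"))
    data.table::fwrite(res$records, ap, sep = "\t")
    if (nrow(res$mtas) > 0) {
      res$mtas <- cbind(trait = tr, res$mtas)
      all_mtas[[tr]] <- res$mtas
    }
  }
  mtas <- if (length(all_mtas)) do.call(rbind, c(all_mtas,
                                                 make.row.names = FALSE)) else
    data.frame(trait = character(0), snp = character(0))
  mp <- file.path(config$out_dir, "mtas.tsv")
  data.table::fwrite(mtas, mp, sep = "\t")
  qp <- file.path(config$out_dir, "qc_report.json")
  jsonlite::write_json(unclass(qc$report), qp, auto_unbox = TRUE)
  .write_manifest(config, "gwas", c(mtas = mp, qc = qp),
                  c(markers_pass = qc$report$n_pass, mtas = nrow(mtas)))
  .stage_log("gwas", sprintf("%d markers pass QC; %d MTA(s)",
                             qc$report$n_pass, nrow(mtas)))
  invisible(list(mtas = mtas, qc = qc$report))
}

#' Run the haplo-pheno stage
#'
#' For every candidate gene of every MTA: extract the functional in-gene
#' variants, call haplotypes, tabulate frequencies, compare trait means with
#' ANOVA + Duncan letters, flag the superior haplotype, and list donor
#' accessions.  Writes per-gene TSVs and a cross-gene `haplo_summary.tsv`.
#'
#' @param config A [run_config()].
#' @return The summary `data.frame`, invisibly.
#' @export
cmd_haplopheno <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  mtas <- data.table::fread(file.path(config$out_dir, "mtas.tsv"),
                            data.table = FALSE)
  if (nrow(mtas) == 0) {
    .stage_log("haplopheno", "no MTAs; nothing to do")
    return(invisible(data.frame()))
  }
  G <- read_genotypes(file.path(config$out_dir, "genotypes.vcf"), "vcf")
  models <- read_gene_models(file.path(config$out_dir, "genes.gff3"))
  pheno <- data.table::fread(file.path(config$out_dir, "phenotypes.csv"),
                             data.table = FALSE)
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(mtas)), function(i) {
    genes <- if ("genes" %in% names(mtas) && nzchar(mtas$genes[i]))
      strsplit(mtas$genes[i], ",")[[1]] else
        tryCatch(assign_candidate_genes(mtas$chrom[i], mtas$pos[i],
                                        models)$gene_id,
                 error = function(e) character(0))
    if (length(genes) == 0) return(NULL)
    data.frame(gene = genes, trait = mtas$trait[i], stringsAsFactors = FALSE)
  })))
  if (nrow(pairs) == 0) stop("no candidate genes resolvable for the MTAs")

  summ <- list()
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene[i]; tr <- pairs$trait[i]
    sub <- extract_gene_variants(G, models, gid)
    asg <- call_haplotypes(sub)
    data.table::fwrite(data.frame(accession = names(asg$haplotype),
                                  haplotype = unname(asg$haplotype)),
                       file.path(config$out_dir,
                                 sprintf("hap_assign_%s.tsv", gid)), sep = "\t")
    hp <- haplo_pheno_table(asg, pheno, tr, min_n = th$min_hap_n,
                            alpha = th$alpha)
    data.table::fwrite(hp$table,
                       file.path(config$out_dir,
                                 sprintf("haplo_pheno_%s_%s.tsv", gid, tr)),
                       sep = "\t")
    if (is.null(hp$note)) {
      sup <- superior_haplotype(hp, tr)
      donors <- haplotype_donors(asg, sup$haplotype)
      summ[[length(summ) + 1]] <- data.frame(
        gene = gid, trait = tr, n_haplotypes = nrow(hp$table),
        superior = sup$haplotype, superior_mean = sup$mean,
        separated = sup$separated,
        anova_p = hp$anova$p,
        donors = paste(donors, collapse = ","),
        stringsAsFactors = FALSE)
    } else {
      summ[[length(summ) + 1]] <- data.frame(
        gene = gid, trait = tr, n_haplotypes = nrow(hp$table),
        superior = NA_character_, superior_mean = NA_real_,
        separated = NA, anova_p = NA_real_, donors = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, summ)
  sp <- file.path(config$out_dir, "haplo_summary.tsv")
  data.table::fwrite(out, sp, sep = "\t")
  .write_manifest(config, "haplopheno", c(summary = sp),
                  c(gene_trait_pairs = nrow(out)))
  .stage_log("haplopheno", sprintf("%d gene-trait pair(s) analyzed", nrow(out)))
  invisible(out)
}

#' Run the whole pipeline
#'
#' simulate -> phenotype -> gwas -> haplopheno under one configuration and
#' seed; every stage appends to the run manifest.
#' @param config A [run_config()].
#' @return The haplo-pheno summary, invisibly.
#' @export
run_pipeline <- function(config) {
  cmd_simulate(config)
  cmd_phenotype(config)
  cmd_gwas(config)
  invisible(cmd_haplopheno(config))
}
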