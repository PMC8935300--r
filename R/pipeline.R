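# End-to-end pipeline over simulated data: simulate -> pedigree QC ->
# segregation filter -> Y-SNP scan -> sexSNP + linkage maps -> genetic/
# physical integration -> read-backed Y phasing -> divergence, dating,
# relative rates -> expression ratios.

#' Run the full analysis on a simulated study
#'
#' Executes every pipeline stage in order on data generated from `cfg` and
#' returns a report bundle whose manifest (seed, parameters, versions)
#' suffices to reproduce the run. Any stage failure aborts with a
#' stage-named message.
#'
#' @param cfg A [sim_config()]; its `seed` drives all randomness.
#' @param g Generation time in years for dating (default 25).
#' @param m Mutation rate per site per generation (default 1e-8).
#' @param tolerance Segregation-distortion tolerance (default 0.001).
#' @param lod_group,lod_join,lod_diff Linkage-map thresholds
#'   (defaults 10/8/2).
#' @param min_call_rate Y-SNP scan call-rate policy (default 1.0).
#' @param min_depth Consensus depth threshold (default 2).
#' @param out_dir Optional directory; when given, the VCF, sample sheet,
#'   FASTA, SAM, count matrix and summary tables are written there.
#' @param quiet Suppress per-stage messages.
#' @return List of class `sdr_report`; see the components in the source for
#'   the stage-by-stage outputs, plus `manifest`.
#' @export
run_all <- function(cfg = sim_config(), g = 25, m = 1e-8,
                    tolerance = 0.001, lod_group = 10, lod_join = 8,
                    lod_diff = 2, min_call_rate = 1.0, min_depth = 2L,
                    out_dir = NULL, quiet = FALSE) {
  cfg <- validate_sim_config(cfg)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- stage("simulate", simulate_pedigree_genotypes(cfg))
  gm <- sim$geno
  truth <- sim$truth

  qc <- stage("qc", ibd_check(gm))
  keep_ids <- c(gm$samples$id[gm$samples$role != "offspring"],
                setdiff(qc$id, qc$id[qc$exclude]))
  if (any(qc$exclude)) {
    keep_cols <- gm$samples$id %in% keep_ids
    gm <- genotype_matrix(gm$markers, gm$samples[keep_cols, , drop = FALSE],
                          gm$calls[, keep_cols, drop = FALSE])
  }

  cls <- stage("filter", classify_and_filter(gm, tolerance = tolerance))
  yscan <- stage("yscan", find_y_snps(gm, min_call_rate = min_call_rate))

  gene_table <- truth$genes
  tested <- table(gm$markers$gene_id)
  gene_table$tested <- gene_table$gene_id %in% names(tested)
  nry <- stage("nry_boundaries", nry_boundaries(yscan, gene_table))

  gmx <- stage("sexsnp", add_sex_snp(gm))
  gmap <- stage("map", build_map(gmx, lod_group = lod_group,
                                 lod_join = lod_join, lod_diff = lod_diff,
                                 tolerance = tolerance))
  integration <- stage("integrate", lapply(
    Filter(Negate(is.null), list(male = gmap$male, female = gmap$female)),
    map_physical_integration))

  phase <- stage("phase", {
    lapply(stats::setNames(nm = truth$nry_gene_ids), function(gid) {
      s <- truth$sequences[[gid]]
      snp_rows <- yscan$markers[yscan$markers$gene_id == gid, , drop = FALSE]
      if (nrow(snp_rows) == 0) return(NULL)
      y_snps <- data.frame(cds_pos = snp_rows$cds_pos,
                           x_allele = snp_rows$ref, y_allele = snp_rows$alt)
      reads <- simulate_reads(s$x, s$y, sex = "M", depth = cfg$read_depth,
                              read_length = cfg$read_length,
                              error_rate = cfg$base_error, gene_id = gid)
      parts <- partition_reads(reads, y_snps,
                               reference_length = nchar(s$x))
      list(y_consensus = call_consensus(parts$y_reads, nchar(s$x), min_depth),
           x_consensus = call_consensus(parts$x_reads, nchar(s$x), min_depth),
           n_conflict = parts$n_conflict, y_snps = y_snps, reads = reads)
    })
  })

  divergence <- stage("kaks", {
    rows <- lapply(truth$nry_gene_ids, function(gid) {
      if (is.null(phase[[gid]])) return(NULL)
      res <- kaks(phase[[gid]]$x_consensus$seq, phase[[gid]]$y_consensus$seq)
      data.frame(gene = gid, cds_length = nchar(truth$sequences[[gid]]$x),
                 Sd = res$Sd, S = res$S, Ks = res$Ks,
                 Nd = res$Nd, N = res$N, Ka = res$Ka, ka_ks = res$ka_ks,
                 codons_skipped = res$codons_skipped)
    })
    do.call(rbind, rows)
  })

  rrt <- stage("rrt", {
    out <- lapply(stats::setNames(nm = truth$nry_gene_ids), function(gid) {
      if (is.null(phase[[gid]])) return(NULL)
      tajima_rrt(phase[[gid]]$x_consensus$seq, phase[[gid]]$y_consensus$seq,
                 truth$sequences[[gid]]$outgroup)
    })
    Filter(Negate(is.null), out)
  })

  ages <- stage("date", list(
    per_gene = stats::setNames(
      lapply(divergence$Ks, date_divergence, g = g, m = m), divergence$gene),
    from_max_ks = date_divergence(max(divergence$Ks), g, m),
    from_mean_ks = date_divergence(mean(divergence$Ks), g, m)))

  expression <- stage("express", {
    ex <- simulate_expression(cfg, sim$sheet,
                              gene_lengths = stats::setNames(
                                3L * cfg$gene_length_codons,
                                truth$nry_gene_ids))
    et <- fpkm(ex$counts, ex$lengths, ex$library_sizes, sheet = sim$sheet)
    list(table = et, ratios = ratio_summary(et, sim$sheet))
  })

  report <- structure(list(
    config = cfg, sheet = sim$sheet, truth = truth, qc = qc,
    marker_classes = cls, y_snps = yscan, nry = nry, map = gmap,
    integration = integration, divergence = divergence, rrt = rrt,
    ages = ages, expression = expression$ratios,
    manifest = list(seed = cfg$seed, g = g, m = m, tolerance = tolerance,
                    lod = c(lod_group, lod_join, lod_diff),
                    min_call_rate = min_call_rate, min_depth = min_depth,
                    package_version = as.character(utils::packageVersion("sdrmap")),
                    r_version = R.version.string)),
    class = "sdr_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(gm, file.path(out_dir, "genotypes.vcf"))
    write_sample_sheet(sim$sheet, file.path(out_dir, "samples.tsv"))
    seqs <- unlist(lapply(truth$nry_gene_ids, function(gid) {
      s <- truth$sequences[[gid]]
      stats::setNames(c(s$x, s$y, s$outgroup),
                      paste0(gid, c("_X", "_Y", "_outgroup")))
    }))
    write_fasta(seqs, file.path(out_dir, "gametologs.fasta"))
    utils::write.table(divergence, file.path(out_dir, "divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expression$ratios,
                       file.path(out_dir, "expression_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' @exportS3Method base::print
print.sdr_report <- function(x, ...) {
  cat("SDR analysis report (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  samples:", nrow(x$sheet), "; excluded offspring:",
      sum(x$qc$exclude), "\n")
  cat("  Y-SNPs:", x$y_snps$n, "in",
      length(x$y_snps$per_gene), "gene(s)\n")
  if (!is.null(x$nry$inner))
    cat("  NRY inner span:", paste(round(x$nry$inner, 2), collapse = "-"),
        "Mb; outer bound:", paste(round(x$nry$outer, 2), collapse = "-"),
        "Mb\n")
  if (!is.null(x$divergence))
    cat("  Ks range:", paste(round(range(x$divergence$Ks), 3),
                             collapse = "-"), "\n")
  cat("  age from max Ks:",
      signif(x$ages$from_max_ks$T_years / 1e6, 3), "Myr\n")
  invisible(x)
}
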