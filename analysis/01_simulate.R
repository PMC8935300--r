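# Generate the simulated study: four half-sib crosses segregating for a
# male-specific non-recombining region (NRY) of four genes embedded in a
# 50 Mb low-recombination interval. Writes the standard-format inputs the
# later scripts consume.

source("analysis/00_config.R")

write_vcf(study$geno, file.path(sim_dir, "genotypes.vcf"))
write_sample_sheet(study$sheet, file.path(sim_dir, "samples.tsv"))

seqs <- unlist(lapply(study$truth$nry_gene_ids, function(gid) {
  s <- study$truth$sequences[[gid]]
  stats::setNames(c(s$x, s$y, s$outgroup),
                  paste0(gid, c("_X", "_Y", "_outgroup")))
}))
write_fasta(seqs, file.path(sim_dir, "gametologs.fasta"))

# per-gene aligned read pairs for one male sample, as SAM subset files
for (gid in study$truth$nry_gene_ids) {
  s <- study$truth$sequences[[gid]]
  reads <- simulate_reads(s$x, s$y, sex = "M", depth = cfg$read_depth,
                          read_length = cfg$read_length, gene_id = gid)
  write_sam(reads, file.path(sim_dir, paste0(gid, ".sam")),
            ref_lengths = stats::setNames(nchar(s$x), gid))
}

ex <- simulate_expression(cfg, study$sheet,
                          gene_lengths = stats::setNames(
                            3L * cfg$gene_length_codons,
                            study$truth$nry_gene_ids))
write.table(ex$counts, file.path(sim_dir, "expression_counts.tsv"),
            sep = "\t", quote = FALSE)
write.table(data.frame(sample = names(ex$library_sizes),
                       library_size = ex$library_sizes),
            file.path(sim_dir, "library_sizes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth_tab <- study$truth$markers[, c("chrom", "pos", "gene_id", "is_y_snp",
                                     "cm_male", "cm_female")]
write.table(truth_tab, file.path(sim_dir, "marker_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "simulated %d markers x %d samples; %d true Y-SNPs in genes %s; NRY %g-%g Mb",
  nrow(study$geno$markers), nrow(study$sheet),
  sum(study$truth$markers$is_y_snp),
  paste(study$truth$nry_gene_ids, collapse = ","),
  study$truth$nry_span[1], study$truth$nry_span[2]))
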