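# Allele-specific expression: FPKM and the per-family X/Y ratio summary
# (dosage and Y-degeneration diagnostics).

source("analysis/00_config.R")

counts <- as.matrix(read.delim(file.path(sim_dir, "expression_counts.tsv"),
                               check.names = FALSE))
libs <- read.delim(file.path(sim_dir, "library_sizes.tsv"))
library_sizes <- stats::setNames(libs$library_size, libs$sample)
lengths <- stats::setNames(
  rep(3L * cfg$gene_length_codons, each = 2L), rownames(counts))

et <- fpkm(counts, lengths, library_sizes, sheet = study$sheet)
if (nrow(et$leakage) > 0)
  message("WARNING: Y-copy signal in ", nrow(et$leakage), " female sample(s)")

rs <- ratio_summary(et, study$sheet)
write.table(rs, file.path(res_dir, "expression_ratios.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(attr(rs, "consistency"),
            file.path(res_dir, "expression_ratio_consistency.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("median ratios across families:")
agg <- aggregate(rs[, c("mY_mX", "mXY_fXX", "mX_fXX")],
                 by = list(gene = rs$gene), FUN = median)
print(agg, row.names = FALSE)
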