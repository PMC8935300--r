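# Y-SNP scan, NRY boundary inference, sexSNP-augmented linkage mapping and
# integration of the genetic with the physical map.

source("analysis/00_config.R")

gm <- study$geno
truth <- study$truth

yscan <- find_y_snps(gm)
message(sprintf("Y-SNP scan: %d markers in %d gene(s)",
                yscan$n, length(yscan$per_gene)))
write.table(yscan$markers, file.path(res_dir, "y_snps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

gene_table <- truth$genes
gene_table$tested <- gene_table$gene_id %in% gm$markers$gene_id
nry <- nry_boundaries(yscan, gene_table)
message(sprintf("NRY inner span %0.2f-%0.2f Mb; outer bound %0.2f-%0.2f Mb",
                nry$inner[1], nry$inner[2], nry$outer[1], nry$outer[2]))

gmx <- add_sex_snp(gm)
map <- build_map(gmx)
print(map)
for (sex in c("male", "female")) {
  if (is.null(map[[sex]])) next
  write.table(map[[sex]], file.path(res_dir, paste0("map_", sex, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
mm <- map$male
sx <- mm[!is.na(mm$gene_id) & mm$gene_id == "sexSNP", ]
message(sprintf("sexSNP placed at %.2f cM in group %d", sx$cm, sx$group))

integ <- map_physical_integration(mm)
# low-recombination spans as BED (0-based, half-open: the only place
# 0-based coordinates appear in this workflow)
if (nrow(integ$spans) > 0) {
  bed <- data.frame(chrom = mm$chrom[1],
                    start = as.integer(integ$spans$start) - 1L,
                    end = as.integer(integ$spans$end),
                    name = sprintf("cM_%.2f", integ$spans$cm))
  write.table(bed, file.path(res_dir, "low_recomb_spans.bed"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  big <- integ$spans[which.max(integ$spans$end - integ$spans$start), ]
  message(sprintf("largest constant-cM span: %.1f Mb (%d markers)",
                  (big$end - big$start) / 1e6, big$n_markers))
}
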