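# Pedigree QC (relatedness of offspring to their named parents) and
# segregation-distortion filtering of the markers.

source("analysis/00_config.R")

gm <- study$geno

qc <- ibd_check(gm)
write.table(qc, file.path(res_dir, "qc_relatedness.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("relatedness to father: median %.2f; %d offspring excluded",
                median(qc$ibd_father, na.rm = TRUE), sum(qc$exclude)))

cls <- classify_and_filter(gm, tolerance = 0.001)
write.table(cls, file.path(res_dir, "marker_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("marker classes: %s; %d excluded for distorted segregation",
                paste(names(table(cls$class)), table(cls$class),
                      sep = "=", collapse = ", "),
                sum(!cls$keep)))
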