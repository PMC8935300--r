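# Shared helpers: small hand-built pedigrees and genotype matrices.

# A one-family sheet with explicit offspring genotypes supplied as a
# marker x sample matrix builder.
toy_sheet <- function(n_off = 4L, family = "fam1") {
  rbind(
    data.frame(id = "MOT1", sex = "F", family = family, role = "mother",
               mother_id = NA_character_, father_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = "FAT1", sex = "M", family = family, role = "father",
               mother_id = NA_character_, father_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("%s_o%02d", family, seq_len(n_off)),
               sex = rep(c("M", "F"), length.out = n_off),
               family = family, role = "offspring",
               mother_id = "MOT1", father_id = "FAT1",
               stringsAsFactors = FALSE))
}

toy_markers <- function(n, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_len(n) * 1000L,
             ref = rep_len(c("A", "C", "G", "T"), n),
             alt = rep_len(c("G", "T", "A", "C"), n),
             gene_id = sprintf("g%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Random biallelic genotype matrix for round-trip tests.
random_geno <- function(n_markers, sheet, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(c(0:2, NA), n_markers * nrow(sheet),
                         replace = TRUE, prob = c(.4, .3, .2, .1)),
                  nrow = n_markers)
  genotype_matrix(toy_markers(n_markers), sheet, calls)
}

# A single-family clean testcross chromosome: markers at known cM
# positions, transmissions simulated under the Haldane model, offspring
# genotypes het/hom-ref accordingly. Mimics a fully informative cross.
clean_testcross_sim <- function(true_cm, n_off = 100L, seed = 1) {
  set.seed(seed)
  sheet <- toy_sheet(n_off)
  n_mk <- length(true_cm)
  total <- max(true_cm)
  trans <- matrix(0L, n_mk, n_off)
  for (o in seq_len(n_off)) {
    n_xo <- stats::rpois(1L, total / 100)
    xo <- sort(stats::runif(n_xo, 0, total))
    start <- sample(0:1, 1L)
    trans[, o] <- (start + findInterval(true_cm, xo)) %% 2L
  }
  calls <- cbind(MOT1 = rep(0L, n_mk), FAT1 = rep(1L, n_mk), trans)
  colnames(calls) <- sheet$id
  # offspring sexes are irrelevant here; genotype = maternal 0 + paternal
  mk <- toy_markers(n_mk)
  mk$pos <- as.integer(round(true_cm * 1e6)) + 1000L
  list(gm = genotype_matrix(mk, sheet, calls), trans = trans,
       true_cm = true_cm)
}

extdata <- function(f) system.file("extdata", f, package = "sdrmap")
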