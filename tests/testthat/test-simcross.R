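# The synthetic-data generator: gametolog divergence, pedigrees with an
# embedded non-recombining region, reads and expression counts.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 40, offspring_per_family = 12,
             gene_length_codons = c(200L, 150L, 180L, 160L),
             max_y_snps_per_gene = 6L, ...)
}

test_that("simulate_gametolog_pair hits its divergence targets", {
  anc <- random_cds(400, seed = 2)
  p <- simulate_gametolog_pair(anc, 0, 0, seed = 1)
  expect_identical(p$x, p$y)

  rel_err <- function(seed) {
    p <- simulate_gametolog_pair(anc, 0.08, 0.03, seed = seed)
    cods <- substring(p$x, seq(1, nchar(p$x), 3), seq(3, nchar(p$x), 3))
    expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
    c((p$realized$Ks - 0.08) / 0.08, (p$realized$Ka - 0.03) / 0.03)
  }
  errs <- vapply(1:6, rel_err, numeric(2))
  # targets are met-or-exceeded, and stay within 20% relative on average
  expect_true(all(errs >= -1e-9))
  expect_lt(mean(abs(errs[1, ])), 0.2)
  expect_lt(mean(abs(errs[2, ])), 0.2)
})

test_that("simulate_gametolog_pair is deterministic and validates input", {
  anc <- random_cds(100, seed = 3)
  a <- simulate_gametolog_pair(anc, 0.05, 0.02, seed = 11)
  b <- simulate_gametolog_pair(anc, 0.05, 0.02, seed = 11)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_error(simulate_gametolog_pair("ATGTAA", 0.1, 0.1), "stop")
  expect_error(simulate_gametolog_pair("ATGC", 0.1, 0.1), "multiple of 3")
  # a gene with no synonymous sites cannot reach a synonymous target
  expect_error(simulate_gametolog_pair("ATG", 0.2, 0), "unreachable")
})

test_that("pedigree simulation is deterministic with a fixed config", {
  a <- simulate_pedigree_genotypes(small_cfg(5))
  b <- simulate_pedigree_genotypes(small_cfg(5))
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$sequences, b$truth$sequences)
})

test_that("Y-specific sites are het in all males, hom-ref in all females", {
  sim <- simulate_pedigree_genotypes(small_cfg(7))
  ysnp <- sim$truth$markers$is_y_snp
  males <- sim$sheet$id[sim$sheet$sex == "M"]
  females <- sim$sheet$id[sim$sheet$sex == "F"]
  expect_true(all(sim$geno$calls[ysnp, males] == 1L))
  expect_true(all(sim$geno$calls[ysnp, females] == 0L))
})

test_that("every offspring genotype is Mendelian-consistent", {
  sim <- simulate_pedigree_genotypes(small_cfg(9))
  gm <- sim$geno
  off <- gm$samples[gm$samples$role == "offspring", ]
  alleles <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  for (o in seq_len(nrow(off))) {
    kid <- gm$calls[, off$id[o]]
    mo <- gm$calls[, off$mother_id[o]]
    fa <- gm$calls[, off$father_id[o]]
    possible <- mapply(function(k, m, f) {
      k %in% outer(alleles[[as.character(m)]],
                   alleles[[as.character(f)]], "+")
    }, kid, mo, fa)
    expect_true(all(possible))
  }
})

test_that("zero recombination everywhere makes paternal markers
           co-segregate with sex", {
  cfg <- sim_config(seed = 4, n_genes = 30, n_families = 2,
                    offspring_per_family = 15,
                    sdr_span = c(1, 299), sdr_mult = 0,
                    gene_length_codons = c(150L, 150L, 150L, 150L),
                    max_y_snps_per_gene = 5L)
  sim <- simulate_pedigree_genotypes(cfg)
  gm <- sim$geno
  off <- gm$samples[gm$samples$role == "offspring", ]
  tx <- sdrmap:::.transmissions(gm, "father")
  sex01 <- as.integer(off$sex == "M")
  for (i in which(rowSums(!is.na(tx$trans)) > 0 &
                  !sim$truth$markers$is_y_snp)) {
    for (f in unique(off$family)) {
      idx <- off$family == f & !is.na(tx$trans[i, ])
      if (sum(idx) < 2) next
      agree <- tx$trans[i, idx] == sex01[idx]
      expect_true(all(agree) || all(!agree))
    }
  }
})

test_that("recombinant fractions follow the Haldane map function", {
  cfg <- sim_config(seed = 8, n_genes = 60, n_families = 1,
                    offspring_per_family = 1000,
                    sdr_span = c(200, 250), sdr_mult = 1,
                    alt_freq_range = c(0.45, 0.5))
  sim <- simulate_pedigree_genotypes(cfg)
  gm <- sim$geno
  tx <- sdrmap:::.transmissions(gm, "father")
  cm <- sim$truth$markers$cm_male
  inform <- which(rowSums(!is.na(tx$trans)) > 800)
  # pick the informative pair whose true separation is closest to 50 cM
  dists <- abs(outer(cm[inform], cm[inform], "-"))
  best <- which(abs(dists - 50) == min(abs(dists - 50)), arr.ind = TRUE)[1, ]
  i <- inform[best[1]]; j <- inform[best[2]]
  d_true <- abs(cm[i] - cm[j])
  r <- two_point_rf(tx$trans[i, ], tx$trans[j, ], tx$family)
  expected <- 0.5 * (1 - exp(-2 * d_true / 100))
  expect_lt(abs(r$rf - expected), 4 * sqrt(expected * (1 - expected) / r$n))
})

test_that("offspring sex ratio is consistent with 1:1", {
  cfg <- sim_config(seed = 10, n_genes = 10, n_families = 1,
                    offspring_per_family = 1000, snp_density = 0.2,
                    gene_length_codons = c(60L, 60L, 60L, 60L),
                    max_y_snps_per_gene = 2L)
  sim <- simulate_pedigree_genotypes(cfg)
  n_m <- sum(sim$sheet$sex == "M" & sim$sheet$role == "offspring")
  expect_gt(stats::binom.test(n_m, 1000, 0.5)$p.value, 0.001)
})

test_that("simulated reads respect haplotype of origin", {
  x <- random_cds(300, seed = 12)
  y <- simulate_gametolog_pair(x, 0.08, 0.02, seed = 13)$y
  dsite <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  y_snps <- data.frame(cds_pos = dsite,
                       x_allele = strsplit(x, "")[[1]][dsite],
                       y_allele = strsplit(y, "")[[1]][dsite])

  # error-free reads match their source haplotype exactly
  reads <- simulate_reads(x, y, sex = "M", depth = 10, read_length = 80,
                          seed = 14)
  src <- c(X = x, Y = y)
  expect_true(all(substring(src[reads$source_hap], reads$pos,
                            reads$pos + 79) == reads$seq))

  # a female sample never yields a Y allele at any Y-SNP
  fr <- simulate_reads(x, y, sex = "F", depth = 20, read_length = 80,
                       seed = 15)
  expect_true(all(fr$source_hap == "X"))
  parts <- partition_reads(fr, y_snps, reference_length = nchar(x))
  expect_equal(nrow(parts$y_reads), 0L)

  # male at depth 40: about half of SNP-covering reads carry the Y allele
  mr <- simulate_reads(x, y, sex = "M", depth = 40, read_length = 80,
                       seed = 16)
  pm <- partition_reads(mr, y_snps, reference_length = nchar(x))
  n_y <- length(unique(pm$y_reads$qname))
  n_x <- length(unique(pm$x_reads$qname))
  frac <- n_y / (n_y + n_x)
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / (n_y + n_x)))

  expect_error(simulate_reads(x, y, read_length = 2000), "exceeds")
})

test_that("simulated expression respects sex and dosage structure", {
  cfg <- small_cfg(20)
  sim <- simulate_pedigree_genotypes(cfg)
  ex <- simulate_expression(cfg, sim$sheet)
  females <- sim$sheet$id[sim$sheet$sex == "F"]
  y_rows <- grep("_Y$", rownames(ex$counts))
  expect_true(all(ex$counts[y_rows, females] == 0L))
  expect_true(all(ex$counts >= 0))
  expect_equal(names(ex$library_sizes), sim$sheet$id)
})
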