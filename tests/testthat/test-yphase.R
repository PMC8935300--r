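# Read partitioning by Y-specific alleles and consensus calling.

mk_read <- function(qname, mate, pos, seq, rname = "g") {
  data.frame(qname = qname, mate = mate, flag = c(65L, 129L)[mate],
             rname = rname, pos = pos, seq = seq,
             stringsAsFactors = FALSE)
}

test_that("partition_reads assigns pairs by Y alleles with mate
           propagation", {
  y_snps <- data.frame(cds_pos = 5L, x_allele = "A", y_allele = "G")
  reads <- rbind(
    mk_read("p1", 1, 1, "CCCCGCCC"),   # Y allele at pos 5
    mk_read("p1", 2, 20, "TTTTTTTT"),  # mate covers no SNP
    mk_read("p2", 1, 1, "CCCCACCC"),   # X allele
    mk_read("p2", 2, 20, "TTTTTTTT"),
    mk_read("p3", 1, 12, "TTTTTTTT"),  # pair covers no SNP
    mk_read("p3", 2, 20, "TTTTTTTT"),
    mk_read("p4", 1, 1, "CCCCGCCC"),   # conflicting pair
    mk_read("p4", 2, 2, "CCCACCCC"),
    mk_read("p5", 1, 1, "CCCCTCCC"),   # third allele
    mk_read("p5", 2, 20, "TTTTTTTT"))
  parts <- partition_reads(reads, y_snps, reference_length = 30)

  expect_setequal(unique(parts$y_reads$qname), "p1")
  expect_equal(nrow(parts$y_reads), 2L)      # mate propagated
  expect_setequal(unique(parts$x_reads$qname), "p2")
  expect_setequal(unique(parts$unassigned$qname), c("p3", "p4", "p5"))
  expect_equal(parts$n_conflict, 1L)

  # union/disjointness
  expect_equal(nrow(parts$y_reads) + nrow(parts$x_reads) +
                 nrow(parts$unassigned), nrow(reads))

  # permutation invariance
  perm <- sample(nrow(reads))
  p2 <- partition_reads(reads[perm, ], y_snps, reference_length = 30)
  expect_setequal(p2$y_reads$qname, parts$y_reads$qname)
  expect_setequal(p2$x_reads$qname, parts$x_reads$qname)

  expect_error(partition_reads(reads, data.frame(cds_pos = 99L,
                                                 x_allele = "A",
                                                 y_allele = "G"),
                               reference_length = 30), "beyond")
  expect_error(partition_reads(reads, y_snps[0, ]), "empty")
})

test_that("call_consensus takes per-position majorities with N fallback", {
  reads <- rbind(mk_read("r1", 1, 3, "ACGT"),
                 mk_read("r2", 1, 3, "ACGT"),
                 mk_read("r3", 1, 3, "ACGT"))
  cons <- call_consensus(reads, reference_length = 10, min_depth = 2)
  expect_equal(cons$seq, "NNACGTNNNN")
  expect_equal(cons$depth[3:6], rep(3L, 4))
  expect_false(any(cons$called[c(1:2, 7:10)]))

  # 2 vs 1 disagreement: majority base wins
  reads2 <- rbind(mk_read("r1", 1, 1, "AAAA"),
                  mk_read("r2", 1, 1, "AAAA"),
                  mk_read("r3", 1, 1, "ACAA"))
  expect_equal(substr(call_consensus(reads2, 4)$seq, 2, 2), "A")

  # exact tie emits N, never an ambiguity code
  reads3 <- rbind(mk_read("r1", 1, 1, "AT"),
                  mk_read("r2", 1, 1, "AA"))
  expect_equal(call_consensus(reads3, 2, min_depth = 2)$seq, "AN")

  # empty input: all-N consensus
  empty <- call_consensus(reads3[0, ], 5)
  expect_equal(empty$seq, "NNNNN")
})

test_that("male reads at depth 40 reconstruct the true Y haplotype", {
  x <- random_cds(250, seed = 31)
  y <- simulate_gametolog_pair(x, 0.06, 0.02, seed = 32)$y
  dsite <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  y_snps <- data.frame(cds_pos = dsite,
                       x_allele = strsplit(x, "")[[1]][dsite],
                       y_allele = strsplit(y, "")[[1]][dsite])
  reads <- simulate_reads(x, y, sex = "M", depth = 40, read_length = 100,
                          seed = 33)
  parts <- partition_reads(reads, y_snps, reference_length = nchar(x))
  # error-free: partition recovers the true source labels among assigned
  expect_true(all(parts$y_reads$source_hap == "Y"))
  expect_true(all(parts$x_reads$source_hap == "X"))
  cons <- call_consensus(parts$y_reads, nchar(x), min_depth = 2)
  called <- cons$called
  expect_gt(mean(called), 0.95)
  expect_identical(substring(cons$seq, which(called), which(called)),
                   substring(y, which(called), which(called)))
})

test_that("consensus error rate under base errors stays below the
           binomial majority bound", {
  set.seed(34)
  x <- random_cds(200)
  y <- simulate_gametolog_pair(x, 0.08, 0.02)$y
  dsite <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  y_snps <- data.frame(cds_pos = dsite,
                       x_allele = strsplit(x, "")[[1]][dsite],
                       y_allele = strsplit(y, "")[[1]][dsite])
  e <- 0.05
  n_err <- 0; n_sites <- 0
  for (rep in 1:5) {
    reads <- simulate_reads(x, y, sex = "M", depth = 40, read_length = 100,
                            error_rate = e)
    parts <- partition_reads(reads, y_snps, reference_length = nchar(x))
    cons <- call_consensus(parts$y_reads, nchar(x), min_depth = 2)
    called_y <- dsite[cons$called[dsite]]
    n_sites <- n_sites + length(called_y)
    n_err <- n_err + sum(substring(cons$seq, called_y, called_y) !=
                           substring(y, called_y, called_y))
  }
  # closed-form: at depth d ~ 20 per haplotype, P(majority wrong) for a
  # per-base error e is bounded by the binomial tail P(X >= d/2), X~B(d,e)
  d_hap <- 20
  bound <- pbinom(ceiling(d_hap / 2) - 1, d_hap, e, lower.tail = FALSE)
  expect_lt(n_err / n_sites, bound + 3 * sqrt(bound / n_sites))
})

test_that("SAM subset round-trips and rejects clipped alignments", {
  reads <- rbind(mk_read("p1", 1, 3, "ACGTACGT"),
                 mk_read("p1", 2, 40, "TTGGCCAA"))
  tmp <- tempfile(fileext = ".sam")
  write_sam(reads, tmp, ref_lengths = c(g = 100L))
  back <- read_sam(tmp)
  expect_equal(back$qname, reads$qname)
  expect_equal(back$pos, reads$pos)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$mate, reads$mate)

  lines <- readLines(tmp)
  lines[3] <- sub("\t8M\t", "\t4S4M\t", lines[3])
  writeLines(lines, tmp)
  expect_error(read_sam(tmp), "CIGAR")
})
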