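# Pedigree QC, segregation filtering, Y-SNP scan, boundaries, two-point
# linkage and map-physical integration.

test_that("ibd_check scores allele sharing against named parents", {
  sheet <- toy_sheet(2)
  mk <- toy_markers(120)
  # offspring 1 identical to the mother at every marker
  calls <- matrix(0L, 120, nrow(sheet), dimnames = list(NULL, sheet$id))
  set.seed(1)
  calls[, "MOT1"] <- sample(0:2, 120, replace = TRUE)
  calls[, "FAT1"] <- sample(0:2, 120, replace = TRUE)
  calls[, 3] <- calls[, "MOT1"]
  calls[, 4] <- calls[, "MOT1"]
  gm <- genotype_matrix(mk, sheet, calls)
  res <- ibd_check(gm)
  expect_equal(res$ibd_mother[1], 1.0)

  # all-missing overlap is an error
  calls_na <- calls
  calls_na[, 3] <- NA_integer_
  gm_na <- genotype_matrix(mk, sheet, calls_na)
  expect_error(ibd_check(gm_na), "no genotyped parent")
})

test_that("ibd_check flags only a planted contaminant", {
  set.seed(7)
  n_mk <- 3000
  q <- runif(n_mk, 0.2, 0.5)
  sheet <- toy_sheet(6)
  draw_geno <- function() rbinom(n_mk, 1, q) + rbinom(n_mk, 1, q)
  mo <- draw_geno(); fa <- draw_geno()
  kid <- function() {
    m_allele <- ifelse(mo == 1, rbinom(n_mk, 1, 0.5), mo / 2)
    f_allele <- ifelse(fa == 1, rbinom(n_mk, 1, 0.5), fa / 2)
    as.integer(m_allele + f_allele)
  }
  calls <- cbind(mo, fa, kid(), kid(), kid(), kid(), kid(), draw_geno())
  calls <- calls[, 1:8]
  colnames(calls) <- sheet$id
  gm <- genotype_matrix(toy_markers(n_mk), sheet, calls)
  res <- ibd_check(gm)

  # brute-force expectation of the raw sharing score from the simulated
  # allele-frequency spectrum (enumerating genotype combinations)
  share <- function(a, b) (2 - abs(a - b)) / 2
  exp_po <- exp_un <- 0
  for (i in seq_len(n_mk)) {
    pg <- c((1 - q[i])^2, 2 * q[i] * (1 - q[i]), q[i]^2)
    for (gp in 0:2) for (go in 0:2) {
      # P(offspring go | parent gp): transmitted allele + population allele
      t_probs <- switch(gp + 1, c(1, 0), c(0.5, 0.5), c(0, 1))
      p_go <- sum(vapply(0:1, function(tr) {
        t_probs[tr + 1] * (if ((go - tr) %in% 0:1)
          dbinom(go - tr, 1, q[i]) else 0)
      }, numeric(1)))
      exp_po <- exp_po + pg[gp + 1] * p_go * share(gp, go)
      exp_un <- exp_un + pg[gp + 1] * pg[go + 1] * share(gp, go)
    }
  }
  exp_po <- exp_po / n_mk
  exp_un <- exp_un / n_mk

  true_kids <- 1:5
  expect_lt(max(abs(res$share_mother[true_kids] - exp_po)), 0.02)
  expect_lt(abs(res$share_mother[6] - exp_un), 0.02)

  # relatedness estimate: ~0.5 for true offspring, ~0 for the contaminant;
  # the 0.35 flag separates them
  expect_lt(max(abs(res$ibd_mother[true_kids] - 0.5)), 0.07)
  expect_lt(abs(res$ibd_mother[6]), 0.12)
  expect_identical(res$exclude, c(rep(FALSE, 5), TRUE))
})

test_that("classify_and_filter applies the Mendelian chi-square screen", {
  sheet <- toy_sheet(30)
  mk <- toy_markers(3)
  calls <- matrix(0L, 3, nrow(sheet), dimnames = list(NULL, sheet$id))
  off <- sheet$id[sheet$role == "offspring"]
  # marker 1: perfect 15:15 testcross; marker 2: distorted 25:5;
  # marker 3: uninformative (both parents hom-ref)
  calls[1, "FAT1"] <- 1L; calls[1, off] <- rep(c(1L, 0L), 15)
  calls[2, "FAT1"] <- 1L; calls[2, off] <- c(rep(1L, 25), rep(0L, 5))
  gm <- genotype_matrix(mk, sheet, calls)
  res <- classify_and_filter(gm, tolerance = 0.001)
  expect_equal(res$class, c("paternal-testcross", "paternal-testcross",
                            "uninformative"))
  expect_equal(res$segregation_p[1], 1.0)
  expect_equal(res$segregation_p[2],
               pchisq(40 / 3, df = 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(res$keep, c(TRUE, FALSE, TRUE))
})

test_that("find_y_snps applies the joint cross-family criterion", {
  sheet <- rbind(toy_sheet(10, "fam1"), toy_sheet(10, "fam2"))
  sheet <- sheet[!duplicated(sheet$id), ]
  # two families share parents here; that is fine for the scan itself
  males <- sheet$id[sheet$sex == "M"]
  females <- sheet$id[sheet$sex == "F"]
  mk <- toy_markers(4)
  calls <- matrix(0L, 4, nrow(sheet), dimnames = list(NULL, sheet$id))
  calls[1, males] <- 1L                      # perfect Y-SNP
  calls[2, males] <- 1L; calls[2, males[1]] <- 0L   # one male hom-ref
  calls[3, males] <- 1L; calls[3, females[1]] <- 1L # a het female
  calls[4, males] <- 1L; calls[4, males[2]] <- NA   # one missing call
  gm <- genotype_matrix(mk, sheet, calls)

  res <- find_y_snps(gm)
  expect_equal(res$markers$pos, mk$pos[1])
  expect_equal(res$n, 1L)

  # relaxing the call-rate admits the marker with a missing call
  res2 <- find_y_snps(gm, min_call_rate = 0.9)
  expect_setequal(res2$markers$pos, mk$pos[c(1, 4)])

  # invariance to sample order
  perm <- sample(nrow(sheet))
  gm_p <- genotype_matrix(mk, sheet[perm, ], calls[, perm])
  expect_setequal(find_y_snps(gm_p)$markers$pos, res$markers$pos)
})

test_that("nry_boundaries reports inner span and tested-negative flanks", {
  gt <- read.delim(extdata("sdr_gene_table.tsv"))
  y_genes <- gt$gene_id[!is.na(gt$y_snps) & gt$y_snps > 0]
  res <- nry_boundaries(y_genes, gt)
  expect_equal(res$inner, c(222.55, 223.87))
  expect_equal(res$outer, c(220.99, 225.22))
  expect_equal(res$genes,
               paste0("evm.chr2.", 642:645))
  expect_equal(res$flanks, c("evm.chr2.638", "evm.chr2.649"))

  single <- nry_boundaries("evm.chr2.643", gt)
  expect_equal(single$inner, c(222.97, 222.97))

  empty <- nry_boundaries(character(0), gt)
  expect_null(empty$inner)
})

test_that("add_sex_snp appends a synthetic sex marker", {
  sheet <- toy_sheet(4)
  gm <- random_geno(5, sheet, seed = 3)
  gmx <- add_sex_snp(gm)
  n <- nrow(gmx$markers)
  expect_equal(nrow(gmx$markers), 6L)
  expect_true(gmx$markers$synthetic[n])
  expect_true(is.na(gmx$markers$pos[n]))
  expect_equal(unname(gmx$calls[n, ]),
               ifelse(sheet$sex == "M", 1L, 0L))
  sheet_u <- sheet
  sheet_u$sex[3] <- "unknown"
  gm_u <- genotype_matrix(gm$markers, sheet_u, gm$calls)
  expect_error(add_sex_snp(gm_u), "sexed")
})

test_that("two_point_rf matches the binomial likelihood-ratio by hand", {
  t_a <- rep(c(0L, 1L), 5)
  r0 <- two_point_rf(t_a, t_a)
  expect_equal(r0$rf, 0)
  expect_equal(r0$lod, 10 * log10(2), tolerance = 1e-9)

  t_b <- t_a
  t_b[1:2] <- 1L - t_b[1:2]
  # phase fixed within the single family: 2 recombinants of 10 ... but the
  # per-family majority rule keeps the minimizing phase
  r2 <- two_point_rf(t_a, t_b)
  expect_equal(r2$rf, 0.2)
  expect_equal(r2$lod, 2 * log10(0.2) + 8 * log10(0.8) + 10 * log10(2),
               tolerance = 1e-9)

  t_c <- rep(1L, 10)   # five mismatches; phase-symmetric
  r5 <- two_point_rf(t_a, t_c)
  expect_equal(r5$rf, 0.5)
  expect_equal(r5$lod, 0)

  expect_error(two_point_rf(rep(NA_integer_, 4), rep(0L, 4)),
               "no informative meioses")
})

test_that("unlinked marker clusters form separate linkage groups", {
  set.seed(5)
  n_off <- 40
  sheet <- toy_sheet(n_off)
  off <- sheet$id[sheet$role == "offspring"]
  t1 <- sample(0:1, n_off, replace = TRUE)
  t2 <- sample(0:1, n_off, replace = TRUE)
  mk <- toy_markers(8)
  calls <- matrix(0L, 8, nrow(sheet), dimnames = list(NULL, sheet$id))
  calls[, "FAT1"] <- 1L
  for (i in 1:4) calls[i, off] <- t1
  for (i in 5:8) calls[i, off] <- t2
  gm <- genotype_matrix(mk, sheet, calls)
  map <- build_map(gm)
  expect_equal(length(unique(map$male$group)), 2L)
})

test_that("a clean fully-informative chromosome is ordered and measured
           accurately", {
  true_cm <- sort(c(0, cumsum(runif(59, 0.5, 3))))
  sim <- clean_testcross_sim(true_cm, n_off = 100, seed = 6)
  map <- build_map(sim$gm)
  mm <- map$male
  main <- as.integer(names(which.max(table(mm$group))))
  d <- mm[mm$group == main, ]
  expect_gte(nrow(d), 55)
  tc <- sim$true_cm[match(d$pos, sim$gm$markers$pos)]
  expect_gt(abs(cor(d$cm, tc, method = "spearman")), 0.95)
  len <- max(d$cm)
  expect_lt(abs(len - max(true_cm)) / max(true_cm), 0.25)
})

test_that("map_physical_integration finds constant-cM spans and jumps", {
  # a 50.9 Mb block of co-locating markers between flanking recombining ones
  df <- data.frame(
    pos = c(1e6, 50e6, seq(200.8e6, 251.7e6, length.out = 8), 280e6),
    cm = c(0, 20, rep(45, 8), 60))
  res <- map_physical_integration(df, k = 5)
  expect_equal(nrow(res$spans), 1L)
  expect_equal(res$spans$start, 200.8e6)
  expect_equal(res$spans$end, 251.7e6)
  expect_equal(res$spans$end - res$spans$start, 50.9e6)

  inc <- data.frame(pos = seq(1e6, 100e6, length.out = 20),
                    cm = seq(0, 100, length.out = 20))
  expect_equal(nrow(map_physical_integration(inc)$spans), 0L)

  jump <- data.frame(pos = c(1e6, 2e6, 3e6), cm = c(0, 90, 95))
  disc <- map_physical_integration(jump)$discontinuities
  expect_equal(nrow(disc), 1L)
  expect_equal(disc$cm_jump, 90)
})
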