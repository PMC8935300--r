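# NG86 site/difference counting, Jukes-Cantor correction, dating and the
# relative-rates test.

# Independent oracle: classify the substitution pathways between two codons
# by brute-force enumeration over orderings, excluding stop pathways.
oracle_pair_diffs <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (r in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], r)
    out
  }
  syn_counts <- c()
  for (ord in perms(pos)) {
    cur <- a; syn <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (code[nxt] == "*") { ok <- FALSE; break }
      syn <- syn + (code[cur] == code[nxt])
      cur <- nxt
    }
    if (ok) syn_counts <- c(syn_counts, syn)
  }
  if (length(syn_counts) == 0) return(NULL)
  c(mean(syn_counts), length(pos) - mean(syn_counts))
}

test_that("ng86_sites matches codon-neighbour enumeration", {
  expect_equal(unname(ng86_sites("TTT")), c(1 / 3, 8 / 3))
  expect_equal(unname(ng86_sites("CTT")), c(1, 2))
  expect_equal(unname(ng86_sites("ATG")), c(0, 3))
  # TAT: two of the three 3rd-position changes create stops and are
  # excluded from the denominator, leaving a full synonymous site there
  expect_equal(unname(ng86_sites("TAT")), c(1, 2))
  # every sense codon contributes exactly three sites
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"], character(0))
  totals <- vapply(sense, function(cod) sum(ng86_sites(cod)), numeric(1))
  expect_true(all(abs(totals - 3) < 1e-12))
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_sites("ANT"), "ambiguous")
})

test_that("ng86_pairwise counts sites and pathway-averaged differences", {
  a <- strrep("CTT", 10)
  b <- paste0(strrep("CTT", 9), "CTC")
  r <- ng86_pairwise(a, b)
  expect_equal(r$Sd, 1)
  expect_equal(r$S, 10)
  expect_equal(r$Nd, 0)
  expect_equal(r$N, 20)

  same <- ng86_pairwise(a, a)
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
})

test_that("ng86_pairwise agrees with brute-force pathway enumeration and
           is symmetric", {
  set.seed(42)
  for (rep in 1:8) {
    x <- random_cds(40)
    y <- simulate_gametolog_pair(x, 0.15, 0.1)$y
    r1 <- suppressWarnings(ng86_pairwise(x, y))
    r2 <- suppressWarnings(ng86_pairwise(y, x))
    expect_equal(r1$Sd, r2$Sd)
    expect_equal(r1$S, r2$S)
    # Sd+Nd equals the integer nucleotide difference count over analysed
    # codons; S+N = 3 x analysed codons
    expect_equal(r1$Sd + r1$Nd, round(r1$Sd + r1$Nd), tolerance = 1e-9)
    expect_equal(r1$S + r1$N, 3 * r1$codons_analysed)
    # oracle on each differing codon
    cx <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
    cy <- substring(y, seq(1, nchar(y), 3), seq(3, nchar(y), 3))
    sd <- nd <- 0
    for (i in which(cx != cy)) {
      o <- oracle_pair_diffs(cx[i], cy[i])
      if (!is.null(o)) { sd <- sd + o[1]; nd <- nd + o[2] }
    }
    expect_equal(r1$Sd, sd, tolerance = 1e-9)
    expect_equal(r1$Nd, nd, tolerance = 1e-9)
  }
})

test_that("codons with N or stops are masked, shrinking denominators", {
  a <- paste0("ATG", "NNN", "CTT")
  b <- paste0("ATG", "AAA", "CTC")
  r <- ng86_pairwise(a, b)
  expect_equal(r$codons_analysed, 2L)
  expect_equal(r$codons_skipped, 1L)
  expect_equal(r$S + r$N, 6)
})

test_that("jc_correct implements -(3/4)ln(1-4p/3)", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.1), 0.1073256, tolerance = 1e-6)
  expect_equal(round(jc_correct(43.50 / 455.25), 3), 0.102)
  expect_error(jc_correct(0.75), "saturated")
  expect_error(jc_correct(0.9), "saturated")
  expect_equal(jc_correct(c(0, 0.1)), c(0, 0.1073256), tolerance = 1e-6)
})

test_that("kaks composes counting and correction; ratio undefined at Ks=0", {
  a <- strrep("GAT", 50)
  r <- kaks(a, a)
  expect_equal(r$Ks, 0)
  expect_equal(r$Ka, 0)
  expect_true(is.na(r$ka_ks))

  rc <- kaks_from_counts(3.00, 80.33, 5.00, 249.67)
  expect_equal(round(rc$Ks, 3), 0.038)
  expect_equal(round(rc$Ka, 3), 0.020)
  expect_equal(round(rc$ka_ks, 2), 0.53)
})

test_that("date_divergence applies T = g*Ks/(2m)", {
  expect_equal(date_divergence(0.1, 25, 1e-8)$T_years, 125e6)
  expect_equal(date_divergence(0.048, 25, 1e-8)$T_years, 60e6)
  expect_equal(date_divergence(0, 25, 1e-8)$T_years, 0)
  expect_error(date_divergence(0.1, 25, 0), "positive")
})

test_that("rrt_chisq reproduces the 1-df chi-square", {
  r <- rrt_chisq(4, 14)
  expect_equal(round(r$chi2, 2), 5.56)
  expect_equal(round(r$p, 3), 0.018)
  expect_equal(rrt_chisq(0, 2)$chi2, 2)
  expect_equal(rrt_chisq(3, 3)$chi2, 0)
  expect_equal(rrt_chisq(0, 0)$p, 1)
})

test_that("tajima_rrt classifies site patterns per codon position", {
  # construct an alignment with known pattern counts at position 1
  # mX sites: x differs, y == outgroup; mY sites: y differs
  x <- y <- o <- rep("ATT", 60)
  mx_at <- 1:4          # codons where x differs at position 1
  my_at <- 5:18         # 14 codons where y differs at position 1
  mo_at <- 19:20
  for (i in mx_at) x[i] <- "CTT"
  for (i in my_at) y[i] <- "GTT"
  for (i in mo_at) o[i] <- "TTT"
  res <- tajima_rrt(paste0(x, collapse = ""), paste0(y, collapse = ""),
                    paste0(o, collapse = ""))
  p1 <- res[res$codon_position == "1", ]
  expect_equal(p1$mX, 4)
  expect_equal(p1$mY, 14)
  expect_equal(p1$mO, 2)
  expect_equal(p1$invariable, 40)
  expect_equal(round(p1$chi2, 2), 5.56)
  expect_equal(round(p1$p, 3), 0.018)
  # positions 2 and 3 are invariable throughout
  expect_equal(res$chi2[res$codon_position != "1"], c(0, 0))

  # swapping x and y swaps mX and mY and keeps chi2
  swapped <- tajima_rrt(paste0(y, collapse = ""), paste0(x, collapse = ""),
                        paste0(o, collapse = ""))
  s1 <- swapped[swapped$codon_position == "1", ]
  expect_equal(s1$mX, p1$mY)
  expect_equal(s1$mY, p1$mX)
  expect_equal(s1$chi2, p1$chi2)

  pooled <- tajima_rrt(paste0(x, collapse = ""), paste0(y, collapse = ""),
                       paste0(o, collapse = ""), by_codon_position = FALSE)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$sites, 180L)
})

test_that("tajima_rrt skips sites with ambiguous bases", {
  x <- "ATTNTT"
  y <- "ATTATT"
  o <- "ATTATT"
  res <- tajima_rrt(x, y, o, by_codon_position = FALSE)
  expect_equal(res$sites, 5L)
})
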