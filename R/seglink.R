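# Pedigree QC, segregation filtering, Y-SNP scan, NRY boundary inference,
# sexSNP-augmented two-point linkage mapping and genetic/physical map
# integration.

# Allele-sharing score between two unphased biallelic genotypes (dosages):
# 1 if they share both alleles, 0.5 if one, 0 if none.
.share_score <- function(a, b) (2 - abs(a - b)) / 2

# Frequency-free relatedness estimate (KING-robust kinship, scaled to the
# relatedness coefficient): r = 2 * (N_both_het - 2 N_opposite_hom) /
# (N_het_1 + N_het_2). ~0.5 for a parent-offspring pair, ~0 for an
# unrelated pair, and unaffected by family structure in the sample (no
# allele-frequency estimate is needed).
.king_relatedness <- function(g1, g2) {
  both_het <- sum(g1 == 1L & g2 == 1L)
  opp_hom <- sum((g1 == 0L & g2 == 2L) | (g1 == 2L & g2 == 0L))
  het1 <- sum(g1 == 1L)
  het2 <- sum(g2 == 1L)
  if (het1 + het2 == 0L) return(NA_real_)
  2 * (both_het - 2 * opp_hom) / (het1 + het2)
}

#' Relatedness check of offspring against their named parents
#'
#' For every offspring and each named parent, reports (i) the mean
#' per-marker allele-sharing score (1 = both alleles shared, 0.5 = one,
#' 0 = none; missing calls skipped) as a diagnostic, and (ii) a
#' KING-robust relatedness estimate (frequency-free), which is ~0.5 for a true parent-offspring pair and ~0
#' for an unrelated pair. Offspring whose relatedness with a named parent
#' falls below `threshold` are flagged as possible contaminants and
#' excluded from mapping.
#'
#' @param gm A [genotype_matrix()].
#' @param threshold Exclusion threshold on the relatedness estimate
#'   (default 0.35).
#' @return `data.frame` with per-offspring sharing scores
#'   (`share_mother`, `share_father`), relatedness estimates
#'   (`ibd_mother`, `ibd_father`), marker counts, per-parent flags and an
#'   `exclude` column.
#' @export
ibd_check <- function(gm, threshold = 0.35) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sheet <- gm$samples
  if (nrow(gm$markers) < 100)
    warning("fewer than 100 markers; relatedness estimates will be noisy")
  off <- sheet[sheet$role == "offspring", , drop = FALSE]
  if (nrow(off) == 0) stop("no offspring in sample sheet")

  one <- function(oid, pid) {
    if (is.na(pid) || !pid %in% colnames(gm$calls))
      return(c(NA_real_, NA_real_, 0))
    a <- gm$calls[, oid]
    b <- gm$calls[, pid]
    use <- !is.na(a) & !is.na(b)
    if (!any(use)) return(c(NA_real_, NA_real_, 0))
    c(mean(.share_score(a[use], b[use])),
      .king_relatedness(a[use], b[use]),
      sum(use))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(off)), function(i) {
    m <- one(off$id[i], off$mother_id[i])
    f <- one(off$id[i], off$father_id[i])
    if (m[3] == 0 && f[3] == 0)
      stop("offspring ", off$id[i],
           " has no genotyped parent (or no overlapping calls)")
    data.frame(id = off$id[i],
               share_mother = m[1], ibd_mother = m[2], n_mother = m[3],
               share_father = f[1], ibd_father = f[2], n_father = f[3],
               stringsAsFactors = FALSE)
  }))
  res$flag_mother <- !is.na(res$ibd_mother) & res$ibd_mother < threshold
  res$flag_father <- !is.na(res$ibd_father) & res$ibd_father < threshold
  res$exclude <- res$flag_mother | res$flag_father
  res
}

# Per-family marker informativeness from the parental genotypes.
# Returns "paternal", "maternal", "intercross" or NA (uninformative).
.family_class <- function(father_call, mother_call) {
  if (is.na(father_call) || is.na(mother_call)) return(NA_character_)
  f_het <- father_call == 1L
  m_het <- mother_call == 1L
  if (f_het && !m_het) return("paternal")
  if (!f_het && m_het) return("maternal")
  if (f_het && m_het) return("intercross")
  NA_character_
}

.families <- function(sheet) {
  off <- sheet[sheet$role == "offspring", , drop = FALSE]
  fams <- unique(off[, c("family", "mother_id", "father_id")])
  if (anyDuplicated(fams$family))
    stop("inconsistent parent links: a family maps to several parent pairs")
  fams
}

#' Classify markers and filter on segregation distortion
#'
#' Informativeness is read off the parental genotypes per family
#' (testcross: one parent heterozygous, the other homozygous; intercross:
#' both heterozygous). Observed offspring genotype counts, pooled across
#' informative families, are tested against the Mendelian expectation (1:1
#' for a testcross, 1:2:1 for an intercross) with a chi-square
#' goodness-of-fit test; markers with `p < tolerance` are flagged for
#' exclusion. Uninformative markers pass through labelled.
#'
#' @param gm A [genotype_matrix()] including parent columns.
#' @param tolerance Segregation p-value below which a marker is excluded
#'   (default 0.001).
#' @return `data.frame`, one row per marker: `class` (paternal-testcross /
#'   maternal-testcross / intercross / uninformative), `segregation_p`,
#'   `keep`.
#' @export
classify_and_filter <- function(gm, tolerance = 0.001) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sheet <- gm$samples
  fams <- .families(sheet)
  if (nrow(fams) == 0) stop("no offspring families in sheet")
  off_by_fam <- lapply(fams$family, function(f)
    sheet$id[sheet$role == "offspring" & sheet$family == f])

  n_mk <- nrow(gm$markers)
  class_out <- character(n_mk)
  p_out <- numeric(n_mk)
  for (i in seq_len(n_mk)) {
    chi2 <- 0
    df <- 0L
    fam_classes <- character(0)
    # pooled testcross counts (recoded as carrier/non-carrier of the
    # het parent's transmitted alternate) and pooled intercross counts
    tc <- c(0L, 0L)
    ic <- c(0L, 0L, 0L)
    for (fi in seq_len(nrow(fams))) {
      fa <- gm$calls[i, fams$father_id[fi]]
      mo <- gm$calls[i, fams$mother_id[fi]]
      cls <- .family_class(fa, mo)
      if (is.na(cls)) next
      kid <- gm$calls[i, off_by_fam[[fi]]]
      kid <- kid[!is.na(kid)]
      if (length(kid) == 0) next
      fam_classes <- c(fam_classes, cls)
      if (cls == "intercross") {
        ic <- ic + c(sum(kid == 0L), sum(kid == 1L), sum(kid == 2L))
      } else {
        hom_parent <- if (cls == "paternal") mo else fa
        # offspring matching the hom parent vs het carriers
        hom_class <- if (hom_parent == 0L) 0L else 2L
        tc <- tc + c(sum(kid == 1L), sum(kid == hom_class))
      }
    }
    if (length(fam_classes) == 0) {
      class_out[i] <- "uninformative"
      p_out[i] <- NA_real_
      next
    }
    if (sum(tc) > 0) {
      e <- sum(tc) / 2
      chi2 <- chi2 + sum((tc - e)^2 / e)
      df <- df + 1L
    }
    if (sum(ic) > 0) {
      e <- sum(ic) * c(0.25, 0.5, 0.25)
      chi2 <- chi2 + sum((ic - e)^2 / e)
      df <- df + 2L
    }
    p_out[i] <- if (df > 0)
      stats::pchisq(chi2, df = df, lower.tail = FALSE) else NA_real_
    has <- unique(fam_classes)
    class_out[i] <-
      if (identical(has, "paternal")) "paternal-testcross"
      else if (identical(has, "maternal")) "maternal-testcross"
      else if (identical(has, "intercross")) "intercross"
      else "intercross"  # mixed informativeness across families
  }
  out <- data.frame(gm$markers[, c("chrom", "pos")],
                    class = class_out, segregation_p = p_out,
                    stringsAsFactors = FALSE)
  out$keep <- out$class == "uninformative" |
    (!is.na(out$segregation_p) & out$segregation_p >= tolerance)
  out
}

#' Scan for Y-specific SNPs
#'
#' Returns the markers at which, jointly across all families, every
#' non-missing male (parents and offspring) is heterozygous for the
#' alternative allele and every non-missing female is homozygous reference —
#' the segregation signature of a fixed X/Y difference under male
#' heterogamety. Markers must reach `min_call_rate` across sexed samples and
#' have at least one called male and one called female.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Minimum fraction of sexed samples with a genotype
#'   call (default 1.0: no missing calls tolerated).
#' @return Object of class `y_snp_set`: list with `markers` (marker rows +
#'   `marker_idx`), `per_gene` (named tally by `gene_id`) and `n`.
#' @export
find_y_snps <- function(gm, min_call_rate = 1.0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sheet <- gm$samples
  males <- sheet$id[sheet$sex == "M"]
  females <- sheet$id[sheet$sex == "F"]
  if (length(males) == 0 || length(females) == 0)
    stop("need at least one male and one female sexed sample")
  cm <- gm$calls[, males, drop = FALSE]
  cf <- gm$calls[, females, drop = FALSE]
  called <- rowSums(!is.na(gm$calls[, c(males, females), drop = FALSE]))
  rate <- called / (length(males) + length(females))
  ok <- rowSums(!is.na(cm)) > 0 & rowSums(!is.na(cf)) > 0 &
    rate >= min_call_rate &
    rowSums(cm != 1L, na.rm = TRUE) == 0L &
    rowSums(cf != 0L, na.rm = TRUE) == 0L
  idx <- which(ok)
  mk <- gm$markers[idx, , drop = FALSE]
  mk$marker_idx <- idx
  per_gene <- if ("gene_id" %in% names(mk) && nrow(mk) > 0)
    table(mk$gene_id) else table(character(0))
  structure(list(markers = mk, per_gene = per_gene, n = length(idx)),
            class = "y_snp_set")
}

#' @exportS3Method base::print
print.y_snp_set <- function(x, ...) {
  cat("y_snp_set:", x$n, "Y-specific SNP(s)\n")
  if (x$n > 0) print(x$per_gene)
  invisible(x)
}

#' Infer the boundaries of the non-recombining Y-specific region
#'
#' Given a Y-SNP scan and a table of gene positions, finds the maximal run
#' of Y-SNP-bearing genes not interrupted by any tested gene without
#' Y-SNPs. Reports the inner span (first to last Y-SNP gene) and the outer
#' bound (the nearest flanking genes that were tested for SNPs but carry
#' none), the two resolutions at which the region can be delimited.
#'
#' @param y_set A `y_snp_set` from [find_y_snps()], or a character vector of
#'   Y-SNP-bearing gene ids.
#' @param gene_table `data.frame` with columns `gene_id`, `pos_mb` and
#'   logical `tested` (gene had at least one scorable SNP).
#' @return List with `inner` (c(start, end) in Mb, `NULL` when no Y-SNP
#'   genes), `outer` (flanking-gene positions; `NA` side when no tested
#'   negative flank exists), `genes` (ids in the run) and `flanks` (ids).
#' @export
nry_boundaries <- function(y_set, gene_table) {
  stopifnot(all(c("gene_id", "pos_mb", "tested") %in% names(gene_table)))
  y_genes <- if (inherits(y_set, "y_snp_set")) names(y_set$per_gene)
             else as.character(y_set)
  gt <- gene_table[order(gene_table$pos_mb), , drop = FALSE]
  gt$has_y <- gt$gene_id %in% y_genes
  if (!any(gt$has_y))
    return(list(inner = NULL, outer = NULL, genes = character(0),
                flanks = character(0)))
  # runs of Y-genes separated only by untested genes
  state <- ifelse(gt$has_y, "Y", ifelse(gt$tested, "neg", "untested"))
  runs <- list()
  current <- integer(0)
  for (i in seq_len(nrow(gt))) {
    if (state[i] == "Y") current <- c(current, i)
    else if (state[i] == "neg" && length(current) > 0) {
      runs[[length(runs) + 1L]] <- current
      current <- integer(0)
    }
  }
  if (length(current) > 0) runs[[length(runs) + 1L]] <- current
  best <- runs[[which.max(vapply(runs, length, integer(1)))]]
  ygene_rows <- best[gt$has_y[best]]
  inner <- c(gt$pos_mb[ygene_rows[1]], gt$pos_mb[ygene_rows[length(ygene_rows)]])
  below <- which(state == "neg" & seq_len(nrow(gt)) < ygene_rows[1])
  above <- which(state == "neg" & seq_len(nrow(gt)) > ygene_rows[length(ygene_rows)])
  lo <- if (length(below) > 0) max(below) else NA_integer_
  hi <- if (length(above) > 0) min(above) else NA_integer_
  outer <- c(if (is.na(lo)) NA_real_ else gt$pos_mb[lo],
             if (is.na(hi)) NA_real_ else gt$pos_mb[hi])
  list(inner = inner, outer = outer,
       genes = gt$gene_id[ygene_rows],
       flanks = gt$gene_id[c(lo, hi)[!is.na(c(lo, hi))]])
}

#' Append the sexSNP pseudo-marker
#'
#' Adds a synthetic marker heterozygous in every male and homozygous
#' reference in every female (parents and offspring), so that linkage
#' mapping localizes the sex locus like any other testcross marker. The
#' marker is flagged `synthetic` and carries no physical position.
#'
#' @param gm A [genotype_matrix()]; all samples must be sexed.
#' @return The matrix with the appended marker (gene_id `"sexSNP"`).
#' @export
add_sex_snp <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (any(gm$samples$sex == "unknown"))
    stop("all samples must be sexed to place the sexSNP")
  mk <- gm$markers
  new <- mk[1, , drop = FALSE]
  new[1, ] <- NA
  new$chrom <- NA_character_
  new$pos <- NA_integer_
  new$ref <- "A"
  new$alt <- "T"
  if ("gene_id" %in% names(mk)) new$gene_id <- "sexSNP"
  new$synthetic <- TRUE
  calls <- rbind(gm$calls, ifelse(gm$samples$sex == "M", 1L, 0L))
  genotype_matrix(rbind(mk, new), gm$samples, calls)
}

# Transmitted-allele matrices for testcross markers: for each offspring
# meiosis, which allele (0/1) the phased parent transmitted; NA when the
# family is uninformative at the marker or the call is missing/inconsistent.
.transmissions <- function(gm, parent = c("father", "mother")) {
  parent <- match.arg(parent)
  sheet <- gm$samples
  fams <- .families(sheet)
  off <- sheet[sheet$role == "offspring", , drop = FALSE]
  tr <- matrix(NA_integer_, nrow = nrow(gm$markers), ncol = nrow(off),
               dimnames = list(NULL, off$id))
  ic <- matrix(FALSE, nrow = nrow(gm$markers), ncol = nrow(fams),
               dimnames = list(NULL, fams$family))
  for (fi in seq_len(nrow(fams))) {
    het_id <- if (parent == "father") fams$father_id[fi] else fams$mother_id[fi]
    hom_id <- if (parent == "father") fams$mother_id[fi] else fams$father_id[fi]
    het <- gm$calls[, het_id]
    hom <- gm$calls[, hom_id]
    kids <- off$id[off$family == fams$family[fi]]

    # testcross: this parent het, the other hom
    inform <- which(!is.na(het) & !is.na(hom) & het == 1L & hom != 1L)
    kid_calls <- gm$calls[inform, kids, drop = FALSE]
    zero_rows <- hom[inform] == 0L
    # hom parent 0/0: offspring het received alt (1) from the het parent;
    # hom parent 1/1: offspring het received ref (0).
    t_val <- matrix(NA_integer_, nrow = length(inform), ncol = length(kids))
    t_val[kid_calls == 1L & zero_rows] <- 1L
    t_val[kid_calls == 0L & zero_rows] <- 0L
    t_val[kid_calls == 1L & !zero_rows] <- 0L
    t_val[kid_calls == 2L & !zero_rows] <- 1L
    tr[inform, kids] <- t_val

    # intercross: both parents het; homozygous offspring resolve the
    # transmitted allele, heterozygous offspring stay ambiguous
    inter <- which(!is.na(het) & !is.na(hom) & het == 1L & hom == 1L)
    if (length(inter) > 0) {
      kid_ic <- gm$calls[inter, kids, drop = FALSE]
      t_ic <- matrix(NA_integer_, nrow = length(inter), ncol = length(kids))
      t_ic[kid_ic == 0L] <- 0L
      t_ic[kid_ic == 2L] <- 1L
      tr[inter, kids] <- t_ic
      ic[inter, fams$family[fi]] <- TRUE
    }
  }
  list(trans = tr, family = off$family, ic = ic)
}

#' Two-point recombination fraction and LOD between two testcross markers
#'
#' Transmission vectors hold, per meiosis, the allele the doubly-informative
#' parent passed on (0/1, `NA` skipped). Linkage phase is resolved per
#' family by majority rule (the phase minimizing recombinants); recombinant
#' counts are then pooled. `rf = recombinants / informative meioses`; the
#' LOD score is the base-10 likelihood ratio of the binomial at the
#' (clamped) estimate against free recombination (rf = 0.5), with the
#' `0 * log(0) = 0` convention so that zero recombinants give
#' `LOD = n * log10(2)`.
#'
#' @param trans_a,trans_b Integer vectors of transmitted alleles per meiosis.
#' @param family Factor/character of the family of each meiosis (phase is
#'   per-family).
#' @return List with `rf`, `lod`, `n` (informative meioses), `recombinants`.
#' @export
two_point_rf <- function(trans_a, trans_b, family = rep("f1", length(trans_a))) {
  stopifnot(length(trans_a) == length(trans_b),
            length(family) == length(trans_a))
  rec <- 0L
  n <- 0L
  for (f in unique(family)) {
    i <- family == f & !is.na(trans_a) & !is.na(trans_b)
    if (!any(i)) next
    d <- sum(trans_a[i] != trans_b[i])
    n_f <- sum(i)
    rec <- rec + min(d, n_f - d)
    n <- n + n_f
  }
  if (n == 0L) stop("no informative meioses shared by the two markers")
  rf <- rec / n
  list(rf = rf, lod = .lod(rec, n), n = n, recombinants = rec)
}

.lod <- function(rec, n) {
  rhat <- min(max(rec / n, 0), 0.5)
  term <- function(k, p) if (k == 0L) 0 else k * log10(p)
  term(rec, rhat) + term(n - rec, 1 - rhat) + n * log10(2)
}

# Vectorized pooled recombinant/meiosis counts for all marker pairs of a
# transmission matrix (markers x meioses), phase per family by majority rule.
.pair_counts <- function(tr, family, ic = NULL) {
  m <- nrow(tr)
  rec <- matrix(0, m, m)
  n <- matrix(0, m, m)
  for (f in unique(family)) {
    A <- tr[, family == f, drop = FALSE]
    A0 <- (!is.na(A)) & A == 0L
    A1 <- (!is.na(A)) & A == 1L
    storage.mode(A0) <- "numeric"
    storage.mode(A1) <- "numeric"
    d <- A1 %*% t(A0) + A0 %*% t(A1)
    nf <- (A0 + A1) %*% t(A0 + A1)
    if (!is.null(ic)) {
      # a pair of markers both intercross-derived in this family is
      # unusable: observing both transmissions conditions on the other
      # parent's co-transmission and biases the recombinant count
      bad <- outer(ic[, f], ic[, f], "&")
      d[bad] <- 0
      nf[bad] <- 0
    }
    rec <- rec + pmin(d, nf - d)
    n <- n + nf
  }
  list(rec = rec, n = n)
}

.lod_matrix <- function(pc) {
  rf <- ifelse(pc$n > 0, pc$rec / pc$n, 0.5)
  rhat <- pmin(pmax(rf, 0), 0.5)
  t1 <- ifelse(pc$rec > 0, pc$rec * log10(rhat), 0)
  t2 <- ifelse(pc$n - pc$rec > 0, (pc$n - pc$rec) * log10(1 - rhat), 0)
  lod <- t1 + t2 + pc$n * log10(2)
  lod[pc$n == 0] <- 0
  list(rf = rf, lod = lod)
}

# Local search (2-opt reversals + or-opt segment relocations) minimizing the
# total adjacent cost along a path, from a given starting order.
.polish_path <- function(cost, path) {
  m <- length(path)
  if (m <= 2L) return(path)
  edge <- function(a, b) if (a < 1L || b > m) 0 else cost[path[a], path[b]]
  improved <- TRUE
  passes <- 0L
  eps <- 1e-9
  while (improved && passes < 25L) {
    improved <- FALSE
    passes <- passes + 1L
    # 2-opt: reversing path[i:j] replaces edges (i-1,i),(j,j+1);
    # deltas for all j at fixed i are computed vectorized
    for (i in seq_len(m - 1L)) {
      js <- seq(i + 1L, m)
      a <- if (i > 1L) cost[path[i - 1L], path[js]] else numeric(length(js))
      b <- old2 <- numeric(length(js))
      inner <- js < m
      b[inner] <- cost[path[i], path[js[inner] + 1L]]
      old2[inner] <- cost[cbind(path[js[inner]], path[js[inner] + 1L])]
      delta <- a + b - edge(i - 1L, i) - old2
      jbest <- which.min(delta)
      if (delta[jbest] < -eps) {
        j <- js[jbest]
        path[i:j] <- rev(path[i:j])
        improved <- TRUE
      }
    }
    # or-opt: relocate (possibly reversed) segments of length 1..5
    for (len in 1:5) {
      i <- 1L
      while (i + len - 1L <= m) {
        j <- i + len - 1L
        removal_gain <- edge(i - 1L, i) + edge(j, j + 1L) -
          (if (i > 1L && j < m) cost[path[i - 1L], path[j + 1L]] else 0)
        if (removal_gain > eps) {
          seg <- path[i:j]
          rest <- path[-(i:j)]
          mr <- length(rest)
          base_vec <- c(0, cost[cbind(rest[-mr], rest[-1L])], 0)
          ins_cost <- function(s1, s2)
            c(0, cost[rest, s1]) + c(cost[s2, rest], 0) - base_vec
          d_fwd <- removal_gain - ins_cost(seg[1L], seg[len])
          d_rev <- removal_gain - ins_cost(seg[len], seg[1L])
          d_fwd[i] <- -Inf  # k = i-1 recreates the original path
          kf <- which.max(d_fwd)
          kr <- which.max(d_rev)
          if (max(d_fwd[kf], d_rev[kr]) > eps) {
            if (d_rev[kr] > d_fwd[kf]) {
              seg <- rev(seg)
              k <- kr - 1L
            } else k <- kf - 1L
            path <- append(rest, seg, after = k)
            improved <- TRUE
            next
          }
        }
        i <- i + 1L
      }
    }
  }
  path
}

# Order one linkage group. A skeleton of high-information markers (many
# informative meioses) is seriated first: reliable short edges (enough
# shared meioses, rf below saturation) become additive Haldane cM
# distances, completed to all pairs by graph shortest paths and projected
# to one dimension by classical MDS; local search then polishes the
# skeleton. Remaining low-information markers are inserted one at a time at
# their cheapest position and the full path is polished again. A rare
# spurious zero-rf estimate between markers sharing few meioses therefore
# cannot fold the large-scale order.
.order_markers <- function(rf, rec, n) {
  m <- nrow(rf)
  if (m <= 2L) return(seq_len(m))
  smoothed <- (rec + 1) / (n + 2)
  info <- diag(n)
  anchor <- which(info >= 40)
  if (length(anchor) < max(3L, round(0.2 * m))) anchor <- seq_len(m)
  ma <- length(anchor)
  D <- matrix(Inf, ma, ma)
  ok <- n[anchor, anchor] >= 30 & rf[anchor, anchor] <= 0.35
  D[ok] <- haldane_cm(smoothed[anchor, anchor][ok])
  diag(D) <- 0
  for (k in seq_len(ma)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  if (any(!is.finite(D))) {
    big <- if (any(is.finite(D))) max(D[is.finite(D)]) else 1
    D[!is.finite(D)] <- big * 1.5
  }
  init <- order(stats::cmdscale(D, k = 1)[, 1])
  skel <- .polish_path(smoothed, anchor[init])
  skel <- .refine_by_likelihood(skel, rf, rec, n)
  others <- setdiff(seq_len(m), skel)
  if (length(others) == 0) return(skel)

  # cM coordinates of the skeleton from pooled adjacent rf
  ks <- length(skel)
  skel_cm <- c(0, cumsum(haldane_cm(rf[cbind(skel[-ks], skel[-1L])])))
  # candidate positions: slot midpoints plus the two ends
  slot_x <- c(skel_cm[1] - 2, (skel_cm[-ks] + skel_cm[-1L]) / 2,
              skel_cm[ks] + 2)
  # place each remaining marker by the binomial likelihood of its
  # recombinant counts against every skeleton marker under the Haldane
  # distance implied by each candidate position
  slot_of <- integer(length(others))
  for (oi in seq_along(others)) {
    u <- others[oi]
    rec_u <- rec[u, skel]
    n_u <- n[u, skel]
    use <- n_u > 0
    if (!any(use)) { slot_of[oi] <- which.min(abs(slot_x)); next }
    ll <- vapply(slot_x, function(x) {
      r <- 0.5 * (1 - exp(-2 * abs(x - skel_cm[use]) / 100))
      r <- pmin(pmax(r, 1e-4), 0.4999)
      sum(rec_u[use] * log(r) + (n_u[use] - rec_u[use]) * log(1 - r))
    }, numeric(1))
    slot_of[oi] <- which.max(ll)
  }
  path <- skel
  # assemble: slot s inserts after skeleton index s-1 (slot 1 = before all)
  for (s in sort(unique(slot_of), decreasing = TRUE)) {
    ins <- others[slot_of == s]
    after <- if (s == 1L) 0L else match(skel[s - 1L], path)
    path <- append(path, ins, after = after)
  }
  path
}

# Binomial log-likelihood of placing marker/bin `u` at map position `x`,
# given positions `cms` of, and observed recombinant counts against, the
# other path members (Haldane model).
.placement_ll <- function(x, cms, rec_u, n_u) {
  use <- n_u > 0
  if (!any(use)) return(0)
  r <- 0.5 * (1 - exp(-2 * abs(x - cms[use]) / 100))
  r <- pmin(pmax(r, 1e-4), 0.4999)
  sum(rec_u[use] * log(r) + (n_u[use] - rec_u[use]) * log(1 - r))
}

# Iterative multipoint refinement: each path member in turn is removed and
# re-placed at the slot maximizing its placement likelihood against the
# remaining members at their fitted map positions. Resolves local swaps
# that pairwise path costs leave ambiguous.
.refine_by_likelihood <- function(path, rf, rec, n, rounds = 3L) {
  if (length(path) < 4L) return(path)
  for (round in seq_len(rounds)) {
    moved <- FALSE
    cms <- c(0, cumsum(.fit_gap_cm(path, rf, rec, n)))
    i <- 1L
    while (i <= length(path)) {
      u <- path[i]
      rest <- path[-i]
      rcms <- cms[-i]
      kr <- length(rest)
      slot_x <- c(rcms[1] - 2, (rcms[-kr] + rcms[-1L]) / 2, rcms[kr] + 2)
      ll <- vapply(slot_x, .placement_ll, numeric(1),
                   cms = rcms, rec_u = rec[u, rest], n_u = n[u, rest])
      s <- which.max(ll)
      if (!is.finite(ll[s])) { i <- i + 1L; next }
      new_path <- append(rest, u, after = s - 1L)
      if (!identical(new_path, path)) {
        cur_ll <- .placement_ll(cms[i], rcms, rec[u, rest], n[u, rest])
        if (ll[s] > cur_ll + 1e-9) {
          path <- new_path
          cms <- c(0, cumsum(.fit_gap_cm(path, rf, rec, n)))
          moved <- TRUE
        }
      }
      i <- i + 1L
    }
    if (!moved) break
  }
  path
}

# Complete-linkage binning of co-segregating markers: a marker joins a bin
# only if it shows zero recombinants with every bin member it shares
# meioses with, and at least one such pair rests on >= 25 meioses.
# Complete linkage stops chains of accidental zero estimates from merging
# across real distance.
.bin_markers <- function(members, pc) {
  info <- diag(pc$n)[members]
  bins <- list()
  for (i in members[order(info, decreasing = TRUE)]) {
    placed <- FALSE
    for (b in seq_along(bins)) {
      mem <- bins[[b]]
      nn <- pc$n[i, mem]
      rc <- pc$rec[i, mem]
      if (all(rc[nn > 0] == 0) && any(nn >= 25)) {
        bins[[b]] <- c(mem, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) bins[[length(bins) + 1L]] <- i
  }
  bins
}

# Per-bin consensus transmission vectors. Members are first phase-aligned
# per family against the accumulating consensus (a testcross marker's phase
# is arbitrary per family), then the per-meiosis majority is taken; exact
# ties and uncovered meioses stay NA. Bins therefore reach far higher
# effective meiosis counts than any single member.
.bin_transmissions <- function(bins, tr, family, ic = NULL) {
  fams <- unique(family)
  out <- matrix(NA_integer_, nrow = length(bins), ncol = ncol(tr))
  # source of each consensus entry: 2 = backed by a testcross member,
  # 1 = intercross-derived only, 0 = no data
  src <- matrix(0L, nrow = length(bins), ncol = ncol(tr))
  fam_idx <- match(family, fams)
  member_ic <- function(mem_row, cols) {
    if (is.null(ic)) return(rep(FALSE, length(cols)))
    ic[mem_row, fams[fam_idx[cols]]]
  }
  for (b in seq_along(bins)) {
    mem <- bins[[b]]
    if (length(mem) == 1L) {
      out[b, ] <- tr[mem, ]
      has <- !is.na(tr[mem, ])
      src[b, has] <- ifelse(member_ic(mem, which(has)), 1L, 2L)
      next
    }
    sub <- tr[mem, , drop = FALSE]
    cons <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      row <- sub[i, ]
      for (f in fams) {
        idx <- family == f
        both <- idx & !is.na(row) & !is.na(cons)
        if (!any(both)) next
        if (sum(row[both] != cons[both]) > sum(both) / 2)
          row[idx] <- 1L - row[idx]
      }
      fill <- is.na(cons) & !is.na(row)
      cons[fill] <- row[fill]
    }
    # majority over aligned members
    aligned <- sub
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      for (f in fams) {
        idx <- family == f
        both <- idx & !is.na(row) & !is.na(cons)
        if (!any(both)) next
        if (sum(row[both] != cons[both]) > sum(both) / 2)
          row[idx] <- 1L - row[idx]
      }
      aligned[i, ] <- row
    }
    ones <- colSums(aligned == 1L, na.rm = TRUE)
    zeros <- colSums(aligned == 0L, na.rm = TRUE)
    v <- rep(NA_integer_, ncol(tr))
    v[ones > zeros] <- 1L
    v[zeros > ones] <- 0L
    out[b, ] <- v
    if (is.null(ic)) {
      src[b, !is.na(v)] <- 2L
    } else {
      covered <- !is.na(aligned)
      mem_ic <- ic[mem, fams[fam_idx], drop = FALSE]  # member x meiosis
      tc_backed <- colSums(covered & !mem_ic) > 0
      src[b, !is.na(v) & tc_backed] <- 2L
      src[b, !is.na(v) & !tc_backed] <- 1L
    }
  }
  list(tr = out, src = src)
}

# Global phase alignment of bin transmission vectors. Testcross phase is
# arbitrary per family and per bin; pairwise phase minimization biases
# recombinant counts downward at mid distances. Instead, bins are aligned
# family-by-family along a minimum spanning tree of closest links (where
# alignment is unambiguous); afterwards recombinants are plain mismatches.
.align_bin_phases <- function(bin_tr, family, rf_min) {
  nb <- nrow(bin_tr)
  fams0 <- unique(family)
  if (nb <= 1L)
    return(list(tr = bin_tr,
                anchored = matrix(TRUE, nb, length(fams0),
                                  dimnames = list(NULL, fams0))))
  d <- rf_min
  diag(d) <- Inf
  in_tree <- c(TRUE, rep(FALSE, nb - 1L))
  parent <- rep(NA_integer_, nb)
  best <- d[1L, ]
  best_from <- rep(1L, nb)
  order_added <- 1L
  for (step in seq_len(nb - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    parent[nxt] <- best_from[nxt]
    in_tree[nxt] <- TRUE
    order_added <- c(order_added, nxt)
    upd <- !in_tree & d[nxt, ] < best
    best[upd] <- d[nxt, upd]
    best_from[upd] <- nxt
  }
  fams <- unique(family)
  anchored <- matrix(FALSE, nb, length(fams), dimnames = list(NULL, fams))
  anchored[1L, ] <- TRUE  # the root defines the reference phase
  for (b in order_added[-1L]) {
    p <- parent[b]
    for (f in fams) {
      idx <- family == f
      both <- idx & !is.na(bin_tr[b, ]) & !is.na(bin_tr[p, ])
      if (!anchored[p, f] || d[b, p] > 0.35) next
      nn <- sum(both)
      if (nn < 8L) next
      mm <- sum(bin_tr[b, both] != bin_tr[p, both])
      # anchor only on a decisive majority: a coin-flip alignment would
      # propagate a wrong phase to the whole subtree
      if (mm > 0.25 * nn && mm < 0.75 * nn) next
      if (mm > nn / 2) bin_tr[b, idx] <- 1L - bin_tr[b, idx]
      anchored[b, f] <- TRUE
    }
  }
  # relaxation: anchor remaining blocks against any anchored bin (closest
  # first) with decisive overlap, until nothing changes
  repeat {
    changed <- FALSE
    for (b in seq_len(nb)) {
      for (f in fams) {
        if (anchored[b, f]) next
        idx <- family == f
        if (!any(idx & !is.na(bin_tr[b, ]))) next
        cand <- which(anchored[, f] & d[b, ] <= 0.35)
        cand <- cand[order(d[b, cand])]
        for (a in cand) {
          both <- idx & !is.na(bin_tr[b, ]) & !is.na(bin_tr[a, ])
          nn <- sum(both)
          if (nn < 8L) next
          mm <- sum(bin_tr[b, both] != bin_tr[a, both])
          if (mm > 0.25 * nn && mm < 0.75 * nn) next
          if (mm > nn / 2) bin_tr[b, idx] <- 1L - bin_tr[b, idx]
          anchored[b, f] <- TRUE
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  list(tr = bin_tr, anchored = anchored)
}

# Mismatch counts between phase-aligned transmission vectors: plain counts
# where both bins' phases are anchored in a family, the phase-minimizing
# count otherwise.
.aligned_pair_counts <- function(tr_aligned, family, anchored, src = NULL) {
  nb <- nrow(tr_aligned)
  rec <- matrix(0, nb, nb)
  n <- matrix(0, nb, nb)
  for (f in unique(family)) {
    cols <- family == f
    A <- tr_aligned[, cols, drop = FALSE]
    A0 <- (!is.na(A)) & A == 0L
    A1 <- (!is.na(A)) & A == 1L
    storage.mode(A0) <- "numeric"
    storage.mode(A1) <- "numeric"
    d <- A1 %*% t(A0) + A0 %*% t(A1)
    nf <- (A0 + A1) %*% t(A0 + A1)
    if (!is.null(src)) {
      # meioses where both bins carry intercross-derived data only are
      # excluded pairwise (their joint observation is biased)
      S <- src[, cols, drop = FALSE] == 1L
      A0i <- A0 * S
      A1i <- A1 * S
      d <- d - (A1i %*% t(A0i) + A0i %*% t(A1i))
      nf <- nf - (A0i + A1i) %*% t(A0i + A1i)
    }
    ok <- outer(anchored[, f], anchored[, f], "&")
    rec <- rec + ifelse(ok, d, pmin(d, nf - d))
    n <- n + nf
  }
  list(rec = rec, n = n)
}

# Per-gap map distances along an ordered path, fitted by windowed weighted
# least squares: every informative pair spanning up to `window` gaps
# contributes its Haldane distance, weighted by its meiosis count, and the
# per-gap distances are solved by Gauss-Seidel sweeps under d >= 0. Direct
# adjacent rf estimates from few shared meioses are individually too noisy
# (a shared-n of ~25 gives rf = 0 most of the time at ~1 cM spacing);
# pooling over spanning pairs restores the scale. Gaps fitted below
# `snap_cm` collapse to exactly 0 so that co-located markers share one cM
# position.
.fit_gap_cm <- function(path, rf, rec, n, window = 8L, snap_cm = 0.02) {
  k <- length(path)
  if (k < 2L) return(numeric(0))
  d <- haldane_cm(rf[cbind(path[-k], path[-1L])])
  ia <- ib <- integer(0)
  for (span in seq_len(min(window, k - 1L))) {
    ia <- c(ia, seq_len(k - span))
    ib <- c(ib, seq_len(k - span) + span)
  }
  w <- n[cbind(path[ia], path[ib])]
  r <- rf[cbind(path[ia], path[ib])]
  keep <- w > 0 & r < 0.45
  ia <- ia[keep]; ib <- ib[keep]
  w <- w[keep]
  dobs <- haldane_cm(r[keep])
  if (length(ia) == 0) return(d)
  # nonnegative weighted least squares on the gap lengths, solved by
  # coordinate descent on the normal equations; one trimming round drops
  # pairs in gross disagreement with the fit (e.g. residual phase errors,
  # which saturate the observed distance)
  ng <- k - 1L
  solve_nnls <- function(ia, ib, w, dobs, d) {
    A <- matrix(0, length(ia), ng)
    for (p in seq_along(ia)) A[p, ia[p]:(ib[p] - 1L)] <- 1
    M <- crossprod(A, w * A)
    b <- as.vector(crossprod(A, w * dobs))
    for (it in 1:60) {
      d_old <- d
      for (g in seq_len(ng)) {
        if (M[g, g] <= 0) next
        d[g] <- max(0, (b[g] - sum(M[g, ] * d) + M[g, g] * d[g]) / M[g, g])
      }
      if (max(abs(d - d_old)) < 1e-6) break
    }
    d
  }
  d <- solve_nnls(ia, ib, w, dobs, d)
  cumd <- c(0, cumsum(d))
  resid <- dobs - (cumd[ib] - cumd[ia])
  keep2 <- abs(resid) <= pmax(15, 3 * stats::mad(resid))
  if (any(!keep2) && sum(keep2) > ng)
    d <- solve_nnls(ia[keep2], ib[keep2], w[keep2], dobs[keep2], d)
  # exact co-location: no recombinant observed between direct neighbours
  # across many meioses, or a fitted length below resolution
  adj_rf <- rf[cbind(path[-k], path[-1L])]
  adj_n <- n[cbind(path[-k], path[-1L])]
  d[d < snap_cm | (adj_rf == 0 & adj_n >= 30)] <- 0
  d
}

#' Haldane map function
#'
#' `d = -50 * ln(1 - 2 r)` cM; assumes no crossover interference.
#'
#' @param r Recombination fraction(s), clamped to `[0, 0.45]` for stability.
#' @return Map distance(s) in cM.
#' @export
haldane_cm <- function(r) {
  -50 * log(1 - 2 * pmin(pmax(r, 0), 0.45))
}

#' Build per-sex genetic maps by two-point linkage
#'
#' Markers are classified and filtered for segregation distortion, split by
#' the informative parent (paternal meioses give the male map, maternal the
#' female map), grouped by single-linkage on pairwise LOD `>= lod_group`
#' (leftover singletons joined to their best group when its LOD is
#' `>= lod_join` and exceeds the second best by `>= lod_diff`), ordered
#' within groups by greedy nearest-neighbour chaining with 2-opt refinement
#' on rf, and placed at cumulative Haldane cM positions. Markers showing no
#' recombination with their neighbour share a cM position.
#'
#' @param gm A [genotype_matrix()] (typically after [add_sex_snp()]).
#' @param lod_group LOD threshold for single-linkage grouping (default 10).
#' @param lod_join,lod_diff Thresholds for joining leftover markers
#'   (defaults 8 and 2).
#' @param tolerance Segregation-distortion tolerance (default 0.001).
#' @return Object of class `genetic_map`: list with per-sex `data.frame`s
#'   (`male`, `female`) of marker, group, order and cM position, plus the
#'   thresholds used.
#' @export
build_map <- function(gm, lod_group = 10, lod_join = 8, lod_diff = 2,
                      tolerance = 0.001) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cls <- classify_and_filter(gm, tolerance = tolerance)
  out <- list()
  for (sex in c("male", "female")) {
    parent <- if (sex == "male") "father" else "mother"
    tx <- .transmissions(gm, parent)
    informative <- which(rowSums(!is.na(tx$trans)) > 0 & cls$keep)
    if (length(informative) == 0) {
      if (sex == "male") stop("no informative markers")
      out[[sex]] <- NULL
      next
    }
    tr <- tx$trans[informative, , drop = FALSE]
    pc <- .pair_counts(tr, tx$family,
                       ic = tx$ic[informative, , drop = FALSE])
    rl <- .lod_matrix(pc)
    m <- length(informative)

    # single-linkage components on LOD >= lod_group
    adj <- rl$lod >= lod_group
    diag(adj) <- FALSE
    group <- integer(m)
    gid <- 0L
    for (i in seq_len(m)) {
      if (group[i] != 0L) next
      gid <- gid + 1L
      frontier <- i
      group[i] <- gid
      while (length(frontier) > 0) {
        nb <- which(adj[frontier[1], ] & group == 0L)
        group[nb] <- gid
        frontier <- c(frontier[-1], nb)
      }
    }
    # join leftover singletons
    sizes <- table(group)
    for (i in which(group %in% as.integer(names(sizes)[sizes == 1L]))) {
      others <- which(group != group[i])
      if (length(others) == 0) next
      by_group <- tapply(rl$lod[i, others], group[others], max)
      ord <- order(by_group, decreasing = TRUE)
      best <- by_group[ord[1]]
      second <- if (length(ord) > 1) by_group[ord[2]] else -Inf
      if (best >= lod_join && best - second >= lod_diff)
        group[i] <- as.integer(names(by_group)[ord[1]])
    }

    rows <- list()
    for (g in sort(unique(group))) {
      members <- which(group == g)
      if (length(members) > 1) {
        bins <- .bin_markers(members, pc)
        bt <- .bin_transmissions(bins, tr, tx$family,
                                 ic = tx$ic[informative, , drop = FALSE])
        pcb_min <- .pair_counts(bt$tr, tx$family)
        rf_min <- ifelse(pcb_min$n > 0, pcb_min$rec / pcb_min$n, 0.5)
        ali <- .align_bin_phases(bt$tr, tx$family, rf_min)
        pcb <- .aligned_pair_counts(ali$tr, tx$family, ali$anchored,
                                    src = bt$src)
        rlb <- .lod_matrix(pcb)
        bpath <- .order_markers(rlb$rf, pcb$rec, pcb$n)
        bin_cms <- c(0, cumsum(.fit_gap_cm(bpath, rlb$rf, pcb$rec, pcb$n)))
        # expand bins; order within a shared cM position is not
        # identifiable from rf data, so co-located markers are presented
        # in physical order (synthetic markers without position last)
        ord <- integer(0)
        cms <- numeric(0)
        for (bi in seq_along(bpath)) {
          mem <- bins[[bpath[bi]]]
          p <- gm$markers$pos[informative[mem]]
          mem <- mem[order(p, na.last = TRUE)]
          ord <- c(ord, mem)
          cms <- c(cms, rep(bin_cms[bi], length(mem)))
        }
      } else {
        ord <- members
        cms <- 0
      }
      # orient along physical coordinates when available
      pos <- gm$markers$pos[informative[ord]]
      orient <- if (sum(!is.na(pos)) >= 2)
        suppressWarnings(stats::cor(cms[!is.na(pos)], pos[!is.na(pos)],
                                    method = "spearman")) else NA
      if (isTRUE(orient < 0)) {
        ord <- rev(ord)
        cms <- max(cms) - rev(cms)
        for (run in split(seq_along(ord),
                          cumsum(c(1, abs(diff(cms)) > 1e-9)))) {
          if (length(run) > 1) {
            p <- gm$markers$pos[informative[ord[run]]]
            ord[run] <- ord[run][order(p, na.last = TRUE)]
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        marker_idx = informative[ord],
        chrom = gm$markers$chrom[informative[ord]],
        pos = gm$markers$pos[informative[ord]],
        gene_id = if ("gene_id" %in% names(gm$markers))
          gm$markers$gene_id[informative[ord]] else NA_character_,
        synthetic = gm$markers$synthetic[informative[ord]],
        group = g, order = seq_along(ord), cm = cms,
        stringsAsFactors = FALSE)
    }
    out[[sex]] <- do.call(rbind, rows)
  }
  structure(c(out, list(lod_group = lod_group, lod_join = lod_join,
                        lod_diff = lod_diff)),
            class = "genetic_map")
}

#' @exportS3Method base::print
print.genetic_map <- function(x, ...) {
  for (sex in c("male", "female")) {
    if (is.null(x[[sex]])) next
    cat(sex, "map:", nrow(x[[sex]]), "markers in",
        length(unique(x[[sex]]$group)), "group(s); length",
        round(sum(tapply(x[[sex]]$cm, x[[sex]]$group, max)), 1), "cM\n")
  }
  invisible(x)
}

#' Integrate a genetic map with physical positions
#'
#' Orders the mapped markers physically and reports (i) low-recombination
#' spans: runs of at least `k` consecutive markers sharing one cM position,
#' with their physical extent, and (ii) candidate assembly discontinuities:
#' adjacent physical markers whose cM positions jump by more than
#' `jump_threshold`.
#'
#' @param map_df One sex's `data.frame` from [build_map()] (needs `pos` and
#'   `cm`), or any frame with those columns.
#' @param k Minimum run length for a span (default 5).
#' @param jump_threshold cM jump between physically adjacent markers flagged
#'   as a candidate misassembly (default 50).
#' @return List with `spans` and `discontinuities` `data.frame`s.
#' @export
map_physical_integration <- function(map_df, k = 5L, jump_threshold = 50) {
  stopifnot(all(c("pos", "cm") %in% names(map_df)))
  # cM positions are only comparable within a linkage group
  if ("group" %in% names(map_df) && length(unique(map_df$group)) > 1) {
    parts <- lapply(split(map_df, map_df$group), map_physical_integration,
                    k = k, jump_threshold = jump_threshold)
    return(list(spans = do.call(rbind, lapply(parts, `[[`, "spans")),
                discontinuities = do.call(rbind, lapply(parts, `[[`,
                                                        "discontinuities"))))
  }
  d <- map_df[!is.na(map_df$pos), , drop = FALSE]
  d <- d[order(d$pos), , drop = FALSE]
  spans <- data.frame(start = numeric(0), end = numeric(0),
                      n_markers = integer(0), cm = numeric(0))
  if (nrow(d) > 0) {
    run_id <- cumsum(c(1L, abs(diff(d$cm)) > 1e-9))
    for (r in unique(run_id)) {
      i <- which(run_id == r)
      if (length(i) >= k)
        spans[nrow(spans) + 1L, ] <- list(d$pos[i[1]], d$pos[i[length(i)]],
                                          length(i), d$cm[i[1]])
    }
  }
  disc <- data.frame(pos_a = numeric(0), pos_b = numeric(0),
                     cm_jump = numeric(0))
  if (nrow(d) > 1) {
    jump <- abs(diff(d$cm))
    hit <- which(jump > jump_threshold)
    if (length(hit) > 0)
      disc <- data.frame(pos_a = d$pos[hit], pos_b = d$pos[hit + 1L],
                         cm_jump = jump[hit])
  }
  list(spans = spans, discontinuities = disc)
}
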