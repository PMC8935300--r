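# Synthetic-data generator: everything the pipeline consumes, with ground
# truth for parameter recovery. The default configuration emulates the study
# design the package targets: four half-sib crosses (one shared mother),
# ~25 offspring each, male heterogamety, four NRY genes with X:Y synonymous
# divergence spanning roughly 0.018-0.102, embedded in a ~50 Mb
# low-recombination region in the middle of a single chromosome.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by
#' [simulate_pedigree_genotypes()] and friends. Defaults are the package's
#' study conditions; see the methods vignette for the rationale of each value.
#'
#' @param seed Integer seed; every simulation function derives all its
#'   randomness from it.
#' @param n_genes Total genes on the simulated chromosome (NRY genes
#'   included).
#' @param chr_length_mb Chromosome length in Mb.
#' @param sdr_span Physical interval (Mb) with reduced recombination in both
#'   sexes.
#' @param sdr_mult Recombination multiplier inside `sdr_span`, in `[0, 1]`.
#' @param nry_span Sub-interval (Mb) of `sdr_span` where male recombination
#'   is suppressed completely (multiplier exactly 0).
#' @param nry_gene_pos Physical positions (Mb) of the NRY genes; must lie
#'   inside `nry_span`.
#' @param gene_length_codons CDS length (codons) of each NRY gene.
#' @param target_ks,target_ka Target X:Y synonymous/non-synonymous divergence
#'   per NRY gene (Jukes-Cantor scale), each in `[0, 0.5)`.
#' @param n_families Number of crosses; the last two share a mother (half-sib
#'   design) when `n_families > 1`.
#' @param offspring_per_family F1 individuals per cross.
#' @param map_length_cM Named vector `c(female=, male=)`: total per-sex map
#'   length of the chromosome in cM (after applying the multipliers).
#' @param snp_density Expected heterozygous SNPs per ordinary gene (Poisson
#'   mean).
#' @param max_y_snps_per_gene At most this many of a gene's fixed X/Y
#'   differences surface as called markers (joint genotype calling does not
#'   recover every divergent site in real data).
#' @param alt_freq_range Range of the alternate-allele frequency from which
#'   parental genotypes at ordinary markers are drawn.
#' @param read_length,read_depth,base_error Read simulation defaults.
#' @param geno_error,geno_missing Genotyping error and missingness rates
#'   (default 0).
#' @param fpkm_means `data.frame` with one row per NRY gene and columns
#'   `fXX`, `mX`, `mY`: expression means (FPKM) of the female X total and the
#'   male X and Y copies.
#' @param library_size Mean mapped fragments per sample.
#' @param nb_size Negative-binomial size (inverse dispersion) for counts.
#' @param outgroup_ks,outgroup_ka Divergence of the simulated outgroup from
#'   the X/Y ancestor.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 250L,
                       chr_length_mb = 300,
                       sdr_span = c(200, 250),
                       sdr_mult = 0.05,
                       nry_span = c(222, 224),
                       nry_gene_pos = c(222.55, 222.97, 223.53, 223.87),
                       gene_length_codons = c(644L, 110L, 410L, 920L),
                       target_ks = c(0.102, 0.038, 0.033, 0.018),
                       target_ka = c(0.031, 0.020, 0.008, 0.007),
                       n_families = 4L,
                       offspring_per_family = 25L,
                       map_length_cM = c(female = 90, male = 109),
                       snp_density = 2,
                       max_y_snps_per_gene = 12L,
                       alt_freq_range = c(0.15, 0.5),
                       read_length = 100L,
                       read_depth = 40,
                       base_error = 0,
                       geno_error = 0,
                       geno_missing = 0,
                       fpkm_means = NULL,
                       library_size = 2e7,
                       nb_size = 30,
                       outgroup_ks = 0.30,
                       outgroup_ka = 0.10) {
  k <- length(nry_gene_pos)
  if (is.null(fpkm_means)) {
    fxx <- c(40, 33, 29, 16)[seq_len(k)]
    fpkm_means <- data.frame(fXX = fxx, mX = fxx / 2, mY = fxx / 2)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chr_length_mb = chr_length_mb, sdr_span = sdr_span,
              sdr_mult = sdr_mult, nry_span = nry_span,
              nry_gene_pos = nry_gene_pos,
              gene_length_codons = as.integer(gene_length_codons),
              target_ks = target_ks, target_ka = target_ka,
              n_families = as.integer(n_families),
              offspring_per_family = as.integer(offspring_per_family),
              map_length_cM = map_length_cM, snp_density = snp_density,
              max_y_snps_per_gene = as.integer(max_y_snps_per_gene),
              alt_freq_range = alt_freq_range,
              read_length = as.integer(read_length), read_depth = read_depth,
              base_error = base_error, geno_error = geno_error,
              geno_missing = geno_missing, fpkm_means = fpkm_means,
              library_size = library_size, nb_size = nb_size,
              outgroup_ks = outgroup_ks, outgroup_ka = outgroup_ka)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$n_families > 0, cfg$offspring_per_family > 0,
            cfg$chr_length_mb > 0, cfg$snp_density >= 0,
            cfg$read_length > 0, cfg$read_depth > 0,
            cfg$sdr_mult >= 0, cfg$sdr_mult <= 1,
            all(cfg$map_length_cM > 0),
            all(c("female", "male") %in% names(cfg$map_length_cM)))
  if (cfg$sdr_span[1] >= cfg$sdr_span[2] || cfg$nry_span[1] >= cfg$nry_span[2])
    stop("sdr_span and nry_span must be increasing intervals")
  if (cfg$nry_span[1] < cfg$sdr_span[1] || cfg$nry_span[2] > cfg$sdr_span[2])
    stop("nry_span must lie inside sdr_span")
  if (any(cfg$nry_gene_pos < cfg$nry_span[1] | cfg$nry_gene_pos > cfg$nry_span[2]))
    stop("all NRY genes must lie inside nry_span")
  k <- length(cfg$nry_gene_pos)
  if (length(cfg$gene_length_codons) != k || length(cfg$target_ks) != k ||
      length(cfg$target_ka) != k || nrow(cfg$fpkm_means) != k)
    stop("per-NRY-gene vectors must all have length ", k)
  if (any(cfg$target_ks < 0 | cfg$target_ks >= 0.5 |
          cfg$target_ka < 0 | cfg$target_ka >= 0.5))
    stop("divergence targets must lie in [0, 0.5)")
  if (cfg$n_genes < k + 2L)
    stop("need at least ", k + 2L, " genes to flank the NRY")
  structure(cfg, class = "sim_config")
}

#' Random intact coding sequence
#'
#' @param n_codons Number of codons.
#' @param seed Optional seed.
#' @return A codon sequence with no internal stop codons.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- rownames(.site_table())[!.is_stop(rownames(.site_table()))]
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Apply random substitutions to `seq` until its divergence from `ref` meets
# the targets. Mutations are proposed one at a time, classified by codon
# context, rejected when they would create a stop codon or when their class
# has already reached its target. `mutate_which` = "both" alternates the
# mutated lineage between the pair members.
.diverge_until <- function(x, y, target_ks, target_ka, mutate = c("x", "y")) {
  n <- nchar(x)
  cur <- list(x = x, y = y)
  res <- suppressWarnings(kaks(cur$x, cur$y))
  ks_met <- function(r) target_ks <= 0 || (!is.na(r$Ks) && r$Ks >= target_ks)
  ka_met <- function(r) target_ka <= 0 || (!is.na(r$Ka) && r$Ka >= target_ka)
  if (target_ks > 0 && res$S == 0)
    stop("target Ks unreachable: no synonymous sites in this sequence")
  cap <- 600L * n
  proposals <- 0L
  while (!(ks_met(res) && ka_met(res))) {
    proposals <- proposals + 1L
    if (proposals > cap)
      stop("divergence target unreachable on this sequence ",
           "(exhausted ", cap, " proposals)")
    lane <- sample(mutate, 1L)
    site <- sample.int(n, 1L)
    old <- substr(cur[[lane]], site, site)
    new <- sample(setdiff(BASES, old), 1L)
    ci <- (site - 1L) %/% 3L
    codon_old <- substr(cur[[lane]], ci * 3L + 1L, ci * 3L + 3L)
    codon_new <- codon_old
    substr(codon_new, (site - 1L) %% 3L + 1L, (site - 1L) %% 3L + 1L) <- new
    if (.is_stop(codon_new)) next
    syn <- translate_codon(codon_new) == translate_codon(codon_old)
    if (syn && ks_met(res)) next
    if (!syn && ka_met(res)) next
    substr(cur[[lane]], site, site) <- new
    res <- suppressWarnings(kaks(cur$x, cur$y))
  }
  list(x = cur$x, y = cur$y, realized = res)
}

#' Simulate a diverged X/Y gametolog pair
#'
#' Starting from a shared ancestral CDS, substitutions are placed one at a
#' time on a randomly chosen lineage, classified as synonymous or
#' non-synonymous by their codon context, and accepted until the realized
#' NG86 + Jukes-Cantor divergence first meets or exceeds the targets.
#' Mutations creating stop codons are rejected and redrawn.
#'
#' @param ancestral_cds Codon sequence (length multiple of 3, no internal
#'   stops).
#' @param target_ks,target_ka Target divergence values in `[0, 0.5)`.
#' @param seed Optional seed.
#' @return List with `x`, `y` (diverged sequences sharing the ancestral
#'   reading frame) and `realized` (the [kaks()] result for the pair).
#' @export
simulate_gametolog_pair <- function(ancestral_cds, target_ks, target_ka,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ancestral_cds <- toupper(ancestral_cds)
  cods <- .split_codons(ancestral_cds)
  if (!all(grepl("^[ACGT]{3}$", cods))) stop("ancestral CDS must be A/C/G/T only")
  if (any(.is_stop(cods))) stop("ancestral CDS contains internal stop codons")
  stopifnot(target_ks >= 0, target_ks < 0.5, target_ka >= 0, target_ka < 0.5)
  if (target_ks == 0 && target_ka == 0)
    return(list(x = ancestral_cds, y = ancestral_cds,
                realized = suppressWarnings(kaks(ancestral_cds, ancestral_cds))))
  .diverge_until(ancestral_cds, ancestral_cds, target_ks, target_ka)
}

# --- genetic map machinery -------------------------------------------------

# Piecewise-constant recombination-rate weights along the chromosome for one
# sex; NRY suppression applies to the male map only (female X chromosomes
# keep the background SDR reduction there).
.rate_breaks <- function(cfg, sex) {
  br <- sort(unique(c(0, cfg$sdr_span, if (sex == "male") cfg$nry_span,
                      cfg$chr_length_mb)))
  mid <- (br[-1] + br[-length(br)]) / 2
  w <- ifelse(mid >= cfg$sdr_span[1] & mid <= cfg$sdr_span[2], cfg$sdr_mult, 1)
  if (sex == "male")
    w[mid >= cfg$nry_span[1] & mid <= cfg$nry_span[2]] <- 0
  list(breaks = br, weights = w)
}

# cM position of physical positions (Mb) on the per-sex map, scaled so the
# whole chromosome spans cfg$map_length_cM[sex].
.cm_positions <- function(pos_mb, cfg, sex) {
  rb <- .rate_breaks(cfg, sex)
  seg_len <- diff(rb$breaks) * rb$weights
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  idx <- findInterval(pos_mb, rb$breaks, rightmost.closed = TRUE)
  raw <- cum[idx] + (pos_mb - rb$breaks[idx]) * rb$weights[idx]
  raw / total * unname(cfg$map_length_cM[[sex]])
}

# One meiosis under the Haldane (no-interference) model: crossover count is
# Poisson in the map length in Morgans, positions uniform in map distance.
# Returns the transmitted allele at each marker plus the haplotype index
# function (needed to score which sex haplotype a gamete carries).
.meiosis <- function(hap_alleles, cm, total_cm) {
  n_xo <- stats::rpois(1L, total_cm / 100)
  xo <- sort(stats::runif(n_xo, 0, total_cm))
  start <- sample(1:2, 1L)
  hap_at <- function(g) 1L + (start - 1L + findInterval(g, xo)) %% 2L
  idx <- hap_at(cm)
  list(alleles = hap_alleles[cbind(seq_along(cm), idx)], hap_at = hap_at,
       crossovers = xo, start = start)
}

#' Simulate half-sib pedigrees with an embedded non-recombining region
#'
#' Generates the full family design: parental haplotypes, meioses under the
#' Haldane model with sex-specific maps (male recombination suppressed to 0
#' inside the NRY span, both sexes reduced across the SDR span), offspring
#' whose sex is the paternal sex haplotype they inherited, and a genotype
#' matrix over ordinary SNP markers plus the fixed X/Y differences of the
#' NRY genes (which surface as markers heterozygous in males only).
#'
#' @param cfg A [sim_config()].
#' @return List with `geno` (a [genotype_matrix()] including parents),
#'   `sheet` (sample sheet) and `truth` (ground truth: gene table, marker
#'   table with per-sex cM and Y-SNP flags, NRY/SDR spans, per-gene
#'   haplotype sequences and realized divergence, parental haplotypes,
#'   per-meiosis crossovers).
#' @export
simulate_pedigree_genotypes <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  chrom <- "chrS1"
  k <- length(cfg$nry_gene_pos)

  # gene table: ordinary genes spread evenly outside a window around the NRY
  n_ord <- cfg$n_genes - k
  ord_pos <- seq(2, cfg$chr_length_mb - 2, length.out = n_ord)
  avoid <- c(cfg$nry_span[1] - 1, cfg$nry_span[2] + 1)
  ord_pos <- ord_pos[ord_pos < avoid[1] | ord_pos > avoid[2]]
  pos_all <- sort(c(ord_pos, cfg$nry_gene_pos))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_along(pos_all)),
                      pos_mb = pos_all,
                      is_nry = pos_all %in% cfg$nry_gene_pos,
                      stringsAsFactors = FALSE)
  nry_gene_ids <- genes$gene_id[genes$is_nry]

  # gametolog pairs + outgroup for the NRY genes
  seqs <- vector("list", k)
  names(seqs) <- nry_gene_ids
  for (i in seq_len(k)) {
    anc <- random_cds(cfg$gene_length_codons[i])
    pair <- .diverge_until(anc, anc, cfg$target_ks[i], cfg$target_ka[i])
    # outgroup: all divergence on its own branch, ancestor left untouched
    og <- .diverge_until(anc, anc, cfg$outgroup_ks, cfg$outgroup_ka,
                         mutate = "y")$y
    bx <- strsplit(pair$x, "")[[1]]
    byv <- strsplit(pair$y, "")[[1]]
    dsite <- which(bx != byv)
    seqs[[i]] <- list(ancestral = anc, x = pair$x, y = pair$y, outgroup = og,
                      realized = pair$realized,
                      y_snps = data.frame(cds_pos = dsite,
                                          x_allele = bx[dsite],
                                          y_allele = byv[dsite],
                                          stringsAsFactors = FALSE))
  }

  # marker table: ordinary het SNPs + NRY fixed X/Y differences
  mk <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    start_bp <- round(g$pos_mb * 1e6)
    if (g$is_nry) {
      ys <- seqs[[g$gene_id]]$y_snps
      if (nrow(ys) > cfg$max_y_snps_per_gene)
        ys <- ys[sort(sample.int(nrow(ys), cfg$max_y_snps_per_gene)), ,
                 drop = FALSE]
      if (nrow(ys) == 0) next
      mk[[length(mk) + 1L]] <- data.frame(
        chrom = chrom, pos = start_bp + ys$cds_pos - 1L,
        ref = ys$x_allele, alt = ys$y_allele, gene_id = g$gene_id,
        cds_pos = ys$cds_pos, is_y_snp = TRUE, alt_freq = 0,
        stringsAsFactors = FALSE)
    } else {
      n_snp <- stats::rpois(1L, cfg$snp_density)
      if (n_snp == 0) next
      off <- sort(sample.int(5000L, n_snp))
      ra <- t(replicate(n_snp, sample(BASES, 2L)))
      mk[[length(mk) + 1L]] <- data.frame(
        chrom = chrom, pos = start_bp + off, ref = ra[, 1L], alt = ra[, 2L],
        gene_id = g$gene_id, cds_pos = off, is_y_snp = FALSE,
        alt_freq = stats::runif(n_snp, cfg$alt_freq_range[1],
                                cfg$alt_freq_range[2]),
        stringsAsFactors = FALSE)
    }
  }
  markers <- do.call(rbind, mk)
  markers <- markers[!duplicated(markers$pos), , drop = FALSE]
  markers <- markers[order(markers$pos), , drop = FALSE]
  rownames(markers) <- NULL
  n_mk <- nrow(markers)
  markers$cm_male <- .cm_positions(markers$pos / 1e6, cfg, "male")
  markers$cm_female <- .cm_positions(markers$pos / 1e6, cfg, "female")

  # pedigree: one shared mother between the last two families (half-sibs)
  n_mothers <- if (cfg$n_families > 1L) cfg$n_families - 1L else 1L
  fam_mother <- pmin(seq_len(cfg$n_families), n_mothers)
  mothers <- sprintf("MOT%d", seq_len(n_mothers))
  fathers <- sprintf("FAT%d", seq_len(cfg$n_families))

  draw_haps <- function(is_mother) {
    h <- matrix(stats::rbinom(2L * n_mk, 1L, markers$alt_freq), ncol = 2L)
    h[markers$is_y_snp, ] <- 0L
    if (!is_mother) h[markers$is_y_snp, 2L] <- 1L  # hap 2 is the Y
    h
  }
  haps <- c(stats::setNames(lapply(mothers, function(i) draw_haps(TRUE)), mothers),
            stats::setNames(lapply(fathers, function(i) draw_haps(FALSE)), fathers))

  sdr_cm_male <- .cm_positions(mean(cfg$nry_span), cfg, "male")
  tot_m <- unname(cfg$map_length_cM[["male"]])
  tot_f <- unname(cfg$map_length_cM[["female"]])

  samples <- data.frame(id = character(0), sex = character(0),
                        family = character(0), role = character(0),
                        mother_id = character(0), father_id = character(0),
                        stringsAsFactors = FALSE)
  calls <- list()
  crossovers <- list()
  for (m in seq_len(n_mothers))
    samples[nrow(samples) + 1L, ] <- list(mothers[m], "F", NA_character_,
                                          "mother", NA_character_, NA_character_)
  for (f in seq_len(cfg$n_families))
    samples[nrow(samples) + 1L, ] <- list(fathers[f], "M", NA_character_,
                                          "father", NA_character_, NA_character_)
  for (p in samples$id)
    calls[[p]] <- haps[[p]][, 1L] + haps[[p]][, 2L]

  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("fam%d", f)
    mo <- mothers[fam_mother[f]]
    fa <- fathers[f]
    samples$family[samples$id %in% c(mo, fa)] <- fam  # last assignment wins for shared mother
    for (o in seq_len(cfg$offspring_per_family)) {
      oid <- sprintf("%s_o%02d", fam, o)
      gm <- .meiosis(haps[[mo]], markers$cm_female, tot_f)
      gp <- .meiosis(haps[[fa]], markers$cm_male, tot_m)
      sex <- if (gp$hap_at(sdr_cm_male) == 2L) "M" else "F"
      samples[nrow(samples) + 1L, ] <- list(oid, sex, fam, "offspring", mo, fa)
      calls[[oid]] <- gm$alleles + gp$alleles
      crossovers[[oid]] <- list(maternal = gm$crossovers,
                                paternal = gp$crossovers)
    }
  }
  call_mat <- do.call(cbind, calls[samples$id])

  if (cfg$geno_error > 0) {
    flip <- which(stats::runif(length(call_mat)) < cfg$geno_error)
    call_mat[flip] <- (call_mat[flip] + sample(1:2, length(flip),
                                               replace = TRUE)) %% 3L
  }
  if (cfg$geno_missing > 0)
    call_mat[stats::runif(length(call_mat)) < cfg$geno_missing] <- NA_integer_

  gm_cols <- c("chrom", "pos", "ref", "alt", "gene_id", "cds_pos")
  geno <- genotype_matrix(markers[, gm_cols], samples, call_mat)
  truth <- list(config = cfg, genes = genes, markers = markers,
                nry_span = cfg$nry_span, sdr_span = cfg$sdr_span,
                nry_gene_ids = nry_gene_ids, sequences = seqs,
                parent_haplotypes = haps, crossovers = crossovers,
                sdr_cm = c(male = sdr_cm_male))
  list(geno = geno, sheet = samples, truth = truth)
}

#' Simulate aligned paired reads over a gametolog pair
#'
#' Paired records are drawn from fragments sampled uniformly along the gene;
#' a male sample draws each fragment from the X or Y haplotype with equal
#' probability, a female sample from the X only. Coordinates are on the X
#' reference (1-based); the true source haplotype is recorded per read.
#'
#' @param x_seq,y_seq Aligned gametolog sequences (equal length).
#' @param sex `"M"` or `"F"`.
#' @param depth Fold coverage.
#' @param read_length Read length in bases; must not exceed the gene length.
#' @param error_rate Per-base substitution error probability.
#' @param fragment_length Outer distance between mates (clamped to the gene).
#' @param gene_id Reference name used in the records.
#' @param sample_id Prefix for read names.
#' @param seed Optional seed.
#' @return `data.frame` with columns `qname`, `mate` (1/2), `flag` (SAM mate
#'   bits), `rname`, `pos`, `seq`, `source_hap` ("X"/"Y" truth label).
#' @export
simulate_reads <- function(x_seq, y_seq, sex = "M", depth = 40,
                           read_length = 100L, error_rate = 0,
                           fragment_length = NULL, gene_id = "gene",
                           sample_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nchar(x_seq) == nchar(y_seq), depth > 0, sex %in% c("M", "F"))
  L <- nchar(x_seq)
  if (read_length > L)
    stop("read_length (", read_length, ") exceeds gene length (", L, ")")
  if (is.null(fragment_length)) fragment_length <- round(2.5 * read_length)
  fragment_length <- max(read_length, min(fragment_length, L))
  n_frag <- ceiling(depth * L / (2 * read_length))
  starts <- sample.int(L - fragment_length + 1L, n_frag, replace = TRUE)
  hap <- if (sex == "F") rep("X", n_frag) else
    sample(c("X", "Y"), n_frag, replace = TRUE)
  src <- c(X = x_seq, Y = y_seq)
  pos1 <- starts
  pos2 <- starts + fragment_length - read_length
  seq1 <- substring(src[hap], pos1, pos1 + read_length - 1L)
  seq2 <- substring(src[hap], pos2, pos2 + read_length - 1L)
  if (error_rate > 0) {
    garble <- function(s) {
      vapply(s, function(one) {
        b <- strsplit(one, "")[[1]]
        hit <- which(stats::runif(length(b)) < error_rate)
        for (h in hit) b[h] <- sample(setdiff(BASES, b[h]), 1L)
        paste0(b, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    seq1 <- garble(seq1)
    seq2 <- garble(seq2)
  }
  qname <- sprintf("%s_%s_f%05d", sample_id, gene_id, seq_len(n_frag))
  out <- rbind(
    data.frame(qname = qname, mate = 1L, flag = 65L, rname = gene_id,
               pos = pos1, seq = seq1, source_hap = hap,
               stringsAsFactors = FALSE),
    data.frame(qname = qname, mate = 2L, flag = 129L, rname = gene_id,
               pos = pos2, seq = seq2, source_hap = hap,
               stringsAsFactors = FALSE))
  out[order(out$qname, out$mate), , drop = FALSE]
}

#' Simulate per-sample allele-specific expression counts
#'
#' Draws negative-binomial counts for the X- and Y-copy of each NRY gene in
#' every sample. Females express the X copies only (Y-copy counts are 0);
#' male X-copy means default to half the female total, reflecting one X
#' versus two.
#'
#' @param cfg A [sim_config()].
#' @param sheet Sample sheet (e.g. from [simulate_pedigree_genotypes()]).
#' @param gene_lengths Optional named vector of CDS lengths (bases) for the
#'   NRY genes; defaults to `3 * gene_length_codons` from the config.
#' @param seed Optional seed (defaults to `cfg$seed + 1`).
#' @return List with `counts` (gene-copy x sample matrix; rownames
#'   `<gene>_X`/`<gene>_Y`), `lengths` (bases per gene copy),
#'   `library_sizes` (per sample) and `gene_ids`.
#' @export
simulate_expression <- function(cfg, sheet, gene_lengths = NULL, seed = NULL) {
  cfg <- validate_sim_config(cfg)
  sheet <- validate_sample_sheet(sheet)
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  k <- length(cfg$nry_gene_pos)
  gene_ids <- if (!is.null(names(gene_lengths))) names(gene_lengths) else
    sprintf("nry%d", seq_len(k))
  if (is.null(gene_lengths))
    gene_lengths <- stats::setNames(3L * cfg$gene_length_codons, gene_ids)
  lib <- stats::setNames(round(cfg$library_size *
                                 exp(stats::rnorm(nrow(sheet), 0, 0.1))),
                         sheet$id)
  copies <- as.vector(rbind(paste0(gene_ids, "_X"), paste0(gene_ids, "_Y")))
  lengths <- stats::setNames(rep(unname(gene_lengths), each = 2L), copies)
  counts <- matrix(0L, nrow = length(copies), ncol = nrow(sheet),
                   dimnames = list(copies, sheet$id))
  for (s in seq_len(nrow(sheet))) {
    male <- sheet$sex[s] == "M"
    for (g in seq_len(k)) {
      mu_x <- if (male) cfg$fpkm_means$mX[g] else cfg$fpkm_means$fXX[g]
      mu_y <- if (male) cfg$fpkm_means$mY[g] else 0
      len_kb <- gene_lengths[[g]] / 1000
      scale <- len_kb * lib[[s]] / 1e6
      counts[2L * g - 1L, s] <- stats::rnbinom(1L, mu = mu_x * scale,
                                               size = cfg$nb_size)
      counts[2L * g, s] <- if (mu_y > 0)
        stats::rnbinom(1L, mu = mu_y * scale, size = cfg$nb_size) else 0L
    }
  }
  list(counts = counts, lengths = lengths, library_sizes = lib,
       gene_ids = gene_ids)
}
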