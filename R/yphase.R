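# Partition aligned reads by Y-specific alleles (propagating mates) and call
# per-gametolog consensus sequences.

#' Partition read pairs by the Y-specific alleles they carry
#'
#' A pair in which any mate carries the Y allele at one or more Y-SNPs (and
#' no mate carries an X allele at any Y-SNP) goes to `y_reads`, both mates
#' included; the converse goes to `x_reads`. Pairs covering no Y-SNP, pairs
#' supporting a third allele only, and conflicting pairs (Y allele on one
#' read, X allele on another) are `unassigned`; conflicts are counted.
#' Assignment depends only on read content, never on input order.
#'
#' @param reads `data.frame` with columns `qname`, `pos` (1-based), `seq`
#'   (e.g. from [simulate_reads()] or [read_sam()]).
#' @param y_snps `data.frame` with columns `cds_pos` (1-based position on
#'   the reference), `x_allele`, `y_allele`.
#' @param reference_length Optional; when given, Y-SNP positions beyond it
#'   raise an error.
#' @return List with `y_reads`, `x_reads`, `unassigned` (row subsets of
#'   `reads`) and `n_conflict`.
#' @export
partition_reads <- function(reads, y_snps, reference_length = NULL) {
  stopifnot(all(c("qname", "pos", "seq") %in% names(reads)),
            all(c("cds_pos", "x_allele", "y_allele") %in% names(y_snps)))
  if (nrow(y_snps) == 0) stop("y_snps is empty for this gene")
  if (!is.null(reference_length) &&
      any(y_snps$cds_pos > reference_length | y_snps$cds_pos < 1))
    stop("y_snps reference positions beyond the reference length")

  read_len <- nchar(reads$seq)
  has_x <- logical(nrow(reads))
  has_y <- logical(nrow(reads))
  for (s in seq_len(nrow(y_snps))) {
    p <- y_snps$cds_pos[s]
    cov <- reads$pos <= p & p <= reads$pos + read_len - 1L
    if (!any(cov)) next
    base <- substr(reads$seq[cov], p - reads$pos[cov] + 1L,
                   p - reads$pos[cov] + 1L)
    has_x[cov] <- has_x[cov] | base == y_snps$x_allele[s]
    has_y[cov] <- has_y[cov] | base == y_snps$y_allele[s]
  }
  pair_x <- tapply(has_x, reads$qname, any)
  pair_y <- tapply(has_y, reads$qname, any)
  verdict <- ifelse(pair_y & !pair_x, "Y",
                    ifelse(pair_x & !pair_y, "X",
                           ifelse(pair_x & pair_y, "conflict", "none")))
  v <- verdict[reads$qname]
  list(y_reads = reads[v == "Y", , drop = FALSE],
       x_reads = reads[v == "X", , drop = FALSE],
       unassigned = reads[v %in% c("none", "conflict"), , drop = FALSE],
       n_conflict = sum(verdict == "conflict"))
}

#' Call a majority-rule consensus over a reference
#'
#' Per reference position, the majority base among covering reads; positions
#' with depth below `min_depth` or an exact tie emit `N` (never an IUPAC
#' ambiguity code), so downstream codon analyses skip rather than guess.
#'
#' @param reads `data.frame` with `pos` and `seq` columns (may be empty).
#' @param reference_length Length of the reference sequence.
#' @param min_depth Minimum covering reads for a call (default 2).
#' @return Object of class `consensus_sequence`: list with `seq` (string of
#'   length `reference_length`), `depth` (integer vector) and `called`
#'   (logical mask).
#' @export
call_consensus <- function(reads, reference_length, min_depth = 2L) {
  stopifnot(reference_length > 0)
  counts <- matrix(0L, nrow = 4L, ncol = reference_length,
                   dimnames = list(BASES, NULL))
  if (nrow(reads) > 0) {
    all_pos <- integer(0)
    all_code <- integer(0)
    for (i in seq_len(nrow(reads))) {
      b <- strsplit(reads$seq[i], "")[[1]]
      p <- reads$pos[i] + seq_along(b) - 1L
      keep <- b %in% BASES & p >= 1L & p <= reference_length
      all_pos <- c(all_pos, p[keep])
      all_code <- c(all_code, match(b[keep], BASES))
    }
    if (length(all_pos) > 0) {
      tab <- tabulate((all_pos - 1L) * 4L + all_code,
                      nbins = 4L * reference_length)
      counts <- matrix(tab, nrow = 4L, dimnames = list(BASES, NULL))
    }
  }
  depth <- colSums(counts)
  top <- apply(counts, 2L, max)
  tie <- colSums(counts == rep(top, each = 4L) & counts > 0L) > 1L
  base <- BASES[apply(counts, 2L, which.max)]
  base[depth < min_depth | tie] <- "N"
  structure(list(seq = paste0(base, collapse = ""),
                 depth = as.integer(depth),
                 called = depth >= min_depth & !tie),
            class = "consensus_sequence")
}

#' @exportS3Method base::print
print.consensus_sequence <- function(x, ...) {
  cat("consensus_sequence: length", nchar(x$seq), ",",
      sum(x$called), "called positions, mean depth",
      round(mean(x$depth), 1), "\n")
  invisible(x)
}

#' Write aligned reads as a SAM subset
#'
#' Emits the restricted dialect the phasing stage consumes: QNAME, FLAG
#' (paired + first/last mate bits), RNAME, POS, MAPQ 60, full-match CIGAR,
#' SEQ; no clipping or indels.
#'
#' @param reads `data.frame` with `qname`, `flag`, `rname`, `pos`, `seq`.
#' @param path Output path.
#' @param ref_lengths Named vector of reference lengths for the `@SQ`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, ref_lengths) {
  stopifnot(!is.null(names(ref_lengths)))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                      as.integer(ref_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t0\t0\t%s\t*",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  nchar(reads$seq), reads$seq)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_sam
#' @return `read_sam`: `data.frame` with `qname`, `mate`, `flag`, `rname`,
#'   `pos`, `seq`. Records whose CIGAR is not a single full-length match
#'   (soft clips, indels) are rejected with a message.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(qname = character(0), mate = integer(0),
                      flag = integer(0), rname = character(0),
                      pos = integer(0), seq = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- vapply(f, length, integer(1))
  if (any(n_fields < 10)) stop("malformed SAM record(s): fewer than 10 fields")
  get <- function(k) vapply(f, `[`, character(1), k)
  cigar <- get(6)
  bad <- !grepl("^[0-9]+M$", cigar)
  if (any(bad))
    stop("unsupported CIGAR (clipping/indels) in ", sum(bad),
         " record(s); only full-match alignments are accepted")
  flag <- as.integer(get(2))
  data.frame(qname = get(1),
             mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
             flag = flag, rname = get(3), pos = as.integer(get(4)),
             seq = toupper(get(10)), stringsAsFactors = FALSE)
}
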