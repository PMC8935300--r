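# Genotype data model and readers/writers shared by all pipeline stages.
# Positions are 1-based (VCF convention) everywhere inside the package; the
# only 0-based coordinates ever emitted are BED intervals, which are
# documented at the point of writing.

GT_CODES <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L, `./.` = NA_integer_)

#' Read a sample sheet
#'
#' Tab-separated file with columns `id`, `sex` (M/F/unknown), `family`,
#' `role` (mother/father/offspring), `mother_id`, `father_id` (empty for
#' parents). Offspring must name both parents; parents must not carry parent
#' links.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with the six columns above.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet Sample sheet `data.frame`.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate a sample sheet
#'
#' @param sheet `data.frame` with columns `id`, `sex`, `family`, `role`,
#'   `mother_id`, `father_id`.
#' @return The sheet, invisibly unchanged, after validation.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("id", "sex", "family", "role", "mother_id", "father_id")
  missing_cols <- setdiff(req, names(sheet))
  if (length(missing_cols) > 0)
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sheet$id)) stop("duplicated sample ids in sheet")
  if (!all(sheet$sex %in% c("M", "F", "unknown")))
    stop("sex must be one of M, F, unknown")
  if (!all(sheet$role %in% c("mother", "father", "offspring")))
    stop("role must be one of mother, father, offspring")
  off <- sheet$role == "offspring"
  if (any(off & (is.na(sheet$mother_id) | is.na(sheet$father_id))))
    stop("every offspring must name both parents")
  if (any(!off & (!is.na(sheet$mother_id) | !is.na(sheet$father_id))))
    stop("parents must not carry parent links")
  bad <- off & (!sheet$mother_id %in% sheet$id | !sheet$father_id %in% sheet$id)
  if (any(bad))
    stop("offspring with parent ids absent from the sheet: ",
         paste(sheet$id[bad], collapse = ", "))
  sheet
}

#' Construct a genotype matrix
#'
#' The central genotype container: biallelic SNP markers by samples, with
#' genotypes coded as alternate-allele dosage (0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = missing).
#'
#' @param markers `data.frame` with columns `chrom`, `pos` (1-based physical,
#'   `NA` allowed for synthetic markers), `ref`, `alt` (single bases) and
#'   optionally `gene_id`, `cds_pos`, `synthetic`.
#' @param samples Sample sheet rows for the genotyped samples, in column
#'   order of `calls`.
#' @param calls Integer matrix, markers x samples, values in {0, 1, 2, NA}.
#' @return Object of class `genotype_matrix` (list with `markers`, `samples`,
#'   `calls`).
#' @export
genotype_matrix <- function(markers, samples, calls) {
  stopifnot(is.data.frame(markers), is.data.frame(samples), is.matrix(calls))
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(markers)))
    stop("markers need chrom, pos, ref, alt columns")
  if (nrow(markers) != nrow(calls) || nrow(samples) != ncol(calls))
    stop("call grid dimensions do not match marker/sample tables")
  if (!all(is.na(calls) | calls %in% 0:2)) stop("calls must be 0, 1, 2 or NA")
  if (!all(grepl("^[ACGT]$", markers$ref) & grepl("^[ACGT]$", markers$alt)))
    stop("markers must be biallelic SNPs (single-base ref and alt)")
  if (!"synthetic" %in% names(markers)) markers$synthetic <- FALSE
  for (chr in unique(markers$chrom[!is.na(markers$pos)])) {
    p <- markers$pos[markers$chrom == chr & !is.na(markers$pos)]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within ", chr)
  }
  rownames(calls) <- NULL
  colnames(calls) <- samples$id
  structure(list(markers = markers, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$markers), "markers x",
      nrow(x$samples), "samples\n")
  cat("  chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  cat("  missing calls:", sum(is.na(x$calls)), "\n")
  invisible(x)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads VCF v4.x with a GT FORMAT field. Multiallelic records and indels are
#' skipped (with a reported count), mirroring a SNP-only analysis; `./.` is
#' kept as missing. Every VCF sample must be present in the sample sheet.
#'
#' @param path Path to a VCF file.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @return A [genotype_matrix()]; attribute `n_skipped` carries the count of
#'   skipped (multiallelic/indel) records.
#' @export
read_vcf <- function(path, sheet) {
  sheet <- validate_sample_sheet(sheet)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  vcf_samples <- colnames(gt)[-1L]
  unknown <- setdiff(vcf_samples, sheet$id)
  if (length(unknown) > 0)
    stop("VCF samples absent from sample sheet: ", paste(unknown, collapse = ", "))

  keep <- grepl("^[ACGT]$", fix$REF) & grepl("^[ACGT]$", fix$ALT)
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " multiallelic/indel record(s) skipped")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  gt_field <- apply(gt[, -1L, drop = FALSE], 2L, function(col) {
    vapply(strsplit(col, ":", fixed = TRUE), `[`, character(1), 1L)
  })
  gt_field <- matrix(gt_field, nrow = nrow(fix),
                     dimnames = list(NULL, vcf_samples))
  gt_field[is.na(gt_field) | gt_field == "."] <- "./."
  bad <- !(gt_field %in% names(GT_CODES))
  if (any(bad))
    stop("malformed GT value(s): ",
         paste(unique(gt_field[bad]), collapse = ", "))
  calls <- matrix(GT_CODES[gt_field], nrow = nrow(fix),
                  dimnames = list(NULL, vcf_samples))

  markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  if ("ID" %in% names(fix)) {
    gene <- ifelse(fix$ID == "." | is.na(fix$ID), NA_character_, fix$ID)
    markers$gene_id <- gene
  }
  samples <- sheet[match(vcf_samples, sheet$id), , drop = FALSE]
  rownames(samples) <- NULL
  gm <- genotype_matrix(markers, samples, calls)
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF v4.2
#'
#' Inverse of [read_vcf()] on the supported dialect (biallelic SNPs, GT
#' only). Synthetic markers without a physical position (e.g. the sexSNP)
#' are dropped with a message, since VCF records require a position.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- !is.na(gm$markers$pos)
  if (any(!keep))
    message(sum(!keep), " marker(s) without physical position dropped on write")
  mk <- gm$markers[keep, , drop = FALSE]
  calls <- gm$calls[keep, , drop = FALSE]
  gt_strings <- matrix(names(GT_CODES)[c(1L, 2L, 4L)][calls + 1L],
                       nrow = nrow(calls))
  gt_strings[is.na(calls)] <- "./."
  id_col <- if ("gene_id" %in% names(mk))
    ifelse(is.na(mk$gene_id), ".", mk$gene_id) else rep(".", nrow(mk))
  body <- paste(mk$chrom, mk$pos, id_col, mk$ref, mk$alt, ".", ".", ".", "GT",
                apply(gt_strings, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sdrmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$id), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write FASTA as named character vectors
#'
#' Thin wrappers over Biostrings for the package's plain-string sequence
#' convention.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
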