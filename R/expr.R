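# FPKM computation and X/Y expression-ratio summaries: the dosage and
# Y-degeneration diagnostics.

#' Compute FPKM from raw counts
#'
#' `FPKM = count / (length/1000 * library_size/1e6)` per gene copy and
#' sample. Female samples with non-zero Y-copy counts are flagged as a
#' leakage diagnostic when a sample sheet is supplied.
#'
#' @param counts Gene-copy x sample count matrix; Y copies identified by
#'   rownames ending in `"_Y"`.
#' @param lengths Named effective lengths in bases (one per row of
#'   `counts`); must be positive.
#' @param library_sizes Named mapped-fragment totals (one per column); must
#'   be positive.
#' @param sheet Optional sample sheet for the leakage diagnostic.
#' @return List of class `expression_table`: `counts`, `fpkm`, `lengths`,
#'   `library_sizes`, `leakage` (data.frame of female samples with Y-copy
#'   signal, possibly empty).
#' @export
fpkm <- function(counts, lengths, library_sizes, sheet = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  lengths <- lengths[rownames(counts)]
  library_sizes <- library_sizes[colnames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every count row needs a positive length")
  if (any(is.na(library_sizes)) || any(library_sizes <= 0))
    stop("every sample needs a positive library size")
  denom <- outer(lengths / 1000, library_sizes / 1e6)
  fp <- counts / denom
  leakage <- data.frame(sample = character(0), gene_copy = character(0),
                        count = numeric(0))
  if (!is.null(sheet)) {
    females <- intersect(colnames(counts), sheet$id[sheet$sex == "F"])
    y_rows <- grep("_Y$", rownames(counts), value = TRUE)
    if (length(females) > 0 && length(y_rows) > 0) {
      sub <- counts[y_rows, females, drop = FALSE]
      hit <- which(sub > 0, arr.ind = TRUE)
      if (nrow(hit) > 0)
        leakage <- data.frame(sample = females[hit[, 2]],
                              gene_copy = y_rows[hit[, 1]],
                              count = sub[hit])
    }
  }
  structure(list(counts = counts, fpkm = fp, lengths = lengths,
                 library_sizes = library_sizes, leakage = leakage),
            class = "expression_table")
}

#' Per-family X/Y expression-ratio summary
#'
#' For each gene and family, the medians of FPKM over samples within
#' sex: `fXX` (female X total), `mX` and `mY` (male X- and Y-copy), and the
#' ratios `mY/mX` (Y degeneration), `mXY/fXX = (mX + mY)/fXX` (total male vs
#' female) and `mX/fXX` (per-X dosage; ~0.5 expected for one X vs two).
#' Ratios are computed from the medians (`method = "ratio_of_medians"`,
#' the default) and are `NA` whenever the denominator median is 0; for
#' `mY/mX` an alternative `"median_of_ratios"` over per-male sample ratios
#' is available (cross-sex ratios are unpaired and always use medians).
#'
#' @param et An `expression_table` from [fpkm()].
#' @param sheet Sample sheet; every grouped family needs at least one male
#'   and one female.
#' @param grouping `"family"` (default) or `"all"` (one pooled group).
#' @param method Ratio construction for `mY/mX` (see above).
#' @return `data.frame`: `family`, `gene`, `fXX`, `mX`, `mY`, `mY_mX`,
#'   `mXY_fXX`, `mX_fXX`; attribute `consistency` holds per-gene ranges of
#'   each ratio across families.
#' @export
ratio_summary <- function(et, sheet, grouping = c("family", "all"),
                          method = c("ratio_of_medians", "median_of_ratios")) {
  stopifnot(inherits(et, "expression_table"))
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  sheet <- validate_sample_sheet(sheet)
  x_rows <- grep("_X$", rownames(et$fpkm), value = TRUE)
  genes <- sub("_X$", "", x_rows)
  if (!all(paste0(genes, "_Y") %in% rownames(et$fpkm)))
    stop("every gene needs paired _X and _Y rows")
  samples <- intersect(colnames(et$fpkm), sheet$id)
  fam_of <- stats::setNames(sheet$family, sheet$id)
  fam_of[sheet$role != "offspring"] <- NA  # parents not grouped into F1 medians
  groups <- if (grouping == "all") list(all = samples) else
    split(samples, fam_of[samples])
  groups <- groups[!is.na(names(groups))]

  rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    males <- ids[stats::setNames(sheet$sex, sheet$id)[ids] == "M"]
    females <- ids[stats::setNames(sheet$sex, sheet$id)[ids] == "F"]
    if (length(males) == 0 || length(females) == 0)
      stop("group '", g, "' lacks samples of one sex")
    for (gene in genes) {
      fxx <- stats::median(et$fpkm[paste0(gene, "_X"), females])
      mx <- stats::median(et$fpkm[paste0(gene, "_X"), males])
      my <- stats::median(et$fpkm[paste0(gene, "_Y"), males])
      my_mx <- if (method == "median_of_ratios") {
        per <- et$fpkm[paste0(gene, "_Y"), males] /
               et$fpkm[paste0(gene, "_X"), males]
        stats::median(per[is.finite(per)])
      } else if (mx > 0) my / mx else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        family = g, gene = gene, fXX = fxx, mX = mx, mY = my,
        mY_mX = my_mx,
        mXY_fXX = if (fxx > 0) (mx + my) / fxx else NA_real_,
        mX_fXX = if (fxx > 0) mx / fxx else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  cons <- do.call(rbind, lapply(split(out, out$gene), function(d)
    data.frame(gene = d$gene[1],
               mY_mX_min = min(d$mY_mX), mY_mX_max = max(d$mY_mX),
               mX_fXX_min = min(d$mX_fXX), mX_fXX_max = max(d$mX_fXX))))
  rownames(cons) <- NULL
  attr(out, "consistency") <- cons
  out
}
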