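# Nei-Gojobori (1986) divergence, Jukes-Cantor correction, divergence dating
# and Tajima's relative-rates test. All sequence arguments are plain upper-case
# character strings over {A,C,G,T,N,-}; lengths must be multiples of 3 and the
# two (or three) sequences must be pre-aligned and gap-stripped codon-wise.

BASES <- c("A", "C", "G", "T")

.ng86_cache <- new.env(parent = emptyenv())

#' Translate a codon with the standard genetic code
#'
#' @param codon Character vector of 3-letter codons over A/C/G/T.
#' @return Character vector of one-letter amino acids, `"*"` for stops.
#' @keywords internal
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

.is_stop <- function(codon) translate_codon(codon) == "*"

# 64 x 2 matrix of NG86 fractional site counts, built once per session.
.site_table <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  all_codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                      1L, paste0, collapse = "")
  tab <- matrix(NA_real_, nrow = length(all_codons), ncol = 2L,
                dimnames = list(all_codons, c("syn", "nonsyn")))
  for (cod in all_codons) {
    if (.is_stop(cod)) next
    aa <- translate_codon(cod)
    syn_total <- 0
    for (pos in 1:3) {
      alt <- BASES[BASES != substr(cod, pos, pos)]
      neigh <- vapply(alt, function(b) {
        x <- cod; substr(x, pos, pos) <- b; x
      }, character(1))
      keep <- !.is_stop(neigh)        # changes to stops excluded per position
      if (!any(keep)) next
      syn_total <- syn_total + mean(translate_codon(neigh[keep]) == aa)
    }
    tab[cod, ] <- c(syn_total, 3 - syn_total)
  }
  .ng86_cache$sites <- tab
  tab
}

#' NG86 synonymous and non-synonymous site counts for one codon
#'
#' Each of the nine single-base neighbours of the codon is classified as
#' synonymous or non-synonymous under the standard genetic code; changes that
#' create a stop codon are excluded from the per-position denominator, so
#' every sense codon contributes exactly three sites in total.
#'
#' @param codon A single sense codon, e.g. `"CTT"`.
#' @return Named numeric vector `c(syn = , nonsyn = )`; `syn + nonsyn == 3`.
#' @examples
#' ng86_sites("TTT")  # c(syn = 1/3, nonsyn = 8/3)
#' @export
ng86_sites <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("ambiguous base in codon '", codon, "'; mask it upstream")
  if (.is_stop(codon)) stop("'", codon, "' is a stop codon")
  tab <- .site_table()
  c(syn = tab[codon, "syn"], nonsyn = tab[codon, "nonsyn"])
}

# Pathway-averaged substitution counts between two sense codons.
# Returns c(sd, nd) or NULL when every substitution pathway passes through a
# stop codon. Memoised: at most 64*64 entries.
.codon_pair_diffs <- function(a, b) {
  key <- paste0(a, b)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(if (identical(hit, "blocked")) NULL else hit)

  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) {
    val <- c(sd = 0, nd = 0)
    assign(key, val, envir = .ng86_cache)
    return(val)
  }
  orders <- .permutations(pos)
  syn_per_path <- numeric(0)
  for (ord in orders) {
    cur <- a
    syn <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (.is_stop(nxt) && nxt != b) { ok <- FALSE; break }  # stop intermediate
      if (.is_stop(nxt)) { ok <- FALSE; break }              # b itself a stop
      syn <- syn + (translate_codon(cur) == translate_codon(nxt))
      cur <- nxt
    }
    if (ok) syn_per_path <- c(syn_per_path, syn)
  }
  if (length(syn_per_path) == 0L) {
    assign(key, "blocked", envir = .ng86_cache)
    return(NULL)
  }
  sd <- mean(syn_per_path)
  val <- c(sd = sd, nd = k - sd)
  assign(key, val, envir = .ng86_cache)
  val
}

# All orderings of a small index vector (k <= 3 here).
.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Pairwise NG86 substitution and site counts
#'
#' Counts synonymous and non-synonymous differences between two aligned coding
#' sequences by the Nei-Gojobori (1986) method: fractional site classification
#' per codon and averaging of substitution pathways for codons differing at
#' more than one position, with pathways passing through stop codons excluded
#' (remaining pathways weighted equally). Codons containing an ambiguous base
#' (N), a gap, or a stop in either sequence are skipped and tallied.
#'
#' @param a,b Aligned coding sequences (equal length, multiple of 3).
#' @return List with `Sd`, `S`, `Nd`, `N`, `ps`, `pn`, `codons_analysed`,
#'   `codons_skipped`. `Sd + Nd` equals the total nucleotide differences over
#'   analysed codons; `S + N` equals 3 x analysed codons.
#' @export
ng86_pairwise <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned to equal length")
  ca <- .split_codons(a)
  cb <- .split_codons(b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  clean[clean] <- !.is_stop(ca[clean]) & !.is_stop(cb[clean])

  tab <- .site_table()
  Sd <- Nd <- 0
  skipped_extra <- 0L
  use <- which(clean)
  for (i in use[ca[use] != cb[use]]) {
    d <- .codon_pair_diffs(ca[i], cb[i])
    if (is.null(d)) {
      warning("codon ", i, " (", ca[i], "/", cb[i],
              "): all substitution pathways pass through a stop; skipped")
      clean[i] <- FALSE
      skipped_extra <- skipped_extra + 1L
      next
    }
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  S <- (sum(tab[ca[clean], "syn"]) + sum(tab[cb[clean], "syn"])) / 2
  N <- (sum(tab[ca[clean], "nonsyn"]) + sum(tab[cb[clean], "nonsyn"])) / 2
  list(Sd = Sd, S = S, Nd = Nd, N = N,
       ps = if (S > 0) Sd / S else NA_real_,
       pn = if (N > 0) Nd / N else NA_real_,
       codons_analysed = sum(clean),
       codons_skipped = length(ca) - sum(clean))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`, correcting an observed proportion of
#' differences for unobserved multiple substitutions.
#'
#' @param p Observed proportion(s) of differences per site, in `[0, 0.75)`.
#' @return Corrected divergence(s).
#' @examples
#' jc_correct(43.50 / 455.25)  # 0.102
#' @export
jc_correct <- function(p) {
  stopifnot(is.numeric(p))
  bad <- !is.na(p) & (p < 0 | p >= 0.75)
  if (any(bad))
    stop("proportion saturated or invalid (p must be in [0, 0.75)): ",
         paste(signif(p[bad], 4), collapse = ", "))
  -0.75 * log(1 - 4 * p / 3)
}

.divergence_result <- function(counts) {
  ks <- if (is.na(counts$ps)) NA_real_ else jc_correct(counts$ps)
  ka <- if (is.na(counts$pn)) NA_real_ else jc_correct(counts$pn)
  ratio <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  c(counts, list(Ks = ks, Ka = ka, ka_ks = ratio))
}

#' Synonymous and non-synonymous divergence between two coding sequences
#'
#' NG86 counting ([ng86_pairwise()]) followed by Jukes-Cantor correction of
#' `ps` and `pn`. The Ka/Ks ratio is reported as `NA` when `Ks` is 0.
#'
#' @inheritParams ng86_pairwise
#' @return List with `Sd`, `S`, `Nd`, `N`, `ps`, `pn`, `Ks`, `Ka`, `ka_ks`,
#'   `codons_analysed`, `codons_skipped`.
#' @export
kaks <- function(a, b) {
  .divergence_result(ng86_pairwise(a, b))
}

#' Divergence from pre-tabulated NG86 counts
#'
#' Applies the Jukes-Cantor correction to published per-gene substitution and
#' site counts (synonymous differences/sites, non-synonymous
#' differences/sites), reproducing Ks, Ka and Ka/Ks from a results table.
#'
#' @param sd,s Synonymous differences and sites (fractional).
#' @param nd,n Non-synonymous differences and sites (fractional).
#' @return List as in [kaks()] (count fields echoed).
#' @export
kaks_from_counts <- function(sd, s, nd, n) {
  stopifnot(s > 0, n > 0, sd >= 0, nd >= 0)
  .divergence_result(list(Sd = sd, S = s, Nd = nd, N = n,
                          ps = sd / s, pn = nd / n,
                          codons_analysed = NA_integer_,
                          codons_skipped = NA_integer_))
}

#' Date the cessation of X:Y recombination from synonymous divergence
#'
#' `T = g * Ks / (2 m)`: with a per-generation mutation rate `m` at neutral
#' sites and a generation time of `g` years, synonymous X:Y divergence `Ks`
#' accumulates along two lineages since recombination stopped.
#'
#' @param ks Synonymous divergence (substitutions per synonymous site).
#' @param g Generation time in years.
#' @param m Mutation rate per site per generation; must be positive.
#' @return List with `T_years` and the inputs.
#' @examples
#' date_divergence(0.1, 25, 1e-8)$T_years  # 125e6
#' @export
date_divergence <- function(ks, g, m) {
  stopifnot(is.numeric(ks), ks >= 0, g > 0)
  if (!is.numeric(m) || m <= 0) stop("mutation rate m must be positive")
  list(T_years = g * ks / (2 * m), ks = ks, g = g, m = m)
}

#' Relative-rates chi-square from lineage-specific substitution counts
#'
#' Tajima's 1D test statistic: `chi2 = (mX - mY)^2 / (mX + mY)` compared to a
#' chi-square distribution with 1 df (upper tail, no continuity correction).
#' When `mX + mY = 0` the statistic is 0 and p = 1.
#'
#' @param mx,my Substitutions unique to the X- and Y-lineage respectively.
#' @return List with `chi2` and `p`.
#' @examples
#' rrt_chisq(4, 14)  # chi2 = 5.56, p = 0.018
#' @export
rrt_chisq <- function(mx, my) {
  stopifnot(mx >= 0, my >= 0)
  if (mx + my == 0) return(list(chi2 = 0, p = 1))
  chi2 <- (mx - my)^2 / (mx + my)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Tajima's relative-rates test on a tripartite alignment
#'
#' Classifies each alignment site by its pattern: all three sequences equal
#' (invariable), the X-sequence differing from Y = outgroup (`mX`), the
#' Y-sequence differing (`mY`), the outgroup differing (`mO`), or all three
#' distinct (`other`). Sites where any sequence carries a non-ACGT base are
#' skipped. Under equal X and Y rates, `mX` and `mY` are symmetric, so
#' `(mX - mY)^2 / (mX + mY)` is compared to chi-square with 1 df.
#'
#' @param x,y,outgroup Aligned sequences of equal length (multiple of 3).
#' @param by_codon_position If `TRUE` (default) the test is run separately for
#'   1st, 2nd and 3rd codon positions; otherwise all sites are pooled.
#' @return `data.frame` with columns `codon_position` (`"all"` when pooled),
#'   `sites`, `invariable`, `mX`, `mY`, `mO`, `other`, `chi2`, `p`.
#' @export
tajima_rrt <- function(x, y, outgroup, by_codon_position = TRUE) {
  x <- toupper(x); y <- toupper(y); outgroup <- toupper(outgroup)
  if (nchar(x) != nchar(y) || nchar(x) != nchar(outgroup))
    stop("the three sequences must be aligned to equal length")
  if (nchar(x) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  bx <- strsplit(x, "")[[1]]
  by <- strsplit(y, "")[[1]]
  bo <- strsplit(outgroup, "")[[1]]
  ok <- bx %in% BASES & by %in% BASES & bo %in% BASES
  pos <- ((seq_along(bx) - 1L) %% 3L) + 1L
  pattern <- rep(NA_character_, length(bx))
  pattern[ok & bx == by & by == bo] <- "invariable"
  pattern[ok & by == bo & bx != by] <- "mX"
  pattern[ok & bx == bo & by != bx] <- "mY"
  pattern[ok & bx == by & bo != bx] <- "mO"
  pattern[ok & is.na(pattern)] <- "other"

  groups <- if (by_codon_position) split(pattern[ok], pos[ok])
            else list(all = pattern[ok])
  rows <- lapply(names(groups), function(g) {
    pat <- groups[[g]]
    counts <- vapply(c("invariable", "mX", "mY", "mO", "other"),
                     function(k) sum(pat == k), integer(1))
    ct <- rrt_chisq(counts[["mX"]], counts[["mY"]])
    data.frame(codon_position = g, sites = length(pat),
               invariable = counts[["invariable"]],
               mX = counts[["mX"]], mY = counts[["mY"]], mO = counts[["mO"]],
               other = counts[["other"]], chi2 = ct$chi2, p = ct$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
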