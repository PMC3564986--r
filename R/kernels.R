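#' Drop markers in complete linkage disequilibrium
#'
#' Within each chromosome, maximal runs of adjacent markers whose genotype
#' columns are identical across all lines are collapsed to their leftmost
#' member; all other markers are retained in map order. Complete LD is taken
#' literally as exactly identical columns. The operation is idempotent.
#'
#' @param geno genotype matrix (lines x markers) in map order.
#' @param map the matching \linkS4class{GeneticMap}.
#' @return integer vector of retained marker indices (map order).
#' @export
dedupCompleteLD <- function(geno, map) {
  stopifnot(ncol(geno) == length(map@marker))
  keep <- logical(ncol(geno))
  for (ch in unique(map@chrom)) {
    idx <- which(map@chrom == ch)
    keep[idx[1]] <- TRUE
    if (length(idx) > 1) {
      for (j in 2:length(idx))
        keep[idx[j]] <- !identical(unname(geno[, idx[j]]),
                                   unname(geno[, idx[j - 1]]))
    }
  }
  which(keep)
}

#' Allele frequencies of the common-parent allele
#'
#' Frequency of the +1-coded allele at each marker:
#' \eqn{p_i = (\#\{+1\} + 0.5\,\#\{0\}) / n}.
#'
#' @param geno genotype matrix with entries in \{-1, 0, +1\}.
#' @return numeric vector of per-marker frequencies in [0, 1].
#' @export
alleleFreq <- function(geno) {
  if (length(geno) == 0 || nrow(geno) == 0) stop("empty genotype matrix")
  stopifnot(all(geno %in% c(-1, 0, 1)))
  (colSums(geno == 1) + 0.5 * colSums(geno == 0)) / nrow(geno)
}

#' Genomic relationship matrix
#'
#' \eqn{A = M M^T / (2 \sum_i p_i (1 - p_i))} with M the raw coded marker
#' matrix (no centring) and p the +1-allele frequencies. For fully homozygous
#' +/-1 coding with all p = 0.5 the diagonal equals 2 exactly.
#'
#' @param geno genotype matrix M (lines x markers).
#' @param freqs per-marker allele frequencies; computed from \code{geno} when
#'   missing.
#' @return symmetric n x n relationship matrix with the denominator attached
#'   as attribute \code{"denom"}.
#' @export
computeGRM <- function(geno, freqs = alleleFreq(geno)) {
  stopifnot(length(freqs) == ncol(geno))
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0)
    stop("monomorphic marker panel: 2*sum p(1-p) is zero")
  A <- tcrossprod(geno) / denom
  A <- (A + t(A)) / 2
  rownames(A) <- colnames(A) <- rownames(geno)
  attr(A, "denom") <- denom
  attr(A, "markers") <- ncol(geno)
  A
}

#' Thin markers to a minimum spacing
#'
#' Greedy left-to-right thinning per chromosome: keep the first marker, then
#' every next marker at distance >= \code{c} cM from the last kept one, and
#' always keep the chromosome's final marker so the genomic coverage is not
#' compromised. \code{c = 0} keeps every marker.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param c minimum spacing in cM (>= 0).
#' @return integer vector of retained marker indices (map order).
#' @export
thinMarkers <- function(map, c) {
  stopifnot(c >= 0)
  keep <- integer(0)
  for (ch in unique(map@chrom)) {
    idx <- which(map@chrom == ch)
    pos <- map@pos[idx]
    sel <- 1L
    last <- pos[1]
    if (length(idx) > 1) {
      for (j in 2:length(idx)) {
        if (pos[j] - last >= c) {
          sel <- c(sel, j)
          last <- pos[j]
        }
      }
      if (sel[length(sel)] != length(idx)) sel <- c(sel, length(idx))
    }
    keep <- c(keep, idx[sel])
  }
  keep
}
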