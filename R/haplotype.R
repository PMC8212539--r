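# Read-level three-haplotype support for mosaic candidates. A genuine
# post-zygotic mutation rides on exactly one parental haplotype, so reads
# co-covering the candidate and a nearby heterozygous variant should show
# exactly three of the four allele combinations.

#' Assess three-haplotype support for a mosaic candidate
#'
#' Given counts of reads (or read pairs) co-observing the candidate allele
#' (ref/alt) and a linked heterozygous site's allele (ref/alt), the verdict
#' is \code{supported} when exactly three of the four combinations exceed
#' the noise floor, \code{unsupported} when all four do (four haplotypes
#' imply an artifact or two independent events) or when fewer than three
#' are seen at adequate depth, and \code{undecidable} below the minimum
#' read count.
#'
#' @param rr,ra,ar,aa Co-observation counts (candidate allele first:
#'   \code{rr} = candidate ref + linked ref, \code{ra} = candidate ref +
#'   linked alt, \code{ar} = candidate alt + linked ref, \code{aa} =
#'   candidate alt + linked alt). Vectorised.
#' @param noise_floor Fraction of total reads below which a combination is
#'   treated as sequencing noise (default 0.02; must be in [0, 0.5)).
#' @param min_reads Minimum total reads for a decidable verdict (default 10).
#' @return Character vector of verdicts.
#' @examples
#' three_haplotype_support(20, 15, 8, 0)
#' @export
three_haplotype_support <- function(rr, ra, ar, aa, noise_floor = 0.02,
                                    min_reads = 10) {
  if (noise_floor < 0 || noise_floor >= 0.5)
    stop("noise_floor must be in [0, 0.5)")
  counts <- cbind(rr, ra, ar, aa)
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- rowSums(counts)
  above <- rowSums(counts > noise_floor * total)
  verdict <- ifelse(total < min_reads, "undecidable",
                    ifelse(above == 3, "supported", "unsupported"))
  as.character(verdict)
}

#' Apply the three-haplotype check to a co-observation table
#'
#' @param coobs Data frame with columns \code{rr}, \code{ra}, \code{ar},
#'   \code{aa} (one row per mosaic candidate), as produced by
#'   \code{\link{simulate_study}} or an alignment adapter.
#' @inheritParams three_haplotype_support
#' @return \code{coobs} with a \code{verdict} column appended.
#' @export
haplotype_verdicts <- function(coobs, noise_floor = 0.02, min_reads = 10) {
  coobs$verdict <- three_haplotype_support(coobs$rr, coobs$ra, coobs$ar,
                                           coobs$aa, noise_floor, min_reads)
  coobs
}
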