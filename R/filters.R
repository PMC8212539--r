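# Staged presence/absence filters reducing raw multi-sample calls to
# off-target or de novo candidates. Each filter maps a variant_table to a
# subset of its rows; "absent" always means an explicit homozygous-reference
# call (code 1), never a missing genotype (code 0) -- fail-closed.

#' Remove sites that are monomorphic across all samples
#'
#' A site carries inter-sample information only if at least two distinct
#' non-missing genotype codes are observed. Sites where every covered
#' sample shares one code -- including sites missing in all samples -- are
#' removed.
#'
#' @param vt A \code{variant_table}.
#' @return The filtered \code{variant_table}.
#' @export
filter_monomorphic <- function(vt) {
  keep <- apply(vt$codes, 1L, function(z) length(unique(z[z != 0L])) >= 2L)
  subset_sites(vt, keep)
}

#' Remove sites with no coverage in the parental line
#'
#' Without a parental genotype a variant cannot be established as de novo.
#'
#' @param vt A \code{variant_table}.
#' @param parent_id Parental sample id (defaults to the design's parent).
#' @export
filter_no_parent_coverage <- function(vt, parent_id = vt$design$parent_line) {
  if (!parent_id %in% colnames(vt$codes))
    stop("unknown parent sample: ", parent_id)
  subset_sites(vt, vt$codes[, parent_id] != 0L)
}

#' Remove variants segregating in the reference population
#'
#' Exact (chrom, pos, ref, alt) match against the blacklist; a different
#' alternate allele at the same position is retained.
#'
#' @param vt A \code{variant_table}.
#' @param blacklist A \code{population_blacklist}.
#' @export
filter_population <- function(vt, blacklist) {
  subset_sites(vt, !(site_keys(vt) %in% blacklist$keys))
}

#' Keep sites passing the mapping-quality threshold
#'
#' Site-level RMS mapping quality must reach \code{threshold} (60 denotes
#' uniquely mapped reads in common aligners). Missing MQ fails the filter.
#'
#' @param vt A \code{variant_table}.
#' @param threshold Minimum MQ (default 60).
#' @param strict_equal If \code{TRUE}, require MQ exactly equal to
#'   \code{threshold} rather than at least it.
#' @export
filter_mapq <- function(vt, threshold = 60, strict_equal = FALSE) {
  mq <- vt$sites$mq
  keep <- if (strict_equal) !is.na(mq) & mq == threshold else !is.na(mq) & mq >= threshold
  subset_sites(vt, keep)
}

#' Select candidate off-target sites by clonal presence/absence
#'
#' A mutation induced in the edited cell line before cloning must be carried
#' by the edited line and its cloned animals, and absent (explicit
#' homozygous reference) from the parental line and every control clone.
#'
#' @param vt A \code{variant_table}.
#' @param design Study design (defaults to the table's).
#' @param relaxed If \code{TRUE}, require presence in at least one edited
#'   clone instead of all of them.
#' @export
select_offtarget_candidates <- function(vt, design = vt$design, relaxed = FALSE) {
  present <- vt$codes == 2L | vt$codes == 3L
  absent <- vt$codes == 1L
  ec <- present[, design$edited_clones, drop = FALSE]
  in_edited <- if (relaxed) rowSums(ec) >= 1L else rowSums(ec) == ncol(ec)
  keep <- present[, design$edited_line] & in_edited &
    absent[, design$parent_line] &
    rowSums(absent[, design$control_clones, drop = FALSE]) ==
      length(design$control_clones)
  subset_sites(vt, keep)
}

#' Select variants unique to one sample
#'
#' Keeps sites where \code{sample_id} carries the variant (code 2 or 3) and
#' every other sample is explicitly homozygous reference. By default a
#' missing genotype in any other sample disqualifies the site.
#'
#' @param vt A \code{variant_table}.
#' @param sample_id The carrier sample.
#' @param allow_missing_others If \code{TRUE}, other samples may be missing
#'   (code 0) rather than explicitly reference.
#' @export
select_sample_unique <- function(vt, sample_id, allow_missing_others = FALSE) {
  if (!sample_id %in% colnames(vt$codes))
    stop("unknown sample: ", sample_id)
  others <- setdiff(colnames(vt$codes), sample_id)
  oc <- vt$codes[, others, drop = FALSE]
  ok_others <- if (allow_missing_others) oc == 1L | oc == 0L else oc == 1L
  keep <- (vt$codes[, sample_id] %in% c(2L, 3L)) &
    rowSums(ok_others) == length(others)
  subset_sites(vt, keep)
}

#' Select variants separating a sample group from the parental line
#'
#' \code{direction = "group_gain"} keeps sites carried (code 2/3) by every
#' group member but explicitly reference in the parent with zero alternate
#' reads; \code{direction = "parent_only"} is the mirror image. The
#' zero-alt-read condition removes sites likely miscalled as homozygous
#' reference.
#'
#' @param vt A \code{variant_table}.
#' @param group_ids Non-empty character vector of group samples.
#' @param parent_id Parental sample id.
#' @param direction \code{"group_gain"} or \code{"parent_only"}.
#' @export
select_group_vs_parent <- function(vt, group_ids,
                                   parent_id = vt$design$parent_line,
                                   direction = c("group_gain", "parent_only")) {
  direction <- match.arg(direction)
  if (length(group_ids) == 0) stop("group_ids must be non-empty")
  present <- vt$codes == 2L | vt$codes == 3L
  clean_ref <- vt$codes == 1L & !is.na(vt$alt_reads) & vt$alt_reads == 0L
  gp <- present[, group_ids, drop = FALSE]
  gr <- clean_ref[, group_ids, drop = FALSE]
  keep <- if (direction == "group_gain") {
    rowSums(gp) == length(group_ids) & clean_ref[, parent_id]
  } else {
    present[, parent_id] & rowSums(gr) == length(group_ids)
  }
  subset_sites(vt, keep)
}

#' Annotate candidates with automated review-proxy flags
#'
#' Stands in for manual read-level inspection with reproducible annotations:
#' proximity (< 10 bp) to another candidate indel, a homopolymer run of at
#' least 6 bp within 10 bp of the site in the reference, and coincidence
#' with a call discarded in another sample. Flags annotate; they never
#' silently remove candidates.
#'
#' @param vt Candidate \code{variant_table}.
#' @param reference Optional \code{DNAStringSet} (or FASTA path) for the
#'   homopolymer check.
#' @param discarded Optional \code{variant_table} of calls discarded
#'   elsewhere; positional overlap is flagged.
#' @return \code{vt} with a \code{review_flags} column added to its sites.
#' @export
annotate_candidates <- function(vt, reference = NULL, discarded = NULL) {
  n <- n_sites(vt)
  flags <- vector("list", n)
  is_indel <- nchar(vt$sites$ref) != nchar(vt$sites$alt)
  for (i in seq_len(n)) {
    near <- vt$sites$chrom == vt$sites$chrom[i] & is_indel &
      abs(vt$sites$pos - vt$sites$pos[i]) < 10 & seq_len(n) != i
    if (any(near)) flags[[i]] <- c(flags[[i]], "near_indel")
  }
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*", "", names(reference))
    for (i in seq_len(n)) {
      chrom <- vt$sites$chrom[i]
      if (!chrom %in% names(reference)) next
      len <- Biostrings::width(reference[chrom])
      lo <- max(1L, vt$sites$pos[i] - 10L)
      hi <- min(len, vt$sites$pos[i] + 10L)
      win <- as.character(Biostrings::subseq(reference[[chrom]], lo, hi))
      if (grepl("A{6}|C{6}|G{6}|T{6}", win))
        flags[[i]] <- c(flags[[i]], "homopolymer")
    }
  }
  if (!is.null(discarded) && n_sites(discarded) > 0) {
    dk <- paste(discarded$sites$chrom, discarded$sites$pos)
    hit <- paste(vt$sites$chrom, vt$sites$pos) %in% dk
    for (i in which(hit)) flags[[i]] <- c(flags[[i]], "discarded_elsewhere")
  }
  vt$sites$review_flags <- vapply(flags, function(f)
    if (is.null(f)) "" else paste(unique(f), collapse = ","), character(1))
  vt
}
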