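# Guide-homology off-target site discovery: exhaustive scan of both strands
# for protospacer matches within a mismatch budget, gated by an adjacent
# IUPAC PAM pattern (Cas-OFFinder-style, without bulges).

#' Specify a CRISPR guide
#'
#' @param protospacer 20-nt DNA string (A/C/G/T) matched against the genome;
#'   written 5' to 3' with the PAM immediately 3'.
#' @param pam IUPAC PAM pattern (default \code{"NGG"} for SpCas9). The PAM
#'   is a hard constraint and its bases are not counted as mismatches.
#' @param max_mismatches Mismatch budget over the protospacer (default 5).
#' @return A \code{guide_spec}.
#' @examples
#' guide_spec("ATGGGTGTTCTTCTGGCTGT")
#' @export
guide_spec <- function(protospacer, pam = "NGG", max_mismatches = 5L) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != 20) stop("protospacer must be 20 nt")
  if (!grepl("^[ACGT]+$", protospacer)) stop("protospacer must be A/C/G/T only")
  if (!all(strsplit(pam, "")[[1]] %in% names(IUPAC_SETS)))
    stop("pam must use IUPAC nucleotide codes")
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  structure(list(protospacer = protospacer, pam = pam,
                 max_mismatches = as.integer(max_mismatches)),
            class = "guide_spec")
}

# does the genomic 3-mer (etc.) satisfy the IUPAC pam pattern?
# Ambiguous genome bases fail every position (fail-closed).
pam_ok <- function(seq_chars, pam_chars) {
  all(mapply(function(g, p) g %in% IUPAC_SETS[[p]], seq_chars, pam_chars))
}

load_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  names(reference) <- sub("\\s.*", "", names(reference))
  reference
}

# scan a single strand's character string; returns 1-based match starts,
# mismatch counts and positions within the given sequence orientation
scan_strand_hits <- function(seq, guide) {
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  hits <- Biostrings::matchPattern(guide$protospacer, seq,
                                   max.mismatch = guide$max_mismatches)
  starts <- Biostrings::start(hits)
  # PAM must fit immediately 3' of the protospacer
  starts <- starts[starts + plen + pamlen - 1L <= length(seq)]
  if (!length(starts)) return(NULL)
  pam_chars <- strsplit(guide$pam, "")[[1]]
  proto_chars <- strsplit(guide$protospacer, "")[[1]]
  keep <- logical(length(starts))
  mm <- integer(length(starts))
  mmpos <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    pm <- strsplit(as.character(Biostrings::subseq(seq, s + plen, s + plen + pamlen - 1L)), "")[[1]]
    if (!pam_ok(pm, pam_chars)) next
    win <- strsplit(as.character(Biostrings::subseq(seq, s, s + plen - 1L)), "")[[1]]
    bad <- which(win != proto_chars)
    if (length(bad) > guide$max_mismatches) next  # ambiguous bases add mismatches
    keep[i] <- TRUE
    mm[i] <- length(bad)
    mmpos[[i]] <- bad
  }
  if (!any(keep)) return(NULL)
  list(start = starts[keep], mismatches = mm[keep], mmpos = mmpos[keep])
}

#' Scan a genome for guide-homologous off-target sites
#'
#' Examines every position of every contig on both strands, reporting
#' protospacer matches within the mismatch budget that carry the PAM
#' immediately 3' on the matched strand. Ambiguous genome bases (N etc.)
#' count as mismatches in the protospacer window and never satisfy a PAM
#' position. Mismatch positions are numbered 1..20 from the PAM-distal
#' (5') end of the protospacer.
#'
#' @param reference FASTA path or a \code{Biostrings::DNAStringSet}.
#' @param guide A \code{\link{guide_spec}}.
#' @return Data frame: chrom, start, end (1-based inclusive protospacer
#'   span), strand, matched_seq (genomic sequence in protospacer
#'   orientation), mismatches, mismatch_positions (comma-separated), sorted
#'   by contig order, start, then strand. Contigs shorter than
#'   protospacer + PAM are skipped with a message.
#' @export
scan_genome <- function(reference, guide) {
  reference <- load_reference(reference)
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  res <- list()
  for (chrom in names(reference)) {
    seq <- reference[[chrom]]
    L <- length(seq)
    if (L < plen + pamlen) {
      message("contig ", chrom, " shorter than ", plen + pamlen, " nt; skipped")
      next
    }
    fwd <- scan_strand_hits(seq, guide)
    if (!is.null(fwd)) {
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = fwd$start, end = fwd$start + plen - 1L,
        strand = "+", matched_seq = vapply(seq_along(fwd$start), function(i)
          as.character(Biostrings::subseq(seq, fwd$start[i], fwd$start[i] + plen - 1L)),
          character(1)),
        mismatches = fwd$mismatches,
        mismatch_positions = vapply(fwd$mmpos, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
    rc <- Biostrings::reverseComplement(seq)
    rev <- scan_strand_hits(rc, guide)
    if (!is.null(rev)) {
      # rc index i corresponds to genome index L - i + 1
      gstart <- L - (rev$start + plen - 1L) + 1L
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = gstart, end = gstart + plen - 1L,
        strand = "-", matched_seq = vapply(seq_along(rev$start), function(i)
          as.character(Biostrings::subseq(rc, rev$start[i], rev$start[i] + plen - 1L)),
          character(1)),
        mismatches = rev$mismatches,
        mismatch_positions = vapply(rev$mmpos, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), matched_seq = character(),
                      mismatches = integer(), mismatch_positions = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  ord <- order(match(out$chrom, names(reference)), out$start, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export scanned sites as BED6
#'
#' BED uses 0-based half-open spans; name is the matched sequence and score
#' the mismatch count.
#'
#' @param sites Output of \code{\link{scan_genome}}.
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(sites$chrom, sites$start - 1L, sites$end,
                    sites$matched_seq, sites$mismatches, sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# full protospacer+PAM genomic span of a scanned site
site_span <- function(sites, pamlen = 3L) {
  lo <- ifelse(sites$strand == "+", sites$start, sites$start - pamlen)
  hi <- ifelse(sites$strand == "+", sites$end + pamlen, sites$end)
  data.frame(lo = lo, hi = hi)
}

#' Match candidate mutations to predicted off-target sites
#'
#' Reports every (candidate, site) pair on the same contig within
#' \code{window} bp. Distance is zero when the candidate position lies
#' inside the protospacer + PAM span, otherwise the gap to the nearer span
#' edge.
#'
#' @param candidates Data frame with columns \code{chrom} and \code{pos}.
#' @param sites Output of \code{\link{scan_genome}}.
#' @param window Maximum distance in bp (default 50).
#' @param pam_length PAM length used for the site span (default 3).
#' @return Data frame of pairs: candidate index/chrom/pos, site index,
#'   site start/strand, distance.
#' @export
match_candidates <- function(candidates, sites, window = 50, pam_length = 3L) {
  out <- list()
  if (nrow(candidates) && nrow(sites)) {
    span <- site_span(sites, pam_length)
    for (i in seq_len(nrow(candidates))) {
      same <- which(sites$chrom == candidates$chrom[i])
      if (!length(same)) next
      d <- pmax(span$lo[same] - candidates$pos[i],
                candidates$pos[i] - span$hi[same], 0)
      hit <- same[d <= window]
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          candidate = i, chrom = candidates$chrom[i], pos = candidates$pos[i],
          site = hit, site_start = sites$start[hit],
          site_strand = sites$strand[hit],
          distance = d[d <= window], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(candidate = integer(), chrom = character(),
                      pos = integer(), site = integer(), site_start = integer(),
                      site_strand = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# mismatches of the protospacer against a window substring (character level)
count_mm <- function(win_chars, proto_chars) {
  sum(win_chars != proto_chars)
}

#' Inspect the flanking sequence of a candidate for guide homology
#'
#' Exhaustively aligns the protospacer at every offset of the +/- flank
#' window around the candidate, on both strands, and reports (a) the
#' minimal-mismatch alignment with an adjacent PAM and (b) the overall
#' minimal-mismatch alignment ignoring the PAM. Ties break to the smaller
#' genomic coordinate, then the + strand. A window truncated at a contig
#' edge is computed on the truncated window and flagged.
#'
#' @param chrom,pos Candidate coordinate (1-based).
#' @param reference FASTA path or \code{DNAStringSet}.
#' @param guide A \code{\link{guide_spec}}.
#' @param flank Half-window size in bp (default 75).
#' @return List with \code{best_pam} and \code{best_any} (each NULL or a
#'   list of start, strand, mismatches, seq) and \code{truncated}.
#' @export
flank_homology <- function(chrom, pos, reference, guide, flank = 75) {
  reference <- load_reference(reference)
  if (!chrom %in% names(reference)) stop("unknown contig: ", chrom)
  seq <- reference[[chrom]]
  L <- length(seq)
  if (pos < 1 || pos > L) stop("candidate position outside contig bounds")
  lo <- max(1L, pos - as.integer(flank))
  hi <- min(L, pos + as.integer(flank))
  truncated <- lo > pos - flank || hi < pos + flank
  win <- as.character(Biostrings::subseq(seq, lo, hi))
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  proto_chars <- strsplit(guide$protospacer, "")[[1]]
  pam_chars <- strsplit(guide$pam, "")[[1]]

  best_pam <- NULL
  best_any <- NULL
  consider <- function(best, cand) {
    if (is.null(best)) return(cand)
    if (cand$mismatches < best$mismatches) return(cand)
    if (cand$mismatches == best$mismatches &&
        (cand$start < best$start ||
         (cand$start == best$start && cand$strand == "+" && best$strand == "-")))
      return(cand)
    best
  }
  for (strand in c("+", "-")) {
    s_chars <- strsplit(if (strand == "+") win else revcomp_chr(win), "")[[1]]
    wlen <- length(s_chars)
    if (wlen < plen) next
    for (off in 1:(wlen - plen + 1L)) {
      mmn <- count_mm(s_chars[off:(off + plen - 1L)], proto_chars)
      gstart <- if (strand == "+") lo + off - 1L else lo + (wlen - (off + plen - 1L))
      cand <- list(start = gstart, strand = strand, mismatches = mmn,
                   seq = paste(s_chars[off:(off + plen - 1L)], collapse = ""))
      best_any <- consider(best_any, cand)
      if (off + plen + pamlen - 1L <= wlen &&
          pam_ok(s_chars[(off + plen):(off + plen + pamlen - 1L)], pam_chars))
        best_pam <- consider(best_pam, cand)
    }
  }
  list(best_pam = best_pam, best_any = best_any, truncated = truncated)
}

#' Length of a 1-based inclusive genomic interval
#'
#' @param start,end Interval bounds, 1-based inclusive; \code{end >= start}.
#' @return \code{end - start + 1} base pairs.
#' @examples
#' interval_length(57340856, 57349715)  # the long-range amplicon span
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start")
  end - start + 1
}
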