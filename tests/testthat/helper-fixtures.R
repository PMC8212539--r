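# Shared fixtures: variant tables built in code, and independent oracles
# (naive character-level genome scanner, exact enumeration helpers) kept
# deliberately separate from the package implementation.

default_design <- study_design()

# build a variant_table from a codes matrix (rows = sites); read depths are
# derived from the codes unless given explicitly
make_table <- function(codes, mq = 60, design = default_design,
                       ref_reads = NULL, alt_reads = NULL,
                       chrom = "chr1", pos = NULL, ref = "A", alt = "C") {
  codes <- matrix(as.integer(codes), nrow = NROW(codes),
                  ncol = length(design_samples(design)),
                  dimnames = list(NULL, design_samples(design)))
  n <- nrow(codes)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref_reads)) {
    ref_reads <- matrix(0L, n, ncol(codes))
    ref_reads[codes == 1L] <- 50L
    ref_reads[codes == 2L] <- 25L
  }
  if (is.null(alt_reads)) {
    alt_reads <- matrix(0L, n, ncol(codes))
    alt_reads[codes == 2L] <- 25L
    alt_reads[codes == 3L] <- 50L
  }
  dimnames(ref_reads) <- dimnames(alt_reads) <- dimnames(codes)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      mq = rep_len(mq, n), stringsAsFactors = FALSE)
  clonemut:::new_variant_table(sites, codes, ref_reads, alt_reads, design)
}

# one codes row in design-sample order BEF2, CC14, 1802, 1803, 1804, 1805, B071
codes_row <- function(BEF2 = 1, CC14 = 1, `1802` = 1, `1803` = 1, `1804` = 1,
                      `1805` = 1, B071 = 1) {
  matrix(c(BEF2, CC14, `1802`, `1803`, `1804`, `1805`, B071), nrow = 1)
}

# ---- naive scanner oracle: pure character-by-character sliding window ----

oracle_iupac <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))

oracle_revcomp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

oracle_scan_one <- function(chars, proto, pam, mm_max) {
  plen <- length(proto); pamlen <- length(pam)
  L <- length(chars)
  hits <- NULL
  if (L < plen + pamlen) return(NULL)
  for (i in seq_len(L - plen - pamlen + 1L)) {
    pam_win <- chars[(i + plen):(i + plen + pamlen - 1L)]
    ok <- TRUE
    for (j in seq_len(pamlen))
      if (!pam_win[j] %in% oracle_iupac[[pam[j]]]) { ok <- FALSE; break }
    if (!ok) next
    mm <- sum(chars[i:(i + plen - 1L)] != proto)
    if (mm <= mm_max)
      hits <- rbind(hits, data.frame(start = i, mismatches = mm,
                                     seq = paste(chars[i:(i + plen - 1L)],
                                                 collapse = "")))
  }
  hits
}

oracle_scan_genome <- function(genome, guide) {
  proto <- strsplit(guide$protospacer, "")[[1]]
  pam <- strsplit(guide$pam, "")[[1]]
  out <- NULL
  for (chrom in names(genome)) {
    chars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    L <- length(chars)
    f <- oracle_scan_one(chars, proto, pam, guide$max_mismatches)
    if (!is.null(f))
      out <- rbind(out, data.frame(chrom = chrom, start = f$start,
                                   end = f$start + 19L, strand = "+",
                                   matched_seq = f$seq,
                                   mismatches = f$mismatches,
                                   stringsAsFactors = FALSE))
    r <- oracle_scan_one(oracle_revcomp(chars), proto, pam,
                         guide$max_mismatches)
    if (!is.null(r)) {
      gstart <- L - (r$start + 19L) + 1L
      out <- rbind(out, data.frame(chrom = chrom, start = gstart,
                                   end = gstart + 19L, strand = "-",
                                   matched_seq = r$seq,
                                   mismatches = r$mismatches,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(out)
  out <- out[order(match(out$chrom, names(genome)), out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# random genome as a DNAStringSet, independent of the simulator
random_genome <- function(sizes, seed) {
  set.seed(seed)
  seqs <- vapply(sizes, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("ctg", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}
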