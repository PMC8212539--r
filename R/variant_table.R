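#' Define the clonal study design
#'
#' A clonal study consists of a parental cell line, an edited cell line
#' derived from it, and cloned animals generated by somatic cell nuclear
#' transfer from either line. All presence/absence filtering logic is
#' expressed relative to this design.
#'
#' @param parent_line Sample id of the parental (non-edited) cell line.
#' @param edited_line Sample id of the gene-edited cell clone.
#' @param edited_clones Character vector of cloned animals generated from
#'   the edited line.
#' @param control_clones Character vector of cloned animals generated from
#'   the parental line.
#' @return An object of class \code{study_design}.
#' @examples
#' design <- study_design()
#' design_samples(design)
#' @export
study_design <- function(parent_line = "BEF2", edited_line = "CC14",
                         edited_clones = c("1805", "B071"),
                         control_clones = c("1802", "1803", "1804")) {
  ids <- c(parent_line, edited_line, edited_clones, control_clones)
  if (anyDuplicated(ids)) stop("sample ids in a study design must be distinct")
  if (length(edited_clones) < 1 || length(control_clones) < 1)
    stop("need at least one edited clone and one control clone")
  structure(list(parent_line = parent_line, edited_line = edited_line,
                 edited_clones = as.character(edited_clones),
                 control_clones = as.character(control_clones)),
            class = "study_design")
}

#' @rdname study_design
#' @param design A \code{study_design}.
#' @export
design_samples <- function(design) {
  c(design$parent_line, design$edited_line,
    design$control_clones, design$edited_clones)
}

#' @rdname study_design
#' @export
cloned_calves <- function(design) {
  c(design$control_clones, design$edited_clones)
}

new_variant_table <- function(sites, codes, ref_reads, alt_reads, design,
                              flags = NULL) {
  n <- nrow(sites)
  stopifnot(nrow(codes) == n, nrow(ref_reads) == n, nrow(alt_reads) == n)
  if (is.null(flags)) flags <- character(n)
  rownames(codes) <- rownames(ref_reads) <- rownames(alt_reads) <- NULL
  structure(list(sites = sites, codes = codes, ref_reads = ref_reads,
                 alt_reads = alt_reads, design = design, flags = flags),
            class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", ncol(x$codes), "samples\n")
  cat("samples:", paste(colnames(x$codes), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a variant table
#' @param vt A \code{variant_table}.
#' @export
n_sites <- function(vt) nrow(vt$sites)

subset_sites <- function(vt, keep) {
  new_variant_table(vt$sites[keep, , drop = FALSE],
                    vt$codes[keep, , drop = FALSE],
                    vt$ref_reads[keep, , drop = FALSE],
                    vt$alt_reads[keep, , drop = FALSE],
                    vt$design, vt$flags[keep])
}

site_keys <- function(vt) {
  variant_key(vt$sites$chrom, vt$sites$pos, vt$sites$ref, vt$sites$alt)
}

# dummy-code one expanded (record, alt-allele) genotype column.
# 0 = missing/no coverage, 1 = hom ref, 2 = het, 3 = hom alt -- counted
# relative to the single alt allele of the split record.
code_gt <- function(gt, allele_idx) {
  out <- integer(length(gt))
  al <- strsplit(gt, "[/|]")
  for (i in seq_along(gt)) {
    a <- al[[i]]
    if (length(a) == 0 || is.na(gt[i]) || any(a == ".")) {
      out[i] <- 0L
    } else {
      k <- sum(a == as.character(allele_idx[i]))
      out[i] <- if (k == 0L) 1L else if (k == length(a)) 3L else 2L
    }
  }
  out
}

#' Read a multi-sample VCF into the pipeline's variant table
#'
#' Loads genotypes (FORMAT/GT), per-sample allele depths (FORMAT/AD) and the
#' site-level RMS mapping quality (INFO/MQ) for every sample in the study
#' design. Genotypes are dummy coded per alternate allele: 0 = no coverage,
#' 1 = homozygous reference, 2 = heterozygous, 3 = homozygous alternate.
#' Multi-allelic records are split into one row per alternate allele, with
#' allele depths subset accordingly. Records without an MQ annotation get
#' \code{NA}, which fails the mapping-quality filter (fail-closed).
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param design A \code{study_design}; every design sample must be present
#'   in the VCF (missing samples are a hard error naming the sample).
#' @return A \code{variant_table}: sites data frame (chrom, pos, ref, alt,
#'   mq) plus per-sample code / ref-read / alt-read matrices. Rows with a
#'   malformed AD field are flagged (never silently dropped).
#' @export
read_variant_table <- function(vcf_path, design) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(design_samples(design), vcf_samples)
  if (length(missing))
    stop("design sample(s) not present in VCF: ", paste(missing, collapse = ", "))
  samples <- design_samples(design)

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  nrec <- nrow(fix)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  mq <- suppressWarnings(vcfR::extract.info(vcf, "MQ", as.numeric = TRUE))
  if (is.null(mq)) mq <- rep(NA_real_, nrec)

  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  nalt <- lengths(alt_split)
  rec <- rep(seq_len(nrec), nalt)
  aidx <- sequence(nalt)

  sites <- data.frame(chrom = fix$CHROM[rec],
                      pos = as.integer(fix$POS[rec]),
                      ref = fix$REF[rec],
                      alt = unlist(alt_split),
                      mq = mq[rec],
                      stringsAsFactors = FALSE)

  ns <- length(samples)
  nsite <- length(rec)
  codes <- matrix(0L, nsite, ns, dimnames = list(NULL, samples))
  rr <- matrix(NA_integer_, nsite, ns, dimnames = list(NULL, samples))
  ar <- matrix(NA_integer_, nsite, ns, dimnames = list(NULL, samples))
  flags <- character(nsite)

  for (s in samples) {
    codes[, s] <- code_gt(gt[rec, s], aidx)
    ads <- strsplit(ad[rec, s], ",", fixed = TRUE)
    for (i in seq_len(nsite)) {
      a <- ads[[i]]
      need <- aidx[i] + 1L
      if (length(a) < need || is.na(a[1])) {
        if (codes[i, s] != 0L) flags[i] <- "malformed_ad"
        next
      }
      rv <- suppressWarnings(as.integer(a[1]))
      av <- suppressWarnings(as.integer(a[need]))
      if (is.na(rv) || is.na(av)) {
        flags[i] <- "malformed_ad"
      } else {
        rr[i, s] <- rv
        ar[i, s] <- av
      }
    }
  }
  bad <- sum(flags != "")
  if (bad) message(bad, " record(s) flagged with malformed allele-depth fields")
  new_variant_table(sites, codes, rr, ar, design, flags)
}

#' Write a variant table back to VCF
#'
#' Emits a minimal VCF v4.2 with INFO/MQ and FORMAT GT:AD. Each row is
#' bi-allelic (split upstream), so codes map back losslessly:
#' 0 -> "./.", 1 -> "0/0", 2 -> "0/1", 3 -> "1/1".
#'
#' @param vt A \code{variant_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  samples <- colnames(vt$codes)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_map <- c("./.", "0/0", "0/1", "1/1")
  n <- n_sites(vt)
  body <- character(n)
  info <- ifelse(is.na(vt$sites$mq), ".",
                 paste0("MQ=", format(vt$sites$mq, trim = TRUE)))
  for (i in seq_len(n)) {
    cells <- vapply(samples, function(s) {
      rr <- vt$ref_reads[i, s]; ar <- vt$alt_reads[i, s]
      ad <- if (is.na(rr) || is.na(ar)) "." else paste0(rr, ",", ar)
      paste0(gt_map[vt$codes[i, s] + 1L], ":", ad)
    }, character(1))
    body[i] <- paste(c(vt$sites$chrom[i], vt$sites$pos[i], ".",
                       vt$sites$ref[i], vt$sites$alt[i], ".", ".",
                       info[i], "GT:AD", cells), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export a variant table as TSV
#'
#' Columns: chrom, pos, ref, alt, mq, then per-sample
#' \code{<sample>.code}, \code{<sample>.ref_reads}, \code{<sample>.alt_reads}.
#'
#' @inheritParams write_variant_table
#' @export
export_variant_table <- function(vt, path) {
  df <- vt$sites
  for (s in colnames(vt$codes)) {
    df[[paste0(s, ".code")]] <- vt$codes[, s]
    df[[paste0(s, ".ref_reads")]] <- vt$ref_reads[, s]
    df[[paste0(s, ".alt_reads")]] <- vt$alt_reads[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a population variant blacklist
#'
#' Variants segregating in a large unrelated population are not de novo
#' candidates; they are removed by exact (chrom, pos, ref, alt) match.
#' Accepts either a VCF (multi-allelic records are split) or a 4-column
#' TSV (chrom, pos, ref, alt; a header line is tolerated).
#'
#' @param path Path to the blacklist file.
#' @return An object of class \code{population_blacklist} holding the exact
#'   match key set.
#' @export
load_population_blacklist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  is_vcf <- length(lines) > 0 && startsWith(lines[1], "##fileformat")
  keys <- character(0)
  if (is_vcf) {
    data_lines <- lines[!startsWith(lines, "#")]
    if (length(data_lines)) {
      parts <- strsplit(data_lines, "\t", fixed = TRUE)
      for (i in seq_along(parts)) {
        p <- parts[[i]]
        if (length(p) < 5 || is.na(suppressWarnings(as.integer(p[2]))))
          stop("unparseable blacklist VCF line ", i, ": ", data_lines[i])
        alts <- strsplit(p[5], ",", fixed = TRUE)[[1]]
        keys <- c(keys, variant_key(p[1], as.integer(p[2]), p[4], alts))
      }
    }
  } else if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    start <- 1L
    if (is.na(suppressWarnings(as.integer(parts[[1]][2])))) start <- 2L  # header
    for (i in seq_along(parts)[seq_along(parts) >= start]) {
      p <- parts[[i]]
      pos <- suppressWarnings(as.integer(p[2]))
      if (length(p) < 4 || is.na(pos))
        stop("unparseable blacklist line ", i, ": ", lines[i])
      keys <- c(keys, variant_key(p[1], pos, p[3], p[4]))
    }
  }
  keys <- unique(keys)
  message("loaded population blacklist with ", length(keys), " variant keys")
  structure(list(keys = keys), class = "population_blacklist")
}

#' @exportS3Method base::print
print.population_blacklist <- function(x, ...) {
  cat("population_blacklist:", length(x$keys), "variant keys\n")
  invisible(x)
}

#' @rdname load_population_blacklist
#' @param chrom,pos,ref,alt Vectors describing variants to test.
#' @param blacklist A \code{population_blacklist}.
#' @export
blacklist_member <- function(blacklist, chrom, pos, ref, alt) {
  variant_key(chrom, pos, ref, alt) %in% blacklist$keys
}
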