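# Substitution-class assignment (six strand-collapsed classes),
# developmental-stage attribution of de novo mutations, spectrum tables and
# their exact comparisons, and genome-distribution summaries.

MUT_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
STAGES <- c("post_transfection", "culture_expansion", "calf_development",
            "unassigned")

#' Assign the strand-collapsed substitution class
#'
#' SNVs are collapsed onto the pyrimidine strand: when the reference base is
#' a purine both alleles are complemented, giving the six classes C>A, C>G,
#' C>T, T>A, T>C, T>G.
#'
#' @param ref_base,alt_base Single bases (A/C/G/T), vectorised;
#'   \code{ref != alt}.
#' @return Character vector of classes.
#' @examples
#' assign_class("G", "T")  # C>A after complementing
#' @export
assign_class <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  if (!all(ref_base %in% c("A", "C", "G", "T")) ||
      !all(alt_base %in% c("A", "C", "G", "T")))
    stop("bases must be A, C, G or T")
  if (any(ref_base == alt_base)) stop("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref_base %in% c("A", "G")
  r <- ifelse(purine, comp[ref_base], ref_base)
  a <- ifelse(purine, comp[alt_base], alt_base)
  unname(paste0(r, ">", a))
}

#' Per-sample dosage labels for every site of a variant table
#'
#' Maps genotype codes and read depths to one label per (site, sample):
#' \code{missing} (code 0), \code{absent} (explicit homozygous reference),
#' or the \code{\link{classify_dosage}} label (heterozygous / mosaic /
#' homozygous_alt / inconsistent) for carriers.
#'
#' @param vt A \code{variant_table}.
#' @param cfg A \code{\link{test_config}}.
#' @return Character matrix, sites x samples.
#' @export
dosage_label_matrix <- function(vt, cfg = test_config()) {
  labels <- matrix("absent", n_sites(vt), ncol(vt$codes),
                   dimnames = list(NULL, colnames(vt$codes)))
  labels[vt$codes == 0L] <- "missing"
  carrier <- which(vt$codes == 2L | vt$codes == 3L)
  if (length(carrier)) {
    cl <- classify_dosage(vt$alt_reads[carrier], vt$ref_reads[carrier],
                          vt$codes[carrier], cfg)
    labels[carrier] <- cl$label
  }
  labels
}

# stage rules for one site given its per-sample labels; returns the stage
# and a conflict flag (more than one rule fired, or a calf mosaic with
# another carrier sample -- e.g. heterozygous in the edited line)
stage_for_labels <- function(lab, design) {
  carrier_labs <- c("heterozygous", "mosaic", "homozygous_alt")
  calves <- cloned_calves(design)
  parent_absent <- lab[design$parent_line] == "absent"
  post <- lab[design$edited_line] == "heterozygous" &&
    all(lab[design$edited_clones] == "heterozygous") &&
    parent_absent && all(lab[design$control_clones] == "absent")
  culture_line_mosaic <- lab[design$edited_line] == "mosaic"
  het_calves <- calves[lab[calves] == "heterozygous"]
  culture_unique <- length(het_calves) == 1 && parent_absent &&
    lab[design$edited_line] == "absent" &&
    all(lab[setdiff(calves, het_calves)] == "absent")
  culture <- culture_line_mosaic || culture_unique
  mosaic_calves <- calves[lab[calves] == "mosaic"]
  calf_dev <- length(mosaic_calves) > 0
  calf_conflict <- calf_dev &&
    any(lab[setdiff(names(lab), mosaic_calves)] %in% carrier_labs)
  fired <- c(post, culture, calf_dev)
  conflict <- sum(fired) > 1 || calf_conflict
  list(stage = if (!conflict && sum(fired) == 1) STAGES[which(fired)]
         else "unassigned",
       conflict = conflict)
}

#' Attribute a developmental stage to each de novo mutation
#'
#' Stages mirror the clonal lineage: \code{post_transfection} mutations are
#' heterozygous in the edited cell line and in both edited clones but
#' absent elsewhere (arisen before the clonal bottleneck);
#' \code{culture_expansion} mutations are either mosaic in the edited cell
#' line or heterozygous and unique to a single cloned calf (arisen in the
#' donor cell during culture); \code{calf_development} mutations are mosaic
#' in a cloned calf (arisen after its first cell division). Sites firing
#' more than one rule are \code{unassigned} with a warning.
#'
#' @param vt Candidate \code{variant_table} (post filter cascade).
#' @param design Study design.
#' @param labels Optional precomputed \code{\link{dosage_label_matrix}}.
#' @param cfg A \code{\link{test_config}} (used when \code{labels} is NULL).
#' @return Character vector of stages, one per site.
#' @export
attribute_stage <- function(vt, design = vt$design, labels = NULL,
                            cfg = test_config()) {
  if (is.null(labels)) labels <- dosage_label_matrix(vt, cfg)
  res <- lapply(seq_len(nrow(labels)),
                function(i) stage_for_labels(labels[i, ], design))
  conflicts <- sum(vapply(res, `[[`, logical(1), "conflict"))
  if (conflicts)
    warning(conflicts,
            " site(s) with conflicting stage evidence left unassigned")
  vapply(res, `[[`, character(1), "stage")
}

#' Build mutation records from a candidate table
#'
#' One record per (site, carrier sample): substitution class for SNVs
#' (indels are kept as kind \code{"indel"}), carrier dosage label, and the
#' site's attributed stage.
#'
#' @param vt Candidate \code{variant_table}.
#' @param design Study design.
#' @param cfg A \code{\link{test_config}}.
#' @return Data frame: chrom, pos, ref, alt, carrier, kind, mut_class,
#'   stage, dosage_label.
#' @export
mutation_records <- function(vt, design = vt$design, cfg = test_config()) {
  labels <- dosage_label_matrix(vt, cfg)
  stage <- attribute_stage(vt, design, labels = labels)
  is_snv <- nchar(vt$sites$ref) == 1 & nchar(vt$sites$alt) == 1
  recs <- list()
  for (s in colnames(vt$codes)) {
    idx <- which(vt$codes[, s] %in% c(2L, 3L))
    if (!length(idx)) next
    cls <- rep("indel", length(idx))
    snv_i <- is_snv[idx]
    if (any(snv_i))
      cls[snv_i] <- assign_class(vt$sites$ref[idx][snv_i],
                                 vt$sites$alt[idx][snv_i])
    recs[[s]] <- data.frame(
      chrom = vt$sites$chrom[idx], pos = vt$sites$pos[idx],
      ref = vt$sites$ref[idx], alt = vt$sites$alt[idx], carrier = s,
      kind = ifelse(snv_i, "SNV", "indel"), mut_class = cls,
      stage = stage[idx],
      dosage_label = labels[cbind(idx, match(s, colnames(labels)))],
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), carrier = character(),
                      kind = character(), mut_class = character(),
                      stage = character(), dosage_label = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Tabulate the mutation spectrum per group
#'
#' Counts SNVs in the six strand-collapsed classes per group; indels are
#' tallied separately and excluded from the class table.
#'
#' @param records Data frame from \code{\link{mutation_records}} (needs
#'   \code{mut_class}, \code{kind} and the grouping column).
#' @param grouping Name of the grouping column (default \code{"stage"}).
#' @return List of class \code{spectrum_table}: \code{classes} (groups x 6
#'   count matrix), \code{indels} (per-group count), \code{totals}
#'   (per-group SNV total).
#' @export
build_spectrum <- function(records, grouping = "stage") {
  groups <- unique(records[[grouping]])
  classes <- matrix(0L, length(groups), length(MUT_CLASSES),
                    dimnames = list(groups, MUT_CLASSES))
  indels <- stats::setNames(integer(length(groups)), groups)
  for (g in groups) {
    sub <- records[records[[grouping]] == g, , drop = FALSE]
    snv <- sub[sub$kind == "SNV", , drop = FALSE]
    tab <- table(factor(snv$mut_class, levels = MUT_CLASSES))
    classes[g, ] <- as.integer(tab)
    indels[g] <- sum(sub$kind == "indel")
  }
  structure(list(classes = classes, indels = indels,
                 totals = rowSums(classes)),
            class = "spectrum_table")
}

#' @exportS3Method base::print
print.spectrum_table <- function(x, ...) {
  cat("spectrum_table (SNV counts per class):\n")
  print(cbind(x$classes, indel = x$indels))
  invisible(x)
}

#' Compare mutation spectra between groups per class
#'
#' For each substitution class, forms the 2 x k table (class count versus
#' all other classes, per group) and applies the exact Fisher test. P-values
#' are reported raw (per class, uncorrected) by default.
#'
#' @param spectrum A \code{spectrum_table} with at least two groups.
#' @param correct Optional multiplicity correction method passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}).
#' @return Named numeric vector of per-class p-values.
#' @export
compare_spectra <- function(spectrum, correct = "none") {
  if (nrow(spectrum$classes) < 2) stop("need at least two groups")
  p <- vapply(MUT_CLASSES, function(cl) {
    tab <- rbind(spectrum$classes[, cl],
                 spectrum$totals - spectrum$classes[, cl])
    fisher_exact_2xk(tab)
  }, numeric(1))
  stats::p.adjust(p, method = correct)
}

#' Binned genome distribution of mutations
#'
#' Counts mutations (SNVs and indels) per fixed-width bin per group, and
#' computes a variance-to-mean dispersion index per group to assess
#' clustering (1 under a uniform random spread).
#'
#' @param records Data frame with \code{chrom}, \code{pos} and the grouping
#'   column.
#' @param bin_size Bin width in bp (>= 1).
#' @param contig_lengths Optional named vector of contig lengths so empty
#'   trailing bins enter the dispersion index.
#' @param grouping Grouping column name (default \code{"stage"}).
#' @return List: \code{bins} (data frame chrom, bin_start, group, count)
#'   and \code{dispersion} (per-group variance/mean of bin counts).
#' @export
distribution_summary <- function(records, bin_size, contig_lengths = NULL,
                                 grouping = "stage") {
  if (bin_size < 1) stop("bin_size must be >= 1")
  if (!nrow(records))
    return(list(bins = data.frame(chrom = character(), bin_start = integer(),
                                  group = character(), count = integer()),
                dispersion = numeric(0)))
  records$bin_start <- (records$pos - 1L) %/% as.integer(bin_size) * as.integer(bin_size) + 1L
  agg <- stats::aggregate(list(count = rep(1L, nrow(records))),
                          by = list(chrom = records$chrom,
                                    bin_start = records$bin_start,
                                    group = records[[grouping]]),
                          FUN = sum)
  groups <- unique(records[[grouping]])
  disp <- stats::setNames(numeric(length(groups)), groups)
  for (g in groups) {
    counts <- agg$count[agg$group == g]
    if (!is.null(contig_lengths)) {
      total_bins <- sum(ceiling(contig_lengths / bin_size))
      counts <- c(counts, rep(0L, max(0L, total_bins - length(counts))))
    }
    disp[g] <- if (length(counts) > 1 && mean(counts) > 0)
      stats::var(counts) / mean(counts) else NA_real_
  }
  list(bins = agg, dispersion = disp)
}
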