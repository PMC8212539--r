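# End-to-end driver: runs the shared pre-filters once, then the de novo,
# off-target and group-comparison branches, and emits report tables
# (per-calf filter counts, pairwise test matrix, spectra) plus a
# machine-readable JSON summary.

#' Run the full clonal mutation analysis
#'
#' Applies the staged cascade -- monomorphic removal, parental-coverage
#' filter, population filter -- then branches: per-calf unique de novo
#' candidates with heterozygous/mosaic dosage classification; off-target
#' candidates (edited-lineage presence pattern) with optional genome-wide
#' guide scanning, candidate/site matching and flank homology; and
#' group-versus-parent comparisons. The Bonferroni family size for the
#' dosage tests defaults to the number of tests performed in each branch.
#'
#' @param x A \code{variant_table} or a VCF path.
#' @param design A \code{\link{study_design}} (required when \code{x} is a
#'   path).
#' @param blacklist Optional \code{population_blacklist} or path.
#' @param reference Optional FASTA path or \code{DNAStringSet}; enables
#'   review-proxy annotation and the off-target scan.
#' @param guide Optional \code{\link{guide_spec}}; enables the off-target
#'   scan and flank-homology checks.
#' @param config Named list of overrides: \code{mapq_threshold} (60),
#'   \code{alpha} (0.05), \code{m} (dosage-test count), \code{relaxed_offtarget}
#'   (FALSE), \code{match_window} (50), \code{bin_size} (1e4),
#'   \code{strict} (drop flagged candidates from "likely" counts; flags
#'   always annotate).
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A report bundle: \code{filter_report}, \code{pool_n},
#'   \code{table1} (per-calf counts), \code{table2} (pairwise p-value
#'   matrix, heterozygous above the diagonal, mosaic below),
#'   \code{offtarget}, \code{group_compare}, \code{spectra}, \code{config}.
#' @export
run_pipeline <- function(x, design = NULL, blacklist = NULL, reference = NULL,
                         guide = NULL, config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(mapq_threshold = 60, alpha = 0.05, m = NULL,
                                relaxed_offtarget = FALSE, match_window = 50,
                                bin_size = 1e4, strict = FALSE), config)
  if (is.character(x)) {
    if (is.null(design)) stop("design is required when reading from a VCF")
    vt <- read_variant_table(x, design)
  } else {
    vt <- x
    design <- design %||% vt$design
  }
  if (is.character(blacklist)) blacklist <- load_population_blacklist(blacklist)
  if (is.character(reference)) reference <- load_reference(reference)

  stages <- list(raw = vt)
  stages$monomorphic_removed <- filter_monomorphic(vt)
  stages$parent_covered <- filter_no_parent_coverage(stages$monomorphic_removed)
  pool <- if (!is.null(blacklist))
    filter_population(stages$parent_covered, blacklist)
  else stages$parent_covered
  stages$population_filtered <- pool
  filter_report <- data.frame(stage = names(stages),
                              count = vapply(stages, n_sites, integer(1)),
                              stringsAsFactors = FALSE)
  pool_n <- n_sites(pool)
  calves <- cloned_calves(design)

  # ---- de novo branch: per-calf unique candidates ----
  per_calf <- lapply(calves, function(calf) {
    u <- select_sample_unique(pool, calf)
    m <- filter_mapq(u, cfg$mapq_threshold)
    list(unique = u, mq = m)
  })
  names(per_calf) <- calves
  m_denovo <- cfg$m %||% max(sum(vapply(per_calf, function(z) n_sites(z$mq),
                                        integer(1))), 1L)
  tcfg <- test_config(alpha = cfg$alpha, m = m_denovo)

  table1 <- data.frame(sample = calves, unique = NA_integer_,
                       mq_pass = NA_integer_, candidate_het = NA_integer_,
                       likely_het = NA_integer_, candidate_mosaic = NA_integer_,
                       likely_mosaic = NA_integer_, stringsAsFactors = FALSE)
  denovo_candidates <- list()
  for (k in seq_along(calves)) {
    calf <- calves[k]
    mqt <- per_calf[[calf]]$mq
    cl <- if (n_sites(mqt))
      classify_dosage(mqt$alt_reads[, calf], mqt$ref_reads[, calf],
                      mqt$codes[, calf], tcfg)
    else data.frame(label = character(0))
    mqt$sites$dosage_label <- if (n_sites(mqt)) cl$label else character(0)
    mqt <- annotate_candidates(mqt, reference = reference)
    clean <- mqt$sites$review_flags == ""
    table1$unique[k] <- n_sites(per_calf[[calf]]$unique)
    table1$mq_pass[k] <- n_sites(mqt)
    table1$candidate_het[k] <- sum(cl$label == "heterozygous")
    table1$likely_het[k] <- sum(cl$label == "heterozygous" & clean)
    table1$candidate_mosaic[k] <- sum(cl$label == "mosaic")
    table1$likely_mosaic[k] <- sum(cl$label == "mosaic" & clean)
    denovo_candidates[[calf]] <- mqt
  }
  if (!cfg$strict) {
    table1$likely_het <- table1$candidate_het
    table1$likely_mosaic <- table1$candidate_mosaic
  }

  table2 <- pairwise_count_tests(
    stats::setNames(table1$likely_het, calves),
    stats::setNames(table1$likely_mosaic, calves), pool_n)

  # ---- off-target branch ----
  ot <- select_offtarget_candidates(pool, design,
                                    relaxed = cfg$relaxed_offtarget)
  ot_mq <- filter_mapq(ot, cfg$mapq_threshold)
  ot_res <- list(candidates = ot_mq, mosaic_sidechannel = NULL,
                 sites = NULL, matches = NULL, flank = NULL,
                 stage_counts = c(presence = n_sites(ot), mq = n_sites(ot_mq)))
  if (n_sites(ot_mq)) {
    ocfg <- test_config(alpha = cfg$alpha, m = cfg$m %||% n_sites(ot_mq))
    lineage <- c(design$edited_line, design$edited_clones)
    labs <- dosage_label_matrix(ot_mq, ocfg)[, lineage, drop = FALSE]
    any_mosaic <- apply(labs == "mosaic", 1L, any)
    consistent <- apply(labs == "heterozygous" | labs == "homozygous_alt",
                        1L, all)
    # mosaic candidates leave the off-target branch but stay reported
    ot_res$mosaic_sidechannel <- subset_sites(ot_mq, any_mosaic)
    ot_res$candidates <- subset_sites(ot_mq, consistent)
    ot_res$stage_counts <- c(ot_res$stage_counts,
                             dosage_consistent = n_sites(ot_res$candidates))
  }
  if (!is.null(reference) && !is.null(guide)) {
    sites <- scan_genome(reference, guide)
    cand <- ot_res$candidates$sites
    ot_res$sites <- sites
    ot_res$matches <- match_candidates(cand, sites, window = cfg$match_window)
    if (nrow(cand))
      ot_res$flank <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
        fh <- flank_homology(cand$chrom[i], cand$pos[i], reference, guide)
        data.frame(chrom = cand$chrom[i], pos = cand$pos[i],
                   pam_hit_mismatches = fh$best_pam$mismatches %||% NA_integer_,
                   any_hit_mismatches = fh$best_any$mismatches %||% NA_integer_,
                   stringsAsFactors = FALSE)
      }))
  }

  # ---- group-versus-parent comparison ----
  edited_group <- c(design$edited_line, design$edited_clones)
  group_counts <- data.frame(
    group = c("edited", "control"),
    gain = c(n_sites(filter_mapq(select_group_vs_parent(pool, edited_group,
                                                        direction = "group_gain"),
                                 cfg$mapq_threshold)),
             n_sites(filter_mapq(select_group_vs_parent(pool, design$control_clones,
                                                        direction = "group_gain"),
                                 cfg$mapq_threshold))),
    loss = c(n_sites(filter_mapq(select_group_vs_parent(pool, edited_group,
                                                        direction = "parent_only"),
                                 cfg$mapq_threshold)),
             n_sites(filter_mapq(select_group_vs_parent(pool, design$control_clones,
                                                        direction = "parent_only"),
                                 cfg$mapq_threshold))),
    stringsAsFactors = FALSE)
  group_compare <- list(
    counts = group_counts,
    gain_p = if (pool_n < 1) NA_real_ else
      two_proportion_test(group_counts$gain[1], pool_n,
                          group_counts$gain[2], pool_n)$p,
    loss_p = if (pool_n < 1) NA_real_ else
      two_proportion_test(group_counts$loss[1], pool_n,
                          group_counts$loss[2], pool_n)$p)

  # ---- spectra over staged de novo records ----
  pool_mq <- filter_mapq(pool, cfg$mapq_threshold)
  records <- mutation_records(pool_mq, design,
                              test_config(alpha = cfg$alpha, m = m_denovo))
  staged <- records[records$stage != "unassigned", , drop = FALSE]
  spectra <- list(records = staged, spectrum = NULL, pvalues = NULL,
                  distribution = NULL)
  if (nrow(staged)) {
    site_records <- staged[!duplicated(paste(staged$chrom, staged$pos,
                                             staged$alt, staged$stage)), ]
    spectra$spectrum <- build_spectrum(site_records)
    if (nrow(spectra$spectrum$classes) >= 2 &&
        sum(spectra$spectrum$totals) > 0)
      spectra$pvalues <- compare_spectra(spectra$spectrum)
    spectra$distribution <- distribution_summary(site_records, cfg$bin_size)
  }

  bundle <- list(filter_report = filter_report, pool_n = pool_n,
                 table1 = table1, table2 = table2,
                 denovo_candidates = denovo_candidates,
                 offtarget = ot_res, group_compare = group_compare,
                 spectra = spectra, config = cfg, design = design)
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Pairwise two-proportion tests over per-sample counts
#'
#' Builds the pairwise p-value matrix for two count sets over a common
#' denominator: heterozygous-count p-values above the diagonal, mosaic
#' below.
#'
#' @param het_counts,mosaic_counts Named vectors (same names).
#' @param n Common number of tested sites per sample.
#' @param continuity Continuity correction flag.
#' @return A square matrix with NA on the diagonal.
#' @export
pairwise_count_tests <- function(het_counts, mosaic_counts, n,
                                 continuity = TRUE) {
  ids <- names(het_counts)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  if (n < 1) return(m)  # no tested sites: nothing to compare
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j)
      m[i, j] <- two_proportion_test(het_counts[i], n, het_counts[j], n,
                                     continuity)$p
    if (i > j)
      m[i, j] <- two_proportion_test(mosaic_counts[i], n, mosaic_counts[j], n,
                                     continuity)$p
  }
  m
}

#' Write the report bundle to disk
#'
#' TSVs for the filter report, per-calf counts and pairwise tests, VCF/TSV
#' for candidate sets, and a machine-readable JSON summary.
#'
#' @param bundle Output of \code{\link{run_pipeline}}.
#' @param dir Output directory.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$filter_report, file.path(dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$table1, file.path(dir, "per_calf_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(bundle$table2, 10),
                     file.path(dir, "pairwise_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE,
                     col.names = NA)
  if (!is.null(bundle$offtarget$candidates) &&
      n_sites(bundle$offtarget$candidates))
    export_variant_table(bundle$offtarget$candidates,
                         file.path(dir, "offtarget_candidates.tsv"))
  if (!is.null(bundle$spectra$spectrum)) {
    utils::write.table(cbind(bundle$spectra$spectrum$classes,
                             indel = bundle$spectra$spectrum$indels),
                       file.path(dir, "spectrum.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  summary <- list(
    pool_n = bundle$pool_n,
    filter_counts = stats::setNames(as.list(bundle$filter_report$count),
                                    bundle$filter_report$stage),
    per_calf = bundle$table1,
    total_likely_het = sum(bundle$table1$likely_het),
    total_likely_mosaic = sum(bundle$table1$likely_mosaic),
    offtarget_candidates = n_sites(bundle$offtarget$candidates),
    offtarget_site_matches = if (is.null(bundle$offtarget$matches)) NA
      else nrow(bundle$offtarget$matches),
    group_compare = bundle$group_compare[c("gain_p", "loss_p")],
    spectra_pvalues = as.list(bundle$spectra$pvalues),
    config = bundle$config[vapply(bundle$config, is.atomic, logical(1))])
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  cfg_yaml <- bundle$config[vapply(bundle$config, is.atomic, logical(1))]
  yaml::write_yaml(cfg_yaml, file.path(dir, "config.yaml"))
  invisible(dir)
}
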