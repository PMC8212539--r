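# Truth-labelled synthetic clonal study: a random reference genome with
# planted guide-homologous sites, and a seven-sample variant call set with
# the lineage structure of a clone-based editing experiment (parental line,
# edited line, control clones, edited clones), so every analysis stage is
# testable against a known truth registry.

#' Simulator parameters
#'
#' Defaults describe the study conditions the pipeline targets: clonal
#' lines accumulating 3.5 +/- 0.5 mutations per genome per population
#' doubling, roughly 20 doublings before and after the clonal split,
#' sequencing depth near 50x, and mosaic mutations at allele dosages
#' between 0.1 and 0.35.
#'
#' @param genome_size Total genome length in bp (split across contigs).
#' @param n_contigs Number of contigs.
#' @param germline_variant_rate Per-bp rate of stable germline variants
#'   (shared by every sample; removed as monomorphic).
#' @param population_shared_fraction Fraction of germline/background
#'   variants present in the population blacklist.
#' @param unstable_site_rate Per-bp rate of unstable background sites with
#'   inconsistent genotypes across samples (calling noise in repetitive
#'   regions); blacklisted ones keep MQ 60, the rest get low MQ.
#' @param parent_dropout_rate Fraction of unstable sites with no parental
#'   coverage (exercises the parent-coverage filter).
#' @param doublings_pre_split Population doublings between transfection and
#'   the clonal isolation of the edited line.
#' @param doublings_post_split Doublings during expansion of each donor
#'   culture.
#' @param mu_per_doubling,mu_sd Mutations per genome per doubling
#'   (mean 3.5, sd 0.5).
#' @param cc14_mosaic_mean Mean count of mosaic mutations in the edited
#'   cell line (culture stage).
#' @param calf_mosaic_mean Mean count of mosaic mutations per cloned calf
#'   (development stage).
#' @param mosaic_dosage_range Uniform range for true mosaic allele dosage
#'   (subset of (0, 0.5)).
#' @param mean_depth Mean sequencing depth per sample per site.
#' @param depth_dispersion 0 for Poisson depth; > 0 adds negative-binomial
#'   overdispersion.
#' @param error_rate Per-read miscall probability. 0 selects the idealised
#'   noise-free mode: deterministic depths, allele counts and genotype
#'   codes.
#' @param indel_fraction Fraction of de novo mutations that are indels.
#' @param class_bias Optional named list (by stage) of weights over the six
#'   substitution classes, to plant stage-specific spectra.
#' @param planted_offtarget_count Number of degenerate protospacer copies
#'   planted in the reference.
#' @param offtarget_mismatches Mismatch counts for the planted copies
#'   (recycled; values 1..5).
#' @param offtarget_mutation_count De novo mutations planted within 50 bp
#'   of planted off-target sites (carried by the edited lineage).
#' @param protospacer,pam On-target guide sequence planted once in the
#'   reference.
#' @return A \code{simulator_params} list.
#' @export
simulator_params <- function(genome_size = 5e5, n_contigs = 5,
                             germline_variant_rate = 1e-3,
                             population_shared_fraction = 0.9,
                             unstable_site_rate = 1e-4,
                             parent_dropout_rate = 0.05,
                             doublings_pre_split = 20,
                             doublings_post_split = 20,
                             mu_per_doubling = 3.5, mu_sd = 0.5,
                             cc14_mosaic_mean = 5,
                             calf_mosaic_mean = 10,
                             mosaic_dosage_range = c(0.1, 0.35),
                             mean_depth = 50, depth_dispersion = 0,
                             error_rate = 0.005,
                             indel_fraction = 0.1,
                             class_bias = NULL,
                             planted_offtarget_count = 0,
                             offtarget_mismatches = 1:5,
                             offtarget_mutation_count = 0,
                             protospacer = "ATGGGTGTTCTTCTGGCTGT",
                             pam = "AGG") {
  stopifnot(genome_size >= 1e4, n_contigs >= 1,
            mosaic_dosage_range[1] > 0, mosaic_dosage_range[2] < 0.5,
            error_rate >= 0, error_rate < 0.5)
  structure(as.list(environment()), class = "simulator_params")
}

# draw a random DNA string of length n
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# degenerate copy of the protospacer with exactly m mismatches
degenerate_copy <- function(protospacer, m) {
  chars <- strsplit(protospacer, "")[[1]]
  idx <- sample(length(chars), m)
  for (i in idx) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

#' Simulate a reference genome with planted guide-homologous sites
#'
#' Generates a random genome containing the on-target protospacer + PAM
#' exactly once, plus \code{planted_offtarget_count} degenerate copies with
#' the requested mismatch counts, each with a concrete NGG PAM, on random
#' strands. Planted spans never overlap.
#'
#' @param params A \code{\link{simulator_params}}.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List: \code{genome} (\code{DNAStringSet}), \code{sites} (data
#'   frame of planted spans: chrom, start, end, strand, mismatches, name;
#'   the on-target site is named \code{"on_target"}), \code{guide}.
#' @export
simulate_reference <- function(params = simulator_params(), seed = 1) {
  set.seed(seed)
  contig_len <- rep(floor(params$genome_size / params$n_contigs),
                    params$n_contigs)
  contig_len[1] <- contig_len[1] + params$genome_size - sum(contig_len)
  contigs <- vapply(contig_len, random_dna, character(1))
  names(contigs) <- paste0("chr", seq_along(contigs))

  occupied <- lapply(contigs, function(x) integer(0))
  place <- function(seq23, mm, name) {
    for (attempt in 1:200) {
      ci <- sample(length(contigs), 1)
      L <- contig_len[ci]
      if (L < nchar(seq23) + 10) next
      start <- sample(L - nchar(seq23) - 1L, 1) + 1L
      span <- start:(start + nchar(seq23) - 1L)
      if (any(span %in% occupied[[ci]])) next
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") seq23 else revcomp_chr(seq23)
      substr(contigs[ci], start, start + nchar(seq23) - 1L) <<- ins
      occupied[[ci]] <<- c(occupied[[ci]], span)
      # protospacer span within the inserted protospacer+PAM
      pstart <- if (strand == "+") start else start + 3L
      return(data.frame(chrom = names(contigs)[ci], start = pstart,
                        end = pstart + 19L, strand = strand,
                        mismatches = mm, name = name,
                        stringsAsFactors = FALSE))
    }
    stop("genome too small to place planted sites")
  }

  sites <- place(paste0(params$protospacer, params$pam), 0L, "on_target")
  if (params$planted_offtarget_count > 0) {
    mms <- rep_len(params$offtarget_mismatches, params$planted_offtarget_count)
    for (i in seq_len(params$planted_offtarget_count)) {
      copy <- degenerate_copy(params$protospacer, mms[i])
      pam <- paste0(sample(c("A", "C", "G", "T"), 1), "GG")
      sites <- rbind(sites, place(paste0(copy, pam), mms[i],
                                  paste0("offtarget_", i)))
    }
  }
  genome <- Biostrings::DNAStringSet(contigs)
  list(genome = genome, sites = sites,
       guide = guide_spec(params$protospacer))
}

# ML genotype code from allele counts under a simple three-genotype model
call_code <- function(alt, depth, err) {
  if (depth == 0) return(0L)
  p <- c(err, 0.5, 1 - err)
  ll <- alt * log(p) + (depth - alt) * log1p(-p)
  c(1L, 2L, 3L)[which.max(ll)]
}

sample_position <- function(contig_names, contig_len, used, need_next = FALSE) {
  repeat {
    ci <- sample(length(contig_names), 1)
    pos <- sample(contig_len[ci] - 1L, 1)
    key <- paste0(ci, ":", pos)
    if (!key %in% used$keys) {
      used$keys <- c(used$keys, key)
      return(list(chrom = contig_names[ci], ci = ci, pos = pos))
    }
  }
}

# choose alt allele (and possibly re-draw position) honouring a class bias
draw_snv <- function(genome_chars, contig_names, contig_len, used, bias) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (is.null(bias)) {
    loc <- sample_position(contig_names, contig_len, used)
    ref <- genome_chars[[loc$ci]][loc$pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    return(c(loc, list(ref = ref, alt = alt)))
  }
  cls <- sample(MUT_CLASSES, 1, prob = bias[MUT_CLASSES])
  want <- substr(cls, 1, 1)  # pyrimidine-strand ref
  alt_py <- substr(cls, 3, 3)
  repeat {
    loc <- sample_position(contig_names, contig_len, used)
    ref <- genome_chars[[loc$ci]][loc$pos]
    if (ref == want) return(c(loc, list(ref = ref, alt = alt_py)))
    if (comp[ref] == want) return(c(loc, list(ref = ref, alt = comp[alt_py])))
    used$keys <- used$keys[-length(used$keys)]  # release and retry
  }
}

#' Simulate a complete clonal study
#'
#' Builds the seven-sample variant call set implied by the clonal lineage:
#' stable germline variants (shared by all samples), unstable background
#' sites (population-blacklisted or low-MQ), post-transfection heterozygous
#' mutations shared by the edited line and its clones, culture-expansion
#' mutations (unique heterozygous per calf, plus mosaic in the edited
#' line), and calf-development mosaic mutations. Depths are drawn around
#' \code{mean_depth}, alternate read counts binomially at the true dosage
#' (with per-read miscalls), and genotype codes by maximum likelihood --
#' unless \code{error_rate = 0}, which produces deterministic, noise-free
#' calls.
#'
#' @param params A \code{\link{simulator_params}}.
#' @param seed Integer seed.
#' @param reference Output of \code{\link{simulate_reference}}; generated
#'   internally (same seed) when NULL.
#' @param design A \code{\link{study_design}}.
#' @return List: \code{table} (a \code{variant_table}), \code{truth} (the
#'   planted-mutation registry: coordinates, alleles, kind, class, stage,
#'   carriers, true dosage, MQ, blacklist flag, off-target link),
#'   \code{blacklist} (a \code{population_blacklist}), \code{coobs}
#'   (co-observation counts for planted mosaics), \code{reference},
#'   \code{design}, \code{params}.
#' @export
simulate_study <- function(params = simulator_params(), seed = 1,
                           reference = NULL, design = study_design()) {
  if (is.null(reference)) reference <- simulate_reference(params, seed)
  set.seed(seed + 1000003L)
  samples <- design_samples(design)
  calves <- cloned_calves(design)
  contig_names <- names(reference$genome)
  contig_len <- Biostrings::width(reference$genome)
  genome_chars <- lapply(seq_along(contig_names), function(i)
    strsplit(as.character(reference$genome[[i]]), "")[[1]])
  used <- new.env()
  used$keys <- paste0(match(reference$sites$chrom, contig_names), ":",
                      reference$sites$start)  # keep planted spans variant-free

  noise_free <- params$error_rate == 0
  err <- params$error_rate
  gt_err <- max(err, 1e-3)  # genotyper's assumed per-read error

  rows <- list()
  add_row <- function(loc, ref, alt, kind, cls, stage, carriers, dosage,
                      mq = 60, blacklisted = FALSE, offtarget = NA_character_,
                      parent_dropout = FALSE, unstable_codes = NULL) {
    rows[[length(rows) + 1L]] <<- list(
      chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alt, kind = kind,
      mut_class = cls, stage = stage, carriers = carriers, dosage = dosage,
      mq = mq, blacklisted = blacklisted, offtarget = offtarget,
      parent_dropout = parent_dropout, unstable_codes = unstable_codes)
  }

  draw_variant <- function(stage, bias = NULL) {
    kind <- if (stats::runif(1) < params$indel_fraction) "indel" else "SNV"
    if (kind == "SNV") {
      v <- draw_snv(genome_chars, contig_names, contig_len, used, bias)
      list(loc = v[c("chrom", "ci", "pos")], ref = v$ref, alt = v$alt,
           kind = "SNV", cls = assign_class(v$ref, v$alt))
    } else {
      loc <- sample_position(contig_names, contig_len, used)
      ref <- genome_chars[[loc$ci]][loc$pos]
      if (stats::runif(1) < 0.5) {
        alt <- paste0(ref, sample(c("A", "C", "G", "T"), 1))  # insertion
      } else {
        ref <- paste0(ref, genome_chars[[loc$ci]][loc$pos + 1L])  # deletion
        alt <- substr(ref, 1, 1)
      }
      list(loc = loc, ref = ref, alt = alt, kind = "indel", cls = "indel")
    }
  }

  bias_for <- function(stage) {
    if (is.null(params$class_bias)) NULL else params$class_bias[[stage]]
  }

  # --- stable germline variants (shared by all samples) ---
  n_germ <- stats::rpois(1, params$germline_variant_rate * params$genome_size)
  for (i in seq_len(n_germ)) {
    v <- draw_variant("germline")
    dose <- if (stats::runif(1) < 0.5) 0.5 else 1.0
    add_row(v$loc, v$ref, v$alt, v$kind, v$cls, "germline", samples, dose,
            blacklisted = stats::runif(1) < params$population_shared_fraction)
  }

  # --- unstable background sites (calling noise / repeat regions) ---
  n_unst <- stats::rpois(1, params$unstable_site_rate * params$genome_size)
  for (i in seq_len(n_unst)) {
    v <- draw_variant("unstable")
    codes <- sample(1:3, length(samples), replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
    if (length(unique(codes)) == 1) codes[1] <- (codes[1] %% 3) + 1L
    bl <- stats::runif(1) < params$population_shared_fraction
    add_row(v$loc, v$ref, v$alt, v$kind, v$cls, "unstable", character(0), NA,
            mq = if (bl) 60 else round(stats::runif(1, 20, 59)),
            blacklisted = bl,
            parent_dropout = stats::runif(1) < params$parent_dropout_rate,
            unstable_codes = codes)
  }

  # --- post-transfection mutations: edited line + both edited clones ---
  pt_carriers <- c(design$edited_line, design$edited_clones)
  mu_pre <- max(stats::rnorm(1, params$mu_per_doubling, params$mu_sd), 0.1)
  n_post <- stats::rpois(1, mu_pre * params$doublings_pre_split)
  for (i in seq_len(n_post)) {
    v <- draw_variant("post_transfection", bias_for("post_transfection"))
    add_row(v$loc, v$ref, v$alt, v$kind, v$cls, "post_transfection",
            pt_carriers, 0.5)
  }

  # --- culture-expansion: unique heterozygous per calf ---
  for (calf in calves) {
    mu_c <- max(stats::rnorm(1, params$mu_per_doubling, params$mu_sd), 0.1)
    n_c <- stats::rpois(1, mu_c * params$doublings_post_split)
    for (i in seq_len(n_c)) {
      v <- draw_variant("culture_expansion", bias_for("culture_expansion"))
      add_row(v$loc, v$ref, v$alt, v$kind, v$cls, "culture_expansion",
              calf, 0.5)
    }
  }

  # --- culture-expansion: mosaic in the edited cell line ---
  n_cc_mos <- stats::rpois(1, params$cc14_mosaic_mean)
  for (i in seq_len(n_cc_mos)) {
    v <- draw_variant("culture_expansion", bias_for("culture_expansion"))
    add_row(v$loc, v$ref, v$alt, v$kind, v$cls, "culture_expansion",
            design$edited_line,
            stats::runif(1, params$mosaic_dosage_range[1],
                         params$mosaic_dosage_range[2]))
  }

  # --- calf-development mosaics ---
  for (calf in calves) {
    n_m <- stats::rpois(1, params$calf_mosaic_mean)
    for (i in seq_len(n_m)) {
      v <- draw_variant("calf_development", bias_for("calf_development"))
      add_row(v$loc, v$ref, v$alt, v$kind, v$cls, "calf_development", calf,
              stats::runif(1, params$mosaic_dosage_range[1],
                           params$mosaic_dosage_range[2]))
    }
  }

  # --- mutations linked to planted off-target sites ---
  ot_sites <- reference$sites[reference$sites$name != "on_target", , drop = FALSE]
  if (params$offtarget_mutation_count > 0 && nrow(ot_sites) == 0)
    stop("offtarget_mutation_count > 0 requires planted off-target sites")
  for (i in seq_len(params$offtarget_mutation_count)) {
    s <- ot_sites[((i - 1L) %% nrow(ot_sites)) + 1L, ]
    ci <- match(s$chrom, contig_names)
    repeat {
      pos <- s$start + sample(-50:50, 1)
      if (pos >= 1 && pos < contig_len[ci] &&
          !paste0(ci, ":", pos) %in% used$keys) break
    }
    used$keys <- c(used$keys, paste0(ci, ":", pos))
    ref <- genome_chars[[ci]][pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    add_row(list(chrom = s$chrom, pos = pos), ref, alt, "SNV",
            assign_class(ref, alt), "post_transfection", pt_carriers, 0.5,
            offtarget = s$name)
  }

  # --- materialise the per-sample call matrices ---
  nsite <- length(rows)
  ns <- length(samples)
  codes <- matrix(1L, nsite, ns, dimnames = list(NULL, samples))
  rr <- matrix(NA_integer_, nsite, ns, dimnames = list(NULL, samples))
  ar <- matrix(NA_integer_, nsite, ns, dimnames = list(NULL, samples))

  depth_draw <- function(k) {
    if (noise_free) rep(params$mean_depth, k)
    else if (params$depth_dispersion > 0)
      stats::rnbinom(k, mu = params$mean_depth,
                     size = 1 / params$depth_dispersion)
    else stats::rpois(k, params$mean_depth)
  }

  for (i in seq_len(nsite)) {
    r <- rows[[i]]
    depth <- depth_draw(ns)
    if (r$parent_dropout) depth[match(design$parent_line, samples)] <- 0L
    for (j in seq_len(ns)) {
      s <- samples[j]
      if (!is.null(r$unstable_codes)) {
        d_true <- c(0, 0.5, 1)[r$unstable_codes[j]]
      } else {
        d_true <- if (s %in% r$carriers) r$dosage else 0
      }
      if (noise_free) {
        alt <- round(depth[j] * d_true)
        code <- if (depth[j] == 0) 0L
          else if (!is.null(r$unstable_codes)) r$unstable_codes[j]
          else if (!(s %in% r$carriers)) 1L
          else if (d_true == 1) 3L else 2L
      } else {
        p_alt <- d_true * (1 - err) + (1 - d_true) * err
        alt <- stats::rbinom(1, depth[j], p_alt)
        code <- call_code(alt, depth[j], gt_err)
      }
      codes[i, j] <- code
      rr[i, j] <- depth[j] - alt
      ar[i, j] <- alt
    }
  }

  sites <- data.frame(chrom = vapply(rows, `[[`, character(1), "chrom"),
                      pos = vapply(rows, function(r) as.integer(r$pos), integer(1)),
                      ref = vapply(rows, `[[`, character(1), "ref"),
                      alt = vapply(rows, `[[`, character(1), "alt"),
                      mq = vapply(rows, function(r) as.numeric(r$mq), numeric(1)),
                      stringsAsFactors = FALSE)
  ord <- order(match(sites$chrom, contig_names), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  codes <- codes[ord, , drop = FALSE]
  rr <- rr[ord, , drop = FALSE]
  ar <- ar[ord, , drop = FALSE]
  rows <- rows[ord]

  truth <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    kind = vapply(rows, `[[`, character(1), "kind"),
    mut_class = vapply(rows, `[[`, character(1), "mut_class"),
    stage = vapply(rows, `[[`, character(1), "stage"),
    carriers = vapply(rows, function(r) paste(r$carriers, collapse = ","),
                      character(1)),
    true_dosage = vapply(rows, function(r) as.numeric(r$dosage[1]), numeric(1)),
    mq = sites$mq,
    population_shared = vapply(rows, `[[`, logical(1), "blacklisted"),
    offtarget_site = vapply(rows, `[[`, character(1), "offtarget"),
    stringsAsFactors = FALSE)

  blk <- truth[truth$population_shared, , drop = FALSE]
  blacklist <- structure(
    list(keys = unique(variant_key(blk$chrom, blk$pos, blk$ref, blk$alt))),
    class = "population_blacklist")

  # --- co-observation tables for planted mosaics ---
  mos <- which(truth$stage %in% c("culture_expansion", "calf_development") &
                 !is.na(truth$true_dosage) & truth$true_dosage < 0.5 &
                 truth$carriers != "" & !grepl(",", truth$carriers))
  mos <- mos[truth$true_dosage[mos] >= params$mosaic_dosage_range[1] - 1e-9]
  co_err <- if (noise_free) 0 else 0.01
  coobs <- NULL
  if (length(mos)) {
    n_reads <- depth_draw(length(mos))
    tabs <- t(vapply(seq_along(mos), function(k) {
      d <- truth$true_dosage[mos[k]]
      p <- c(rr = 0.5, ra = 0.5 - d, ar = 0, aa = d)
      p <- p * (1 - co_err) + co_err / 4
      if (noise_free) {
        cnt <- round(p * n_reads[k])
        cnt[1] <- n_reads[k] - sum(cnt[-1])
        cnt
      } else {
        as.numeric(stats::rmultinom(1, n_reads[k], p))
      }
    }, numeric(4)))
    coobs <- data.frame(chrom = truth$chrom[mos], pos = truth$pos[mos],
                        carrier = truth$carriers[mos],
                        true_dosage = truth$true_dosage[mos],
                        rr = tabs[, 1], ra = tabs[, 2], ar = tabs[, 3],
                        aa = tabs[, 4], stringsAsFactors = FALSE)
  } else {
    coobs <- data.frame(chrom = character(), pos = integer(),
                        carrier = character(), true_dosage = numeric(),
                        rr = integer(), ra = integer(), ar = integer(),
                        aa = integer(), stringsAsFactors = FALSE)
  }

  table <- new_variant_table(sites, codes, rr, ar, design)
  list(table = table, truth = truth, blacklist = blacklist, coobs = coobs,
       reference = reference, design = design, params = params)
}

#' Write a simulated study to disk
#'
#' Emits reference FASTA, planted-site BED, study VCF, truth-registry TSV,
#' blacklist TSV and co-observation TSV into \code{dir}.
#'
#' @param study Output of \code{\link{simulate_study}}.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             bed = file.path(dir, "planted_sites.bed"),
             vcf = file.path(dir, "study.vcf"),
             truth = file.path(dir, "truth.tsv"),
             blacklist = file.path(dir, "blacklist.tsv"),
             coobs = file.path(dir, "coobservation.tsv"))
  Biostrings::writeXStringSet(study$reference$genome, paths["fasta"])
  s <- study$reference$sites
  utils::write.table(data.frame(s$chrom, s$start - 1L, s$end, s$name, s$mismatches,
                                s$strand),
                     paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_variant_table(study$table, paths["vcf"])
  utils::write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  blk <- study$truth[study$truth$population_shared,
                     c("chrom", "pos", "ref", "alt")]
  utils::write.table(blk, paths["blacklist"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$coobs, paths["coobs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
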