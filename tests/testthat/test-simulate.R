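test_that("reference simulation is deterministic and places the on-target once", {
  p <- simulator_params(genome_size = 2e4, n_contigs = 2)
  r1 <- simulate_reference(p, seed = 3)
  r2 <- simulate_reference(p, seed = 3)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$sites, r2$sites)
  hits <- scan_genome(r1$genome, guide_spec(p$protospacer, max_mismatches = 0))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 0L)
})

test_that("study simulation is deterministic under a fixed seed", {
  p <- simulator_params(genome_size = 2e4, n_contigs = 2)
  s1 <- simulate_study(p, seed = 9)
  s2 <- simulate_study(p, seed = 9)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$table$codes, s2$table$codes)
  expect_identical(s1$table$alt_reads, s2$table$alt_reads)
  expect_identical(s1$coobs, s2$coobs)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("simulated VCF round-trips through the reader with zero loss", {
  p <- simulator_params(genome_size = 2e4, n_contigs = 2)
  st <- simulate_study(p, seed = 14)
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(st$table, tmp)
  back <- read_variant_table(tmp, st$design)
  expect_equal(back$codes, st$table$codes)
  expect_equal(back$sites$mq, st$table$sites$mq)
  obs <- back$codes != 0L
  expect_equal(back$alt_reads[obs], st$table$alt_reads[obs])
})

test_that("zero mutation rates yield no de novo candidates", {
  p <- simulator_params(genome_size = 2e4, n_contigs = 2,
                        doublings_pre_split = 0, doublings_post_split = 0,
                        cc14_mosaic_mean = 0, calf_mosaic_mean = 0,
                        mu_per_doubling = 0, mu_sd = 0)
  st <- simulate_study(p, seed = 4)
  expect_false(any(st$truth$stage %in%
                     c("post_transfection", "culture_expansion",
                       "calf_development")))
  out <- run_pipeline(st$table, blacklist = st$blacklist)
  expect_equal(sum(out$table1$unique), 0L)
  expect_equal(n_sites(out$offtarget$candidates), 0L)
})

test_that("noise-free cascade recovers the planted de novo set exactly", {
  p <- simulator_params(genome_size = 5e4, n_contigs = 3, error_rate = 0)
  st <- simulate_study(p, seed = 6)
  pool <- filter_mapq(filter_population(filter_no_parent_coverage(
    filter_monomorphic(st$table)), st$blacklist))
  truth_dn <- st$truth[st$truth$stage %in%
                         c("post_transfection", "culture_expansion",
                           "calf_development"), ]
  expect_setequal(clonemut:::site_keys(pool),
                  clonemut:::variant_key(truth_dn$chrom, truth_dn$pos,
                                         truth_dn$ref, truth_dn$alt))
  # per-calf unique sets equal the per-calf planted sets
  for (calf in cloned_calves(st$design)) {
    u <- select_sample_unique(pool, calf)
    t_calf <- truth_dn[truth_dn$carriers == calf, ]
    expect_setequal(clonemut:::site_keys(u),
                    clonemut:::variant_key(t_calf$chrom, t_calf$pos,
                                           t_calf$ref, t_calf$alt))
  }
})

test_that("error-free planted unique counts equal the configured plan", {
  p <- simulator_params(genome_size = 5e4, n_contigs = 2, error_rate = 0,
                        mu_per_doubling = 2, mu_sd = 0,
                        doublings_post_split = 10, calf_mosaic_mean = 0,
                        cc14_mosaic_mean = 0, indel_fraction = 0)
  st <- simulate_study(p, seed = 22)
  out <- run_pipeline(st$table, blacklist = st$blacklist)
  for (calf in cloned_calves(st$design)) {
    planted <- sum(st$truth$stage == "culture_expansion" &
                     st$truth$carriers == calf)
    expect_equal(out$table1$unique[out$table1$sample == calf], planted)
  }
})

test_that("mean per-calf culture mutations track mu x doublings", {
  p <- simulator_params(genome_size = 1e5, n_contigs = 2,
                        doublings_post_split = 20)
  counts <- unlist(lapply(1:4, function(s) {
    st <- simulate_study(p, seed = 100 + s)
    tab <- st$truth[st$truth$stage == "culture_expansion" &
                      !grepl(",", st$truth$carriers) &
                      st$truth$carriers != "CC14", ]
    table(factor(tab$carriers, levels = cloned_calves(st$design)))
  }))
  expected <- p$mu_per_doubling * p$doublings_post_split
  # Poisson with a normal rate mixture: se ~ sqrt((mu*D + (sd*D)^2)/n)
  se <- sqrt((expected + (p$mu_sd * p$doublings_post_split)^2) /
               length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("planted off-target mutations are matched to their sites", {
  p <- simulator_params(genome_size = 5e4, n_contigs = 3, error_rate = 0,
                        planted_offtarget_count = 4,
                        offtarget_mismatches = c(2, 3),
                        offtarget_mutation_count = 5,
                        doublings_pre_split = 0)
  st <- simulate_study(p, seed = 28)
  out <- run_pipeline(st$table, blacklist = st$blacklist,
                      reference = st$reference$genome,
                      guide = st$reference$guide)
  linked <- st$truth[!is.na(st$truth$offtarget_site), ]
  expect_equal(nrow(linked), 5L)
  # every planted linked mutation appears among candidate/site matches
  got <- paste(out$offtarget$matches$chrom, out$offtarget$matches$pos)
  expect_true(all(paste(linked$chrom, linked$pos) %in% got))
})

test_that("with no planted off-target link the match list is empty", {
  p <- simulator_params(genome_size = 3e4, n_contigs = 2, error_rate = 0,
                        doublings_pre_split = 0, indel_fraction = 0)
  st <- simulate_study(p, seed = 31)
  out <- run_pipeline(st$table, blacklist = st$blacklist,
                      reference = st$reference$genome,
                      guide = st$reference$guide)
  expect_equal(nrow(out$offtarget$matches), 0L)
})
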