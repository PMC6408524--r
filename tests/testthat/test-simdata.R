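test_that("generators are deterministic functions of (parameters, seed)", {
  expect_identical(random_genome(500, 0.4, 7), random_genome(500, 0.4, 7))
  expect_false(random_genome(500, 0.4, 7) == random_genome(500, 0.4, 8))
  expect_identical(random_genome(0, 0.5, 1), "")

  gnn <- build_gnn_archive()
  cfg <- dimer_configuration("CC", 6)
  g <- random_genome(150, 0.5, 3)
  expect_identical(plant_design(g, 75, cfg, gnn, seed = 9),
                   plant_design(g, 75, cfg, gnn, seed = 9))

  ref <- amplicon_ref("d", random_genome(100, 0.5, 5), cut_site = 50)
  al <- list(list(type = "del", at = 48, len = 3, fraction = 0.2))
  expect_identical(simulate_amplicon_reads(ref, al, 500, 0.01, seed = 4),
                   simulate_amplicon_reads(ref, al, 500, 0.01, seed = 4))

  loci <- data.frame(chrom = "c", start = 0L, end = 50L, rate = 10)
  expect_identical(simulate_capture_events(loci, seed = 2),
                   simulate_capture_events(loci, seed = 2))
  # generators restore the caller's RNG state
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(random_genome(100, 0.5, 99)); after <- runif(1)
  expect_identical(before, after)
})

test_that("random genomes track the requested GC content", {
  g <- random_genome(1e5, 0.5, 1)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
  g6 <- random_genome(1e5, 0.65, 2)
  gc6 <- sum(strsplit(g6, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc6 - 0.65), 3 * sqrt(0.65 * 0.35 / 1e5))
})

test_that("plant/scan round-trips across the whole grammar", {
  gnn <- build_gnn_archive()
  # six-finger: every architecture x allowed gap x skip-plan pair
  plans6 <- enumerate_skip_plans(6)
  idx <- 0
  for (arch in zfn_architectures()) {
    for (g in default_gap_sets()[[arch]]) {
      for (lp in plans6[c(1, 4)]) {
        for (rp in plans6[c(2, 3)]) {
          idx <- idx + 1
          cfg <- dimer_configuration(arch, g, lp, rp)
          genome <- random_genome(130, 0.5, idx)
          planted <- plant_design(genome, 65, cfg, gnn, seed = idx)
          d <- scan_designs(planted$genome, gnn, cfg)$designs
          expect_true(any(d$base_step == 65 & d$arch == arch),
                      info = paste(arch, g, skip_plan_label(lp),
                                   skip_plan_label(rp)))
        }
      }
    }
  }
  # five-finger arrays, including intra-module J3-4 skips, need a
  # skip-capable archive
  skiparc <- module_archive(rbind(
    finger_module("s1", "GAT"), finger_module("s1b", "GTC"),
    finger_module("s2a", c("GAC", "GTT"), skip_capable_internal = TRUE),
    finger_module("s2b", c("GCA", "GGT"), skip_capable_internal = TRUE)),
    name = "skipcap")
  for (plan in enumerate_skip_plans(5)) {
    cfg <- dimer_configuration("NN", 8, plan, skip_plan(5))
    genome <- random_genome(120, 0.5, 500 + length(plan$junctions))
    planted <- plant_design(genome, 60, cfg, skiparc, seed = 1)
    d <- scan_designs(planted$genome, skiparc, cfg)$designs
    expect_true(any(d$base_step == 60), info = skip_plan_label(plan))
  }
  # with a non-skip-capable archive an intra-module skip cannot be planted
  expect_error(
    plant_design(random_genome(120, 0.5, 1), 60,
                 dimer_configuration("NN", 8, skip_plan(5, "J3-4"),
                                     skip_plan(5)), gnn, seed = 1),
    "internal skip")
  # a plant that does not fit the genome is rejected
  expect_error(plant_design(random_genome(30, 0.5, 1), 15,
                            dimer_configuration("CC", 6), gnn, seed = 1),
               "does not fit")
})

test_that("a planted NC design is invisible to a CC-only grammar at its step", {
  gnn <- build_gnn_archive()
  genome <- random_genome(140, 0.5, 8)
  planted <- plant_design(genome, 70, dimer_configuration("NC", 6), gnn,
                          seed = 3)
  d_cc <- scan_designs(planted$genome, gnn,
                       dimer_configuration("CC", 6))$designs
  expect_false(any(d_cc$base_step == 70))
  d_nc <- scan_designs(planted$genome, gnn,
                       dimer_configuration("NC", 6))$designs
  expect_true(any(d_nc$base_step == 70))
})

test_that("per-step planting tiles a window to density 1.0", {
  gnn <- build_gnn_archive()
  genome <- random_genome(160, 0.5, 12)
  steps <- 60:73
  designs <- scan_planted_steps(genome, steps,
                                dimer_configuration("NN", 8), gnn, seed = 2)
  prof <- targeting_density(designs, c(60, 74))
  expect_equal(prof$density, 1)
  # dropping planted steps lowers the density by exactly their share
  designs2 <- designs[!designs$base_step %in% c(62, 70), ]
  expect_equal(targeting_density(designs2, c(60, 74))$density, 12 / 14)
})

test_that("simulated reads carry the planted allele spectrum exactly", {
  ref <- amplicon_ref("amp", random_genome(110, 0.5, 21), cut_site = 55)
  # all fractions zero -> pure wild type
  sim0 <- simulate_amplicon_reads(ref, list(), n_reads = 50, error_rate = 0,
                                  seed = 1)
  expect_true(all(sim0$reads == ref$sequence))
  # realized counts are multinomial and sum to n_reads
  al <- list(list(type = "del", at = 53, len = 4, fraction = 0.3),
             list(type = "ins", at = 55, seq = "GG", fraction = 0.1))
  sim <- simulate_amplicon_reads(ref, al, n_reads = 1000, error_rate = 0,
                                 seed = 6)
  expect_equal(sum(sim$truth$alleles$count), 1000L)
  at <- call_alleles(sim$reads, ref)
  got <- at$alleles[at$alleles$is_indel, ]
  want <- sim$truth$alleles[sim$truth$alleles$key != "WT", ]
  expect_setequal(got$allele, want$key)
  expect_equal(got$count[match(want$key, got$allele)], want$count)
  expect_error(
    simulate_amplicon_reads(ref, list(list(type = "del", at = 1, len = 1,
                                           fraction = 1.2))),
    "fractions")
})

test_that("capture-event simulation plants rates, decoy tags and replicates", {
  loci <- data.frame(chrom = c("c1", "c2"), start = c(100L, 5000L),
                     end = c(150L, 5050L), rate = c(60, 30),
                     n_best_hits = c(1L, 3L))
  sim <- simulate_capture_events(loci, control_rate = 0, n_replicates = 4,
                                 seed = 9)
  e <- sim$events
  expect_setequal(unique(e$replicate), paste0("rep", 1:4))
  expect_true(all(e$arm == "treated"))  # control rate 0 -> no control events
  expect_true(all(e$position[e$chrom == "c1"] >= 100 &
                    e$position[e$chrom == "c1"] < 150))
  expect_true(all(e$n_best_hits[e$chrom == "c2"] == 3L))
  # with zero control, every treated cluster passes the fold filter
  cl <- apply_filters(
    cluster_events(e[e$replicate == "rep1", ]),
    e[0, ], "c9:1-2")
  expect_true(all(cl$fold_pass))
  # high-rate loci are supported in all four replicates
  cand <- call_offtarget_candidates(e, e[0, ], "c9:1-2")
  expect_true(all(cand$n_replicates == 4L))
})

test_that("FASTQ round-trips through the Biostrings-backed writers", {
  reads <- c("ACGTACGT", "TTTTGGGG", "ACGT")
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  expect_equal(read_fastq(f), setNames(reads, paste0("read", 1:3)))
  ref <- amplicon_ref("fq", random_genome(80, 0.5, 2), cut_site = 40)
  fq <- tempfile(fileext = ".fastq")
  sim <- simulate_amplicon_reads(ref, list(), n_reads = 20, error_rate = 0,
                                 seed = 3, fastq = fq)
  expect_equal(unname(call_alleles(fq, ref)$n_reads), 20L)
})
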