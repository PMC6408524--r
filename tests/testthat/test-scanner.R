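gnn <- build_gnn_archive()

test_that("scanner finds assemblable sites with the orientation convention", {
  # 18 consecutive G matches the all-GGG six-finger assembly on the top strand
  s <- find_zfp_sites(strrep("G", 18), gnn, 6, skip_plan(6))
  expect_true(any(s$start == 0 & s$end == 18 & s$strand == "+" &
                    s$triplets == "GGG,GGG,GGG,GGG,GGG,GGG"))
  # empty sequence scans to nothing
  expect_equal(nrow(find_zfp_sites("", gnn, 6)), 0L)
  # a non-G first base kills any top-strand site at offset 0: the 5'-most
  # triplet must start with G
  s2 <- find_zfp_sites(paste0("T", strrep("G", 17)), gnn, 6, skip_plan(6))
  expect_false(any(s2$start == 0 & s2$strand == "+"))
  expect_error(find_zfp_sites("ACGT", gnn, 4), "5 or 6")
})

test_that("scanner and pairing match brute-force enumeration on random inputs", {
  set.seed(401)
  for (case in 1:40) {
    arc <- random_archive(1000 + case, n1 = 2L, n2 = 4L,
                          skip_capable = case %% 2 == 0)
    L <- sample(70:160, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    fc <- if (case %% 2 == 0) 5L else 6L
    plans <- enumerate_skip_plans(fc)[sample.int(4, sample(2:4, 1))]
    if (case %% 3 != 0) {
      # plant a design so the comparison exercises non-trivial matches
      arch <- sample(zfn_architectures(), 1)
      cfg <- try(dimer_configuration(
        arch, sample(default_gap_sets()[[arch]], 1),
        plans[[sample.int(length(plans), 1)]],
        plans[[sample.int(length(plans), 1)]]), silent = TRUE)
      if (!inherits(cfg, "try-error")) {
        pl <- try(plant_design(seq, L %/% 2, cfg, arc, seed = case),
                  silent = TRUE)
        if (!inherits(pl, "try-error")) seq <- pl$genome
      }
    }
    got <- find_zfp_sites(seq, arc, fc, plans)
    want <- orc_find_sites(seq, arc, fc, plans)
    expect_equal(got, want, info = paste("case", case))

    gaps <- default_gap_sets()
    cfgs <- lapply(zfn_architectures(), function(a) {
      dimer_configuration(a, sample(gaps[[a]], 1),
                          plans[[sample.int(length(plans), 1)]],
                          plans[[sample.int(length(plans), 1)]])
    })
    expect_equal(design_ids(pair_dimers(got, cfgs)), orc_pair(got, cfgs),
                 info = paste("pair case", case))
  }
})

test_that("site pairing follows architecture strand and gap rules", {
  cfg <- dimer_configuration("CC", 6)
  # plant a canonical dimer: left site on bottom strand, right on top
  g <- random_genome(120, 0.45, 21)
  p <- plant_design(g, 60, cfg, gnn, seed = 2)
  sites <- find_zfp_sites(p$genome, gnn, 6, skip_plan(6))
  d <- pair_dimers(sites, cfg)
  expect_gte(nrow(d), 1L)
  expect_true(all(d$left_strand == "-" & d$right_strand == "+"))
  expect_true(any(d$base_step == 60))
  # the same sites cannot form an NC dimer (both sites must share a strand)
  expect_equal(nrow(pair_dimers(sites, dimer_configuration("NC", 6))), 0L)
})

test_that("a locus planted once per architecture yields one design per architecture", {
  g <- random_genome(520, 0.45, 77)
  centers <- c(CC = 60L, NC = 180L, CN = 300L, NN = 420L)
  cfgs <- lapply(names(centers), function(a) {
    dimer_configuration(a, default_gap_sets()[[a]][1])
  })
  names(cfgs) <- names(centers)
  for (a in names(centers)) {
    pl <- plant_design(g, centers[[a]], cfgs[[a]], gnn, seed = match(a, names(centers)))
    g <- pl$genome
  }
  res <- scan_designs(g, gnn, unname(cfgs))
  d <- res$designs
  for (a in names(centers)) {
    expect_equal(unique(d$arch[d$base_step == centers[[a]]]), a)
  }
  expect_equal(nrow(d), 4L)
})

test_that("site and design sets are monotone in archive, architectures, skips", {
  cfg_all <- enumerate_configurations(finger_count = 6, skips_enabled = TRUE)
  cfg_cc <- enumerate_configurations("CC", finger_count = 6)
  for (seed in 1:5) {
    g <- random_genome(300, 0.6, seed)
    g <- plant_design(g, 150, dimer_configuration("CC", 6), gnn,
                      seed = seed)$genome
    small <- module_archive(gnn$modules[gnn$modules$n_fingers == 2L &
                                          seq_len(272) %% 3 == 0, ],
                            name = "sub")
    s_small <- find_zfp_sites(g, small, 6, skip_plan(6))
    s_full <- find_zfp_sites(g, gnn, 6, skip_plan(6))
    expect_lte(nrow(s_small), nrow(s_full))
    n_cc <- count_designs(g, gnn, cfg_cc)
    n_all <- count_designs(g, gnn, cfg_all)
    expect_lte(n_cc, n_all)
    s_noskip <- find_zfp_sites(g, gnn, 6, skip_plan(6))
    s_skips <- find_zfp_sites(g, gnn, 6)
    expect_lte(nrow(s_noskip), nrow(s_skips))
  }
})

test_that("scanning the reverse complement mirrors sites and swaps NC/CN", {
  g <- random_genome(200, 0.55, 9)
  g <- plant_design(g, 100, dimer_configuration("NC", 6), gnn, seed = 4)$genome
  L <- nchar(g)
  fwd <- find_zfp_sites(g, gnn, 6)
  rev <- find_zfp_sites(revcomp(g), gnn, 6)
  flip <- c("+" = "-", "-" = "+")
  mirrored <- data.frame(start = L - rev$end, end = L - rev$start,
                         strand = unname(flip[rev$strand]),
                         finger_count = rev$finger_count,
                         skip_plan = rev$skip_plan, modules = rev$modules,
                         triplets = rev$triplets, stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand,
                             mirrored$skip_plan, mirrored$modules), ]
  rownames(mirrored) <- NULL
  expect_equal(mirrored, fwd)

  # design level: NC designs on the forward strand appear as CN on the revcomp
  nc <- pair_dimers(fwd, dimer_configuration("NC", 6))
  cn_rc <- pair_dimers(rev, dimer_configuration("CN", 6))
  expect_equal(nrow(nc), nrow(cn_rc))
  expect_gte(nrow(nc), 1L)
})

test_that("scanner output is deterministic and input-order independent", {
  g <- plant_design(random_genome(150, 0.5, 3), 75,
                    dimer_configuration("NN", 8), gnn, seed = 5)$genome
  s1 <- find_zfp_sites(g, gnn, 6)
  s2 <- find_zfp_sites(g, gnn, 6)
  expect_identical(s1, s2)
  cfgs <- enumerate_configurations(finger_count = 6, skips_enabled = TRUE)
  d1 <- pair_dimers(s1, cfgs)
  shuffled <- s1[sample.int(nrow(s1)), ]
  d2 <- pair_dimers(shuffled, rev(cfgs))
  expect_equal(design_ids(d1), design_ids(d2))
})

test_that("targeting density counts covered base steps over the region", {
  expect_equal(targeting_density(.empty <- data.frame(base_step = integer(0)),
                                 c(0, 28))$density, 0)
  d <- data.frame(base_step = 0:27)
  expect_equal(targeting_density(d, c(0, 28))$density, 1)
  d25 <- data.frame(base_step = setdiff(0:27, c(3, 11, 20)))
  expect_equal(targeting_density(d25, c(0, 28))$density, 25 / 28)
  # a region of length L is scored at L base steps
  expect_equal(nrow(targeting_density(d, c(0, 28))$steps), 28L)
  expect_error(targeting_density(d, c(5, 6)), "length >= 2")
})

test_that("interface writers emit BED6, TSV and JSON", {
  g <- plant_design(random_genome(120, 0.5, 13), 60,
                    dimer_configuration("CC", 6), gnn, seed = 6)$genome
  res <- scan_designs(g, gnn, dimer_configuration("CC", 6))
  fb <- tempfile(fileext = ".bed")
  write_sites_bed(res$sites, fb, chrom = "toy")
  bed <- read.table(fb, sep = "\t")
  expect_equal(ncol(bed), 6L)
  expect_true(all(bed$V6 %in% c("+", "-")))
  ft <- tempfile(fileext = ".tsv")
  write_designs_tsv(res$designs, ft, chrom = "toy")
  expect_equal(nrow(read.table(ft, header = TRUE, sep = "\t")),
               nrow(res$designs))
  fj <- tempfile(fileext = ".json")
  write_density_json(targeting_density(res$designs, c(0, 120)), fj)
  parsed <- jsonlite::fromJSON(fj)
  expect_equal(parsed$region, c(0, 120))
  expect_true(parsed$density >= 0 && parsed$density <= 1)
})
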