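# Deterministic generators: toy genomes with planted ZFN dimer targets,
# amplicon read sets with planted indel spectra, and capture-event tables
# with planted off-target structure. Every generator is a pure function of
# (parameters, seed) and returns a truth record sufficient to compute the
# downstream expected values exactly.

# Run code under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random genome sequence
#'
#' @param length Sequence length (>= 0).
#' @param gc Target GC fraction in `[0, 1]` (default 0.5); realized
#'   composition is binomial around it.
#' @param seed RNG seed; identical inputs give identical sequences.
#' @return A DNA string.
#' @export
random_genome <- function(length, gc = 0.5, seed = 0L) {
  stopifnot(length >= 0, gc >= 0, gc <= 1)
  if (length == 0L) return("")
  with_seed(seed, paste(
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""))
}

# Pick one concrete base for each IUPAC code in a character vector.
.sample_concrete <- function(chars) {
  vapply(chars, function(ch) {
    b <- iupac_bases(ch)
    if (length(b) == 1L) b else sample(b, 1L)
  }, "", USE.NAMES = FALSE)
}

# Choose modules and emit a concrete, matchable site sequence for one side
# of a layout. Returns list(seq, module_ids, triplets).
.materialize_site <- function(plan, archive, composition = NULL,
                              module_ids = NULL) {
  fr <- site_frame(plan$finger_count, plan, composition)
  mods <- archive$modules
  chars <- rep(NA_character_, fr$site_len)
  ids <- character(length(fr$slots))
  trs <- character(0)
  for (s in seq_along(fr$slots)) {
    sl <- fr$slots[[s]]
    if (is.null(module_ids)) {
      elig <- which(mods$n_fingers == sl$n_fingers &
                      (!sl$internal_skip | mods$skip_capable_internal))
      if (!length(elig)) {
        stop("no archive module can fill a ", sl$n_fingers, "-finger slot",
             if (sl$internal_skip) " with an internal skip" else "")
      }
      pick <- if (length(elig) == 1L) elig else sample(elig, 1L)
    } else {
      pick <- match(module_ids[s], mods$id)
      if (is.na(pick)) stop("module id not in archive: ", module_ids[s])
    }
    ids[s] <- mods$id[pick]
    tchars <- strsplit(gsub(",", "", mods$triplets[pick], fixed = TRUE),
                       "", fixed = TRUE)[[1]]
    chars[sl$positions + 1L] <- .sample_concrete(tchars)
    trs <- c(trs, .split_triplets(mods$triplets[pick]))
  }
  if (length(fr$skip_positions)) {
    chars[fr$skip_positions + 1L] <- sample(c("A", "C", "G", "T"),
                                            length(fr$skip_positions),
                                            replace = TRUE)
  }
  list(seq = paste(chars, collapse = ""), module_ids = ids, triplets = trs)
}

#' Plant a ZFN dimer design into a genome
#'
#' Realizes the layout for `config` at the given cleavage base step, picks
#' archive modules for each side (at random among eligible modules, or as
#' given), and writes strand-correct matchable sequence at both half-site
#' intervals; skipped bases are randomized and the gap is left untouched.
#' By construction the scanner finds at least one design at the planted base
#' step when run with the planted configuration.
#'
#' @param genome DNA string.
#' @param center Cleavage base step (0-based).
#' @param config A `dimer_config`.
#' @param archive A `module_archive`.
#' @param seed RNG seed.
#' @param composition Optional module composition (see
#'   [default_composition()]).
#' @param left_modules,right_modules Optional module ids (5'->3' site order)
#'   to use instead of random picks.
#' @return List with `genome` (modified string) and `truth` (planted layout,
#'   module choices, site sequences, seed).
#' @export
plant_design <- function(genome, center, config, archive, seed = 0L,
                         composition = NULL, left_modules = NULL,
                         right_modules = NULL) {
  layout <- realize_layout(center, config)
  if (layout$left$start < 0L || layout$right$end > nchar(genome)) {
    stop("layout [", layout$left$start, ",", layout$right$end,
         ") does not fit in a genome of length ", nchar(genome))
  }
  with_seed(seed, {
    left <- .materialize_site(config$left_skip, archive, composition,
                              left_modules)
    right <- .materialize_site(config$right_skip, archive, composition,
                               right_modules)
    for (side in list(list(site = layout$left, mat = left),
                      list(site = layout$right, mat = right))) {
      s <- side$mat$seq
      if (side$site$strand == "-") s <- revcomp(s)
      substr(genome, side$site$start + 1L, side$site$end) <- s
    }
    list(genome = genome,
         truth = list(center = center, arch = config$arch,
                      gap_bp = config$gap_bp, layout = layout,
                      left = c(layout$left, list(modules = left$module_ids,
                                                 site_seq = left$seq)),
                      right = c(layout$right, list(modules = right$module_ids,
                                                   site_seq = right$seq)),
                      seed = seed))
  })
}

#' Plant one design per base step and scan each planted genome
#'
#' For each requested base step, plants a design into a fresh copy of the
#' genome, scans that copy with the planted configuration, and pools the
#' recovered designs. This mirrors the tiling experiment the density readout
#' models -- one ZFN pair designed per base step of a window, each verified
#' independently -- and avoids adjacent plants overwriting each other, which
#' overlapping half-sites at consecutive steps of a single genome otherwise
#' would.
#'
#' @param genome DNA string (must accommodate the layout at every step).
#' @param steps Integer vector of cleavage base steps to plant.
#' @param config A `dimer_config` (or list, one per step, recycled).
#' @param archive A `module_archive`.
#' @param seed Base seed; step i uses `seed + i`.
#' @return data.frame of pooled designs (as from [pair_dimers()]) covering
#'   the planted steps.
#' @export
scan_planted_steps <- function(genome, steps, config, archive, seed = 0L) {
  cfgs <- if (inherits(config, "dimer_config")) {
    rep(list(config), length(steps))
  } else rep(config, length.out = length(steps))
  pooled <- list()
  for (i in seq_along(steps)) {
    planted <- plant_design(genome, steps[i], cfgs[[i]], archive,
                            seed = seed + i)
    res <- scan_designs(planted$genome, archive, cfgs[[i]])
    pooled[[i]] <- res$designs[res$designs$base_step == steps[i], ,
                               drop = FALSE]
  }
  designs <- do.call(rbind, pooled)
  designs <- designs[!duplicated(designs$id), , drop = FALSE]
  rownames(designs) <- NULL
  designs
}

# Apply a single indel edit (0-based) to a sequence.
.apply_edit <- function(seq, edit) {
  n <- nchar(seq)
  at <- as.integer(edit$at)
  if (edit$type == "del") {
    len <- as.integer(edit$len)
    stopifnot(at >= 0L, at + len <= n)
    paste0(substr(seq, 1L, at), substr(seq, at + len + 1L, n))
  } else if (edit$type == "ins") {
    stopifnot(at >= 0L, at <= n)
    paste0(substr(seq, 1L, at), toupper(edit$seq), substr(seq, at + 1L, n))
  } else {
    stop("edit type must be 'del' or 'ins'")
  }
}

# Canonical (left-normalized) allele key for an edit on a reference, in the
# same format the indel caller uses.
.edit_key <- function(edit, refseq) {
  refc <- strsplit(toupper(refseq), "", fixed = TRUE)[[1]]
  if (edit$type == "del") {
    pos <- .leftshift_del(refc, as.integer(edit$at), as.integer(edit$len))
    paste0("D@", pos, ":", edit$len)
  } else {
    sh <- .leftshift_ins(refc, as.integer(edit$at), toupper(edit$seq))
    paste0("I@", sh$pos, ":", sh$ins)
  }
}

#' Simulate amplicon deep-sequencing reads with a planted indel spectrum
#'
#' Reads are drawn multinomially from the allele pool (planted indel alleles
#' plus wild type for the remaining fraction) and substitution errors are
#' applied at `error_rate` per base. Indel sequencing errors are not
#' simulated, so the planted allele counts are the exact truth for the indel
#' caller.
#'
#' @param ref An [amplicon_ref()].
#' @param alleles List of edits, each a list with `type` (`"del"`/`"ins"`),
#'   `at` (0-based position), `len` (deletions) or `seq` (insertions), and
#'   `fraction`. Fractions must sum to <= 1; the remainder is wild type.
#' @param n_reads Number of reads (default 10000).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param seed RNG seed.
#' @param fastq Optional path; when given the reads are also written as
#'   FASTQ.
#' @return List with `reads` (character vector, shuffled) and `truth` (per
#'   allele: canonical key, planted fraction, realized count; plus
#'   `n_reads`, `error_rate`, `seed`).
#' @export
simulate_amplicon_reads <- function(ref, alleles, n_reads = 10000L,
                                    error_rate = 0.001, seed = 0L,
                                    fastq = NULL) {
  stopifnot(inherits(ref, "amplicon_ref"))
  fracs <- vapply(alleles, function(a) as.numeric(a$fraction), numeric(1))
  if (any(fracs < 0) || sum(fracs) > 1 + 1e-12) {
    stop("allele fractions must be >= 0 and sum to <= 1")
  }
  seqs <- c(vapply(alleles, function(a) .apply_edit(ref$sequence, a), ""),
            ref$sequence)
  keys <- c(vapply(alleles, function(a) .edit_key(a, ref$sequence), ""), "WT")
  probs <- c(fracs, 1 - sum(fracs))
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1L, n_reads, probs))
    reads <- rep(seqs, counts)
    lens <- nchar(reads)
    n_err <- stats::rbinom(length(reads), lens, error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(lens[i], n_err[i])
      chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (p in pos) {
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      reads[i] <- paste(chars, collapse = "")
    }
    reads <- sample(reads)
    truth <- list(alleles = data.frame(key = keys, fraction = probs,
                                       count = counts,
                                       stringsAsFactors = FALSE),
                  n_reads = as.integer(n_reads), error_rate = error_rate,
                  seed = seed)
    if (!is.null(fastq)) write_fastq(reads, fastq)
    list(reads = reads, truth = truth)
  })
}

#' Simulate duplex-capture integration-event tables
#'
#' Per locus and replicate, the treated arm receives `Poisson(rate)` unique
#' integrations placed uniformly in the locus interval with random strands;
#' the control arm receives `Poisson(control_rate)` (overridable per locus
#' via a `control_rate` column). Multimapping decoys are tagged via an
#' `n_best_hits` column (default 1).
#'
#' @param true_loci data.frame with columns `chrom`, `start`, `end`, `rate`,
#'   and optionally `control_rate`, `n_best_hits`, `name`.
#' @param control_rate Default control-arm event rate per locus per
#'   replicate (default 0).
#' @param n_replicates Number of replicates (default 4, the full-quadruplicate
#'   design).
#' @param seed RNG seed.
#' @return List with `events` (treated + control event data.frame) and
#'   `truth` (the locus table plus `n_replicates` and `seed`).
#' @export
simulate_capture_events <- function(true_loci, control_rate = 0,
                                    n_replicates = 4L, seed = 0L) {
  loci <- true_loci
  if (is.null(loci$control_rate)) loci$control_rate <- control_rate
  if (is.null(loci$n_best_hits)) loci$n_best_hits <- 1L
  if (is.null(loci$name)) loci$name <- paste0("locus", seq_len(nrow(loci)))
  stopifnot(all(loci$rate >= 0), all(loci$control_rate >= 0))
  with_seed(seed, {
    out <- list()
    emit <- function(i, r, n, arm) {
      if (n == 0L) return(NULL)
      width <- loci$end[i] - loci$start[i]
      integration_events(
        chrom = loci$chrom[i],
        position = loci$start[i] + sample.int(width, n, replace = TRUE) - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        n_best_hits = loci$n_best_hits[i],
        replicate = paste0("rep", r), arm = arm)
    }
    for (i in seq_len(nrow(loci))) {
      for (r in seq_len(n_replicates)) {
        out[[length(out) + 1L]] <- emit(i, r, stats::rpois(1L, loci$rate[i]),
                                        "treated")
        out[[length(out) + 1L]] <- emit(i, r,
                                        stats::rpois(1L, loci$control_rate[i]),
                                        "control")
      }
    }
    events <- do.call(rbind, out)
    if (is.null(events)) {
      events <- integration_events(character(0), integer(0), character(0),
                                   integer(0), character(0), character(0))
    }
    list(events = events,
         truth = list(loci = loci, n_replicates = as.integer(n_replicates),
                      seed = seed))
  })
}

#' Write reads as FASTQ (constant high quality)
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param ids Optional read names.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids %||% paste0("read", seq_along(reads))
  q <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), ""))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(x, q), filepath = path)
  invisible(path)
}

#' Read FASTQ sequences as a character vector
#' @param path FASTQ (or FASTA) file path.
#' @return Character vector of sequences.
#' @export
read_fastq <- function(path) {
  fmt <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) "fasta"
         else "fastq"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}
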