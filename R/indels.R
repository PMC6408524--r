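# Amplicon indel quantification. Reads are globally aligned to the amplicon
# reference (end-gap-free on the reference side), indel operations are
# left-normalized so that allele keys are canonical, and a read is an indel
# allele iff it carries an insertion or deletion overlapping the expected
# cut window. Background correction reclassifies indel alleles shared with
# an untreated control; significance uses Fisher's exact test with a
# Bonferroni correction over the number of loci tested.

#' Construct an amplicon reference
#'
#' @param locus_id Locus identifier.
#' @param sequence Reference amplicon sequence (A/C/G/T).
#' @param cut_site Expected cleavage base step (0-based) within the amplicon;
#'   used to derive the cut window when `cut_window` is not given.
#' @param cut_window Optional `c(start, end)` (0-based half-open) interval in
#'   which indels count as edits; defaults to `cut_site` +/- `window_halfwidth`
#'   clipped to the amplicon. Indels outside the window are ignored as
#'   PCR/sequencing artifacts.
#' @param window_halfwidth Half-width in bp of the default window (20).
#' @return Object of class `amplicon_ref`.
#' @export
amplicon_ref <- function(locus_id, sequence, cut_site = NULL,
                         cut_window = NULL, window_halfwidth = 20L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (is.null(cut_window)) {
    if (is.null(cut_site)) stop("give either cut_site or cut_window")
    cut_window <- c(max(0L, cut_site - window_halfwidth),
                    min(n, cut_site + window_halfwidth))
  }
  cut_window <- as.integer(cut_window)
  if (cut_window[1] < 0L || cut_window[2] > n || cut_window[1] >= cut_window[2]) {
    stop("cut_window must be a non-empty interval within the amplicon")
  }
  structure(list(locus_id = locus_id, sequence = sequence,
                 cut_window = cut_window),
            class = "amplicon_ref")
}

# Left-normalize a deletion: shift while the base before the deletion equals
# its last deleted base. refc is the reference as a character vector; pos is
# the 0-based start of the deleted interval.
.leftshift_del <- function(refc, pos, len) {
  while (pos > 0L && refc[pos] == refc[pos + len]) pos <- pos - 1L
  pos
}

# Left-normalize an insertion of string `ins` before 0-based position pos.
.leftshift_ins <- function(refc, pos, ins) {
  chars <- strsplit(ins, "", fixed = TRUE)[[1]]
  k <- length(chars)
  while (pos > 0L && refc[pos] == chars[k]) {
    chars <- c(refc[pos], chars[-k])
    pos <- pos - 1L
  }
  list(pos = pos, ins = paste(chars, collapse = ""))
}

# Extract indel operations from one gapped alignment (pattern = read,
# subject = reference), as a data.frame of ops with 0-based ref coordinates.
.alignment_ops <- function(pat, sub, sub_start) {
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  sc <- strsplit(sub, "", fixed = TRUE)[[1]]
  n <- length(pc)
  ops <- list()
  rp <- sub_start - 1L  # 0-based ref position of the next reference base
  i <- 1L
  while (i <= n) {
    if (sc[i] == "-") {
      j <- i
      while (j <= n && sc[j] == "-") j <- j + 1L
      ops[[length(ops) + 1L]] <-
        list(type = "I", pos = rp, len = j - i,
             seq = paste(pc[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (pc[i] == "-") {
      j <- i
      while (j <= n && pc[j] == "-") j <- j + 1L
      ops[[length(ops) + 1L]] <- list(type = "D", pos = rp, len = j - i,
                                      seq = "")
      rp <- rp + (j - i)
      i <- j
    } else {
      rp <- rp + 1L
      i <- i + 1L
    }
  }
  ops
}

# Canonical edit key for a set of ops on refseq: left-normalize each op,
# keep those overlapping the window, format "D@pos:len" / "I@pos:SEQ"
# joined by "+"; "WT" when no windowed indel remains.
.ops_key <- function(ops, refc, window) {
  keys <- character(0)
  pos_order <- integer(0)
  for (op in ops) {
    if (op$type == "D") {
      pos <- .leftshift_del(refc, op$pos, op$len)
      if (pos < window[2] && pos + op$len > window[1]) {
        keys <- c(keys, paste0("D@", pos, ":", op$len))
        pos_order <- c(pos_order, pos)
      }
    } else {
      sh <- .leftshift_ins(refc, op$pos, op$seq)
      if (sh$pos >= window[1] && sh$pos <= window[2]) {
        keys <- c(keys, paste0("I@", sh$pos, ":", sh$ins))
        pos_order <- c(pos_order, sh$pos)
      }
    }
  }
  if (!length(keys)) "WT" else paste(keys[order(pos_order, keys)], collapse = "+")
}

#' Call alleles from amplicon reads
#'
#' Each read is aligned to the reference (whole read, free reference ends;
#' match +1, mismatch -1, affine gaps costing 8 to open a 1-bp gap and 1 per
#' additional base). Indel operations are left-normalized and reads are
#' grouped into alleles by their edit key; a read is an indel allele iff at
#' least one insertion or deletion overlaps the cut window. Substitutions
#' are not indels. Reads shorter than `min_read_frac` of the reference are
#' discarded and counted in `n_discarded`.
#'
#' @param reads Character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTQ/FASTA file.
#' @param ref An [amplicon_ref()].
#' @param min_read_frac Minimum read length as a fraction of the reference
#'   length (default 0.5).
#' @return Object of class `allele_table`: list with `locus_id`, `alleles`
#'   (data.frame `allele`, `count`, `is_indel`, `frequency`), `n_reads`
#'   (reads kept), `n_discarded`, `cut_window`.
#' @export
call_alleles <- function(reads, ref, min_read_frac = 0.5) {
  stopifnot(inherits(ref, "amplicon_ref"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  reads <- toupper(as.character(reads))
  if (!length(reads)) stop("no reads supplied")
  keep <- nchar(reads) >= min_read_frac * nchar(ref$sequence)
  n_disc <- sum(!keep)
  reads <- reads[keep]
  if (!length(reads)) stop("all reads discarded by the length filter")
  counts <- table(reads)
  useq <- names(counts)
  refc <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]

  keys <- character(length(useq))
  exact <- useq == ref$sequence
  keys[exact] <- "WT"
  todo <- which(!exact)
  if (length(todo)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(useq[todo]),
      Biostrings::DNAString(ref$sequence),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 7, gapExtension = 1)
    pats <- as.character(Biostrings::pattern(aln))
    subs <- as.character(Biostrings::subject(aln))
    sstart <- Biostrings::start(Biostrings::subject(aln))
    for (k in seq_along(todo)) {
      ops <- .alignment_ops(pats[k], subs[k], sstart[k])
      keys[todo[k]] <- .ops_key(ops, refc, ref$cut_window)
    }
  }
  agg <- tapply(as.integer(counts), keys, sum)
  alleles <- data.frame(allele = names(agg), count = as.integer(agg),
                        stringsAsFactors = FALSE)
  alleles$is_indel <- alleles$allele != "WT"
  n <- sum(alleles$count)
  alleles$frequency <- alleles$count / n
  alleles <- alleles[order(-alleles$count, alleles$allele), , drop = FALSE]
  rownames(alleles) <- NULL
  structure(list(locus_id = ref$locus_id, alleles = alleles, n_reads = n,
                 n_discarded = n_disc, cut_window = ref$cut_window),
            class = "allele_table")
}

#' Percent indel reads in an allele table
#' @param x An `allele_table`.
#' @return Numeric percentage in `[0, 100]`.
#' @export
pct_indels <- function(x) {
  stopifnot(inherits(x, "allele_table"))
  if (x$n_reads == 0L) return(NA_real_)
  100 * sum(x$alleles$count[x$alleles$is_indel]) / x$n_reads
}

#' @export
print.allele_table <- function(x, ...) {
  cat("allele_table '", x$locus_id, "': ", nrow(x$alleles), " alleles, ",
      x$n_reads, " reads (", x$n_discarded, " discarded), %indels ",
      format(pct_indels(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Background-correct a treated allele table against a control
#'
#' Indel alleles whose edit key also appears as an indel allele in the
#' control sample are reclassified as non-indel in the treated table (they
#' are shared artifacts, not nuclease edits). Totals are unchanged; the
#' operation never increases the indel fraction and is idempotent.
#'
#' @param treated,control `allele_table`s from the same locus.
#' @return The corrected treated `allele_table`.
#' @export
background_correct <- function(treated, control) {
  stopifnot(inherits(treated, "allele_table"), inherits(control, "allele_table"))
  if (!identical(treated$locus_id, control$locus_id)) {
    stop("allele tables come from different loci: '", treated$locus_id,
         "' vs '", control$locus_id, "'")
  }
  shared <- control$alleles$allele[control$alleles$is_indel]
  treated$alleles$is_indel[treated$alleles$allele %in% shared] <- FALSE
  treated
}

# Two-sided Fisher exact p for the 2x2 table rbind(c(a, b), c(c, d)).
.fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE))$p.value
}

#' Indel significance of treated vs control with Bonferroni correction
#'
#' Two-sided Fisher's exact test on the 2x2 table (indel / non-indel reads x
#' treated / control), Bonferroni-adjusted over `n_tests` loci:
#' `p_adjusted = min(1, p_raw * n_tests)`. A locus is significant iff
#' `p_adjusted < 0.05` and the treated indel fraction exceeds the control's.
#'
#' @param treated,control `allele_table`s.
#' @param n_tests Number of loci tested in the experiment (>= 1).
#' @return List with `p_raw`, `p_adjusted`, `significant`, `treated_frac`,
#'   `control_frac`, `n_tests`, and `note` (non-`NA` when either arm has
#'   zero reads, in which case the test is undefined and flagged).
#' @export
indel_significance <- function(treated, control, n_tests = 1L) {
  stopifnot(n_tests >= 1L)
  ti <- sum(treated$alleles$count[treated$alleles$is_indel])
  tn <- treated$n_reads - ti
  ci <- sum(control$alleles$count[control$alleles$is_indel])
  cn <- control$n_reads - ci
  if (treated$n_reads == 0L || control$n_reads == 0L) {
    return(list(p_raw = NA_real_, p_adjusted = NA_real_, significant = NA,
                treated_frac = NA_real_, control_frac = NA_real_,
                n_tests = as.integer(n_tests),
                note = "zero total reads in one arm; test undefined"))
  }
  p <- .fisher_p(ti, tn, ci, cn)
  p_adj <- min(1, p * n_tests)
  tf <- ti / treated$n_reads
  cf <- ci / control$n_reads
  list(p_raw = p, p_adjusted = p_adj,
       significant = p_adj < 0.05 && tf > cf,
       treated_frac = tf, control_frac = cf,
       n_tests = as.integer(n_tests), note = NA_character_)
}

#' Write an allele table as TSV
#' @param x An `allele_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_table <- function(x, path) {
  utils::write.table(x$alleles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
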