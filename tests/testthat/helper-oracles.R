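# Independent oracles used across the suite. These re-derive expectations
# from first principles (explicit IUPAC sets, pattern strings, choose()-based
# hypergeometric enumeration, flood-fill clustering) and deliberately avoid
# the package's bit-mask / merge-based code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

ORC_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

ORC_COMPAT <- local({
  codes <- names(ORC_IUPAC)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(ORC_IUPAC[[a]], ORC_IUPAC[[b]])) > 0
  }
  m
})

orc_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x),
                     "", fixed = TRUE)[[1]]), collapse = "")
}

# Pattern chars for an assembly: triplets 5'->3' with "N" inserted after
# triplet i when junction J(fc-i)-(fc-i+1) is skipped.
orc_pattern <- function(triplets, fc, junctions) {
  out <- character(0)
  for (i in seq_len(fc)) {
    out <- c(out, strsplit(triplets[i], "", fixed = TRUE)[[1]])
    if (i < fc && paste0("J", fc - i, "-", fc - i + 1) %in% junctions) {
      out <- c(out, "N")
    }
  }
  out
}

orc_match_offsets <- function(seqchars, pat) {
  L <- length(seqchars)
  pl <- length(pat)
  if (L < pl) return(integer(0))
  noff <- L - pl + 1L
  ok <- rep(TRUE, noff)
  for (j in seq_len(pl)) {
    ok <- ok & ORC_COMPAT[pat[j], seqchars[j:(j + noff - 1L)]]
  }
  which(ok) - 1L
}

# Brute-force site enumeration: every offset x strand x plan x module combo.
orc_find_sites <- function(seq, archive, fc, plans, composition = NULL) {
  mods <- archive$modules
  composition <- composition %||%
    (if (fc == 6) c(2L, 2L, 2L) else c(1L, 2L, 2L))
  ends <- cumsum(composition)
  starts <- c(1L, head(ends, -1L) + 1L)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") toupper(seq) else orc_revcomp(toupper(seq))
    schars <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(schars)
    for (plan in plans) {
      # eligibility per slot: intra-slot skipped junction needs a
      # skip-capable module
      slot_mods <- lapply(seq_along(composition), function(k) {
        t_idx <- starts[k]:ends[k]
        junc <- if (length(t_idx) > 1) {
          paste0("J", fc - head(t_idx, -1L), "-", fc - head(t_idx, -1L) + 1L)
        } else character(0)
        internal <- any(junc %in% plan$junctions)
        which(mods$n_fingers == composition[k] &
                (!internal | mods$skip_capable_internal))
      })
      if (any(lengths(slot_mods) == 0)) next
      combos <- expand.grid(slot_mods, KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(combos))) {
        idx <- as.integer(combos[r, ])
        trips <- unlist(lapply(idx, function(i) {
          strsplit(mods$triplets[i], ",", fixed = TRUE)[[1]]
        }))
        pat <- orc_pattern(trips, fc, plan$junctions)
        for (off in orc_match_offsets(schars, pat)) {
          st <- if (strand == "+") off else L - (off + length(pat))
          rows[[length(rows) + 1L]] <- data.frame(
            start = st, end = st + length(pat), strand = strand,
            finger_count = fc,
            skip_plan = if (length(plan$junctions)) {
              paste(sort(plan$junctions), collapse = "+")
            } else "none",
            modules = paste(mods$id[idx], collapse = ","),
            triplets = paste(mods$triplets[idx], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), finger_count = integer(0),
                      skip_plan = character(0), modules = character(0),
                      triplets = character(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$strand, out$skip_plan, out$modules), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force dimer pairing over all ordered site pairs.
orc_pair <- function(sites, configs) {
  strands <- list(CC = c("-", "+"), NC = c("+", "+"),
                  CN = c("-", "-"), NN = c("+", "-"))
  ids <- character(0)
  for (cfg in configs) {
    st <- strands[[cfg$arch]]
    lab <- function(p) if (length(p$junctions)) {
      paste(sort(p$junctions), collapse = "+")
    } else "none"
    for (i in seq_len(nrow(sites))) {
      for (j in seq_len(nrow(sites))) {
        if (sites$strand[i] == st[1] && sites$strand[j] == st[2] &&
            sites$finger_count[i] == cfg$left_skip$finger_count &&
            sites$finger_count[j] == cfg$right_skip$finger_count &&
            sites$skip_plan[i] == lab(cfg$left_skip) &&
            sites$skip_plan[j] == lab(cfg$right_skip) &&
            sites$start[j] == sites$end[i] + cfg$gap_bp) {
          ids <- c(ids, paste(cfg$arch, cfg$gap_bp,
                              sites$start[i], sites$strand[i],
                              sites$skip_plan[i], sites$modules[i],
                              sites$start[j], sites$strand[j],
                              sites$skip_plan[j], sites$modules[j],
                              sep = "|"))
        }
      }
    }
  }
  sort(unique(ids))
}

# Two-sided Fisher exact p by direct hypergeometric enumeration with
# choose(); sums the probabilities of all tables (fixed margins) no more
# probable than the observed one.
orc_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0L, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p0 <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# Clustering oracle: connected components of the "within window_bp" graph,
# grown by flood fill (order-free).
orc_cluster_components <- function(positions, window_bp) {
  n <- length(positions)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(positions[i] - positions[j]) <= window_bp &&
            comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Random archive generator for oracle-equivalence tests: triplets biased
# toward partial degeneracy so matches occur at useful rates.
random_archive <- function(seed, n1 = 2L, n2 = 4L, skip_capable = FALSE) {
  set.seed(seed)
  rand_triplet <- function() {
    paste(sample(c("A", "C", "G", "T", "N", "R", "Y", "S", "W"), 3,
                 replace = TRUE, prob = c(rep(1, 4), 1.5, rep(0.6, 4))),
          collapse = "")
  }
  mods <- list()
  for (i in seq_len(n1)) {
    mods[[length(mods) + 1L]] <- finger_module(sprintf("o1_%02d", i),
                                               rand_triplet())
  }
  for (i in seq_len(n2)) {
    mods[[length(mods) + 1L]] <- finger_module(
      sprintf("o2_%02d", i), c(rand_triplet(), rand_triplet()),
      skip_capable_internal = skip_capable && (i %% 2 == 0))
  }
  module_archive(do.call(rbind, mods), name = paste0("rand", seed))
}

design_ids <- function(designs) sort(designs$id)
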