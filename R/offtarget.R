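# Candidate off-target calling from mapped duplex-capture integration
# events. The pipeline consumes mapped events (BED-like tables), not raw
# reads: per replicate, unique integrations are clustered by single linkage
# within 100 bp, clusters pass a filter cascade (>= fivefold over the same
# locus in control, all reads mapping equally well to fewer than three loci,
# chromosome on the known-region whitelist, >= 10 kb from the intended
# target), and loci must recur in at least two replicates.

#' Construct an integration-event table
#'
#' @param chrom,position,strand Event coordinates (0-based positions).
#' @param n_best_hits Count of equally-best alignments for the supporting
#'   read (>= 1).
#' @param replicate Replicate identifier.
#' @param arm `"treated"` or `"control"`.
#' @return data.frame with the five event columns plus `arm`.
#' @export
integration_events <- function(chrom, position, strand = "+",
                               n_best_hits = 1L, replicate = "r1",
                               arm = "treated") {
  df <- data.frame(chrom = as.character(chrom),
                   position = as.integer(position),
                   strand = as.character(strand),
                   n_best_hits = as.integer(n_best_hits),
                   replicate = as.character(replicate),
                   arm = as.character(arm),
                   stringsAsFactors = FALSE)
  if (any(df$n_best_hits < 1L)) stop("n_best_hits must be >= 1")
  df
}

#' Parse a region string "chrom:start-end" (0-based half-open)
#' @param x Region string, or a list/vector `(chrom, start, end)`.
#' @return List with `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) {
    return(list(chrom = as.character(x$chrom), start = as.integer(x$start),
                end = as.integer(x$end)))
  }
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)$", x))[[1]]
    if (length(m) == 4L) {
      return(list(chrom = m[2], start = as.integer(m[3]),
                  end = as.integer(m[4])))
    }
  }
  if (length(x) == 3L) {
    return(list(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                end = as.integer(x[[3]])))
  }
  stop("cannot parse region: supply 'chrom:start-end' or (chrom, start, end)")
}

#' Remove duplicate integration events
#'
#' One event is kept per (chrom, position, strand, replicate, arm); the same
#' position on opposite strands counts as two distinct integrations.
#'
#' @param events Event data.frame (see [integration_events()]).
#' @return Deduplicated events, sorted by (arm, replicate, chrom, position,
#'   strand).
#' @export
dedupe_events <- function(events) {
  key <- events[, c("chrom", "position", "strand", "replicate", "arm")]
  events <- events[!duplicated(key), , drop = FALSE]
  events <- events[order(events$arm, events$replicate, events$chrom,
                         events$position, events$strand), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Cluster integration events by single linkage along each chromosome
#'
#' Consecutive sorted events at most `window_bp` apart join the same cluster
#' (so chains like 0, 90, 180 form one cluster under a 100-bp window). The
#' result is a partition of the events and is invariant under input order.
#'
#' @param events Deduplicated events from a single arm (and typically a
#'   single replicate).
#' @param window_bp Linkage distance in bp (default 100).
#' @return data.frame of clusters: `cluster_id`, `chrom`, `start`, `end`
#'   (half-open, covering member positions), `n_events`, `max_best_hits`,
#'   `replicate` (`NA` if members span several replicates).
#' @export
cluster_events <- function(events, window_bp = 100L) {
  if (length(unique(events$arm)) > 1L) {
    stop("cluster_events expects events from a single arm")
  }
  events <- dedupe_events(events)
  out <- list()
  for (chrom in sort(unique(events$chrom))) {
    ev <- events[events$chrom == chrom, , drop = FALSE]
    ev <- ev[order(ev$position, ev$strand), , drop = FALSE]
    new_cluster <- c(TRUE, diff(ev$position) > window_bp)
    cid <- cumsum(new_cluster)
    for (k in unique(cid)) {
      m <- ev[cid == k, , drop = FALSE]
      reps <- unique(m$replicate)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = min(m$position), end = max(m$position) + 1L,
        n_events = nrow(m), max_best_hits = max(m$n_best_hits),
        replicate = if (length(reps) == 1L) reps else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_events = integer(0), max_best_hits = integer(0),
               replicate = character(0), stringsAsFactors = FALSE)
  }
  clusters <- clusters[order(clusters$chrom, clusters$start), , drop = FALSE]
  clusters$cluster_id <- seq_len(nrow(clusters))
  rownames(clusters) <- NULL
  clusters
}

#' Apply the off-target filter cascade to treated clusters
#'
#' Flags each cluster with:
#' * `fold_pass`: unique treated integrations >= `fold` times the control
#'   count at the same locus (control events within the cluster interval
#'   padded by `window_bp`); a control count of 0 passes.
#' * `multimap_pass`: every member read maps equally well to fewer than
#'   `max_best_hits` loci.
#' * `known_pass`: chromosome is on the `known_chroms` whitelist (`NULL`
#'   disables the filter).
#' * `distance_pass`: cluster lies at least `min_distance` bp from the
#'   intended target.
#'
#' A cluster is a candidate iff all four pass (`passed_all`). The cluster
#' overlapping the intended target is flagged `is_on_target` (it fails the
#' distance filter by construction but is carried for reporting).
#'
#' @param clusters data.frame from [cluster_events()] (treated arm).
#' @param control_events Control-arm events (deduplicated internally).
#' @param on_target Intended target, `"chrom:start-end"` or
#'   `(chrom, start, end)`.
#' @param fold Fold-enrichment threshold over control (default 5; the
#'   comparison is `>=`).
#' @param max_best_hits Reads must map to fewer than this many loci
#'   (default 3).
#' @param min_distance Minimum distance from the intended target in bp
#'   (default 10000).
#' @param window_bp Padding used to match control events to a cluster
#'   (default 100).
#' @param known_chroms Chromosome whitelist, or `NULL` for no filter.
#' @return `clusters` with `control_count`, `distance_bp`, the four flag
#'   columns, `is_on_target`, and `passed_all`.
#' @export
apply_filters <- function(clusters, control_events, on_target,
                          fold = 5L, max_best_hits = 3L,
                          min_distance = 10000L, window_bp = 100L,
                          known_chroms = NULL) {
  ot <- parse_region(on_target)
  ctrl <- if (NROW(control_events)) dedupe_events(control_events) else NULL
  n <- nrow(clusters)
  control_count <- integer(n)
  distance_bp <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.null(ctrl)) {
      control_count[i] <- sum(
        ctrl$chrom == clusters$chrom[i] &
          ctrl$position >= clusters$start[i] - window_bp &
          ctrl$position < clusters$end[i] + window_bp)
    }
    distance_bp[i] <- if (clusters$chrom[i] != ot$chrom) Inf else {
      max(0L, max(ot$start - clusters$end[i], clusters$start[i] - ot$end))
    }
  }
  clusters$control_count <- control_count
  clusters$distance_bp <- distance_bp
  clusters$fold_pass <- control_count == 0L |
    clusters$n_events >= fold * control_count
  clusters$multimap_pass <- clusters$max_best_hits < max_best_hits
  clusters$known_pass <- if (is.null(known_chroms)) rep(TRUE, n) else
    clusters$chrom %in% known_chroms
  clusters$distance_pass <- distance_bp >= min_distance
  clusters$is_on_target <- clusters$chrom == ot$chrom &
    clusters$start < ot$end & clusters$end > ot$start
  clusters$passed_all <- clusters$fold_pass & clusters$multimap_pass &
    clusters$known_pass & clusters$distance_pass
  clusters
}

#' Merge per-replicate candidates and require replicate consensus
#'
#' Per-replicate clusters are merged into loci by interval overlap (>= 1 bp,
#' same chromosome); a locus is retained iff supported by at least
#' `min_replicates` replicates. Capture events are summed over replicates.
#' Loci are ranked by descending capture events with the on-target locus
#' first when present; ties break by coordinate.
#'
#' @param candidates data.frame of per-replicate clusters (columns `chrom`,
#'   `start`, `end`, `n_events`, `replicate`, optionally `is_on_target`).
#' @param min_replicates Minimum supporting replicates (default 2).
#' @return data.frame of candidate loci: `rank`, `chrom`, `start`, `end`,
#'   `capture_events`, `n_replicates`, `is_on_target`.
#' @export
replicate_consensus <- function(candidates, min_replicates = 2L) {
  empty <- data.frame(rank = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      capture_events = integer(0), n_replicates = integer(0),
                      is_on_target = logical(0), stringsAsFactors = FALSE)
  if (!NROW(candidates)) return(empty)
  if (is.null(candidates$is_on_target)) candidates$is_on_target <- FALSE
  out <- list()
  for (chrom in sort(unique(candidates$chrom))) {
    cc <- candidates[candidates$chrom == chrom, , drop = FALSE]
    cc <- cc[order(cc$start, cc$end), , drop = FALSE]
    gid <- integer(nrow(cc))
    gid[1] <- 1L
    cur_end <- cc$end[1]
    for (i in seq_len(nrow(cc))[-1]) {
      if (cc$start[i] < cur_end) {       # >= 1 bp overlap
        gid[i] <- gid[i - 1L]
        cur_end <- max(cur_end, cc$end[i])
      } else {
        gid[i] <- gid[i - 1L] + 1L
        cur_end <- cc$end[i]
      }
    }
    for (g in unique(gid)) {
      m <- cc[gid == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = min(m$start), end = max(m$end),
        capture_events = sum(m$n_events),
        n_replicates = length(unique(m$replicate)),
        is_on_target = any(m$is_on_target),
        stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[loci$n_replicates >= min_replicates, , drop = FALSE]
  if (!nrow(loci)) return(empty)
  loci <- loci[order(!loci$is_on_target, -loci$capture_events, loci$chrom,
                     loci$start), , drop = FALSE]
  loci$rank <- seq_len(nrow(loci))
  rownames(loci) <- NULL
  loci[, c("rank", "chrom", "start", "end", "capture_events",
           "n_replicates", "is_on_target")]
}

#' Full off-target candidate pipeline
#'
#' Dedupe both arms, cluster the treated arm per replicate, apply the filter
#' cascade against the matching replicate's control events (all control
#' events when the replicate is absent from the control arm), and take the
#' replicate consensus. The on-target cluster is carried through for
#' reporting (rank 1 when captured); off-target candidates are the rows with
#' `is_on_target == FALSE`.
#'
#' @param treated_events,control_events Event data.frames.
#' @param on_target Intended target region.
#' @inheritParams apply_filters
#' @param min_replicates Minimum supporting replicates (default 2).
#' @return Candidate-locus data.frame as from [replicate_consensus()].
#' @export
call_offtarget_candidates <- function(treated_events, control_events,
                                      on_target, window_bp = 100L,
                                      fold = 5L, max_best_hits = 3L,
                                      min_distance = 10000L,
                                      min_replicates = 2L,
                                      known_chroms = NULL) {
  treated <- dedupe_events(treated_events)
  ctrl <- if (NROW(control_events)) dedupe_events(control_events) else
    control_events
  per_rep <- list()
  for (r in unique(treated$replicate)) {
    cl <- cluster_events(treated[treated$replicate == r, , drop = FALSE],
                         window_bp = window_bp)
    if (!nrow(cl)) next
    cmatch <- if (NROW(ctrl) && r %in% ctrl$replicate) {
      ctrl[ctrl$replicate == r, , drop = FALSE]
    } else ctrl
    fl <- apply_filters(cl, cmatch, on_target, fold = fold,
                        max_best_hits = max_best_hits,
                        min_distance = min_distance, window_bp = window_bp,
                        known_chroms = known_chroms)
    per_rep[[length(per_rep) + 1L]] <-
      fl[fl$passed_all | fl$is_on_target, , drop = FALSE]
  }
  cand <- if (length(per_rep)) do.call(rbind, per_rep) else NULL
  replicate_consensus(cand, min_replicates = min_replicates)
}

#' Read integration events from a BED6-like TSV
#'
#' Columns: chrom, start, end, name (replicate), score (n_best_hits),
#' strand. Positions are taken from `start` (0-based).
#'
#' @param path File path.
#' @param arm Arm label to attach (`"treated"` or `"control"`).
#' @return Event data.frame.
#' @export
read_events_bed <- function(path, arm = "treated") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "name", "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "integer", "character"))
  integration_events(df$chrom, df$start, df$strand, df$score, df$name, arm)
}

#' Write integration events as a BED6-like TSV
#' @param events Event data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  lines <- paste(events$chrom, events$position, events$position + 1L,
                 events$replicate, events$n_best_hits, events$strand,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
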