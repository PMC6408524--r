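# Genome scanning: find every ZFP binding site assemblable from archive
# modules, pair sites into dimer designs under the architecture grammar, and
# score per-base-step targeting density. All coordinates 0-based half-open.

#' Default module composition for an assembly, in 5'->3' site order
#'
#' Six-finger ZFPs comprise three two-finger modules; five-finger ZFPs two
#' two-finger modules and one one-finger module placed carboxy-terminal in
#' the protein, i.e. 5'-most on the target site.
#'
#' @param finger_count 5 or 6.
#' @return Integer vector of module sizes (fingers), 5'->3' along the site.
#' @export
default_composition <- function(finger_count) {
  switch(as.character(finger_count),
         "6" = c(2L, 2L, 2L),
         "5" = c(1L, 2L, 2L),
         stop("finger_count must be 5 or 6, got ", finger_count))
}

# Geometry of a (finger_count, skip_plan, composition) assembly along its
# site. Triplet i (5'->3', 1-based) belongs to finger (finger_count - i + 1);
# the junction after triplet i is J(fc-i)-(fc-i+1). Returns the site length,
# per-slot base positions (0-based offsets of each module's triplet bases
# within the site), whether each slot must absorb an intra-module skip, and
# the offsets of skipped (unconstrained) bases.
site_frame <- function(finger_count, plan, composition = NULL) {
  fc <- as.integer(finger_count)
  composition <- composition %||% default_composition(fc)
  if (sum(composition) != fc) {
    stop("composition ", paste(composition, collapse = "+"),
         " does not sum to finger_count ", fc)
  }
  junction_after <- function(i) paste0("J", fc - i, "-", fc - i + 1L)
  triplet_start <- integer(fc)
  skip_positions <- integer(0)
  skipped_after <- logical(fc)  # skip between triplet i and i+1?
  p <- 0L
  for (i in seq_len(fc)) {
    triplet_start[i] <- p
    p <- p + 3L
    if (i < fc && junction_after(i) %in% plan$junctions) {
      skipped_after[i] <- TRUE
      skip_positions <- c(skip_positions, p)
      p <- p + 1L
    }
  }
  ends <- cumsum(composition)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  slots <- lapply(seq_along(composition), function(s) {
    t_idx <- starts[s]:ends[s]
    list(
      n_fingers = composition[s],
      positions = unlist(lapply(t_idx, function(i) triplet_start[i] + 0:2)),
      internal_skip = any(skipped_after[utils::head(t_idx, -1L)])
    )
  })
  list(site_len = p, slots = slots, skip_positions = skip_positions)
}

.empty_sites <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             finger_count = integer(0), skip_plan = character(0),
             modules = character(0), triplets = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for assemblable ZFP binding sites
#'
#' Finds every (position, strand, skip plan, module triple) combination whose
#' concatenated triplets -- with one unconstrained base at each skipped
#' junction -- match the sequence. Degenerate IUPAC codes in archive triplets
#' (and in the sequence) match by intersection. A skip falling inside a
#' two-finger module is taken only by modules with
#' `skip_capable_internal = TRUE`.
#'
#' @param seq DNA string over the IUPAC alphabet.
#' @param archive A `module_archive`.
#' @param finger_count 5 or 6 fingers per ZFP.
#' @param skip_plans List of `skip_plan`s to consider (default: all four).
#' @param composition Module sizes in 5'->3' site order (default
#'   [default_composition()]).
#' @return data.frame of binding sites with columns `start`, `end` (0-based
#'   half-open), `strand`, `finger_count`, `skip_plan` (label), `modules`
#'   (comma-joined ids, 5'->3'), `triplets` (comma-joined matched triplets);
#'   ordered by (start, strand, plan, modules).
#' @examples
#' gnn <- build_gnn_archive()
#' find_zfp_sites(strrep("G", 18), gnn, 6, list(skip_plan(6)))
#' @export
find_zfp_sites <- function(seq, archive, finger_count,
                           skip_plans = NULL, composition = NULL) {
  stopifnot(inherits(archive, "module_archive"))
  fc <- as.integer(finger_count)
  if (!fc %in% c(5L, 6L)) stop("finger_count must be 5 or 6, got ", fc)
  if (inherits(skip_plans, "skip_plan")) skip_plans <- list(skip_plans)
  skip_plans <- skip_plans %||% enumerate_skip_plans(fc)
  mods <- archive$modules
  if (!nrow(mods)) stop("archive is empty; nothing to scan with")
  L <- nchar(seq)
  out <- list()
  if (L > 0L) {
    fwd <- dna_mask(seq)
    rcm <- rev(mask_complement(fwd))
    mod_masks <- lapply(mods$triplets,
                        function(t) dna_mask(gsub(",", "", t, fixed = TRUE)))
    for (strand in c("+", "-")) {
      mvec <- if (strand == "+") fwd else rcm
      for (plan in skip_plans) {
        fr <- site_frame(fc, plan, composition)
        noff <- L - fr$site_len + 1L
        if (noff < 1L) next
        slot_hits <- vector("list", length(fr$slots))
        ok_all <- rep(TRUE, noff)
        for (s in seq_along(fr$slots)) {
          sl <- fr$slots[[s]]
          elig <- which(mods$n_fingers == sl$n_fingers &
                          (!sl$internal_skip | mods$skip_capable_internal))
          if (!length(elig)) { ok_all <- rep(FALSE, noff); break }
          hit <- matrix(TRUE, nrow = noff, ncol = length(elig))
          for (e in seq_along(elig)) {
            mm <- mod_masks[[elig[e]]]
            h <- rep(TRUE, noff)
            for (j in seq_along(sl$positions)) {
              h <- h & bitwAnd(mvec[sl$positions[j] + seq_len(noff)], mm[j]) != 0L
            }
            hit[, e] <- h
          }
          slot_hits[[s]] <- list(elig = elig, hit = hit)
          ok_all <- ok_all & rowSums(hit) > 0L
        }
        for (off in which(ok_all)) {
          choices <- lapply(slot_hits, function(sh) sh$elig[sh$hit[off, ]])
          combos <- expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)
          combos <- combos[, rev(seq_along(choices)), drop = FALSE]
          o0 <- off - 1L
          if (strand == "+") {
            st <- o0; en <- o0 + fr$site_len
          } else {
            st <- L - (o0 + fr$site_len); en <- L - o0
          }
          ids <- apply(combos, 1L, function(r) paste(mods$id[r], collapse = ","))
          trs <- apply(combos, 1L, function(r) paste(mods$triplets[r], collapse = ","))
          out[[length(out) + 1L]] <- data.frame(
            start = st, end = en, strand = strand, finger_count = fc,
            skip_plan = skip_plan_label(plan), modules = ids, triplets = trs,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else .empty_sites()
  sites <- sites[order(sites$start, sites$strand, sites$skip_plan,
                       sites$modules), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

.empty_designs <- function() {
  data.frame(base_step = integer(0), arch = character(0), gap_bp = integer(0),
             left_start = integer(0), left_end = integer(0),
             left_strand = character(0), left_plan = character(0),
             left_modules = character(0),
             right_start = integer(0), right_end = integer(0),
             right_strand = character(0), right_plan = character(0),
             right_modules = character(0), id = character(0),
             stringsAsFactors = FALSE)
}

#' Pair binding sites into ZFN dimer designs
#'
#' All ordered site pairs whose intervals, strands, finger counts and skip
#' plans realize one of the given configurations become designs. The
#' cleavage base step of a gap `[b, c)` is `floor((b + c)/2)`. Designs
#' identical in layout and module choices are reported once; the same layout
#' with different modules is a distinct design (a distinct protein pair).
#'
#' @param sites data.frame from [find_zfp_sites()] (same reference).
#' @param configs A `dimer_config` or list of them.
#' @param region Optional `c(start, end)`; keep only designs whose cleavage
#'   base step lies in `[start, end - 1]`.
#' @return data.frame of designs, ordered by (base step, architecture, left
#'   start, id).
#' @export
pair_dimers <- function(sites, configs, region = NULL) {
  if (inherits(configs, "dimer_config")) configs <- list(configs)
  out <- list()
  for (cfg in configs) {
    st <- arch_strands(cfg$arch)
    lsel <- sites[sites$strand == st[1] &
                    sites$finger_count == cfg$left_skip$finger_count &
                    sites$skip_plan == skip_plan_label(cfg$left_skip), ,
                  drop = FALSE]
    rsel <- sites[sites$strand == st[2] &
                    sites$finger_count == cfg$right_skip$finger_count &
                    sites$skip_plan == skip_plan_label(cfg$right_skip), ,
                  drop = FALSE]
    if (!nrow(lsel) || !nrow(rsel)) next
    for (i in seq_len(nrow(lsel))) {
      js <- which(rsel$start == lsel$end[i] + cfg$gap_bp)
      for (j in js) {
        out[[length(out) + 1L]] <- data.frame(
          base_step = (lsel$end[i] + rsel$start[j]) %/% 2L,
          arch = cfg$arch, gap_bp = cfg$gap_bp,
          left_start = lsel$start[i], left_end = lsel$end[i],
          left_strand = lsel$strand[i], left_plan = lsel$skip_plan[i],
          left_modules = lsel$modules[i],
          right_start = rsel$start[j], right_end = rsel$end[j],
          right_strand = rsel$strand[j], right_plan = rsel$skip_plan[j],
          right_modules = rsel$modules[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  designs <- if (length(out)) do.call(rbind, out) else .empty_designs()
  if (nrow(designs)) {
    designs$id <- paste(designs$arch, designs$gap_bp,
                        designs$left_start, designs$left_strand,
                        designs$left_plan, designs$left_modules,
                        designs$right_start, designs$right_strand,
                        designs$right_plan, designs$right_modules, sep = "|")
    designs <- designs[!duplicated(designs$id), , drop = FALSE]
  } else {
    designs$id <- character(0)
  }
  if (!is.null(region) && nrow(designs)) {
    designs <- designs[designs$base_step >= region[1] &
                         designs$base_step <= region[2] - 1L, , drop = FALSE]
  }
  designs <- designs[order(designs$base_step, designs$arch,
                           designs$left_start, designs$id), , drop = FALSE]
  rownames(designs) <- NULL
  designs
}

#' Per-base-step targeting density of a design set over a region
#'
#' A region `[start, end)` of length L is scored at L base steps (one per
#' base position, matching the 28-position accounting of a 28-bp window).
#' Density is the fraction of base steps covered by at least one design's
#' cleavage center.
#'
#' @param designs data.frame from [pair_dimers()] (only `base_step` is used).
#' @param region `c(start, end)`, 0-based half-open, length >= 2.
#' @return Object of class `density_profile`: list with `region`, `steps`
#'   (data.frame `base_step`, `n_designs`), and `density` in `[0, 1]`.
#' @export
targeting_density <- function(designs, region) {
  region <- as.integer(region)
  if (length(region) != 2L || region[2] - region[1] < 2L) {
    stop("region must be c(start, end) with length >= 2")
  }
  steps <- region[1]:(region[2] - 1L)
  counts <- vapply(steps, function(s) sum(designs$base_step == s), integer(1))
  structure(list(
    region = region,
    steps = data.frame(base_step = steps, n_designs = counts),
    density = mean(counts > 0L)
  ), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density_profile over [", x$region[1], ",", x$region[2], "): ",
      sum(x$steps$n_designs > 0), "/", nrow(x$steps),
      " base steps covered, density ", format(x$density, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Count distinct ZFN dimer designs on a sequence
#'
#' Scans for all binding sites needed by the configurations, pairs them, and
#' counts designs deduplicated by (layout, module choices). Enlarging the
#' archive, the architecture set, or the skip options never decreases the
#' count.
#'
#' @inheritParams find_zfp_sites
#' @param configs List of `dimer_config`s (e.g. from
#'   [enumerate_configurations()]).
#' @return Integer design count.
#' @export
count_designs <- function(seq, archive, configs, composition = NULL) {
  nrow(scan_designs(seq, archive, configs, composition)$designs)
}

#' Scan a sequence and pair designs in one step
#'
#' @inheritParams count_designs
#' @param region Optional region filter passed to [pair_dimers()].
#' @return List with `sites` and `designs` data.frames.
#' @export
scan_designs <- function(seq, archive, configs, composition = NULL,
                         region = NULL) {
  if (inherits(configs, "dimer_config")) configs <- list(configs)
  need <- unique(do.call(rbind, lapply(configs, function(cfg) {
    data.frame(fc = c(cfg$left_skip$finger_count, cfg$right_skip$finger_count),
               plan = c(skip_plan_label(cfg$left_skip),
                        skip_plan_label(cfg$right_skip)))
  })))
  sites <- do.call(rbind, lapply(unique(need$fc), function(fc) {
    plans <- lapply(unique(need$plan[need$fc == fc]), parse_skip_plan,
                    finger_count = fc)
    find_zfp_sites(seq, archive, fc, plans, composition)
  }))
  sites <- sites[!duplicated(sites), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, designs = pair_dimers(sites, configs, region))
}

#' Write binding sites as BED6
#'
#' @param sites data.frame from [find_zfp_sites()].
#' @param path Output path.
#' @param chrom Chromosome/record name for column 1.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path, chrom = "seq") {
  lines <- if (nrow(sites)) {
    name <- paste0(sites$finger_count, "F[", sites$skip_plan, "]:",
                   sites$modules)
    paste(chrom, sites$start, sites$end, name, 0L, sites$strand, sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a design table as TSV
#' @param designs data.frame from [pair_dimers()].
#' @param path Output path.
#' @param chrom Record name prepended as first column.
#' @return `path`, invisibly.
#' @export
write_designs_tsv <- function(designs, path, chrom = "seq") {
  df <- cbind(chrom = rep(chrom, nrow(designs)), designs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a density profile as JSON
#' @param profile A `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_json <- function(profile, path) {
  obj <- list(region = profile$region, density = profile$density,
              steps = profile$steps)
  writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA), path)
  invisible(path)
}
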