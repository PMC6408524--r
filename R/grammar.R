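# The dimer architecture grammar. A ZFN dimer is two zinc-finger proteins,
# each fused to the FokI cleavage domain at either its carboxy (C) or amino
# (N) terminus, bound on half-sites flanking a spacer gap where FokI
# dimerizes and cuts. The attachment point dictates which strand each ZFP
# must bind:
#
#   CC (canonical): half-sites on opposite strands converging on the gap
#                   (left site bottom strand, right site top strand).
#   NC / CN:        one amino-terminal fusion; both half-sites on the same
#                   strand (top for NC, bottom for CN). Structurally the same
#                   protein pair, counted as distinct configurations at a
#                   fixed locus because the sequence requirements differ.
#   NN:             both amino-terminal; the strand-inverse of canonical.
#
# Base-skipping linkers additionally allow exactly one unread base between
# the triplets of otherwise-adjacent fingers at specific junctions, shifting
# the recognition frame without moving the cleavage center.

ZFN_ARCHS <- c("CC", "NC", "CN", "NN")

#' Dimer architectures
#'
#' @return The four architecture codes: `"CC"` (canonical), `"NC"`, `"CN"`,
#'   `"NN"`.
#' @export
zfn_architectures <- function() ZFN_ARCHS

#' Strand assignment of the two half-sites for an architecture
#'
#' @param arch One of `"CC"`, `"NC"`, `"CN"`, `"NN"`.
#' @return Length-2 character vector: strands of the left and right site.
#' @export
arch_strands <- function(arch) {
  switch(match.arg(arch, ZFN_ARCHS),
         CC = c("-", "+"), NC = c("+", "+"),
         CN = c("-", "-"), NN = c("+", "-"))
}

#' Default allowed gap (spacer) sets per architecture, in bp
#'
#' NC/CN use 6-7 bp (6 bp is the minimal spacing allowing FokI dimerization
#' with the amino-terminal linkers); NN defaults to the 7-9 bp range where
#' activity is high, widenable to 5-9; canonical CC uses the conventional
#' 5-6 bp spacing of the standard carboxy-terminal linker.
#'
#' @return Named list of integer vectors keyed by architecture.
#' @export
default_gap_sets <- function() {
  list(CC = c(5L, 6L), NC = c(6L, 7L), CN = c(6L, 7L), NN = c(7L, 8L, 9L))
}

#' Allowed skip junctions for a finger count
#'
#' Junction `Jk-(k+1)` lies between fingers k and k+1, with finger 1 the
#' amino-terminal finger (binding the 3'-most triplet) and finger n the
#' carboxy-terminal one (binding the 5'-most). Six-finger arrays admit skips
#' at J2-3 and J4-5 (the two inter-module boundaries of a 2+2+2 assembly);
#' five-finger arrays at J2-3 and J3-4.
#'
#' @param finger_count 5 or 6.
#' @return Character vector of junction labels.
#' @export
skip_junctions <- function(finger_count) {
  switch(as.character(finger_count),
         "6" = c("J2-3", "J4-5"),
         "5" = c("J2-3", "J3-4"),
         stop("finger_count must be 5 or 6, got ", finger_count))
}

#' Construct a skip plan
#'
#' @param finger_count 5 or 6.
#' @param junctions Subset of [skip_junctions()] for that finger count at
#'   which a 1-bp skip is inserted (the skipped base is unconstrained).
#' @return Object of class `skip_plan`.
#' @export
skip_plan <- function(finger_count, junctions = character(0)) {
  allowed <- skip_junctions(finger_count)
  junctions <- as.character(junctions)
  bad <- setdiff(junctions, allowed)
  if (length(bad)) {
    stop("junction(s) ", paste(bad, collapse = ", "),
         " not allowed for a ", finger_count, "-finger array (allowed: ",
         paste(allowed, collapse = ", "), ")")
  }
  structure(list(finger_count = as.integer(finger_count),
                 junctions = sort(unique(junctions))),
            class = "skip_plan")
}

#' Enumerate all skip plans for a finger count
#'
#' All subsets of the allowed junction set, in deterministic order: the
#' no-skip plan first, then lexicographically.
#'
#' @param finger_count 5 or 6.
#' @return List of `skip_plan` objects (always 4: 2^2 subsets).
#' @examples
#' length(enumerate_skip_plans(6))   # 4
#' @export
enumerate_skip_plans <- function(finger_count) {
  js <- sort(skip_junctions(finger_count))
  list(skip_plan(finger_count),
       skip_plan(finger_count, js[1]),
       skip_plan(finger_count, js[2]),
       skip_plan(finger_count, js))
}

#' Label for a skip plan ("none" or junctions joined with "+")
#' @param plan A `skip_plan`.
#' @return Character scalar.
#' @export
skip_plan_label <- function(plan) {
  if (!length(plan$junctions)) "none" else paste(plan$junctions, collapse = "+")
}

#' Parse a skip-plan label back into a `skip_plan`
#' @param label Label as produced by [skip_plan_label()].
#' @param finger_count 5 or 6.
#' @return A `skip_plan`.
#' @export
parse_skip_plan <- function(label, finger_count) {
  if (identical(label, "none") || !nzchar(label)) {
    skip_plan(finger_count)
  } else {
    skip_plan(finger_count, strsplit(label, "+", fixed = TRUE)[[1]])
  }
}

#' Recognition span of a skip plan in bp
#'
#' 3 bases per finger plus one skipped base per skipped junction.
#'
#' @param plan A `skip_plan`.
#' @return Integer span.
#' @export
skip_plan_span <- function(plan) 3L * plan$finger_count + length(plan$junctions)

#' @export
print.skip_plan <- function(x, ...) {
  cat("skip_plan: ", x$finger_count, " fingers, skips: ",
      skip_plan_label(x), " (span ", skip_plan_span(x), " bp)\n", sep = "")
  invisible(x)
}

#' Number of dimer configurations per cleavage site
#'
#' The configurational multiplicity is |architectures| x (skip plans per
#' ZFN)^2. Relative to the canonical no-skip baseline (multiplicity 1) this
#' gives the fold-increase in design options: 4 from the architectures alone,
#' 16 from skip options across the two ZFNs of a dimer, 64 combined.
#'
#' @param archs Subset of [zfn_architectures()].
#' @param finger_count 5 or 6 (both admit 4 skip plans).
#' @param skips_enabled Whether base-skipping linkers are available.
#' @return Integer count of distinct configurations.
#' @examples
#' configuration_multiplicity("CC", 6, FALSE)                       # 1
#' configuration_multiplicity(zfn_architectures(), 6, FALSE)        # 4
#' configuration_multiplicity(zfn_architectures(), 6, TRUE)         # 64
#' @export
configuration_multiplicity <- function(archs, finger_count = 6L,
                                       skips_enabled = FALSE) {
  archs <- unique(as.character(archs))
  if (!length(archs)) stop("archs must be non-empty")
  bad <- setdiff(archs, ZFN_ARCHS)
  if (length(bad)) stop("unknown architecture(s): ", paste(bad, collapse = ", "))
  m_skip <- if (isTRUE(skips_enabled)) {
    length(enumerate_skip_plans(finger_count))
  } else 1L
  length(archs) * m_skip^2L
}

#' Construct a dimer configuration
#'
#' @param arch Architecture code.
#' @param gap_bp Spacer length in bp; must lie in the architecture's allowed
#'   gap set.
#' @param left_skip,right_skip `skip_plan`s for the left and right ZFN
#'   (default: six-finger, no skips).
#' @param gap_sets Allowed gap sets (see [default_gap_sets()]).
#' @return Object of class `dimer_config`.
#' @export
dimer_configuration <- function(arch, gap_bp,
                                left_skip = skip_plan(6L),
                                right_skip = skip_plan(6L),
                                gap_sets = default_gap_sets()) {
  arch <- match.arg(arch, ZFN_ARCHS)
  gap_bp <- as.integer(gap_bp)
  if (!gap_bp %in% gap_sets[[arch]]) {
    stop("gap of ", gap_bp, " bp not in the allowed set for architecture ",
         arch, " (", paste(gap_sets[[arch]], collapse = ", "), ")")
  }
  structure(list(arch = arch, gap_bp = gap_bp,
                 left_skip = left_skip, right_skip = right_skip),
            class = "dimer_config")
}

#' @export
print.dimer_config <- function(x, ...) {
  cat("dimer_config: ", x$arch, ", gap ", x$gap_bp, " bp, left ",
      x$left_skip$finger_count, "F[", skip_plan_label(x$left_skip),
      "], right ", x$right_skip$finger_count, "F[",
      skip_plan_label(x$right_skip), "]\n", sep = "")
  invisible(x)
}

#' Enumerate dimer configurations
#'
#' Cartesian product of architectures, their allowed gaps, and skip plans for
#' each ZFN of the dimer.
#'
#' @param archs Architectures to include.
#' @param finger_count Fingers per ZFN (applied to both sides).
#' @param skips_enabled If `FALSE` only the no-skip plan is used.
#' @param gap_sets Allowed gap sets per architecture.
#' @return List of `dimer_config` objects, deterministic order
#'   (architecture, gap, left plan, right plan).
#' @export
enumerate_configurations <- function(archs = zfn_architectures(),
                                     finger_count = 6L,
                                     skips_enabled = FALSE,
                                     gap_sets = default_gap_sets()) {
  plans <- if (isTRUE(skips_enabled)) {
    enumerate_skip_plans(finger_count)
  } else {
    list(skip_plan(finger_count))
  }
  out <- list()
  for (arch in intersect(ZFN_ARCHS, archs)) {
    for (g in gap_sets[[arch]]) {
      for (lp in plans) {
        for (rp in plans) {
          out[[length(out) + 1L]] <-
            dimer_configuration(arch, g, lp, rp, gap_sets = gap_sets)
        }
      }
    }
  }
  out
}

#' Realize a configuration as binding-site geometry around a cleavage center
#'
#' Coordinates are 0-based half-open. The cleavage center of a gap `[b, c)`
#' is `(b + c)/2`; even gaps place it on an integer base step, odd gaps on a
#' half-integer which is assigned to base step `floor(center)`. Given the
#' base step and a configuration, the gap and both strand-assigned half-site
#' intervals are fixed:
#'
#' * CC: left site on the bottom strand, 5' end gap-proximal; right site on
#'   the top strand, 5' end gap-proximal.
#' * NC: both sites on the top strand (upstream 3' end gap-proximal,
#'   downstream 5' end gap-proximal); CN is its mirror on the bottom strand.
#' * NN: the strand swap of CC.
#'
#' @param cleavage_center Integer base step on which cleavage is centered.
#' @param config A `dimer_config`.
#' @return Object of class `dimer_layout`: list with `cleavage_center`,
#'   `left`, `gap`, `right` (each a list with `start`, `end`, and for sites
#'   `strand`), and `config`.
#' @examples
#' cfg <- dimer_configuration("CC", 6)
#' realize_layout(100, cfg)  # gap [97,103), left [79,97) "-", right [103,121) "+"
#' @export
realize_layout <- function(cleavage_center, config) {
  stopifnot(inherits(config, "dimer_config"))
  center <- as.integer(cleavage_center)
  g <- config$gap_bp
  gs <- center - g %/% 2L
  ge <- gs + g
  st <- arch_strands(config$arch)
  llen <- skip_plan_span(config$left_skip)
  rlen <- skip_plan_span(config$right_skip)
  structure(list(
    cleavage_center = center,
    left = list(start = gs - llen, end = gs, strand = st[1]),
    gap = list(start = gs, end = ge),
    right = list(start = ge, end = ge + rlen, strand = st[2]),
    config = config
  ), class = "dimer_layout")
}

#' @export
print.dimer_layout <- function(x, ...) {
  cat("dimer_layout @", x$cleavage_center, " [", x$config$arch, "]: left [",
      x$left$start, ",", x$left$end, ")", x$left$strand, " gap [",
      x$gap$start, ",", x$gap$end, ") right [", x$right$start, ",",
      x$right$end, ")", x$right$strand, "\n", sep = "")
  invisible(x)
}
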