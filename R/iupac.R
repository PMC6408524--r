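# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8). Two codes are
# compatible iff their masks intersect; matching degenerate archive triplets
# against (possibly degenerate) genome sequence reduces to bitwAnd() != 0.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# complement of a 4-bit mask: A<->T, C<->G, bit-reversal of the nibble
.comp_bits <- local({
  m <- 0:15
  ((m %/% 1L) %% 2L) * 8L + ((m %/% 2L) %% 2L) * 4L +
    ((m %/% 4L) %% 2L) * 2L + ((m %/% 8L) %% 2L) * 1L
})

#' Convert a DNA string to a vector of IUPAC bit masks
#'
#' @param x A single DNA string (IUPAC alphabet, case-insensitive).
#' @return Integer vector of 4-bit masks, one per base.
#' @keywords internal
dna_mask <- function(x) {
  if (!nzchar(x)) return(integer(0))
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- unname(IUPAC_BITS[chars])
  if (anyNA(m)) {
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(chars[is.na(m)]), collapse = ", "))
  }
  m
}

mask_complement <- function(mask) .comp_bits[mask + 1L]

#' Reverse complement of an IUPAC DNA string
#'
#' @param x A single DNA string over the IUPAC alphabet.
#' @return The reverse complement, degenerate codes complemented correctly
#'   (e.g. R -> Y, M -> K).
#' @examples
#' revcomp("GATTACA")
#' revcomp("GRN")
#' @export
revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  comp <- chartr("ACGTMRWSYKVHDBNacgtmrwsykvhdbn",
                 "TGCAKYWSRMBDHVNtgcakywsrmbdhvn", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Expand an IUPAC code to its concrete bases
#'
#' @param code A single IUPAC character.
#' @return Character vector of the A/C/G/T bases the code stands for.
#' @keywords internal
iupac_bases <- function(code) {
  m <- IUPAC_BITS[[toupper(code)]]
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
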