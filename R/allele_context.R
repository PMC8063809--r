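## Allele calling by exact context matching.
##
## Each variant is represented by a pair of short "context" sequences:
## the reference window around the site, and the same window with the
## edit applied.  A read is assigned to an allele by exact substring
## search of the two contexts.  Exactness is essential for indels inside
## homopolymer runs: a 6-G and a 7-G context differ only in run length,
## and any mismatch tolerance would collapse the distinction.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the distinguishing ref/alt sequence contexts around a variant
#'
#' Starting from `flank` bases on each side of the edited region, the
#' context is widened as needed until the two contexts are mutually
#' distinguishable (neither a substring of the other):
#'
#' * For an insertion or deletion of base `b` adjacent to a homopolymer
#'   run of `b`, flanks are measured from the run boundaries, so both
#'   contexts always contain the entire run plus at least one non-run
#'   anchor base on each side.  This is what keeps, e.g., a 6-G
#'   reference context distinguishable from a 7-G insertion context.
#' * If the window cannot supply a full flank on either side, the whole
#'   window becomes the context.
#' * If the two contexts are still not distinguishable, flanks grow
#'   symmetrically one base at a time; exhausting the window is an
#'   error.
#'
#' @param ref_window Reference sequence window containing the site
#'   (uppercase ACGT).
#' @param variant_offset 0-based offset of `variant$ref` within
#'   `ref_window`.
#' @param variant An [variant()] object.
#' @param flank Bases retained on each side of the edited region
#'   (default 4, which yields the conventional ~10-mer contexts for an
#'   SNV).
#' @return An object of class `"ap_context_pair"` with elements
#'   `variant`, `ref_context`, `alt_context`, `flank_left`,
#'   `flank_right`, `orientation`.
#' @examples
#' v <- variant("chr13", 51964900, "C", "T")
#' build_contexts("CCCGTGGACC", 8, v)
#' @export
build_contexts <- function(ref_window, variant_offset, variant, flank = 4L) {
  stopifnot(inherits(variant, "ap_variant"))
  ref_window <- toupper(ref_window)
  if (!grepl("^[ACGT]+$", ref_window)) stop("ref_window must be ACGT only")
  flank <- as.integer(flank)
  stopifnot(flank >= 1L)
  n <- nchar(ref_window)
  e1 <- as.integer(variant_offset) + 1L           # 1-based start of edit
  e2 <- e1 + nchar(variant$ref) - 1L              # 1-based end of edit
  if (e1 < 1L || e2 > n ||
      substr(ref_window, e1, e2) != variant$ref)
    stop("reference window disagrees with variant")

  # anchor region: the edit itself, extended over any homopolymer run
  # that an inserted/deleted base belongs to
  a1 <- e1; a2 <- e2
  kind <- variant_kind(variant)
  if (kind != "SNV") {
    long <- if (kind == "insertion") variant$alt else variant$ref
    short <- if (kind == "insertion") variant$ref else variant$alt
    extra <- substr(long, nchar(short) + 1L, nchar(long))
    bases <- unique(strsplit(extra, "", fixed = TRUE)[[1]])
    if (length(bases) == 1L) {
      b <- bases
      while (a1 > 1L && substr(ref_window, a1 - 1L, a1 - 1L) == b) a1 <- a1 - 1L
      while (a2 < n && substr(ref_window, a2 + 1L, a2 + 1L) == b) a2 <- a2 + 1L
      if ((a1 - 1L < 1L && substr(ref_window, 1L, 1L) == b) ||
          (a2 + 1L > n && substr(ref_window, n, n) == b))
        stop("window exhausted: homopolymer run reaches the window edge, ",
             "no anchor base available")
    }
  }

  L <- a1 - flank
  R <- a2 + flank
  if (L < 1L || R > n) { L <- 1L; R <- n }  # short window: use it whole

  build <- function(L, R) {
    refc <- substr(ref_window, L, R)
    altc <- paste0(substr(ref_window, L, e1 - 1L), variant$alt,
                   substr(ref_window, e2 + 1L, R))
    list(refc = refc, altc = altc)
  }
  distinguishable <- function(ctx) {
    !grepl(ctx$refc, ctx$altc, fixed = TRUE) &&
      !grepl(ctx$altc, ctx$refc, fixed = TRUE)
  }
  ctx <- build(L, R)
  while (!distinguishable(ctx)) {
    if (L == 1L && R == n)
      stop("window exhausted before contexts became distinguishable")
    L <- max(1L, L - 1L); R <- min(n, R + 1L)
    ctx <- build(L, R)
  }
  structure(list(variant = variant,
                 ref_context = ctx$refc, alt_context = ctx$altc,
                 flank_left = e1 - L, flank_right = R - e2,
                 orientation = "reference_forward"),
            class = "ap_context_pair")
}

#' @export
print.ap_context_pair <- function(x, ...) {
  cat(sprintf("<context pair> %s\n  REF %s\n  ALT %s\n",
              x$variant$label, x$ref_context, x$alt_context))
  invisible(x)
}

#' Contexts from a full reference sequence
#'
#' Convenience wrapper slicing a generous window around `pos` out of
#' `refseq` before calling [build_contexts()].
#'
#' @param refseq Full reference/amplicon sequence.
#' @param pos 1-based position of the first base of `variant$ref` in
#'   `refseq`.
#' @param variant An [variant()] object.
#' @param flank See [build_contexts()].
#' @return An `"ap_context_pair"`.
#' @export
contexts_from_reference <- function(refseq, pos, variant, flank = 4L) {
  refseq <- toupper(refseq)
  pos <- as.integer(pos)
  # margin: flank plus room for homopolymer-run extension
  margin <- flank + 16L
  L <- max(1L, pos - margin)
  R <- min(nchar(refseq), pos + nchar(variant$ref) - 1L + margin)
  build_contexts(substr(refseq, L, R), pos - L, variant, flank = flank)
}

#' Call the allele carried by a read
#'
#' Exact substring search of the ref and alt contexts (and, when
#' `both_strands`, their reverse complements) in each read sequence.
#' `N` bases never match.
#'
#' @param read_seq Character vector of read sequences (uppercase ACGTN).
#' @param cp An `"ap_context_pair"` from [build_contexts()].
#' @param both_strands Also search reverse-complement contexts; use for
#'   raw FASTQ reads, whose orientation is unknown.  Alignment-derived
#'   sequences are already reference-forward, so the default is off.
#' @return Character vector over `read_seq` with values `"REF"`,
#'   `"ALT"`, `"NONE"`, `"AMBIGUOUS"`.
#' @export
match_allele <- function(read_seq, cp, both_strands = FALSE) {
  stopifnot(inherits(cp, "ap_context_pair"))
  ref_hit <- grepl(cp$ref_context, read_seq, fixed = TRUE)
  alt_hit <- grepl(cp$alt_context, read_seq, fixed = TRUE)
  if (isTRUE(both_strands)) {
    ref_hit <- ref_hit | grepl(.revcomp(cp$ref_context), read_seq, fixed = TRUE)
    alt_hit <- alt_hit | grepl(.revcomp(cp$alt_context), read_seq, fixed = TRUE)
  }
  out <- rep("NONE", length(read_seq))
  out[ref_hit & !alt_hit] <- "REF"
  out[alt_hit & !ref_hit] <- "ALT"
  out[ref_hit & alt_hit] <- "AMBIGUOUS"
  out
}
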