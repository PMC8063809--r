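#' Construct a heterozygous variant
#'
#' A variant is a single edit of the reference: a substitution (SNV), a
#' simple insertion (alt extends ref) or a simple deletion (ref extends
#' alt).  Coordinates are 1-based; `gpos` is the genomic position of the
#' first reference base affected, following VCF/HGVS convention for
#' indels (the shared anchor base is part of both alleles).
#'
#' @param chrom Chromosome name.
#' @param gpos 1-based genomic position of the first reference base
#'   affected.
#' @param ref Reference allele (uppercase ACGT, non-empty).
#' @param alt Alternate allele (uppercase ACGT, non-empty, != ref).
#' @param cdna_pos Optional 1-based cDNA (c.) coordinate of the variant.
#' @param label Optional free-text identifier.
#' @return An object of class `"ap_variant"`.
#' @examples
#' variant("chr13", 51958362, "G", "GG", cdna_pos = 2304)
#' @export
variant <- function(chrom, gpos, ref, alt, cdna_pos = NULL, label = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  gpos <- as.integer(gpos)
  stopifnot(length(gpos) == 1L, !is.na(gpos), gpos >= 1L)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    stop("ref and alt must be non-empty uppercase ACGT strings")
  if (ref == alt) stop("ref and alt must differ")
  kind <- .variant_kind(ref, alt)
  if (kind == "complex")
    stop("complex variants (neither SNV nor simple indel) are not supported")
  if (!is.null(cdna_pos)) {
    cdna_pos <- as.integer(cdna_pos)
    stopifnot(!is.na(cdna_pos), cdna_pos >= 1L)
  }
  structure(
    list(chrom = chrom, gpos = gpos, ref = ref, alt = alt,
         cdna_pos = cdna_pos,
         label = if (is.null(label)) sprintf("%s:%d:%s:%s", chrom, gpos, ref, alt) else label),
    class = "ap_variant")
}

.variant_kind <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L) return("SNV")
  if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) return("insertion")
  if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) return("deletion")
  "complex"
}

#' Variant kind
#'
#' @param v An `ap_variant`.
#' @return One of `"SNV"`, `"insertion"`, `"deletion"`.
#' @export
variant_kind <- function(v) {
  stopifnot(inherits(v, "ap_variant"))
  .variant_kind(v$ref, v$alt)
}

#' @export
print.ap_variant <- function(x, ...) {
  cat(sprintf("<variant> %s:%d %s>%s (%s)%s\n", x$chrom, x$gpos, x$ref, x$alt,
              variant_kind(x),
              if (is.null(x$cdna_pos)) "" else sprintf(" c.%d", x$cdna_pos)))
  invisible(x)
}

#' Parse a variant literal of the form "chr13:51958362:G:GG"
#'
#' Also accepts the colon-separated form with a trailing cDNA coordinate,
#' "chr13:51958362:G:GG:2304".
#'
#' @param spec Character literal.
#' @return An `ap_variant`.
#' @export
parse_variant <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) < 4L || length(parts) > 5L)
    stop("variant literal must be chrom:pos:ref:alt[:cdna_pos], got: ", spec)
  variant(parts[1], as.integer(parts[2]), parts[3], parts[4],
          cdna_pos = if (length(parts) == 5L) as.integer(parts[5]) else NULL)
}

#' Genomic distance between two variants
#'
#' Distance is the plain coordinate difference `|gpos2 - gpos1|`, also
#' reported in kb rounded half-up to one decimal.  Contrast with
#' [cdna_span()], which is an inclusive span.
#'
#' @param v1,v2 `ap_variant` objects on the same chromosome.
#' @return A list with elements `bp` (integer) and `kb` (numeric, one
#'   decimal).
#' @examples
#' a <- variant("chr13", 51958362, "G", "GG")
#' b <- variant("chr13", 51964900, "C", "T")
#' genomic_distance(a, b)  # 6538 bp, 6.5 kb
#' @export
genomic_distance <- function(v1, v2) {
  stopifnot(inherits(v1, "ap_variant"), inherits(v2, "ap_variant"))
  if (v1$chrom != v2$chrom)
    stop("cross-chromosome phase not supported")
  bp <- abs(v2$gpos - v1$gpos)
  # round half-up at 1 decimal (base round() is half-even)
  kb <- floor(bp / 100 + 0.5) / 10
  list(bp = as.integer(bp), kb = kb)
}

#' Inclusive cDNA span between two c. coordinates
#'
#' Returns `|c2 - c1| + 1`, the number of transcript bases from one
#' variant through the other inclusive.  The inclusive convention is the
#' one under which the span of c.1841 and c.2304 is 464 bp.
#'
#' @param c1,c2 1-based cDNA coordinates.
#' @return Integer span in bases.
#' @export
cdna_span <- function(c1, c2) {
  c1 <- as.integer(c1); c2 <- as.integer(c2)
  if (is.na(c1) || is.na(c2) || c1 < 1L || c2 < 1L)
    stop("cDNA coordinates must be positive integers")
  abs(c2 - c1) + 1L
}

#' Construct a transcript exon model
#'
#' Exons are 1-based closed genomic intervals given in transcript 5'->3'
#' order: starts strictly increase on the + strand and strictly decrease
#' on the - strand.
#'
#' @param name Transcript identifier.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons A two-column matrix or data.frame of (start, end), or a
#'   list of length-2 vectors, in transcript order.
#' @param cds_start_tpos 1-based transcript coordinate of the first
#'   coding base.
#' @return An object of class `"ap_transcript"`.
#' @export
transcript_model <- function(name, chrom, strand, exons, cds_start_tpos = 1L) {
  stopifnot(strand %in% c("+", "-"))
  if (is.list(exons) && !is.data.frame(exons))
    exons <- do.call(rbind, exons)
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(is.na(exons)) || any(exons < 1L) || any(exons[, 1] > exons[, 2]))
    stop("exons must be valid 1-based closed intervals")
  n <- nrow(exons)
  if (n > 1L) {
    d <- diff(exons[, 1])
    if (strand == "+" && any(d <= 0))
      stop("+ strand exon starts must strictly increase in transcript order")
    if (strand == "-" && any(d >= 0))
      stop("- strand exon starts must strictly decrease in transcript order")
    srt <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(srt[-n, 2] >= srt[-1, 1])) stop("exons overlap")
  }
  tlen <- sum(exons[, 2] - exons[, 1] + 1L)
  cds_start_tpos <- as.integer(cds_start_tpos)
  if (is.na(cds_start_tpos) || cds_start_tpos < 1L || cds_start_tpos > tlen)
    stop("cds_start_tpos outside transcript")
  structure(list(name = name, chrom = chrom, strand = strand, exons = exons,
                 cds_start_tpos = cds_start_tpos, tlen = tlen),
            class = "ap_transcript")
}

#' @export
print.ap_transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s %s(%s), %d exon(s), length %d, CDS starts at t.%d\n",
              x$name, x$chrom, x$strand, nrow(x$exons), x$tlen, x$cds_start_tpos))
  invisible(x)
}

#' Map a genomic position to a transcript coordinate
#'
#' Counts exonic bases from the transcript 5' end through `gpos`,
#' respecting strand.  Intronic or out-of-range positions are an error.
#'
#' @param tm An `ap_transcript`.
#' @param gpos 1-based genomic position.
#' @return 1-based transcript position.
#' @seealso [map_transcript_to_genomic()], [map_transcript_to_cds()]
#' @export
map_genomic_to_transcript <- function(tm, gpos) {
  stopifnot(inherits(tm, "ap_transcript"))
  gpos <- as.integer(gpos)
  off <- 0L
  for (i in seq_len(nrow(tm$exons))) {
    s <- tm$exons[i, 1]; e <- tm$exons[i, 2]
    if (gpos >= s && gpos <= e) {
      within <- if (tm$strand == "+") gpos - s else e - gpos
      return(unname(off + within + 1L))
    }
    off <- off + (e - s + 1L)
  }
  stop("position not exonic: ", gpos)
}

#' Map a transcript coordinate back to the genome
#'
#' Inverse of [map_genomic_to_transcript()].
#'
#' @param tm An `ap_transcript`.
#' @param tpos 1-based transcript position.
#' @return 1-based genomic position.
#' @export
map_transcript_to_genomic <- function(tm, tpos) {
  stopifnot(inherits(tm, "ap_transcript"))
  tpos <- as.integer(tpos)
  if (is.na(tpos) || tpos < 1L || tpos > tm$tlen)
    stop("transcript position out of range: ", tpos)
  off <- 0L
  for (i in seq_len(nrow(tm$exons))) {
    s <- tm$exons[i, 1]; e <- tm$exons[i, 2]
    w <- e - s + 1L
    if (tpos <= off + w) {
      within <- tpos - off - 1L
      return(unname(if (tm$strand == "+") s + within else e - within))
    }
    off <- off + w
  }
  stop("unreachable")
}

#' Transcript position to CDS (c.) coordinate
#'
#' @param tm An `ap_transcript`.
#' @param tpos 1-based transcript position.
#' @return `tpos - cds_start_tpos + 1`.
#' @export
map_transcript_to_cds <- function(tm, tpos) {
  stopifnot(inherits(tm, "ap_transcript"))
  as.integer(tpos) - tm$cds_start_tpos + 1L
}
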