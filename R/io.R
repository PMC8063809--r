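## Standard-format readers and writers.  Alignment input is used purely
## as a read-pair container: no re-alignment, no CIGAR walking --
## allele calls downstream are sequence-context based.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace token of each header.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate FASTA names in ", path)
  stats::setNames(toupper(as.character(ss)), nm)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

.strip_mate_suffix <- function(x) sub("(/[12]| .*)$", "", x)

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read name-synchronized paired FASTQ files
#'
#' Plain 4-line FASTQ, Phred+33, optionally gzipped.  R1/R2 names must
#' match after stripping `/1`, `/2` or space suffixes.  With a
#' `callback`, files are processed in chunks of `chunk_size` pairs and
#' only the chunk is held in memory; the callback receives each chunk
#' data.frame.
#'
#' @param path_r1,path_r2 FASTQ paths.
#' @param chunk_size Pairs per chunk (default 100000).
#' @param callback Optional `function(chunk_df)` for streaming.
#' @return Without a callback, a data.frame with columns `name`,
#'   `seq1`, `qual1`, `seq2`, `qual2`; with one, the total pair count,
#'   invisibly.
#' @export
read_fastq_pairs <- function(path_r1, path_r2, chunk_size = 100000L,
                             callback = NULL) {
  con1 <- .open_maybe_gz(path_r1); on.exit(close(con1), add = TRUE)
  con2 <- .open_maybe_gz(path_r2); on.exit(close(con2), add = TRUE)
  out <- list()
  total <- 0L
  repeat {
    l1 <- readLines(con1, n = 4L * chunk_size)
    l2 <- readLines(con2, n = 4L * chunk_size)
    if (length(l1) == 0L && length(l2) == 0L) break
    if (length(l1) %% 4L != 0L || length(l2) %% 4L != 0L ||
        length(l1) != length(l2))
      stop("truncated or desynchronized FASTQ near line ",
           total * 4L + max(length(l1), length(l2)))
    np <- length(l1) %/% 4L
    i <- seq_len(np) * 4L - 3L
    h1 <- l1[i]; h2 <- l2[i]
    if (any(substr(h1, 1, 1) != "@") || any(substr(h2, 1, 1) != "@"))
      stop("malformed FASTQ header near line ", total * 4L + 1L)
    n1 <- .strip_mate_suffix(substring(h1, 2L))
    n2 <- .strip_mate_suffix(substring(h2, 2L))
    bad <- which(n1 != n2)
    if (length(bad))
      stop("R1/R2 name mismatch at pair ", total + bad[1], ": ",
           n1[bad[1]], " vs ", n2[bad[1]])
    chunk <- data.frame(name = n1,
                        seq1 = toupper(l1[i + 1L]), qual1 = l1[i + 3L],
                        seq2 = toupper(l2[i + 1L]), qual2 = l2[i + 3L],
                        stringsAsFactors = FALSE)
    if (any(nchar(chunk$seq1) != nchar(chunk$qual1)) ||
        any(nchar(chunk$seq2) != nchar(chunk$qual2)))
      stop("sequence/quality length mismatch near pair ", total + 1L)
    total <- total + np
    if (is.null(callback)) out[[length(out) + 1L]] <- chunk
    else callback(chunk)
    if (length(l1) < 4L * chunk_size) break
  }
  if (is.null(callback)) {
    if (total == 0L) stop("no reads in ", path_r1)
    do.call(rbind, out)
  } else invisible(total)
}

#' Write paired reads as FASTQ
#'
#' @param reads Data.frame with `name`, `seq1`, `qual1`, `seq2`,
#'   `qual2`.
#' @param path_r1,path_r2 Output paths (`.gz` suffix gzips).
#' @export
write_fastq_pairs <- function(reads, path_r1, path_r2) {
  wr <- function(path, seq, qual) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    writeLines(paste0("@", reads$name, "\n", seq, "\n+\n", qual), con)
  }
  wr(path_r1, reads$seq1, reads$qual1)
  wr(path_r2, reads$seq2, reads$qual2)
  invisible(c(path_r1, path_r2))
}

#' Read pairs from a SAM/BAM file
#'
#' Primary alignments only; pairs are reconstructed by query name.
#' Stored sequences are returned as stored (reference-forward for
#' mapped reads); unmapped mates are retained with their sequence.
#' The pair's leftmost mapped position becomes the dedup `anchor`.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @return Data.frame `name`, `seq1`, `qual1`, `seq2`, `qual2`,
#'   `anchor`.
#' @export
read_alignment_pairs <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "seq", "qual", "pos"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(res$qname) == 0L) stop("no alignments in ", path)
  first <- bitwAnd(res$flag, 64L) > 0L
  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  d1 <- data.frame(name = res$qname[first], seq1 = seqs[first],
                   qual1 = quals[first], pos1 = res$pos[first],
                   stringsAsFactors = FALSE)
  d2 <- data.frame(name = res$qname[!first], seq2 = seqs[!first],
                   qual2 = quals[!first], pos2 = res$pos[!first],
                   stringsAsFactors = FALSE)
  m <- merge(d1, d2, by = "name", sort = FALSE)
  if (nrow(m) == 0L) stop("no complete pairs in ", path)
  m$anchor <- paste(pmin(m$pos1, m$pos2, na.rm = TRUE),
                    pmax(m$pos1, m$pos2, na.rm = TRUE), sep = "-")
  m[, c("name", "seq1", "qual1", "seq2", "qual2", "anchor")]
}

#' Read variants from a minimal VCF
#'
#' Takes CHROM, POS, REF and the first ALT of each record verbatim (no
#' normalization); genotypes are ignored.
#'
#' @param path VCF file.
#' @return List of [variant()] objects.
#' @export
read_variants_vcf <- function(path) {
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(v)
  ref <- as.character(VariantAnnotation::ref(v))
  alt <- vapply(VariantAnnotation::alt(v),
                function(a) as.character(a)[1], character(1))
  lapply(seq_along(rr), function(i)
    variant(as.character(GenomicRanges::seqnames(rr)[i]),
            GenomicRanges::start(rr)[i], ref[i], alt[i]))
}

#' Read a transcript model from a one-record BED12 file
#'
#' Blocks become exons (converted to 1-based closed coordinates);
#' minus-strand blocks are reordered into transcript 5'->3' order.
#'
#' @param path BED12 file with exactly one record.
#' @param cds_start_tpos See [transcript_model()].
#' @return An `"ap_transcript"`.
#' @export
read_transcript_bed12 <- function(path, cds_start_tpos = 1L) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) != 1L) stop("expected exactly one BED12 record in ", path)
  bl <- gr$blocks[[1]]
  ex <- cbind(GenomicRanges::start(gr) + S4Vectors::start(bl) - 1L,
              GenomicRanges::start(gr) + S4Vectors::end(bl) - 1L)
  strand <- as.character(GenomicRanges::strand(gr))
  if (!strand %in% c("+", "-")) stop("BED12 record must be stranded")
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  transcript_model(if (!is.null(gr$name)) gr$name else "tx",
                   as.character(GenomicRanges::seqnames(gr)), strand, ex,
                   cds_start_tpos)
}

#' Read a transcript model from a simple TSV
#'
#' Four tab-separated columns: name, chrom, strand, comma-separated
#' `start-end` exon intervals in transcript order.
#'
#' @param path TSV file (one row).
#' @param cds_start_tpos See [transcript_model()].
#' @return An `"ap_transcript"`.
#' @export
read_transcript_tsv <- function(path, cds_start_tpos = 1L) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(d) != 1L || ncol(d) < 4L)
    stop("expected one row of 4 columns in ", path)
  iv <- strsplit(strsplit(d[1, 4], ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  ex <- do.call(rbind, lapply(iv, as.integer))
  transcript_model(d[1, 1], d[1, 2], d[1, 3], ex, cds_start_tpos)
}

.flatten_summary <- function(x) {
  sc <- lapply(x$site_counts, function(s) {
    out <- list(site = s$site, n_ref = s$n_ref, n_alt = s$n_alt,
                depth = s$depth,
                alt_frequency = if (s$depth > 0) s$n_alt / s$depth else NA)
    if (!is.null(s$test)) out <- c(out, s$test["p_value"],
                                   list(conf_low = s$test$conf_int[1],
                                        conf_high = s$test$conf_int[2],
                                        flag = s$test$flag))
    out
  })
  list(version = as.character(utils::packageVersion("ampliphase")),
       n_raw_pairs = x$n_raw_pairs, n_kept_pairs = x$n_kept_pairs,
       n_duplicates_removed = x$n_duplicates_removed,
       dedup_method = x$dedup_method,
       n_informative_a = x$n_informative_a,
       n_informative_b = x$n_informative_b,
       n_informative_both = x$n_informative_both,
       both_site_fraction = x$both_site_fraction,
       table = unclass(x$table)[c("n_rr", "n_ra", "n_ar", "n_aa",
                                  "n_site_a_only", "n_site_b_only",
                                  "n_uninformative", "n_conflict",
                                  "n_informative")],
       phase = list(configuration = x$phase$configuration,
                    cis_support = x$phase$cis_support,
                    trans_support = x$phase$trans_support,
                    support_fraction = x$phase$support_fraction,
                    p_value = x$phase$p_value),
       haplotype_expression = x$haplotype_expression,
       sites = sc,
       params = x$params)
}

#' Write a phase-analysis report
#'
#' JSON carries the full summary including the effective configuration
#' echo; TSV has one row per site plus one phase row, with a stable
#' field order.
#'
#' @param summary An `"ap_run_summary"` (see [summarize_run()] /
#'   [run_phase_analysis()]).
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("json", "tsv")`.
#' @return Paths of the files written, invisibly.
#' @export
write_report <- function(summary, dir, formats = c("json", "tsv")) {
  stopifnot(inherits(summary, "ap_run_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- .flatten_summary(summary)
  paths <- character(0)
  if ("json" %in% formats) {
    p <- file.path(dir, "phase_report.json")
    jsonlite::write_json(flat, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    paths <- c(paths, p)
  }
  if ("tsv" %in% formats) {
    p <- file.path(dir, "phase_report.tsv")
    rows <- lapply(flat$sites, function(s)
      data.frame(record = "site", label = s$site,
                 n_ref = s$n_ref, n_alt = s$n_alt,
                 value = s$alt_frequency,
                 p_value = if (!is.null(s$p_value)) s$p_value else NA,
                 flag = if (!is.null(s$flag)) s$flag else NA,
                 stringsAsFactors = FALSE))
    rows <- c(rows, list(data.frame(
      record = "phase", label = flat$phase$configuration,
      n_ref = flat$phase$cis_support, n_alt = flat$phase$trans_support,
      value = flat$phase$support_fraction, p_value = flat$phase$p_value,
      flag = NA, stringsAsFactors = FALSE)))
    utils::write.table(do.call(rbind, rows), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
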