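## UMI extraction and PCR-duplicate collapsing.
##
## Duplicates are collapsed BEFORE any allele counting, so that
## amplification bias (including allele-biased amplification) cannot
## distort allele frequencies.  The directional method reproduces the
## published UMI-tools default: within a grouping anchor, UMI a absorbs
## UMI b when Hamming(a, b) <= 1 and count(a) >= 2*count(b) - 1, and
## each connected component under directed reachability from its
## highest-count UMI collapses to a single molecule.

#' Extract UMIs from raw read pairs
#'
#' Two placement schemes are supported: `name_suffix`, where the read
#' name ends in `_<UMI>`, and `inline_prefix`, where mate 1 begins with
#' `umi_len` UMI bases, which are trimmed from sequence and quality.
#'
#' @param pairs A data.frame of raw pairs with columns `name`, `seq1`,
#'   `qual1`, `seq2`, `qual2` (e.g. from [read_fastq_pairs()]).
#' @param scheme `"name_suffix"` or `"inline_prefix"`.
#' @param umi_len UMI length in bases (default 8).
#' @return The input data.frame with a `umi` column added (and, for
#'   `inline_prefix`, the UMI bases removed from `seq1`/`qual1`).
#' @export
extract_umi <- function(pairs, scheme = c("name_suffix", "inline_prefix"),
                        umi_len = 8L) {
  scheme <- match.arg(scheme)
  umi_len <- as.integer(umi_len)
  stopifnot(is.data.frame(pairs), umi_len >= 1L)
  if (scheme == "name_suffix") {
    m <- regmatches(pairs$name, regexpr("_[ACGT]+$", pairs$name))
    bad <- !grepl("_[ACGT]+$", pairs$name)
    if (any(bad))
      stop("read name lacks _UMI suffix: ", pairs$name[which(bad)[1]])
    umi <- substring(m, 2L)
    if (any(nchar(umi) != umi_len))
      stop("UMI length mismatch in read name: ",
           pairs$name[which(nchar(umi) != umi_len)[1]])
    pairs$umi <- umi
  } else {
    short <- nchar(pairs$seq1) <= umi_len
    if (any(short))
      stop("mate 1 shorter than UMI length: ", pairs$name[which(short)[1]])
    pairs$umi <- substr(pairs$seq1, 1L, umi_len)
    if (any(!grepl("^[ACGT]+$", pairs$umi)))
      stop("non-ACGT base in inline UMI: ",
           pairs$name[which(!grepl("^[ACGT]+$", pairs$umi))[1]])
    pairs$seq1 <- substring(pairs$seq1, umi_len + 1L)
    pairs$qual1 <- substring(pairs$qual1, umi_len + 1L)
  }
  pairs
}

## Directional clustering of a UMI count table.  Returns an integer
## vector mapping each UMI (names of `counts`) to a cluster id.
## Hamming-1 neighbours are found by hash lookup of all single-base
## substitutions (O(u * 3 * len)), not pairwise comparison, so large
## UMI sets stay tractable.
.cluster_directional <- function(counts) {
  umis <- names(counts)
  u <- length(umis)
  if (u == 1L) return(stats::setNames(1L, umis))
  len <- nchar(umis[1])
  from <- integer(0); to <- integer(0)
  for (p in seq_len(len)) {
    for (b in c("A", "C", "G", "T")) {
      cand <- umis
      substr(cand, p, p) <- b
      j <- match(cand, umis)
      ok <- which(!is.na(j) & j != seq_len(u))
      from <- c(from, ok); to <- c(to, j[ok])
    }
  }
  # directed edge i -> j when count_i >= 2*count_j - 1
  keep <- counts[from] >= 2L * counts[to] - 1L
  from <- from[keep]; to <- to[keep]
  adj <- split(to, factor(from, levels = seq_len(u)))
  ord <- order(-counts, umis)
  cluster <- integer(u)
  cid <- 0L
  for (root in ord) {
    if (cluster[root] != 0L) next
    cid <- cid + 1L
    queue <- root
    while (length(queue)) {
      node <- queue[[1]]; queue <- queue[-1]
      if (cluster[node] != 0L) next
      cluster[node] <- cid
      nxt <- adj[[node]]
      queue <- c(queue, nxt[cluster[nxt] == 0L])
    }
  }
  stats::setNames(cluster, umis)
}

#' Collapse PCR duplicates by UMI
#'
#' Pairs are grouped by `(UMI cluster, anchor)`.  The anchor defaults to
#' an `anchor` column when present (alignment start in alignment mode,
#' or the pair's two-site allele signature in alignment-free amplicon
#' mode); otherwise all pairs share one anchor.  Within a cluster the
#' representative is drawn from the pairs carrying the cluster's root
#' (highest-count) UMI: highest mean base quality first, ties broken by
#' lexicographically smallest name.
#'
#' A `dup_count` column records how many input pairs each representative
#' stands for; when present on input (e.g. when re-deduplicating already
#' collapsed pairs) it weights the UMI counts, which makes `dedup_pairs`
#' idempotent.
#'
#' @param pairs Data.frame with columns `name`, `umi`, `seq1`, `qual1`,
#'   `seq2`, `qual2` and optionally `anchor`, `dup_count`.
#' @param method `"exact"` (identical UMIs only) or `"directional"`
#'   (adjacency clustering, see module header).
#' @return A list with `kept` (data.frame of representative pairs, input
#'   order preserved, with `dup_count`) and `stats` (`n_input`,
#'   `n_kept`, `n_removed`, `method`).
#' @export
dedup_pairs <- function(pairs, method = c("directional", "exact")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs), "umi" %in% names(pairs))
  n <- nrow(pairs)
  if (n == 0L)
    return(list(kept = pairs,
                stats = list(n_input = 0L, n_kept = 0L, n_removed = 0L,
                             method = method)))
  if (length(unique(nchar(pairs$umi))) != 1L)
    stop("mixed UMI lengths")
  anchor <- if ("anchor" %in% names(pairs)) as.character(pairs$anchor)
            else rep("*", n)
  w <- if ("dup_count" %in% names(pairs)) as.integer(pairs$dup_count)
       else rep(1L, n)
  meanq <- (vapply(pairs$qual1, function(q) mean(utf8ToInt(q)), 0) +
            vapply(pairs$qual2, function(q) mean(utf8ToInt(q)), 0)) / 2

  keep <- logical(n)
  total <- integer(n)
  for (a in unique(anchor)) {
    idx <- which(anchor == a)
    umi <- pairs$umi[idx]
    if (method == "exact") {
      grp <- umi
    } else {
      counts <- tapply(w[idx], umi, sum)
      counts <- stats::setNames(as.integer(counts), names(counts))
      cl <- .cluster_directional(counts)
      grp <- as.character(cl[umi])
    }
    for (g in unique(grp)) {
      members <- idx[grp == g]
      # representative comes from the cluster's root UMI (highest
      # weighted count, ties lexicographic); within those, highest mean
      # quality, then smallest name.  Carrying the root UMI + its count
      # forward makes a second dedup pass a no-op.
      cnt <- tapply(w[members], pairs$umi[members], sum)
      root <- names(cnt)[order(-as.integer(cnt), names(cnt))][1]
      mr <- members[pairs$umi[members] == root]
      best <- mr[order(-meanq[mr], pairs$name[mr])][1]
      keep[best] <- TRUE
      total[best] <- as.integer(cnt[root])
    }
  }
  kept <- pairs[keep, , drop = FALSE]
  kept$dup_count <- total[keep]
  rownames(kept) <- NULL
  list(kept = kept,
       stats = list(n_input = n, n_kept = nrow(kept),
                    n_removed = n - nrow(kept), method = method))
}
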