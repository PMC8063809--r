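# Independent brute-force oracles used across the suite.  These are
# deliberately written from first principles, not by calling the
# package functions they check.

# enumerate exonic genomic positions of a transcript model in
# transcript 5'->3' order
oracle_exonic_walk <- function(exons, strand) {
  unlist(lapply(seq_len(nrow(exons)), function(i) {
    s <- exons[i, 1]; e <- exons[i, 2]
    if (strand == "+") s:e else e:s
  }))
}

# directional UMI clustering by explicit graph construction and
# directed reachability from the highest-count unassigned node
oracle_directional <- function(counts) {
  umis <- names(counts)
  u <- length(umis)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  adj <- matrix(FALSE, u, u)
  for (i in seq_len(u)) for (j in seq_len(u)) {
    if (i != j && hamming(umis[i], umis[j]) <= 1 &&
        counts[i] >= 2 * counts[j] - 1)
      adj[i, j] <- TRUE
  }
  reach <- function(start, alive) {
    seen <- start
    repeat {
      new <- integer(0)
      for (s in seen) {
        cand <- which(adj[s, ] & alive)
        new <- c(new, setdiff(cand, seen))
      }
      if (!length(new)) return(seen)
      seen <- c(seen, unique(new))
    }
  }
  cluster <- rep(NA_integer_, u)
  cid <- 0
  ord <- order(-counts, umis)
  for (root in ord) {
    if (!is.na(cluster[root])) next
    cid <- cid + 1
    alive <- is.na(cluster)
    cluster[reach(root, alive)] <- cid
  }
  stats::setNames(cluster, umis)
}

# minimum-likelihood two-sided exact binomial p-value by full pmf
# enumeration (same 1+1e-7 relative guard as the classical definition)
oracle_binom_p <- function(x, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Clopper-Pearson 95% interval from the beta quantile definition
oracle_clopper_pearson <- function(x, n) {
  lo <- if (x == 0) 0 else qbeta(0.025, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(0.975, x + 1, n - x)
  c(lo, hi)
}

# merge rule written straight from its specification table
oracle_merge <- function(c1, c2) {
  if (c1 == "AMBIGUOUS" || c2 == "AMBIGUOUS") return("AMBIGUOUS")
  if (c1 == "NONE") return(c2)
  if (c2 == "NONE") return(c1)
  if (c1 == c2) return(c1)
  "AMBIGUOUS"  # REF vs ALT contradiction
}

random_umis <- function(n_unique, len = 4) {
  replicate(n_unique,
            paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
}

# a minimal valid pairs data.frame for dedup tests
pairs_df <- function(umis, anchor = "*", qual = NULL, names = NULL) {
  n <- length(umis)
  data.frame(
    name = if (is.null(names)) sprintf("p%03d", seq_len(n)) else names,
    umi = umis,
    seq1 = strrep("A", 10), qual1 = if (is.null(qual)) strrep("F", 10)
                                    else qual,
    seq2 = strrep("A", 10), qual2 = if (is.null(qual)) strrep("F", 10)
                                    else qual,
    anchor = anchor, stringsAsFactors = FALSE)
}
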