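## Per-site and per-haplotype allelic expression.
##
## Counts enter these functions only after UMI deduplication, so the
## alt-allele fraction estimates molecule (not read) abundance and is
## protected from allele-biased PCR amplification.  A premature stop
## codon on one allele typically shows up here as an alt fraction well
## below 0.5 (consistent with nonsense-mediated decay; interpretive
## only, never computed as fact).

#' Deduplicated allele counts at one site
#'
#' @param site Site label.
#' @param n_ref,n_alt Non-negative deduplicated pair counts.
#' @return An object of class `"ap_site_counts"` with derived `depth`.
#' @export
site_allele_counts <- function(site, n_ref, n_alt) {
  n_ref <- as.integer(n_ref); n_alt <- as.integer(n_alt)
  if (is.na(n_ref) || is.na(n_alt) || n_ref < 0L || n_alt < 0L)
    stop("counts must be non-negative integers")
  structure(list(site = site, n_ref = n_ref, n_alt = n_alt,
                 depth = n_ref + n_alt),
            class = "ap_site_counts")
}

#' Alternate-allele frequency at a site
#'
#' @param c An `"ap_site_counts"`.
#' @return `n_alt / depth`, in \[0, 1\].
#' @export
allele_frequency <- function(c) {
  stopifnot(inherits(c, "ap_site_counts"))
  if (c$depth < 1L) stop("no informative reads")
  c$n_alt / c$depth
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial test of `n_alt` out of `depth` against
#' `null_fraction` (minimum-likelihood two-sided definition: the sum of
#' probabilities of all outcomes no more likely than the observed one),
#' with a Clopper-Pearson 95% confidence interval.  The flag is
#' `BALANCED` when `p >= alpha`, otherwise `ALT_LOWER`/`ALT_HIGHER` by
#' the sign of the observed frequency minus `null_fraction`.
#'
#' @param c An `"ap_site_counts"` with `depth >= 1`.
#' @param null_fraction Null alt fraction, in (0, 1); default 0.5
#'   (balanced biallelic expression).
#' @param alpha Significance level for the flag (default 0.05).
#' @return List with `p_value`, `conf_int` (length 2), `estimate`,
#'   `flag`.
#' @export
imbalance_test <- function(c, null_fraction = 0.5, alpha = 0.05) {
  stopifnot(inherits(c, "ap_site_counts"))
  if (c$depth < 1L) stop("no informative reads")
  if (!is.numeric(null_fraction) || null_fraction <= 0 || null_fraction >= 1)
    stop("null_fraction must lie strictly between 0 and 1")
  bt <- stats::binom.test(c$n_alt, c$depth, p = null_fraction,
                          conf.level = 0.95)
  est <- c$n_alt / c$depth
  flag <- if (bt$p.value >= alpha) "BALANCED"
          else if (est < null_fraction) "ALT_LOWER" else "ALT_HIGHER"
  list(p_value = bt$p.value,
       conf_int = as.numeric(bt$conf.int),
       estimate = est,
       flag = flag)
}

#' Per-haplotype expression fractions
#'
#' Partitions double-informative pairs into the two phase-consistent
#' haplotype classes (trans: `{ra, ar}`; cis: `{rr, aa}`) and returns
#' each class's fraction of phase-consistent pairs, plus the fraction
#' of phase-inconsistent pairs as a QC metric (chimeric templates,
#' residual sequencing error).
#'
#' @param table An `"ap_haplotype_table"`.
#' @param call An `"ap_phase_call"` with configuration `CIS` or
#'   `TRANS`.
#' @return List with `hap1_fraction`, `hap2_fraction` (of
#'   phase-consistent pairs), `hap1_class`, `hap2_class`,
#'   `inconsistent_fraction` (of all double-informative pairs).
#' @export
haplotype_expression <- function(table, call) {
  stopifnot(inherits(table, "ap_haplotype_table"),
            inherits(call, "ap_phase_call"))
  if (!call$configuration %in% c("CIS", "TRANS"))
    stop("phase call must be CIS or TRANS, got ", call$configuration)
  if (call$configuration == "TRANS") {
    h1 <- table$n_ar; h2 <- table$n_ra
    classes <- c("alt_A|ref_B", "ref_A|alt_B")
  } else {
    h1 <- table$n_aa; h2 <- table$n_rr
    classes <- c("alt_A|alt_B", "ref_A|ref_B")
  }
  consistent <- h1 + h2
  if (consistent == 0L) stop("no phase-consistent pairs")
  list(hap1_fraction = h1 / consistent,
       hap2_fraction = h2 / consistent,
       hap1_class = classes[1], hap2_class = classes[2],
       inconsistent_fraction =
         (table$n_informative - consistent) / table$n_informative)
}
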