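## End-to-end phase analysis: context building, per-mate allele calls,
## mate merging, UMI dedup, tabulation, phase call, per-site and
## per-haplotype expression.

#' Run the full phase analysis on read pairs
#'
#' Order of operations: per-mate allele calls at both sites by exact
#' context matching; mate merging; UMI extraction; duplicate collapse
#' (grouping anchor = the pair's two-site call signature in
#' alignment-free mode, or the `anchor` column when the pairs came from
#' an alignment); tabulation of the deduplicated observations; the
#' cis/trans call; per-site allele frequencies and imbalance tests; and
#' per-haplotype expression when the phase call is definitive.
#'
#' @param pairs Data.frame of read pairs (`name`, `seq1`, `qual1`,
#'   `seq2`, `qual2`, optional `anchor`) from [read_fastq_pairs()],
#'   [read_alignment_pairs()] or [simulate_pairs()].
#' @param ref Reference amplicon/transcript sequence, or a named FASTA
#'   vector of length 1 from [read_fasta()].
#' @param variant_a,variant_b [variant()] objects; `gpos` is the
#'   1-based position within `ref`.
#' @param flank Context flank, see [build_contexts()].
#' @param both_strands Search reverse-complement contexts too; default
#'   `TRUE` for raw reads.  Set `FALSE` for alignment input, whose
#'   sequences are already reference-forward.
#' @param umi_scheme `"name_suffix"`, `"inline_prefix"`, or `"none"`
#'   to skip deduplication.
#' @param umi_len UMI length.
#' @param dedup_method `"directional"`, `"exact"`, or `"none"`.
#' @param min_informative,min_support_fraction See [call_phase()].
#' @param null_fraction,alpha See [imbalance_test()].
#' @return An `"ap_run_summary"` with per-site imbalance tests attached
#'   to `site_counts` and, for a definitive call,
#'   `haplotype_expression`.
#' @examples
#' sim <- simulate_pairs(sim_config(n_pairs = 300, seed = 42))
#' run_phase_analysis(sim$reads, sim$config$ref_amplicon,
#'                    sim$config$variant_a, sim$config$variant_b)
#' @export
run_phase_analysis <- function(pairs, ref, variant_a, variant_b,
                               flank = 4L, both_strands = TRUE,
                               umi_scheme = c("name_suffix",
                                              "inline_prefix", "none"),
                               umi_len = 8L,
                               dedup_method = c("directional", "exact",
                                                "none"),
                               min_informative = 10L,
                               min_support_fraction = 0.9,
                               null_fraction = 0.5, alpha = 0.05) {
  umi_scheme <- match.arg(umi_scheme)
  dedup_method <- match.arg(dedup_method)
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1L)
  if (length(ref) != 1L) stop("ref must be a single sequence")
  ref <- toupper(unname(ref))

  cpa <- contexts_from_reference(ref, variant_a$gpos, variant_a, flank)
  cpb <- contexts_from_reference(ref, variant_b$gpos, variant_b, flank)

  n_raw <- nrow(pairs)
  if (umi_scheme != "none")
    pairs <- extract_umi(pairs, umi_scheme, umi_len)

  call_a <- merge_mate_calls(match_allele(pairs$seq1, cpa, both_strands),
                             match_allele(pairs$seq2, cpa, both_strands))
  call_b <- merge_mate_calls(match_allele(pairs$seq1, cpb, both_strands),
                             match_allele(pairs$seq2, cpb, both_strands))

  dd <- NULL
  if (umi_scheme != "none" && dedup_method != "none") {
    if (!"anchor" %in% names(pairs))
      pairs$anchor <- paste(call_a, call_b, sep = "|")
    pairs$.row <- seq_len(nrow(pairs))
    dd <- dedup_pairs(pairs, dedup_method)
    sel <- dd$kept$.row
    call_a <- call_a[sel]
    call_b <- call_b[sel]
  }

  tab <- tabulate_pairs(call_a, call_b)
  phase <- call_phase(tab, min_informative, min_support_fraction)

  mk_site <- function(label, calls) {
    sc <- site_allele_counts(label, sum(calls == "REF"),
                             sum(calls == "ALT"))
    sc$test <- if (sc$depth >= 1L)
      imbalance_test(sc, null_fraction, alpha) else NULL
    sc
  }
  sites <- list(mk_site(variant_a$label, call_a),
                mk_site(variant_b$label, call_b))

  params <- list(flank = flank, both_strands = both_strands,
                 umi_scheme = umi_scheme, umi_len = umi_len,
                 dedup_method = dedup_method,
                 min_informative = min_informative,
                 min_support_fraction = min_support_fraction,
                 null_fraction = null_fraction, alpha = alpha,
                 ref_context_a = cpa$ref_context,
                 alt_context_a = cpa$alt_context,
                 ref_context_b = cpb$ref_context,
                 alt_context_b = cpb$alt_context)
  out <- summarize_run(n_raw, if (is.null(dd)) NULL else dd$stats,
                       tab, sites, phase, params)
  out$haplotype_expression <-
    if (phase$configuration %in% c("CIS", "TRANS"))
      haplotype_expression(tab, phase) else NULL
  out
}
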