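## Cis/trans phase calling from per-pair allele observations.
##
## Each deduplicated read pair yields one allele call per variant site
## (the union of its two mates' evidence).  Pairs informative at both
## sites populate a 2x2 haplotype configuration table; cis support is
## the (REF,REF)+(ALT,ALT) diagonal, trans support the off-diagonal.

#' Merge the two mates' allele calls at one site
#'
#' `NONE` defers to the other mate; agreeing calls stand; `REF` vs
#' `ALT` is a contradiction and becomes `AMBIGUOUS`; `AMBIGUOUS`
#' dominates everything.
#'
#' @param c1,c2 Character vectors of allele calls
#'   (`REF`/`ALT`/`NONE`/`AMBIGUOUS`), recycled to a common length.
#' @return Merged call vector.
#' @export
merge_mate_calls <- function(c1, c2) {
  lv <- c("REF", "ALT", "NONE", "AMBIGUOUS")
  stopifnot(all(c1 %in% lv), all(c2 %in% lv))
  n <- max(length(c1), length(c2))
  c1 <- rep_len(c1, n); c2 <- rep_len(c2, n)
  out <- character(n)
  amb <- c1 == "AMBIGUOUS" | c2 == "AMBIGUOUS" |
    (c1 == "REF" & c2 == "ALT") | (c1 == "ALT" & c2 == "REF")
  out[amb] <- "AMBIGUOUS"
  rest <- !amb
  out[rest] <- ifelse(c1[rest] == "NONE", c2[rest], c1[rest])
  out
}

#' Tabulate per-pair observations into a haplotype configuration table
#'
#' Classification of a pair by its merged calls `(call_A, call_B)`:
#' both in `{REF, ALT}` fills the 2x2 cells `n_rr`, `n_ra`, `n_ar`,
#' `n_aa` (first letter = site A, second = site B); an `AMBIGUOUS` call
#' at either site makes the pair a conflict; otherwise a single
#' informative site counts as `n_site_a_only`/`n_site_b_only` and
#' double `NONE` as `n_uninformative`.
#'
#' @param call_a,call_b Character vectors of merged calls, same length.
#' @return An object of class `"ap_haplotype_table"`.
#' @export
tabulate_pairs <- function(call_a, call_b) {
  stopifnot(length(call_a) == length(call_b))
  inf_a <- call_a %in% c("REF", "ALT")
  inf_b <- call_b %in% c("REF", "ALT")
  conflict <- call_a == "AMBIGUOUS" | call_b == "AMBIGUOUS"
  both <- inf_a & inf_b & !conflict
  tab <- list(
    n_rr = sum(both & call_a == "REF" & call_b == "REF"),
    n_ra = sum(both & call_a == "REF" & call_b == "ALT"),
    n_ar = sum(both & call_a == "ALT" & call_b == "REF"),
    n_aa = sum(both & call_a == "ALT" & call_b == "ALT"),
    n_site_a_only = sum(!conflict & inf_a & !inf_b),
    n_site_b_only = sum(!conflict & !inf_a & inf_b),
    n_uninformative = sum(!conflict & !inf_a & !inf_b),
    n_conflict = sum(conflict))
  haplotype_table(tab)
}

#' Construct a haplotype configuration table from counts
#'
#' @param counts Named list/vector with `n_rr`, `n_ra`, `n_ar`, `n_aa`
#'   and optionally `n_site_a_only`, `n_site_b_only`,
#'   `n_uninformative`, `n_conflict` (default 0).
#' @return An `"ap_haplotype_table"`.
#' @export
haplotype_table <- function(counts) {
  fields <- c("n_rr", "n_ra", "n_ar", "n_aa",
              "n_site_a_only", "n_site_b_only", "n_uninformative",
              "n_conflict")
  tab <- stats::setNames(as.list(integer(8)), fields)
  for (f in names(counts)) {
    if (!f %in% fields) stop("unknown table field: ", f)
    v <- as.integer(counts[[f]])
    if (is.na(v) || v < 0L) stop("negative or missing count: ", f)
    tab[[f]] <- v
  }
  tab$n_informative <- tab$n_rr + tab$n_ra + tab$n_ar + tab$n_aa
  structure(tab, class = "ap_haplotype_table")
}

#' @export
print.ap_haplotype_table <- function(x, ...) {
  cat("<haplotype table>        site B\n")
  cat(sprintf("                REF      ALT\n"))
  cat(sprintf("  site A REF %5d    %5d\n", x$n_rr, x$n_ra))
  cat(sprintf("         ALT %5d    %5d\n", x$n_ar, x$n_aa))
  cat(sprintf("  A only %d | B only %d | uninformative %d | conflict %d\n",
              x$n_site_a_only, x$n_site_b_only, x$n_uninformative,
              x$n_conflict))
  invisible(x)
}

#' Call cis/trans phase from a haplotype configuration table
#'
#' Cis support is `n_rr + n_aa`, trans support `n_ra + n_ar`.  With at
#' least `min_informative` double-informative pairs, the configuration
#' whose support fraction reaches `min_support_fraction` is called;
#' otherwise the call is `AMBIGUOUS`.  A two-sided exact binomial
#' p-value against a symmetric 0.5 null (the probability of the
#' observed minority count or more extreme) is reported for
#' transparency; it does not drive the call.
#'
#' @param table An `"ap_haplotype_table"`.
#' @param min_informative Minimum double-informative pairs for any call
#'   (default 10).
#' @param min_support_fraction Minimum majority support fraction
#'   (default 0.9).
#' @return An object of class `"ap_phase_call"`: `configuration`
#'   (`CIS`/`TRANS`/`AMBIGUOUS`/`INSUFFICIENT_DATA`),
#'   `support_fraction`, `p_value`, `cis_support`, `trans_support`,
#'   `table`.
#' @export
call_phase <- function(table, min_informative = 10L,
                       min_support_fraction = 0.9) {
  stopifnot(inherits(table, "ap_haplotype_table"))
  cis <- table$n_rr + table$n_aa
  trans <- table$n_ra + table$n_ar
  n <- cis + trans
  if (n < min_informative) {
    config <- "INSUFFICIENT_DATA"
    support <- if (n > 0) max(cis, trans) / n else NA_real_
    p <- NA_real_
  } else {
    support <- max(cis, trans) / n
    config <- if (support >= min_support_fraction) {
      if (cis >= trans) "CIS" else "TRANS"
    } else "AMBIGUOUS"
    p <- stats::binom.test(min(cis, trans), n, p = 0.5)$p.value
  }
  structure(list(configuration = config, support_fraction = support,
                 p_value = p, cis_support = cis, trans_support = trans,
                 min_informative = as.integer(min_informative),
                 min_support_fraction = min_support_fraction,
                 table = table),
            class = "ap_phase_call")
}

#' @export
print.ap_phase_call <- function(x, ...) {
  cat(sprintf("<phase call> %s (cis %d, trans %d, support %.3f, p = %.3g)\n",
              x$configuration, x$cis_support, x$trans_support,
              x$support_fraction, x$p_value))
  invisible(x)
}

#' Summarize a phase-analysis run
#'
#' Collects the run-level metrics mirrored from targeted amplicon phase
#' analyses: total and deduplicated pair counts, per-site informative
#' pair counts and allele frequencies, the fraction of pairs
#' informative at both sites, and the phase call.
#'
#' @param n_raw_pairs Input pair count before deduplication.
#' @param dedup_stats Stats record from [dedup_pairs()] (or `NULL` when
#'   deduplication was skipped).
#' @param table Post-dedup `"ap_haplotype_table"`.
#' @param site_counts List of two [site_allele_counts()] records
#'   (site A, site B), post-dedup.
#' @param phase An `"ap_phase_call"`.
#' @param params Optional named list of effective parameters to echo.
#' @return An object of class `"ap_run_summary"` (a named list).
#' @export
summarize_run <- function(n_raw_pairs, dedup_stats, table, site_counts,
                          phase, params = list()) {
  stopifnot(inherits(table, "ap_haplotype_table"),
            inherits(phase, "ap_phase_call"))
  n_kept <- if (is.null(dedup_stats)) n_raw_pairs else dedup_stats$n_kept
  inf_a <- table$n_informative + table$n_site_a_only
  inf_b <- table$n_informative + table$n_site_b_only
  total_tab <- table$n_informative + table$n_site_a_only +
    table$n_site_b_only + table$n_uninformative + table$n_conflict
  structure(list(
    n_raw_pairs = n_raw_pairs,
    n_kept_pairs = n_kept,
    n_duplicates_removed = if (is.null(dedup_stats)) 0L
                           else dedup_stats$n_removed,
    dedup_method = if (is.null(dedup_stats)) "none"
                   else dedup_stats$method,
    n_informative_a = inf_a,
    n_informative_b = inf_b,
    n_informative_both = table$n_informative,
    both_site_fraction = if (total_tab > 0)
      table$n_informative / total_tab else 0,
    site_counts = site_counts,
    table = table,
    phase = phase,
    params = params),
    class = "ap_run_summary")
}

#' @export
print.ap_run_summary <- function(x, ...) {
  cat(sprintf("<run summary> %d pairs (%d after dedup, %d duplicates removed)\n",
              x$n_raw_pairs, x$n_kept_pairs, x$n_duplicates_removed))
  cat(sprintf("  informative: A %d, B %d, both %d (fraction %.3f)\n",
              x$n_informative_a, x$n_informative_b, x$n_informative_both,
              x$both_site_fraction))
  for (sc in x$site_counts)
    cat(sprintf("  site %s: ref %d, alt %d (alt frequency %.3f)\n",
                sc$site, sc$n_ref, sc$n_alt,
                if (sc$depth > 0) sc$n_alt / sc$depth else NA))
  print(x$phase)
  invisible(x)
}
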