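## Captured-vs-missed stratification of a reference peak set, the Welch
## comparisons run on the strata, and the qPCR relative-quantification
## helper.

#' Partition reference peaks by query capture
#'
#' Splits the reference set into peaks overlapped (>= 1 bp) by the query
#' ("captured") and the rest ("missed"). The partition reconciles exactly
#' with [capture()]: `nrow(captured) == captured_ref`.
#'
#' @param reference nonempty [peak_set()].
#' @param query [peak_set()] on the same layout.
#' @param min_bp minimum overlap in bp.
#' @return object of class `StratifiedPeaks`: list with `captured` and
#'   `missed` PeakSets.
#' @export
stratify <- function(reference, query, min_bp = 1L) {
  if (nrow(reference) == 0L) stop("stratify needs a nonempty reference")
  layout <- attr(reference, "layout")
  hits <- overlap_pairs(as.data.frame(reference), as.data.frame(query),
                        layout, min_bp = min_bp)
  captured <- rep(FALSE, nrow(reference))
  captured[unique(hits$q)] <- TRUE
  structure(list(captured = peak_subset(reference, captured),
                 missed = peak_subset(reference, !captured)),
            class = "StratifiedPeaks")
}

#' @export
print.StratifiedPeaks <- function(x, ...) {
  cat(sprintf("StratifiedPeaks: %d captured / %d missed\n",
              nrow(x$captured), nrow(x$missed)))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return object of class `WelchResult`: list with t, df, p_two_sided,
#'   mean_a, mean_b, n_a, n_b.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test needs >= 2 observations per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("welch_t_test: both groups have zero variance")
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b)),
            class = "WelchResult")
}

#' @export
print.WelchResult <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4g, df = %.2f, p = %.3g (means %.4g vs %.4g)\n",
              x$t, x$df, x$p_two_sided, x$mean_a, x$mean_b))
  invisible(x)
}

quartile_summary <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(v), mean = mean(v), q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Compare peak significance between captured and missed strata
#'
#' Welch test on the `-log10(q)` values of captured versus missed
#' reference peaks — the test of whether the query preferentially captures
#' the most significant reference peaks. Peaks without a q-value are
#' dropped (warned when they are more than half of a stratum).
#'
#' @param strata a [stratify()] result.
#' @return list with `test` (a `WelchResult`, a = captured, b = missed)
#'   and `summary` (per-stratum n/mean/quartiles for box plots).
#' @export
compare_strata_significance <- function(strata) {
  vals <- function(ps) ps$neg_log10_q[!is.na(ps$neg_log10_q)]
  qc <- vals(strata$captured); qm <- vals(strata$missed)
  for (nm in c("captured", "missed")) {
    ps <- strata[[nm]]
    n_missing <- sum(is.na(ps$neg_log10_q))
    if (nrow(ps) > 0L && n_missing == nrow(ps))
      stop("all q-values missing in ", nm, " stratum")
    if (n_missing > nrow(ps) / 2)
      warning("> 50% of q-values missing in ", nm, " stratum")
  }
  test <- welch_t_test(qc, qm)
  list(test = test,
       summary = rbind(captured = quartile_summary(qc),
                       missed = quartile_summary(qm)))
}

#' Compare orthogonal read density between strata
#'
#' Coverage-adjusted density ([density_ratio()]) of an orthogonal fragment
#' set (e.g. ATAC-seq reads) over the captured and missed strata. When a
#' list of fragment sets is supplied, per-sample density pairs feed a
#' Welch test.
#'
#' @param strata a [stratify()] result with both strata nonempty.
#' @param orthogonal a [fragment_set()] or list of them.
#' @param layout a [genome_layout()].
#' @return list with `density_captured`, `density_missed` (per sample) and
#'   `test` (`WelchResult` over per-sample values; NULL for < 2 samples).
#' @export
compare_strata_density <- function(strata, orthogonal, layout) {
  if (nrow(strata$captured) == 0L || nrow(strata$missed) == 0L)
    stop("both strata must be nonempty")
  if (inherits(orthogonal, "FragmentSet")) orthogonal <- list(orthogonal)
  dc <- vapply(orthogonal, density_ratio, 0,
               regions = as.data.frame(strata$captured), layout = layout)
  dm <- vapply(orthogonal, density_ratio, 0,
               regions = as.data.frame(strata$missed), layout = layout)
  test <- if (length(orthogonal) >= 2L) welch_t_test(dc, dm) else NULL
  list(density_captured = dc, density_missed = dm, test = test)
}

#' qPCR relative quantification (2^-ddCt)
#'
#' `2^-(Ct_sample - Ct_control)`: the fold level of a sample relative to a
#' genomic-DNA control run in parallel, under perfect per-cycle doubling.
#'
#' @param ct_sample,ct_dna cycle-threshold values (finite, > 0); vectors
#'   are paired elementwise.
#' @return relative level(s), 1 when sample equals control.
#' @export
delta_delta_ct <- function(ct_sample, ct_dna) {
  if (any(!is.finite(ct_sample)) || any(!is.finite(ct_dna)) ||
      any(ct_sample <= 0) || any(ct_dna <= 0))
    stop("Ct values must be finite and positive")
  2^(-(ct_sample - ct_dna))
}

#' Triplicate qPCR summary
#'
#' Computes per-replicate `2^-ddCt` levels and their mean and sample SD
#' (n - 1 denominator), for error bars on the linear fold-level scale.
#'
#' @param ct_sample,ct_dna equal-length replicate Ct vectors.
#' @return list with `values`, `mean`, `sd`.
#' @export
delta_delta_ct_replicates <- function(ct_sample, ct_dna) {
  stopifnot(length(ct_sample) == length(ct_dna))
  v <- delta_delta_ct(ct_sample, ct_dna)
  list(values = v, mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0)
}
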