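## Capture benchmarking: the proportion of query peaks falling into
## reference peaks (precision), the proportion of reference peaks captured
## (recall), and their F1 combination. A query peak overlapping several
## reference peaks counts once toward tp; each reference peak counts once
## toward captured_ref — both quantities are proportions of peaks, so no
## double counting on either side.

#' Capture of a reference peak set by a query peak set
#'
#' Computes the benchmark contingency of a query peak set against a
#' reference set: `tp` query peaks overlapping at least one reference peak,
#' `fp` query peaks overlapping none, `captured_ref` reference peaks hit by
#' at least one query peak, `fn` reference peaks missed, plus
#' `precision = tp / (tp + fp)`, `recall = captured_ref / n_reference`,
#' and the F1 score `tp / (tp + (fp + fn) / 2)`.
#'
#' @param query,reference [peak_set()]s on a shared layout, already
#'   filtered.
#' @param min_bp minimum overlap in bp (default 1).
#' @return An object of class `CaptureResult` (a list of the counts and
#'   rates above).
#' @export
capture <- function(query, reference, min_bp = 1L) {
  layout <- attr(query, "layout")
  hits <- overlap_pairs(as.data.frame(query), as.data.frame(reference),
                        layout, min_bp = min_bp)
  n_query <- nrow(query)
  n_ref <- nrow(reference)
  tp <- length(unique(hits$q))
  fp <- n_query - tp
  captured_ref <- length(unique(hits$s))
  fn <- n_ref - captured_ref
  if (n_query == 0L) warning("empty query: precision undefined")
  if (n_ref == 0L) warning("empty reference: recall undefined")
  precision <- if (n_query > 0L) tp / n_query else NaN
  recall <- if (n_ref > 0L) captured_ref / n_ref else NaN
  res <- list(n_query = n_query, n_reference = n_ref, tp = tp, fp = fp,
              fn = fn, captured_ref = captured_ref,
              precision = precision, recall = recall)
  res$f1 <- f1_score(res)
  structure(res, class = "CaptureResult")
}

#' @export
print.CaptureResult <- function(x, ...) {
  cat(sprintf(paste0("CaptureResult: %d query vs %d reference peaks\n",
                     "  tp=%d fp=%d fn=%d captured_ref=%d\n",
                     "  precision=%.4f recall=%.4f F1=%.4f\n"),
              x$n_query, x$n_reference, x$tp, x$fp, x$fn, x$captured_ref,
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' @export
as.data.frame.CaptureResult <- function(x, ...) {
  data.frame(n_query = x$n_query, n_ref = x$n_reference, tp = x$tp,
             fp = x$fp, fn = x$fn, captured_ref = x$captured_ref,
             precision = x$precision, recall = x$recall, f1 = x$f1)
}

#' F1 score from capture counts
#'
#' `F1 = tp / (tp + (fp + fn) / 2)`, the weighted average of precision and
#' recall that ignores the true negatives occupying most of the genome.
#' When the query-side tp equals the reference-side captured count this is
#' algebraically `2PR / (P + R)`.
#'
#' @param result a `CaptureResult`, or any list with tp/fp/fn counts.
#' @return F1 in [0, 1]; NaN (with a warning) when all counts are zero.
#' @export
f1_score <- function(result) {
  tp <- result$tp; fp <- result$fp; fn <- result$fn
  if (tp + fp + fn == 0) {
    warning("tp + fp + fn = 0: F1 undefined")
    return(NaN)
  }
  tp / (tp + (fp + fn) / 2)
}

#' Precision/recall sweep across peak-calling thresholds
#'
#' Runs [capture()] for a family of query peak sets obtained at different
#' calling stringencies and tabulates the result, flagging thresholds that
#' meet a precision floor (default 0.75, i.e. "precision above 75%").
#'
#' @param queries named list of [peak_set()]s, one per threshold; names are
#'   the threshold labels.
#' @param reference reference [peak_set()].
#' @param min_bp minimum overlap in bp.
#' @param precision_floor precision that a threshold must reach to be
#'   flagged as high-precision.
#' @return data.frame with one row per threshold: threshold, the
#'   `CaptureResult` fields, and `meets_floor`.
#' @export
precision_recall_sweep <- function(queries, reference, min_bp = 1L,
                                   precision_floor = 0.75) {
  if (length(queries) == 0L) stop("need at least one threshold")
  labels <- names(queries)
  if (is.null(labels)) labels <- as.character(seq_along(queries))
  rows <- lapply(seq_along(queries), function(i) {
    cbind(data.frame(threshold = labels[i]),
          as.data.frame(capture(queries[[i]], reference, min_bp = min_bp)))
  })
  out <- do.call(rbind, rows)
  out$meets_floor <- !is.na(out$precision) & out$precision > precision_floor
  out
}

#' Capture at a fixed genomic base budget
#'
#' Truncates the query to its highest-scoring peaks, accumulating width
#' until the budget is first reached (the peak crossing the budget is kept
#' whole, no splitting), then runs [capture()]. This makes peak sets of
#' different breadth comparable at equal genomic coverage. Peaks are ranked
#' by `signal_value`, falling back to `score` when all signal values are
#' equal; ties break by genomic position for determinism.
#'
#' @param query,reference [peak_set()]s.
#' @param base_budget total bp of query coverage allowed (> 0).
#' @param min_bp minimum overlap in bp.
#' @return A `CaptureResult` for the truncated query; the truncated set is
#'   attached as attribute `truncated_query`.
#' @export
coverage_matched_capture <- function(query, reference, base_budget,
                                     min_bp = 1L) {
  if (!is.numeric(base_budget) || length(base_budget) != 1L || base_budget <= 0)
    stop("base_budget must be a positive number of bases")
  key <- query$signal_value
  if (length(key) && all(key == key[1L])) key <- query$score
  ord <- order(-key, match(query$chrom, attr(query, "layout")$chrom_names),
               query$start, query$end)
  cum <- cumsum(peak_widths(query)[ord])
  n_keep <- if (length(cum) == 0L) 0L else which(cum >= base_budget)[1L]
  if (is.na(n_keep)) n_keep <- length(cum)  # budget exceeds total coverage
  truncated <- peak_subset(query, sort(ord[seq_len(n_keep)]))
  res <- capture(truncated, reference, min_bp = min_bp)
  attr(res, "truncated_query") <- truncated
  res
}

#' Peak width summary
#'
#' @param peaks nonempty [peak_set()].
#' @return list with min/median/mean/max width and the full `widths`
#'   vector (for distribution plots).
#' @export
peak_width_stats <- function(peaks) {
  if (nrow(peaks) == 0L) stop("peak_width_stats needs a nonempty PeakSet")
  w <- peak_widths(peaks)
  list(n = length(w), min = min(w), median = stats::median(w),
       mean = mean(w), max = max(w), widths = w)
}

#' Peak multiplicity: overlapping a-peaks per b-peak
#'
#' For each peak of `b`, counts the peaks of `a` overlapping it (e.g. how
#' many narrow caller peaks fall in one broad caller peak), and summarises
#' over all b peaks and over b peaks with at least one overlap.
#'
#' @param a,b [peak_set()]s on one layout; `b` nonempty.
#' @param min_bp minimum overlap in bp.
#' @return list with mean/sd (all b peaks), conditional_mean/conditional_sd
#'   (b peaks with >= 1 overlap), and the per-b-peak `counts` vector.
#' @export
peak_multiplicity <- function(a, b, min_bp = 1L) {
  if (nrow(b) == 0L) stop("peak_multiplicity needs a nonempty b set")
  layout <- attr(b, "layout")
  hits <- overlap_pairs(as.data.frame(a), as.data.frame(b), layout,
                        min_bp = min_bp)
  counts <- tabulate(hits$s, nbins = nrow(b))
  pos <- counts[counts > 0L]
  list(mean = mean(counts), sd = stats::sd(counts),
       conditional_mean = if (length(pos)) mean(pos) else NaN,
       conditional_sd = if (length(pos)) stats::sd(pos) else NaN,
       counts = counts)
}

#' Binary peak-occupancy correlation between samples
#'
#' Merges the union of all input peak sets into disjoint bins, scores each
#' sample 0/1 per bin by overlap, and returns the Pearson correlation
#' matrix of the binary membership vectors, together with an average-linkage
#' clustering order on 1 - r for heatmap display.
#'
#' @param sets named list of >= 2 [peak_set()]s on one layout.
#' @param min_bp minimum overlap in bp.
#' @return list with `correlation` (samples x samples), `occupancy`
#'   (samples x bins 0/1 matrix), `bins` (the merged intervals) and
#'   `order` (clustering order; NULL if any correlation is undefined).
#' @export
occupancy_correlation <- function(sets, min_bp = 1L) {
  if (length(sets) < 2L) stop("occupancy_correlation needs >= 2 peak sets")
  labels <- names(sets)
  if (is.null(labels)) labels <- paste0("sample_", seq_along(sets))
  layout <- attr(sets[[1L]], "layout")
  bins <- merge_intervals(do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[, c("chrom", "start", "end")])), layout)
  occ <- matrix(0L, nrow = length(sets), ncol = nrow(bins),
                dimnames = list(labels, NULL))
  for (i in seq_along(sets)) {
    hits <- overlap_pairs(as.data.frame(sets[[i]]), bins, layout,
                          min_bp = min_bp)
    occ[i, unique(hits$s)] <- 1L
  }
  degenerate <- apply(occ, 1L, function(v) all(v == v[1L]))
  if (any(degenerate))
    warning("sample(s) with constant occupancy: ",
            paste(labels[degenerate], collapse = ", "),
            " have undefined correlations")
  cmat <- suppressWarnings(stats::cor(t(occ)))
  ord <- NULL
  if (!anyNA(cmat)) {
    hc <- stats::hclust(stats::as.dist(1 - cmat), method = "average")
    ord <- hc$order
  }
  list(correlation = cmat, occupancy = occ, bins = bins, order = ord)
}
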