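## Chromatin-state and promoter-window annotation of peak sets. A peak is
## assigned every state whose segments it overlaps, so one peak can fall
## into several categories and per-state percentages may sum past 100.

#' Assign chromatin states to peaks
#'
#' Each peak receives every state label whose segmentation segments it
#' overlaps by >= 1 bp. Peaks on chromosomes absent from the segmentation
#' (or overlapping no segment) get the explicit label "unannotated" so the
#' percentages stay interpretable.
#'
#' @param peaks a [peak_set()].
#' @param segmentation a [read_segmentation()] table (chrom/start/end/state).
#' @return object of class `StateAssignment`: list with `per_peak` (list of
#'   label vectors), `percent` (named per-state percentage of all peaks)
#'   and `mean_states_per_peak` (counting real states only).
#' @export
assign_states <- function(peaks, segmentation) {
  if (nrow(segmentation) == 0L) stop("segmentation must be nonempty")
  layout <- attr(peaks, "layout")
  n <- nrow(peaks)
  per_peak <- rep(list(character(0)), n)
  if (n > 0L) {
    hits <- overlap_pairs(as.data.frame(peaks), segmentation, layout)
    if (nrow(hits)) {
      lab <- split(segmentation$state[hits$s], hits$q)
      for (k in names(lab))
        per_peak[[as.integer(k)]] <- sort(unique(lab[[k]]))
    }
  }
  n_states <- lengths(per_peak)
  per_peak[n_states == 0L] <- list("unannotated")
  states <- sort(unique(c(attr(segmentation, "states"),
                          unlist(per_peak))))
  counts <- vapply(states, function(s)
    sum(vapply(per_peak, function(p) s %in% p, TRUE)), 0L)
  structure(list(per_peak = per_peak,
                 percent = if (n > 0L) 100 * counts / n else counts * 0,
                 mean_states_per_peak = if (n > 0L) mean(n_states) else NaN),
            class = "StateAssignment")
}

#' @export
print.StateAssignment <- function(x, ...) {
  cat("StateAssignment over", length(x$per_peak), "peak(s):\n")
  print(round(x$percent, 2))
  cat(sprintf("mean states per peak: %.3f\n", x$mean_states_per_peak))
  invisible(x)
}

#' Strand-aware promoter windows around TSS
#'
#' For a plus-strand TSS at position `t`, the window is
#' `[t - upstream_bp, t + downstream_bp)`; minus-strand windows are
#' mirrored. Windows are clipped to chromosome bounds and merged.
#'
#' @param tss data.frame with chrom/pos/strand (see [read_tss()];
#'   strand "." is treated as "+").
#' @param layout a [genome_layout()].
#' @param upstream_bp,downstream_bp window extents in bp (>= 0).
#' @return merged interval table of promoter windows.
#' @export
promoter_windows <- function(tss, layout, upstream_bp = 1500L,
                             downstream_bp = 1500L) {
  if (upstream_bp < 0 || downstream_bp < 0)
    stop("window extents must be nonnegative")
  if (nrow(tss) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  minus <- tss$strand == "-"
  start <- ifelse(minus, tss$pos - downstream_bp, tss$pos - upstream_bp)
  end <- ifelse(minus, tss$pos + upstream_bp, tss$pos + downstream_bp)
  start <- pmax(start, 0)
  end <- pmin(end, layout$chrom_lengths[tss$chrom])
  keep <- start < end
  merge_intervals(data.frame(chrom = tss$chrom[keep], start = start[keep],
                             end = end[keep]), layout)
}

#' Promoter overlap statistics of a peak set
#'
#' @param peaks a [peak_set()].
#' @param promoters nonempty interval table (merged internally).
#' @return list with `fraction_in_promoters` (peaks overlapping >= 1
#'   promoter / all peaks), `mean_peaks_per_promoter` and
#'   `n_promoters`.
#' @export
promoter_overlap_stats <- function(peaks, promoters) {
  if (nrow(promoters) == 0L) stop("promoters must be nonempty")
  layout <- attr(peaks, "layout")
  merged <- merge_intervals(promoters, layout)
  hits <- overlap_pairs(as.data.frame(peaks), merged, layout)
  frac <- if (nrow(peaks)) length(unique(hits$q)) / nrow(peaks) else NaN
  per_prom <- tabulate(hits$s, nbins = nrow(merged))
  list(fraction_in_promoters = frac,
       mean_peaks_per_promoter = mean(per_prom),
       n_promoters = nrow(merged))
}
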