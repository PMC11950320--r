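## Fragment-level signal-quality metrics. Membership rules: "reads in
## peaks" metrics (FRiP, specificity, density enrichment) use >= 1 bp
## fragment overlap with the merged region set; binned counts and
## enrichment matrices use the fragment midpoint, which assigns each
## fragment to exactly one bin.

frag_midpoints <- function(frags) floor((frags$start + frags$end) / 2)

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

## Count fragments overlapping (>= 1 bp) the union of a region table.
n_frags_in_regions <- function(frags, regions, layout) {
  if (nrow(regions) == 0L || nrow(frags) == 0L) return(0L)
  merged <- merge_intervals(regions, layout)
  length(unique(overlap_pairs(as.data.frame(frags), merged, layout)$q))
}

#' Fraction of fragments in peaks (FRiP)
#'
#' The canonical signal-to-noise metric: the fraction of a sample's
#' fragments overlapping (by >= 1 bp) the merged peak intervals. Duplicate
#' fragments are included unless `dedup = TRUE`.
#'
#' @param frags nonempty [fragment_set()].
#' @param peaks a [peak_set()]; empty peaks give FRiP 0.
#' @param dedup drop flagged duplicates before computing.
#' @return FRiP in [0, 1].
#' @export
frip <- function(frags, peaks, dedup = FALSE) {
  if (dedup) frags <- fragment_subset(frags, !frags$duplicate)
  if (nrow(frags) == 0L) stop("frip needs a nonempty FragmentSet")
  if (nrow(peaks) == 0L) return(0)
  layout <- attr(frags, "layout")
  n_frags_in_regions(frags, as.data.frame(peaks), layout) / nrow(frags)
}

#' Cross-mark specificity ratio
#'
#' Of the fragments falling in either mark's reference peaks, the
#' proportion falling in the same mark's peaks:
#' `n_same / (n_same + n_other)`. Fragments overlapping both peak sets
#' count toward both (their number is reported in attribute `n_both`).
#'
#' @param frags nonempty [fragment_set()].
#' @param same_mark reference peaks of the profiled modification.
#' @param other_mark reference peaks of the other modification.
#' @return ratio in [0, 1]; NaN with a warning when no fragment touches
#'   either set.
#' @export
specificity_ratio <- function(frags, same_mark, other_mark) {
  if (nrow(frags) == 0L) stop("specificity_ratio needs a nonempty FragmentSet")
  layout <- attr(frags, "layout")
  fdf <- as.data.frame(frags)
  in_same <- rep(FALSE, nrow(frags)); in_other <- rep(FALSE, nrow(frags))
  if (nrow(same_mark) > 0L)
    in_same[unique(overlap_pairs(fdf, merge_intervals(as.data.frame(same_mark), layout), layout)$q)] <- TRUE
  if (nrow(other_mark) > 0L)
    in_other[unique(overlap_pairs(fdf, merge_intervals(as.data.frame(other_mark), layout), layout)$q)] <- TRUE
  n_same <- sum(in_same); n_other <- sum(in_other)
  if (n_same + n_other == 0L) {
    warning("no fragments in either peak set: specificity undefined")
    return(structure(NaN, n_same = 0L, n_other = 0L, n_both = 0L))
  }
  structure(n_same / (n_same + n_other), n_same = n_same, n_other = n_other,
            n_both = sum(in_same & in_other))
}

#' Coverage-adjusted fragment density in a region set
#'
#' `(fraction of fragments in regions) / (fraction of genome bases in
#' regions)`; 1.0 means no enrichment over a uniform genome-wide spread.
#' Regions are merged internally so overlapping inputs are not counted
#' twice.
#'
#' @param frags nonempty [fragment_set()].
#' @param regions data.frame of intervals covering > 0 bases.
#' @param layout a [genome_layout()].
#' @return density ratio >= 0.
#' @export
density_ratio <- function(frags, regions, layout) {
  if (nrow(frags) == 0L) stop("density_ratio needs a nonempty FragmentSet")
  merged <- merge_intervals(regions, layout)
  region_bases <- sum(merged$end - merged$start)
  if (region_bases == 0) stop("regions cover zero bases")
  frac_frags <- n_frags_in_regions(frags, merged, layout) / nrow(frags)
  frac_bases <- region_bases / layout$total_bases
  frac_frags / frac_bases
}

## ---- binned counts ---------------------------------------------------------

bins_per_chrom <- function(layout, bin_bp) {
  ceiling(layout$chrom_lengths / bin_bp)
}

#' Genome-wide binned fragment counts
#'
#' Tiles each chromosome with `bin_bp` bins (last bin truncated) and counts
#' each sample's fragments by midpoint. Returns a `BinnedCounts` object:
#' a samples x bins matrix plus the bin coordinate table.
#'
#' @param samples list of [fragment_set()]s on one layout.
#' @param layout a [genome_layout()].
#' @param bin_bp bin size in bp (default 500).
#' @return object of class `BinnedCounts` with elements `matrix`,
#'   `bins` (chrom/start/end), `bin_bp`, `layout`.
#' @export
binned_counts <- function(samples, layout, bin_bp = 500L) {
  if (bin_bp < 1) stop("bin_bp must be >= 1")
  if (inherits(samples, "FragmentSet")) samples <- list(samples)
  labels <- vapply(samples, attr, "", "sample")
  npc <- bins_per_chrom(layout, bin_bp)
  offsets <- c(0, cumsum(npc))[seq_along(npc)]
  names(offsets) <- layout$chrom_names
  n_bins <- sum(npc)
  mat <- matrix(0L, nrow = length(samples), ncol = n_bins,
                dimnames = list(labels, NULL))
  for (i in seq_along(samples)) {
    fs <- samples[[i]]
    if (nrow(fs) == 0L) next
    idx <- offsets[fs$chrom] + floor(frag_midpoints(fs) / bin_bp) + 1
    mat[i, ] <- tabulate(idx, nbins = n_bins)
  }
  bins <- do.call(rbind, lapply(seq_along(layout$chrom_names), function(ci) {
    k <- npc[ci]
    data.frame(chrom = layout$chrom_names[ci],
               start = (seq_len(k) - 1) * bin_bp,
               end = pmin(seq_len(k) * bin_bp, layout$chrom_lengths[ci]))
  }))
  rownames(bins) <- NULL
  structure(list(matrix = mat, bins = bins, bin_bp = bin_bp, layout = layout),
            class = "BinnedCounts")
}

#' @export
print.BinnedCounts <- function(x, ...) {
  cat(sprintf("BinnedCounts: %d sample(s) x %d bins of %d bp\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_bp))
  invisible(x)
}

#' Quantile-normalize binned counts
#'
#' Classical quantile normalization across samples (each sample's sorted
#' vector is replaced by the cross-sample mean of order statistics; tied
#' ranks get the mean of the tied positions), followed by rounding to the
#' nearest integer (round-half-to-even).
#'
#' @param counts a [binned_counts()] object with >= 2 samples.
#' @return `BinnedCounts` with the normalized, integer-rounded matrix.
#' @export
quantile_normalize <- function(counts) {
  mat <- counts$matrix
  if (nrow(mat) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input")
    return(counts)
  }
  norm <- t(limma::normalizeQuantiles(t(mat), ties = TRUE))
  counts$matrix <- round(norm)
  dimnames(counts$matrix) <- dimnames(mat)
  counts
}

#' Pearson correlation of binned counts between samples
#'
#' @param counts a [binned_counts()] object with >= 2 samples.
#' @param restrict_to optional interval table; only bins overlapping these
#'   regions (>= 1 bp) enter the correlation.
#' @return samples x samples Pearson correlation matrix; zero-variance
#'   samples give NaN pairs with a warning.
#' @export
count_correlation <- function(counts, restrict_to = NULL) {
  mat <- counts$matrix
  if (nrow(mat) < 2L) stop("count_correlation needs >= 2 samples")
  if (!is.null(restrict_to)) {
    merged <- merge_intervals(restrict_to, counts$layout)
    keep <- unique(overlap_pairs(counts$bins, merged, counts$layout)$q)
    mat <- mat[, keep, drop = FALSE]
  }
  degenerate <- apply(mat, 1L, function(v) stats::sd(v) == 0)
  if (any(degenerate))
    warning("zero-variance sample(s): ",
            paste(rownames(mat)[degenerate], collapse = ", "))
  suppressWarnings(stats::cor(t(mat)))
}

#' Fingerprint curve of signal concentration
#'
#' Counts fragments in fixed-size genomic bins, ranks bins by count, and
#' reports the cumulative count along the rank order. The default
#' normalization divides the cumulative counts by the count of the
#' highest-scoring single bin (`mode = "max_bin"`); the conventional
#' cumulative-fraction-of-total curve is available as `mode = "total"`.
#'
#' @param frags nonempty [fragment_set()].
#' @param layout a [genome_layout()].
#' @param bin_bp bin size (default 1000).
#' @param mode "max_bin" (default) or "total".
#' @return data.frame with `rank_fraction` (x) and `cumulative` (y),
#'   both nondecreasing.
#' @export
fingerprint_curve <- function(frags, layout, bin_bp = 1000L,
                              mode = c("max_bin", "total")) {
  mode <- match.arg(mode)
  if (nrow(frags) == 0L) stop("fingerprint_curve needs fragments")
  bc <- binned_counts(list(frags), layout, bin_bp = bin_bp)
  v <- sort(as.numeric(bc$matrix[1L, ]))
  denom <- if (mode == "max_bin") max(v) else sum(v)
  data.frame(rank_fraction = seq_along(v) / length(v),
             cumulative = cumsum(v) / denom)
}

#' Anchor-centered fragment enrichment matrix
#'
#' Counts fragment midpoints in fixed-width columns of a +/- `window_bp`
#' window around 1-bp anchors (peak summits or TSS). Window parts falling
#' off a chromosome end contribute zero counts and the anchor is flagged
#' truncated.
#'
#' @param frags a [fragment_set()].
#' @param anchors data.frame with chrom/pos (1-bp anchor positions), e.g.
#'   from [peak_summits()] or [read_tss()].
#' @param window_bp half-window in bp (default 3000).
#' @param bin_bp column width in bp (default 50); must divide
#'   `2 * window_bp`.
#' @return list with `matrix` (anchors x columns), `column_mid` (column
#'   centers relative to anchor), `profile` (column means) and `truncated`
#'   (logical per anchor).
#' @export
enrichment_matrix <- function(frags, anchors, window_bp = 3000L, bin_bp = 50L) {
  if (nrow(anchors) == 0L) stop("enrichment_matrix needs anchors")
  n_col <- as.integer(2 * window_bp / bin_bp)
  if (n_col * bin_bp != 2 * window_bp)
    stop("bin_bp must divide 2 * window_bp")
  layout <- attr(frags, "layout")
  mat <- matrix(0L, nrow = nrow(anchors), ncol = n_col)
  mids <- frag_midpoints(frags)
  truncated <- logical(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$pos[i]
    lo <- a - window_bp; hi <- a + window_bp
    truncated[i] <- lo < 0 || hi > layout$chrom_lengths[anchors$chrom[i]]
    sel <- frags$chrom == anchors$chrom[i] & mids >= lo & mids < hi
    if (any(sel))
      mat[i, ] <- tabulate(floor((mids[sel] - lo) / bin_bp) + 1L, nbins = n_col)
  }
  list(matrix = mat,
       column_mid = seq(-window_bp + bin_bp / 2, window_bp - bin_bp / 2,
                        by = bin_bp),
       profile = colMeans(mat), truncated = truncated)
}

#' Summit anchor positions of a peak set
#'
#' `start + summit_offset` where a summit is recorded, otherwise the peak
#' midpoint.
#'
#' @param peaks a [peak_set()].
#' @return data.frame with chrom/pos.
#' @export
peak_summits <- function(peaks) {
  pos <- ifelse(is.na(peaks$summit_offset),
                floor((peaks$start + peaks$end) / 2),
                peaks$start + peaks$summit_offset)
  data.frame(chrom = peaks$chrom, pos = pos)
}

#' Downsample a fragment set
#'
#' Uniform sampling without replacement to exactly `n` fragments,
#' reproducible for a fixed seed.
#'
#' @param frags a [fragment_set()].
#' @param n target fragment count, `0 < n <= n_fragments`.
#' @param seed integer RNG seed.
#' @return Downsampled `FragmentSet`.
#' @export
downsample <- function(frags, n, seed) {
  if (n <= 0 || n > nrow(frags))
    stop("n must satisfy 0 < n <= n_fragments")
  idx <- with_seed(seed, sort(sample.int(nrow(frags), n)))
  fragment_subset(frags, idx)
}

#' Mark duplicate fragments
#'
#' Fragments with an identical (chrom, start, end) span are grouped; the
#' first of each group stays unflagged and the rest are flagged duplicate —
#' the paired-end fragment analogue of coordinate-based alignment duplicate
#' marking. Idempotent.
#'
#' @param frags a [fragment_set()].
#' @return list with `fragments` (flags set), `duplication_rate` (percent
#'   of fragments flagged) and `n_unique`.
#' @export
mark_duplicates <- function(frags) {
  key <- paste(frags$chrom, frags$start, frags$end, sep = ":")
  flag <- duplicated(key)
  out <- frags
  out$duplicate <- flag
  rate <- if (nrow(frags)) 100 * sum(flag) / nrow(frags) else 0
  list(fragments = out, duplication_rate = rate, n_unique = sum(!flag))
}

#' Fragment-length distribution QC
#'
#' Per-bp histogram of fragment widths, modal width(s), and the fraction of
#' sub-100 bp fragments (the short, sub-nucleosomal population).
#'
#' @param frags nonempty [fragment_set()].
#' @return list with `histogram` (data.frame width/count), `modes`,
#'   `fraction_short` (< 100 bp), `mean`, `median`.
#' @export
fragment_length_distribution <- function(frags) {
  if (nrow(frags) == 0L) stop("fragment_length_distribution needs fragments")
  w <- frags$end - frags$start
  tab <- table(w)
  hist <- data.frame(width = as.integer(names(tab)),
                     count = as.integer(tab))
  list(histogram = hist,
       modes = hist$width[hist$count == max(hist$count)],
       fraction_short = mean(w < 100),
       mean = mean(w), median = stats::median(w))
}
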