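#' Genome layout
#'
#' A genome layout names the chromosomes of the working genome and gives
#' their lengths in base pairs. All coordinates in the package are 0-based,
#' half-open (BED convention), and every interval container carries a layout
#' so that off-genome coordinates are caught early. Chromosome order is the
#' order given here (the order of a `chrom.sizes` file) and is used for
#' sorting throughout.
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths positive integer lengths (bp), one per chromosome.
#' @return An object of class `GenomeLayout` with elements `chrom_names`,
#'   `chrom_lengths` (named) and `total_bases`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) == 0L)
    stop("a genome layout needs at least one chromosome")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome names in layout: ",
         paste(unique(chrom_names[duplicated(chrom_names)]), collapse = ", "))
  if (length(chrom_lengths) != length(chrom_names))
    stop("chrom_names and chrom_lengths must have equal length")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != floor(chrom_lengths)))
    stop("chromosome lengths must be positive integers")
  names(chrom_lengths) <- chrom_names
  structure(
    list(chrom_names = chrom_names, chrom_lengths = chrom_lengths,
         total_bases = sum(chrom_lengths)),
    class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chrom_names), "chromosome(s),",
      format(x$total_bases, big.mark = ","), "bp total\n")
  invisible(x)
}

## ---- interval tables -------------------------------------------------------
## Intervals are plain data.frames with columns chrom/start/end (+ strand for
## stranded inputs). Validation against a layout is centralised here.

#' Build an interval table
#'
#' @param chrom,start,end vectors of equal length; 0-based half-open spans.
#' @param strand optional strand, one of "+", "-", "." (default ".").
#' @param layout optional [genome_layout()] to validate against.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
gintervals <- function(chrom, start, end, strand = ".", layout = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  if (!is.null(layout)) validate_intervals(df, layout)
  df
}

validate_intervals <- function(df, layout, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- !(df$chrom %in% layout$chrom_names)
  if (any(bad))
    stop(what, " on chromosome absent from layout: ",
         paste(unique(df$chrom[bad]), collapse = ", "))
  len <- layout$chrom_lengths[df$chrom]
  if (any(df$start < 0) || any(df$start >= df$end) || any(df$end > len))
    stop("invalid ", what, " coordinates: need 0 <= start < end <= chrom length")
  invisible(df)
}

## Sort rows by (layout chromosome order, start, end); stable.
sort_by_layout <- function(df, layout) {
  if (nrow(df) == 0L) return(df)
  ord <- order(match(df$chrom, layout$chrom_names), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Internal bridge to GenomicRanges (1-based closed coordinates).
as_granges <- function(df, layout) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = layout$chrom_names),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

## Index pairs (query_idx, subject_idx) of rows overlapping by >= min_bp.
overlap_pairs <- function(a, b, layout, min_bp = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(q = integer(0), s = integer(0)))
  hits <- GenomicRanges::findOverlaps(as_granges(a, layout),
                                      as_granges(b, layout),
                                      minoverlap = min_bp)
  data.frame(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

## ---- PeakSet ---------------------------------------------------------------

peak_columns <- c("chrom", "start", "end", "name", "score", "signal_value",
                  "neg_log10_p", "neg_log10_q", "summit_offset")

#' Peak set
#'
#' A `PeakSet` is a sorted table of peaks on a genome layout, optionally
#' carrying narrowPeak-style statistics: a display `score` (0-1000), a
#' `signal_value`, `-log10(p)`, `-log10(q)` and a summit offset from the
#' peak start. Missing statistics are `NA` (the narrowPeak `-1` sentinel on
#' disk). Provenance (sample label, caller label, dedup flag) travels as
#' attributes so that benchmark tables can be labelled.
#'
#' @param df data.frame with at least chrom/start/end; optional columns
#'   name, score, signal_value, neg_log10_p, neg_log10_q, summit_offset.
#' @param layout a [genome_layout()].
#' @param sample sample label.
#' @param caller caller label, e.g. "macs2-like", "seacr-like", "reference",
#'   "synthetic".
#' @param dedup logical; whether the peaks were called on deduplicated
#'   fragments.
#' @return An object of class `PeakSet` (a data.frame).
#' @export
peak_set <- function(df, layout, sample = "sample", caller = "synthetic",
                     dedup = FALSE) {
  stopifnot(inherits(layout, "GenomeLayout"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (is.null(df$name)) df$name <- if (n) paste0("peak_", seq_len(n)) else character(0)
  if (is.null(df$score)) df$score <- rep(0L, n)
  if (is.null(df$signal_value)) df$signal_value <- rep(0, n)
  if (is.null(df$neg_log10_p)) df$neg_log10_p <- rep(NA_real_, n)
  if (is.null(df$neg_log10_q)) df$neg_log10_q <- rep(NA_real_, n)
  if (is.null(df$summit_offset)) df$summit_offset <- rep(NA_real_, n)
  df <- df[, peak_columns]
  df$chrom <- as.character(df$chrom)
  validate_intervals(df, layout, "peak")
  w <- df$end - df$start
  so <- df$summit_offset
  if (any(!is.na(so) & (so < 0 | so >= w)))
    stop("summit_offset must lie in [0, peak width)")
  df <- sort_by_layout(df, layout)
  structure(df, class = c("PeakSet", "data.frame"), layout = layout,
            sample = sample, caller = caller, dedup = dedup)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peak(s) [sample=%s, caller=%s, dedup=%s]\n",
              nrow(x), attr(x, "sample"), attr(x, "caller"),
              attr(x, "dedup")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more\n")
  invisible(x)
}

## Rebuild a PeakSet from a row subset, keeping provenance.
peak_subset <- function(ps, keep) {
  df <- as.data.frame(ps)[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("PeakSet", "data.frame"), layout = attr(ps, "layout"),
            sample = attr(ps, "sample"), caller = attr(ps, "caller"),
            dedup = attr(ps, "dedup"))
}

peak_widths <- function(ps) ps$end - ps$start

## ---- FragmentSet -----------------------------------------------------------

#' Fragment set
#'
#' A `FragmentSet` holds the sequenced fragments of one sample: one genomic
#' span per fragment plus a logical `duplicate` flag (set by
#' [mark_duplicates()]). `read_multiplier` records how many reads one
#' fragment represents (2 for paired-end data); it affects only reporting
#' (`mapped_reads`), never the metrics, whose unit is the fragment.
#'
#' @param df data.frame with columns chrom/start/end (and optionally
#'   duplicate).
#' @param layout a [genome_layout()].
#' @param sample sample label.
#' @param read_multiplier reads per fragment (default 2, paired-end).
#' @return An object of class `FragmentSet` (a data.frame).
#' @export
fragment_set <- function(df, layout, sample = "sample", read_multiplier = 2) {
  stopifnot(inherits(layout, "GenomeLayout"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$duplicate)) df$duplicate <- rep(FALSE, nrow(df))
  df <- df[, c("chrom", "start", "end", "duplicate")]
  df$chrom <- as.character(df$chrom)
  validate_intervals(df, layout, "fragment")
  rownames(df) <- NULL
  structure(df, class = c("FragmentSet", "data.frame"), layout = layout,
            sample = sample, read_multiplier = read_multiplier)
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet: %d fragment(s), %d mapped reads [sample=%s]\n",
              nrow(x), mapped_reads(x), attr(x, "sample")))
  invisible(x)
}

#' Mapped-read count of a fragment set
#'
#' @param frags a [fragment_set()].
#' @return `n_fragments * read_multiplier`.
#' @export
mapped_reads <- function(frags) nrow(frags) * attr(frags, "read_multiplier")

fragment_subset <- function(fs, keep) {
  df <- as.data.frame(fs)[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("FragmentSet", "data.frame"), layout = attr(fs, "layout"),
            sample = attr(fs, "sample"),
            read_multiplier = attr(fs, "read_multiplier"))
}

## ---- interval algebra ------------------------------------------------------

#' Merge intervals into their union
#'
#' Collapses a set of intervals into the minimal sorted list of disjoint
#' intervals covering exactly the same bases. Touching-but-not-overlapping
#' intervals ([10,20) and [20,30)) are merged into one run, as in
#' `bedtools merge`.
#'
#' @param intervals data.frame with chrom/start/end.
#' @param layout a [genome_layout()].
#' @return data.frame of disjoint sorted intervals.
#' @export
merge_intervals <- function(intervals, layout) {
  validate_intervals(intervals, layout)
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  red <- GenomicRanges::reduce(as_granges(intervals, layout))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1,
             end = GenomicRanges::end(red))
}

#' Do two intervals overlap by at least `min_bp` bases?
#'
#' Strand is ignored; half-open adjacency ([10,20) vs [20,30)) is not an
#' overlap.
#'
#' @param a,b single-row interval data.frames (or list-like with chrom,
#'   start, end).
#' @param min_bp minimum overlap in bp (default 1).
#' @return logical scalar.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (!is.numeric(min_bp) || length(min_bp) != 1L || min_bp < 1)
    stop("min_bp must be a positive integer")
  if (a$chrom != b$chrom) return(FALSE)
  (min(a$end, b$end) - max(a$start, b$start)) >= min_bp
}

## ---- filters ---------------------------------------------------------------

#' Remove peaks overlapping a blacklist
#'
#' Drops every peak overlapping any blacklisted interval by at least one
#' base, the standard pre-analysis exclusion of artifact-prone regions. The
#' number removed is attached as attribute `n_removed`.
#'
#' @param peaks a [peak_set()].
#' @param blacklist data.frame of intervals on the same layout.
#' @return The filtered `PeakSet`, order preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  layout <- attr(peaks, "layout")
  validate_intervals(blacklist, layout, "blacklist interval")
  hit <- rep(FALSE, nrow(peaks))
  if (nrow(blacklist) > 0L && nrow(peaks) > 0L)
    hit[unique(overlap_pairs(as.data.frame(peaks), blacklist, layout)$q)] <- TRUE
  out <- peak_subset(peaks, !hit)
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Keep only records on an allowed chromosome list
#'
#' Used to drop mitochondrial and other non-standard chromosomes before
#' analysis. Works on both peak and fragment sets.
#'
#' @param x a `PeakSet` or `FragmentSet`.
#' @param allowed character vector of chromosome names (subset of layout).
#' @return Same class as `x`, restricted to `allowed`.
#' @export
filter_chromosomes <- function(x, allowed) {
  if (length(allowed) == 0L) stop("allowed chromosome list must be nonempty")
  layout <- attr(x, "layout")
  if (!all(allowed %in% layout$chrom_names))
    stop("allowed chromosomes not all present in layout")
  keep <- x$chrom %in% allowed
  if (inherits(x, "PeakSet")) peak_subset(x, keep) else fragment_subset(x, keep)
}

#' Filter fragments by length
#'
#' Retains fragments with `min_bp <= width < max_bp`. The exclusive upper
#' bound encodes "under 1000 bp"; short-fragment exclusion ("< 100 bp") is
#' `min_bp = 100`, which keeps width exactly 100.
#'
#' @param frags a [fragment_set()].
#' @param max_bp exclusive maximum width (default 1000).
#' @param min_bp inclusive minimum width (default 1).
#' @return Filtered `FragmentSet`.
#' @export
filter_fragment_length <- function(frags, max_bp = 1000L, min_bp = 1L) {
  if (min_bp > max_bp) stop("min_bp must not exceed max_bp")
  w <- frags$end - frags$start
  fragment_subset(frags, w >= min_bp & w < max_bp)
}

#' Pool fragment sets
#'
#' Concatenates the fragments of several samples into one set (the in-memory
#' analogue of merging alignment files across samples). The constituent
#' sample labels are recorded in the pooled sample label and in attribute
#' `pooled_from`.
#'
#' @param sets nonempty list of [fragment_set()]s on one layout.
#' @return Pooled `FragmentSet` with `n = sum(n_i)`.
#' @export
pool_fragments <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("pool_fragments needs a nonempty list of FragmentSets")
  stopifnot(all(vapply(sets, inherits, TRUE, "FragmentSet")))
  layout <- attr(sets[[1L]], "layout")
  labels <- vapply(sets, attr, "", "sample")
  df <- do.call(rbind, lapply(sets, as.data.frame))
  out <- fragment_set(df, layout,
                      sample = paste0("pooled(", paste(labels, collapse = "+"), ")"),
                      read_multiplier = attr(sets[[1L]], "read_multiplier"))
  attr(out, "pooled_from") <- labels
  out
}
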