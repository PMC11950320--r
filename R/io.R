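## Readers/writers for the BED-family formats the toolkit touches. All
## coordinates on disk are BED (0-based half-open), matching the in-memory
## convention, so parsing is column mapping plus validation. Writers are
## deterministic: fixed column order, "%.6g" reals, newline-terminated.

read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(trimws(lines))]
}

split_fields <- function(lines, n_expected, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_expected)
  if (length(bad))
    stop(sprintf("%s: line %d has %d column(s), expected >= %d",
                 path, bad[1L], nf[bad[1L]], n_expected))
  fields
}

num_field <- function(x, what, line, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric %s '%s'",
                 path, line[bad[1L]], what, x[bad[1L]]))
  v
}

fmt_num <- function(x) formatC(x, format = "g", digits = 6)

#' Read a chrom.sizes file into a genome layout
#'
#' @param path two-column whitespace-delimited file: chromosome name,
#'   length in bp. File order defines chromosome order.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0L) stop(path, ": empty chrom.sizes file")
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop(sprintf("%s: line %d has fewer than 2 columns", path, which(nf < 2L)[1L]))
  nm <- vapply(fields, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(len) | len != floor(len))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer chromosome length", path, bad[1L]))
  dup <- which(duplicated(nm))
  if (length(dup))
    stop(sprintf("%s: line %d: duplicate chromosome '%s'", path, dup[1L], nm[dup[1L]]))
  genome_layout(nm, len)
}

#' Write a genome layout as chrom.sizes
#' @param layout a [genome_layout()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  writeLines(paste(layout$chrom_names,
                   format(layout$chrom_lengths, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

dialect_ncol <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L, broadPeak = 9L)

#' Read a peak file
#'
#' Supports BED3, BED6, ENCODE narrowPeak (BED6+4: signal, -log10 p,
#' -log10 q, summit offset) and broadPeak (BED6+3, no summit). The `-1`
#' sentinel in statistical columns (and in the summit column) maps to
#' missing. Records on chromosomes absent from the layout are dropped with
#' a warning by default (`strict = TRUE` errors instead), since real peak
#' files routinely contain alt contigs.
#'
#' @param path tab-delimited peak file.
#' @param layout a [genome_layout()].
#' @param dialect one of "bed3", "bed6", "narrowPeak", "broadPeak".
#' @param sample,caller,dedup provenance labels for the resulting set.
#' @param strict error (TRUE) or drop-with-warning (FALSE, default) on
#'   off-layout chromosomes.
#' @return A sorted [peak_set()].
#' @export
read_peaks <- function(path, layout, dialect = c("narrowPeak", "broadPeak",
                                                 "bed6", "bed3"),
                       sample = basename(path), caller = "reference",
                       dedup = FALSE, strict = FALSE) {
  dialect <- match.arg(dialect)
  lines <- read_lines_checked(path)
  empty <- peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0)), layout,
                    sample = sample, caller = caller, dedup = dedup)
  if (length(lines) == 0L) return(empty)
  fields <- split_fields(lines, dialect_ncol[[dialect]], path)
  ln <- seq_along(lines)
  col <- function(i) vapply(fields, `[`, "", i)
  df <- data.frame(chrom = col(1L),
                   start = num_field(col(2L), "start", ln, path),
                   end = num_field(col(3L), "end", ln, path),
                   stringsAsFactors = FALSE)
  if (dialect != "bed3") {
    df$name <- col(4L)
    df$score <- num_field(col(5L), "score", ln, path)
  }
  if (dialect %in% c("narrowPeak", "broadPeak")) {
    df$signal_value <- num_field(col(7L), "signalValue", ln, path)
    p <- num_field(col(8L), "pValue", ln, path)
    q <- num_field(col(9L), "qValue", ln, path)
    df$neg_log10_p <- ifelse(p < 0, NA_real_, p)
    df$neg_log10_q <- ifelse(q < 0, NA_real_, q)
  }
  if (dialect == "narrowPeak") {
    s <- num_field(col(10L), "summit", ln, path)
    df$summit_offset <- ifelse(s < 0, NA_real_, s)
  }
  off <- !(df$chrom %in% layout$chrom_names)
  if (any(off)) {
    if (strict)
      stop(sprintf("%s: line %d: chromosome '%s' not in layout",
                   path, which(off)[1L], df$chrom[which(off)[1L]]))
    warning(sprintf("%s: dropped %d record(s) on off-layout chromosomes",
                    path, sum(off)))
    df <- df[!off, , drop = FALSE]
  }
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("%s: record with start >= end (%s:%g-%g)",
                 path, df$chrom[bad[1L]], df$start[bad[1L]], df$end[bad[1L]]))
  peak_set(df, layout, sample = sample, caller = caller, dedup = dedup)
}

#' Write a peak set
#'
#' narrowPeak/broadPeak writers clamp `score` to [0, 1000] (UCSC
#' convention) and encode missing statistics as `-1`.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @param dialect output dialect (see [read_peaks()]).
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "broadPeak",
                                                 "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(peaks)
  coords <- function() paste(df$chrom,
                             format(df$start, scientific = FALSE, trim = TRUE),
                             format(df$end, scientific = FALSE, trim = TRUE),
                             sep = "\t")
  lines <- switch(dialect,
    bed3 = coords(),
    {
      score <- pmin(pmax(round(df$score), 0), 1000)
      base6 <- paste(coords(), df$name, score, ".", sep = "\t")
      if (dialect == "bed6") base6 else {
        sentinel <- function(x) ifelse(is.na(x), "-1", fmt_num(x))
        b9 <- paste(base6, fmt_num(df$signal_value),
                    sentinel(df$neg_log10_p), sentinel(df$neg_log10_q),
                    sep = "\t")
        if (dialect == "broadPeak") b9 else
          paste(b9, ifelse(is.na(df$summit_offset), "-1",
                           format(df$summit_offset, scientific = FALSE, trim = TRUE)),
                sep = "\t")
      }
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read a fragment BED3 file
#'
#' One fragment per line; duplicate flags start unset.
#'
#' @param path BED3 file.
#' @param layout a [genome_layout()].
#' @param sample sample label.
#' @param read_multiplier reads per fragment (default 2, paired-end).
#' @param strict see [read_peaks()].
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, layout, sample = basename(path),
                           read_multiplier = 2, strict = FALSE) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0L)
    return(fragment_set(data.frame(chrom = character(0), start = numeric(0),
                                   end = numeric(0)), layout,
                        sample = sample, read_multiplier = read_multiplier))
  fields <- split_fields(lines, 3L, path)
  ln <- seq_along(lines)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = num_field(vapply(fields, `[`, "", 2L), "start", ln, path),
                   end = num_field(vapply(fields, `[`, "", 3L), "end", ln, path),
                   stringsAsFactors = FALSE)
  off <- !(df$chrom %in% layout$chrom_names)
  if (any(off)) {
    if (strict)
      stop(sprintf("%s: line %d: chromosome '%s' not in layout",
                   path, which(off)[1L], df$chrom[which(off)[1L]]))
    warning(sprintf("%s: dropped %d record(s) on off-layout chromosomes",
                    path, sum(off)))
    df <- df[!off, , drop = FALSE]
  }
  fragment_set(df, layout, sample = sample, read_multiplier = read_multiplier)
}

#' Write fragments as BED3
#' @param frags a [fragment_set()].
#' @param path output path.
#' @param dedup write only non-duplicate fragments.
#' @export
write_fragments <- function(frags, path, dedup = FALSE) {
  df <- as.data.frame(frags)
  if (dedup) df <- df[!df$duplicate, , drop = FALSE]
  writeLines(paste(df$chrom,
                   format(df$start, scientific = FALSE, trim = TRUE),
                   format(df$end, scientific = FALSE, trim = TRUE), sep = "\t"),
             path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' @param path 4-column bedGraph (chrom, start, end, value).
#' @param layout a [genome_layout()].
#' @return data.frame of sorted, non-overlapping steps with columns
#'   chrom/start/end/value.
#' @export
read_bedgraph <- function(path, layout) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  fields <- split_fields(lines, 4L, path)
  ln <- seq_along(lines)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = num_field(vapply(fields, `[`, "", 2L), "start", ln, path),
                   end = num_field(vapply(fields, `[`, "", 3L), "end", ln, path),
                   value = num_field(vapply(fields, `[`, "", 4L), "value", ln, path),
                   stringsAsFactors = FALSE)
  validate_intervals(df, layout, "bedGraph step")
  df <- sort_by_layout(df, layout)
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  if (nrow(df) > 1L && any(same & df$start[-1L] < df$end[-nrow(df)]))
    stop(path, ": overlapping bedGraph steps")
  df
}

#' Write a coverage track as bedGraph
#' @param track data.frame with chrom/start/end/value.
#' @param path output path.
#' @param layout a [genome_layout()] used for sorting.
#' @export
write_bedgraph <- function(track, path, layout) {
  track <- sort_by_layout(track, layout)
  writeLines(paste(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   fmt_num(track$value), sep = "\t"), path)
  invisible(path)
}

#' Read a chromatin-state segmentation (BED4)
#'
#' @param path BED4 file; column 4 is the state label.
#' @param layout a [genome_layout()].
#' @return data.frame of sorted segments (chrom/start/end/state) with the
#'   label set in attribute `states`.
#' @export
read_segmentation <- function(path, layout) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), state = character(0))
    attr(out, "states") <- character(0)
    return(out)
  }
  fields <- split_fields(lines, 4L, path)
  ln <- seq_along(lines)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   start = num_field(vapply(fields, `[`, "", 2L), "start", ln, path),
                   end = num_field(vapply(fields, `[`, "", 3L), "end", ln, path),
                   state = vapply(fields, `[`, "", 4L),
                   stringsAsFactors = FALSE)
  validate_intervals(df, layout, "segment")
  df <- sort_by_layout(df, layout)
  attr(df, "states") <- sort(unique(df$state))
  df
}

#' Read TSS anchors from BED6
#'
#' The interval start is taken as the 1-bp transcription start site; strand
#' comes from column 6.
#'
#' @param path BED6 file.
#' @param layout a [genome_layout()].
#' @return data.frame with chrom/pos/strand.
#' @export
read_tss <- function(path, layout) {
  lines <- read_lines_checked(path)
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      strand = character(0)))
  fields <- split_fields(lines, 6L, path)
  ln <- seq_along(lines)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1L),
                   pos = num_field(vapply(fields, `[`, "", 2L), "start", ln, path),
                   strand = vapply(fields, `[`, "", 6L),
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-", ".")))
    stop(path, ": strand column must be one of '+', '-', '.'")
  df
}
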