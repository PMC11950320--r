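# Independent brute-force oracles and fixture builders. The oracles work
# per base or per pair on toy genomes and never call the interval machinery
# they are used to check.

toy_layout <- function(len = 1e4, n = 1L, names = paste0("chrT", seq_len(n)))
  genome_layout(names, rep(len, n))

rand_intervals <- function(n, layout, max_w = 500L) {
  ci <- sample.int(length(layout$chrom_names), n, replace = TRUE)
  len <- layout$chrom_lengths[ci]
  w <- sample.int(max_w, n, replace = TRUE)
  start <- floor(stats::runif(n) * (len - w))
  data.frame(chrom = layout$chrom_names[ci], start = start, end = start + w,
             stringsAsFactors = FALSE)
}

rand_peakset <- function(n, layout, ...) {
  df <- rand_intervals(n, layout)
  df$signal_value <- stats::runif(n, 0, 10)
  df$neg_log10_q <- stats::rexp(n, 0.2)
  peak_set(df, layout, ...)
}

rand_fragset <- function(n, layout, ...) {
  fragment_set(rand_intervals(n, layout, max_w = 300L), layout, ...)
}

# Per-base union oracle: paint a logical vector per chromosome, read back
# the TRUE runs.
oracle_union <- function(intervals, layout) {
  pieces <- lapply(layout$chrom_names, function(cn) {
    cov <- logical(layout$chrom_lengths[[cn]])
    sub <- intervals[intervals$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      cov[(sub$start[i] + 1):sub$end[i]] <- TRUE
    if (!any(cov)) return(NULL)
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(chrom = cn, start = starts[r$values], end = ends[r$values],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  rownames(out) <- NULL
  out
}

# All-pairs overlap oracle: logical matrix [i, j] of whether interval i of
# `a` overlaps interval j of `b` by >= min_bp.
oracle_overlap_matrix <- function(a, b, min_bp = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(matrix(FALSE, nrow(a), nrow(b)))
  same <- outer(a$chrom, b$chrom, "==")
  ov <- outer(a$end, b$end, pmin) - outer(a$start, b$start, pmax)
  same & (ov >= min_bp)
}

oracle_capture <- function(query, reference, min_bp = 1L) {
  m <- oracle_overlap_matrix(as.data.frame(query), as.data.frame(reference),
                             min_bp)
  tp <- sum(rowSums(m) > 0)
  captured_ref <- sum(colSums(m) > 0)
  list(tp = tp, fp = nrow(query) - tp, captured_ref = captured_ref,
       fn = nrow(reference) - captured_ref)
}
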