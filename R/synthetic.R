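## Synthetic benchmark generator. Emulates the structure of a real
## benchmarking study on a desk-scale toy genome: a reference peak set with
## per-peak significance, query peak sets whose capture probability rises
## with reference significance (logistic model), and fragment sets with a
## configured FRiP, duplication rate and bimodal fragment-length mixture
## (~180 bp nucleosomal mode plus a sub-100 bp mode). Every generator is
## deterministic for a fixed seed, and the ground truth (capture flags,
## in-peak flags) is returned so metrics can be validated against it.

#' Synthetic benchmark configuration
#'
#' Defaults describe the emulated study conditions: a 6 Mb toy genome,
#' 1,000 reference peaks of lognormal width (median ~800 bp) carrying
#' exponential -log10(q) significance, a logistic capture model on
#' -log10(q), 20,000 fragments at FRiP 0.40 with a 60% duplication rate,
#' and a 0.2/0.8 short/nucleosomal fragment-length mixture.
#'
#' @param n_chroms,chrom_len toy genome shape (chromosomes x bp).
#' @param n_ref_peaks reference peak count.
#' @param width_meanlog,width_sdlog lognormal peak-width parameters
#'   (log-bp).
#' @param q_rate,q_offset exponential rate and offset of the reference
#'   -log10(q) distribution.
#' @param capture_intercept,capture_slope logistic capture model:
#'   `P(captured) = plogis(intercept + slope * neg_log10_q)`.
#' @param jitter_sd boundary jitter SD (bp) applied to captured copies.
#' @param n_false_query_peaks background query peaks overlapping no
#'   reference peak.
#' @param n_fragments total fragments (uniques + duplicate copies).
#' @param target_frip fraction of fragments placed inside peaks.
#' @param target_duplication fraction of fragments that are duplicate
#'   copies, in [0, 1).
#' @param frag_long_mean,frag_long_sd nucleosomal length mode (bp).
#' @param frag_short_mean,frag_short_sd short length mode (bp).
#' @param frag_short_weight mixture weight of the short mode.
#' @param open_chromatin_bias placement-weight multiplier (>= 1) for the
#'   accessible peak subset.
#' @param accessible_fraction fraction of peaks designated accessible.
#' @param seed integer RNG seed.
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_chroms = 3L, chrom_len = 2e6,
                             n_ref_peaks = 1000L,
                             width_meanlog = log(800), width_sdlog = 0.45,
                             q_rate = 0.2, q_offset = 2,
                             capture_intercept = -2, capture_slope = 0.5,
                             jitter_sd = 50,
                             n_false_query_peaks = 200L,
                             n_fragments = 20000L,
                             target_frip = 0.40,
                             target_duplication = 0.60,
                             frag_long_mean = 180, frag_long_sd = 25,
                             frag_short_mean = 60, frag_short_sd = 15,
                             frag_short_weight = 0.2,
                             open_chromatin_bias = 1,
                             accessible_fraction = 0.5,
                             seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms), chrom_len = chrom_len,
              n_ref_peaks = as.integer(n_ref_peaks),
              width_meanlog = width_meanlog, width_sdlog = width_sdlog,
              q_rate = q_rate, q_offset = q_offset,
              capture_intercept = capture_intercept,
              capture_slope = capture_slope, jitter_sd = jitter_sd,
              n_false_query_peaks = as.integer(n_false_query_peaks),
              n_fragments = as.integer(n_fragments),
              target_frip = target_frip,
              target_duplication = target_duplication,
              frag_long_mean = frag_long_mean, frag_long_sd = frag_long_sd,
              frag_short_mean = frag_short_mean, frag_short_sd = frag_short_sd,
              frag_short_weight = frag_short_weight,
              open_chromatin_bias = open_chromatin_bias,
              accessible_fraction = accessible_fraction,
              seed = as.integer(seed))
  if (cfg$target_frip < 0 || cfg$target_frip > 1)
    stop("target_frip must be in [0, 1]")
  if (cfg$target_duplication < 0 || cfg$target_duplication >= 1)
    stop("target_duplication must be in [0, 1)")
  if (cfg$frag_short_weight < 0 || cfg$frag_short_weight > 1)
    stop("frag_short_weight must be in [0, 1]")
  if (cfg$open_chromatin_bias < 1)
    stop("open_chromatin_bias must be >= 1")
  structure(cfg, class = c("SyntheticConfig", "list"))
}

#' Toy genome layout of a configuration
#' @param config a [synthetic_config()].
#' @return A [genome_layout()] with chromosomes "chr1", "chr2", ...
#' @export
synthetic_layout <- function(config) {
  genome_layout(paste0("chr", seq_len(config$n_chroms)),
                rep(config$chrom_len, config$n_chroms))
}

## Place k non-overlapping intervals of the given widths uniformly on
## [0, len) with >= min_gap between neighbours. Uniform over feasible
## placements via the spacings construction.
place_nonoverlapping <- function(widths, len, min_gap = 1000) {
  k <- length(widths)
  if (k == 0L) return(numeric(0))
  slack <- len - sum(widths) - (k - 1) * min_gap
  if (slack <= 0)
    stop("peaks cannot be placed without overlap; use a larger layout ",
         "or fewer/narrower peaks")
  cuts <- sort(stats::runif(k))
  extra <- diff(c(0, cuts)) * slack
  starts <- numeric(k)
  starts[1L] <- extra[1L]
  if (k > 1L)
    for (i in 2:k)
      starts[i] <- starts[i - 1L] + widths[i - 1L] + min_gap + extra[i]
  floor(starts)
}

#' Generate a synthetic reference peak set
#'
#' Places `n_ref_peaks` non-overlapping peaks uniformly (>= 1 kb gaps)
#' across the toy genome, with lognormal widths and exponential
#' `-log10(q)` significance per the configuration. `signal_value` equals
#' the significance; the summit sits at the peak centre.
#'
#' @param config a [synthetic_config()].
#' @return A [peak_set()] with caller label "reference".
#' @export
generate_reference <- function(config) {
  layout <- synthetic_layout(config)
  with_seed(config$seed, {
    n <- config$n_ref_peaks
    if (n == 0L)
      return(peak_set(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0)),
                      layout, sample = "synthetic_reference",
                      caller = "reference"))
    # apportion peaks to chromosomes proportionally to length
    share <- layout$chrom_lengths / layout$total_bases
    n_per <- floor(n * share)
    rem <- n - sum(n_per)
    if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1
    widths <- pmax(100, round(stats::rlnorm(n, config$width_meanlog,
                                            config$width_sdlog)))
    rows <- list()
    w_off <- 0L
    for (ci in seq_along(layout$chrom_names)) {
      k <- n_per[ci]
      if (k == 0L) next
      w <- widths[w_off + seq_len(k)]
      w_off <- w_off + k
      starts <- place_nonoverlapping(w, layout$chrom_lengths[ci])
      rows[[ci]] <- data.frame(chrom = layout$chrom_names[ci],
                               start = starts, end = starts + w)
    }
    df <- do.call(rbind, rows)
    df$neg_log10_q <- config$q_offset + stats::rexp(n, config$q_rate)
    df$neg_log10_p <- df$neg_log10_q + 0.3  # p always at least as significant
    df$signal_value <- df$neg_log10_q
    df$score <- pmin(1000, round(10 * df$neg_log10_q))
    df$summit_offset <- floor((df$end - df$start) / 2)
    df$name <- paste0("ref_", seq_len(n))
    peak_set(df, layout, sample = "synthetic_reference", caller = "reference")
  })
}

## Rejection-sample n intervals with the configured width distribution that
## avoid a forbidden region set.
sample_background_peaks <- function(n, config, layout, forbidden) {
  out <- NULL
  tries <- 0L
  while (is.null(out) || nrow(out) < n) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("could not place background peaks clear of the reference; ",
           "use a larger layout")
    m <- max(2L * n, 32L)
    ci <- sample.int(length(layout$chrom_names), m, replace = TRUE,
                     prob = layout$chrom_lengths)
    w <- pmax(100, round(stats::rlnorm(m, config$width_meanlog,
                                       config$width_sdlog)))
    start <- floor(stats::runif(m) * (layout$chrom_lengths[ci] - w))
    cand <- data.frame(chrom = layout$chrom_names[ci], start = start,
                       end = start + w)
    cand <- cand[cand$start >= 0, , drop = FALSE]
    if (nrow(forbidden) > 0L && nrow(cand) > 0L) {
      hit <- unique(overlap_pairs(cand, forbidden, layout)$q)
      if (length(hit)) cand <- cand[-hit, , drop = FALSE]
    }
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic query peak set with known capture truth
#'
#' Each reference peak is captured with probability
#' `plogis(intercept + slope * neg_log10_q)`; captured peaks are copied
#' with Gaussian boundary jitter. `n_false_query_peaks` additional peaks
#' are placed in the background, overlapping no reference peak. The
#' per-reference capture flags are the generator's ground truth.
#'
#' @param config a [synthetic_config()].
#' @param reference nonempty [peak_set()] from [generate_reference()].
#' @return list with `query` (a `PeakSet`) and `truth` (logical vector,
#'   one flag per reference peak).
#' @export
generate_query <- function(config, reference) {
  if (nrow(reference) == 0L) stop("reference must be nonempty")
  layout <- attr(reference, "layout")
  with_seed(config$seed + 1L, {
    p_cap <- stats::plogis(config$capture_intercept +
                           config$capture_slope * reference$neg_log10_q)
    captured <- stats::runif(nrow(reference)) < p_cap
    cap <- as.data.frame(reference)[captured, , drop = FALSE]
    if (nrow(cap) > 0L) {
      cap$start <- cap$start + round(stats::rnorm(nrow(cap), 0, config$jitter_sd))
      cap$end <- cap$end + round(stats::rnorm(nrow(cap), 0, config$jitter_sd))
      cap$start <- pmax(cap$start, 0)
      cap$end <- pmin(cap$end, layout$chrom_lengths[cap$chrom])
      bad <- cap$start >= cap$end
      cap$end[bad] <- cap$start[bad] + 100
      cap$end <- pmin(cap$end, layout$chrom_lengths[cap$chrom])
    }
    keep_cols <- c("chrom", "start", "end", "neg_log10_q", "neg_log10_p",
                   "signal_value", "score")
    cap <- cap[, keep_cols, drop = FALSE]
    n_false <- config$n_false_query_peaks
    if (n_false > 0L) {
      bg <- sample_background_peaks(n_false, config, layout,
                                    as.data.frame(reference))
      bg$neg_log10_q <- config$q_offset +
        stats::rexp(n_false, config$q_rate * 2)  # false peaks weaker
      bg$neg_log10_p <- bg$neg_log10_q + 0.3
      bg$signal_value <- bg$neg_log10_q
      bg$score <- pmin(1000, round(10 * bg$neg_log10_q))
      df <- rbind(cap, bg)
    } else df <- cap
    if (nrow(df)) {
      df$summit_offset <- floor((df$end - df$start) / 2)
      df$name <- paste0("query_", seq_len(nrow(df)))
    }
    list(query = peak_set(df, layout, sample = "synthetic_query",
                          caller = "synthetic"),
         truth = captured)
  })
}

## Draw n fragment lengths from the bimodal mixture, truncated at >= 20 bp.
sample_fragment_lengths <- function(n, config) {
  short <- stats::runif(n) < config$frag_short_weight
  len <- ifelse(short,
                stats::rnorm(n, config$frag_short_mean, config$frag_short_sd),
                stats::rnorm(n, config$frag_long_mean, config$frag_long_sd))
  pmax(20, round(len))
}

## Sample n unique fragments: in-peak (midpoint uniform inside a
## width/bias-weighted random peak) or background (whole fragment clear of
## all peaks, so the realised FRiP is the in-peak fraction exactly).
sample_unique_fragments <- function(n, config, peaks, layout, accessible) {
  merged_peaks <- if (nrow(peaks)) {
    merge_intervals(as.data.frame(peaks), layout)
  } else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  in_peak <- stats::runif(n) < config$target_frip & nrow(peaks) > 0L
  n_in <- sum(in_peak); n_bg <- n - n_in
  rows_in <- NULL
  if (n_in > 0L) {
    wts <- (peaks$end - peaks$start) *
      ifelse(accessible, config$open_chromatin_bias, 1)
    pk <- sample.int(nrow(peaks), n_in, replace = TRUE, prob = wts)
    mid <- floor(peaks$start[pk] +
                 stats::runif(n_in) * (peaks$end[pk] - peaks$start[pk]))
    len <- sample_fragment_lengths(n_in, config)
    start <- mid - floor(len / 2)
    end <- start + len
    chrom <- peaks$chrom[pk]
    start <- pmax(start, 0)
    end <- pmin(end, layout$chrom_lengths[chrom])
    rows_in <- data.frame(chrom = chrom, start = start, end = end)
  }
  rows_bg <- NULL
  if (n_bg > 0L) {
    got <- NULL
    tries <- 0L
    while (is.null(got) || nrow(got) < n_bg) {
      tries <- tries + 1L
      if (tries > 500L) stop("background fragment sampling failed; peaks ",
                             "cover too much of the layout")
      m <- max(ceiling(1.5 * n_bg), 64L)
      len <- sample_fragment_lengths(m, config)
      ci <- sample.int(length(layout$chrom_names), m, replace = TRUE,
                       prob = layout$chrom_lengths)
      start <- floor(stats::runif(m) * (layout$chrom_lengths[ci] - len))
      cand <- data.frame(chrom = layout$chrom_names[ci], start = start,
                         end = start + len)
      cand <- cand[cand$start >= 0, , drop = FALSE]
      if (nrow(merged_peaks) > 0L && nrow(cand) > 0L) {
        hit <- unique(overlap_pairs(cand, merged_peaks, layout)$q)
        if (length(hit)) cand <- cand[-hit, , drop = FALSE]
      }
      got <- rbind(got, cand)
    }
    rows_bg <- got[seq_len(n_bg), , drop = FALSE]
  }
  df <- rbind(rows_in, rows_bg)
  df$in_peak <- rep(c(TRUE, FALSE), c(n_in, n_bg))
  df
}

#' Generate a synthetic fragment set
#'
#' Unique fragments are placed first: with probability `target_frip` a
#' fragment lies inside a (width- and accessibility-weighted) random peak,
#' otherwise wholly in the background. Lengths come from the bimodal
#' normal mixture, truncated at 20 bp. Duplicate copies are then created
#' by uniform resampling of existing fragments with replacement until the
#' duplicate fraction reaches `target_duplication`. Ground-truth in-peak
#' flags are attached as attribute `in_peak`.
#'
#' @param config a [synthetic_config()].
#' @param peaks the [peak_set()] in which signal fragments are placed.
#' @return A [fragment_set()] of `n_fragments` fragments.
#' @export
generate_fragments <- function(config, peaks) {
  layout <- attr(peaks, "layout")
  with_seed(config$seed + 2L, {
    n_total <- config$n_fragments
    n_unique <- max(1L, round(n_total * (1 - config$target_duplication)))
    n_dup <- n_total - n_unique
    accessible <- stats::runif(nrow(peaks)) < config$accessible_fraction
    uniq <- sample_unique_fragments(n_unique, config, peaks, layout,
                                    accessible)
    # enforce pairwise-distinct spans so the realised duplication rate is
    # exactly the number of copies added below
    for (pass in 1:20) {
      key <- paste(uniq$chrom, uniq$start, uniq$end)
      dup <- duplicated(key)
      if (!any(dup)) break
      repl <- sample_unique_fragments(sum(dup), config, peaks, layout,
                                      accessible)
      uniq[dup, ] <- repl
    }
    df <- uniq
    if (n_dup > 0L) {
      src <- sample.int(n_unique, n_dup, replace = TRUE)
      df <- rbind(uniq, uniq[src, , drop = FALSE])
    }
    out <- fragment_set(df[, c("chrom", "start", "end")], layout,
                        sample = "synthetic_fragments")
    attr(out, "in_peak") <- df$in_peak
    out
  })
}

#' Per-base coverage track from fragments
#'
#' Encodes the fragment-overlap depth at every base as maximal constant
#' bedGraph-style steps (zero-depth runs omitted). Total mass is conserved:
#' `sum(value * width)` equals the summed fragment widths.
#'
#' @param frags a [fragment_set()].
#' @param layout a [genome_layout()].
#' @return data.frame of sorted steps chrom/start/end/value.
#' @export
coverage_from_fragments <- function(frags, layout) {
  pieces <- lapply(layout$chrom_names, function(cn) {
    sel <- frags$chrom == cn
    if (!any(sel)) return(NULL)
    s <- frags$start[sel]; e <- frags$end[sel]
    delta <- c(rep(1, length(s)), rep(-1, length(e)))
    pos <- c(s, e)
    agg <- tapply(delta, pos, sum)
    bounds <- as.numeric(names(agg))
    depth <- cumsum(as.numeric(agg))
    k <- length(bounds)
    if (k < 2L) return(NULL)
    step <- data.frame(chrom = cn, start = bounds[-k], end = bounds[-1L],
                       value = depth[-k])
    step[step$value > 0, , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Threshold peak caller on a coverage track
#'
#' A deliberately simple caller for end-to-end synthetic runs: bases whose
#' coverage reaches the `(1 - top_fraction)` quantile of the nonzero step
#' values are merged (contiguous runs joined) into peaks, each carrying the
#' maximum inside coverage as `signal_value`. `top_fraction = 1` keeps all
#' nonzero coverage.
#'
#' @param coverage a step table (chrom/start/end/value), e.g. from
#'   [coverage_from_fragments()].
#' @param layout a [genome_layout()].
#' @param top_fraction fraction of top nonzero steps to keep, in (0, 1].
#' @param sample sample label for the result.
#' @return A [peak_set()] (caller label "threshold").
#' @export
threshold_peak_caller <- function(coverage, layout, top_fraction = 0.1,
                                  sample = "synthetic") {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  nz <- coverage[coverage$value > 0, , drop = FALSE]
  if (nrow(nz) == 0L) {
    warning("all-zero coverage: no peaks called")
    return(peak_set(data.frame(chrom = character(0), start = numeric(0),
                               end = numeric(0)), layout,
                    sample = sample, caller = "threshold"))
  }
  thr <- stats::quantile(nz$value, 1 - top_fraction, names = FALSE)
  keep <- nz[nz$value >= thr, , drop = FALSE]
  merged <- merge_intervals(keep[, c("chrom", "start", "end")], layout)
  hits <- overlap_pairs(keep, merged, layout)
  sig <- vapply(seq_len(nrow(merged)), function(i) {
    max(keep$value[hits$q[hits$s == i]])
  }, 0)
  merged$signal_value <- sig
  merged$score <- pmin(1000, round(sig * 100))
  merged$name <- paste0("called_", seq_len(nrow(merged)))
  peak_set(merged, layout, sample = sample, caller = "threshold")
}
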