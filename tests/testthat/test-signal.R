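test_that("FRiP counts fragment-in-peak fractions", {
  gl <- toy_layout(len = 1e4)
  peaks <- peak_set(data.frame(chrom = "chrT1", start = 1000, end = 2000), gl)
  inside <- fragment_set(data.frame(chrom = "chrT1",
                                    start = seq(1100, 1800, by = 100),
                                    end = seq(1100, 1800, by = 100) + 50), gl)
  expect_equal(frip(inside, peaks), 1)
  expect_equal(frip(inside, peak_subset(peaks, FALSE)), 0)
  expect_error(frip(fragment_subset(inside, logical(8)), peaks), "nonempty")
  # half in, half out
  mixed <- fragment_set(data.frame(chrom = "chrT1",
                                   start = c(1100, 1200, 5000, 6000),
                                   end = c(1150, 1250, 5050, 6050)), gl)
  expect_equal(frip(mixed, peaks), 0.5)
})

test_that("generator hits its target FRiP at n = 20000", {
  cfg <- synthetic_config(seed = 301)
  ref <- generate_reference(cfg)
  frags <- generate_fragments(cfg, ref)
  expect_equal(frip(frags, ref), 0.40, tolerance = 0.02 / 0.40)
  # direct counting oracle against the generator's own truth flags
  expect_equal(frip(frags, ref), mean(attr(frags, "in_peak")))
})

test_that("specificity ratio partitions reads between the two marks", {
  gl <- toy_layout(len = 1e5)
  same <- peak_set(data.frame(chrom = "chrT1", start = 0, end = 1000), gl)
  other <- peak_set(data.frame(chrom = "chrT1", start = 5e4,
                               end = 5e4 + 1000), gl)
  in_same <- fragment_set(data.frame(chrom = "chrT1", start = 100:109,
                                     end = 200:209), gl)
  expect_equal(as.numeric(specificity_ratio(in_same, same, other)), 1)

  both <- fragment_set(data.frame(chrom = "chrT1",
                                  start = c(100, 200, 50100, 50200),
                                  end = c(150, 250, 50150, 50250)), gl)
  expect_equal(as.numeric(specificity_ratio(both, same, other)), 0.5)

  nowhere <- fragment_set(data.frame(chrom = "chrT1", start = 9e4,
                                     end = 9e4 + 50), gl)
  expect_warning(v <- specificity_ratio(nowhere, same, other), "undefined")
  expect_true(is.nan(v))

  # 9:1 synthetic placement
  set.seed(302)
  n <- 5000
  pick_same <- runif(n) < 0.9
  start <- ifelse(pick_same, 0, 5e4) + floor(runif(n) * 900)
  frags <- fragment_set(data.frame(chrom = "chrT1", start = start,
                                   end = start + 80), gl)
  expect_equal(as.numeric(specificity_ratio(frags, same, other)), 0.9,
               tolerance = 0.02 / 0.9)
})

test_that("density ratio is coverage-adjusted enrichment", {
  gl <- toy_layout(len = 1e4, n = 2L)
  set.seed(303)
  frags <- rand_fragset(2000L, gl)
  whole <- data.frame(chrom = gl$chrom_names, start = 0,
                      end = gl$chrom_lengths)
  expect_equal(density_ratio(frags, whole, gl), 1.0)
  expect_error(density_ratio(frags, whole[0, ], gl), "zero bases")

  # all fragments inside a 10% region -> ratio 10
  region <- data.frame(chrom = "chrT1", start = 0, end = 2000)
  st <- floor(runif(500) * 1900)
  inside <- fragment_set(data.frame(chrom = "chrT1", start = st,
                                    end = st + 50), gl)
  expect_equal(density_ratio(inside, region, gl), 10)

  # uniform fragments: ratio ~ 1 within 3 SE for an arbitrary region set
  n <- 50000
  ci <- sample(1:2, n, TRUE)
  start <- floor(runif(n) * (gl$chrom_lengths[ci] - 1))
  unif <- fragment_set(data.frame(chrom = gl$chrom_names[ci], start = start,
                                  end = start + 1), gl)
  regions <- rand_intervals(10L, gl)
  merged <- merge_intervals(regions, gl)
  p <- sum(merged$end - merged$start) / gl$total_bases
  se <- sqrt(p * (1 - p) / n) / p
  expect_equal(density_ratio(unif, regions, gl), 1.0, tolerance = 3 * se)
})

test_that("binned counts follow the midpoint rule and conserve totals", {
  gl <- toy_layout(len = 1e4)
  one <- fragment_set(data.frame(chrom = "chrT1", start = 0, end = 180), gl)
  bc <- binned_counts(list(one), gl, bin_bp = 500)
  expect_equal(ncol(bc$matrix), 20L)
  expect_equal(unname(bc$matrix[1, 1]), 1L)
  expect_equal(sum(bc$matrix), 1L)

  set.seed(304)
  gl2 <- toy_layout(len = 7777, n = 2L)   # truncated last bin
  fs <- rand_fragset(500L, gl2)
  bc <- binned_counts(list(fs, fs), gl2, bin_bp = 500)
  expect_equal(ncol(bc$matrix), 2 * ceiling(7777 / 500))
  expect_equal(unname(rowSums(bc$matrix)), c(500L, 500L))
  # per-fragment loop oracle
  mids <- floor((fs$start + fs$end) / 2)
  want <- integer(ncol(bc$matrix))
  for (i in seq_len(nrow(fs))) {
    off <- if (fs$chrom[i] == "chrT2") ceiling(7777 / 500) else 0L
    bin <- off + mids[i] %/% 500 + 1L
    want[bin] <- want[bin] + 1L
  }
  expect_equal(unname(bc$matrix[1, ]), want)
})

test_that("quantile normalization equalizes sorted vectors then rounds", {
  gl <- toy_layout(len = 2000)
  mk <- function(v) {
    bc <- binned_counts(list(rand_fragset(1L, gl)), gl, bin_bp = 500)
    bc$matrix <- v
    bc
  }
  # hand-computed order-statistic means for a 2x4 matrix
  m <- rbind(a = c(5, 2, 3, 4), b = c(4, 1, 4, 2))
  bc <- mk(m)
  qn <- quantile_normalize(bc)
  # sorted columns: a=(2,3,4,5), b=(1,2,4,4); order-stat means
  # (1.5, 2.5, 4, 4.5); b's tied 4s share rank 3.5 -> 4.25; then
  # round-half-to-even
  expect_equal(unname(qn$matrix["a", ]), c(4, 2, 2, 4))
  expect_equal(unname(qn$matrix["b", ]), c(4, 2, 4, 2))

  set.seed(305)
  perm <- rbind(x = sample(1:100), y = sample(1:100))
  qn2 <- quantile_normalize(mk(perm))
  expect_identical(sort(qn2$matrix["x", ]), sort(qn2$matrix["y", ]))
  expect_equal(quantile_normalize(qn2)$matrix, qn2$matrix)  # idempotent

  ident <- rbind(u = 1:8, v = 1:8)
  expect_equal(quantile_normalize(mk(ident))$matrix, ident,
               ignore_attr = TRUE)
  one <- mk(matrix(1:4, nrow = 1, dimnames = list("solo", NULL)))
  expect_warning(same <- quantile_normalize(one), ">= 2 samples")
  expect_equal(same$matrix, one$matrix)
})

test_that("count correlation supports restriction and flags degeneracy", {
  set.seed(306)
  gl <- toy_layout(len = 1e4)
  fs1 <- rand_fragset(300L, gl, sample = "s1")
  fs2 <- rand_fragset(300L, gl, sample = "s2")
  fs3 <- rand_fragset(300L, gl, sample = "s3")
  bc <- binned_counts(list(fs1, fs2, fs3), gl, bin_bp = 500)
  cc <- count_correlation(bc)
  expect_equal(diag(cc), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(cc, cor(t(bc$matrix)))
  whole <- data.frame(chrom = "chrT1", start = 0, end = 1e4)
  expect_equal(count_correlation(bc, restrict_to = whole), cc)

  flat <- bc
  flat$matrix[1, ] <- 5L
  expect_warning(fc <- count_correlation(flat), "zero-variance")
  expect_true(all(is.na(fc["s1", c("s2", "s3")])))
})

test_that("fingerprint curve has forced endpoints and matches sort-cumsum", {
  gl <- toy_layout(len = 1e4)
  # all fragments in one bin
  conc <- fragment_set(data.frame(chrom = "chrT1", start = rep(100, 50),
                                  end = rep(150, 50)), gl)
  fp <- fingerprint_curve(conc, gl, bin_bp = 1000)
  expect_equal(fp$cumulative[1:9], rep(0, 9))
  expect_equal(fp$cumulative[10], 1)
  expect_true(all(diff(fp$cumulative) >= 0))

  # perfectly uniform: linear in rank under max-bin normalization
  unif <- fragment_set(data.frame(chrom = "chrT1",
                                  start = seq(0, 9000, by = 1000) + 10,
                                  end = seq(0, 9000, by = 1000) + 60), gl)
  fp <- fingerprint_curve(unif, gl, bin_bp = 1000)
  expect_equal(fp$cumulative, 1:10)
  expect_equal(fingerprint_curve(unif, gl, 1000, mode = "total")$cumulative,
               (1:10) / 10)

  set.seed(307)
  fs <- rand_fragset(400L, gl)
  fp <- fingerprint_curve(fs, gl, bin_bp = 1000)
  counts <- sort(binned_counts(list(fs), gl, 1000)$matrix[1, ])
  expect_equal(fp$cumulative, cumsum(counts) / max(counts))
  expect_gte(utils::tail(fp$cumulative, 1), 1)   # total/max >= 1
  expect_error(fingerprint_curve(fragment_subset(fs, logical(400)), gl),
               "fragments")
})

test_that("enrichment matrix counts midpoints around anchors", {
  gl <- toy_layout(len = 1e4)
  anchor <- data.frame(chrom = "chrT1", pos = 5000)
  one <- fragment_set(data.frame(chrom = "chrT1", start = 4990, end = 5010),
                      gl)
  em <- enrichment_matrix(one, anchor, window_bp = 3000, bin_bp = 50)
  expect_equal(ncol(em$matrix), 120L)
  expect_equal(sum(em$matrix), 1L)
  expect_equal(which(em$matrix[1, ] == 1L), 61L)  # central column
  expect_false(em$truncated[1])

  empty <- fragment_subset(one, FALSE)
  expect_true(all(enrichment_matrix(empty, anchor)$matrix == 0))

  # incidence-count oracle over multiple anchors (windows may share frags)
  set.seed(308)
  fs <- rand_fragset(300L, gl)
  anchors <- data.frame(chrom = "chrT1", pos = c(2000, 2500, 9900))
  em <- enrichment_matrix(fs, anchors, window_bp = 1000, bin_bp = 100)
  mids <- floor((fs$start + fs$end) / 2)
  want <- sum(vapply(anchors$pos, function(a)
    sum(mids >= a - 1000 & mids < a + 1000), 0))
  expect_equal(sum(em$matrix), want)
  expect_true(em$truncated[3])                    # 9900 + 1000 > chrom end
  expect_equal(em$profile, colMeans(em$matrix))
  expect_error(enrichment_matrix(fs, anchors[0, ]), "anchors")
})

test_that("downsampling is deterministic and FRiP-preserving", {
  set.seed(309)
  gl <- toy_layout(len = 1e5)
  fs <- rand_fragset(5000L, gl)
  all_of_it <- downsample(fs, 5000L, seed = 9)
  key <- function(df) sort(paste(df$chrom, df$start, df$end))
  expect_equal(key(all_of_it), key(fs))
  expect_identical(as.data.frame(downsample(fs, 100L, seed = 4)),
                   as.data.frame(downsample(fs, 100L, seed = 4)))
  expect_error(downsample(fs, 5001L, seed = 1), "n must")

  peaks <- rand_peakset(50L, gl)
  f_full <- frip(fs, peaks)
  f_down <- frip(downsample(fs, 1000L, seed = 11), peaks)
  expect_equal(f_down, f_full, tolerance = 3 * sqrt(f_full * (1 - f_full) / 1000) / f_full)
})

test_that("duplicate marking groups identical spans and is idempotent", {
  gl <- toy_layout()
  uniq <- fragment_set(data.frame(chrom = "chrT1", start = 1:10 * 100,
                                  end = 1:10 * 100 + 80), gl)
  expect_equal(mark_duplicates(uniq)$duplication_rate, 0)

  rep4 <- fragment_set(data.frame(chrom = "chrT1", start = rep(100, 4),
                                  end = rep(200, 4)), gl)
  md <- mark_duplicates(rep4)
  expect_equal(md$duplication_rate, 75)
  expect_equal(md$n_unique, 1L)
  again <- mark_duplicates(md$fragments)
  expect_identical(again$fragments$duplicate, md$fragments$duplicate)

  cfg <- synthetic_config(seed = 310)
  frags <- generate_fragments(cfg, generate_reference(cfg))
  rate <- mark_duplicates(frags)$duplication_rate
  expect_equal(rate, 60, tolerance = 2 / 60)
})

test_that("fragment length QC reports modes and short fraction", {
  gl <- toy_layout()
  all180 <- fragment_set(data.frame(chrom = "chrT1", start = 1:20 * 300,
                                    end = 1:20 * 300 + 180), gl)
  fl <- fragment_length_distribution(all180)
  expect_equal(fl$modes, 180L)
  expect_equal(fl$fraction_short, 0)

  half <- fragment_set(data.frame(chrom = "chrT1", start = 1:20 * 300,
                                  end = 1:20 * 300 + rep(c(50, 180), 10)),
                       gl)
  expect_equal(fragment_length_distribution(half)$fraction_short, 0.5)

  cfg <- synthetic_config(seed = 311)
  frags <- generate_fragments(cfg, generate_reference(cfg))
  expect_equal(fragment_length_distribution(frags)$fraction_short, 0.2,
               tolerance = 0.02 / 0.2)
})
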