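test_that("binning aggregates and masks low-coverage bins strictly below 10", {
  d <- data.frame(chrom = "c", start = c(0, 250, 500, 1000),
                  end = c(250, 500, 750, 1500),
                  count = c(5, 4, 10, 100))
  bm <- bin_and_mask(d, bin = 500)
  expect_equal(bm$count, c(9, 10, 100))
  expect_equal(bm$masked, c(TRUE, FALSE, FALSE))  # 9 masked, 10 kept

  ov <- data.frame(chrom = "c", start = c(0, 200), end = c(500, 700),
                   count = c(1, 1))
  expect_error(bin_and_mask(ov), "overlapping")
})

test_that("log2 ratios use the genome median as diploid baseline", {
  trk <- toy_track(c(rep(100, 10), 150))
  l2 <- log2_ratio(trk)
  expect_equal(attr(l2, "baseline"), 100)
  expect_equal(l2$log2[11], log2(1.5), tolerance = 1e-12)
  expect_equal(l2$log2[1], 0)

  all_masked <- toy_track(rep(5, 4))
  expect_error(log2_ratio(all_masked), "masked")

  # median baseline is robust to a focal trisomy covering < 25% of bins
  set.seed(5)
  cnt <- c(rpois(300, 400), rpois(90, 600))
  trk2 <- toy_track(cnt)
  expect_lt(abs(attr(log2_ratio(trk2), "baseline") - 400) / 400, 0.02)
})

test_that("ploidy rescaling keeps ratios on the diploid scale", {
  trk <- toy_track(rep(100, 20))
  l4 <- log2_ratio(trk, ploidy = 4)
  expect_equal(unique(l4$log2), -1)  # tetraploid baseline reads as copy 1/2
})

test_that("a constant track yields one neutral segment", {
  trk <- toy_track(rep(400, 60))
  segs <- call_segments(segment_log2(log2_ratio(trk)))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$mean_log2, 0)
  expect_equal(segs$call, "neutral")
})

test_that("noiseless piecewise-constant tracks give exact breakpoints", {
  cnt <- rep(400, 300); cnt[151:200] <- 600
  segs <- segment_log2(log2_ratio(toy_track(cnt)))
  expect_equal(segs$start, c(0, 150 * 500, 200 * 500))
  expect_equal(segs$end, c(150 * 500, 200 * 500, 300 * 500))
  expect_equal(segs$mean_log2[2], log2(1.5), tolerance = 1e-12)
})

test_that("a planted 100-bin gain is recovered with the right mean", {
  set.seed(21)
  cnt <- rpois(400, 400); cnt[151:250] <- rpois(100, 600)
  segs <- call_segments(segment_log2(log2_ratio(toy_track(cnt))))
  g <- segs[segs$call == "gain", ]
  expect_equal(nrow(g), 1L)
  ov <- max(0, min(g$end, 250 * 500) - max(g$start, 150 * 500))
  expect_gte(ov / (100 * 500), 0.9)
  expect_gte(ov / (g$end - g$start), 0.9)
  expect_lt(abs(g$mean_log2 - log2(1.5)), 0.05)
})

test_that("events below the minimum probe count are not called", {
  set.seed(8)
  cnt <- rpois(200, 400); cnt[50:53] <- rpois(4, 800)
  segs <- call_segments(segment_log2(log2_ratio(toy_track(cnt))))
  expect_true(all(segs$call == "neutral"))
})

test_that("segments partition the unmasked extent and survive count scaling", {
  set.seed(31)
  cnt <- rpois(300, 400); cnt[101:160] <- rpois(60, 800)
  trk <- toy_track(cnt)
  segs <- segment_log2(log2_ratio(trk))
  expect_equal(segs$start[-1], segs$end[-nrow(segs)])  # no gaps/overlaps
  expect_equal(min(segs$start), 0)
  expect_equal(max(segs$end), 300 * 500)
  # doubling all counts leaves calls unchanged (median absorbs scale)
  trk2 <- toy_track(cnt * 2)
  c1 <- call_segments(segs)
  c2 <- call_segments(segment_log2(log2_ratio(trk2)))
  expect_equal(c1$call, c2$call)
  expect_equal(c1$start, c2$start)
})

test_that("gain/loss calls and display bands are independent", {
  segs <- data.frame(chrom = "c", start = 0, end = 5000, n_bins = 10,
                     mean_log2 = c(0.26, -0.24, -1, 0.1))
  cc <- call_segments(segs, merge = FALSE)
  expect_equal(cc$call, c("gain", "neutral", "loss", "neutral"))
  expect_equal(cc$band, c("within-gain-band", "within-loss-band",
                          "within-loss-band", "outside"))
  # hemizygous loss in a diploid sits exactly at the loss-band lower edge
  expect_equal(expected_log2(1, 2), -1)
  expect_equal(round(expected_log2(3, 2), 2), 0.58)
})

test_that("recurrence counts clones per bin and flags whole-chromosome aneuploidy", {
  lens <- data.frame(chrom = "chr3", length = 10000)
  gain <- data.frame(chrom = "chr3", start = 0, end = 10000, n_bins = 20,
                     mean_log2 = 0.58, call = "gain", band = "outside")
  neut <- transform(gain, call = "neutral")
  segl <- list(c1 = gain, c2 = gain, c3 = neut)
  out <- summarize_recurrence(segl, lens)
  expect_true(all(abs(out$recurrence$fraction - 2 / 3) < 1e-12))
  expect_equal(sort(out$aneuploidies$clone), c("c1", "c2"))

  none <- summarize_recurrence(list(c1 = neut), lens)
  expect_true(all(none$recurrence$fraction == 0))
  expect_equal(nrow(none$aneuploidies), 0L)
})

test_that("planted whole-chromosome trisomy recurrence is recovered from simulated clones", {
  cfg <- sim_config(seed = 17)
  n_clones <- 10; n_carrier <- 8
  segl <- list()
  for (i in seq_len(n_clones)) {
    ov <- if (i <= n_carrier)
      data.frame(chrom = "chrIII", start = 0, end = 150000, copy = 3) else NULL
    trk <- simulate_depth_track(cfg, clone = paste0("cl", i),
                                copy_overrides = ov)
    bm <- bin_and_mask(trk[, c("chrom", "start", "end", "count")])
    segl[[paste0("cl", i)]] <- call_segments(segment_log2(log2_ratio(bm)))
  }
  out <- summarize_recurrence(segl, cfg$genome$chrom_lengths)
  chr3 <- out$recurrence[out$recurrence$chrom == "chrIII", ]
  expect_lt(abs(mean(chr3$fraction) - n_carrier / n_clones), 0.1)
  expect_gte(sum(out$aneuploidies$chrom == "chrIII" &
                   out$aneuploidies$call == "gain"), n_carrier - 1)
})
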