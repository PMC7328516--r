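test_that("peak filtering applies both retention rules", {
  # strict 'more than five reads', inclusive 'at least 5% of gene total'
  cases <- list(
    list(counts = c(6, 100, 4), keep = c(6, 100)),   # 6/110 = 5.45% >= 5%
    list(counts = c(5, 95), keep = 95),              # 5 is not > five
    list(counts = c(6, 200), keep = 200))            # 6/206 = 2.9% < 5%
  for (cs in cases) {
    p <- peaks_df(seq(100, by = 200, length.out = length(cs$counts)),
                  cs$counts)
    expect_identical(filter_peaks(p)$count, as.numeric(cs$keep))
  }
  expect_identical(nrow(filter_peaks(peaks_df(integer(0), numeric(0)))), 0L)
})

test_that("close peaks merge at the stronger position, summing counts", {
  m <- merge_peaks(peaks_df(c(100, 130), c(10, 30)))
  expect_identical(m$site, 130L); expect_identical(m$count, 40)
  m <- merge_peaks(peaks_df(c(100, 130), c(30, 10)))
  expect_identical(m$site, 100L); expect_identical(m$count, 40)
  # exactly 50 nt apart: no merge ('closer than 50' is strict)
  m <- merge_peaks(peaks_df(c(100, 150), c(10, 30)))
  expect_identical(nrow(m), 2L)
  # equal counts: merged peak sits at the more distal (3') position
  expect_identical(merge_peaks(peaks_df(c(100, 130), c(5, 5)))$site, 130L)
  expect_identical(merge_peaks(peaks_df(c(100, 130), c(5, 5)),
                               strand = "-")$site, 100L)
})

test_that("merging iterates closest-pair-first with lower-coordinate ties", {
  m <- merge_peaks(peaks_df(c(100, 149, 198), c(20, 50, 20)))
  expect_identical(m$site, 149L)
  expect_identical(m$count, 90)
})

test_that("merge is idempotent and conserves counts", {
  withr::local_seed(7)
  for (i in 1:50) {
    p <- random_peaklist()
    m <- merge_peaks(p)
    expect_identical(sum(m$count), sum(p$count))
    expect_identical(merge_peaks(m)$site, m$site)
    if (nrow(m) > 1) expect_true(all(diff(m$site) >= 50))
  }
})

test_that("filter+merge matches the brute-force oracle on random inputs", {
  withr::local_seed(42)
  for (i in 1:200) {
    p <- random_peaklist()
    got <- merge_peaks(filter_peaks(p))
    want <- oracle_filter_merge(p)
    expect_identical(got$site, as.integer(want$site))
    expect_identical(got$count, want$count)
  }
})

test_that("genes segment into PAS-terminated windows, TSS first", {
  g <- toy_gene("g1", "+")
  s <- segment_gene(g, peaks_df(c(400, 900), c(50, 100)))
  expect_identical(s$segments$start, c(0L, 400L))
  expect_identical(s$segments$end, c(400L, 900L))
  expect_true(s$eligible)
  expect_identical(s$peaks$site, c(400L, 900L))  # 5'->3'

  # minus strand: proximal segment is the rightmost
  gm <- toy_gene("g2", "-")
  sm <- segment_gene(gm, peaks_df(c(600, 100), c(50, 100), strand = "-"))
  expect_identical(sm$peaks$site, c(600L, 100L))  # transcription order
  expect_identical(sm$segments$start, c(599L, 99L))
  expect_identical(sm$segments$end, c(1000L, 599L))
})

test_that("genes with fewer than two retained peaks are ineligible", {
  g <- toy_gene()
  expect_false(segment_gene(g, peaks_df(900, 100))$eligible)
  s0 <- segment_gene(g, peaks_df(integer(0), numeric(0)))
  expect_false(s0$eligible)
  expect_identical(nrow(s0$segments), 0L)
})

test_that("segmentation is invariant under genome mirroring", {
  withr::local_seed(3)
  L <- 5000L
  for (i in 1:20) {
    sites <- sort(sample(500:4500, sample(2:6, 1)))
    counts <- sample(6:300, length(sites))
    g <- gene_model("g", "c", "+", 0, L, "ncRNA")
    s_fwd <- segment_gene(g, merge_peaks(filter_peaks(peaks_df(sites, counts))))
    # mirror: x -> L - x (1-based sites), strand flip
    pm <- peaks_df(L - sites + 1L, counts, strand = "-")
    gm <- gene_model("g", "c", "-", 0, L, "ncRNA")
    s_rev <- segment_gene(gm, merge_peaks(filter_peaks(pm), strand = "-"))
    # same number of segments, mirrored coordinates, same 5'->3' counts
    expect_identical(nrow(s_rev$segments), nrow(s_fwd$segments))
    expect_identical(s_rev$peaks$count, s_fwd$peaks$count)
    expect_identical(s_rev$peaks$site, L - s_fwd$peaks$site + 1L)
    expect_identical(s_rev$segments$start, L - s_fwd$segments$end)
    expect_identical(s_rev$segments$end, L - s_fwd$segments$start)
  }
})

test_that("coverage quantification integrates bedGraph depth per segment", {
  dir <- withr::local_tempdir()
  g <- toy_gene("g1", "+")
  segm <- list(g1 = segment_gene(g, peaks_df(c(200, 400), c(50, 100))))
  # uniform depth 10 over segment 1 ([0,200)); half of segment 2 at 4
  writeLines(c("chrI\t0\t200\t10", "chrI\t200\t300\t4"),
             file.path(dir, "a.bedGraph"))
  writeLines("chrI\t500\t600\t2", file.path(dir, "b.bedGraph"))  # outside
  sheet <- sample_sheet(c("a", "b"), c("wt", "mut"),
                        path = file.path(dir, c("a.bedGraph", "b.bedGraph")))
  sc <- quantify_segments(segm, sheet, read_length = 100)
  expect_identical(unname(sc$counts[, "a"]), c(20, 4))   # 2000/100, 400/100
  expect_identical(unname(sc$depth[, "a"]), c(10, 2))    # mean depths
  expect_identical(unname(sc$counts[, "b"]), c(0, 0))    # zero coverage
  expect_identical(sc$pas_site, c(200L, 400L))

  writeLines("chrI\t0\t100\t-1", file.path(dir, "a.bedGraph"))
  expect_error(quantify_segments(segm, sheet), "negative coverage")
})

test_that("filter-order flag changes results when merging would rescue peaks", {
  g <- toy_gene()
  # two weak peaks 30 nt apart: individually <5% of total, together above
  p <- peaks_df(c(100, 130, 900), c(20, 20, 600))
  genes <- list(g1 = g)
  seg_ff <- segment_genes(genes, p)$g1                      # filter first
  seg_mf <- segment_genes(genes, p, order = "merge_first")$g1
  expect_identical(nrow(seg_ff$segments), 1L)  # weak pair dropped
  expect_identical(nrow(seg_mf$segments), 2L)  # merged pair survives
})
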