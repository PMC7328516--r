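test_that("gene models validate their invariants", {
  expect_error(gene_model("g1", "chrI", "+", 100, 100, "ncRNA"),
               "start must be < end")
  expect_error(gene_model("g1", "chrI", "*", 0, 10, "ncRNA"), "strand")
  expect_error(
    gene_model("g1", "chrI", "+", 0, 1000, "coding",
               utr5 = c(0, 100), cds = c(100, 1200), utr3 = c(700, 1000)),
    "cds outside gene")
  expect_error(
    gene_model("g1", "chrI", "+", 0, 1000, "coding",
               utr5 = c(100, 700), cds = c(0, 100), utr3 = c(700, 1000)),
    "out of order")
  # minus strand mirrors the feature order
  expect_s3_class(toy_gene(strand = "-"), "gene_model")
})

test_that("GFF3 round-trips through write and read, keeping conventions", {
  genes <- list(g1 = toy_gene("g1", "+"), g2 = toy_gene("g2", "-"),
                nc1 = gene_model("nc1", "chrI", "+", 2000, 2500, "ncRNA"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(genes, path)
  back <- read_gene_models(path)
  expect_identical(names(back), names(genes))
  for (id in names(genes)) {
    expect_identical(back[[id]]$start, genes[[id]]$start)
    expect_identical(back[[id]]$end, genes[[id]]$end)
    expect_identical(back[[id]]$biotype, genes[[id]]$biotype)
    expect_equal(back[[id]]$utr3, genes[[id]]$utr3)
    expect_equal(back[[id]]$cds, genes[[id]]$cds)
  }
  # GFF3 1-based closed -> internal 0-based half-open on the raw text
  txt <- readLines(path)
  g1row <- txt[grepl("\tgene\t", txt) & grepl("ID=g1", txt)]
  expect_match(g1row, "\t1\t1000\t")  # internal [0,1000)
})

test_that("genes without CDS rows become ncRNA", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gX",
               "chrI\tsrc\texon\t1001\t2000\t.\t+\t.\tID=gX.e;Parent=gX"),
             path)
  gm <- read_gene_models(path)
  expect_identical(gm$gX$biotype, "ncRNA")
  expect_identical(gm$gX$start, 1000L)
  expect_identical(gm$gX$end, 2000L)
})

test_that("malformed GFF3 reports the offending line number", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrI\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chrI\tsrc\tgene\t200"), path)
  expect_error(read_gene_models(path), "line 3")
})

test_that("PAS peaks read from BED6 with coordinate conversion", {
  genes <- list(g1 = toy_gene("g1", "+"))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrI\t99\t100\tg1\t12\t+", path)
  p <- read_pas_peaks(path, genes)
  expect_identical(p$site, 100L)
  expect_identical(p$count, 12)
  expect_identical(p$gene_id, "g1")
})

test_that("unknown gene names are skipped with a warning; bad rows error", {
  genes <- list(g1 = toy_gene("g1", "+"))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t99\t100\tg1\t12\t+",
               "chrI\t199\t200\tunknown_gene\t7\t+"), path)
  expect_warning(p <- read_pas_peaks(path, genes), "1 peak\\(s\\) skipped")
  expect_identical(nrow(p), 1L)

  writeLines("chrI\t99\t100\tg1\tNA\t+", path)
  expect_error(read_pas_peaks(path, genes), "non-numeric score")

  writeLines("chrI\t99\t100\tg1\t12\t-", path)
  expect_error(read_pas_peaks(path, genes), "strand mismatch.*g1")
})

test_that("positional fallback assigns peaks downstream of gene ends", {
  genes <- list(g1 = toy_gene("g1", "+"),
                g2 = gene_model("g2", "chrI", "-", 3000, 4000, "ncRNA"))
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrI\t1050\t1051\t.\t30\t+",    # 51 nt past g1 end
               "chrI\t2899\t2900\t.\t40\t-"),   # 100 nt before g2 start
             path)
  p <- read_pas_peaks(path, genes, positional_fallback = TRUE)
  expect_identical(p$gene_id, c("g1", "g2"))
  # outside the 200-nt window the peak is dropped
  writeLines("chrI\t1300\t1301\t.\t30\t+", path)
  expect_warning(p2 <- read_pas_peaks(path, genes, positional_fallback = TRUE))
  expect_identical(nrow(p2), 0L)
})

test_that("PAS peaks round-trip through BED", {
  p <- peaks_df(c(100, 250, 900), c(12, 40, 7))
  path <- withr::local_tempfile(fileext = ".bed")
  write_pas_peaks(p, path)
  back <- read_pas_peaks(path, list(g1 = toy_gene("g1", "+")))
  expect_identical(back$site, p$site)
  expect_identical(back$count, p$count)
})

test_that("segment count tables read against a sample sheet", {
  sheet <- sample_sheet(c("s1", "s2", "s3"), c("wt", "mut", "mut"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsegment_index\ts1\ts2\ts3",
               "g1\t1\t10\t12\t9", "g1\t2\t5\t6\t0",
               "g2\t1\t0\t0\t0", "g2\t2\t3\t1\t2"), path)
  sc <- read_segment_counts(path, sheet)
  expect_identical(dim(sc), c(4L, 3L))
  expect_identical(levels(sc$condition), c("wt", "mut"))
  expect_identical(unname(sc$counts["g2:1", ]), c(0, 0, 0))  # all-zero row kept

  writeLines(c("gene_id\tsegment_index\ts1\ts2",
               "g1\t1\t10\t12"), path)
  expect_error(read_segment_counts(path, sheet), "missing from table: s3")

  writeLines(c("gene_id\tsegment_index\ts1\ts2\ts3\ts4",
               "g1\t1\t10\t12\t9\t1"), path)
  expect_error(read_segment_counts(path, sheet), "absent from sample sheet")

  writeLines(c("gene_id\tsegment_index\ts1\ts2\ts3",
               "g1\t1\t10\t-2\t9"), path)
  expect_error(read_segment_counts(path, sheet), "negative")
})

test_that("segment count tables round-trip", {
  sheet <- sample_sheet(c("a", "b"), c("wt", "mut"))
  m <- matrix(c(4, 7, 0, 11), 2, 2, dimnames = list(NULL, c("a", "b")))
  sc <- segment_counts(m, sheet, gene_id = c("g1", "g1"),
                       segment_index = 1:2, pas_site = c(400L, 900L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segment_counts(sc, path)
  back <- read_segment_counts(path, sheet)
  expect_equal(back$counts, sc$counts)
  expect_identical(back$pas_site, sc$pas_site)
})

test_that("sample sheets enforce a two-level design", {
  expect_error(sample_sheet(c("a", "b"), c("x", "x")), "two condition levels")
  expect_error(sample_sheet(c("a", "b", "c"), c("x", "y", "z")),
               "two condition levels")
  sh <- sample_sheet(c("a", "b", "c"), c("mut", "wt", "mut"))
  expect_identical(levels(sh$condition)[1], "wt")  # wt is the reference
})
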