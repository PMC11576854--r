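test_that("parse_bed maps fields, skips headers, and rejects bad records", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200"), p)
  df <- parse_bed(p)
  expect_equal(df, data.frame(chrom = "chr1", start = 100L, end = 200L,
                              stringsAsFactors = FALSE))

  writeLines(c("track name=peaks", "chr1\t100\t200\tpk1\t7.5"), p)
  df <- parse_bed(p)
  expect_equal(nrow(df), 1)
  expect_equal(df$name, "pk1")
  expect_equal(df$score, 7.5)

  writeLines(c("chr1\t200\t100"), p)
  expect_error(parse_bed(p), "line 1")
})

test_that("merge_intervals matches bedtools -d semantics and the per-base oracle", {
  a <- data.frame(chrom = "chr1", start = c(100L, 250L), end = c(200L, 300L))
  expect_equal(merge_intervals(a, 100L),
               data.frame(chrom = "chr1", start = 100L, end = 300L,
                          stringsAsFactors = FALSE))
  # separation 101 > 100: the dilation oracle keeps them apart
  b <- data.frame(chrom = "chr1", start = c(100L, 301L), end = c(200L, 400L))
  expect_equal(merge_intervals(b, 100L), oracle_merge(b, 100L))
  expect_equal(nrow(merge_intervals(b, 100L)), 2)
  # gap 0 identity on an already-merged set
  c1 <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(merge_intervals(c1, 0L),
               data.frame(chrom = "chr1", start = 100L, end = 200L,
                          stringsAsFactors = FALSE))
  expect_equal(nrow(merge_intervals(a[0, ], 50L)), 0)
})

test_that("merge_intervals is idempotent and equals the oracle on random sets", {
  set.seed(11)
  for (rep in 1:20) {
    x <- random_intervals(sample(1:60, 1))
    gap <- sample(c(0L, 1L, 50L, 100L, 500L), 1)
    m <- merge_intervals(x, gap)
    expect_equal(m, oracle_merge(x, gap))
    expect_equal(merge_intervals(m, gap), m)
  }
})

test_that("intersect_counts handles abutment, rejects overlapping input, matches oracle", {
  a <- data.frame(chrom = "c", start = 0L, end = 10L)
  b <- data.frame(chrom = "c", start = 5L, end = 15L)
  r <- intersect_counts(a, b)
  expect_equal(r$shared_a, 1)
  expect_equal(r$a_only, 0)
  # half-open abutment does not overlap
  b2 <- data.frame(chrom = "c", start = 10L, end = 20L)
  expect_equal(intersect_counts(a, b2)$shared_a, 0)
  bad <- data.frame(chrom = "c", start = c(0L, 5L), end = c(10L, 12L))
  expect_error(intersect_counts(bad, b), "overlap")

  set.seed(12)
  for (rep in 1:10) {
    x <- merge_intervals(random_intervals(50), 0L)
    y <- merge_intervals(random_intervals(50), 0L)
    minov <- sample(c(1L, 10L, 100L), 1)
    r <- intersect_counts(x, y, min_overlap_bp = minov)
    expect_equal(r$shared_a, oracle_overlap_count(x, y, minov))
    expect_equal(r$shared_b, oracle_overlap_count(y, x, minov))
    expect_equal(r$a_only + r$shared_a, nrow(x))
    expect_equal(r$b_only + r$shared_b, nrow(y))
  }
})

test_that("nearest_tss links within 10 kb, breaks ties lexicographically, matches oracle", {
  ann <- data.frame(gene_id = c("gB", "gA"), chrom = "c", strand = "+",
                    tss = c(1100L, 20000L), start = c(1100L, 20000L),
                    end = c(3100L, 22000L), stringsAsFactors = FALSE)
  r1 <- data.frame(chrom = "c", start = 1000L, end = 1200L)
  link <- nearest_tss(r1, ann)
  expect_equal(link$gene_id, "gB")
  expect_equal(link$distance, 0L)
  # nearest TSS beyond 10 kb -> unlinked
  r2 <- data.frame(chrom = "c", start = 0L, end = 100L)
  expect_equal(nrow(nearest_tss(r2, ann[2, , drop = FALSE])), 0)
  # equidistant tie goes to the smaller gene id
  ann2 <- data.frame(gene_id = c("gB", "gA"), chrom = "c", strand = "+",
                     tss = c(900L, 1300L), start = c(900L, 1300L),
                     end = c(2900L, 3300L), stringsAsFactors = FALSE)
  r3 <- data.frame(chrom = "c", start = 1000L, end = 1201L)
  expect_equal(nearest_tss(r3, ann2)$gene_id, "gA")

  set.seed(13)
  for (rep in 1:10) {
    regions <- random_intervals(100)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                        chrom = sample(c("chrA", "chrB"), 20, replace = TRUE),
                        strand = "+", tss = sample.int(50000, 20),
                        stringsAsFactors = FALSE)
    genes$start <- genes$tss; genes$end <- genes$tss + 1000L
    expect_equal(nearest_tss(regions, genes), oracle_nearest(regions, genes, 10000L))
  }
})

test_that("annotate_feature follows midpoint precedence", {
  ann <- data.frame(gene_id = "g1", chrom = "c", strand = "+", tss = 10000L,
                    start = 10000L, end = 20000L,
                    exons = "10000-10300;15000-15500",
                    stringsAsFactors = FALSE)
  # midpoint 300 bp upstream of the TSS -> promoter
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 9600L, end = 9800L), ann),
               "promoter")
  # midpoint in the gene body outside exons -> intron
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 12000L, end = 12100L), ann),
               "intron")
  # exon overlapping the promoter window -> promoter wins
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 10100L, end = 10200L), ann),
               "promoter")
  # exon outside the promoter window
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 15100L, end = 15300L), ann),
               "exon")
  # past the transcript end within 500 bp -> TTS
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 20100L, end = 20200L), ann),
               "TTS")
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 40000L, end = 40100L), ann),
               "intergenic")
  # minus strand: promoter upstream means higher coordinates
  ann2 <- transform(ann, strand = "-", tss = 19999L)
  expect_equal(annotate_feature(data.frame(chrom = "c", start = 20500L, end = 20700L), ann2),
               "promoter")
})

test_that("feature labels cover every region exactly once", {
  set.seed(14)
  regions <- random_intervals(80)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:10), chrom = "chrA", strand = "+",
                    tss = seq(2000L, 47000L, by = 5000L), stringsAsFactors = FALSE)
  ann$start <- ann$tss; ann$end <- ann$tss + 2000L
  labs <- annotate_feature(regions, ann)
  expect_length(labs, nrow(regions))
  expect_true(all(labs %in% c("promoter", "5'UTR", "3'UTR", "exon",
                              "intron", "TTS", "intergenic")))
})

test_that("bed/bedgraph/annotation/gmt writers round-trip through their readers", {
  d <- withr::local_tempdir()
  iv <- genomic_intervals(c("chr1", "chr2"), c(0L, 500L), c(100L, 900L),
                          name = c("a", "b"), score = c(1.5, -2))
  write_bed(iv, file.path(d, "x.bed"))
  expect_equal(parse_bed(file.path(d, "x.bed")), iv)

  bins <- data.frame(chrom = "chr1", start = seq(0L, 975L, 25L),
                     end = seq(25L, 1000L, 25L), value = runif(40) * 10)
  tr <- signal_track(bins, library_size = 1e6)
  write_bedgraph(tr, file.path(d, "x.bedgraph"))
  tr2 <- read_bedgraph(file.path(d, "x.bedgraph"), library_size = 1e6)
  expect_equal(tr2$bins, tr$bins, tolerance = 1e-12)
  # non-uniform bins are rejected
  expect_error(signal_track(rbind(bins, data.frame(chrom = "chr1", start = 1000L,
                                                   end = 1010L, value = 1)), 1e6),
               "25 bp")

  sets <- list(SET_A = c("g1", "g2"), SET_B = "g3")
  write_gmt(sets, file.path(d, "x.gmt"))
  expect_equal(read_gmt(file.path(d, "x.gmt")), sets)
})
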