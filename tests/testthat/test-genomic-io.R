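test_that("read_bedgraph parses intervals, tolerates track lines, reports bad lines", {
  f <- write_fixture("chr1 100 200 5.0", ".bedGraph")
  out <- read_bedgraph(f)
  expect_equal(nrow(out), 1)
  expect_equal(out$chrom, "chr1")
  expect_equal(out$start, 100L)
  expect_equal(out$end, 200L)
  expect_equal(out$value, 5)

  empty <- write_fixture(character(0), ".bedGraph")
  expect_equal(nrow(read_bedgraph(empty)), 0)

  with_header <- write_fixture(
    c("track type=bedGraph name=x", "chr1\t0\t10\t1.5", "chr1\t10\t20\t2.5"),
    ".bedGraph"
  )
  out <- read_bedgraph(with_header)
  expect_equal(nrow(out), 2)
  expect_equal(out$value, c(1.5, 2.5))

  bad <- write_fixture(c("chr1 0 10 1.0", "chr1 10 20 oops"), ".bedGraph")
  expect_error(read_bedgraph(bad), "line")
  expect_error(read_bedgraph(tempfile()), "does not exist")
})

test_that("read_narrowpeak maps signalValue to height and summit offsets", {
  f <- write_fixture(
    c(
      "chr1\t100\t300\tpk1\t50\t.\t7.5\t3.2\t2.1\t40",
      "chr1\t500\t600\tpk2\t10\t.\t2.0\t1.0\t0.5\t-1"
    ),
    ".narrowPeak"
  )
  out <- read_narrowpeak(f)
  expect_equal(out$height, c(7.5, 2.0))
  expect_equal(out$summit, c(140L, NA_integer_))
  expect_error(read_narrowpeak(write_fixture("chr1\t1\t2\tx", ".narrowPeak")), "10 columns")
})

test_that("BED6 TSS follows the strand convention and duplicates are fatal", {
  f <- write_fixture(
    c("chr1\t1000\t2000\tg1\t0\t+", "chr1\t1000\t2000\tg2\t0\t-"),
    ".bed"
  )
  out <- read_gene_annotation(f, "bed6")
  expect_equal(out$tss[out$gene_id == "g1"], 1000L)
  expect_equal(out$tss[out$gene_id == "g2"], 1999L)

  dup <- write_fixture(
    c("chr1\t0\t10\tg1\t0\t+", "chr1\t20\t30\tg1\t0\t+"), ".bed"
  )
  expect_error(read_gene_annotation(dup, "bed6"), "duplicate gene_id")

  bad_strand <- write_fixture("chr1\t0\t10\tg1\t0\t*", ".bed")
  expect_error(read_gene_annotation(bad_strand, "bed6"), "strand")
})

test_that("GTF gene rows are parsed with the 1-based to 0-based shift", {
  f <- write_fixture(
    c(
      "# comment",
      "chr2\tsrc\tgene\t1001\t2000\t.\t+\t.\tgene_id \"gA\"; gene_name \"A\";",
      "chr2\tsrc\texon\t1001\t1200\t.\t+\t.\tgene_id \"gA\";",
      "chr2\tsrc\tgene\t5001\t6000\t.\t-\t.\tgene_id \"gB\";"
    ),
    ".gtf"
  )
  out <- read_gene_annotation(f, "gtf")
  expect_equal(nrow(out), 2)
  expect_equal(out$tss[out$gene_id == "gA"], 1000L)
  expect_equal(out$tss[out$gene_id == "gB"], 5999L)
})

test_that("promoter windows are strand-aware, 2 kb long, and clip at the origin", {
  genes <- tibble::tibble(
    gene_id = c("p", "m"), chrom = "chr1", tss = c(10000L, 10000L),
    strand = c("+", "-")
  )
  win <- promoter_windows(genes)
  expect_equal(win$start, c(8500L, 9500L))
  expect_equal(win$end, c(10500L, 11500L))
  expect_true(all(win$end - win$start == 2000L))

  near0 <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 1000L, strand = "+")
  expect_warning(winc <- promoter_windows(near0), "clipped")
  expect_equal(winc$start, 0L)
  expect_equal(winc$end, 1500L)
  expect_true(winc$clipped)
})

test_that("strand reversal reflects the promoter window about the TSS", {
  for (seed in 1:5) {
    tss <- withr::with_seed(seed, sample(5000:50000, 1))
    g <- tibble::tibble(
      gene_id = c("f", "r"), chrom = "c", tss = tss, strand = c("+", "-")
    )
    win <- promoter_windows(g)
    expect_equal(win$start[1] - tss, -(win$end[2] - tss))
    expect_equal(win$end[1] - tss, -(win$start[2] - tss))
  }
})

test_that("peaks_from_signal finds threshold runs intersected with the window", {
  window <- tibble::tibble(chrom = "c", start = 8500L, end = 10500L)
  flat <- tibble::tibble(chrom = "c", start = 8500L, end = 10500L, value = 0)
  expect_equal(nrow(peaks_from_signal(flat, window)), 0)

  block <- tibble::tibble(chrom = "c", start = 9000L, end = 9200L, value = 7)
  pk <- peaks_from_signal(block, window)
  expect_equal(pk$start, 9000L)
  expect_equal(pk$end, 9200L)
  expect_equal(pk$height, 7)

  # Two blocks separated by a sub-threshold gap stay two peaks; heights are
  # the per-run maxima and the summit sits on the first maximal interval.
  two <- tibble::tibble(
    chrom = "c",
    start = c(9000L, 9100L, 9150L, 9300L),
    end = c(9100L, 9150L, 9300L, 9400L),
    value = c(3, 5, 0.2, 4)
  )
  pks <- peaks_from_signal(two, window, min_height = 1)
  expect_equal(nrow(pks), 2)
  expect_equal(pks$start, c(9000L, 9300L))
  expect_equal(pks$end, c(9150L, 9400L))
  expect_equal(pks$height, c(5, 4))
  expect_equal(pks$summit[1], 9125L)

  # Intervals crossing the window edge are trimmed to it.
  wide <- tibble::tibble(chrom = "c", start = 8000L, end = 9000L, value = 2)
  trimmed <- peaks_from_signal(wide, window)
  expect_equal(trimmed$start, 8500L)
  expect_error(peaks_from_signal(block, window, min_height = 0), "min_height")
})

test_that("peak features follow the stated H, D, W formulas", {
  pk <- tibble::tibble(chrom = "c", start = 9000L, end = 9200L, height = 7)
  feat <- extract_peak_features(pk, tss = 10000L)
  expect_equal(feat$height, 7)
  expect_equal(feat$width, 200L)
  expect_equal(feat$distance, 900L)

  centred <- tibble::tibble(chrom = "c", start = 9900L, end = 10100L, height = 1)
  expect_equal(extract_peak_features(centred, 10000L)$distance, 0L)
})

test_that("select_strongest takes max height with distance/start tie-breaks, order-invariantly", {
  peaks <- tibble::tibble(
    chrom = "c",
    start = c(9000L, 9400L, 9800L),
    end = c(9200L, 9600L, 10000L),
    height = c(3, 9, 5)
  )
  expect_equal(select_strongest(peaks, 10000L)$height, 9)
  expect_equal(select_strongest(peaks[2, ], 10000L)$start, 9400L)

  tied <- tibble::tibble(
    chrom = "c",
    start = c(9850L, 9550L), # distances 50 and 350 from tss 10000
    end = c(9950L, 9650L),
    height = c(9, 9)
  )
  expect_equal(select_strongest(tied, 10000L)$start, 9850L)
  for (perm in list(1:2, 2:1)) {
    expect_equal(select_strongest(tied[perm, ], 10000L)$start, 9850L)
  }
})

test_that("join_expression is a strict inner join with warnings for unmatched keys", {
  features <- tibble::tibble(
    gene_id = "g1", day = c(0L, 1L, 3L, 5L, 7L, 11L, 15L, 18L),
    height = 1, distance = 10, width = 100
  )
  expression <- tibble::tibble(
    gene_id = "g1", day = features$day, expression = rnorm(8)
  )
  expect_equal(nrow(join_expression(features, expression)), 8)

  expect_warning(
    out <- join_expression(features, expression[-1, ]),
    "without expression"
  )
  expect_equal(nrow(out), 7)

  disjoint <- dplyr::mutate(expression, gene_id = "g2")
  expect_warning(expect_warning(out2 <- join_expression(features, disjoint)))
  expect_equal(nrow(out2), 0)

  expect_error(
    join_expression(dplyr::bind_rows(features, features[1, ]), expression),
    "duplicate"
  )
})

test_that("extract_features drops peakless genes with a warning", {
  genes <- tibble::tibble(
    gene_id = c("hit", "miss"), chrom = "c", tss = c(10000L, 50000L),
    strand = c("+", "+")
  )
  track <- tibble::tibble(chrom = "c", start = 9000L, end = 9200L, value = 7)
  expect_warning(feats <- extract_features(track, genes, day = 3), "miss")
  expect_equal(feats$gene_id, "hit")
  expect_equal(feats$height, 7)
  expect_equal(feats$distance, 900)
  expect_equal(feats$width, 200)
})
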