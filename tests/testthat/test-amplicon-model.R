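# breakpoint-graph and cycles file dialects, interval arithmetic

test_that("graph files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "SequenceEdge: StartPosition, EndPosition, PredictedCopyCount",
    "sequence\tchr1:10001-\tchr1:20000+\t8.000000\t120.000000"), f)
  g <- read_graph_file(f, amplicon_id = "amp1", sample_id = "s1")
  expect_s3_class(g, "amplicon_graph")
  expect_equal(nrow(g$segments), 1)
  expect_equal(g$segments$end - g$segments$start + 1, 10000)
  expect_equal(nrow(g$edges), 0)

  # 3 segments + 1 discordant edge joining segment 3 end to segment 1 start
  seg <- seg_df("chr1", c(10001, 30001, 50001), c(20000, 40000, 60000),
                c(8, 9, 10))
  ed <- edge_df("chr1", 60000, "head", "chr1", 10001, "tail", cn = 7.5)
  g2 <- amplicon_graph("amp2", "s1", seg, ed)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_graph_file(g2, f2)
  g2b <- read_graph_file(f2, amplicon_id = "amp2", sample_id = "s1")
  expect_equal(g2b$segments$start, g2$segments$start)
  expect_equal(g2b$segments$copy_count, g2$segments$copy_count)
  expect_equal(g2b$edges, g2$edges)
  # second round trip is byte-identical
  f3 <- withr::local_tempfile(fileext = ".txt")
  write_graph_file(g2b, f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("malformed graph records are rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("header", "sequence\tchr1:5000-\tchr1:4000+\t3.0"), f)
  expect_error(read_graph_file(f), "line 2")
  writeLines(c("header", "sequence\tchr1:XYZ-\tchr1:4000+\t3.0"), f)
  expect_error(read_graph_file(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_graph_file(f), "empty")
  writeLines(c("header", "sequence\tchr1:100-\tchr1:900+\t2.0",
               "weirdrecord\tfoo"), f)
  expect_warning(read_graph_file(f), "weirdrecord")
})

test_that("cycles files parse walks, sentinels and reject bad references", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Segment\t1\tchr1\t100\t5000",
               "Segment\t2\tchr1\t6000\t9000",
               "Cycle=1;Copy_count=12.0;Segments=1+,2+"), f)
  d <- read_cycles_file(f, amplicon_id = "amp1")
  expect_equal(nrow(d$cycles), 1)
  expect_true(d$cycles$is_cyclic[1])
  expect_equal(d$cycles$weight[1], 12)

  writeLines(c("Segment\t1\tchr1\t100\t5000",
               "Segment\t2\tchr1\t6000\t9000",
               "Cycle=1;Copy_count=4.0;Segments=0+,1+,2-,0-"), f)
  d2 <- read_cycles_file(f, amplicon_id = "amp1")
  expect_false(d2$cycles$is_cyclic[1])
  expect_equal(d2$cycles$segments[[1]], c("1+", "2-"))

  writeLines(c("Segment\t1\tchr1\t100\t5000",
               "Cycle=1;Copy_count=4.0;Segments=1+,3+"), f)
  expect_error(read_cycles_file(f), "undefined segment id")
  writeLines(c("Segment\t1\tchr1\t100\t5000",
               "Segment\t1\tchr1\t100\t5000"), f)
  expect_error(read_cycles_file(f), "duplicate")
})

test_that("cycles writer orders deterministically and round-trips", {
  segs <- data.frame(seg_id = 1:2, chrom = "chr2",
                     start = c(100, 7000), end = c(5000, 9000))
  cyc <- data.frame(cycle_id = 1:2, weight = c(3, 11),
                    is_cyclic = c(FALSE, TRUE))
  cyc$segments <- I(list("1+", c("1+", "2+")))
  d <- decomposition("ampX", segs, cyc)
  f <- withr::local_tempfile(fileext = ".txt")
  write_cycles_file(d, f)
  d2 <- read_cycles_file(f, amplicon_id = "ampX")
  # heaviest walk first after writing
  expect_equal(d2$cycles$weight, c(11, 3))
  expect_equal(d2$cycles$is_cyclic, c(TRUE, FALSE))
  expect_equal(d2$cycles$segments[[1]], c("1+", "2+"))
  expect_equal(d2$segments[order(d2$segments$seg_id), ]$start, segs$start)
})

test_that("breakpoint edges are symmetric under endpoint swap", {
  e1 <- edge_df("chr2", 5e6, "head", "chr1", 1e6, "tail")
  e2 <- edge_df("chr1", 1e6, "tail", "chr2", 5e6, "head")
  expect_identical(edge_keys(rbind(e1)), edge_keys(rbind(e2)))
  seg <- seg_df(c("chr1", "chr2"), c(1e6, 4.9e6), c(1.1e6, 5e6), 8)
  g1 <- amplicon_graph("a", "s", seg, e1)
  g2 <- amplicon_graph("a", "s", seg, e2)
  expect_equal(g1$edges, g2$edges)
})

test_that("graph invariants are enforced", {
  expect_error(amplicon_graph("a", "s",
                              seg_df("chr1", c(100, 500), c(1000, 1500),
                                     5)),
               "overlap")
  seg <- seg_df("chr1", 1000, 2000, -1)
  expect_error(amplicon_graph("a", "s", seg), "negative")
  # discordant endpoint off every segment boundary
  seg2 <- seg_df("chr1", 1000, 2000, 8)
  bad <- edge_df("chr1", 1500, "head", "chr1", 1000, "tail")
  expect_error(amplicon_graph("a", "s", seg2, bad), "boundar")
  # concordant edges must join adjacent positions
  bad2 <- edge_df("chr1", 2000, "head", "chr1", 2500, "tail",
                  kind = "concordant")
  expect_error(amplicon_graph("a", "s", seg2, bad2), "adjacent")
})

test_that("amplified_intervals matches per-base brute force and merges", {
  seg <- seg_df("chr1", c(1000, 3000, 5000), c(2000, 4000, 6000),
                c(8, 3, 6))
  g <- amplicon_graph("a", "s", seg)
  got <- amplified_intervals(g, 4.5)
  expect_equal(nrow(got), 2)
  expect_equal(got$start, c(1000, 5000))

  # abutting segments merge into one at a permissive threshold
  seg2 <- seg_df("chr1", c(1000, 2001), c(2000, 3000), c(5, 6))
  got2 <- amplified_intervals(amplicon_graph("b", "s", seg2), 0.1)
  expect_equal(nrow(got2), 1)
  expect_equal(c(got2$start, got2$end), c(1000, 3000))

  # randomized graphs against the per-base oracle
  set.seed(42)
  for (rep in 1:10) {
    n <- 50
    start <- sort(sample.int(5e5, n)) * 10
    seg <- seg_df(sample(paste0("chr", 1:3), n, replace = TRUE),
                  start, start + sample.int(5000, n), runif(n, 0, 12))
    seg <- seg[!duplicated(seg$chrom) | TRUE, ]
    # drop overlaps within a chromosome to satisfy the graph invariant
    keep <- rep(TRUE, n)
    for (chr in unique(seg$chrom)) {
      idx <- which(seg$chrom == chr)
      idx <- idx[order(seg$start[idx])]
      last_end <- -Inf
      for (i in idx) {
        if (seg$start[i] <= last_end) keep[i] <- FALSE
        else last_end <- seg$end[i]
      }
    }
    seg <- seg[keep, ]
    g <- amplicon_graph("r", "s", seg)
    got <- amplified_intervals(g, 4.5)
    expect_intervals_equal(got, brute_amplified(seg, 4.5))
  }
})

test_that("amplified length is monotone non-increasing in the threshold", {
  set.seed(7)
  start <- seq(1e5, by = 1e4, length.out = 30)
  seg <- seg_df("chr1", start, start + sample.int(8000, 30), runif(30, 0, 15))
  g <- amplicon_graph("m", "s", seg)
  lens <- vapply(c(0.5, 2, 4.5, 6, 10, 14),
                 function(thr) intervals_total_length(amplified_intervals(g, thr)),
                 numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("base-R interval scans agree with the GenomicRanges route", {
  set.seed(99)
  rand_iv <- function(n) {
    s <- sample.int(1e5, n)
    genomic_intervals(sample(paste0("chr", 1:3), n, replace = TRUE),
                      s, s + sample.int(5e3, n))
  }
  for (rep in 1:20) {
    a <- rand_iv(8); b <- rand_iv(8)
    ga <- GenomicRanges::reduce(GenomicRanges::GRanges(
      a$chrom, IRanges::IRanges(a$start, a$end)))
    gb <- GenomicRanges::reduce(GenomicRanges::GRanges(
      b$chrom, IRanges::IRanges(b$start, b$end)))
    expect_equal(intervals_intersect_length(a, b),
                 sum(IRanges::width(suppressWarnings(
                   GenomicRanges::intersect(ga, gb)))))
    expect_equal(intervals_union_length(a, b),
                 sum(IRanges::width(suppressWarnings(
                   GenomicRanges::reduce(c(ga, gb))))))
  }
})
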