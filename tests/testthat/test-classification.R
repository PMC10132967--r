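# foldback detection, the classification cascade, deduplication ranking

test_that("foldbacks are inverted near-coincident same-chromosome edges", {
  seg <- seg_df("chr17", c(1e6, 1.002e6 + 1), c(1.002e6, 1.1e6), 12)
  fb <- edge_df("chr17", 1e6, "head", "chr17", 1.002e6, "head")
  g <- amplicon_graph("a", "s", seg, fb)
  expect_equal(nrow(detect_foldbacks(g, 25000)), 1)

  ht <- edge_df("chr17", 1e6, "head", "chr17", 1.002e6 + 1, "tail")
  g2 <- amplicon_graph("a", "s", seg, ht)
  expect_equal(nrow(detect_foldbacks(g2, 25000)), 0)

  # too far apart
  seg3 <- seg_df("chr17", c(1e6, 1.1e6), c(1.05e6, 1.2e6), 12)
  far <- edge_df("chr17", 1e6, "tail", "chr17", 1.1e6, "tail")
  g3 <- amplicon_graph("a", "s", seg3, far)
  expect_equal(nrow(detect_foldbacks(g3, 25000)), 0)
  expect_equal(nrow(detect_foldbacks(g3, 2e5)), 1)
})

test_that("random edge sets match a brute-force foldback scan", {
  set.seed(31)
  chroms <- paste0("chr", 1:3)
  n <- 100
  # place edges on boundaries of a dense segment grid so validation passes
  starts <- seq(1e5, by = 5e4, length.out = 80)
  seg <- seg_df(rep(chroms, length.out = 80), starts, starts + 4e4, 10)
  bounds <- rbind(data.frame(chrom = seg$chrom, pos = seg$start),
                  data.frame(chrom = seg$chrom, pos = seg$end))
  i1 <- sample.int(nrow(bounds), n, replace = TRUE)
  i2 <- sample.int(nrow(bounds), n, replace = TRUE)
  edges <- edge_df(bounds$chrom[i1], bounds$pos[i1],
                   sample(c("head", "tail"), n, TRUE),
                   bounds$chrom[i2], bounds$pos[i2],
                   sample(c("head", "tail"), n, TRUE))
  g <- amplicon_graph("r", "s", seg, edges)
  got <- detect_foldbacks(g, 25000)
  e <- g$edges[g$edges$kind == "discordant", ]
  manual <- e[e$chrom1 == e$chrom2 & abs(e$pos1 - e$pos2) <= 25000 &
                e$side1 == e$side2, ]
  expect_equal(nrow(got), nrow(manual))
  expect_equal(got, manual)
})

make_decomp <- function(id, seg, cycles_weight, cyclic, tokens) {
  segs <- data.frame(seg_id = seq_len(nrow(seg)), chrom = seg$chrom,
                     start = seg$start, end = seg$end)
  cyc <- data.frame(cycle_id = seq_along(cycles_weight),
                    weight = cycles_weight, is_cyclic = cyclic)
  cyc$segments <- I(tokens)
  decomposition(id, segs, cyc)
}

test_that("cascade archetypes classify as expected", {
  # cyclic walk at amplified weight covering all amplified bases -> ecDNA
  seg <- seg_df("chr1", 1e6, 1.09e6, 20)
  edges <- edge_df("chr1", 1.09e6, "head", "chr1", 1e6, "tail", cn = 20)
  g <- amplicon_graph("e1", "s", seg, edges)
  d <- make_decomp("e1", seg, 20, TRUE, list("1+"))
  got <- classify_amplicon(g, d)
  expect_equal(got$amplicon_class, "ecDNA")
  expect_equal(got$n_ecdna_species, 1)
  expect_equal(got$max_copy_number, 20)

  # foldback-dominated ladder, no qualifying cycle -> BFB
  seg2 <- seg_df("chr2", c(1e6, 1.012e6, 1.19e6),
                 c(1.012e6 - 1, 1.19e6 - 1, 1.2e6), c(8, 16, 8))
  fb <- rbind(
    edge_df("chr2", 1e6, "tail", "chr2", 1.012e6, "tail", cn = 8),
    edge_df("chr2", 1.2e6, "head", "chr2", 1.19e6 - 1, "head", cn = 8))
  g2 <- amplicon_graph("b1", "s", seg2, fb)
  d2 <- make_decomp("b1", seg2, c(6, 4), c(FALSE, FALSE),
                    list(c("1+", "2+"), "2+"))
  expect_equal(classify_amplicon(g2, d2)$amplicon_class, "BFB")

  # many non-foldback junctions, no cycle -> complex non-cyclic
  seg3 <- seg_df("chr3", c(1e6, 2e6, 3e6), c(1.1e6, 2.1e6, 3.1e6), 8)
  web <- rbind(
    edge_df("chr3", 1.1e6, "head", "chr3", 2e6, "tail", cn = 4),
    edge_df("chr3", 2.1e6, "head", "chr3", 1e6, "tail", cn = 4),
    edge_df("chr3", 2.1e6, "head", "chr3", 3e6, "tail", cn = 4))
  g3 <- amplicon_graph("c1", "s", seg3, web)
  d3 <- make_decomp("c1", seg3, c(4, 3), c(FALSE, FALSE),
                    list("1+", c("2+", "3+")))
  expect_equal(classify_amplicon(g3, d3)$amplicon_class,
               "complex_non_cyclic")

  # amplified run with no junctions -> linear
  g4 <- amplicon_graph("l1", "s", seg_df("chr4", 1e6, 1.3e6, 7))
  d4 <- make_decomp("l1", seg_df("chr4", 1e6, 1.3e6, 7), 7, FALSE,
                    list("1+"))
  expect_equal(classify_amplicon(g4, d4)$amplicon_class, "linear")

  # mismatched identifiers are refused
  expect_error(classify_amplicon(g4, d3), "different amplicons")
})

test_that("two disjoint qualifying cycles count as two ecDNA species", {
  seg <- seg_df(c("chr1", "chr2"), c(1e6, 5e6), c(1.1e6, 5.1e6), 18)
  edges <- rbind(
    edge_df("chr1", 1.1e6, "head", "chr1", 1e6, "tail", cn = 18),
    edge_df("chr2", 5.1e6, "head", "chr2", 5e6, "tail", cn = 18))
  g <- amplicon_graph("m1", "s", seg, edges)
  d <- make_decomp("m1", seg, c(18, 18), c(TRUE, TRUE),
                   list("1+", "2+"))
  # each cycle explains one of the two equal-sized amplified components,
  # i.e. just under half of the amplified bases
  got <- classify_amplicon(g, d,
                           classifier_params(ecdna_cycle_weight_min = 0.4))
  expect_equal(got$amplicon_class, "ecDNA")
  expect_equal(got$n_ecdna_species, 2)
})

test_that("classification is deterministic", {
  cfg <- default_config()
  st <- simulate_structure(toy_genome(), "ecDNA", cfg, seed = 77,
                           grade = "EAC")
  a <- classify_amplicon(st$graph, st$decomposition)
  b <- classify_amplicon(st$graph, st$decomposition)
  expect_identical(a[c("amplicon_class", "max_copy_number",
                       "n_ecdna_species", "complexity_bits")],
                   b[c("amplicon_class", "max_copy_number",
                       "n_ecdna_species", "complexity_bits")])
})

test_that("dedup keeps the best-ranked, largest, lexicographically first", {
  ec <- toy_ecdna("a_ec", "chr1", 1e6, 1e5, 20)
  lin_seg <- seg_df("chr1", 1.05e6, 1.25e6, 6)
  lin <- classify_amplicon(
    amplicon_graph("b_lin", "s1", lin_seg),
    make_decomp("b_lin", lin_seg, 6, FALSE, list("1+")))
  expect_equal(vapply(deduplicate_amplicons(list(lin, ec)),
                      function(a) a$amplicon_id, character(1)), "a_ec")

  # same class: largest amplified footprint wins
  big <- toy_ecdna("bfb_big", "chr2", 1e6, 12e5, 18)
  small <- toy_ecdna("bfb_small", "chr2", 1.5e6, 8e5, 18)
  expect_equal(deduplicate_amplicons(list(small, big))[[1]]$amplicon_id,
               "bfb_big")

  # disjoint amplicons are all kept; the operation is idempotent and
  # order-invariant
  other <- toy_ecdna("c_ec", "chr3", 2e6, 1e5, 15)
  once <- deduplicate_amplicons(list(ec, lin, other))
  twice <- deduplicate_amplicons(once)
  expect_equal(vapply(once, function(a) a$amplicon_id, character(1)),
               vapply(twice, function(a) a$amplicon_id, character(1)))
  perm <- deduplicate_amplicons(list(other, ec, lin))
  expect_equal(vapply(once, function(a) a$amplicon_id, character(1)),
               vapply(perm, function(a) a$amplicon_id, character(1)))
})

test_that("sample status aggregates species over amplicons", {
  expect_equal(sample_ecdna_status(list()),
               list(is_positive = FALSE, n_species = 0L))
  ec <- toy_ecdna("a", "chr1", 1e6, 1e5, 20)
  ec2 <- toy_ecdna("b", "chr2", 1e6, 1e5, 16)
  lin_seg <- seg_df("chr3", 1e6, 1.2e6, 6)
  lin <- classify_amplicon(
    amplicon_graph("c", "s1", lin_seg),
    make_decomp("c", lin_seg, 6, FALSE, list("1+")))
  expect_equal(sample_ecdna_status(list(ec, lin)),
               list(is_positive = TRUE, n_species = 1L))
  expect_equal(sample_ecdna_status(list(ec, ec2)),
               list(is_positive = TRUE, n_species = 2L))
})
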