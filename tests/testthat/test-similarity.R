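# breakpoint matching, the similarity score and its empirical null

test_that("identical edge lists match fully; tolerance is a hard boundary", {
  e <- rbind(edge_df("chr1", 1e6, "head", "chr1", 2e6, "tail"),
             edge_df("chr1", 3e6, "head", "chr2", 4e6, "tail"),
             edge_df("chr2", 5e6, "head", "chr2", 6e6, "head"))
  expect_equal(nrow(match_breakpoints(e, e, tol = 100)), 3)

  shifted <- e[1, ]
  shifted$pos1 <- shifted$pos1 + 150
  shifted$pos2 <- shifted$pos2 + 150
  expect_equal(nrow(match_breakpoints(e[1, ], shifted, tol = 100)), 0)
  expect_equal(nrow(match_breakpoints(e[1, ], shifted, tol = 200)), 1)

  # endpoint-swapped edges still match
  sw <- edge_df("chr1", 2e6, "tail", "chr1", 1e6, "head")
  expect_equal(nrow(match_breakpoints(e[1, ], sw, tol = 0)), 1)
})

# exhaustive maximum bipartite matching for small instances
brute_matching <- function(edges_a, edges_b, tol) {
  compat <- function(i, j) {
    nrow(match_breakpoints(edges_a[i, , drop = FALSE],
                           edges_b[j, , drop = FALSE], tol)) == 1
  }
  na <- nrow(edges_a); nb <- nrow(edges_b)
  cm <- outer(seq_len(na), seq_len(nb), Vectorize(compat))
  best <- 0
  recurse <- function(i, used) {
    if (i > na) return(0)
    top <- recurse(i + 1, used)  # skip edge i
    for (j in seq_len(nb)) {
      if (!used[j] && cm[i, j]) {
        used2 <- used; used2[j] <- TRUE
        top <- max(top, 1 + recurse(i + 1, used2))
      }
    }
    top
  }
  recurse(1, rep(FALSE, nb))
}

test_that("greedy matching achieves the exhaustive optimum on small sets", {
  set.seed(17)
  rand_edges <- function(n) {
    p1 <- sample.int(1e6, n) * 3
    p2 <- sample.int(1e6, n) * 3 + 1e6
    edge_df(sample(paste0("chr", 1:2), n, TRUE), p1,
            sample(c("head", "tail"), n, TRUE),
            sample(paste0("chr", 1:2), n, TRUE), p2,
            sample(c("head", "tail"), n, TRUE))
  }
  for (rep in 1:15) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- rand_edges(na)
    b <- rand_edges(nb)
    # make some b edges jittered copies of a edges so matches exist
    ncopy <- min(na, nb, sample(0:3, 1))
    if (ncopy > 0) {
      b[seq_len(ncopy), ] <- a[seq_len(ncopy), ]
      b$pos1[seq_len(ncopy)] <- b$pos1[seq_len(ncopy)] +
        sample(-80:80, ncopy, TRUE)
      b$pos2[seq_len(ncopy)] <- b$pos2[seq_len(ncopy)] +
        sample(-80:80, ncopy, TRUE)
    }
    got <- nrow(match_breakpoints(a, b, tol = 100))
    expect_equal(got, brute_matching(a, b, tol = 100))
  }
})

test_that("score is 1 on self, 0 on disjoint, and matches hand computation", {
  a <- toy_ecdna("a", "chr1", 1e6, 1e5, 20)
  expect_equal(similarity_score(a, a)$score, 1.0)

  b <- toy_ecdna("b", "chr2", 5e6, 2e5, 15)
  expect_equal(similarity_score(a, b)$score, 0.0)

  # a: one 100 kb interval + 2 junctions; b: interval extended to 150 kb,
  # sharing exactly 1 of its 2 junctions
  seg_a <- seg_df("chr1", 1e6, 1e6 + 1e5 - 1, 20)
  ed_a <- rbind(
    edge_df("chr1", 1e6 + 1e5 - 1, "head", "chr1", 1e6, "tail", cn = 20),
    edge_df("chr1", 1e6, "tail", "chr3", 2e6, "head", cn = 5))
  ga <- amplicon_graph("ha", "s1",
                       rbind(seg_a, seg_df("chr3", 1.9e6, 2e6, 20)), ed_a)
  da <- decomposition("ha", data.frame(seg_id = 1L, chrom = "chr1",
                                       start = 1e6, end = 1e6 + 1e5 - 1),
                      local({
                        cy <- data.frame(cycle_id = 1L, weight = 20,
                                         is_cyclic = TRUE)
                        cy$segments <- I(list("1+")); cy
                      }))
  seg_b <- seg_df("chr1", 1e6, 1e6 + 1.5e5 - 1, 20)
  ed_b <- rbind(
    edge_df("chr1", 1e6 + 1.5e5 - 1, "head", "chr1", 1e6, "tail", cn = 20),
    edge_df("chr1", 1e6, "tail", "chr3", 2e6, "head", cn = 5))
  gb <- amplicon_graph("hb", "s2",
                       rbind(seg_b, seg_df("chr3", 1.9e6, 2e6, 20)), ed_b)
  # compare footprints on chr1 only: restrict amplified intervals by hand
  A <- classify_amplicon(ga, da)
  A$amplified <- genomic_intervals("chr1", 1e6, 1e6 + 1e5 - 1)
  B <- A
  B$amplicon_id <- "hb"
  B$graph <- gb
  B$amplified <- genomic_intervals("chr1", 1e6, 1e6 + 1.5e5 - 1)
  res <- similarity_score(A, B)
  expect_equal(res$genomic_jaccard, 1e5 / 1.5e5, tolerance = 1e-6)
  expect_equal(res$breakpoint_jaccard, 1 / 3)
  expect_equal(res$score, (res$genomic_jaccard + res$breakpoint_jaccard) / 2)

  # empty amplified intervals are an error
  E <- A; E$amplified <- E$amplified[0, ]
  expect_error(similarity_score(E, B), "non-empty")
})

test_that("score is symmetric, bounded, and monotone in shared content", {
  cfg <- default_config()
  set.seed(12)
  for (rep in 1:25) {
    a <- classify_structure(simulate_structure(toy_genome(), "ecDNA", cfg,
                                               seed = 1000 + rep))
    b <- classify_structure(simulate_structure(toy_genome(), "ecDNA", cfg,
                                               seed = 2000 + rep))
    sab <- similarity_score(a, b)$score
    sba <- similarity_score(b, a)$score
    expect_equal(sab, sba)
    expect_gte(sab, 0); expect_lte(sab, 1)
  }

  # adding a shared junction never decreases the score; an unshared one
  # never increases it
  base_a <- toy_ecdna("ma", "chr1", 1e6, 1e5, 20)
  base_b <- toy_ecdna("mb", "chr1", 1.02e6, 1e5, 18, sample_id = "s2")
  s0 <- similarity_score(base_a, base_b)$score
  shared <- edge_df("chr2", 3e6, "head", "chr2", 3.5e6, "tail")
  a2 <- base_a; a2$graph$edges <- rbind(a2$graph$edges, shared)
  b2 <- base_b; b2$graph$edges <- rbind(b2$graph$edges, shared)
  expect_gte(similarity_score(a2, b2)$score, s0)
  a3 <- base_a
  a3$graph$edges <- rbind(a3$graph$edges,
                          edge_df("chr4", 8e6, "head", "chr4", 8.5e6,
                                  "tail"))
  expect_lte(similarity_score(a3, base_b)$score, s0)
})

test_that("the empirical p-value follows the add-one formula and the seed", {
  a <- toy_ecdna("pa", "chr1", 1e6, 1e5, 20)
  res <- similarity_score(a, a)
  # 999 null scores all below 1 -> p = 1/1000
  res1 <- similarity_p_value(res, a, a, background = NULL,
                             null_scores = rep(0.3, 999))
  expect_equal(res1$p_value, 1 / 1000)
  # observed score 0 -> p = 1
  b <- toy_ecdna("pb", "chr3", 5e6, 1e5, 15)
  res0 <- similarity_score(a, b)
  expect_equal(similarity_p_value(res0, a, b, background = NULL,
                                  null_scores = runif(500))$p_value, 1)

  # reproducible bit-for-bit under a fixed seed (random-placement null);
  # a cramped genome forces frequent overlap so seeds are distinguishable
  g <- c(chr1 = 5e5)
  n1 <- null_similarity_scores(list(), n_null = 120, seed = 9, genome = g,
                               pair_a = a, pair_b = a)
  n2 <- null_similarity_scores(list(), n_null = 120, seed = 9, genome = g,
                               pair_a = a, pair_b = a)
  expect_identical(n1, n2)
  n3 <- null_similarity_scores(list(), n_null = 120, seed = 10, genome = g,
                               pair_a = a, pair_b = a)
  expect_false(identical(n1, n3))
  expect_gt(sum(n1 > 0), 0)
})

test_that("empirical cross-patient null is used when pairs are plentiful", {
  cfg <- default_config()
  bg <- lapply(1:20, function(i) {
    amp <- classify_structure(simulate_structure(toy_genome(), "ecDNA", cfg,
                                                 seed = 5000 + i))
    amp$patient_id <- paste0("p", i)
    amp
  })
  # 20 amplicons from distinct patients: 190 distinct pairs >= n_null = 100
  ns <- null_similarity_scores(bg, n_null = 100, seed = 3)
  expect_length(ns, 100)
  expect_true(all(ns >= 0 & ns <= 1))
  expect_identical(ns, null_similarity_scores(bg, n_null = 100, seed = 3))
})

test_that("clonal pairs are found within patients and not across lineages", {
  cfg <- default_config()
  parent <- simulate_structure(toy_genome(), "ecDNA", cfg, seed = 41,
                               amplicon_id = "sA_amplicon1",
                               sample_id = "sA", grade = "HGD",
                               lineage_id = "L1")
  child <- evolve_clone(parent, 1, cfg, seed = 42,
                        amplicon_id = "sB_amplicon1", sample_id = "sB")
  unrelated <- simulate_structure(toy_genome(), "ecDNA", cfg, seed = 43,
                                  amplicon_id = "sC_amplicon1",
                                  sample_id = "sC", grade = "HGD",
                                  lineage_id = "L2")
  mk_sample <- function(st, sid, pat, tp, hist) {
    list(sample_id = sid, patient_id = pat, time_point = tp,
         level_cm = 30, histology_windowed = hist,
         amplicons = list(classify_structure(st)))
  }
  samples <- list(
    mk_sample(parent, "sA", "pat1", "TP1", "HGD"),
    mk_sample(child, "sB", "pat1", "TP2", "EAC"),
    mk_sample(unrelated, "sC", "pat2", "TP1", "HGD"))
  pairs <- find_clonal_pairs(samples, n_null = 200, seed = 5,
                             genome = toy_genome())
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$patient_id, "pat1")
  expect_equal(pairs$sample_a, "sA")       # less severe histology first
  expect_lt(pairs$p_value, 0.05)
  expect_gt(pairs$cn_delta, 0)

  # a patient with two structurally unrelated ecDNAs yields no pair
  other <- simulate_structure(toy_genome(), "ecDNA", cfg, seed = 44,
                              amplicon_id = "sD_amplicon1",
                              sample_id = "sD", grade = "HGD",
                              lineage_id = "L3")
  samples2 <- list(
    mk_sample(unrelated, "sC", "pat2", "TP1", "HGD"),
    mk_sample(other, "sD", "pat2", "TP2", "EAC"),
    mk_sample(parent, "sA", "pat1", "TP1", "HGD"))
  pairs2 <- find_clonal_pairs(samples2, n_null = 200, seed = 5,
                              genome = toy_genome())
  expect_equal(nrow(pairs2), 0)
})
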