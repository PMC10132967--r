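# fixture builders shared across test files; everything is generated in
# code so the suite carries no data files

seg_df <- function(chrom, start, end, cn, coverage = NA_real_) {
  data.frame(chrom = chrom, start = start, end = end, copy_count = cn,
             coverage = coverage, stringsAsFactors = FALSE)
}

edge_df <- function(chrom1, pos1, side1, chrom2, pos2, side2,
                    kind = "discordant", cn = 5, support = 10) {
  data.frame(chrom1 = chrom1, pos1 = pos1, side1 = side1,
             chrom2 = chrom2, pos2 = pos2, side2 = side2,
             kind = kind, copy_count = cn, support = support,
             stringsAsFactors = FALSE)
}

# a one-segment circular amplicon as a classified object
toy_ecdna <- function(id = "a1", chrom = "chr1", start = 1e6, len = 1e5,
                      cn = 20, sample_id = "s1") {
  seg <- seg_df(chrom, start, start + len - 1, cn)
  edges <- edge_df(chrom, start + len - 1, "head", chrom, start, "tail",
                   cn = cn)
  g <- amplicon_graph(id, sample_id, seg, edges)
  d <- decomposition(id,
                     data.frame(seg_id = 1L, chrom = chrom, start = start,
                                end = start + len - 1),
                     local({
                       cy <- data.frame(cycle_id = 1L, weight = cn,
                                        is_cyclic = TRUE)
                       cy$segments <- I(list("1+"))
                       cy
                     }))
  classify_amplicon(g, d)
}

# per-base brute force: union of covered bases above a threshold
brute_amplified <- function(segments, thr) {
  out <- list()
  for (chr in unique(segments$chrom)) {
    sub <- segments[segments$chrom == chr & segments$copy_count >= thr, ,
                    drop = FALSE]
    if (nrow(sub) == 0) next
    bases <- sort(unique(unlist(mapply(seq, sub$start, sub$end,
                                       SIMPLIFY = FALSE))))
    if (length(bases) == 0) next
    # allow a 1 bp gap when reconstituting runs, matching the merge rule
    brk <- c(0, which(diff(bases) > 2), length(bases))
    for (k in seq_len(length(brk) - 1)) {
      run <- bases[(brk[k] + 1):brk[k + 1]]
      out[[length(out) + 1]] <- data.frame(chrom = chr, start = min(run),
                                           end = max(run),
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(data.frame(chrom = character(),
                                          start = numeric(),
                                          end = numeric()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

expect_intervals_equal <- function(a, b) {
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_equal(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
}

default_config <- function(seed = 1, design = "fhcc") {
  sim_config(seed = seed, design = design)
}

classify_structure <- function(st, params = classifier_params()) {
  classify_amplicon(st$graph, st$decomposition, params)
}
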