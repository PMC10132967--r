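#' Amplicon similarity and clonality
#'
#' To decide whether genomically overlapping amplicons observed in different
#' biopsies of the same patient share a common origin, amplicons are
#' compared with a similarity score in \[0, 1\] combining two Jaccard
#' indices: the base-pair Jaccard of the amplified genomic footprints and
#' the Jaccard of the matched discordant junction sets. Significance is
#' assessed empirically against a null of cross-patient amplicon pairs
#' (which cannot be clonally related), falling back to a random-placement
#' null when too few background pairs exist. Within-patient ecDNA pairs
#' that overlap genomically and score significantly are called clonal.
#'
#' @name similarity
NULL

#' Match discordant breakpoint edges between two amplicons
#'
#' Greedy one-to-one matching in deterministic coordinate order: two edges
#' match when, for some assignment of endpoints (allowing the whole-edge
#' endpoint swap), both endpoint positions agree within `tol` bp on the same
#' chromosome and the endpoint sides agree. Among compatible candidates the
#' closest (smallest maximum endpoint offset) is taken first.
#'
#' @param edges_a,edges_b Edge data frames (as in [amplicon_graph()];
#'   discordant rows are used).
#' @param tol Position tolerance in bp.
#' @return Data frame with columns `idx_a`, `idx_b` (row indices of the
#'   matched discordant edges).
#' @export
match_breakpoints <- function(edges_a, edges_b, tol = 100) {
  stopifnot(tol >= 0)
  a <- canonical_edges(edges_a[edges_a$kind == "discordant", , drop = FALSE])
  b <- canonical_edges(edges_b[edges_b$kind == "discordant", , drop = FALSE])
  na <- nrow(a); nb <- nrow(b)
  out <- data.frame(idx_a = integer(), idx_b = integer())
  if (na == 0 || nb == 0) return(out)
  # pairwise offsets; canonicalization already resolves the whole-edge
  # endpoint swap for exact edges, but a swapped comparison is still needed
  # when tolerance flips the canonical order of near-coincident endpoints
  off <- matrix(Inf, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d1 <- abs(a$pos1[i] - b$pos1[j]); d2 <- abs(a$pos2[i] - b$pos2[j])
    if (a$chrom1[i] == b$chrom1[j] && a$chrom2[i] == b$chrom2[j] &&
        a$side1[i] == b$side1[j] && a$side2[i] == b$side2[j] &&
        d1 <= tol && d2 <= tol) {
      off[i, j] <- max(d1, d2)
    }
    s1 <- abs(a$pos1[i] - b$pos2[j]); s2 <- abs(a$pos2[i] - b$pos1[j])
    if (a$chrom1[i] == b$chrom2[j] && a$chrom2[i] == b$chrom1[j] &&
        a$side1[i] == b$side2[j] && a$side2[i] == b$side1[j] &&
        s1 <= tol && s2 <= tol) {
      off[i, j] <- min(off[i, j], max(s1, s2))
    }
  }
  used_b <- rep(FALSE, nb)
  idx_a <- integer(0); idx_b <- integer(0)
  for (i in seq_len(na)) {
    cand <- which(!used_b & is.finite(off[i, ]))
    if (length(cand) == 0) next
    best <- cand[which.min(off[i, cand])]
    used_b[best] <- TRUE
    idx_a <- c(idx_a, i); idx_b <- c(idx_b, best)
  }
  data.frame(idx_a = idx_a, idx_b = idx_b)
}

#' Amplicon similarity score
#'
#' `genomic_jaccard` is the base-pair Jaccard index of the two amplified
#' footprints; `breakpoint_jaccard` is m / (|E_a| + |E_b| - m) over
#' discordant edges with m matches from [match_breakpoints()]. The combined
#' score is their mean when both amplicons carry at least one discordant
#' edge, otherwise the genomic Jaccard alone.
#'
#' @param a,b `classified_amplicon` objects with non-empty amplified
#'   intervals.
#' @param tol Breakpoint position tolerance in bp.
#' @return List of class `similarity_result` with fields `amplicon_a`,
#'   `amplicon_b`, `genomic_jaccard`, `breakpoint_jaccard`, `score`,
#'   `p_value` (NA until [similarity_p_value()]), `n_null`.
#' @export
similarity_score <- function(a, b, tol = 100) {
  if (nrow(a$amplified) == 0 || nrow(b$amplified) == 0) {
    stop("similarity requires non-empty amplified intervals")
  }
  gj <- if (!intervals_overlap_any(a$amplified, b$amplified)) 0 else
    intervals_intersect_length(a$amplified, b$amplified) /
      intervals_union_length(a$amplified, b$amplified)
  ea <- a$graph$edges[a$graph$edges$kind == "discordant", , drop = FALSE]
  eb <- b$graph$edges[b$graph$edges$kind == "discordant", , drop = FALSE]
  if (nrow(ea) > 0 && nrow(eb) > 0) {
    m <- nrow(match_breakpoints(ea, eb, tol))
    bj <- m / (nrow(ea) + nrow(eb) - m)
    score <- (gj + bj) / 2
  } else {
    bj <- NA_real_
    score <- gj
  }
  structure(list(amplicon_a = a$amplicon_id, amplicon_b = b$amplicon_id,
                 genomic_jaccard = gj, breakpoint_jaccard = bj,
                 score = score, p_value = NA_real_, n_null = 0L),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity> %s vs %s: score %.3f (genomic %.3f, breakpoint %s), p %s\n",
              x$amplicon_a, x$amplicon_b, x$score, x$genomic_jaccard,
              ifelse(is.na(x$breakpoint_jaccard), "NA",
                     sprintf("%.3f", x$breakpoint_jaccard)),
              ifelse(is.na(x$p_value), "NA", format(x$p_value))))
  invisible(x)
}

#' Empirical significance of a similarity score
#'
#' Null similarity scores are computed on `n_null` amplicon pairs sampled
#' (with a fixed seed) from cross-patient background pairs -- pairs that
#' cannot be clonally related. The p-value is
#' `(1 + #\{null >= observed\}) / (n_null + 1)`. When the background yields
#' fewer than `n_null` distinct pairs, a random-placement null is used
#' instead: the two amplicons' footprints (with their junctions) are placed
#' uniformly on the genome and re-scored. Callers must ensure the
#' background amplicons come from patients other than those of `a` and `b`.
#'
#' @param result A [similarity_score()] result for the pair.
#' @param a,b The two amplicons of the pair.
#' @param background List of cross-patient `classified_amplicon` objects.
#' @param n_null Number of null draws (>= 100).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param tol Breakpoint tolerance, as in [similarity_score()].
#' @param genome Named vector of chromosome lengths for the
#'   random-placement fallback.
#' @param null_scores Optional precomputed null scores (e.g. from
#'   [null_similarity_scores()]) to reuse across pairs.
#' @return The result with `p_value` and `n_null` filled in.
#' @export
similarity_p_value <- function(result, a, b, background, n_null = 1000,
                               seed = 1, tol = 100, genome = NULL,
                               null_scores = NULL) {
  stopifnot(n_null >= 100)
  if (is.null(null_scores)) {
    null_scores <- null_similarity_scores(background, n_null = n_null,
                                          seed = seed, tol = tol,
                                          genome = genome,
                                          pair_a = a, pair_b = b)
  }
  result$p_value <- (1 + sum(null_scores >= result$score)) /
    (length(null_scores) + 1)
  result$n_null <- length(null_scores)
  result
}

#' Null distribution of similarity scores
#'
#' @inheritParams similarity_p_value
#' @param pair_a,pair_b Amplicons used by the random-placement fallback when
#'   the empirical background is too small.
#' @return Numeric vector of `n_null` null scores.
#' @export
null_similarity_scores <- function(background, n_null = 1000, seed = 1,
                                   tol = 100, genome = NULL,
                                   pair_a = NULL, pair_b = NULL) {
  # cross-patient pairs: all unordered pairs whose patient labels differ
  patient_of <- vapply(background, function(x)
    attr_or(x, "patient_id", x$sample_id), character(1))
  n <- length(background)
  pairs <- if (n >= 2) {
    idx <- utils::combn(n, 2)
    keep <- patient_of[idx[1, ]] != patient_of[idx[2, ]]
    idx[, keep, drop = FALSE]
  } else matrix(integer(0), nrow = 2)

  rng <- make_rng(seed)
  if (ncol(pairs) >= n_null) {
    sel <- sample_int(rng, ncol(pairs), n_null)
    vapply(sel, function(k) {
      similarity_score(background[[pairs[1, k]]],
                       background[[pairs[2, k]]], tol)$score
    }, numeric(1))
  } else {
    if (is.null(genome)) {
      stop("background has fewer than n_null distinct cross-patient pairs ",
           "and no genome model was supplied for the random-placement null")
    }
    if (is.null(pair_a) || is.null(pair_b)) {
      stop("random-placement null requires the tested pair's amplicons")
    }
    vapply(seq_len(n_null), function(k) {
      ra <- random_place(pair_a, genome, rng)
      rb <- random_place(pair_b, genome, rng)
      similarity_score(ra, rb, tol)$score
    }, numeric(1))
  }
}

attr_or <- function(x, name, default) {
  v <- x[[name]]
  if (is.null(v) || is.na(v)) default else v
}

# rigidly relocate each per-chromosome component of an amplicon's amplified
# footprint (and the junction endpoints riding on it) to a uniform random
# position; relocated components may land on each other, so the footprint
# is re-merged. Only the fields similarity_score() reads are rebuilt.
random_place <- function(amp, genome, rng) {
  fp <- amp$amplified
  edges <- amp$graph$edges
  for (chr in unique(fp$chrom)) {
    rows <- fp$chrom == chr
    lo <- min(fp$start[rows]); hi <- max(fp$end[rows])
    span <- hi - lo + 1
    ok <- names(genome)[genome >= span]
    new_chr <- ok[sample_int(rng, length(ok), 1)]
    new_lo <- 1 + floor(runif_rng(rng, 1) * (genome[[new_chr]] - span))
    delta <- new_lo - lo
    er1 <- edges$chrom1 == chr & edges$pos1 >= lo - 2 & edges$pos1 <= hi + 2
    er2 <- edges$chrom2 == chr & edges$pos2 >= lo - 2 & edges$pos2 <= hi + 2
    fp$start[rows] <- fp$start[rows] + delta
    fp$end[rows] <- fp$end[rows] + delta
    fp$chrom[rows] <- new_chr
    edges$pos1[er1] <- edges$pos1[er1] + delta
    edges$chrom1[er1] <- new_chr
    edges$pos2[er2] <- edges$pos2[er2] + delta
    edges$chrom2[er2] <- new_chr
  }
  amp$amplified <- iv_merge_base(fp)
  amp$graph <- list(edges = edges)
  amp
}

#' Find clonal ecDNA pairs within patients
#'
#' For each patient, ecDNA amplicons from different sequencing biopsies are
#' paired when their amplified footprints overlap genomically and their
#' similarity is significant against the cross-patient null. Each pair is
#' oriented so that the first member is the one with the less severe
#' (windowed) histology, ties broken by time point then sample id, and
#' carries the copy-number change between the two occurrences.
#'
#' @param samples List of `cohort_sample` objects (see [load_cohort()]):
#'   each with `sample_id`, `patient_id`, `time_point`,
#'   `histology_windowed` and `amplicons` (deduplicated classified
#'   amplicons).
#' @param score_min Minimum similarity score for a pair to be considered
#'   (default 0: any genomic overlap qualifies, significance is left to
#'   the p-value).
#' @param alpha Significance level on the empirical p-value.
#' @param tol Breakpoint tolerance in bp.
#' @param n_null Null draws per excluded-patient background.
#' @param seed Integer seed.
#' @param genome Optional chromosome-length vector for the
#'   random-placement fallback.
#' @return Data frame with one row per clonal pair: patient, samples,
#'   amplicon ids, score components, p-value, copy numbers, histology
#'   grades, `same_histology` and `cn_delta` (second minus first).
#' @export
find_clonal_pairs <- function(samples, score_min = 0, alpha = 0.05,
                              tol = 100, n_null = 1000, seed = 1,
                              genome = NULL) {
  # flat table of ecDNA amplicons with their sample context
  recs <- list()
  for (s in samples) {
    for (a in s$amplicons) {
      if (a$amplicon_class != "ecDNA") next
      a$patient_id <- s$patient_id
      recs[[length(recs) + 1]] <- list(
        amp = a, sample_id = s$sample_id, patient_id = s$patient_id,
        time_point = s$time_point,
        histology = attr_or(s, "histology_windowed", NA_character_))
    }
  }
  empty <- data.frame(patient_id = character(), sample_a = character(),
                      sample_b = character(), amplicon_a = character(),
                      amplicon_b = character(), genomic_jaccard = numeric(),
                      breakpoint_jaccard = numeric(), score = numeric(),
                      p_value = numeric(), cn_a = numeric(), cn_b = numeric(),
                      histology_a = character(), histology_b = character(),
                      same_histology = logical(), cn_delta = numeric(),
                      stringsAsFactors = FALSE)
  if (length(recs) < 2) return(empty)
  pat <- vapply(recs, function(r) r$patient_id, character(1))

  null_cache <- new.env(parent = emptyenv())
  rows <- list()
  for (p in unique(pat)) {
    idx <- which(pat == p)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (k in seq_len(ncol(cmb))) {
      r1 <- recs[[cmb[1, k]]]; r2 <- recs[[cmb[2, k]]]
      if (r1$sample_id == r2$sample_id) next
      if (!intervals_overlap_any(r1$amp$amplified, r2$amp$amplified)) next
      res <- similarity_score(r1$amp, r2$amp, tol)
      if (res$score < score_min) next
      if (!exists(p, envir = null_cache)) {
        bg <- lapply(recs[pat != p], function(r) {
          a <- r$amp; a$patient_id <- r$patient_id; a
        })
        assign(p, null_similarity_scores(bg, n_null = n_null,
                                         seed = seed + stable_hash(p),
                                         tol = tol, genome = genome,
                                         pair_a = r1$amp, pair_b = r2$amp),
               envir = null_cache)
      }
      res <- similarity_p_value(res, r1$amp, r2$amp, background = NULL,
                                n_null = n_null, seed = seed, tol = tol,
                                null_scores = get(p, envir = null_cache))
      if (res$p_value >= alpha) next
      # orient: first = less severe histology, then earlier time point
      g1 <- grade_rank(r1$histology); g2 <- grade_rank(r2$histology)
      flip <- (!is.na(g1) && !is.na(g2) && g2 < g1) ||
        (identical(g1, g2) && (r2$time_point < r1$time_point ||
           (r2$time_point == r1$time_point && r2$sample_id < r1$sample_id)))
      if (flip) { tmp <- r1; r1 <- r2; r2 <- tmp }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p, sample_a = r1$sample_id, sample_b = r2$sample_id,
        amplicon_a = r1$amp$amplicon_id, amplicon_b = r2$amp$amplicon_id,
        genomic_jaccard = res$genomic_jaccard,
        breakpoint_jaccard = res$breakpoint_jaccard, score = res$score,
        p_value = res$p_value,
        cn_a = r1$amp$max_copy_number, cn_b = r2$amp$max_copy_number,
        histology_a = r1$histology, histology_b = r2$histology,
        same_histology = identical(r1$histology, r2$histology),
        cn_delta = r2$amp$max_copy_number - r1$amp$max_copy_number,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$sample_a, out$sample_b, out$amplicon_a), ,
      drop = FALSE]
}
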