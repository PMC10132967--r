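#' Amplicon classification
#'
#' Each reconstructed amplicon is assigned one of four classes by a decision
#' cascade over its breakpoint graph and cycle decomposition:
#'
#' * **ecDNA** -- a cyclic walk at amplified copy number explains most of the
#'   amplified content (circularity at amplified copy number is the
#'   operative signature of extrachromosomal DNA);
#' * **BFB** -- breakage-fusion-bridge: not ecDNA, and foldback (inverted,
#'   near-coincident) junctions carry a substantial share of the discordant
#'   copy-count weight;
#' * **complex non-cyclic** -- neither of the above, but several discordant
#'   junctions touch the amplified intervals;
#' * **linear** -- everything else that passed seeding.
#'
#' Class ranks order the labels for deduplication: ecDNA (1) < BFB (2) <
#' complex non-cyclic (3) < linear (4). All thresholds are exposed through
#' [classifier_params()]; the defaults are this package's convention.
#'
#' @name classification
NULL

AMPLICON_CLASSES <- c("ecDNA", "BFB", "complex_non_cyclic", "linear")

class_rank <- function(label) match(label, AMPLICON_CLASSES)

#' Classifier parameters
#'
#' @param cn_min Amplified copy-number threshold (default 4.5).
#' @param ecdna_cycle_weight_min Minimum fraction of amplified bases a
#'   qualifying cyclic walk must cover (default 0.5).
#' @param foldback_frac_min Minimum fraction of discordant copy-count weight
#'   on foldback edges for a BFB call (default 0.25).
#' @param foldback_dist_max Maximum distance in bp between the two endpoints
#'   of a foldback edge (default 25000).
#' @param complex_edge_min Minimum number of discordant edges touching
#'   amplified intervals for a complex non-cyclic call (default 3).
#' @export
classifier_params <- function(cn_min = 4.5, ecdna_cycle_weight_min = 0.5,
                              foldback_frac_min = 0.25,
                              foldback_dist_max = 25000,
                              complex_edge_min = 3) {
  stopifnot(ecdna_cycle_weight_min >= 0, ecdna_cycle_weight_min <= 1,
            foldback_frac_min >= 0, foldback_frac_min <= 1)
  structure(list(cn_min = cn_min,
                 ecdna_cycle_weight_min = ecdna_cycle_weight_min,
                 foldback_frac_min = foldback_frac_min,
                 foldback_dist_max = foldback_dist_max,
                 complex_edge_min = complex_edge_min),
            class = "classifier_params")
}

#' Detect foldback edges
#'
#' Foldbacks are discordant edges whose two endpoints lie on the same
#' chromosome within `dist_max` bp of each other in inverted (head-to-head
#' or tail-to-tail) orientation -- the junction signature of
#' breakage-fusion-bridge cycles.
#'
#' @param graph An [amplicon_graph()].
#' @param dist_max Maximum endpoint separation in bp.
#' @return The qualifying rows of `graph$edges`.
#' @export
detect_foldbacks <- function(graph, dist_max = 25000) {
  e <- graph$edges
  e <- e[e$kind == "discordant", , drop = FALSE]
  if (nrow(e) == 0) return(e)
  keep <- e$chrom1 == e$chrom2 & abs(e$pos1 - e$pos2) <= dist_max &
    e$side1 == e$side2
  e[keep, , drop = FALSE]
}

#' Classify one amplicon
#'
#' Applies the decision cascade described in [classification] and counts
#' distinct ecDNA species as connected clusters of qualifying cyclic walks
#' whose genomic footprints are disjoint between clusters.
#'
#' @param graph An [amplicon_graph()].
#' @param decomp The matching [decomposition()].
#' @param params A [classifier_params()].
#' @return An object of class `classified_amplicon` with elements
#'   `amplicon_id`, `sample_id`, `graph`, `decomposition`, `amplicon_class`,
#'   `rank`, `amplified`, `max_copy_number`, `n_ecdna_species`,
#'   `complexity_bits`.
#' @export
classify_amplicon <- function(graph, decomp, params = classifier_params()) {
  if (!identical(graph$amplicon_id, decomp$amplicon_id)) {
    stop("graph and decomposition describe different amplicons: ",
         graph$amplicon_id, " vs ", decomp$amplicon_id)
  }
  amp <- amplified_intervals(graph, params$cn_min)
  amp_len <- intervals_total_length(amp)
  max_cn <- if (nrow(graph$segments) == 0) 0 else {
    over <- graph$segments$copy_count >= params$cn_min
    if (any(over)) max(graph$segments$copy_count[over]) else
      max(graph$segments$copy_count)
  }

  cyc <- decomp$cycles[decomp$cycles$is_cyclic & decomp$cycles$weight > 0, ,
                       drop = FALSE]
  qualifying <- integer(0)
  touching_weight <- 0
  if (nrow(cyc) > 0 && amp_len > 0) {
    fps <- lapply(cyc$segments, function(s) cycle_footprint(decomp, s))
    covers <- vapply(fps, function(fp)
      intervals_intersect_length(fp, amp) / amp_len, numeric(1))
    touches <- vapply(fps, function(fp) intervals_overlap_any(fp, amp),
                      logical(1))
    touching_weight <- sum(cyc$weight[touches])
    qualifying <- which(cyc$weight >= params$cn_min &
                          covers >= params$ecdna_cycle_weight_min)
    is_ecdna <- length(qualifying) > 0 || touching_weight >= params$cn_min
  } else {
    is_ecdna <- FALSE
    fps <- list()
  }

  disc <- graph$edges[graph$edges$kind == "discordant", , drop = FALSE]
  fold <- detect_foldbacks(graph, params$foldback_dist_max)
  disc_weight <- sum(disc$copy_count)
  fold_frac <- if (disc_weight > 0) sum(fold$copy_count) / disc_weight else 0
  is_bfb <- !is_ecdna && nrow(fold) >= 2 && fold_frac >= params$foldback_frac_min

  n_disc_amp <- if (nrow(disc) == 0 || amp_len == 0) 0 else {
    touch1 <- point_in_intervals(disc$chrom1, disc$pos1, amp, slop = 1)
    touch2 <- point_in_intervals(disc$chrom2, disc$pos2, amp, slop = 1)
    sum(touch1 | touch2)
  }
  is_complex <- !is_ecdna && !is_bfb && n_disc_amp >= params$complex_edge_min

  label <- if (is_ecdna) "ecDNA" else if (is_bfb) "BFB" else
    if (is_complex) "complex_non_cyclic" else "linear"

  n_species <- 0
  if (is_ecdna) {
    if (length(qualifying) > 0) {
      n_species <- count_footprint_clusters(fps[qualifying])
    } else {
      n_species <- 1
    }
  }

  structure(list(amplicon_id = graph$amplicon_id, sample_id = graph$sample_id,
                 graph = graph, decomposition = decomp,
                 amplicon_class = label, rank = class_rank(label),
                 amplified = amp, max_copy_number = max_cn,
                 n_ecdna_species = n_species,
                 complexity_bits = tryCatch(complexity_score(decomp),
                                            error = function(e) NA_real_)),
            class = "classified_amplicon")
}

# connected components of footprints under genomic overlap
count_footprint_clusters <- function(fps) {
  n <- length(fps)
  if (n == 0) return(0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0, n - 1))) for (j in seq(i + 1, n)) {
    if (intervals_overlap_any(fps[[i]], fps[[j]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @export
print.classified_amplicon <- function(x, ...) {
  cat(sprintf("<classified_amplicon> %s: %s, max CN %.1f, %d ecDNA species, %.2f bits\n",
              x$amplicon_id, x$amplicon_class, x$max_copy_number,
              x$n_ecdna_species, x$complexity_bits))
  invisible(x)
}

#' Deduplicate overlapping amplicons within one sample
#'
#' Among amplicons whose amplified intervals share at least one base,
#' exactly one per overlap-connected component is kept: the best (lowest)
#' class rank, ties broken by largest total amplified length, residual ties
#' by lexicographic amplicon id. Idempotent and order-invariant.
#'
#' @param amplicons List of [classify_amplicon()] results from one sample.
#' @return Filtered list, ordered by amplicon id.
#' @export
deduplicate_amplicons <- function(amplicons) {
  n <- length(amplicons)
  if (n <= 1) return(amplicons)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (intervals_overlap_any(amplicons[[i]]$amplified,
                              amplicons[[j]]$amplified)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), comp), function(idx) {
    rk <- vapply(amplicons[idx], function(a) a$rank, numeric(1))
    sz <- vapply(amplicons[idx], function(a)
      intervals_total_length(a$amplified), numeric(1))
    id <- vapply(amplicons[idx], function(a) a$amplicon_id, character(1))
    idx[order(rk, -sz, id)][1]
  }, integer(1))
  out <- amplicons[sort(keep)]
  ids <- vapply(out, function(a) a$amplicon_id, character(1))
  out[order(ids)]
}

#' Per-sample ecDNA status
#'
#' @param amplicons Deduplicated list of classified amplicons for one
#'   sample.
#' @return List with `is_positive` (any ecDNA amplicon) and `n_species`
#'   (total distinct ecDNA species).
#' @export
sample_ecdna_status <- function(amplicons) {
  if (length(amplicons) == 0) return(list(is_positive = FALSE, n_species = 0L))
  labels <- vapply(amplicons, function(a) a$amplicon_class, character(1))
  species <- vapply(amplicons, function(a) a$n_ecdna_species, numeric(1))
  list(is_positive = any(labels == "ecDNA"),
       n_species = as.integer(sum(species)))
}

#' Tabulate classified amplicons
#'
#' @param amplicons List of classified amplicons (any number of samples).
#' @return Data frame with one row per amplicon: `sample_id`, `amplicon_id`,
#'   `class`, `n_ecdna_species`, `max_copy_number`, `complexity_bits`,
#'   `amplified_length`.
#' @export
classification_table <- function(amplicons) {
  if (length(amplicons) == 0) {
    return(data.frame(sample_id = character(), amplicon_id = character(),
                      class = character(), n_ecdna_species = integer(),
                      max_copy_number = numeric(), complexity_bits = numeric(),
                      amplified_length = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(
    sample_id = vapply(amplicons, function(a) a$sample_id, character(1)),
    amplicon_id = vapply(amplicons, function(a) a$amplicon_id, character(1)),
    class = vapply(amplicons, function(a) a$amplicon_class, character(1)),
    n_ecdna_species = vapply(amplicons, function(a)
      as.integer(a$n_ecdna_species), integer(1)),
    max_copy_number = vapply(amplicons, function(a) a$max_copy_number,
                             numeric(1)),
    complexity_bits = vapply(amplicons, function(a) a$complexity_bits,
                             numeric(1)),
    amplified_length = vapply(amplicons, function(a)
      intervals_total_length(a$amplified), numeric(1)),
    stringsAsFactors = FALSE)
}
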