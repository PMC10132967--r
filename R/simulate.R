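#' Synthetic cohort generator
#'
#' Generates complete, self-contained toy cohorts -- a small genome, gene
#' models, amplicon structures of every class, longitudinal clonal ecDNA,
#' copy-number segment files, breakpoint-graph/cycles files, cohort
#' metadata and histology -- together with a ground-truth table, so the
#' whole pipeline is testable without access to protected patient data.
#'
#' Two study designs are emulated. The `fhcc` design is a longitudinal
#' case-control cohort: 40 cancer-outcome (CO) and 40 non-cancer-outcome
#' (NCO) patients, two sequencing biopsies (upper/lower oesophageal levels)
#' at each of two time points, with independently collected histology
#' records at, near, or away from the sequencing levels. ecDNA positivity
#' and histology categories are planted deterministically at the cohort's
#' design rates (13/40 CO vs 1/40 NCO patients ecDNA-positive; at TP-1 all
#' on-level-matched ecDNA samples sit in high-grade dysplasia; at TP-2 most
#' sit in adenocarcinoma), including eight within-patient clonal ecDNA
#' lineages whose copy number escalates with histological progression.
#' Randomness drives structure coordinates, copy numbers and noise, never
#' the planted counts. The `cambridge` design is a cross-sectional
#' surveillance cohort (42 NDBE/LGD, 25 HGD, 51 early-stage and 88
#' late-stage adenocarcinoma patients, one biopsy each) with ecDNA planted
#' in 0, 1, 13 and 38 patients respectively.
#'
#' @name synthetic-data
NULL

#' Toy genome
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return Named vector of chromosome lengths.
#' @export
toy_genome <- function(n_chrom = 4, chrom_length = 1e7) {
  stats::setNames(rep(chrom_length, n_chrom), paste0("chr", seq_len(n_chrom)))
}

#' Toy gene models
#'
#' 15 genes per chromosome (20 kb each, alternating strand) at fixed
#' positions; 3 per chromosome are flagged oncogenes and 6 genome-wide are
#' immunomodulatory.
#'
#' @param genome From [toy_genome()].
#' @return List with `genes` (gene-model data frame), `oncogenes`,
#'   `immunomodulatory` (symbol vectors).
#' @export
toy_genes <- function(genome = toy_genome()) {
  per_chrom <- 15
  rows <- list()
  for (chr in names(genome)) {
    starts <- seq(400001, by = 620000, length.out = per_chrom)
    rows[[chr]] <- data.frame(
      chrom = chr, start = starts, end = starts + 19999,
      name = sprintf("%s_g%02d", chr, seq_len(per_chrom)),
      strand = rep(c("+", "-"), length.out = per_chrom),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  genes <- gene_models(df$chrom, df$start, df$end, df$name, df$strand)
  onc <- genes$name[sub(".*_g", "", genes$name) %in% c("01", "06", "11")]
  imm <- c(genes$name[sub(".*_g", "", genes$name) == "03"],
           genes$name[genes$chrom %in% c("chr1", "chr2") &
                        sub(".*_g", "", genes$name) == "08"])
  list(genes = genes, oncogenes = onc, immunomodulatory = imm)
}

#' Simulation configuration
#'
#' @param seed Master integer seed; identical configurations produce
#'   byte-identical cohorts.
#' @param design `"fhcc"` (longitudinal case-control) or `"cambridge"`
#'   (cross-sectional surveillance).
#' @param n_chrom,chrom_length Toy genome shape.
#' @param ecdna_cn_median,fscna_cn_median Median copy number of the
#'   log-normal CN distributions for ecDNA and for other focal
#'   amplifications.
#' @param cn_sdlog Log-scale SD of the CN distributions.
#' @param cn_escalation_factor Multiplier applied to a clonal ecDNA's copy
#'   number per histology-grade advance.
#' @param clone_noise Two-element range of the multiplicative noise applied
#'   when a clone is propagated (set `c(1, 1)` to disable).
#' @param rearrangement_steps_by_grade Named vector of extra decomposition
#'   elements per histology grade (structure-complexity knob).
#' @param ecdna_prevalence Named per-group patient-level ecDNA prevalence;
#'   planted counts are `round(prevalence * n_patients)`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, design = c("fhcc", "cambridge"),
                       n_chrom = 4, chrom_length = 1e7,
                       ecdna_cn_median = 15, fscna_cn_median = 8,
                       cn_sdlog = 0.25, cn_escalation_factor = 1.5,
                       clone_noise = c(0.9, 1.1),
                       rearrangement_steps_by_grade =
                         c(NDBE = 0, LGD = 0, HGD = 1, EAC = 3),
                       ecdna_prevalence = NULL) {
  design <- match.arg(design)
  if (is.null(ecdna_prevalence)) {
    ecdna_prevalence <- if (design == "fhcc") {
      c(CO = 13 / 40, NCO = 1 / 40)
    } else {
      c(ndbe_lgd = 0, hgd = 1 / 25, early_eac = 13 / 51, late_eac = 38 / 88)
    }
  }
  stopifnot(all(ecdna_prevalence >= 0 & ecdna_prevalence <= 1))
  structure(list(seed = as.integer(seed), design = design,
                 n_chrom = n_chrom, chrom_length = chrom_length,
                 ecdna_cn_median = ecdna_cn_median,
                 fscna_cn_median = fscna_cn_median, cn_sdlog = cn_sdlog,
                 cn_escalation_factor = cn_escalation_factor,
                 clone_noise = clone_noise,
                 rearrangement_steps_by_grade = rearrangement_steps_by_grade,
                 ecdna_prevalence = ecdna_prevalence),
            class = "sim_config")
}

# ---------------------------------------------------------------------------
# structure archetypes
# ---------------------------------------------------------------------------

# sample a segment of given length not overlapping `taken` (interval df)
sample_region <- function(rng, genome, len, taken, max_retry = 50) {
  for (i in seq_len(max_retry)) {
    chr <- names(genome)[sample_int(rng, length(genome), 1)]
    start <- 1 + floor(runif_rng(rng, 1) * (genome[[chr]] - len - 1))
    cand <- genomic_intervals(chr, start, start + len - 1)
    if (!intervals_overlap_any(cand, taken)) return(cand)
  }
  stop("segment sampling collision after ", max_retry, " retries")
}

#' Simulate one amplicon structure
#'
#' Archetypes: `ecDNA` -- 1-5 sampled segments (more at higher grades)
#' joined into a closed cycle at amplified copy number, with low-weight
#' satellite cycles at higher grades; `BFB` -- a three-segment foldback
#' ladder with stepwise copy number and two inverted near-coincident
#' junctions; `complex_non_cyclic` -- several segments joined by a web of
#' discordant junctions with only linear decomposition walks; `linear` -- a
#' single amplified run with no discordant junctions.
#'
#' @param genome From [toy_genome()].
#' @param kind Class label to generate.
#' @param config A [sim_config()].
#' @param seed Integer seed for this structure.
#' @param amplicon_id,sample_id Identifiers.
#' @param grade Histology grade of the carrying sample (drives structure
#'   complexity through `rearrangement_steps_by_grade`).
#' @param center_gene Optional single-row gene model the first segment is
#'   placed around.
#' @param lineage_id Clonal lineage label recorded in the truth table.
#' @param genes Gene models used to record planted gene content.
#' @return List with `graph`, `decomposition` and `truth` (one-row data
#'   frame).
#' @export
simulate_structure <- function(genome, kind, config, seed,
                               amplicon_id = "amp1", sample_id = "s1",
                               grade = "HGD", center_gene = NULL,
                               lineage_id = amplicon_id, genes = NULL) {
  stopifnot(kind %in% AMPLICON_CLASSES)
  rng <- make_rng(seed)
  steps <- unname(config$rearrangement_steps_by_grade[grade])
  if (is.na(steps)) steps <- 0
  gen <- switch(kind,
    ecDNA = sim_ecdna(rng, genome, config, steps, center_gene),
    BFB = sim_bfb(rng, genome, config),
    complex_non_cyclic = sim_complex(rng, genome, config),
    linear = sim_linear(rng, genome, config))
  graph <- amplicon_graph(amplicon_id, sample_id, gen$segments, gen$edges)
  decomp <- decomposition(amplicon_id, gen$dsegments, gen$cycles)
  planted <- if (is.null(genes)) "" else {
    inside <- vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      any(gen$segments$chrom == g$chrom & gen$segments$start <= g$start &
            gen$segments$end >= g$end)
    }, logical(1))
    paste(genes$name[inside], collapse = ",")
  }
  truth <- data.frame(sample_id = sample_id, amplicon_id = amplicon_id,
                      true_class = kind, true_cn = gen$cn,
                      lineage_id = lineage_id, genes_planted = planted,
                      stringsAsFactors = FALSE)
  list(graph = graph, decomposition = decomp, truth = truth)
}

draw_cn <- function(rng, config, ecdna = TRUE) {
  med <- if (ecdna) config$ecdna_cn_median else config$fscna_cn_median
  max(5.5, rlnorm_rng(rng, 1, log(med), config$cn_sdlog))
}

# build the decomposition segment table (coordinate-sorted ids) and map
# graph segments to signed tokens
dseg_table <- function(segments) {
  seg <- sort_intervals(segments[, c("chrom", "start", "end")])
  seg$seg_id <- seq_len(nrow(seg))
  rownames(seg) <- NULL
  seg[, c("seg_id", "chrom", "start", "end")]
}

token_of <- function(dseg, chrom, start, sign = "+") {
  id <- dseg$seg_id[dseg$chrom == chrom & dseg$start == start]
  paste0(id, sign)
}

sim_ecdna <- function(rng, genome, config, steps, center_gene) {
  n_seg <- sample_int(rng, 3, 1) + if (steps >= 3) 2L else 0L
  cn <- draw_cn(rng, config, ecdna = TRUE)
  segs <- empty_intervals()
  for (k in seq_len(n_seg)) {
    len <- round(runif_rng(rng, 1, 60000, 400000))
    if (k == 1 && !is.null(center_gene)) {
      m1 <- round(runif_rng(rng, 1, 10000, 100000))
      m2 <- round(runif_rng(rng, 1, 10000, 100000))
      cand <- genomic_intervals(center_gene$chrom,
                                max(1, center_gene$start - m1),
                                center_gene$end + m2)
      if (intervals_overlap_any(cand, segs)) {
        cand <- sample_region(rng, genome, len, segs)
      }
    } else {
      cand <- sample_region(rng, genome, len, segs)
    }
    segs <- rbind(segs, cand)
  }
  segments <- segs
  segments$copy_count <- cn
  segments$coverage <- cn * 15
  # close the cycle through the segments in sampled order
  edges <- empty_edges()
  for (k in seq_len(n_seg)) {
    nxt <- if (k == n_seg) 1 else k + 1
    edges <- rbind(edges, data.frame(
      chrom1 = segs$chrom[k], pos1 = segs$end[k], side1 = "head",
      chrom2 = segs$chrom[nxt], pos2 = segs$start[nxt], side2 = "tail",
      kind = "discordant", copy_count = cn, support = round(cn * 10),
      stringsAsFactors = FALSE))
  }
  dseg <- dseg_table(segments)
  main_tokens <- vapply(seq_len(n_seg), function(k)
    token_of(dseg, segs$chrom[k], segs$start[k]), character(1))
  cycles <- data.frame(cycle_id = 1L, weight = cn, is_cyclic = TRUE,
                       stringsAsFactors = FALSE)
  cycles$segments <- I(list(main_tokens))
  n_sat <- steps
  for (s in seq_len(n_sat)) {
    pick <- sort(sample_int(rng, n_seg, max(1, sample_int(rng, n_seg, 1))))
    w <- cn * runif_rng(rng, 1, 0.05, 0.25)
    sat <- data.frame(cycle_id = 1L + s, weight = w, is_cyclic = TRUE,
                      stringsAsFactors = FALSE)
    sat$segments <- I(list(main_tokens[pick]))
    cycles <- rbind(cycles, sat)
  }
  list(segments = segments, edges = edges, dsegments = dseg,
       cycles = cycles, cn = cn)
}

sim_bfb <- function(rng, genome, config) {
  cn <- draw_cn(rng, config, ecdna = FALSE)
  l1 <- round(runif_rng(rng, 1, 10000, 20000))
  l2 <- round(runif_rng(rng, 1, 100000, 200000))
  l3 <- round(runif_rng(rng, 1, 8000, 18000))
  anchor <- sample_region(rng, genome, l1 + l2 + l3, empty_intervals())
  s1 <- c(anchor$start, anchor$start + l1 - 1)
  s2 <- c(s1[2] + 1, s1[2] + l2)
  s3 <- c(s2[2] + 1, s2[2] + l3)
  chr <- anchor$chrom
  segments <- data.frame(
    chrom = chr, start = c(s1[1], s2[1], s3[1]), end = c(s1[2], s2[2], s3[2]),
    copy_count = c(cn, 2 * cn, cn), coverage = c(cn, 2 * cn, cn) * 15,
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(chrom1 = chr, pos1 = s3[2], side1 = "head",
               chrom2 = chr, pos2 = s2[2], side2 = "head",
               kind = "discordant", copy_count = cn, support = round(cn * 10),
               stringsAsFactors = FALSE),
    data.frame(chrom1 = chr, pos1 = s1[1], side1 = "tail",
               chrom2 = chr, pos2 = s2[1], side2 = "tail",
               kind = "discordant", copy_count = cn, support = round(cn * 10),
               stringsAsFactors = FALSE),
    data.frame(chrom1 = chr, pos1 = s1[2], side1 = "head",
               chrom2 = chr, pos2 = s2[1], side2 = "tail",
               kind = "concordant", copy_count = 2 * cn,
               support = round(cn * 20), stringsAsFactors = FALSE),
    data.frame(chrom1 = chr, pos1 = s2[2], side1 = "head",
               chrom2 = chr, pos2 = s3[1], side2 = "tail",
               kind = "concordant", copy_count = 2 * cn,
               support = round(cn * 20), stringsAsFactors = FALSE))
  dseg <- dseg_table(segments)
  cycles <- data.frame(cycle_id = c(1L, 2L), weight = c(cn * 0.6, cn * 0.4),
                       is_cyclic = c(FALSE, FALSE), stringsAsFactors = FALSE)
  cycles$segments <- I(list(c("1+", "2+"), c("2+", "3+")))
  list(segments = segments, edges = edges, dsegments = dseg,
       cycles = cycles, cn = 2 * cn)
}

sim_complex <- function(rng, genome, config) {
  cn <- draw_cn(rng, config, ecdna = FALSE)
  segs <- empty_intervals()
  for (k in 1:3) {
    len <- round(runif_rng(rng, 1, 60000, 250000))
    segs <- rbind(segs, sample_region(rng, genome, len, segs))
  }
  segments <- segs
  segments$copy_count <- cn * c(1, 0.9, 0.8)
  segments$coverage <- segments$copy_count * 15
  mk <- function(i, j) data.frame(
    chrom1 = segs$chrom[i], pos1 = segs$end[i], side1 = "head",
    chrom2 = segs$chrom[j], pos2 = segs$start[j], side2 = "tail",
    kind = "discordant", copy_count = cn / 2, support = round(cn * 5),
    stringsAsFactors = FALSE)
  edges <- rbind(mk(1, 2), mk(2, 1), mk(2, 3), mk(3, 2))
  dseg <- dseg_table(segments)
  cycles <- data.frame(cycle_id = 1:3, weight = cn * c(0.5, 0.3, 0.2),
                       is_cyclic = FALSE, stringsAsFactors = FALSE)
  tok <- function(k) token_of(dseg, segs$chrom[k], segs$start[k])
  cycles$segments <- I(list(tok(1), tok(2), tok(3)))
  list(segments = segments, edges = edges, dsegments = dseg,
       cycles = cycles, cn = cn)
}

sim_linear <- function(rng, genome, config) {
  cn <- draw_cn(rng, config, ecdna = FALSE)
  len <- round(runif_rng(rng, 1, 100000, 400000))
  seg <- sample_region(rng, genome, len, empty_intervals())
  segments <- seg
  segments$copy_count <- cn
  segments$coverage <- cn * 15
  dseg <- dseg_table(segments)
  cycles <- data.frame(cycle_id = 1L, weight = cn, is_cyclic = FALSE,
                       stringsAsFactors = FALSE)
  cycles$segments <- I(list("1+"))
  list(segments = segments, edges = empty_edges(), dsegments = dseg,
       cycles = cycles, cn = cn)
}

#' Propagate a clonal ecDNA to another biopsy
#'
#' The child shares the parent's segments and junctions; its copy number is
#' the parent's multiplied by `cn_escalation_factor^grade_delta` and by
#' bounded multiplicative noise. A positive `grade_delta` additionally
#' raises decomposition diversity (extra satellite cycles) and, for
#' structures with at least three segments, extends the outermost segment
#' slightly so one junction is displaced -- the child still shares over 80%
#' of amplified bases and at least half of the junctions.
#'
#' @param parent Structure list from [simulate_structure()] (must be
#'   ecDNA).
#' @param grade_delta Histology-grade advance of the child sample relative
#'   to the parent (integer >= 0).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param amplicon_id,sample_id Identifiers of the child.
#' @param noise Apply multiplicative copy-number noise (default TRUE).
#' @return Structure list for the child.
#' @export
evolve_clone <- function(parent, grade_delta, config, seed,
                         amplicon_id = paste0(parent$truth$amplicon_id, "c"),
                         sample_id = parent$truth$sample_id, noise = TRUE) {
  if (parent$truth$true_class != "ecDNA") stop("clonal parent must be ecDNA")
  stopifnot(grade_delta >= 0)
  rng <- make_rng(seed)
  f <- config$cn_escalation_factor^grade_delta
  if (noise) {
    f <- f * runif_rng(rng, 1, config$clone_noise[1], config$clone_noise[2])
  }
  seg <- parent$graph$segments
  edges <- parent$graph$edges
  cycles <- parent$decomposition$cycles
  dseg <- parent$decomposition$segments
  seg$copy_count <- seg$copy_count * f
  seg$coverage <- seg$coverage * f
  edges$copy_count <- edges$copy_count * f
  cycles$weight <- cycles$weight * f

  if (grade_delta > 0) {
    if (nrow(seg) >= 3) {
      # extend the coordinate-last segment's 3' end, displacing its junction
      ord <- order(seg$chrom, seg$start)
      i <- ord[length(ord)]
      ext <- round(runif_rng(rng, 1, 0.05, 0.1) * (seg$end[i] - seg$start[i]))
      extended <- genomic_intervals(seg$chrom[i], seg$start[i],
                                    seg$end[i] + ext)
      others <- seg[-i, c("chrom", "start", "end"), drop = FALSE]
      if (!intervals_overlap_any(extended, others)) {
        hit <- edges$chrom1 == seg$chrom[i] & edges$pos1 == seg$end[i] &
          edges$side1 == "head"
        hit2 <- edges$chrom2 == seg$chrom[i] & edges$pos2 == seg$end[i] &
          edges$side2 == "head"
        dhit <- dseg$chrom == seg$chrom[i] & dseg$end == seg$end[i]
        edges$pos1[hit] <- seg$end[i] + ext
        edges$pos2[hit2] <- seg$end[i] + ext
        dseg$end[dhit] <- seg$end[i] + ext
        seg$end[i] <- seg$end[i] + ext
      }
    }
    main <- cycles$segments[[which.max(cycles$weight)]]
    for (s in seq_len(grade_delta)) {
      pick <- sort(sample_int(rng, length(main),
                              max(1, sample_int(rng, length(main), 1))))
      w <- max(cycles$weight) * runif_rng(rng, 1, 0.05, 0.25)
      sat <- data.frame(cycle_id = max(cycles$cycle_id) + 1L, weight = w,
                        is_cyclic = TRUE, stringsAsFactors = FALSE)
      sat$segments <- I(list(main[pick]))
      cycles <- rbind(cycles, sat)
    }
  }
  graph <- amplicon_graph(amplicon_id, sample_id, seg, edges)
  decomp <- decomposition(amplicon_id, dseg, cycles)
  truth <- data.frame(sample_id = sample_id, amplicon_id = amplicon_id,
                      true_class = "ecDNA",
                      true_cn = parent$truth$true_cn * f,
                      lineage_id = parent$truth$lineage_id,
                      genes_planted = parent$truth$genes_planted,
                      stringsAsFactors = FALSE)
  list(graph = graph, decomposition = decomp, truth = truth)
}
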