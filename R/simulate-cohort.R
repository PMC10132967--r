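#' Cohort-level simulation
#'
#' [simulate_cohort()] lays out a study design (samples, histology records,
#' planted amplicon structures) and writes it to disk in the file dialects
#' the rest of the package consumes. See [synthetic-data] for the design
#' emulated by each configuration.
#'
#' @name simulate-cohort
NULL

# --- FHCC-like longitudinal case-control design -----------------------------

TP_LEVELS <- c(U = 30, L = 32)

fhcc_sample_frame <- function() {
  pats <- c(sprintf("co%02d", 1:40), sprintf("nc%02d", 1:40))
  grid <- expand.grid(pos = c("U", "L"), time_point = c("TP1", "TP2"),
                      patient_id = pats, stringsAsFactors = FALSE)
  data.frame(sample_id = paste(grid$patient_id, grid$time_point, grid$pos,
                               sep = "_"),
             patient_id = grid$patient_id,
             group = ifelse(grepl("^co", grid$patient_id), "CO", "NCO"),
             time_point = grid$time_point,
             level_cm = unname(TP_LEVELS[grid$pos]),
             stringsAsFactors = FALSE)
}

# amplicon plan: one row per structure to generate
amp_plan_row <- function(sample_id, patient_id, idx, kind, lineage_id,
                         role = "solo", grade = "HGD", grade_delta = 0) {
  data.frame(sample_id = sample_id, patient_id = patient_id, idx = idx,
             kind = kind, lineage_id = lineage_id, role = role,
             grade = grade, grade_delta = grade_delta,
             stringsAsFactors = FALSE)
}

plant_fhcc <- function(config) {
  samples <- fhcc_sample_frame()
  prev <- config$ecdna_prevalence
  n_pos <- round(prev[["CO"]] * 40)
  n_pos_nco <- round(prev[["NCO"]] * 40)
  sid <- function(p, tp, pos) sprintf("co%02d_%s_%s", p, tp, pos)

  plan <- list()
  add <- function(...) plan[[length(plan) + 1]] <<- amp_plan_row(...)
  tp1_set <- if (n_pos >= 1) seq_len(min(7, n_pos)) else integer(0)
  tp2_set <- if (n_pos >= 3) seq(3, n_pos) else integer(0)
  cross_set <- intersect(tp1_set, tp2_set)            # cross-TP clonal lineages
  mate_set <- intersect(tp2_set, 8:10)                # within-TP2 clone mates

  for (p in tp1_set) {
    lin <- sprintf("lin_co%02d", p)
    role <- if (p %in% cross_set) "parent" else "solo"
    add(sid(p, "TP1", "U"), sprintf("co%02d", p), 1L, "ecDNA", lin, role,
        grade = "HGD")
  }
  for (p in tp2_set) {
    lin <- sprintf("lin_co%02d", p)
    grade <- if (n_pos == 13 && p %in% c(12, 13)) "HGD" else "EAC"
    if (p %in% cross_set) {
      add(sid(p, "TP2", "U"), sprintf("co%02d", p), 1L, "ecDNA", lin,
          "child", grade = grade, grade_delta = 1)
    } else if (p %in% mate_set) {
      add(sid(p, "TP2", "U"), sprintf("co%02d", p), 1L, "ecDNA", lin,
          "parent", grade = grade)
      add(sid(p, "TP2", "L"), sprintf("co%02d", p), 1L, "ecDNA", lin,
          "child", grade = grade, grade_delta = 0)
    } else {
      add(sid(p, "TP2", "U"), sprintf("co%02d", p), 1L, "ecDNA", lin,
          "solo", grade = grade)
    }
  }
  if (n_pos >= 11) {
    # a second, independent ecDNA species in one positive sample
    add(sid(11, "TP2", "U"), "co11", 2L, "ecDNA", "lin_co11b", "solo",
        grade = "EAC")
  }
  for (q in seq_len(n_pos_nco)) {
    add(sprintf("nc%02d_TP2_U", q), sprintf("nc%02d", q), 1L, "ecDNA",
        sprintf("lin_nc%02d", q), "solo", grade = "NDBE")
  }
  # non-ecDNA focal amplifications sprinkled into negative samples
  other <- c("linear", "BFB", "complex_non_cyclic")
  k <- 0
  for (p in seq(14, 40, by = 3)) {
    k <- k + 1
    add(sid(p, "TP1", "L"), sprintf("co%02d", p), 1L,
        other[(k - 1) %% 3 + 1], sprintf("lin_co%02d_f", p), grade = "LGD")
  }
  for (q in seq(2, 40, by = 4)) {
    k <- k + 1
    add(sprintf("nc%02d_TP2_L", q), sprintf("nc%02d", q), 1L,
        other[(k - 1) %% 3 + 1], sprintf("lin_nc%02d_f", q), grade = "LGD")
  }
  plan <- do.call(rbind, plan)

  histology <- if (n_pos == 13) fhcc_histology_default() else
    fhcc_histology_generic(plan)
  list(samples = samples, histology = histology, plan = plan)
}

# the default planting: reproduces the design's category counts exactly
fhcc_histology_default <- function() {
  rows <- list()
  add <- function(pat, tp, level, grade) {
    rows[[length(rows) + 1]] <<- data.frame(
      patient_id = pat, time_point = tp, level_cm = level, grade = grade,
      stringsAsFactors = FALSE)
  }
  co <- function(p) sprintf("co%02d", p)
  # TP-1
  for (p in c(1:6, 8:13)) add(co(p), "TP1", 30, "HGD")
  add(co(7), "TP1", 30.5, "HGD")
  for (p in 1:15) add(co(p), "TP1", 32, "HGD")
  for (p in 16:40) add(co(p), "TP1", 32,
                       if (p %% 2 == 0) "LGD" else "NDBE")
  # TP-2
  for (p in c(1:11, 15:17)) add(co(p), "TP2", 30, "EAC")
  for (p in c(12, 13, 14)) add(co(p), "TP2", 30, "HGD")
  for (p in c(1:7, 11:18)) add(co(p), "TP2", 32, "EAC")
  for (p in 19:40) add(co(p), "TP2", 32, "HGD")
  for (p in 8:10) add(co(p), "TP2", 32.5, "EAC")
  for (p in 1:40) add(co(p), "TP2", 36, "EAC")   # diagnosis biopsy
  # NCO: never beyond LGD
  for (q in 1:40) {
    g <- if (q %% 2 == 0) "LGD" else "NDBE"
    for (tp in c("TP1", "TP2")) for (lv in c(30, 32)) {
      add(sprintf("nc%02d", q), tp, lv, g)
    }
  }
  do.call(rbind, rows)
}

# fallback for non-default prevalences: on-level records everywhere,
# grades escalating with outcome group and planted positivity
fhcc_histology_generic <- function(plan) {
  samples <- fhcc_sample_frame()
  pos_samples <- unique(plan$sample_id[plan$kind == "ecDNA"])
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples[i, ]
    g <- if (s$group == "NCO") {
      if (stable_hash(s$patient_id) %% 2 == 0) "LGD" else "NDBE"
    } else if (s$time_point == "TP1") {
      if (s$sample_id %in% pos_samples) "HGD" else "LGD"
    } else {
      if (s$sample_id %in% pos_samples) "EAC" else "HGD"
    }
    data.frame(patient_id = s$patient_id, time_point = s$time_point,
               level_cm = s$level_cm, grade = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# --- Cambridge-like cross-sectional design ----------------------------------

plant_cambridge <- function(config) {
  sizes <- c(ndbe_lgd = 42, hgd = 25, early_eac = 51, late_eac = 88)
  prefix <- c(ndbe_lgd = "nd", hgd = "hg", early_eac = "ee", late_eac = "le")
  prev <- config$ecdna_prevalence
  samples <- list(); hist <- list(); plan <- list()
  other <- c("linear", "BFB", "complex_non_cyclic")
  k <- 0
  for (grp in names(sizes)) {
    n <- sizes[[grp]]
    n_pos <- round(prev[[grp]] * n)
    for (i in seq_len(n)) {
      pat <- sprintf("%s%03d", prefix[[grp]], i)
      sid <- paste0(pat, "_S1")
      samples[[length(samples) + 1]] <- data.frame(
        sample_id = sid, patient_id = pat, group = grp, time_point = "TP1",
        level_cm = 30, stringsAsFactors = FALSE)
      grade <- switch(grp,
                      ndbe_lgd = if (i <= 27) "NDBE" else "LGD",
                      hgd = "HGD", early_eac = "EAC", late_eac = "EAC")
      hist[[length(hist) + 1]] <- data.frame(
        patient_id = pat, time_point = "TP1", level_cm = 30, grade = grade,
        stringsAsFactors = FALSE)
      if (i <= n_pos) {
        plan[[length(plan) + 1]] <- amp_plan_row(
          sid, pat, 1L, "ecDNA", paste0("lin_", pat), grade = grade)
      } else if (i %% 4 == 0) {
        k <- k + 1
        plan[[length(plan) + 1]] <- amp_plan_row(
          sid, pat, 1L, other[(k - 1) %% 3 + 1], paste0("lin_", pat, "_f"),
          grade = grade)
      }
    }
  }
  list(samples = do.call(rbind, samples), histology = do.call(rbind, hist),
       plan = do.call(rbind, plan))
}

# --- structure generation and on-disk output --------------------------------

#' Simulate a cohort to disk
#'
#' Writes `genome.tsv`, `genes.bed`, `oncogenes.txt`,
#' `immunomodulatory.txt`, `samples.tsv`, `histology.tsv`, `truth.tsv` and
#' one directory per sample under `samples/` containing the sample's
#' copy-number segment file (`<sample>.cns`) and one
#' `<amplicon>_graph.txt` / `<amplicon>_cycles.txt` pair per planted focal
#' amplification. Output is deterministic given `config$seed`: running
#' twice produces byte-identical trees.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the cohort metadata, truth table, genome
#'   and gene models.
#' @export
simulate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  genome <- toy_genome(config$n_chrom, config$chrom_length)
  gn <- toy_genes(genome)
  layout <- if (config$design == "fhcc") plant_fhcc(config) else
    plant_cambridge(config)

  # generate structures; parents before children within each lineage
  plan <- layout$plan
  structures <- list()   # sample_id -> list of structure lists
  truth <- list()
  lineage_store <- new.env(parent = emptyenv())
  if (!is.null(plan) && nrow(plan) > 0) {
    ord <- order(match(plan$role, c("solo", "parent", "child")),
                 plan$sample_id, plan$idx)
    plan <- plan[ord, , drop = FALSE]
    for (i in seq_len(nrow(plan))) {
      r <- plan[i, ]
      amp_id <- sprintf("%s_amplicon%d", r$sample_id, r$idx)
      if (r$role == "child") {
        parent <- get(r$lineage_id, envir = lineage_store)
        st <- evolve_clone(parent, r$grade_delta, config,
                           seed = sub_seed(config$seed, amp_id),
                           amplicon_id = amp_id, sample_id = r$sample_id)
      } else {
        center <- NULL
        if (r$kind == "ecDNA" && stable_hash(r$lineage_id) %% 3 != 0) {
          gi <- stable_hash(r$lineage_id) %% length(gn$oncogenes) + 1
          center <- gn$genes[gn$genes$name == gn$oncogenes[gi], , drop = FALSE]
        }
        st <- simulate_structure(genome, r$kind, config,
                                 seed = sub_seed(config$seed, amp_id),
                                 amplicon_id = amp_id,
                                 sample_id = r$sample_id, grade = r$grade,
                                 center_gene = center,
                                 lineage_id = r$lineage_id, genes = gn$genes)
        if (r$role == "parent") assign(r$lineage_id, st, envir = lineage_store)
      }
      structures[[r$sample_id]] <- c(structures[[r$sample_id]], list(st))
      truth[[length(truth) + 1]] <- st$truth
    }
  }

  # --- write everything -----------------------------------------------------
  w <- function(df, name, col.names = TRUE) {
    utils::write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  w(data.frame(chrom = names(genome), length = format_int(genome)),
    "genome.tsv")
  gb <- gn$genes[, c("chrom", "start", "end", "name", "strand")]
  gb$start <- format_int(gb$start); gb$end <- format_int(gb$end)
  w(gb, "genes.tsv", col.names = FALSE)
  writeLines(gn$oncogenes, file.path(outdir, "oncogenes.txt"))
  writeLines(gn$immunomodulatory, file.path(outdir, "immunomodulatory.txt"))
  smp <- layout$samples
  smp$level_cm <- sprintf("%g", smp$level_cm)
  w(smp, "samples.tsv")
  hs <- layout$histology[order(layout$histology$patient_id,
                               layout$histology$time_point,
                               layout$histology$level_cm), , drop = FALSE]
  hs$level_cm <- sprintf("%g", hs$level_cm)
  w(hs, "histology.tsv")
  tr <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(sample_id = character(), amplicon_id = character(),
               true_class = character(), true_cn = numeric(),
               lineage_id = character(), genes_planted = character())
  tr <- tr[order(tr$sample_id, tr$amplicon_id), , drop = FALSE]
  tr$true_cn <- format_cn(tr$true_cn)
  w(tr, "truth.tsv")

  sdir <- file.path(outdir, "samples")
  dir.create(sdir, showWarnings = FALSE)
  for (i in seq_len(nrow(layout$samples))) {
    sid <- layout$samples$sample_id[i]
    d <- file.path(sdir, sid)
    dir.create(d, showWarnings = FALSE)
    write_sample_cns(sid, structures[[sid]], genome, config,
                     file.path(d, paste0(sid, ".cns")))
    for (st in structures[[sid]]) {
      write_graph_file(st$graph,
                       file.path(d, paste0(st$graph$amplicon_id, "_graph.txt")))
      write_cycles_file(st$decomposition,
                        file.path(d, paste0(st$graph$amplicon_id,
                                            "_cycles.txt")))
    }
  }
  invisible(list(dir = outdir, samples = layout$samples,
                 histology = layout$histology, truth = tr, plan = plan,
                 genome = genome, genes = gn, config = config))
}

# diploid background broken into a few noisy segments per chromosome, with
# the planted amplicon segments riding on top at their copy number
write_sample_cns <- function(sample_id, structures, genome, config, path) {
  rng <- make_rng(sub_seed(config$seed, paste0("cns_", sample_id)))
  rows <- list()
  for (chr in names(genome)) {
    cuts <- round(seq(1, genome[[chr]] + 1, length.out = 5))
    for (k in seq_len(4)) {
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = chr, start = cuts[k], end = cuts[k + 1] - 1,
        cn = runif_rng(rng, 1, 1.8, 2.3), stringsAsFactors = FALSE)
    }
  }
  bg <- do.call(rbind, rows)
  amp <- list()
  for (st in structures %||% list()) {
    seg <- st$graph$segments
    amp[[length(amp) + 1]] <- data.frame(
      chromosome = seg$chrom, start = seg$start, end = seg$end,
      cn = seg$copy_count, stringsAsFactors = FALSE)
  }
  df <- rbind(bg, if (length(amp)) do.call(rbind, amp))
  df <- df[order(df$chromosome, df$start, df$end), , drop = FALSE]
  df$start <- format_int(df$start); df$end <- format_int(df$end)
  df$cn <- format_cn(df$cn)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
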