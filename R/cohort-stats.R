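#' Cohort association statistics
#'
#' Histology pairing and the association statistics used for the cohort
#' analyses: one-sided Fisher's exact tests on 2x2 tables, odds ratios with
#' Woolf (normal-approximation) confidence intervals and the Haldane
#' correction (0.5 added to every cell when any cell is zero), Mann-Whitney
#' U tests and Levene's variance test. No multiple-testing correction is
#' applied across the table family; each statistic is reported raw.
#'
#' @name cohort-stats
NULL

HISTOLOGY_LEVELS <- c("NDBE", "LGD", "HGD", "EAC")

#' Ordered histology grade
#'
#' Grades form the total order NDBE < LGD < HGD < EAC.
#'
#' @param x Character vector of grades.
#' @return Ordered factor.
#' @export
histology_grade <- function(x) {
  bad <- !is.na(x) & !x %in% HISTOLOGY_LEVELS
  if (any(bad)) stop("unknown histology grade: ", x[bad][1])
  factor(x, levels = HISTOLOGY_LEVELS, ordered = TRUE)
}

grade_rank <- function(x) match(x, HISTOLOGY_LEVELS)

most_severe <- function(grades) {
  r <- grade_rank(grades)
  if (all(is.na(r))) NA_character_ else HISTOLOGY_LEVELS[max(r, na.rm = TRUE)]
}

#' Pair sequencing biopsies with histology records
#'
#' A sequencing biopsy gets on-level histology when a histology biopsy from
#' the same patient and time point was taken at the identical oesophageal
#' level (height above the gastro-oesophageal junction), and windowed
#' histology when one was taken within `window_cm` of it (inclusive). When
#' several records qualify the most severe grade is assigned.
#'
#' @param samples Data frame with columns `sample_id`, `patient_id`,
#'   `time_point`, `level_cm`.
#' @param histology Data frame with columns `patient_id`, `time_point`,
#'   `level_cm`, `grade`.
#' @param window_cm Window half-width in cm (default 1).
#' @return `samples` with added character columns `histology_on_level` and
#'   `histology_windowed` (NA when no record qualifies).
#' @export
pair_histology <- function(samples, histology, window_cm = 1) {
  stopifnot(window_cm >= 0)
  eps <- 1e-9
  on_level <- character(nrow(samples))
  windowed <- character(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    rec <- histology[histology$patient_id == samples$patient_id[i] &
                       histology$time_point == samples$time_point[i], ,
                     drop = FALSE]
    d <- abs(rec$level_cm - samples$level_cm[i])
    on_level[i] <- most_severe(rec$grade[d <= eps])
    windowed[i] <- most_severe(rec$grade[d <= window_cm + eps])
  }
  samples$histology_on_level <- on_level
  samples$histology_windowed <- windowed
  samples
}

#' 2x2 contingency table
#'
#' @param a,b,c,d Non-negative counts, rows = exposure (a,b top row),
#'   columns = outcome (a,c first column).
#' @return 2x2 integer matrix.
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x))) stop("counts must be non-negative integers")
  matrix(as.integer(x), nrow = 2, byrow = TRUE)
}

#' One-sided Fisher's exact test
#'
#' Exact hypergeometric upper-tail probability of enrichment in cell (1,1):
#' the p-value is the probability, over all tables with the observed
#' margins, of a count in cell a at least as large as observed. Computed in
#' log space via `lchoose`, accurate to well over 12 significant digits.
#'
#' @param t 2x2 matrix (see [contingency_table()]).
#' @return The one-sided (greater) p-value.
#' @export
fisher_one_sided <- function(t) {
  stopifnot(is.matrix(t), all(dim(t) == 2))
  if (all(t == 0)) stop("all-zero contingency table")
  a <- t[1, 1]
  m <- t[1, 1] + t[1, 2]   # row 1 total
  n <- t[2, 1] + t[2, 2]   # row 2 total
  k <- t[1, 1] + t[2, 1]   # column 1 total
  hi <- min(m, k)
  ks <- a:hi
  logp <- lchoose(m, ks) + lchoose(n, k - ks) - lchoose(m + n, k)
  mx <- max(logp)
  exp(mx) * sum(exp(logp - mx))
}

#' Odds ratio with confidence interval
#'
#' OR = (a d)/(b c) with the Haldane correction -- 0.5 added to every cell
#' -- applied if and only if any cell is zero. The default interval is the
#' Woolf normal approximation on the log odds ratio with standard error
#' sqrt(1/a + 1/b + 1/c + 1/d) over the (possibly corrected) cells; the
#' exact conditional interval from [stats::fisher.test()] is available via
#' `method = "conditional"`.
#'
#' @param t 2x2 matrix.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"woolf"` (default) or `"conditional"`.
#' @return List with `or`, `ci_low`, `ci_high`, `haldane_applied`.
#' @export
odds_ratio_ci <- function(t, conf_level = 0.95,
                          method = c("woolf", "conditional")) {
  stopifnot(is.matrix(t), all(dim(t) == 2))
  method <- match.arg(method)
  haldane <- any(t == 0)
  tc <- if (haldane) t + 0.5 else t
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  if (method == "woolf") {
    se <- sqrt(sum(1 / tc))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    ft <- stats::fisher.test(t, conf.level = conf_level)
    ci <- ft$conf.int
  }
  list(or = or, ci_low = ci[1], ci_high = ci[2], haldane_applied = haldane)
}

#' Mann-Whitney U test
#'
#' Rank-sum test on two samples. For combined sizes of at most 12
#' observations the null distribution of U is enumerated exactly over all
#' assignments of the pooled values (valid under ties); larger samples use
#' the tie-corrected normal approximation with continuity correction.
#' `alternative = "greater"` tests whether `x` is stochastically greater
#' than `y`.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return The p-value.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("empty input")
  nx <- length(x); ny <- length(y)
  u_stat <- function(ix, pooled, nx) {
    # U for the sample indexed by ix within pooled values
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  pooled <- c(x, y)
  u <- u_stat(seq_len(nx), pooled, nx)
  if (nx + ny <= 12) {
    combos <- utils::combn(nx + ny, nx)
    us <- apply(combos, 2, function(ix) u_stat(ix, pooled, nx))
    p_greater <- mean(us >= u)
    p_less <- mean(us <= u)
  } else {
    nn <- nx + ny
    r <- rank(pooled)
    ties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    sigma <- sqrt(sigma2)
    p_greater <- stats::pnorm((u - 0.5 - mu) / sigma, lower.tail = FALSE)
    p_less <- stats::pnorm((u + 0.5 - mu) / sigma)
  }
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two.sided = min(1, 2 * min(p_greater, p_less)))
}

#' Levene's test for equality of variances
#'
#' Levene's W: a one-way ANOVA F test on the absolute deviations from the
#' group means, with the p-value from the F distribution.
#'
#' @param x,y Numeric vectors of length >= 2.
#' @return The p-value.
#' @export
levene <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("both groups need >= 2 values")
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  if (all(zx == 0) && all(zy == 0)) stop("degenerate input: no within-group deviation")
  z <- c(zx, zy)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Build the cohort 2x2 tables
#'
#' From per-sample ecDNA status and paired histology, reconstructs the
#' association tables of the study design:
#'
#' * `early_vs_ndbe` -- patient-level ecDNA by histology group, early-stage
#'   EAC vs NDBE/LGD (rows = group, columns = ecDNA+/-);
#' * `late_vs_early` -- late-stage vs early-stage EAC, patient level;
#' * `co_vs_nco` -- cancer-outcome vs non-cancer-outcome arm, any-sample
#'   ecDNA at patient level;
#' * `tp1_hgd` -- cancer-outcome TP-1 samples with on-level histology:
#'   rows = ecDNA status, columns = HGD vs less severe;
#' * `tp2_eac` -- cancer-outcome TP-2 samples with on-level histology:
#'   rows = ecDNA status, columns = EAC vs less severe.
#'
#' A patient is ecDNA-positive when any of their samples is. Only tables
#' whose groups are present in the input are emitted; all tables are
#' invariant to sample order.
#'
#' @param samples Data frame with columns `sample_id`, `patient_id`,
#'   `group`, `time_point`, `ecdna_positive`, `histology_on_level`.
#' @return Named list of 2x2 matrices.
#' @export
build_cohort_tables <- function(samples) {
  out <- list()
  pat <- stats::aggregate(ecdna_positive ~ patient_id + group, data = samples,
                          FUN = any)
  pat_pos <- function(grp) {
    sub <- pat[pat$group == grp, ]
    c(pos = sum(sub$ecdna_positive), neg = sum(!sub$ecdna_positive))
  }
  grp_table <- function(g1, g2) {
    p1 <- pat_pos(g1); p2 <- pat_pos(g2)
    contingency_table(p1["pos"], p1["neg"], p2["pos"], p2["neg"])
  }
  groups <- unique(pat$group)
  if (all(c("early_eac", "ndbe_lgd") %in% groups)) {
    out$early_vs_ndbe <- grp_table("early_eac", "ndbe_lgd")
  }
  if (all(c("late_eac", "early_eac") %in% groups)) {
    out$late_vs_early <- grp_table("late_eac", "early_eac")
  }
  if (all(c("CO", "NCO") %in% groups)) {
    out$co_vs_nco <- grp_table("CO", "NCO")
  }
  tp_table <- function(tp, severe_grade) {
    sub <- samples[samples$group == "CO" & samples$time_point == tp &
                     !is.na(samples$histology_on_level), , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    severe <- grade_rank(sub$histology_on_level) >= grade_rank(severe_grade)
    contingency_table(sum(sub$ecdna_positive & severe),
                      sum(sub$ecdna_positive & !severe),
                      sum(!sub$ecdna_positive & severe),
                      sum(!sub$ecdna_positive & !severe))
  }
  if ("CO" %in% groups) {
    t1 <- tp_table("TP1", "HGD")
    if (!is.null(t1)) out$tp1_hgd <- t1
    t2 <- tp_table("TP2", "EAC")
    if (!is.null(t2)) out$tp2_eac <- t2
  }
  out
}

#' Statistics report for a set of 2x2 tables
#'
#' @param tables Named list of 2x2 matrices (e.g. from
#'   [build_cohort_tables()]).
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return Data frame with one row per table: the four cells, the one-sided
#'   Fisher p-value, odds ratio, confidence bounds and whether the Haldane
#'   correction was applied.
#' @export
cohort_stats_report <- function(tables, conf_level = 0.95) {
  rows <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    o <- odds_ratio_ci(t, conf_level)
    data.frame(table = nm, a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2],
               fisher_p = fisher_one_sided(t), odds_ratio = o$or,
               ci_low = o$ci_low, ci_high = o$ci_high,
               haldane_applied = o$haldane_applied, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
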