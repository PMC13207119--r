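#' Significance stars from a p-value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, empty
#' otherwise or when p is undefined. Boundaries are inclusive.
#'
#' @param p numeric p-value(s), `NA` allowed.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p <= 0.05] <- "*"
  out[!is.na(p) & p <= 0.01] <- "**"
  out[!is.na(p) & p <= 0.001] <- "***"
  out
}

#' Two-tailed pooled-variance Student's t-test
#'
#' The classical equal-variance t statistic with n1 + n2 - 2 degrees of
#' freedom, computed by default on log2-transformed abundances (the noise
#' model is multiplicative); nonpositive values are dropped on the log
#' scale. A Welch option exists behind `var_equal = FALSE`.
#'
#' @param x,y numeric vectors of detected replicate values.
#' @param on_log_scale test log2 values (default `TRUE`).
#' @param var_equal pooled variance (default `TRUE`, classical Student).
#' @return List with `t`, `df`, `p` (all `NA` when either group has fewer
#'   than 2 usable values).
#' @export
student_t_test <- function(x, y, on_log_scale = TRUE, var_equal = TRUE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (on_log_scale) {
    x <- log2(x[x > 0])
    y <- log2(y[y > 0])
  }
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(list(t = NA_real_, df = NA_real_,
                                      p = NA_real_))
  m1 <- mean(x)
  m2 <- mean(y)
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se ^ 4 / ((v1 / n1) ^ 2 / (n1 - 1) + (v2 / n2) ^ 2 / (n2 - 1))
  }
  if (se == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    t_stat <- (m1 - m2) / se
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

group_values <- function(tab, feature, genotype, stage) {
  sel <- tab$samples$genotype == genotype & tab$samples$stage == stage
  i <- match(feature, tab$features$feature_id)
  if (is.na(i)) stop("feature '", feature, "' absent from table",
                     call. = FALSE)
  v <- tab$values[i, sel]
  det <- tab$detected[i, sel]
  list(values = v[det], n_total = sum(sel), n_detected = sum(det))
}

#' Differential result for one feature, mutant and stage
#'
#' log2 fold change of the mutant versus its matched wild type, with a
#' two-tailed pooled t-test on detected replicates. ND replicates are
#' excluded from group means (never zero-filled); a group that is ND in all
#' replicates makes the cell ND with an explanatory status. One-sided ND
#' (signal in one group only) is reported as a +/-Inf sentinel, never
#' imputed.
#'
#' @param tab an [abundance_table()].
#' @param design a [design_map()].
#' @param mutant mutant genotype.
#' @param stage stage label.
#' @param feature feature_id.
#' @param on_log_scale run the t-test on log2 values (default `TRUE`).
#' @return List of class `differential_result`: feature_id, genotype, stage,
#'   log2fc (`NA` = ND), p_value, stars, status (one of ok, nd_both,
#'   nd_mutant_only, nd_wildtype_only, insufficient_replicates).
#' @export
log2_fold_change <- function(tab, design, mutant, stage, feature,
                             on_log_scale = TRUE) {
  wt <- matched_wildtype(design, mutant)
  gm <- group_values(tab, feature, mutant, stage)
  gw <- group_values(tab, feature, wt, stage)
  res <- list(feature_id = feature, genotype = mutant, stage = stage,
              log2fc = NA_real_, p_value = NA_real_, stars = "",
              status = "ok")
  finish <- function(res) {
    res$stars <- p_stars(res$p_value)
    class(res) <- "differential_result"
    res
  }
  if (gm$n_detected == 0L && gw$n_detected == 0L) {
    res$status <- "nd_both"
    return(finish(res))
  }
  if (gm$n_detected == 0L) {
    res$status <- "nd_mutant_only"
    return(finish(res))
  }
  if (gw$n_detected == 0L) {
    res$status <- "nd_wildtype_only"
    return(finish(res))
  }
  if (gm$n_detected < 2L || gw$n_detected < 2L) {
    res$status <- "insufficient_replicates"
    return(finish(res))
  }
  m_mut <- mean(gm$values)
  m_wt <- mean(gw$values)
  res$log2fc <- if (m_wt == 0 && m_mut > 0) {
    Inf
  } else if (m_mut == 0 && m_wt > 0) {
    -Inf
  } else if (m_wt == 0 && m_mut == 0) {
    0
  } else {
    # difference of logs, not log of ratio: exactly antisymmetric in floats
    log2(m_mut) - log2(m_wt)
  }
  tt <- student_t_test(gm$values, gw$values, on_log_scale = on_log_scale)
  res$p_value <- tt$p
  finish(res)
}

#' All differential results for a table
#'
#' @param tab an [abundance_table()].
#' @param design a [design_map()].
#' @param mutants mutant genotypes (default: every design mutant present).
#' @param stages stages (default: all in the table).
#' @param features feature_ids (default: all).
#' @param on_log_scale forwarded to [log2_fold_change()].
#' @return data.frame of class `differential_table` with one row per
#'   feature x mutant x stage.
#' @export
differential_table <- function(tab, design, mutants = NULL, stages = NULL,
                               features = NULL, on_log_scale = TRUE) {
  if (is.null(mutants)) {
    mutants <- intersect(names(design$mutant_to_wildtype),
                         unique(tab$samples$genotype))
  }
  if (is.null(stages)) stages <- unique(tab$samples$stage)
  if (is.null(features)) features <- tab$features$feature_id
  rows <- vector("list",
                 length(features) * length(mutants) * length(stages))
  k <- 0L
  for (st in stages) for (mut in mutants) for (f in features) {
    r <- log2_fold_change(tab, design, mut, st, f,
                          on_log_scale = on_log_scale)
    k <- k + 1L
    rows[[k]] <- data.frame(feature_id = r$feature_id, genotype = r$genotype,
                            stage = r$stage, log2fc = r$log2fc,
                            p_value = r$p_value, stars = r$stars,
                            status = r$status, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' One-way ANOVA with Tukey HSD across genotypes
#'
#' Classical decomposition into between- and within-group sums of squares on
#' detected replicates, followed by Tukey's honestly-significant-difference
#' test via the studentized range distribution for every genotype pair.
#'
#' @param tab an [abundance_table()].
#' @param feature feature_id.
#' @param stage stage label.
#' @param genotypes genotypes to compare (default: all with >= 2 detected
#'   replicates at the stage).
#' @param on_log_scale analyze log2 values (default `TRUE`).
#' @return List of class `anova_tukey_result`: `status` ("ok",
#'   "insufficient_groups" or "no_variance"), `F`, `df`, `p`, and `pairs`
#'   (data.frame genotype_a, genotype_b, diff, p_adj).
#' @export
anova_tukey <- function(tab, feature, stage, genotypes = NULL,
                        on_log_scale = TRUE) {
  if (is.null(genotypes)) genotypes <- unique(tab$samples$genotype)
  groups <- list()
  for (g in genotypes) {
    v <- group_values(tab, feature, g, stage)$values
    if (on_log_scale) v <- log2(v[v > 0])
    if (length(v) >= 2L) groups[[g]] <- v
  }
  k <- length(groups)
  if (k < 2L) {
    return(structure(list(status = "insufficient_groups", F = NA_real_,
                          df = c(NA_real_, NA_real_), p = NA_real_,
                          pairs = NULL),
                     class = "anova_tukey_result"))
  }
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, 1)
  n <- sum(n_i)
  grand <- sum(n_i * m_i) / n
  ss_between <- sum(n_i * (m_i - grand) ^ 2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v)) ^ 2), 1))
  df_b <- k - 1
  df_w <- n - k
  if (diff(range(unlist(groups))) == 0) {
    # every observation identical: F is 0/0, guarded as "no variance"
    return(structure(list(status = "no_variance", F = NA_real_,
                          df = c(df_b, df_w), p = NA_real_, pairs = NULL),
                     class = "anova_tukey_result"))
  }
  msw <- ss_within / df_w
  f_stat <- if (msw == 0) Inf else (ss_between / df_b) / msw
  p <- if (is.infinite(f_stat)) 0 else
    stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  gn <- names(groups)
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    d <- m_i[j] - m_i[i]
    se <- sqrt(msw / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- if (se == 0) {
      if (d == 0) 0 else Inf
    } else {
      abs(d) / se
    }
    p_adj <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(
      genotype_a = gn[i], genotype_b = gn[j], diff = unname(d),
      p_adj = unname(p_adj), stringsAsFactors = FALSE)
  }
  structure(list(status = "ok", F = unname(f_stat), df = c(df_b, df_w),
                 p = unname(p), pairs = do.call(rbind, pairs)),
            class = "anova_tukey_result")
}

#' Export a long-format heatmap table
#'
#' One row per feature x mutant x stage: glyph (square for metabolites,
#' circle for transcripts), pathway annotation, log2fc (ND cells emitted as
#' `"ND"`, one-sided detection as `"+Inf"`/`"-Inf"`), stars and status.
#' Rows are ordered by pathway position (class, branch, step) and then by
#' the display order of mutants (at, r, t, B, Del by default).
#'
#' @param results a [differential_table()].
#' @param catalog a [feature_catalog()].
#' @param path optional TSV output path.
#' @param mutant_order display order of mutants.
#' @param stage_order display order of stages.
#' @return The ordered export data.frame (invisibly when `path` is given).
#' @export
export_heatmap_table <- function(results, catalog, path = NULL,
                                 mutant_order = c("at", "r", "t", "B",
                                                  "Del"),
                                 stage_order = c("MG", "Br", "FR")) {
  idx <- match(results$feature_id, catalog$feature_id)
  out <- data.frame(
    feature_id = results$feature_id,
    glyph = ifelse(catalog$kind[idx] == "transcript", "circle", "square"),
    pathway_class = catalog$pathway_class[idx],
    branch_id = catalog$branch_id[idx],
    step_index = catalog$step_index[idx],
    mutant = results$genotype,
    stage = results$stage,
    log2fc = ifelse(is.na(results$log2fc), "ND",
                    ifelse(is.infinite(results$log2fc),
                           ifelse(results$log2fc > 0, "+Inf", "-Inf"),
                           as.character(results$log2fc))),
    stars = results$stars,
    status = results$status,
    stringsAsFactors = FALSE
  )
  class_order <- c("CAR", "ABA", "MEP", "MVA", "CHL", "TOC", "QUI")
  mutants <- unique(out$mutant)
  mut_rank <- match(out$mutant, c(mutant_order,
                                  setdiff(mutants, mutant_order)))
  ord <- order(match(out$pathway_class, class_order),
               out$branch_id, out$step_index, out$feature_id,
               mut_rank, match(out$stage, stage_order),
               na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    return(invisible(out))
  }
  out
}
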