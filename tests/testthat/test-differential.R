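# differential module: log2fc, pooled t, ANOVA/Tukey, stars, export

test_that("log2fc basics: equality, exact powers of two, ND statuses", {
  d <- default_design()
  tab <- two_group_table(c(8, 8, 8), c(2, 2, 2))
  r <- log2_fold_change(tab, d, "at", "FR", "m1")
  expect_identical(r$log2fc, 2)
  expect_identical(r$status, "ok")
  same <- two_group_table(c(5, 6, 7), c(5, 6, 7))
  expect_equal(log2_fold_change(same, d, "at", "FR", "m1")$log2fc, 0)
  # mutant all-ND, wild type detected -> gray cell
  vals <- matrix(c(2, 2, 2, NA, NA, NA), nrow = 1)
  tab_nd <- abundance_table(vals, !is.na(vals),
                            tiny_catalog(1L, 0L), tiny_samples(n_rep = 3L))
  r_nd <- log2_fold_change(tab_nd, d, "at", "FR", "m1")
  expect_identical(r_nd$status, "nd_mutant_only")
  expect_true(is.na(r_nd$log2fc))
  expect_identical(r_nd$stars, "")
  # both ND, and wild-type-only ND with a +Inf-free status
  all_nd <- abundance_table(matrix(NA_real_, 1, 6),
                            matrix(FALSE, 1, 6),
                            tiny_catalog(1L, 0L), tiny_samples(n_rep = 3L))
  expect_identical(log2_fold_change(all_nd, d, "at", "FR", "m1")$status,
                   "nd_both")
  wt_nd <- abundance_table(matrix(c(NA, NA, NA, 4, 4, 4), nrow = 1),
                           matrix(rep(c(FALSE, TRUE), each = 3), nrow = 1),
                           tiny_catalog(1L, 0L), tiny_samples(n_rep = 3L))
  expect_identical(log2_fold_change(wt_nd, d, "at", "FR", "m1")$status,
                   "nd_wildtype_only")
})

test_that("ND replicates are excluded from means, not zero-filled", {
  d <- default_design()
  vals <- matrix(c(2, 2, 2, 8, 8, NA), nrow = 1)
  tab <- abundance_table(vals, !is.na(vals), tiny_catalog(1L, 0L),
                         tiny_samples(n_rep = 3L))
  expect_identical(log2_fold_change(tab, d, "at", "FR", "m1")$log2fc, 2)
  # a single detected replicate cannot support the statistics
  one_rep <- matrix(c(2, 2, 2, 8, NA, NA), nrow = 1)
  tab1 <- abundance_table(one_rep, !is.na(one_rep), tiny_catalog(1L, 0L),
                          tiny_samples(n_rep = 3L))
  r1 <- log2_fold_change(tab1, d, "at", "FR", "m1")
  expect_identical(r1$status, "insufficient_replicates")
  expect_true(is.na(r1$log2fc))
})

test_that("zero wild-type mean with detected mutant signal gives +Inf", {
  d <- default_design()
  tab <- two_group_table(c(4, 4, 4), c(0, 0, 0))
  r <- log2_fold_change(tab, d, "at", "FR", "m1")
  expect_identical(r$status, "ok")
  expect_identical(r$log2fc, Inf)
})

test_that("antisymmetry: swapping mutant and wild type negates log2fc", {
  set.seed(31)
  fwd <- design_map(c(at = "AC"))
  # a design with the roles reversed: AC treated as mutant of 'at'
  rev <- design_map(c(AC = "at"))
  for (i in 1:50) {
    tab <- two_group_table(runif(3, 1, 50), runif(3, 1, 50))
    a <- log2_fold_change(tab, fwd, "at", "FR", "m1")$log2fc
    b <- log2_fold_change(tab, rev, "AC", "FR", "m1")$log2fc
    expect_identical(a, -b)
  }
})

test_that("pooled t equals the textbook formula and stats::t.test", {
  # closed-form case from first principles: (10,11,12) vs (20,21,22)
  r <- student_t_test(c(10, 11, 12), c(20, 21, 22), on_log_scale = FALSE)
  expect_equal(r$t, -10 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-12)
  expect_equal(r$t, -12.24745, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4), tolerance = 1e-15)
  # identical groups: t = 0, p = 1
  r0 <- student_t_test(c(1, 2, 3), c(1, 2, 3), on_log_scale = FALSE)
  expect_identical(r0$t, 0)
  expect_identical(r0$p, 1)
  # oracle sweep
  set.seed(17)
  for (i in 1:500) {
    x <- rnorm(sample(2:6, 1), 10, 2)
    y <- rnorm(sample(2:6, 1), 11, 3)
    mine <- student_t_test(x, y, on_log_scale = FALSE)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
  # Welch flavor against the oracle too
  xw <- rnorm(5, 0, 1); yw <- rnorm(7, 1, 4)
  mw <- student_t_test(xw, yw, on_log_scale = FALSE, var_equal = FALSE)
  rw <- t.test(xw, yw, var.equal = FALSE)
  expect_equal(mw$p, rw$p.value, tolerance = 1e-12)
})

test_that("t-test degenerate inputs are guarded", {
  expect_true(is.na(student_t_test(c(1, 2), 3, on_log_scale = FALSE)$p))
  r <- student_t_test(c(2, 2), c(3, 3), on_log_scale = FALSE)
  expect_identical(r$p, 0)  # zero variance, different means
  r2 <- student_t_test(c(2, 2), c(2, 2), on_log_scale = FALSE)
  expect_identical(r2$p, 1)
})

test_that("star coding boundaries are inclusive and pure in p", {
  expect_identical(p_stars(c(0.05, 0.01, 0.001)), c("*", "**", "***"))
  expect_identical(p_stars(c(0.0500001, 0.06, NA, 1)), rep("", 4))
  expect_identical(p_stars(c(0.049, 0.0099, 0.0002)),
                   c("*", "**", "***"))
})

test_that("ANOVA + Tukey matches aov/TukeyHSD and F = t^2 for 2 groups", {
  set.seed(23)
  genos <- c("AC", "at", "r", "B")
  samples <- tiny_samples(genos, n_rep = 5L)
  for (i in 1:20) {
    vals <- matrix(exp(rnorm(20, 3, 0.5)), nrow = 1)
    tab <- abundance_table(vals, features = tiny_catalog(1L, 0L),
                           samples = samples)
    mine <- anova_tukey(tab, "m1", "FR", on_log_scale = FALSE)
    df <- data.frame(y = vals[1, ], g = factor(samples$genotype))
    fit <- aov(y ~ g, data = df)
    ref_f <- summary(fit)[[1]]$`F value`[1]
    expect_equal(mine$F, ref_f, tolerance = 1e-10)
    ref_tukey <- TukeyHSD(fit)$g
    for (k in seq_len(nrow(mine$pairs))) {
      key <- paste(mine$pairs$genotype_b[k], mine$pairs$genotype_a[k],
                   sep = "-")
      key2 <- paste(mine$pairs$genotype_a[k], mine$pairs$genotype_b[k],
                    sep = "-")
      ref_p <- if (key %in% rownames(ref_tukey)) ref_tukey[key, "p adj"]
      else ref_tukey[key2, "p adj"]
      expect_equal(mine$pairs$p_adj[k], unname(ref_p), tolerance = 1e-8)
    }
  }
  # F = t^2 with exactly two groups
  s2 <- tiny_samples(c("AC", "at"), n_rep = 4L)
  for (i in 1:20) {
    v <- matrix(runif(8, 1, 9), nrow = 1)
    tab2 <- abundance_table(v, features = tiny_catalog(1L, 0L),
                            samples = s2)
    a <- anova_tukey(tab2, "m1", "FR", on_log_scale = FALSE)
    tt <- student_t_test(v[1, 5:8], v[1, 1:4], on_log_scale = FALSE)
    expect_equal(a$F, tt$t ^ 2, tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases: constants and clear separation", {
  samples <- tiny_samples(c("AC", "at", "r"), n_rep = 3L)
  const <- abundance_table(matrix(5, 1, 9), features = tiny_catalog(1L, 0L),
                           samples = samples)
  expect_identical(anova_tukey(const, "m1", "FR")$status, "no_variance")
  vals <- matrix(c(rep(5, 3), rep(5, 3), rep(40, 3)) +
                   rep(c(0, 0.001, -0.001), 3), nrow = 1)
  tab <- abundance_table(vals, features = tiny_catalog(1L, 0L),
                         samples = samples)
  a <- anova_tukey(tab, "m1", "FR", on_log_scale = FALSE)
  p <- a$pairs
  p05 <- p$p_adj[p$genotype_a == "AC" & p$genotype_b == "at"]
  expect_gt(p05, 0.5)
  expect_lt(min(p$p_adj[p$genotype_b == "r" | p$genotype_a == "r"]), 1e-6)
  one_group <- abundance_table(matrix(1:3, 1), features = tiny_catalog(1L, 0L),
                               samples = tiny_samples("AC", n_rep = 3L))
  expect_identical(anova_tukey(one_group, "m1", "FR")$status,
                   "insufficient_groups")
})

test_that("heatmap export orders rows and encodes glyphs and ND", {
  cfg <- simulation_config(seed = 4L)
  ds <- generate_dataset(cfg)
  res <- differential_table(ds$table, default_design(), stages = "FR")
  out <- export_heatmap_table(res, ds$table$features)
  expect_equal(nrow(out), nrow(ds$table$features) * 5L)
  # transcripts are circles, metabolites squares
  expect_setequal(out$glyph[out$feature_id == "PSY1"], "circle")
  expect_setequal(out$glyph[out$feature_id == "phytoene"], "square")
  # nd cells emitted as the string ND, never numeric
  nd_rows <- out[out$status %in% c("nd_both", "nd_mutant_only"), ]
  expect_true(all(nd_rows$log2fc == "ND"))
  # mutant display order within a feature
  expect_identical(out$mutant[out$feature_id == out$feature_id[1]][1:5],
                   c("at", "r", "t", "B", "Del"))
  # CAR block precedes the CHL block
  expect_lt(max(which(out$pathway_class == "CAR")),
            min(which(out$pathway_class == "CHL")))
  # count arithmetic: 44 CAR metabolites x 5 mutants at one stage
  car_met <- ds$table$features$feature_id[
    ds$table$features$pathway_class == "CAR" &
      ds$table$features$kind == "metabolite"]
  expect_length(car_met, 44L)
  expect_equal(sum(out$glyph == "square" & out$pathway_class == "CAR"),
               44L * 5L)
})
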