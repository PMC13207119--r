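# core model: containers, validation, readers/writers, pathway map

test_that("abundance table validation catches dimension and sign errors", {
  feats <- tiny_catalog()
  samples <- tiny_samples()
  ok <- abundance_table(matrix(1:18, nrow = 3), features = feats,
                        samples = samples)
  expect_s3_class(ok, "abundance_table")
  expect_error(
    abundance_table(matrix(1, nrow = 2, ncol = 6), features = feats,
                    samples = samples),
    "dimensions")
  bad <- matrix(1, 3, 6)
  bad[2, 2] <- -4
  expect_error(abundance_table(bad, features = feats, samples = samples),
               "nonnegative")
})

test_that("feature and sample metadata invariants are enforced", {
  expect_error(feature_catalog(c("a", "a"), kind = "metabolite",
                               pathway_class = "CAR"),
               "duplicate feature_id")
  expect_error(feature_catalog("a", kind = "metabolite",
                               pathway_class = "CAR",
                               branch_id = "core", step_index = NA),
               "together")
  expect_error(feature_catalog("a", kind = "metabolite",
                               pathway_class = "XXX"),
               "pathway_class")
  expect_error(
    sample_metadata("s1", genotype = "AC", background = "M82",
                    stage = "FR", replicate = 1L),
    "background == genotype")
  expect_error(
    sample_metadata(c("s1", "s2"), genotype = "at", background = "AC",
                    stage = "FR", replicate = c(1L, 1L)),
    "duplicate \\(genotype, stage, replicate\\)")
})

test_that("ND cells round the matrix reader as flags, not numbers", {
  feats <- tiny_catalog(n_met = 2L, n_tx = 0L)
  samples <- tiny_samples(n_rep = 1L, genotypes = c("AC", "at"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tAC_FR_1\tat_FR_1",
               "m1\t1.5\t2.5",
               "m2\t3\tND"), tsv)
  tab <- read_abundance_table(tsv, feats, samples)
  expect_identical(tab$detected,
                   matrix(c(TRUE, TRUE, TRUE, FALSE), nrow = 2,
                          dimnames = dimnames(tab$values)))
  expect_true(is.na(tab$values["m2", "at_FR_1"]))
  expect_equal(tab$values["m1", "at_FR_1"], 2.5)
})

test_that("reader names the offending sample, feature, or cell", {
  feats <- tiny_catalog(n_met = 2L, n_tx = 0L)
  samples <- tiny_samples(n_rep = 1L)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\tAC_FR_1\tghost_sample",
               "m1\t1\t2", "m2\t3\t4"), tsv)
  expect_error(read_abundance_table(tsv, feats, samples), "ghost_sample")
  writeLines(c("feature_id\tAC_FR_1\tat_FR_1",
               "m1\t1\t2", "ghost_feature\t3\t4"), tsv)
  expect_error(read_abundance_table(tsv, feats, samples), "ghost_feature")
  writeLines(c("feature_id\tAC_FR_1\tat_FR_1",
               "m1\t1\t-2", "m2\t3\t4"), tsv)
  expect_error(read_abundance_table(tsv, feats, samples), "negative")
  writeLines(c("feature_id\tAC_FR_1\tat_FR_1",
               "m1\t1\t2", "m1\t3\t4"), tsv)
  expect_error(read_abundance_table(tsv, feats, samples), "duplicate")
})

test_that("write -> read round trip is lossless; second write is identical", {
  set.seed(71)
  feats <- tiny_catalog(n_met = 6L, n_tx = 0L)
  samples <- tiny_samples(n_rep = 2L, genotypes = c("AC", "at", "r"))
  for (i in 1:100) {
    # decimal literals: the doubles are exact parses of 6-decimal strings
    vals <- matrix(as.numeric(sprintf("%.6f", runif(36, 0, 50))), nrow = 6)
    det <- matrix(runif(36) > 0.2, nrow = 6)
    vals[!det] <- NA
    tab <- abundance_table(vals, det, feats, samples)
    f1 <- tempfile(fileext = ".tsv")
    write_abundance_table(tab, f1)
    back <- read_abundance_table(f1, feats, samples)
    expect_identical(back$values, tab$values)
    expect_identical(back$detected, tab$detected)
    f2 <- tempfile(fileext = ".tsv")
    write_abundance_table(back, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    unlink(c(f1, f2))
  }
})

test_that("all-detected tables carry no sentinel; empty tables round-trip", {
  feats <- tiny_catalog(n_met = 2L, n_tx = 0L)
  samples <- tiny_samples(n_rep = 1L)
  tab <- abundance_table(matrix(1:4, 2), features = feats,
                         samples = samples)
  f <- tempfile()
  write_abundance_table(tab, f)
  expect_false(any(grepl("ND", readLines(f))))
  empty <- abundance_table(matrix(numeric(0), nrow = 0, ncol = 2),
                           features = feats[0, ], samples = samples)
  write_abundance_table(empty, f)
  expect_length(readLines(f), 1L)  # header only
})

test_that("validate_design reports the panel layout and flags defects", {
  samples <- default_sample_metadata(3L)
  rep_ok <- validate_design(samples, default_design())
  expect_true(all(rep_ok$counts$flag == ""))
  expect_length(rep_ok$unmatched_mutants, 0L)
  expect_equal(sort(unique(rep_ok$counts$n_replicates)), 3L)
  # one mutant with a single FR replicate -> flagged cell
  drop <- samples$sample_id[samples$genotype == "t" &
                              samples$stage == "FR"][2:3]
  crippled <- samples[!samples$sample_id %in% drop, ]
  rep_bad <- validate_design(crippled, default_design())
  flagged <- rep_bad$counts[rep_bad$counts$flag != "", ]
  expect_equal(flagged$genotype, "t")
  expect_equal(flagged$stage, "FR")
  # design omitting Del -> unmatched mutant
  partial <- design_map(c(at = "AC", r = "AC", t = "AC", B = "AC"))
  expect_true("Del" %in% validate_design(samples, partial)$unmatched_mutants)
})

test_that("validate_design is total and matches a brute-force group-by", {
  set.seed(5)
  for (i in 1:20) {
    genos <- sample(c("AC", "M82", "at", "r", "t", "B", "Del"),
                    sample(2:7, 1))
    n_rep <- sample(1:4, 1)
    samples <- tiny_samples(genos, n_rep = n_rep,
                            stages = sample(c("MG", "Br", "FR"),
                                            sample(1:3, 1)))
    rep <- expect_no_error(validate_design(samples, default_design()))
    brute <- table(samples$genotype, samples$stage)
    for (k in seq_len(nrow(rep$counts))) {
      row <- rep$counts[k, ]
      expect_equal(row$n_replicates,
                   unname(brute[row$genotype, row$stage]))
    }
  }
})

test_that("pathway map enforces DAG and branch-fraction invariants", {
  expect_s3_class(chain_map(), "pathway_map")
  expect_equal(nrow(chain_map()$edges), 2L)
  expect_error(
    pathway_map(c("A", "B"),
                data.frame(substrate = c("A", "B"), product = c("B", "A"),
                           gene = c("g1", "g2"))),
    "cycle")
  two_out <- function(f1, f2) pathway_map(
    c("A", "B", "C"),
    data.frame(substrate = c("A", "A"), product = c("B", "C"),
               gene = c("g1", "g2")),
    branch_fractions = list(A = c(B = f1, C = f2)))
  expect_s3_class(two_out(0.6, 0.4), "pathway_map")
  expect_error(two_out(0.6, 0.5), "sum to")
})

test_that("pathway map JSON round-trips and validates gene membership", {
  map <- default_pathway_map()
  f <- tempfile(fileext = ".json")
  write_pathway_map(map, f)
  back <- read_pathway_map(f)
  expect_equal(back$nodes, map$nodes)
  expect_equal(back$edges, map$edges)
  expect_equal(back$branch_fractions, map$branch_fractions)
  # >= 2 branches downstream of lycopene (eps and beta cyclization)
  expect_gte(length(back$branch_fractions[["trans-lycopene"]]), 2L)
  expect_error(read_pathway_map(f, transcript_ids = c("PSY1")),
               "missing from the transcript catalog")
})

test_that("map loader accepts exactly the acyclic graphs", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:7, 1)
    nodes <- paste0("n", seq_len(n))
    n_e <- sample(2:9, 1)
    edges <- data.frame(substrate = sample(nodes, n_e, replace = TRUE),
                        product = sample(nodes, n_e, replace = TRUE),
                        gene = paste0("g", seq_len(n_e)))
    edges <- edges[edges$substrate != edges$product, , drop = FALSE]
    edges <- edges[!duplicated(edges[, 1:2]), , drop = FALSE]
    if (nrow(edges) == 0L) next
    frac <- lapply(split(edges$product, edges$substrate), function(p) {
      stats::setNames(rep(1 / length(p), length(p)), p)
    })
    # independent cycle detector: DFS with colors
    adj <- split(edges$product, edges$substrate)
    color <- stats::setNames(rep(0L, n), nodes)
    cyclic <- FALSE
    visit <- function(v) {
      color[[v]] <<- 1L
      for (w in adj[[v]]) {
        if (color[[w]] == 1L) cyclic <<- TRUE
        else if (color[[w]] == 0L) visit(w)
      }
      color[[v]] <<- 2L
    }
    for (v in nodes) if (color[[v]] == 0L) visit(v)
    got <- tryCatch(
      {pathway_map(nodes, edges, frac); "acyclic"},
      error = function(e) {
        if (grepl("cycle", conditionMessage(e))) "cyclic" else stop(e)
      })
    expect_identical(got, if (cyclic) "cyclic" else "acyclic")
  }
})

test_that("metadata TSV writers and readers round-trip", {
  d <- tempfile()
  dir.create(d)
  feats <- default_feature_catalog()
  samples <- default_sample_metadata()
  write_feature_catalog(feats, file.path(d, "features.tsv"))
  write_sample_metadata(samples, file.path(d, "samples.tsv"))
  feats2 <- read_feature_catalog(file.path(d, "features.tsv"))
  samples2 <- read_sample_metadata(file.path(d, "samples.tsv"))
  expect_equal(as.data.frame(feats2), as.data.frame(feats))
  expect_equal(as.data.frame(samples2), as.data.frame(samples))
  unlink(d, recursive = TRUE)
})
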