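# Fixture builders shared across the suite. Everything is generated in code.

tiny_catalog <- function(n_met = 2L, n_tx = 1L) {
  ids <- c(sprintf("m%d", seq_len(n_met)), sprintf("g%d", seq_len(n_tx)))
  feature_catalog(
    feature_id = ids,
    kind = rep(c("metabolite", "transcript"), c(n_met, n_tx)),
    pathway_class = "CAR"
  )
}

tiny_samples <- function(genotypes = c("AC", "at"), n_rep = 3L,
                         stages = "FR") {
  grid <- expand.grid(replicate = seq_len(n_rep), stage = stages,
                      genotype = genotypes, stringsAsFactors = FALSE)
  sample_metadata(
    sample_id = sprintf("%s_%s_%d", grid$genotype, grid$stage,
                        grid$replicate),
    genotype = grid$genotype,
    background = ifelse(grid$genotype %in% c("AC", "M82"),
                        grid$genotype, "AC"),
    stage = grid$stage, replicate = grid$replicate
  )
}

# features x samples table with the given per-group replicate values
two_group_table <- function(mut_values, wt_values, feature = "m1",
                            mutant = "at", stage = "FR") {
  n <- length(mut_values)
  stopifnot(length(wt_values) == n)
  samples <- tiny_samples(c("AC", mutant), n_rep = n, stages = stage)
  cat1 <- tiny_catalog(n_met = 1L, n_tx = 0L)
  vals <- matrix(c(wt_values, mut_values), nrow = 1L)
  abundance_table(vals, features = cat1, samples = samples)
}

random_abundance_table <- function(n_f = 20L, n_s = 21L, nd_prob = 0.05,
                                   lognormal = TRUE) {
  genos <- c("AC", "M82", "at", "r", "t", "B", "Del")
  n_rep <- ceiling(n_s / length(genos))
  samples <- tiny_samples(genos, n_rep = n_rep, stages = "FR")
  samples <- samples[seq_len(n_s), , drop = FALSE]
  feats <- feature_catalog(sprintf("f%02d", seq_len(n_f)),
                           kind = "metabolite", pathway_class = "CAR")
  vals <- matrix(if (lognormal) exp(rnorm(n_f * n_s, 3, 1))
                 else runif(n_f * n_s, 1, 100), nrow = n_f)
  det <- matrix(runif(n_f * n_s) > nd_prob, nrow = n_f)
  vals[!det] <- NA_real_
  abundance_table(vals, det, feats, samples)
}

# linear chain A -> B -> C with one gene per step
chain_map <- function() {
  pathway_map(
    nodes = c("A", "B", "C"),
    edges = data.frame(substrate = c("A", "B"), product = c("B", "C"),
                       gene = c("gAB", "gBC"))
  )
}

empty_map <- function() {
  pathway_map(character(0),
              data.frame(substrate = character(0), product = character(0),
                         gene = character(0)))
}

no_satellites <- function() {
  data.frame(feature_id = character(0), node = character(0),
             ratio = numeric(0), stringsAsFactors = FALSE)
}

# transcripts-only config with one planted module around a hub plus
# independent decoys; 7 genotypes x 3 replicates at FR = 21 samples,
# no mutations, so correlations are purely module-driven
module_config <- function(rho = 0.95, n_module = 8L, n_decoys = 40L,
                          sigma = 0.25, seed = 1L) {
  members <- c("HUB", sprintf("M%d", seq_len(n_module - 1L)))
  decoys <- sprintf("D%02d", seq_len(n_decoys))
  catalog <- feature_catalog(c(members, decoys), kind = "transcript",
                             pathway_class = "CAR")
  simulation_config(
    n_replicates = 3L, stages = "FR",
    catalog = catalog, map = empty_map(), mutations = list(),
    noise_sigma = sigma, lod = 0,
    satellites = no_satellites(), metabolite_base = NULL,
    transcript_coupling = list(list(members = members, rho = rho)),
    seed = seed
  )
}

hash_tree <- function(dir, exclude = c("run.log", "provenance.json")) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% exclude]
  files <- sort(files)
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", names(h))
  h
}
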