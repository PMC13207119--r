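#' Mutation specification
#'
#' A loss-of-function (lof) mutation transmits only a fraction `lambda` of
#' flux through the edges its target gene catalyzes and piles up the
#' immediate substrate by a backlog factor `1 + (1 - lambda) * kappa`.
#' A gain-of-function (gof) mutation multiplies its edges' branch fractions
#' by `gain` before renormalization.
#'
#' @param genotype genotype label carrying the mutation.
#' @param target_gene transcript feature_id of the mutated gene.
#' @param effect `"lof"` or `"gof"`.
#' @param lambda leakiness in \[0, 1\] (lof only).
#' @param gain multiplier >= 1 on the mutated step's branch fraction
#'   (gof only).
#' @param kappa substrate accumulation factor >= 0 (lof only).
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(genotype, target_gene, effect,
                          lambda = 1, gain = 1, kappa = 0) {
  effect <- match.arg(effect, c("lof", "gof"))
  if (effect == "lof") {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]",
                                       call. = FALSE)
    if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  } else {
    if (gain < 1) stop("gain must be >= 1", call. = FALSE)
  }
  structure(list(genotype = genotype, target_gene = target_gene,
                 effect = effect, lambda = lambda, gain = gain,
                 kappa = kappa),
            class = "mutation_spec")
}

#' The default mutant presets of the panel
#'
#' at / r / t are loss-of-function alleles of IDI1 / PSY1 / CrtISO1
#' (leakiness 0, 0, 0.05; the nonzero leak models a partially leaky allele);
#' B / Del are gain-of-function alleles of CYC-b / LCY-e (gain 5). The
#' allele-strength values are illustrative defaults: no quantitative
#' estimates exist for them.
#'
#' @return Named list of [mutation_spec()] lists, keyed by genotype.
#' @export
default_mutation_presets <- function() {
  list(
    at = list(mutation_spec("at", "IDI1", "lof", lambda = 0, kappa = 1)),
    r = list(mutation_spec("r", "PSY1", "lof", lambda = 0, kappa = 1)),
    t = list(mutation_spec("t", "CrtISO1", "lof", lambda = 0.05, kappa = 1)),
    B = list(mutation_spec("B", "CYC-b", "gof", gain = 5)),
    Del = list(mutation_spec("Del", "LCY-e", "gof", gain = 5))
  )
}

#' Propagate steady-state flux through a pathway map
#'
#' Noiseless multiplicative propagation: every entry node (in-degree 0)
#' receives `stage_input`; each product mean is the sum over incoming edges
#' of substrate mean x branch fraction x edge transmission. Transmission is
#' `lambda` for edges whose gene is lof-mutated and 1 otherwise. A gof
#' mutation multiplies its edges' branch fractions by `gain`, after which
#' each node's outgoing fractions are renormalized to sum to 1. Finally each
#' lof-affected edge multiplies its substrate's reported mean by
#' `1 + (1 - lambda) * kappa` (backlog); the backlog does not feed forward.
#'
#' @param map a [pathway_map()].
#' @param mutations list of [mutation_spec()] for one genotype (possibly
#'   empty).
#' @param stage_input positive flux entering the pathway.
#' @return Named numeric vector of noiseless node means.
#' @export
propagate_flux <- function(map, mutations = list(), stage_input) {
  stopifnot(inherits(map, "pathway_map"), stage_input > 0)
  for (m in mutations) {
    if (!m$target_gene %in% map$edges$gene) {
      stop("mutation targets gene '", m$target_gene,
           "' absent from the pathway map", call. = FALSE)
    }
  }
  edges <- map$edges
  n_e <- nrow(edges)
  frac <- numeric(n_e)
  for (i in seq_len(n_e)) {
    frac[i] <- map$branch_fractions[[edges$substrate[i]]][[edges$product[i]]]
  }
  trans <- rep(1, n_e)
  backlog <- rep(1, n_e)
  for (m in mutations) {
    hit <- edges$gene == m$target_gene
    if (m$effect == "lof") {
      trans[hit] <- m$lambda
      backlog[hit] <- 1 + (1 - m$lambda) * m$kappa
    } else {
      frac[hit] <- frac[hit] * m$gain
    }
  }
  # renormalize outgoing fractions node by node (no-op without gof)
  for (v in unique(edges$substrate)) {
    idx <- which(edges$substrate == v)
    s <- sum(frac[idx])
    if (s > 0) frac[idx] <- frac[idx] / s
  }
  mu <- stats::setNames(numeric(length(map$nodes)), map$nodes)
  indeg <- table(factor(edges$product, levels = map$nodes))
  mu[names(indeg)[indeg == 0L]] <- stage_input
  for (v in map$topo_order) {
    inc <- which(edges$product == v)
    if (length(inc) > 0L) {
      mu[v] <- sum(mu[edges$substrate[inc]] * frac[inc] * trans[inc])
    }
  }
  out <- mu
  for (i in seq_len(n_e)) {
    if (backlog[i] != 1) {
      out[edges$substrate[i]] <- out[edges$substrate[i]] * backlog[i]
    }
  }
  out
}

#' Simulation configuration
#'
#' Collects everything [generate_dataset()] needs. Defaults reproduce the
#' panel design: 7 genotypes x 3 stages x 3 replicates, stage-increasing
#' pathway input, log-normal multiplicative noise (sigma 0.25), LOD 1, and
#' two planted transcript co-expression modules.
#'
#' @param n_replicates replicates per genotype x stage (>= 2).
#' @param genotypes genotype labels (wild types included).
#' @param stages stage labels, in developmental order.
#' @param design a [design_map()].
#' @param catalog a [feature_catalog()].
#' @param map a [pathway_map()].
#' @param mutations named list (genotype -> list of [mutation_spec()]).
#' @param stage_activity named stage -> pathway input flux multiplier.
#' @param base_input flux entering the pathway at multiplier 1.
#' @param noise_sigma sd of log-scale multiplicative noise (>= 0).
#' @param lod detection limit in abundance units (>= 0); noisy values below
#'   it are censored to ND, per replicate.
#' @param satellites data.frame (feature_id, node, ratio) of derived
#'   metabolites.
#' @param metabolite_base matrix (feature x stage) of baseline means for
#'   metabolites outside the flux model.
#' @param transcript_base matrix (gene x stage) of baseline transcript
#'   means; defaults are derived from the catalog.
#' @param transcript_coupling list of planted modules, each
#'   `list(members = feature_ids, rho = loading in (0, 1])`; members share a
#'   per-sample latent factor so their log-scale pairwise Pearson
#'   correlation is `rho`.
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_replicates = 3L,
                              genotypes = c("AC", "M82", "at", "r", "t",
                                            "B", "Del"),
                              stages = c("MG", "Br", "FR"),
                              design = default_design(),
                              catalog = default_feature_catalog(),
                              map = default_pathway_map(),
                              mutations = default_mutation_presets(),
                              stage_activity = c(MG = 1, Br = 2.5, FR = 4),
                              base_input = 100,
                              noise_sigma = 0.25,
                              lod = 1,
                              satellites = default_satellites(),
                              metabolite_base = default_metabolite_base(),
                              transcript_base = NULL,
                              transcript_coupling = default_coupling(),
                              seed = 1L) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (lod < 0) stop("lod must be >= 0", call. = FALSE)
  tx_ids <- catalog$feature_id[catalog$kind == "transcript"]
  bad_gene <- setdiff(unique(map$edges$gene), tx_ids)
  if (length(bad_gene) > 0L) {
    stop("pathway edge gene(s) missing from the transcript catalog: ",
         paste(bad_gene, collapse = ", "), call. = FALSE)
  }
  if (is.null(transcript_base)) {
    transcript_base <- default_transcript_base(catalog, stages)
  }
  for (mod in transcript_coupling) {
    if (mod$rho <= 0 || mod$rho > 1) {
      stop("module loading rho must lie in (0, 1]", call. = FALSE)
    }
    miss <- setdiff(mod$members, catalog$feature_id)
    if (length(miss) > 0L) {
      stop("planted module references unknown feature(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  bad_stage <- setdiff(stages, names(stage_activity))
  if (length(bad_stage) > 0L) {
    stop("stage_activity lacks stage(s): ",
         paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_replicates = as.integer(n_replicates), genotypes = genotypes,
    stages = stages, design = design, catalog = catalog, map = map,
    mutations = mutations, stage_activity = stage_activity,
    base_input = base_input, noise_sigma = noise_sigma, lod = lod,
    satellites = satellites, metabolite_base = metabolite_base,
    transcript_base = transcript_base,
    transcript_coupling = transcript_coupling, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default planted co-expression modules
#' @return List of two modules: the desaturation/isomerization genes
#'   (loading 0.8) and the cyclase/hydroxylase genes (loading 0.75).
#' @export
default_coupling <- function() {
  list(
    list(members = c("PDS", "PTOX", "ZISO", "ZDS", "CrtISO1", "CrtISO2"),
         rho = 0.8),
    list(members = c("LCY-b1", "LCY-b2", "CYC-b", "LCY-e", "LUT5",
                     "CHY1", "CHY2"),
         rho = 0.75)
  )
}

# Baseline transcript means: class-specific stage trend times a fixed
# gene-specific level (deterministic in catalog order).
default_transcript_base <- function(catalog, stages = c("MG", "Br", "FR")) {
  trend <- list(CAR = c(1, 2, 3.5), ABA = c(1, 1.5, 3),
                MEP = c(1, 1.2, 1.5), MVA = c(1, 1, 1),
                CHL = c(1, 0.5, 0.2), TOC = c(1, 1.3, 1.8),
                QUI = c(1, 1, 1.2))
  tx <- catalog[catalog$kind == "transcript", , drop = FALSE]
  base <- matrix(0, nrow = nrow(tx), ncol = length(stages),
                 dimnames = list(tx$feature_id, stages))
  for (i in seq_len(nrow(tx))) {
    lvl <- 60 + 10 * ((i - 1L) %% 9L)
    tr <- trend[[tx$pathway_class[i]]]
    if (is.null(tr)) tr <- rep(1, 3L)
    base[i, ] <- lvl * tr[seq_along(stages)]
  }
  base
}

# Transcriptional response of a mutant: the target gene scales by lambda
# (lof) or gain (gof); a lof additionally triggers a shared compensation
# pattern over the other carotenoid genes (early induction, late
# repression), scaled by severity 1 - lambda. This is what makes mutants
# blocking neighboring steps look alike in profile space.
transcript_modifiers <- function(catalog, mutations) {
  tx <- catalog$feature_id[catalog$kind == "transcript"]
  mod <- stats::setNames(rep(1, length(tx)), tx)
  for (m in mutations) {
    if (m$effect == "lof") {
      sev <- 1 - m$lambda
      pattern <- stats::setNames(rep(0, length(tx)), tx)
      pattern[intersect(car_early_genes, tx)] <- 1
      pattern[intersect(car_late_genes, tx)] <- -0.7
      mod <- mod * 2 ^ (sev * pattern)
      mod[m$target_gene] <- m$lambda
    } else {
      mod[m$target_gene] <- mod[m$target_gene] * m$gain
    }
  }
  mod
}

#' Noiseless transcript means under the mutant panel
#'
#' @param config a [simulation_config()].
#' @param genotypes,stages subsets to simulate (default: all in config).
#' @return List with `means` (a transcript x (genotype, stage) means array
#'   as a named list of matrices per stage) and `modules` (the planted
#'   coupling record).
#' @export
simulate_transcripts <- function(config, genotypes = config$genotypes,
                                 stages = config$stages) {
  catalog <- config$catalog
  tx <- catalog$feature_id[catalog$kind == "transcript"]
  means <- list()
  for (st in stages) {
    m <- matrix(0, nrow = length(tx), ncol = length(genotypes),
                dimnames = list(tx, genotypes))
    for (g in genotypes) {
      muts <- config$mutations[[g]]
      if (is.null(muts)) muts <- list()
      mod <- transcript_modifiers(catalog, muts)
      m[, g] <- config$transcript_base[tx, st] * mod[tx]
    }
    means[[st]] <- m
  }
  list(means = means, modules = config$transcript_coupling)
}

# Noiseless means for every feature x genotype at one stage.
noiseless_means_stage <- function(config, stage) {
  catalog <- config$catalog
  feats <- catalog$feature_id
  genos <- config$genotypes
  out <- matrix(0, nrow = length(feats), ncol = length(genos),
                dimnames = list(feats, genos))
  stage_input <- config$base_input * config$stage_activity[[stage]]
  tx_means <- simulate_transcripts(config, genos, stage)$means[[stage]]
  for (g in genos) {
    muts <- config$mutations[[g]]
    if (is.null(muts)) muts <- list()
    node_mu <- propagate_flux(config$map, muts, stage_input)
    out[names(node_mu), g] <- node_mu
    if (nrow(config$satellites) > 0L) {
      out[config$satellites$feature_id, g] <-
        node_mu[config$satellites$node] * config$satellites$ratio
    }
    mb <- config$metabolite_base
    if (!is.null(mb) && nrow(mb) > 0L) {
      out[rownames(mb), g] <- mb[, stage]
    }
    out[rownames(tx_means), g] <- tx_means[, g]
  }
  out
}

#' Generate a synthetic replicate-level dataset with ground truth
#'
#' Each replicate value is its noiseless mean times `exp(sigma * z)` where
#' `z` is standard normal on the log scale; members of a planted module with
#' loading `rho` share a per-sample latent factor,
#' `z = sqrt(rho) * F + sqrt(1 - rho) * eps`, so their pairwise log-scale
#' Pearson correlation equals `rho`. Values below the LOD are censored to
#' ND after noise, per replicate. Identical config + seed gives bit-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return List with `table` (an [abundance_table()]) and `truth` (class
#'   `synthetic_truth`: `expected_means` feature x genotype x stage array,
#'   `planted_modules`, `planted_genotype_pairs`, `mutation_specs`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  catalog <- config$catalog
  samples <- default_sample_metadata(config$n_replicates, config$genotypes,
                                     config$stages, config$design)
  feats <- catalog$feature_id
  n_f <- length(feats)
  n_s <- nrow(samples)
  expected <- array(
    0, dim = c(n_f, length(config$genotypes), length(config$stages)),
    dimnames = list(feats, config$genotypes, config$stages))
  for (st in config$stages) {
    expected[, , st] <- noiseless_means_stage(config, st)
  }
  member_of <- rep(NA_integer_, n_f)
  names(member_of) <- feats
  for (k in seq_along(config$transcript_coupling)) {
    member_of[config$transcript_coupling[[k]]$members] <- k
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  n_mod <- length(config$transcript_coupling)
  latent <- if (n_mod > 0L) {
    matrix(stats::rnorm(n_mod * n_s), nrow = n_mod, ncol = n_s)
  } else {
    matrix(0, nrow = 0L, ncol = n_s)
  }
  eps <- matrix(stats::rnorm(n_f * n_s), nrow = n_f, ncol = n_s)
  z <- eps
  for (i in seq_len(n_f)) {
    k <- member_of[i]
    if (!is.na(k)) {
      rho <- config$transcript_coupling[[k]]$rho
      z[i, ] <- sqrt(rho) * latent[k, ] + sqrt(1 - rho) * eps[i, ]
    }
  }
  mean_mat <- matrix(0, nrow = n_f, ncol = n_s,
                     dimnames = list(feats, samples$sample_id))
  for (j in seq_len(n_s)) {
    mean_mat[, j] <- expected[, samples$genotype[j], samples$stage[j]]
  }
  values <- mean_mat * exp(config$noise_sigma * z)
  detected <- values >= config$lod
  # lod = 0 keeps exact zeros detected (a measured zero is not ND)
  if (config$lod == 0) detected <- values >= 0
  values[!detected] <- NA_real_
  tab <- abundance_table(values, detected, catalog, samples)
  truth <- structure(list(
    expected_means = expected,
    planted_modules = config$transcript_coupling,
    planted_genotype_pairs = planted_pairs(config),
    mutation_specs = config$mutations
  ), class = "synthetic_truth")
  list(table = tab, truth = truth)
}

# Genotype pairs implied by shared effects: same effect class on
# chain-adjacent pathway steps (the product of one mutated edge is the
# substrate of the other).
planted_pairs <- function(config) {
  genos <- names(config$mutations)
  specs <- lapply(genos, function(g) config$mutations[[g]])
  pairs <- list()
  edge_of <- function(gene) {
    which(config$map$edges$gene == gene)
  }
  if (length(genos) < 2L) return(pairs)
  for (i in seq_len(length(genos) - 1L)) {
    for (j in seq(i + 1L, length(genos))) {
      for (mi in specs[[i]]) for (mj in specs[[j]]) {
        if (mi$effect != mj$effect) next
        ei <- edge_of(mi$target_gene)
        ej <- edge_of(mj$target_gene)
        if (length(ei) == 0L || length(ej) == 0L) next
        adj <- any(outer(
          config$map$edges$product[ei], config$map$edges$substrate[ej],
          "==")) ||
          any(outer(config$map$edges$product[ej],
                    config$map$edges$substrate[ei], "=="))
        if (adj) pairs[[length(pairs) + 1L]] <- c(genos[i], genos[j])
      }
    }
  }
  unique(pairs)
}

#' Write a generated dataset to an output directory
#'
#' Emits abundance.tsv, samples.tsv, features.tsv, pathway_map.json and
#' truth.json (expected means flattened to records).
#'
#' @param dataset result of [generate_dataset()].
#' @param config the [simulation_config()] used.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_table(dataset$table, file.path(dir, "abundance.tsv"))
  write_sample_metadata(dataset$table$samples, file.path(dir, "samples.tsv"))
  write_feature_catalog(dataset$table$features,
                        file.path(dir, "features.tsv"))
  write_pathway_map(config$map, file.path(dir, "pathway_map.json"))
  em <- dataset$truth$expected_means
  truth <- list(
    planted_modules = dataset$truth$planted_modules,
    planted_genotype_pairs = dataset$truth$planted_genotype_pairs,
    expected_means = lapply(dimnames(em)[[3L]], function(st) {
      list(stage = st,
           means = as.data.frame(em[, , st]))
    })
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
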