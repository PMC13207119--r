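# Default catalogs for the tomato carotenoid mutant panel: 44 carotenoid
# metabolites (15 pathway nodes + 29 satellite isomers/derivatives), the
# ABA/CHL/TOC/QUI metabolite panels, 22 carotenoid transcripts and the
# MEP/MVA/ABA/CHL/TOC/QUI transcript panels. Everything is generated in code;
# there is no bundled data file.

car_early_genes <- c("IDI1", "PSY1", "PSY2", "PSY3", "PDS", "PTOX",
                     "ZISO", "ZDS", "CrtISO1", "CrtISO2")
car_late_genes <- c("LCY-b1", "LCY-b2", "CYC-b", "LCY-e", "LUT5",
                    "CHY1", "CHY2", "ZEP", "VDE", "NXS", "CCD1a", "CCD4")

#' Default pathway map of carotenoid biosynthesis
#'
#' Linear desaturation/isomerization core from IPP to all-trans lycopene,
#' then the epsilon-beta branch (delta-carotene, alpha-carotene, lutein) and
#' the beta-beta branch (gamma-carotene, beta-carotene, xanthophylls) with an
#' ABA offtake from violaxanthin. Multistep reactions are collapsed to one
#' gene-labeled edge each; the lycopene cyclization split defaults to
#' 0.4 (epsilon) / 0.6 (beta) and the violaxanthin split to
#' 0.7 (neoxanthin) / 0.3 (ABA).
#'
#' @return A [pathway_map()].
#' @export
default_pathway_map <- function() {
  edges <- data.frame(
    substrate = c("IPP", "GGPP", "phytoene", "phytofluene", "zeta-carotene",
                  "neurosporene", "prolycopene", "trans-lycopene",
                  "trans-lycopene", "delta-carotene", "alpha-carotene",
                  "gamma-carotene", "beta-carotene", "zeaxanthin",
                  "antheraxanthin", "violaxanthin", "violaxanthin"),
    product = c("GGPP", "phytoene", "phytofluene", "zeta-carotene",
                "neurosporene", "prolycopene", "trans-lycopene",
                "delta-carotene", "gamma-carotene", "alpha-carotene",
                "lutein", "beta-carotene", "zeaxanthin", "antheraxanthin",
                "violaxanthin", "neoxanthin", "ABA"),
    gene = c("IDI1", "PSY1", "PDS", "ZISO", "ZDS", "CrtISO2", "CrtISO1",
             "LCY-e", "CYC-b", "LCY-b1", "LUT5", "LCY-b2", "CHY1", "ZEP",
             "ZEP", "NXS", "NCED"),
    stringsAsFactors = FALSE
  )
  nodes <- unique(c(edges$substrate, edges$product))
  pathway_map(
    nodes, edges,
    branch_fractions = list(
      "trans-lycopene" = c("delta-carotene" = 0.4, "gamma-carotene" = 0.6),
      "violaxanthin" = c("neoxanthin" = 0.7, "ABA" = 0.3)
    )
  )
}

#' Satellite metabolites derived from pathway nodes
#'
#' Isomers, epoxides and apocarotenoid derivatives whose noiseless mean is a
#' fixed fraction of a pathway node's mean; they pad the carotenoid panel to
#' the 44 compounds a targeted LC-MS screen resolves while inheriting the
#' mutant flux signature of their parent node.
#'
#' @return data.frame with columns feature_id, node, ratio.
#' @export
default_satellites <- function() {
  sat <- rbind(
    c("9-cis-phytoene", "phytoene", 0.25),
    c("phytoene-1-2-epoxide", "phytoene", 0.05),
    c("13-cis-phytofluene", "phytofluene", 0.30),
    c("9-15-di-cis-zeta-carotene", "zeta-carotene", 0.25),
    c("9-cis-zeta-carotene", "zeta-carotene", 0.10),
    c("7-9-di-cis-neurosporene", "neurosporene", 0.30),
    c("beta-zeacarotene", "neurosporene", 0.05),
    c("alpha-zeacarotene", "neurosporene", 0.04),
    c("5-cis-lycopene", "trans-lycopene", 0.15),
    c("9-cis-lycopene", "trans-lycopene", 0.08),
    c("13-cis-lycopene", "trans-lycopene", 0.05),
    c("15-cis-lycopene", "trans-lycopene", 0.03),
    c("apo-6-lycopenal", "trans-lycopene", 0.02),
    c("apo-8-lycopenal", "trans-lycopene", 0.02),
    c("cis-delta-carotene", "delta-carotene", 0.20),
    c("zeinoxanthin", "alpha-carotene", 0.10),
    c("lutein-5-6-epoxide", "lutein", 0.08),
    c("cis-gamma-carotene", "gamma-carotene", 0.20),
    c("beta-carotene-5-6-epoxide", "beta-carotene", 0.05),
    c("beta-cryptoxanthin", "beta-carotene", 0.10),
    c("beta-apo-8-carotenal", "beta-carotene", 0.02),
    c("cis-antheraxanthin", "antheraxanthin", 0.15),
    c("mutatoxanthin", "antheraxanthin", 0.05),
    c("luteoxanthin", "violaxanthin", 0.15),
    c("cis-violaxanthin", "violaxanthin", 0.20),
    c("auroxanthin", "violaxanthin", 0.05),
    c("violeoxanthin", "violaxanthin", 0.08),
    c("cis-neoxanthin", "neoxanthin", 0.25),
    c("neochrome", "neoxanthin", 0.10),
    c("ABA-glucose-ester", "ABA", 0.30),
    c("phaseic-acid", "ABA", 0.40),
    c("dihydrophaseic-acid", "ABA", 0.25)
  )
  data.frame(feature_id = sat[, 1L], node = sat[, 2L],
             ratio = as.numeric(sat[, 3L]), stringsAsFactors = FALSE)
}

# Baseline means per stage for metabolites outside the flux model.
# Chlorophylls decline through ripening (undetectable at FR under the
# default LOD of 1); tocochromanols rise moderately.
default_metabolite_base <- function() {
  b <- rbind(
    "chlorophyll-a" = c(60, 15, 0.4),
    "chlorophyll-b" = c(25, 6, 0.2),
    "pheophytin-a" = c(8, 3, 0.3),
    "alpha-tocopherol" = c(20, 35, 60),
    "beta-tocopherol" = c(2, 2.5, 3),
    "gamma-tocopherol" = c(8, 12, 18),
    "delta-tocopherol" = c(1.5, 2, 2.5),
    "phylloquinone" = c(5, 4, 3),
    "plastoquinone-9" = c(30, 20, 12),
    "ubiquinone-9" = c(3, 4, 5),
    "ubiquinone-10" = c(6, 8, 10)
  )
  colnames(b) <- c("MG", "Br", "FR")
  b
}

base_feature_class <- function() {
  c("chlorophyll-a" = "CHL", "chlorophyll-b" = "CHL", "pheophytin-a" = "CHL",
    "alpha-tocopherol" = "TOC", "beta-tocopherol" = "TOC",
    "gamma-tocopherol" = "TOC", "delta-tocopherol" = "TOC",
    "phylloquinone" = "QUI", "plastoquinone-9" = "QUI",
    "ubiquinone-9" = "QUI", "ubiquinone-10" = "QUI")
}

panel_transcripts <- function() {
  c("DXS-1" = "MEP", "DXS-2" = "MEP", "DXR" = "MEP",
    "GGPS-2" = "MEP", "GGPS-3" = "MEP",
    "AACT-2" = "MVA", "HMGR-1" = "MVA", "HMGR-2" = "MVA", "FPS" = "MVA",
    "NCED" = "ABA", "AAO3" = "ABA", "PYL1" = "ABA", "PP2C-1" = "ABA",
    "SnRK2" = "ABA",
    "CHLG" = "CHL", "CAO" = "CHL",
    "VTE1" = "TOC", "VTE4" = "TOC",
    "MENG" = "QUI", "SPS1" = "QUI")
}

#' Default feature catalog for the mutant panel
#'
#' 61 metabolites (44 carotenoids, 4 ABA-related, 3 chlorophylls,
#' 4 tocochromanols, 4 quinones, IPP and GGPP precursors) and 42 transcripts
#' (the 22 carotenoid genes plus MEP/MVA/ABA/CHL/TOC/QUI panels). Pathway
#' nodes and the genes catalyzing them carry branch/step annotations used for
#' heatmap-table ordering.
#'
#' @return A [feature_catalog()].
#' @export
default_feature_catalog <- function() {
  map <- default_pathway_map()
  # branch/step along the map: core chain, then each cyclization branch
  branch_of <- c(
    IPP = "core", GGPP = "core", phytoene = "core", phytofluene = "core",
    "zeta-carotene" = "core", neurosporene = "core", prolycopene = "core",
    "trans-lycopene" = "core",
    "delta-carotene" = "eps", "alpha-carotene" = "eps", lutein = "eps",
    "gamma-carotene" = "beta", "beta-carotene" = "beta", zeaxanthin = "beta",
    antheraxanthin = "beta", violaxanthin = "beta", neoxanthin = "beta",
    ABA = "aba"
  )
  step_of <- c(
    IPP = 0L, GGPP = 1L, phytoene = 2L, phytofluene = 3L,
    "zeta-carotene" = 4L, neurosporene = 5L, prolycopene = 6L,
    "trans-lycopene" = 7L,
    "delta-carotene" = 0L, "alpha-carotene" = 1L, lutein = 2L,
    "gamma-carotene" = 0L, "beta-carotene" = 1L, zeaxanthin = 2L,
    antheraxanthin = 3L, violaxanthin = 4L, neoxanthin = 5L,
    ABA = 0L
  )
  class_of_node <- function(n) {
    if (n %in% c("IPP", "GGPP")) "MEP" else if (n == "ABA") "ABA" else "CAR"
  }
  node_rows <- data.frame(
    feature_id = map$nodes,
    display_name = map$nodes,
    kind = "metabolite",
    pathway_class = vapply(map$nodes, class_of_node, ""),
    branch_id = unname(branch_of[map$nodes]),
    step_index = unname(step_of[map$nodes]),
    stringsAsFactors = FALSE
  )
  sat <- default_satellites()
  sat_class <- ifelse(sat$node == "ABA", "ABA", "CAR")
  sat_rows <- data.frame(
    feature_id = sat$feature_id, display_name = sat$feature_id,
    kind = "metabolite", pathway_class = sat_class,
    branch_id = unname(branch_of[sat$node]),
    step_index = unname(step_of[sat$node]),
    stringsAsFactors = FALSE
  )
  base_cls <- base_feature_class()
  base_rows <- data.frame(
    feature_id = names(base_cls), display_name = names(base_cls),
    kind = "metabolite", pathway_class = unname(base_cls),
    branch_id = NA_character_, step_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  car_genes <- c(car_early_genes, car_late_genes)
  # genes inherit the branch/step of the edge product they catalyze
  gene_edge <- match(car_genes, map$edges$gene)
  gene_branch <- ifelse(is.na(gene_edge), NA_character_,
                        branch_of[map$edges$product[gene_edge]])
  gene_step <- ifelse(is.na(gene_edge), NA_integer_,
                      step_of[map$edges$product[gene_edge]])
  car_tx_rows <- data.frame(
    feature_id = car_genes, display_name = car_genes,
    kind = "transcript", pathway_class = "CAR",
    branch_id = unname(gene_branch), step_index = as.integer(gene_step),
    stringsAsFactors = FALSE
  )
  panel <- panel_transcripts()
  panel_rows <- data.frame(
    feature_id = names(panel), display_name = names(panel),
    kind = "transcript", pathway_class = unname(panel),
    branch_id = NA_character_, step_index = NA_integer_,
    stringsAsFactors = FALSE
  )
  x <- rbind(node_rows, sat_rows, base_rows, car_tx_rows, panel_rows)
  feature_catalog(x$feature_id, x$display_name, x$kind, x$pathway_class,
                  x$branch_id, x$step_index)
}

#' Default sample layout: 7 genotypes x 3 stages x n replicates
#'
#' @param n_replicates biological replicates per genotype and stage
#'   (default 3, the panel minimum).
#' @param genotypes genotype labels.
#' @param stages stage labels.
#' @param design a [design_map()] used to assign backgrounds.
#' @return A [sample_metadata()].
#' @export
default_sample_metadata <- function(n_replicates = 3L,
                                    genotypes = c("AC", "M82", "at", "r",
                                                  "t", "B", "Del"),
                                    stages = c("MG", "Br", "FR"),
                                    design = default_design()) {
  wt_set <- unique(design$mutant_to_wildtype)
  grid <- expand.grid(replicate = seq_len(n_replicates), stage = stages,
                      genotype = genotypes, stringsAsFactors = FALSE)
  background <- ifelse(grid$genotype %in% wt_set, grid$genotype,
                       design$mutant_to_wildtype[grid$genotype])
  sample_metadata(
    sample_id = sprintf("%s_%s_%d", grid$genotype, grid$stage,
                        grid$replicate),
    genotype = grid$genotype, background = background,
    stage = grid$stage, replicate = grid$replicate
  )
}

#' Mutated genes of the default panel, keyed by mutant genotype
#' @return Named character vector (at = IDI1, r = PSY1, t = CrtISO1,
#'   B = CYC-b, Del = LCY-e).
#' @export
default_hub_genes <- function() {
  c(at = "IDI1", r = "PSY1", t = "CrtISO1", B = "CYC-b", Del = "LCY-e")
}
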