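#' Run configuration for the end-to-end pipeline
#'
#' One flat configuration drives simulate -> differential -> clustering ->
#' correlation -> hub networks. Either `input_dir` (a directory holding
#' abundance.tsv, samples.tsv, features.tsv as written by [write_dataset()])
#' or a simulation is used as input.
#'
#' @param input_dir optional directory of input tables; when `NULL` the
#'   synthetic generator provides the data.
#' @param sim a [simulation_config()] (used when `input_dir` is `NULL`;
#'   also supplies catalog/design defaults).
#' @param stages stages to process (nonempty).
#' @param hub_genes named character vector mutant -> hub transcript
#'   feature_id; every hub must exist in the transcript catalog.
#' @param tau hub-network threshold (default 0.88).
#' @param correlation_features optional feature subset for the correlation
#'   matrices (e.g. carotenoid panel only); `NULL` = all features.
#' @param min_pairs minimum shared samples per correlation pair.
#' @param on_log_scale statistics on log2 values (default `TRUE`).
#' @param clustering_mode `"log2fc"` or `"zscore"`.
#' @param linkage clustering linkage.
#' @param include_neighbor_edges forwarded to [hub_network()].
#' @param seed integer seed for the simulation.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL,
                       sim = simulation_config(seed = seed),
                       stages = c("MG", "Br", "FR"),
                       hub_genes = default_hub_genes(),
                       tau = 0.88,
                       correlation_features = NULL,
                       min_pairs = 4L,
                       on_log_scale = TRUE,
                       clustering_mode = "log2fc",
                       linkage = "average",
                       include_neighbor_edges = FALSE,
                       seed = 1L) {
  if (length(stages) == 0L) stop("stages must be nonempty", call. = FALSE)
  tx <- sim$catalog$feature_id[sim$catalog$kind == "transcript"]
  bad <- setdiff(hub_genes, tx)
  if (length(bad) > 0L) {
    stop("hub gene(s) absent from the transcript catalog: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(input_dir = input_dir, sim = sim, stages = stages,
                 hub_genes = hub_genes, tau = tau,
                 correlation_features = correlation_features,
                 min_pairs = as.integer(min_pairs),
                 on_log_scale = on_log_scale,
                 clustering_mode = clustering_mode, linkage = linkage,
                 include_neighbor_edges = include_neighbor_edges,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Execute the full pipeline into an output directory
#'
#' Deterministic layout: `input/` (the tables used), `differential/`
#' (per-stage heatmap TSVs), `clustering/` (per-stage Newick + merge TSV),
#' `correlation/` (per-stage matrix + pair TSVs), `networks/` (per hub x
#' stage GraphML + edge TSV, plus summary and trajectory TSVs),
#' `provenance.json` and `run.log`. Identical config + inputs + seed give
#' identical outputs (timestamps only in the log and provenance).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; must be empty or absent).
#' @return `out_dir`, invisibly.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf("[%s] ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  fail <- function(stage_name, e) {
    log_line("FAILED at stage %s: %s", stage_name, conditionMessage(e))
    stop("pipeline stage '", stage_name, "' failed: ",
         conditionMessage(e), call. = FALSE)
  }
  # -- input ---------------------------------------------------------------
  design <- config$sim$design
  catalog <- config$sim$catalog
  tab <- tryCatch({
    if (is.null(config$input_dir)) {
      log_line("simulate: seed %d", config$seed)
      sim_cfg <- config$sim
      sim_cfg$seed <- config$seed
      ds <- generate_dataset(sim_cfg)
      write_dataset(ds, sim_cfg, file.path(out_dir, "input"))
      ds$table
    } else {
      log_line("load: %s", config$input_dir)
      feats <- read_feature_catalog(
        file.path(config$input_dir, "features.tsv"))
      samps <- read_sample_metadata(
        file.path(config$input_dir, "samples.tsv"))
      catalog <- feats
      read_abundance_table(file.path(config$input_dir, "abundance.tsv"),
                           feats, samps)
    }
  }, error = function(e) fail("input", e))
  log_line("input: %d features x %d samples, %d ND cells",
           nrow(tab$values), ncol(tab$values), sum(!tab$detected))
  # -- differential --------------------------------------------------------
  dir.create(file.path(out_dir, "differential"), showWarnings = FALSE)
  tryCatch({
    for (st in config$stages) {
      res <- differential_table(tab, design, stages = st,
                                on_log_scale = config$on_log_scale)
      export_heatmap_table(
        res, catalog,
        path = file.path(out_dir, "differential",
                         sprintf("heatmap_%s.tsv", st)))
      log_line("differential %s: %d rows, %d ND cells", st, nrow(res),
               sum(is.na(res$log2fc)))
    }
  }, error = function(e) fail("differential", e))
  # -- clustering ----------------------------------------------------------
  dir.create(file.path(out_dir, "clustering"), showWarnings = FALSE)
  tryCatch({
    for (st in config$stages) {
      prof <- build_profiles(tab, design, st, mode = config$clustering_mode)
      dend <- hcl_cluster(prof, linkage = config$linkage)
      export_dendrogram(
        dend,
        newick_path = file.path(out_dir, "clustering",
                                sprintf("dendrogram_%s.nwk", st)),
        merges_path = file.path(out_dir, "clustering",
                                sprintf("merges_%s.tsv", st)))
      log_line("clustering %s: %d leaves", st, length(dend$labels))
    }
  }, error = function(e) fail("clustering", e))
  # -- correlation + networks ----------------------------------------------
  dir.create(file.path(out_dir, "correlation"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "networks"), showWarnings = FALSE)
  summaries <- list()
  tryCatch({
    for (st in config$stages) {
      cm <- pearson_matrix(tab, st, features = config$correlation_features,
                           on_log_scale = config$on_log_scale,
                           min_pairs = config$min_pairs)
      write_correlation_matrix(
        cm,
        file.path(out_dir, "correlation", sprintf("pearson_%s.tsv", st)),
        file.path(out_dir, "correlation", sprintf("pairs_%s.tsv", st)))
      log_line("correlation %s: %d features, %d undefined cells", st,
               length(cm$features), sum(is.na(cm$r)))
      for (mut in names(config$hub_genes)) {
        hub <- config$hub_genes[[mut]]
        net <- suppressWarnings(hub_network(
          cm, hub, tau = config$tau,
          include_neighbor_edges = config$include_neighbor_edges))
        base <- sprintf("%s_%s_%s", mut, hub, st)
        export_network(
          net, catalog,
          graphml_path = file.path(out_dir, "networks",
                                   paste0(base, ".graphml")),
          edges_path = file.path(out_dir, "networks",
                                 paste0(base, "_edges.tsv")))
        summaries[[length(summaries) + 1L]] <- network_summary(net)
        log_line("network %s @ %s: %d edges", hub, st,
                 nrow(net$edges))
      }
    }
  }, error = function(e) fail("correlation_networks", e))
  traj <- summarize_trajectories(summaries, stage_order = config$stages)
  utils::write.table(traj, file.path(out_dir, "networks",
                                     "trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # -- provenance ----------------------------------------------------------
  prov <- list(
    package_version = as.character(utils::packageVersion("ripenet")),
    seed = config$seed,
    stages = config$stages,
    tau = config$tau,
    hub_genes = as.list(config$hub_genes),
    min_pairs = config$min_pairs,
    on_log_scale = config$on_log_scale,
    clustering = list(mode = config$clustering_mode,
                      distance = "one_minus_pearson",
                      linkage = config$linkage),
    input = if (is.null(config$input_dir)) "simulated" else config$input_dir,
    input_digests = input_digests(out_dir, config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("done")
  invisible(out_dir)
}

input_digests <- function(out_dir, config) {
  dir <- if (is.null(config$input_dir)) file.path(out_dir, "input")
  else config$input_dir
  files <- list.files(dir, full.names = TRUE)
  as.list(stats::setNames(vapply(files, function(f)
    unname(tools::md5sum(f)), ""), basename(files)))
}

#' Per-hub connectivity trajectories across stages
#'
#' Tabulates edge counts, sign balance and hub node strength per stage and
#' the stage-to-stage deltas, labeling each hub's trajectory "expanding"
#' (never shrinking, net growth), "contracting" (never growing, net loss),
#' "stable" (no change) or "rewired" (mixed). Labels are descriptive delta
#' signs, not inference.
#'
#' @param summaries list of [network_summary()] objects (>= 2 stages per
#'   hub to get deltas).
#' @param stage_order stage ordering for the deltas.
#' @return data.frame with one row per hub x stage.
#' @export
summarize_trajectories <- function(summaries,
                                   stage_order = c("MG", "Br", "FR")) {
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(hub = s$hub, stage = s$stage, n_edges = s$n_edges,
               n_positive = s$n_positive, n_negative = s$n_negative,
               mean_abs_r = s$mean_abs_r, ns_hub = s$ns_hub,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(df$hub, match(df$stage, stage_order)), , drop = FALSE]
  df$delta_edges <- NA_integer_
  df$trajectory <- NA_character_
  for (h in unique(df$hub)) {
    i <- which(df$hub == h)
    if (length(i) >= 2L) {
      d <- diff(df$n_edges[i])
      df$delta_edges[i[-1L]] <- d
      lab <- if (all(d == 0)) "stable"
      else if (all(d >= 0)) "expanding"
      else if (all(d <= 0)) "contracting"
      else "rewired"
      df$trajectory[i] <- lab
    }
  }
  rownames(df) <- NULL
  df
}
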