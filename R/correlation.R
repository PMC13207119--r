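#' Stage-specific pairwise-complete Pearson correlation matrix
#'
#' Computes Pearson's r between every feature pair over the stage's samples,
#' using for each pair only the samples where both features are detected
#' (ND cells are excluded pairwise, never imputed). On the default log scale
#' nonpositive values are unusable and treated like ND. A cell is undefined
#' (`NA`) when fewer than `min_pairs` samples remain or either variable is
#' constant on the shared samples.
#'
#' @param tab an [abundance_table()].
#' @param stage stage label.
#' @param features feature subset (default: all).
#' @param sample_unit `"replicate"` (default) or `"genotype_mean"`
#'   (replicates collapsed to detected-replicate genotype means first).
#' @param on_log_scale correlate log2 values (default `TRUE`).
#' @param min_pairs minimum shared samples per pair (default 4, >= 3
#'   enforced).
#' @return Object of class `correlation_matrix`: `r`, `n_pairs`,
#'   `features`, `stage`.
#' @export
pearson_matrix <- function(tab, stage, features = NULL,
                           sample_unit = c("replicate", "genotype_mean"),
                           on_log_scale = TRUE, min_pairs = 4L) {
  sample_unit <- match.arg(sample_unit)
  if (min_pairs < 3L) stop("min_pairs must be >= 3", call. = FALSE)
  if (is.null(features)) features <- tab$features$feature_id
  miss <- setdiff(features, tab$features$feature_id)
  if (length(miss) > 0L) {
    stop("feature(s) absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sel <- tab$samples$stage == stage
  if (sum(sel) < min_pairs) {
    stop(sprintf("only %d samples at stage '%s' (< min_pairs = %d)",
                 sum(sel), stage, min_pairs), call. = FALSE)
  }
  fi <- match(features, tab$features$feature_id)
  x <- tab$values[fi, sel, drop = FALSE]
  det <- tab$detected[fi, sel, drop = FALSE]
  if (sample_unit == "genotype_mean") {
    genos <- unique(tab$samples$genotype[sel])
    gm <- matrix(NA_real_, nrow = nrow(x), ncol = length(genos),
                 dimnames = list(features, genos))
    for (g in genos) {
      cols <- tab$samples$genotype[sel] == g
      for (i in seq_len(nrow(x))) {
        v <- x[i, cols][det[i, cols]]
        if (length(v) > 0L) gm[i, g] <- mean(v)
      }
    }
    x <- gm
    det <- !is.na(gm)
  }
  if (on_log_scale) {
    usable <- det & !is.na(x) & x > 0
    x[usable] <- log2(x[usable])
  } else {
    usable <- det
  }
  x[!usable] <- NA_real_
  r_and_n <- masked_pearson(x, usable, min_pairs)
  structure(list(r = r_and_n$r, n_pairs = r_and_n$n, features = features,
                 stage = stage),
            class = "correlation_matrix")
}

# Masked Pearson via moment matrices: r_ij from pairwise-complete sums.
# Rows are pre-centered by their observed mean (r is shift-invariant) to
# keep the moment formula numerically close to a two-pass computation.
masked_pearson <- function(x, mask, min_pairs) {
  m <- mask * 1
  x0 <- x
  ctr <- rowMeans(x, na.rm = TRUE)
  ctr[!is.finite(ctr)] <- 0
  x0 <- x0 - ctr
  x0[!mask] <- 0
  n <- m %*% t(m)
  sx <- x0 %*% t(m)        # sum of x_i over shared samples with j
  sxx <- (x0 ^ 2) %*% t(m)
  sxy <- x0 %*% t(x0)
  cov_n <- n * sxy - sx * t(sx)
  var_i <- n * sxx - sx ^ 2
  var_j <- t(var_i)
  denom <- var_i * var_j
  r <- matrix(NA_real_, nrow(x), nrow(x), dimnames = dimnames(n))
  ok <- n >= min_pairs & denom > 0
  r[ok] <- cov_n[ok] / sqrt(denom[ok])
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r)[diag(n) >= min_pairs & diag(var_i) > 0] <- 1
  list(r = r, n = n)
}

#' Hub-centered thresholded correlation network
#'
#' The star network around one mutated gene's transcript: every feature
#' whose correlation with the hub is defined and has `|r| >= tau` becomes a
#' partner (the panel's threshold 0.88 is the default). Node strength is
#' the weighted degree, the sum of `|r|` over a node's retained edges.
#' Optionally, edges among retained partners passing the same threshold can
#' be added; they are never added silently.
#'
#' @param cm a [pearson_matrix()] result.
#' @param hub hub feature_id (must be in the matrix).
#' @param tau threshold in \[0, 1\] (default 0.88).
#' @param include_neighbor_edges add partner-partner edges (default
#'   `FALSE`).
#' @return Object of class `hub_network`: `hub`, `stage`, `tau`, `edges`
#'   (data.frame from, to, r), `node_strength`, `status` ("ok" or
#'   "empty_hub_row").
#' @export
hub_network <- function(cm, hub, tau = 0.88,
                        include_neighbor_edges = FALSE) {
  if (!hub %in% cm$features) {
    stop("hub '", hub, "' absent from the correlation matrix",
         call. = FALSE)
  }
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  row <- cm$r[hub, ]
  row <- row[names(row) != hub]
  status <- "ok"
  if (all(is.na(row))) {
    status <- "empty_hub_row"
    warning("hub '", hub, "' has no defined correlations", call. = FALSE)
  }
  keep <- !is.na(row) & abs(row) >= tau
  partners <- names(row)[keep]
  edges <- data.frame(from = rep(hub, sum(keep)), to = partners,
                      r = unname(row[keep]), stringsAsFactors = FALSE)
  if (include_neighbor_edges && length(partners) > 1L) {
    for (i in seq_len(length(partners) - 1L)) {
      for (j in seq(i + 1L, length(partners))) {
        rij <- cm$r[partners[i], partners[j]]
        if (!is.na(rij) && abs(rij) >= tau) {
          edges <- rbind(edges, data.frame(
            from = partners[i], to = partners[j], r = unname(rij),
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  nodes <- unique(c(hub, edges$from, edges$to))
  ns <- stats::setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    ns[edges$from[k]] <- ns[edges$from[k]] + abs(edges$r[k])
    ns[edges$to[k]] <- ns[edges$to[k]] + abs(edges$r[k])
  }
  structure(list(hub = hub, stage = cm$stage, tau = tau, edges = edges,
                 node_strength = ns, status = status),
            class = "hub_network")
}

#' Summarize a hub network
#'
#' @param net a [hub_network()].
#' @return List of class `network_summary`: hub, stage, n_edges,
#'   n_positive, n_negative, mean_abs_r (`NA` when empty), ns_hub.
#' @export
network_summary <- function(net) {
  n_edges <- nrow(net$edges)
  structure(list(
    hub = net$hub, stage = net$stage, n_edges = n_edges,
    n_positive = sum(net$edges$r > 0),
    n_negative = sum(net$edges$r < 0),
    mean_abs_r = if (n_edges > 0L) mean(abs(net$edges$r)) else NA_real_,
    ns_hub = unname(net$node_strength[net$hub])
  ), class = "network_summary")
}

#' Export a hub network as GraphML and/or an edge TSV
#'
#' GraphML carries node attributes (kind, pathway_class, ns) and edge
#' attributes (r, sign, abs_r); the edge TSV carries the same columns in
#' long form. Both round-trip: see [read_network_graphml()].
#'
#' @param net a [hub_network()].
#' @param catalog a [feature_catalog()] supplying node annotations.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return The igraph object, invisibly.
#' @export
export_network <- function(net, catalog, graphml_path = NULL,
                           edges_path = NULL) {
  nodes <- unique(c(net$hub, net$edges$from, net$edges$to))
  idx <- match(nodes, catalog$feature_id)
  vert <- data.frame(
    name = nodes,
    kind = ifelse(is.na(idx), "unknown", catalog$kind[idx]),
    pathway_class = ifelse(is.na(idx), "unknown",
                           catalog$pathway_class[idx]),
    ns = unname(net$node_strength[nodes]),
    is_hub = nodes == net$hub,
    stringsAsFactors = FALSE
  )
  ed <- net$edges
  if (nrow(ed) > 0L) {
    ed$sign <- ifelse(ed$r > 0, "positive", "negative")
    ed$abs_r <- abs(ed$r)
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     r = numeric(0), sign = character(0),
                     abs_r = numeric(0))
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    meta <- data.frame(hub = rep(net$hub, nrow(ed)),
                       stage = rep(net$stage, nrow(ed)),
                       tau = rep(net$tau, nrow(ed)))
    utils::write.table(
      cbind(meta, ed),
      edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(g)
}

#' Re-read an exported GraphML network
#'
#' @param path GraphML path.
#' @return List with `edges` (from, to, r) and `node_strength`, comparable
#'   to the in-memory [hub_network()] fields.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vt <- igraph::as_data_frame(g, what = "vertices")
  list(edges = ed[, c("from", "to", "r")],
       node_strength = stats::setNames(vt$ns, vt$name),
       hub = vt$name[vt$is_hub])
}

#' Write a correlation matrix as TSV (wide and long form)
#'
#' @param cm a [pearson_matrix()] result.
#' @param matrix_path wide TSV (features x features, `NA` = undefined).
#' @param pairs_path optional long TSV (feature_a, feature_b, r, n_pairs).
#' @export
write_correlation_matrix <- function(cm, matrix_path, pairs_path = NULL) {
  wide <- data.frame(feature_id = cm$features, cm$r, check.names = FALSE)
  utils::write.table(wide, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pairs_path)) {
    n <- length(cm$features)
    ut <- which(upper.tri(cm$r), arr.ind = TRUE)
    long <- data.frame(
      feature_a = cm$features[ut[, 1L]],
      feature_b = cm$features[ut[, 2L]],
      r = cm$r[ut],
      n_pairs = cm$n_pairs[ut]
    )
    utils::write.table(long, pairs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_path)
}
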