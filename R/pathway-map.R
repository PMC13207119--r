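#' Pathway map: a gene-labeled reaction DAG over metabolites
#'
#' Nodes are metabolite feature_ids; each directed edge (substrate -> product)
#' is catalyzed by one transcript feature_id. At a branching substrate, the
#' declared `branch_fractions` split the outgoing flux and must sum to 1;
#' nodes with a single outgoing edge default to fraction 1.
#'
#' @param nodes character vector of metabolite feature_ids.
#' @param edges data.frame with columns `substrate`, `product`, `gene`.
#' @param branch_fractions named list: `branch_fractions[[node]][[product]]`
#'   is the fraction of `node`'s flux routed to `product`. Required for nodes
#'   with more than one outgoing edge.
#' @param transcript_ids optional character vector; when given, every edge
#'   gene must be one of them.
#' @return An object of class `pathway_map` with a precomputed topological
#'   order in `$topo_order`.
#' @export
pathway_map <- function(nodes, edges, branch_fractions = list(),
                        transcript_ids = NULL) {
  nodes <- as.character(nodes)
  edges <- data.frame(substrate = as.character(edges$substrate),
                      product = as.character(edges$product),
                      gene = as.character(edges$gene),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes)) stop("duplicate pathway nodes", call. = FALSE)
  unknown <- setdiff(unique(c(edges$substrate, edges$product)), nodes)
  if (length(unknown) > 0L) {
    stop("edge endpoint(s) not in node list: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(transcript_ids)) {
    bad <- setdiff(unique(edges$gene), transcript_ids)
    if (length(bad) > 0L) {
      stop("edge gene(s) missing from the transcript catalog: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  topo <- topological_order(nodes, edges)
  if (!is.null(topo$cycle)) {
    stop("pathway map contains a cycle: ",
         paste(topo$cycle, collapse = " -> "), call. = FALSE)
  }
  frac <- resolve_branch_fractions(nodes, edges, branch_fractions)
  structure(list(nodes = nodes, edges = edges,
                 branch_fractions = frac, topo_order = topo$order),
            class = "pathway_map")
}

# Kahn's algorithm; returns order, or a witness cycle when none exists.
topological_order <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tb <- table(edges$product)
  indeg[names(tb)] <- as.integer(tb)
  order <- character(0)
  queue <- sort(names(indeg)[indeg == 0L])
  indeg2 <- indeg
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    out <- edges$product[edges$substrate == v]
    for (w in out) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(order) == length(nodes)) return(list(order = order, cycle = NULL))
  # walk backwards within the residual graph until a node repeats
  residual <- names(indeg2)[!names(indeg2) %in% order]
  v <- residual[1L]
  path <- v
  repeat {
    pred <- edges$substrate[edges$product == v]
    pred <- pred[pred %in% residual]
    v <- pred[1L]
    if (v %in% path) {
      cyc <- path[seq(match(v, path), length(path))]
      return(list(order = NULL, cycle = rev(c(cyc, v))))
    }
    path <- c(path, v)
  }
}

resolve_branch_fractions <- function(nodes, edges, branch_fractions) {
  frac <- list()
  for (v in unique(edges$substrate)) {
    prods <- edges$product[edges$substrate == v]
    if (length(prods) == 1L && is.null(branch_fractions[[v]])) {
      frac[[v]] <- stats::setNames(1, prods)
      next
    }
    declared <- branch_fractions[[v]]
    if (is.null(declared)) {
      stop("branching node '", v, "' has no branch_fractions entry",
           call. = FALSE)
    }
    declared <- unlist(declared)
    if (!setequal(names(declared), prods)) {
      stop("branch_fractions for node '", v,
           "' do not name its products exactly", call. = FALSE)
    }
    if (any(declared < 0)) {
      stop("negative branch fraction at node '", v, "'", call. = FALSE)
    }
    if (abs(sum(declared) - 1) > 1e-9) {
      stop(sprintf(
        "branch fractions at node '%s' sum to %.12g, not 1", v,
        sum(declared)), call. = FALSE)
    }
    frac[[v]] <- declared[prods]
  }
  frac
}

#' @export
print.pathway_map <- function(x, ...) {
  n_branch <- sum(vapply(x$branch_fractions, length, 1L) > 1L)
  cat(sprintf("<pathway_map> %d nodes, %d edges, %d branching node(s)\n",
              length(x$nodes), nrow(x$edges), n_branch))
  invisible(x)
}

#' Read / write a pathway map as JSON
#'
#' Schema: `{"nodes": [...], "edges": [{"substrate":..,"product":..,
#' "gene":..}], "branch_fractions": {node: {product: fraction}}}`.
#'
#' @param path file path.
#' @param transcript_ids optional transcript catalog to validate genes
#'   against.
#' @return `read_pathway_map`: a validated [pathway_map()].
#' @export
read_pathway_map <- function(path, transcript_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("nodes", "edges")) {
    if (is.null(doc[[field]])) {
      stop("pathway map JSON lacks required field '", field, "'",
           call. = FALSE)
    }
  }
  bf <- doc$branch_fractions
  if (is.null(bf)) bf <- list()
  pathway_map(doc$nodes, doc$edges, lapply(bf, unlist),
              transcript_ids = transcript_ids)
}

#' @rdname read_pathway_map
#' @param map a `pathway_map`.
#' @export
write_pathway_map <- function(map, path) {
  doc <- list(
    nodes = map$nodes,
    edges = map$edges,
    branch_fractions = lapply(map$branch_fractions, as.list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
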