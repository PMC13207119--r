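#' Genotype profiles in the joint feature space at one stage
#'
#' `log2fc` mode builds one profile per mutant (log2 fold change vs the
#' matched wild type, ND or one-sided cells masked); `zscore` mode builds
#' one profile per genotype including wild types (detected-replicate means,
#' z-scored per feature across genotypes over unmasked entries).
#'
#' @param tab an [abundance_table()].
#' @param design a [design_map()].
#' @param stage stage label.
#' @param mode `"log2fc"` (default) or `"zscore"`.
#' @param features feature subset (default: all).
#' @return List of class `genotype_profiles`: `values` (genotype x feature
#'   matrix), `mask` (logical, `TRUE` = usable), `stage`, `mode`.
#' @export
build_profiles <- function(tab, design, stage,
                           mode = c("log2fc", "zscore"), features = NULL) {
  mode <- match.arg(mode)
  if (!stage %in% tab$samples$stage) {
    stop("stage '", stage, "' absent from table", call. = FALSE)
  }
  if (is.null(features)) features <- tab$features$feature_id
  if (mode == "log2fc") {
    genos <- unique(tab$samples$genotype)
    wt_set <- unique(design$mutant_to_wildtype)
    unmatched <- setdiff(genos, c(wt_set, names(design$mutant_to_wildtype)))
    if (length(unmatched) > 0L) {
      stop("mutant(s) without a matched wild type: ",
           paste(unmatched, collapse = ", "), call. = FALSE)
    }
    mutants <- intersect(names(design$mutant_to_wildtype), genos)
    vals <- matrix(NA_real_, nrow = length(mutants),
                   ncol = length(features),
                   dimnames = list(mutants, features))
    for (m in mutants) for (f in features) {
      r <- log2_fold_change(tab, design, m, stage, f)
      if (r$status == "ok" && is.finite(r$log2fc)) vals[m, f] <- r$log2fc
    }
  } else {
    genos <- unique(tab$samples$genotype)
    vals <- matrix(NA_real_, nrow = length(genos), ncol = length(features),
                   dimnames = list(genos, features))
    for (g in genos) for (f in features) {
      gv <- group_values(tab, f, g, stage)
      if (gv$n_detected > 0L) vals[g, f] <- mean(gv$values)
    }
    for (f in features) {
      v <- vals[, f]
      use <- !is.na(v)
      if (sum(use) >= 2L && stats::sd(v[use]) > 0) {
        vals[use, f] <- (v[use] - mean(v[use])) / stats::sd(v[use])
      } else {
        vals[, f] <- NA_real_
      }
    }
  }
  structure(list(values = vals, mask = !is.na(vals), stage = stage,
                 mode = mode),
            class = "genotype_profiles")
}

#' Pairwise profile distances on mutually unmasked entries
#'
#' @param profiles a [build_profiles()] result.
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @param min_shared minimum shared unmasked entries per pair (default 3).
#' @return Symmetric distance matrix (labels = genotypes).
#' @export
profile_distances <- function(profiles,
                              distance = c("one_minus_pearson",
                                           "euclidean"),
                              min_shared = 3L) {
  distance <- match.arg(distance)
  v <- profiles$values
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    use <- profiles$mask[i, ] & profiles$mask[j, ]
    if (sum(use) < min_shared) {
      stop(sprintf(
        "profiles '%s' and '%s' share only %d unmasked entries (< %d)",
        rownames(v)[i], rownames(v)[j], sum(use), min_shared),
        call. = FALSE)
    }
    a <- v[i, use]
    b <- v[j, use]
    d[i, j] <- d[j, i] <- if (distance == "euclidean") {
      sqrt(sum((a - b) ^ 2))
    } else {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        stop(sprintf(
          "profile '%s' or '%s' is constant on shared entries",
          rownames(v)[i], rownames(v)[j]), call. = FALSE)
      }
      1 - stats::cor(a, b)
    }
  }
  d
}

#' Agglomerative hierarchical clustering of genotype profiles
#'
#' Classic bottom-up agglomeration under average (UPGMA, default), complete
#' or Ward (ward.D2 update) linkage. Ties in the minimum inter-cluster
#' distance are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labeled by its smallest leaf), so the tree is
#' deterministic and independent of input order.
#'
#' @param profiles a [build_profiles()] result, or a symmetric distance
#'   matrix with dimnames.
#' @param distance,linkage method choices.
#' @param min_shared forwarded to [profile_distances()].
#' @return Object of class `dendrogram_table`: `merges` (data.frame a, b,
#'   height, id; negative entries are leaves, positive are prior merges),
#'   `labels`, `distance`, `linkage`.
#' @export
hcl_cluster <- function(profiles,
                        distance = c("one_minus_pearson", "euclidean"),
                        linkage = c("average", "complete", "ward"),
                        min_shared = 3L) {
  linkage <- match.arg(linkage)
  d <- if (is.matrix(profiles)) {
    profiles
  } else {
    profile_distances(profiles, distance = distance,
                      min_shared = min_shared)
  }
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 profiles to cluster", call. = FALSE)
  # sort leaves by label so index-based tie-breaks are lexicographic
  ord <- order(labels)
  labels <- labels[ord]
  d <- d[ord, ord, drop = FALSE]
  active <- seq_len(n)             # current cluster ids (neg leaf / pos merge)
  members <- as.list(seq_len(n))   # leaf indices per active cluster
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  cur <- d
  merges <- data.frame(a = integer(0), b = integer(0), height = numeric(0),
                       id = integer(0))
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (is.null(best) || cur[i, j] < best$d - 1e-15) {
        best <- list(i = i, j = j, d = cur[i, j])
      }
      # equal distances: (i, j) pairs are visited in lexicographic order of
      # the smallest-leaf labels, so the first hit wins
    }
    i <- best$i
    j <- best$j
    h <- best$d
    new_id <- step
    merges <- rbind(merges, data.frame(a = ids[i], b = ids[j], height = h,
                                       id = new_id))
    new_members <- sort(c(members[[i]], members[[j]]))
    # Lance-Williams update against every other active cluster
    keep <- setdiff(seq_len(m), c(i, j))
    new_row <- numeric(length(keep))
    for (kk in seq_along(keep)) {
      k <- keep[kk]
      new_row[kk] <- switch(
        linkage,
        average = (sizes[i] * cur[i, k] + sizes[j] * cur[j, k]) /
          (sizes[i] + sizes[j]),
        complete = max(cur[i, k], cur[j, k]),
        ward = sqrt(((sizes[i] + sizes[k]) * cur[i, k] ^ 2 +
                       (sizes[j] + sizes[k]) * cur[j, k] ^ 2 -
                       sizes[k] * cur[i, j] ^ 2) /
                      (sizes[i] + sizes[j] + sizes[k]))
      )
    }
    cur <- cur[keep, keep, drop = FALSE]
    cur <- rbind(cbind(cur, new_row), c(new_row, 0))
    members <- c(members[keep], list(new_members))
    ids <- c(ids[keep], new_id)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    active <- seq_along(ids)
  }
  structure(list(merges = merges, labels = labels,
                 distance = if (is.matrix(profiles)) "precomputed"
                 else match.arg(distance),
                 linkage = linkage),
            class = "dendrogram_table")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges (the last k - 1 in the agglomeration
#' sequence, since heights are non-decreasing for the supported linkages).
#'
#' @param dend a [hcl_cluster()] result.
#' @param k number of clusters, 1 <= k <= number of leaves.
#' @return Named integer vector: cluster membership per leaf label.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]", call. = FALSE)
  assign_id <- seq_len(n)
  cluster_of_merge <- integer(n - 1L)
  n_keep <- n - k
  for (s in seq_len(n_keep)) {
    row <- dend$merges[s, ]
    pick <- function(x) if (x < 0) assign_id[-x] else cluster_of_merge[x]
    ca <- pick(row$a)
    cb <- pick(row$b)
    assign_id[assign_id == cb] <- ca
    cluster_of_merge[cluster_of_merge == cb] <- ca
    cluster_of_merge[row$id] <- ca
  }
  out <- match(assign_id, unique(assign_id))
  names(out) <- dend$labels
  out
}

#' Convert to a stats::hclust object
#'
#' @param x a `dendrogram_table`.
#' @param ... unused.
#' @return An `hclust` object (merge/height/labels), enabling plotting and
#'   Newick export through ape.
#' @export
as.hclust.dendrogram_table <- function(x, ...) {
  n <- length(x$labels)
  merge <- as.matrix(x$merges[, c("a", "b")])
  dimnames(merge) <- NULL
  hc <- list(merge = merge, height = x$merges$height,
             order = seq_len(n), labels = x$labels,
             method = x$linkage, call = match.call(),
             dist.method = x$distance)
  class(hc) <- "hclust"
  # a displayable leaf order consistent with the merges
  hc$order <- order_leaves(merge, n)
  hc
}

order_leaves <- function(merge, n) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1L]), expand(merge[i, 2L]))
  }
  expand(n - 1L)
}

#' Export a dendrogram as Newick plus a merge table
#'
#' Branch lengths encode merge heights; the companion TSV lists the raw
#' merge sequence.
#'
#' @param dend a `dendrogram_table`.
#' @param newick_path path for the Newick file (optional).
#' @param merges_path path for the merge-table TSV (optional).
#' @return The Newick string, invisibly.
#' @export
export_dendrogram <- function(dend, newick_path = NULL, merges_path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(dend))
  nwk <- ape::write.tree(phy)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(merges_path)) {
    utils::write.table(dend$merges, merges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(nwk)
}
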