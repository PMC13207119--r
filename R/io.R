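#' Read an abundance matrix TSV
#'
#' Dialect: tab-separated; row 1 = sample_ids (first cell `feature_id`),
#' column 1 = feature_ids, cells = decimal numbers or the ND sentinel.
#' Features must be rows and samples columns; the transpose is rejected,
#' never guessed. Row and column order are preserved from the file.
#'
#' @param path TSV path.
#' @param features a [feature_catalog()] covering every row id.
#' @param samples a [sample_metadata()] covering every column id.
#' @param nd sentinel token for not-detected cells (default `"ND"`).
#' @return A validated [abundance_table()].
#' @export
read_abundance_table <- function(path, features, samples, nd = "ND") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  sample_ids <- colnames(raw)[-1L]
  feature_ids <- raw[[1L]]
  unknown_s <- setdiff(sample_ids, samples$sample_id)
  if (length(unknown_s) > 0L) {
    stop("table names sample(s) absent from metadata: ",
         paste(unknown_s, collapse = ", "), call. = FALSE)
  }
  unknown_f <- setdiff(feature_ids, features$feature_id)
  if (length(unknown_f) > 0L) {
    stop("table names feature(s) absent from the catalog: ",
         paste(unknown_f, collapse = ", "), call. = FALSE)
  }
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup) > 0L) {
    stop("duplicate feature row(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  detected <- cells != nd
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad_num <- detected & is.na(values)
  if (any(bad_num)) {
    idx <- which(bad_num, arr.ind = TRUE)[1L, ]
    stop(sprintf("cell (%s, %s) is neither numeric nor the sentinel '%s'",
                 feature_ids[idx[1L]], sample_ids[idx[2L]], nd),
         call. = FALSE)
  }
  neg <- detected & values < 0
  if (any(neg)) {
    idx <- which(neg, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance at (%s, %s)",
                 feature_ids[idx[1L]], sample_ids[idx[2L]]), call. = FALSE)
  }
  values[!detected] <- NA_real_
  abundance_table(values, detected,
                  features[match(feature_ids, features$feature_id), ,
                           drop = FALSE],
                  samples[match(sample_ids, samples$sample_id), ,
                          drop = FALSE])
}

#' Write an abundance matrix TSV
#'
#' Emits exactly the dialect [read_abundance_table()] accepts; ND cells are
#' written as the sentinel. Number formatting uses R's 15-significant-digit
#' decimal representation, so write -> read -> write is byte-stable.
#'
#' @param tab an [abundance_table()].
#' @param path output path.
#' @param nd sentinel token (default `"ND"`).
#' @export
write_abundance_table <- function(tab, path, nd = "ND") {
  validate_abundance_table(tab)
  v <- tab$values
  cells <- matrix(as.character(v), nrow = nrow(v))
  cells[!tab$detected] <- nd
  header <- paste(c("feature_id", tab$samples$sample_id), collapse = "\t")
  body <- apply(cbind(tab$features$feature_id, cells), 1L, paste,
                collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, if (nrow(v) > 0L) body), con, sep = "\n")
  invisible(path)
}

#' Read / write the sidecar metadata TSVs
#'
#' Sample metadata columns: sample_id, genotype, background, stage,
#' replicate. Feature metadata columns: feature_id, display_name, kind,
#' pathway_class, branch_id, step_index (empty cells = absent annotation).
#'
#' @param path TSV path.
#' @param ... passed to the respective validating constructor.
#' @return The validated metadata object.
#' @export
read_sample_metadata <- function(path, ...) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  sample_metadata(x$sample_id, x$genotype, x$background, x$stage,
                  as.integer(x$replicate), ...)
}

#' @rdname read_sample_metadata
#' @export
read_feature_catalog <- function(path, ...) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", check.names = FALSE)
  branch <- ifelse(is.na(x$branch_id) | x$branch_id == "",
                   NA_character_, x$branch_id)
  step <- suppressWarnings(as.integer(x$step_index))
  feature_catalog(x$feature_id, x$display_name, x$kind, x$pathway_class,
                  branch, step, ...)
}

#' @rdname read_sample_metadata
#' @param samples a `sample_metadata` data.frame.
#' @export
write_sample_metadata <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_sample_metadata
#' @param features a `feature_catalog` data.frame.
#' @export
write_feature_catalog <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
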