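#' Feature catalog constructor
#'
#' Builds and validates a feature catalog: one row per measured feature
#' (metabolite or transcript) with its pathway annotation. The catalog is the
#' row universe of every [abundance_table()].
#'
#' @param feature_id character, short unique identifiers.
#' @param display_name character, free-text names (defaults to `feature_id`).
#' @param kind character, `"metabolite"` or `"transcript"`.
#' @param pathway_class character, one of `"CAR"`, `"ABA"`, `"MEP"`, `"MVA"`,
#'   `"CHL"`, `"TOC"`, `"QUI"` (extensible via `extra_classes`).
#' @param branch_id optional character, pathway branch label (`NA` allowed).
#' @param step_index optional integer, 0-based position along the branch.
#'   Must be present exactly when `branch_id` is, and non-negative.
#' @param extra_classes additional pathway class labels to accept.
#' @return A `data.frame` of class `feature_catalog`.
#' @export
feature_catalog <- function(feature_id,
                            display_name = feature_id,
                            kind,
                            pathway_class,
                            branch_id = NA_character_,
                            step_index = NA_integer_,
                            extra_classes = character()) {
  cat_df <- data.frame(
    feature_id = as.character(feature_id),
    display_name = as.character(display_name),
    kind = as.character(kind),
    pathway_class = as.character(pathway_class),
    branch_id = as.character(branch_id),
    step_index = as.integer(step_index),
    stringsAsFactors = FALSE
  )
  validate_feature_catalog(cat_df, extra_classes = extra_classes)
  class(cat_df) <- c("feature_catalog", "data.frame")
  cat_df
}

#' @rdname feature_catalog
#' @param x a feature catalog data.frame.
#' @export
validate_feature_catalog <- function(x, extra_classes = character()) {
  required <- c("feature_id", "display_name", "kind", "pathway_class",
                "branch_id", "step_index")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("feature catalog is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- x$feature_id[duplicated(x$feature_id)]
  if (length(dup) > 0L) {
    stop("duplicate feature_id in catalog: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(x$kind), c("metabolite", "transcript"))
  if (length(bad_kind) > 0L) {
    stop("unknown feature kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  classes <- c("CAR", "ABA", "MEP", "MVA", "CHL", "TOC", "QUI", extra_classes)
  bad_cls <- setdiff(unique(x$pathway_class), classes)
  if (length(bad_cls) > 0L) {
    stop("unknown pathway_class: ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  # step_index present iff branch_id present, and non-negative
  mismatch <- xor(is.na(x$branch_id), is.na(x$step_index))
  if (any(mismatch)) {
    stop("branch_id and step_index must be present together; offenders: ",
         paste(x$feature_id[mismatch], collapse = ", "), call. = FALSE)
  }
  neg <- !is.na(x$step_index) & x$step_index < 0L
  if (any(neg)) {
    stop("negative step_index for: ",
         paste(x$feature_id[neg], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Sample metadata constructor
#'
#' One row per biological-replicate sample. Wild-type genotypes must have
#' `background` equal to themselves and (genotype, stage, replicate) must be
#' unique.
#'
#' @param sample_id unique sample identifiers.
#' @param genotype genotype labels (e.g. `"AC"`, `"M82"`, `"at"`, `"r"`,
#'   `"t"`, `"B"`, `"Del"`; the vocabulary is open).
#' @param background genetic background, one of the wild-type genotypes.
#' @param stage stage labels; defaults accepted are `"MG"`, `"Br"`, `"FR"`
#'   plus anything in `extra_stages`.
#' @param replicate positive integer replicate number.
#' @param wildtypes genotypes considered wild type (background donors).
#' @param extra_stages additional stage labels to accept.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, genotype, background, stage, replicate,
                            wildtypes = c("AC", "M82"),
                            extra_stages = character()) {
  sm <- data.frame(
    sample_id = as.character(sample_id),
    genotype = as.character(genotype),
    background = as.character(background),
    stage = as.character(stage),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_metadata(sm, wildtypes = wildtypes,
                           extra_stages = extra_stages)
  class(sm) <- c("sample_metadata", "data.frame")
  sm
}

#' @rdname sample_metadata
#' @param x a sample metadata data.frame.
#' @export
validate_sample_metadata <- function(x, wildtypes = c("AC", "M82"),
                                     extra_stages = character()) {
  required <- c("sample_id", "genotype", "background", "stage", "replicate")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("sample metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0L) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  stages <- c("MG", "Br", "FR", extra_stages)
  bad_stage <- setdiff(unique(x$stage), stages)
  if (length(bad_stage) > 0L) {
    stop("unknown stage: ", paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(x$replicate) | x$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  key <- paste(x$genotype, x$stage, x$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    off <- x$sample_id[duplicated(key)]
    stop("duplicate (genotype, stage, replicate): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  is_wt <- x$genotype %in% wildtypes
  bad_wt <- is_wt & x$background != x$genotype
  if (any(bad_wt)) {
    stop("wild-type samples must have background == genotype; offenders: ",
         paste(x$sample_id[bad_wt], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Abundance table container
#'
#' The single input currency of every analysis stage: a features x samples
#' matrix of nonnegative abundances with an explicit parallel detected mask.
#' Not-detected (ND) cells are below the detection limit: they are distinct
#' from measured zeros, carry `NA` in `values`, and are excluded from every
#' downstream statistic rather than zero-filled.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Cells may be `NA` only where `detected` is `FALSE`.
#' @param detected logical matrix, same dimensions; `FALSE` marks ND cells.
#' @param features a [feature_catalog()] whose order matches the rows.
#' @param samples a [sample_metadata()] whose order matches the columns.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, detected = NULL, features, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(detected)) detected <- !is.na(values)
  detected <- array(as.logical(detected), dim = dim(values))
  if (nrow(values) != nrow(features) || ncol(values) != nrow(samples)) {
    stop(sprintf(
      "matrix dimensions %dx%d do not match %d features x %d samples",
      nrow(values), ncol(values), nrow(features), nrow(samples)),
      call. = FALSE)
  }
  values[!detected] <- NA_real_
  rownames(values) <- features$feature_id
  colnames(values) <- samples$sample_id
  dimnames(detected) <- dimnames(values)
  tab <- structure(
    list(values = values, detected = detected,
         features = features, samples = samples),
    class = "abundance_table"
  )
  validate_abundance_table(tab)
  tab
}

#' @rdname abundance_table
#' @param tab an `abundance_table`.
#' @export
validate_abundance_table <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  validate_feature_catalog(tab$features,
                           extra_classes = unique(tab$features$pathway_class))
  nf <- nrow(tab$features)
  ns <- nrow(tab$samples)
  if (!identical(dim(tab$values), c(nf, ns)) ||
      !identical(dim(tab$detected), c(nf, ns))) {
    stop(sprintf(
      "matrix dimensions %dx%d do not match %d features x %d samples",
      nrow(tab$values), ncol(tab$values), nf, ns), call. = FALSE)
  }
  det <- tab$detected
  v <- tab$values
  bad <- det & (!is.finite(v) | v < 0)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "detected cell (%s, %s) is not a finite nonnegative number",
      rownames(v)[idx[1L]], colnames(v)[idx[2L]]), call. = FALSE)
  }
  if (any(!det & !is.na(v))) {
    stop("ND cells must carry NA values", call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples (%d ND cells)\n",
              nrow(x$values), ncol(x$values), sum(!x$detected)))
  cat("  kinds: ", paste(sprintf("%s=%d", names(table(x$features$kind)),
                                 table(x$features$kind)), collapse = ", "),
      "\n", sep = "")
  cat("  stages:", paste(unique(x$samples$stage), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an abundance table
#'
#' @param tab an `abundance_table`.
#' @param features feature_ids to keep (default all, original order kept).
#' @param samples sample_ids to keep (default all).
#' @return A new `abundance_table`.
#' @export
subset_table <- function(tab, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(tab$values)) else {
    miss <- setdiff(features, tab$features$feature_id)
    if (length(miss) > 0L) {
      stop("feature(s) absent from table: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    match(features, tab$features$feature_id)
  }
  si <- if (is.null(samples)) seq_len(ncol(tab$values)) else {
    miss <- setdiff(samples, tab$samples$sample_id)
    if (length(miss) > 0L) {
      stop("sample(s) absent from table: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    match(samples, tab$samples$sample_id)
  }
  abundance_table(tab$values[fi, si, drop = FALSE],
                  tab$detected[fi, si, drop = FALSE],
                  tab$features[fi, , drop = FALSE],
                  tab$samples[si, , drop = FALSE])
}
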