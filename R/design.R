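#' Design map: mutant to matched wild type
#'
#' Each mutant genotype is normalized against one wild-type background
#' (here AC for at, r, t, B and M82 for Del by default).
#'
#' @param mutant_to_wildtype named character vector, names = mutant genotypes,
#'   values = matched wild-type genotypes.
#' @return An object of class `design_map`.
#' @export
design_map <- function(mutant_to_wildtype) {
  m <- as.character(mutant_to_wildtype)
  names(m) <- names(mutant_to_wildtype)
  if (is.null(names(m)) || any(names(m) == "")) {
    stop("mutant_to_wildtype must be a fully named vector", call. = FALSE)
  }
  if (anyDuplicated(names(m))) {
    stop("each mutant must map to exactly one wild type", call. = FALSE)
  }
  structure(list(mutant_to_wildtype = m), class = "design_map")
}

#' The default panel design: at, r, t, B vs AC and Del vs M82.
#' @return A `design_map`.
#' @export
default_design <- function() {
  design_map(c(at = "AC", r = "AC", t = "AC", B = "AC", Del = "M82"))
}

#' Matched wild type of a mutant
#' @param design a `design_map`.
#' @param mutant mutant genotype label.
#' @return The wild-type genotype label.
#' @export
matched_wildtype <- function(design, mutant) {
  wt <- design$mutant_to_wildtype[[mutant]]
  if (is.null(wt)) {
    stop("mutant '", mutant, "' has no matched wild type in the design",
         call. = FALSE)
  }
  wt
}

#' Audit a sample set against a design map
#'
#' Report-only check (never raises): replicate counts per (genotype, stage),
#' flags for cells with fewer than 2 replicates (a t-test is impossible
#' there), and mutants lacking a matched wild type.
#'
#' @param samples a [sample_metadata()] data.frame.
#' @param design a [design_map()].
#' @return A list of class `design_report` with elements `counts`
#'   (genotype, stage, n_replicates, flag) and `unmatched_mutants`.
#' @export
validate_design <- function(samples, design) {
  wt_set <- unique(design$mutant_to_wildtype)
  counts <- as.data.frame(table(genotype = samples$genotype,
                                stage = samples$stage),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "n_replicates"
  is_mutant <- !(counts$genotype %in% wt_set)
  counts$flag <- ifelse(is_mutant & counts$n_replicates < 2L,
                        "insufficient_replicates", "")
  genos <- unique(samples$genotype)
  mutants <- setdiff(genos, wt_set)
  unmatched <- mutants[!mutants %in% names(design$mutant_to_wildtype)]
  # a mapping whose wild type has no samples is just as unusable
  mapped <- intersect(mutants, names(design$mutant_to_wildtype))
  wt_absent <- mapped[!design$mutant_to_wildtype[mapped] %in% genos]
  structure(list(counts = counts,
                 unmatched_mutants = sort(c(unmatched, wt_absent))),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  n_flag <- sum(x$counts$flag != "")
  cat(sprintf("<design_report> %d genotype x stage cells, %d flagged\n",
              nrow(x$counts), n_flag))
  if (n_flag > 0L) print(x$counts[x$counts$flag != "", ])
  if (length(x$unmatched_mutants) > 0L) {
    cat("unmatched mutants:", paste(x$unmatched_mutants, collapse = ", "),
        "\n")
  }
  invisible(x)
}
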