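# Readers and writers. The count table is the single source of truth for
# sample order; metadata is re-indexed to it.

#' Read an OTU count table
#'
#' Reads a TSV/CSV count table with a header row of OTU identifiers and a
#' first column of sample identifiers (or the transpose, with
#' `orientation = "otus_by_samples"`). Files ending in `.biom` are read with
#' the biomformat package when available.
#'
#' @param path file path. Separator is inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param orientation `"samples_by_otus"` (default) or `"otus_by_samples"`.
#' @return validated samples x OTUs integer-like matrix with sample row
#'   names and OTU column names.
#' @export
read_count_table <- function(path,
                             orientation = c("samples_by_otus",
                                             "otus_by_samples")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    M <- t(as.matrix(biomformat::biom_data(b)))   # biom stores OTU x sample
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, comment.char = "#")
    M <- as.matrix(df)
    if (orientation == "otus_by_samples") M <- t(M)
  }
  if (!is.numeric(M)) stop("count table contains non-numeric cells")
  if (any(!is.finite(M))) stop("count table contains non-finite values")
  if (any(M < 0)) stop("count table contains negative counts")
  if (anyDuplicated(rownames(M))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(M))) stop("duplicate OTU identifiers")
  M
}

#' Read and align sample metadata
#'
#' Reads a CSV/TSV metadata file, aligns its rows to the sample order of the
#' count table, and optionally builds a [matched_design()]. Character/factor
#' variables used as submodels are expanded to indicator columns by the test
#' functions (reference level = first observed).
#'
#' @param path file path (separator inferred from extension).
#' @param table optional count table whose row names define sample order.
#' @param sample_id_col,set_id_col column names for sample and set labels.
#' @param submodels optional ordered character vector of variable columns;
#'   when given, a `"matched_design"` is returned instead of a data.frame.
#' @param confounders optional character vector of confounder columns (used
#'   with `submodels`).
#' @param adjust_set_id passed to [matched_design()].
#' @return aligned data.frame, or a `"matched_design"` when `submodels` is
#'   given.
#' @export
read_metadata <- function(path, table = NULL, sample_id_col = "sample_id",
                          set_id_col = "set_id", submodels = NULL,
                          confounders = NULL, adjust_set_id = TRUE) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!sample_id_col %in% names(df))
    stop("metadata lacks a '", sample_id_col, "' column")
  if (!is.null(table)) {
    ids <- rownames(as.matrix(table))
    miss <- setdiff(ids, df[[sample_id_col]])
    if (length(miss))
      stop("metadata missing sample(s): ", paste(miss, collapse = ", "))
    df <- df[match(ids, df[[sample_id_col]]), , drop = FALSE]
    rownames(df) <- NULL
  }
  used <- c(set_id_col, submodels, confounders)
  used <- used[!grepl(":", used %||% character())]
  for (v in intersect(used, names(df)))
    if (anyNA(df[[v]])) stop("missing values in variable '", v, "'")
  if (is.null(submodels)) return(df)
  subm <- lapply(submodels, .expand_var, metadata = df)
  names(subm) <- submodels
  conf <- if (length(confounders))
    do.call(cbind, lapply(confounders, .expand_var, metadata = df)) else NULL
  matched_design(df[[set_id_col]], subm, confounders = conf,
                 adjust_set_id = adjust_set_id,
                 sample_ids = df[[sample_id_col]])
}

#' Write test or evaluation results
#'
#' Writes tab-separated results with run metadata (seed, permutations,
#' package version) as `#` header comments and numbers at 6 significant
#' digits. For an LDM fit the per-OTU table is written to `otu_path` when
#' given. Identical runs produce byte-identical files.
#'
#' @param result a `"permanova_fit"`, `"ldm_fit"` or `"eval_result"`.
#' @param path output TSV path.
#' @param otu_path optional output path for the per-OTU table (LDM fits).
#' @return invisibly, the path(s) written.
#' @export
write_results <- function(result, path, otu_path = NULL) {
  ver <- as.character(utils::packageVersion("permatch"))
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 6L)
    df
  }
  dump <- function(df, header, file) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(fmt(df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (inherits(result, "permanova_fit")) {
    hdr <- c(paste0("# permatch ", ver),
             paste0("# seed: ", result$seed),
             paste0("# n_perm: ", result$n_perm),
             paste0("# permute: ", result$permute),
             paste0("# distance: ", result$metric))
    dump(data.frame(submodel = names(result$statistic),
                    pseudo.F = unname(result$statistic),
                    p.value = unname(result$p.value)), hdr, path)
  } else if (inherits(result, "ldm_fit")) {
    hdr <- c(paste0("# permatch ", ver),
             paste0("# seed: ", result$seed),
             paste0("# n_perm: ", result$n_perm),
             paste0("# permute: ", result$permute),
             paste0("# scales: ", paste(result$scales, collapse = ",")))
    g <- result$global
    g$omnibus.p <- result$omnibus_p[g$submodel]
    dump(g, hdr, path)
    if (!is.null(otu_path) && length(result$otu))
      dump(do.call(rbind, lapply(names(result$otu), function(nm)
        cbind(submodel = nm, result$otu[[nm]]))), hdr, otu_path)
  } else if (inherits(result, "eval_result")) {
    cfg <- result$config
    hdr <- c(paste0("# permatch ", ver),
             paste0("# seed: ", cfg$seed),
             paste0("# scenario: ", cfg$scenario),
             paste0("# method: ", cfg$method),
             paste0("# strategy: ", cfg$strategy),
             paste0("# n_perm: ", cfg$n_perm))
    dump(data.frame(rejection_rate = result$rejection_rate, se = result$se,
                    sensitivity = result$sensitivity,
                    empirical_fdr = result$empirical_fdr,
                    n_replicates = cfg$n_replicates), hdr, path)
  } else stop("unsupported result type")
  invisible(c(path, otu_path))
}
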