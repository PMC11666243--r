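#' Read and write sorted-bin guide count tables
#'
#' Tab-separated interchange format: columns `guide_id`, `gene`, `is_nt`,
#' then `high_repK` / `low_repK` integer pairs. The round trip is
#' lossless.
#'
#' @param path File path.
#' @param counts ScreenCounts data.frame.
#' @return `read_counts()` returns the data.frame; `write_counts()`
#'   returns `path` invisibly.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("guide_id", "gene", "is_nt")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("count table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$guide_id)) stop("duplicated guide ids")
  if (!length(grep("^(high|low)_", names(df)))) {
    stop("count table has no high_*/low_* columns")
  }
  df$is_nt <- as.logical(df$is_nt)
  df
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then tab-separated member ids.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicated set names in GMT")
  sets
}

#' Read a lipid abundance table and its phenotype vector
#'
#' The lipid CSV holds `species_id`, `class`, then one numeric column of
#' log abundance per perturbation (the deposited layout: values in log,
#' normalized to the non-targeting control). The phenotype CSV holds
#' `perturbation`, `phenotype`.
#'
#' @param path CSV file path.
#' @return data.frame in the documented layout.
#' @export
read_lipid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("species_id", "class"), names(df))
  if (length(miss)) {
    stop("lipid table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(is.na(df$class) | df$class == "")) stop("missing class labels")
  perts <- setdiff(names(df), c("species_id", "class"))
  if (length(perts) < 3) stop("need at least 3 perturbation columns")
  df
}

#' @rdname read_lipid_csv
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("perturbation", "phenotype"), names(df))
  if (length(miss)) {
    stop("phenotype table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read a MAGeCK-style gene summary table
#'
#' Ingests the gene-level output layout of the MAGeCK screen pipeline
#' (columns `id`, `neg|score`, `neg|p-value`, `neg|fdr`, ...,
#' `pos|fdr`, and an `lfc` column, or `neg|lfc`/`pos|lfc`). Each gene is
#' reduced to a single signed log2 fold change and one two-sided FDR:
#' the smaller of the negative- and positive-selection FDRs, with
#' direction taken from the sign of the fold change.
#'
#' @param path Tab-separated gene summary file.
#' @return data.frame `gene`, `lfc`, `fdr`, `direction`
#'   (`"up"`/`"down"`).
#' @export
read_mageck_gene_summary <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  id_col <- intersect(c("id", "gene"), names(df))[1]
  if (is.na(id_col)) stop("gene summary is missing column: id")
  neg_fdr <- intersect(c("neg|fdr", "neg.fdr"), names(df))[1]
  pos_fdr <- intersect(c("pos|fdr", "pos.fdr"), names(df))[1]
  if (is.na(neg_fdr) || is.na(pos_fdr)) {
    stop("gene summary is missing column: neg|fdr or pos|fdr")
  }
  lfc_col <- intersect(c("lfc", "neg|lfc", "neg.lfc"), names(df))[1]
  if (is.na(lfc_col)) stop("gene summary is missing column: lfc")
  lfc <- as.numeric(df[[lfc_col]])
  data.frame(
    gene = df[[id_col]],
    lfc = lfc,
    fdr = pmin(as.numeric(df[[neg_fdr]]), as.numeric(df[[pos_fdr]])),
    direction = ifelse(lfc >= 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' Count directional hits at an FDR threshold
#'
#' The screen's headline filter: genes with FDR below `alpha`, split by
#' the sign of the fold change (knockdowns that increase vs decrease the
#' staining phenotype).
#'
#' @param stats data.frame with `lfc` and `fdr` columns.
#' @param alpha FDR threshold (default 0.05).
#' @return Named integer vector `c(up = ..., down = ...)`.
#' @export
count_fdr_hits <- function(stats, alpha = 0.05) {
  sig <- stats$fdr < alpha
  c(up = sum(sig & stats$lfc > 0), down = sum(sig & stats$lfc < 0))
}

#' Write a results table as TSV
#'
#' @param x data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
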