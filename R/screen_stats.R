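#' Median-of-ratios normalization of sorted-bin guide counts
#'
#' Computes one size factor per count column (sample) as the median ratio
#' of its counts to the per-guide geometric mean across samples, using
#' only guides observed in every sample, then divides each column by its
#' factor. This is the standard median-of-ratios scheme for sequencing
#' count matrices.
#'
#' @param counts A ScreenCounts data.frame as produced by
#'   [simulate_screen()] / [read_counts()]: `guide_id`, `gene`, `is_nt`,
#'   then integer count columns.
#' @return The same data.frame with count columns replaced by normalized
#'   (non-integer) values; size factors attached as
#'   `attr(, "size_factors")`.
#' @examples
#' sim <- simulate_screen(screen_sim_params(n_genes = 10, n_nt_guides = 10,
#'                                          cells_per_guide = 50,
#'                                          reads_per_bin = 1e4), seed = 1)
#' norm <- normalize_counts(sim$counts)
#' attr(norm, "size_factors")
#' @export
normalize_counts <- function(counts) {
  cols <- .count_columns(counts)
  mat <- as.matrix(counts[cols])
  if (any(mat < 0) || any(mat != floor(mat))) {
    stop("counts must be non-negative integers")
  }
  keep <- rowSums(mat > 0) == ncol(mat)
  if (!any(keep)) {
    stop("no guide has nonzero counts in every sample; ",
         "median-of-ratios is undefined (consider total-count scaling)")
  }
  geo <- exp(rowMeans(log(mat[keep, , drop = FALSE])))
  sf <- apply(mat[keep, , drop = FALSE], 2, function(col) {
    stats::median(col / geo)
  })
  out <- counts
  out[cols] <- sweep(mat, 2, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Per-guide log2 fold change between high and low bins
#'
#' For each replicate, computes `log2(high + pc) - log2(low + pc)` on
#' normalized counts and averages across replicates with equal weight.
#' The pseudocount keeps the statistic finite for guides absent from a
#' bin.
#'
#' @param norm_counts Normalized ScreenCounts (see [normalize_counts()]).
#' @param pseudocount Non-negative pseudocount added before the log
#'   (default 0.5).
#' @return data.frame `guide_id`, `gene`, `is_nt`, `lfc` plus one
#'   `lfc_repK` column per replicate.
#' @export
guide_lfc <- function(norm_counts, pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  cols <- .count_columns(norm_counts)
  reps <- sort(unique(sub("^(high|low)_", "", cols)))
  out <- norm_counts[c("guide_id", "gene", "is_nt")]
  lfc_mat <- sapply(reps, function(r) {
    hi <- norm_counts[[paste0("high_", r)]]
    lo <- norm_counts[[paste0("low_", r)]]
    if (is.null(hi) || is.null(lo)) {
      stop("replicate ", r, " is missing a high or low column")
    }
    log2(hi + pseudocount) - log2(lo + pseudocount)
  })
  lfc_mat <- matrix(lfc_mat, nrow = nrow(out),
                    dimnames = list(NULL, paste0("lfc_", reps)))
  out$lfc <- rowMeans(lfc_mat)
  cbind(out, as.data.frame(lfc_mat))
}

#' Gene-level effect sizes with a non-targeting permutation null
#'
#' Aggregates guide log2 fold changes to gene level (median over a gene's
#' guides) and assesses significance against an empirical null built by
#' resampling non-targeting (NT) guide LFCs: for a gene with k guides,
#' the null is the distribution of medians of k NT LFCs drawn with
#' replacement, `n_perm` times. Two-sided p-values use the permutation
#' floor `p = (b + 1) / (n_perm + 1)` where `b` counts null medians at
#' least as extreme in absolute value; FDR is Benjamini-Hochberg over all
#' genes.
#'
#' @param lfcs Output of [guide_lfc()] (or any data.frame with `gene`,
#'   `is_nt`, `lfc`).
#' @param n_perm Number of null resamples (default 10000).
#' @param seed Integer seed for the resampling.
#' @return data.frame `gene`, `lfc`, `p`, `fdr`, `n_guides`, one row per
#'   targeted gene (NT guides form the null, not a row).
#' @export
gene_stats <- function(lfcs, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt_lfc <- lfcs$lfc[lfcs$is_nt]
  if (length(nt_lfc) == 0) stop("no non-targeting guides to build the null")
  if (length(nt_lfc) < 50) {
    warning("only ", length(nt_lfc),
            " NT guides; the permutation null may be unstable")
  }
  tg <- lfcs[!lfcs$is_nt, , drop = FALSE]
  if (nrow(tg) == 0) stop("no targeting guides")
  split_lfc <- split(tg$lfc, tg$gene)
  genes <- names(split_lfc)
  n_guides <- lengths(split_lfc)
  if (any(n_guides == 0)) stop("gene with zero guides")
  obs <- vapply(split_lfc, stats::median, numeric(1))

  # genes with the same guide count share the identical resampling null
  p <- numeric(length(genes))
  for (k in unique(n_guides)) {
    null_meds <- .nt_null_medians(nt_lfc, k, n_perm)
    abs_null <- sort(abs(null_meds))
    idx <- which(n_guides == k)
    b <- n_perm - findInterval(abs(obs[idx]) - 1e-12, abs_null)
    p[idx] <- (b + 1) / (n_perm + 1)
  }
  data.frame(gene = genes, lfc = unname(obs), p = p,
             fdr = stats::p.adjust(p, method = "BH"),
             n_guides = unname(n_guides),
             stringsAsFactors = FALSE, row.names = NULL)
}

.nt_null_medians <- function(nt_lfc, k, n_perm) {
  draws <- matrix(sample(nt_lfc, k * n_perm, replace = TRUE), nrow = k)
  if (k == 1) return(as.numeric(draws))
  # column medians without apply() overhead
  draws <- matrix(draws[order(col(draws), draws)], nrow = k)
  if (k %% 2 == 1) {
    draws[(k + 1) / 2, ]
  } else {
    (draws[k / 2, ] + draws[k / 2 + 1, ]) / 2
  }
}

.count_columns <- function(counts) {
  cols <- grep("^(high|low)_", names(counts), value = TRUE)
  if (length(cols) < 2) stop("no high_*/low_* count columns found")
  cols
}
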