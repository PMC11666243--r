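#' Volcano-product hit calling
#'
#' Calls a gene a hit when the product of its absolute log2 fold change
#' and `-log10(FDR)` reaches the constant contour
#' `1 * -log10(alpha)` — the hyperbola drawn on the screen's volcano
#' plot. Direction comes from the sign of the fold change; the boundary
#' itself counts as a hit.
#'
#' @param stats data.frame with columns `lfc` and `fdr` (as from
#'   [gene_stats()] or [read_mageck_gene_summary()]).
#' @param alpha Significance contour level in (0, 1); default 0.05.
#' @return `stats` with an added factor column `hit` taking values
#'   `"up"`, `"down"`, `"none"`.
#' @examples
#' volcano_hit_call(data.frame(gene = "A", lfc = -2, fdr = 0.01))$hit
#' @export
volcano_hit_call <- function(stats, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (any(!is.finite(stats$lfc)) ||
      any(stats$fdr <= 0 | stats$fdr > 1)) {
    stop("lfc must be finite and fdr in (0, 1]")
  }
  product <- abs(stats$lfc) * (-log10(stats$fdr))
  threshold <- -log10(alpha)
  hit <- ifelse(product >= threshold,
                ifelse(stats$lfc >= 0, "up", "down"), "none")
  stats$hit <- factor(hit, levels = c("up", "down", "none"))
  stats
}

#' Signed prerank score combining effect size and confidence
#'
#' Computes, for each gene,
#' \deqn{score = \left(\frac{|LFC|}{\sigma_{LFC}} +
#'   \frac{nlFDR}{\sigma_{nlFDR}}\right) \cdot D}
#' where `nlFDR = log10(1 / FDR)` and `D` is +1 or -1 so the score's sign
#' matches the fold change (with `D = +1` when `LFC = 0`). The two scale
#' factors are the sample standard deviations (n-1 denominator) of `LFC`
#' and `nlFDR` over the full gene table, giving the effect-size and
#' confidence terms similar weight. FDR values are floored before the log
#' so the score stays finite.
#'
#' @param stats data.frame with `gene`, `lfc`, `fdr`.
#' @param fdr_floor Lower bound applied to FDR before taking logs. Use
#'   `1 / (n_perm + 1)` when the FDRs come from this package's
#'   permutation test, and a tiny constant (e.g. 1e-12) when ingesting
#'   external tables that report FDR = 0.
#' @return data.frame `gene`, `lfc`, `fdr`, `nlfdr`, `score`, sorted as
#'   input. The scale factors are attached as attributes `sigma_lfc` and
#'   `sigma_nlfdr`.
#' @export
prerank_score <- function(stats, fdr_floor = 1e-12) {
  if (nrow(stats) < 2) stop("at least 2 genes needed to estimate scales")
  if (fdr_floor <= 0) stop("fdr_floor must be positive")
  fdr <- pmax(stats$fdr, fdr_floor)
  nlfdr <- log10(1 / fdr)
  sigma_lfc <- stats::sd(stats$lfc)
  sigma_nlfdr <- stats::sd(nlfdr)
  if (sigma_lfc == 0 || sigma_nlfdr == 0) {
    stop("degenerate table: constant lfc or nlFDR column (sd = 0)")
  }
  d <- ifelse(stats$lfc < 0, -1, 1)
  out <- data.frame(gene = stats$gene, lfc = stats$lfc, fdr = stats$fdr,
                    nlfdr = nlfdr,
                    score = (abs(stats$lfc) / sigma_lfc +
                               nlfdr / sigma_nlfdr) * d,
                    stringsAsFactors = FALSE)
  attr(out, "sigma_lfc") <- sigma_lfc
  attr(out, "sigma_nlfdr") <- sigma_nlfdr
  out
}
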