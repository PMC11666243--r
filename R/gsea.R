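#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov running-sum GSEA on a preranked gene list.
#' Genes are ranked by descending score (ties broken by gene identifier);
#' walking down the list, the running sum rises by `|score|^p / N_R` at
#' each set member ("hit") and falls by `1 / (N - N_hit)` otherwise. The
#' enrichment score (ES) is the running sum's maximum deviation from
#' zero. The null distribution permutes gene labels (random sets of equal
#' size) `n_perm` times; NES divides ES by the mean absolute null ES of
#' the same sign, and nominal p and FDR q follow the standard preranked
#' procedure, computed separately for positively and negatively enriched
#' sets.
#'
#' @param scores data.frame with `gene` and `score` columns (e.g. from
#'   [prerank_score()]).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_perm Gene-label permutations for the null (default 1000).
#' @param weight_p Weighting exponent on `|score|` (default 1).
#' @param min_size,max_size Set-size bounds applied after intersecting
#'   each set with the scored genes; sets outside the bounds are dropped.
#' @param seed Integer seed for the permutations.
#' @return data.frame with one row per analyzed set: `set`, `size`,
#'   `es`, `nes`, `p`, `fdr`, `leading_edge` (slash-separated gene ids).
#' @examples
#' sc <- data.frame(gene = paste0("g", 1:20), score = 10:-9)
#' gsea_prerank(sc, list(top = paste0("g", 1:4)), n_perm = 200,
#'              min_size = 2, seed = 1)
#' @export
gsea_prerank <- function(scores, sets, n_perm = 1000, weight_p = 1,
                         min_size = 5, max_size = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (anyDuplicated(scores$gene)) stop("duplicated gene ids in scores")
  ord <- order(-scores$score, scores$gene)
  genes <- scores$gene[ord]
  s <- abs(scores$score[ord])^weight_p
  n <- length(genes)

  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a named list")
  }
  hits_list <- lapply(sets, function(members) {
    which(genes %in% members)
  })
  sizes <- lengths(hits_list)
  if (any(sizes == n)) {
    stop("set(s) covering every scored gene cannot be tested: ",
         paste(names(sets)[sizes == n], collapse = ", "))
  }
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) stop("no set within [min_size, max_size] after intersection")
  hits_list <- hits_list[keep]
  set_names <- names(sets)[keep]
  sizes <- sizes[keep]

  res <- lapply(seq_along(hits_list), function(i) {
    hits <- hits_list[[i]]
    obs <- .gsea_es(s, hits, n)
    null_es <- vapply(seq_len(n_perm), function(j) {
      .gsea_es(s, sort.int(sample.int(n, length(hits))), n)$es
    }, numeric(1))
    pos <- null_es[null_es >= 0]
    neg <- null_es[null_es < 0]
    if (obs$es >= 0) {
      denom <- if (length(pos)) mean(pos) else NA_real_
      p <- (sum(pos >= obs$es) + 1) / (length(pos) + 1)
    } else {
      denom <- if (length(neg)) mean(abs(neg)) else NA_real_
      p <- (sum(neg <= obs$es) + 1) / (length(neg) + 1)
    }
    le <- if (obs$es >= 0) hits[hits <= obs$at] else hits[hits >= obs$at]
    list(es = obs$es, nes = obs$es / denom, p = p,
         null_nes = c(if (length(pos)) pos / mean(pos),
                      if (length(neg)) -abs(neg) / mean(abs(neg))),
         leading_edge = paste(genes[le], collapse = "/"))
  })

  es <- vapply(res, `[[`, numeric(1), "es")
  nes <- vapply(res, `[[`, numeric(1), "nes")
  p <- vapply(res, `[[`, numeric(1), "p")
  null_nes <- unlist(lapply(res, `[[`, "null_nes"))
  fdr <- vapply(nes, .gsea_fdr, numeric(1), nes = nes, null_nes = null_nes)

  out <- data.frame(set = set_names, size = sizes, es = es, nes = nes,
                    p = p, fdr = fdr,
                    leading_edge = vapply(res, `[[`, character(1),
                                          "leading_edge"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, -abs(out$nes)), , drop = FALSE]
}

# Running-sum extremum evaluated only at hit boundaries: the sum peaks
# immediately after a hit increment and troughs immediately before one.
.gsea_es <- function(s, hits, n) {
  k <- length(hits)
  w <- s[hits]
  nr <- sum(w)
  if (nr == 0) w[] <- 1 / k else w <- w / nr
  top <- cumsum(w)
  miss_step <- 1 / (n - k)
  after_hit <- top - (hits - seq_len(k)) * miss_step
  before_hit <- c(0, top[-k]) - (hits - seq_len(k)) * miss_step
  cand <- c(after_hit, before_hit, 0)
  i <- which.max(abs(cand))
  es <- cand[i]
  at <- if (i <= k) hits[i] else if (i <= 2 * k) hits[i - k] - 1L else 0L
  list(es = es, at = at)
}

# Standard preranked FDR: compare the proportion of null NES at least as
# extreme with the proportion of observed NES at least as extreme, within
# the sign of the set's NES.
.gsea_fdr <- function(x, nes, null_nes) {
  if (is.na(x)) return(NA_real_)
  if (x >= 0) {
    num_pool <- null_nes[null_nes >= 0]
    obs_pool <- nes[!is.na(nes) & nes >= 0]
    num <- if (length(num_pool)) mean(num_pool >= x) else 0
    den <- mean(obs_pool >= x)
  } else {
    num_pool <- null_nes[null_nes < 0]
    obs_pool <- nes[!is.na(nes) & nes < 0]
    num <- if (length(num_pool)) mean(num_pool <= x) else 0
    den <- mean(obs_pool <= x)
  }
  min(1, num / max(den, .Machine$double.eps))
}
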