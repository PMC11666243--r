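#' Simulate a FACS sorted-bin CRISPRi screen
#'
#' Generates guide-level sequencing counts for a pooled screen in which
#' cells are stained for an aggregation phenotype and sorted into a
#' phenotype-high and a phenotype-low bin. The generative model per
#' replicate is:
#'
#' 1. Each cell carries one guide. A cell's latent phenotype is
#'    `z = effect(gene) + N(0, cell_noise_sd)`; NT guides have effect 0.
#' 2. Observed log staining intensity adds a cell-size term:
#'    `y = z + size_coupling_beta * size`, with `size ~ N(0, 1)`.
#' 3. Sort gates rank cells on the residual of `y` regressed on `size`
#'    (ordinary least squares, emulating size-corrected gates), or on raw
#'    `y` if `gate_on_residual = FALSE`. Exactly
#'    `floor(bin_fraction * N)` cells enter each bin.
#' 4. Guide abundance in each bin is sequenced by sampling
#'    `reads_per_bin` reads from a multinomial over guides (optionally
#'    Dirichlet-multinomial with concentration
#'    `overdispersion * proportions`).
#'
#' @param params A [screen_sim_params()] object.
#' @param seed Integer seed; the simulation is reproducible given the
#'   seed.
#'
#' @return A list with components
#'   \describe{
#'     \item{counts}{data.frame with `guide_id`, `gene`, `is_nt` and one
#'       `high_repK` / `low_repK` integer column pair per replicate.}
#'     \item{truth}{data.frame with per-gene `gene`, `true_effect` and
#'       `is_null` labels.}
#'     \item{cells}{list of per-replicate diagnostics: mean cell size in
#'       each bin (used to check that residual gating removes size bias).}
#'   }
#' @examples
#' sim <- simulate_screen(screen_sim_params(n_genes = 20, n_nt_guides = 20,
#'                                          cells_per_guide = 50,
#'                                          reads_per_bin = 5e4), seed = 1)
#' head(sim$counts)
#' @export
simulate_screen <- function(params = screen_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "screen_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params

  genes <- sprintf("GENE%04d", seq_len(p$n_genes))
  guide_gene <- rep(genes, each = p$guides_per_gene)
  guide_id <- paste0(guide_gene, "_sg", rep(seq_len(p$guides_per_gene), p$n_genes))
  if (p$n_nt_guides > 0) {
    nt_id <- sprintf("NT_sg%04d", seq_len(p$n_nt_guides))
    guide_id <- c(guide_id, nt_id)
    guide_gene <- c(guide_gene, rep("non-targeting", p$n_nt_guides))
  }
  is_nt <- guide_gene == "non-targeting"
  n_guides <- length(guide_id)

  nonnull <- stats::runif(p$n_genes) < p$frac_nonnull
  magnitude <- stats::rnorm(p$n_genes, p$effect_mean, p$effect_sd)
  effect <- ifelse(nonnull, magnitude * sample(c(-1, 1), p$n_genes, replace = TRUE), 0)
  truth <- data.frame(gene = genes, true_effect = effect,
                      is_null = !nonnull, stringsAsFactors = FALSE)

  guide_effect <- c(rep(effect, each = p$guides_per_gene),
                    rep(0, p$n_nt_guides))

  n_cells <- n_guides * p$cells_per_guide
  n_bin <- floor(p$bin_fraction * n_cells)
  guide_of_cell <- rep.int(seq_len(n_guides), rep.int(p$cells_per_guide, n_guides))

  counts <- data.frame(guide_id = guide_id, gene = guide_gene,
                       is_nt = is_nt, stringsAsFactors = FALSE)
  cells_diag <- vector("list", p$n_reps)

  for (r in seq_len(p$n_reps)) {
    z <- guide_effect[guide_of_cell] + stats::rnorm(n_cells, 0, p$cell_noise_sd)
    size <- stats::rnorm(n_cells)
    y <- z + p$size_coupling_beta * size
    if (p$gate_on_residual) {
      # OLS residual of y on size; closed form avoids lm() on ~1e6 rows
      beta_hat <- stats::cov(y, size) / stats::var(size)
      score <- y - beta_hat * (size - mean(size)) - mean(y)
    } else {
      score <- y
    }
    ord <- order(score)
    lo_cells <- ord[seq_len(n_bin)]
    hi_cells <- ord[seq.int(n_cells - n_bin + 1L, n_cells)]

    hi_counts <- .sample_bin_reads(guide_of_cell[hi_cells], n_guides,
                                   p$reads_per_bin, p$overdispersion)
    lo_counts <- .sample_bin_reads(guide_of_cell[lo_cells], n_guides,
                                   p$reads_per_bin, p$overdispersion)
    counts[[paste0("high_rep", r)]] <- hi_counts
    counts[[paste0("low_rep", r)]] <- lo_counts
    cells_diag[[r]] <- list(mean_size_high = mean(size[hi_cells]),
                            mean_size_low = mean(size[lo_cells]))
  }

  list(counts = counts, truth = truth, cells = cells_diag)
}

# Sequencing depth model: multinomial over guide cell-frequencies in the
# bin, or Dirichlet-multinomial when a finite concentration is given.
.sample_bin_reads <- function(guide_idx, n_guides, depth, concentration) {
  cell_tab <- tabulate(guide_idx, nbins = n_guides)
  prob <- cell_tab / sum(cell_tab)
  if (is.finite(concentration)) {
    g <- stats::rgamma(n_guides, shape = concentration * prob)
    if (sum(g) == 0) g <- prob
    prob <- g / sum(g)
  }
  as.integer(stats::rmultinom(1, depth, prob))
}
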