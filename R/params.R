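#' Parameters for the sorted-bin screen simulator
#'
#' Bundles and validates the generative model behind [simulate_screen()].
#' Defaults describe a desk-scale pooled CRISPRi screen: 1,000 genes with
#' 5 guides each plus 500 non-targeting (NT) controls, two biological
#' replicates, quartile sorting, and sequencing depth of about 180 reads
#' per guide per bin.
#'
#' @param n_genes Number of gene targets in the library.
#' @param guides_per_gene Guides designed against each gene.
#' @param n_nt_guides Number of non-targeting control guides.
#' @param frac_nonnull Fraction of genes whose knockdown shifts the latent
#'   staining phenotype.
#' @param effect_mean Mean absolute shift (in units of `cell_noise_sd`) of
#'   a non-null gene's knockdown on the latent phenotype; the sign of each
#'   gene's effect is drawn at random.
#' @param effect_sd Between-gene standard deviation of the absolute shift.
#' @param cells_per_guide Cells carrying each guide at the sorter, per
#'   replicate.
#' @param size_coupling_beta Slope of observed log staining intensity on
#'   the standard-normal cell-size covariate. Non-zero values reproduce
#'   the size-intensity correlation that sorter gates must correct for.
#' @param cell_noise_sd Cell-to-cell standard deviation of the latent
#'   phenotype (also absorbs measurement noise on log intensity).
#' @param bin_fraction Fraction of gated cells collected into each of the
#'   high and low bins; 0.25 reproduces top/bottom-quartile sorting.
#' @param reads_per_bin Sequencing reads per sorted bin per replicate.
#' @param overdispersion Dirichlet concentration scaling for the count
#'   sampler; `Inf` (default) gives a plain multinomial over guides.
#' @param n_reps Number of biological replicates.
#' @param gate_on_residual Logical; if `TRUE` (default) cells are ranked
#'   on the residual of log intensity regressed on size, emulating
#'   size-corrected sort gates. `FALSE` ranks on raw intensity.
#'
#' @return An object of class `screen_sim_params` (a validated list).
#' @seealso [simulate_screen()]
#' @export
screen_sim_params <- function(n_genes = 1000,
                              guides_per_gene = 5,
                              n_nt_guides = 500,
                              frac_nonnull = 0.1,
                              effect_mean = 2,
                              effect_sd = 0,
                              cells_per_guide = 150,
                              size_coupling_beta = 0.5,
                              cell_noise_sd = 1,
                              bin_fraction = 0.25,
                              reads_per_bin = 1e6,
                              overdispersion = Inf,
                              n_reps = 2,
                              gate_on_residual = TRUE) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_nt_guides >= 0,
            cells_per_guide >= 1, n_reps >= 1)
  if (guides_per_gene < 1) stop("guides_per_gene must be at least 1")
  if (!(frac_nonnull >= 0 && frac_nonnull <= 1)) {
    stop("frac_nonnull must lie in [0, 1]")
  }
  if (!(bin_fraction > 0 && bin_fraction <= 0.5)) {
    stop("bin_fraction must lie in (0, 0.5]")
  }
  if (reads_per_bin <= 0) stop("reads_per_bin must be positive")
  if (cell_noise_sd <= 0) stop("cell_noise_sd must be positive")
  if (overdispersion <= 0) stop("overdispersion must be positive (Inf = multinomial)")
  structure(list(
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_nt_guides = as.integer(n_nt_guides),
    frac_nonnull = frac_nonnull,
    effect_mean = effect_mean,
    effect_sd = effect_sd,
    cells_per_guide = as.integer(cells_per_guide),
    size_coupling_beta = size_coupling_beta,
    cell_noise_sd = cell_noise_sd,
    bin_fraction = bin_fraction,
    reads_per_bin = as.integer(reads_per_bin),
    overdispersion = overdispersion,
    n_reps = as.integer(n_reps),
    gate_on_residual = isTRUE(gate_on_residual)
  ), class = "screen_sim_params")
}

#' Parameters for the lipidome simulator
#'
#' Describes a panel of lipid classes whose species' log-abundances are
#' linearly coupled to a perturbation-level aggregation phenotype, as in a
#' lipidomics experiment across knockdowns of lipid-related genes.
#' Defaults mimic a panel where sphingomyelins (SM) and cholesterol esters
#' (CE) track the phenotype strongly while ceramide-family classes do not.
#'
#' @param n_perturbations Number of perturbations (e.g. gene knockdowns)
#'   profiled; must be at least 3 for downstream regression.
#' @param classes A data.frame with columns `class` (name), `n_species`
#'   (>= 2), `gamma` (class-level coupling of log-abundance to the
#'   phenotype) and `jitter_sd` (species-level spread of the coupling).
#' @param noise_sd Residual standard deviation of species log-abundance.
#' @param phenotype_mean,phenotype_sd Normal distribution of the
#'   perturbation phenotype (log relative aggregation signal).
#'
#' @return An object of class `lipid_sim_params`.
#' @seealso [simulate_lipidome()]
#' @export
lipid_sim_params <- function(n_perturbations = 12,
                             classes = default_lipid_classes(),
                             noise_sd = 0.4,
                             phenotype_mean = 0,
                             phenotype_sd = 1) {
  classes <- as.data.frame(classes)
  req <- c("class", "n_species", "gamma", "jitter_sd")
  miss <- setdiff(req, names(classes))
  if (length(miss)) {
    stop("classes is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (n_perturbations < 3) {
    stop("n_perturbations must be at least 3 (R^2 undefined below)")
  }
  if (any(classes$n_species < 2)) stop("each class needs n_species >= 2")
  if (anyDuplicated(classes$class)) stop("duplicated class names")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(
    n_perturbations = as.integer(n_perturbations),
    classes = classes,
    noise_sd = noise_sd,
    phenotype_mean = phenotype_mean,
    phenotype_sd = phenotype_sd
  ), class = "lipid_sim_params")
}

#' Default lipid-class panel for simulation
#'
#' Five classes patterned on the study system: SM and CE strongly coupled
#' to the aggregation phenotype, ceramides (Cer), lactosylceramides
#' (LacCer) and hexosylceramides (HexCer) nearly uncoupled.
#'
#' @return data.frame with columns class, n_species, gamma, jitter_sd.
#' @export
default_lipid_classes <- function() {
  data.frame(
    class = c("SM", "CE", "Cer", "LacCer", "HexCer"),
    n_species = c(12L, 15L, 18L, 6L, 8L),
    gamma = c(1.0, 0.8, 0.15, 0.1, 0.1),
    jitter_sd = c(0.15, 0.15, 0.1, 0.1, 0.1)
  )
}
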