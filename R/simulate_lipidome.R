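#' Simulate a lipidomics panel coupled to an aggregation phenotype
#'
#' Generates a species-by-perturbation matrix of log lipid abundances
#' (relative to a non-targeting control) in which each species' abundance
#' is linearly coupled to a perturbation-level phenotype with
#' class-structured coupling strength:
#'
#' \deqn{x_{sj} = \alpha_s + \gamma_s \cdot \mathrm{phenotype}_j +
#'   N(0, \sigma_{noise}), \qquad \gamma_s \sim N(\gamma_{class(s)},
#'   \mathrm{jitter})}
#'
#' The phenotype plays the role of the mean ProteoStat signal of each
#' perturbation, and abundances emulate triplicate-averaged, NT-normalized
#' log values.
#'
#' @param params A [lipid_sim_params()] object.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list with components
#'   \describe{
#'     \item{lipids}{data.frame `species_id`, `class`, then one numeric
#'       column per perturbation (log abundance).}
#'     \item{phenotype}{data.frame `perturbation`, `phenotype`.}
#'     \item{truth}{data.frame of species-level couplings `species_id`,
#'       `class`, `gamma`, plus attribute-free class-level gamma in
#'       `params$classes`.}
#'   }
#' @examples
#' sim <- simulate_lipidome(lipid_sim_params(), seed = 7)
#' sim$lipids[1:3, 1:5]
#' @export
simulate_lipidome <- function(params = lipid_sim_params(), seed = NULL) {
  stopifnot(inherits(params, "lipid_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params

  perturbations <- sprintf("KD%02d", seq_len(p$n_perturbations))
  phenotype <- stats::rnorm(p$n_perturbations, p$phenotype_mean, p$phenotype_sd)

  cls <- p$classes
  species_class <- rep(cls$class, cls$n_species)
  species_id <- unlist(lapply(seq_len(nrow(cls)), function(i) {
    sprintf("%s(%02d:0)", cls$class[i], seq_len(cls$n_species[i]))
  }), use.names = FALSE)
  n_species <- length(species_id)

  gamma_s <- stats::rnorm(n_species,
                          mean = rep(cls$gamma, cls$n_species),
                          sd = rep(cls$jitter_sd, cls$n_species))
  alpha_s <- stats::rnorm(n_species, 0, 0.5)

  mat <- outer(gamma_s, phenotype) + alpha_s +
    matrix(stats::rnorm(n_species * p$n_perturbations, 0, p$noise_sd),
           n_species, p$n_perturbations)
  colnames(mat) <- perturbations

  lipids <- cbind(
    data.frame(species_id = species_id, class = species_class,
               stringsAsFactors = FALSE),
    as.data.frame(mat)
  )
  list(
    lipids = lipids,
    phenotype = data.frame(perturbation = perturbations,
                           phenotype = phenotype,
                           stringsAsFactors = FALSE),
    truth = data.frame(species_id = species_id, class = species_class,
                       gamma = gamma_s, stringsAsFactors = FALSE)
  )
}
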