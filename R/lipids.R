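#' Least-squares fit of one lipid species against the phenotype
#'
#' Ordinary least squares of log lipid abundance on the perturbation
#' phenotype, with intercept. The coefficient of determination equals the
#' squared Pearson correlation for this simple regression.
#'
#' @param abundance Numeric vector of log abundances over perturbations.
#' @param phenotype Numeric vector of the same length (>= 3).
#' @return List with `slope`, `intercept`, `r2`.
#' @examples
#' lipid_r2(c(1, 3, 5, 7), c(0, 1, 2, 3))$r2   # exact line -> 1
#' @export
lipid_r2 <- function(abundance, phenotype) {
  if (length(abundance) != length(phenotype)) {
    stop("abundance and phenotype lengths differ")
  }
  if (length(abundance) < 3) stop("need at least 3 perturbations")
  if (any(!is.finite(abundance)) || any(!is.finite(phenotype))) {
    stop("non-finite values")
  }
  if (stats::var(phenotype) == 0) stop("phenotype is constant")
  if (stats::var(abundance) == 0) {
    warning("constant abundance; R^2 set to 0")
    return(list(slope = 0, intercept = mean(abundance), r2 = 0))
  }
  sxy <- stats::cov(phenotype, abundance)
  sxx <- stats::var(phenotype)
  slope <- sxy / sxx
  intercept <- mean(abundance) - slope * mean(phenotype)
  r2 <- sxy^2 / (sxx * stats::var(abundance))
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Fit every lipid species against the phenotype
#'
#' Runs [lipid_r2()] for each species row of a lipid table, optionally on
#' a named subset of perturbations (e.g. the core lipid-related
#' knockdowns).
#'
#' @param lipids data.frame `species_id`, `class`, then one numeric
#'   column per perturbation.
#' @param phenotype data.frame `perturbation`, `phenotype`.
#' @param subset Optional character vector of perturbation ids to
#'   restrict the fit to.
#' @return data.frame `species_id`, `class`, `slope`, `intercept`, `r2`.
#' @export
fit_all_lipids <- function(lipids, phenotype, subset = NULL) {
  perts <- setdiff(names(lipids), c("species_id", "class"))
  if (!all(perts %in% phenotype$perturbation)) {
    stop("perturbation ids in lipid table and phenotype do not match")
  }
  if (!is.null(subset)) {
    missing <- setdiff(subset, perts)
    if (length(missing)) {
      stop("subset perturbations absent from table: ",
           paste(missing, collapse = ", "))
    }
    perts <- subset
  }
  ph <- phenotype$phenotype[match(perts, phenotype$perturbation)]
  fits <- lapply(seq_len(nrow(lipids)), function(i) {
    lipid_r2(as.numeric(lipids[i, perts]), ph)
  })
  data.frame(
    species_id = lipids$species_id,
    class = lipids$class,
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    intercept = vapply(fits, `[[`, numeric(1), "intercept"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    stringsAsFactors = FALSE
  )
}

#' Lipid-class enrichment of association strength (two-sample K-S)
#'
#' For each lipid class, compares the distribution of its species' R^2
#' values against the R^2 values of all lipids with a two-sided
#' two-sample Kolmogorov-Smirnov test. Following the study design, the
#' reference sample includes the class's own members; set
#' `exclusive_reference = TRUE` for the class-vs-rest variant. Because
#' the class overlaps the inclusive reference, between-sample ties always
#' exist and the textbook exact K-S distribution does not apply; instead,
#' when the class is small (`min(n1, n_ref) <= 10`), values are tie-free
#' and the enumeration is tractable, the exact permutation p-value is
#' computed by enumerating all possible class label assignments.
#' Otherwise the asymptotic two-sample p-value is used.
#'
#' @param fits data.frame from [fit_all_lipids()] (`class`, `r2`).
#' @param exclusive_reference Compare each class against all other
#'   lipids instead of all lipids (default FALSE).
#' @param max_enumeration Upper bound on `choose(N, n1)` for the exact
#'   path (default 1e5).
#' @return data.frame `class`, `n_species`, `ks_d`, `p`, `method`;
#'   classes with fewer than 2 species are skipped with a warning.
#' @export
class_ks <- function(fits, exclusive_reference = FALSE,
                     max_enumeration = 1e5) {
  classes <- unique(fits$class)
  res <- lapply(classes, function(cl) {
    x <- fits$r2[fits$class == cl]
    if (length(x) < 2) {
      warning("class ", cl, " has fewer than 2 species; skipped")
      return(NULL)
    }
    ref <- if (exclusive_reference) fits$r2[fits$class != cl] else fits$r2
    d <- .ks_d(x, ref)
    n1 <- length(x)
    n_ref <- length(ref)
    exact_ok <- !exclusive_reference &&
      min(n1, n_ref) <= 10 &&
      !anyDuplicated(fits$r2) &&
      choose(n_ref, n1) <= max_enumeration
    if (exact_ok) {
      p <- .ks_exact_subset_p(x, ref, d)
      method <- "exact-enumeration"
    } else {
      # asymptotic two-sample K-S (ties broken asymptotically by design)
      p <- suppressWarnings(
        stats::ks.test(x, ref, exact = FALSE)$p.value
      )
      method <- "asymptotic"
    }
    data.frame(class = cl, n_species = n1, ks_d = d, p = p,
               method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Two-sample K-S statistic D = sup |ECDF_x - ECDF_y|, evaluated on the
# pooled support (handles overlapping samples).
.ks_d <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

# Exact permutation p for a class-vs-all comparison: under the null the
# class labels are exchangeable across all N species, so enumerate every
# subset of size n1 as the class and count D at least as large.
.ks_exact_subset_p <- function(x, ref, d_obs) {
  n1 <- length(x)
  combos <- utils::combn(length(ref), n1)
  d_all <- apply(combos, 2, function(idx) .ks_d(ref[idx], ref))
  mean(d_all >= d_obs - 1e-12)
}
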