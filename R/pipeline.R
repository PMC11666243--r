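#' Run the full analysis pipeline from a configuration
#'
#' Drives simulate -> normalize -> gene statistics -> hit calling ->
#' prerank score -> GSEA and/or the lipidomic association stage from a
#' single configuration, writing all stage outputs, a log of seeds and
#' parameters, and a machine-readable JSON summary into `out_dir`.
#' Re-running with an identical configuration and seed reproduces every
#' output byte-for-byte.
#'
#' @param config Either a path to a YAML file or a named list with
#'   elements:
#'   \describe{
#'     \item{stages}{character subset of `c("screen", "lipids")`.}
#'     \item{seed}{integer master seed (default 1).}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{screen}{optional list of [screen_sim_params()] arguments,
#'       plus `n_perm`, `alpha`, `gmt` (path to a gene-set file; GSEA
#'       runs only when present) and `gsea_n_perm`.}
#'     \item{lipids}{optional list of [lipid_sim_params()] arguments
#'       (with `classes` as a data.frame or list of lists) plus
#'       `core_subset` (perturbation ids).}
#'   }
#' @return Invisibly, a list with the summary (also written to
#'   `summary.json`) and the paths of written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NULL
  }
  stages <- config$stages
  if (is.null(stages)) stages <- c("screen", "lipids")
  bad <- setdiff(stages, c("screen", "lipids"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "aggscreen_out" else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  # hash the analysis-relevant configuration (paths excluded, so reruns
  # in a different directory are recognizably the same analysis)
  hash_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(hash_file), add = TRUE)
  yaml::write_yaml(config[setdiff(names(config), "out_dir")], hash_file)
  config_hash <- unname(tools::md5sum(hash_file))

  log_lines <- c(
    paste0("aggscreen pipeline | config md5 ", config_hash),
    paste0("seed: ", seed),
    paste0("stages: ", paste(stages, collapse = ", "))
  )
  files <- character(0)
  summary <- list(config_hash = config_hash, seed = seed)

  if ("screen" %in% stages) {
    sc <- config$screen
    n_perm <- if (is.null(sc$n_perm)) 10000L else as.integer(sc$n_perm)
    alpha <- if (is.null(sc$alpha)) 0.05 else sc$alpha
    gmt <- sc$gmt
    gsea_n_perm <- if (is.null(sc$gsea_n_perm)) 1000L else as.integer(sc$gsea_n_perm)
    sim_args <- sc[setdiff(names(sc),
                           c("n_perm", "alpha", "gmt", "gsea_n_perm"))]
    params <- do.call(screen_sim_params, sim_args)

    sim <- tryCatch(simulate_screen(params, seed = seed),
                    error = function(e) stop("stage screen (simulate): ",
                                             conditionMessage(e)))
    norm <- normalize_counts(sim$counts)
    lfcs <- guide_lfc(norm)
    stats <- gene_stats(lfcs, n_perm = n_perm, seed = seed + 1L)
    stats <- volcano_hit_call(stats, alpha = alpha)
    scores <- prerank_score(stats, fdr_floor = 1 / (n_perm + 1))

    files["counts"] <- write_counts(sim$counts,
                                    file.path(out_dir, "screen_counts.tsv"))
    files["truth"] <- write_results(sim$truth,
                                    file.path(out_dir, "screen_truth.tsv"))
    files["gene_stats"] <- write_results(
      cbind(stats, score = scores$score),
      file.path(out_dir, "gene_stats.tsv"))

    hits <- count_fdr_hits(stats, alpha)
    summary$screen <- list(
      n_genes = nrow(stats),
      hits_up = unname(hits["up"]),
      hits_down = unname(hits["down"]),
      volcano_hits = sum(stats$hit != "none")
    )
    log_lines <- c(log_lines,
                   sprintf("screen: %d genes, n_perm=%d, alpha=%g",
                           nrow(stats), n_perm, alpha))

    if (!is.null(gmt)) {
      sets <- read_gmt(gmt)
      gsea <- gsea_prerank(scores, sets, n_perm = gsea_n_perm,
                           seed = seed + 2L)
      files["gsea"] <- write_results(gsea, file.path(out_dir, "gsea.tsv"))
      summary$screen$top_set <- gsea$set[1]
      summary$screen$top_set_fdr <- gsea$fdr[1]
      log_lines <- c(log_lines,
                     sprintf("gsea: %d sets, n_perm=%d", nrow(gsea),
                             gsea_n_perm))
    }
  }

  if ("lipids" %in% stages) {
    lc <- config$lipids
    core_subset <- lc$core_subset
    sim_args <- lc[setdiff(names(lc), "core_subset")]
    if (!is.null(sim_args$classes) && !is.data.frame(sim_args$classes)) {
      sim_args$classes <- do.call(rbind, lapply(sim_args$classes,
                                                as.data.frame))
    }
    params <- do.call(lipid_sim_params, sim_args)
    sim <- tryCatch(simulate_lipidome(params, seed = seed + 10L),
                    error = function(e) stop("stage lipids (simulate): ",
                                             conditionMessage(e)))
    fits <- fit_all_lipids(sim$lipids, sim$phenotype, subset = core_subset)
    ks <- class_ks(fits)

    files["lipids"] <- write_results(sim$lipids,
                                     file.path(out_dir, "lipid_table.tsv"))
    files["lipid_fits"] <- write_results(fits,
                                         file.path(out_dir, "lipid_fits.tsv"))
    files["class_ks"] <- write_results(ks, file.path(out_dir,
                                                     "lipid_class_ks.tsv"))
    best <- ks[which.min(ks$p), ]
    summary$lipids <- list(
      n_species = nrow(fits),
      max_r2_by_class = stats::setNames(
        as.list(vapply(split(fits$r2, fits$class), max, numeric(1))),
        names(split(fits$r2, fits$class))),
      best_class = best$class,
      best_class_p = best$p
    )
    log_lines <- c(log_lines,
                   sprintf("lipids: %d species, %d classes", nrow(fits),
                           nrow(ks)))
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(summary = summary, files = files,
                 summary_path = summary_path))
}
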