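test_that("ES matches the exhaustive running-sum oracle on random instances", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    k <- sample(2:min(10, n - 1), 1)
    scores <- data.frame(gene = sprintf("g%03d", 1:n),
                         score = rnorm(n), stringsAsFactors = FALSE)
    members <- sample(scores$gene, k)
    res <- gsea_prerank(scores, list(s = members), n_perm = 10,
                        min_size = 2, seed = 1)
    ord <- order(-scores$score, scores$gene)
    hit_pos <- which(scores$gene[ord] %in% members)
    es_oracle <- oracle_gsea_es(abs(scores$score[ord]), hit_pos)
    expect_equal(res$es, es_oracle, tolerance = 1e-9)
  }
})

test_that("ES agrees with fgsea's running-sum statistic", {
  skip_if_not_installed("fgsea")
  set.seed(78)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    k <- sample(3:10, 1)
    scores <- data.frame(gene = sprintf("g%03d", 1:n),
                         score = rnorm(n), stringsAsFactors = FALSE)
    members <- sample(scores$gene, k)
    res <- gsea_prerank(scores, list(s = members), n_perm = 10,
                        min_size = 2, seed = 1)
    ord <- order(-scores$score, scores$gene)
    ref <- fgsea::calcGseaStat(
      stats = abs(scores$score[ord]),
      selectedStats = which(scores$gene[ord] %in% members),
      gseaParam = 1, scoreType = "std")
    expect_equal(res$es, ref, tolerance = 1e-9)
  }
})

test_that("hand-computed ES for a 10-gene list with a 2-gene top set", {
  scores <- data.frame(gene = sprintf("g%02d", 1:10),
                       score = c(5, 5, rep(1, 8)) * c(1, 1, rep(-1, 8)))
  # equal |scores| at ranks 1,2: running sum peaks after the second hit
  res <- gsea_prerank(scores, list(top = c("g01", "g02")), n_perm = 10,
                      min_size = 2, seed = 1)
  expect_equal(res$es, 1)  # both hits before any miss -> max deviation 1

  # and a non-trivial placement: hits at ranks 1 and 4, equal weights
  scores2 <- data.frame(gene = sprintf("g%02d", 1:10),
                        score = seq(10, 1))
  res2 <- gsea_prerank(scores2, list(s = c("g01", "g04")), n_perm = 10,
                       min_size = 2, seed = 1)
  w <- c(10, 7) / 17
  running <- cumsum(c(w[1], -1/8, -1/8, w[2], rep(-1/8, 6)))
  expect_equal(res2$es, running[which.max(abs(running))], tolerance = 1e-12)
})

test_that("flipping all score signs negates each set's ES", {
  set.seed(80)
  scores <- data.frame(gene = sprintf("g%03d", 1:40), score = rnorm(40))
  sets <- list(a = sample(scores$gene, 6), b = sample(scores$gene, 8))
  res <- gsea_prerank(scores, sets, n_perm = 10, seed = 2)
  flipped <- scores
  flipped$score <- -scores$score
  res_f <- gsea_prerank(flipped, sets, n_perm = 10, seed = 2)
  res_f <- res_f[match(res$set, res_f$set), ]
  expect_equal(res_f$es, -res$es, tolerance = 1e-12)
})

test_that("iid null scores give |NES| near 1", {
  set.seed(81)
  scores <- data.frame(gene = sprintf("g%03d", 1:200), score = rnorm(200))
  sets <- lapply(1:10, function(i) sample(scores$gene, 15))
  names(sets) <- paste0("s", 1:10)
  res <- gsea_prerank(scores, sets, n_perm = 200, seed = 3)
  expect_equal(mean(abs(res$nes)), 1, tolerance = 0.25)
})

test_that("a coherent up-regulon attains the best FDR among candidate sets", {
  wins <- 0
  eligible <- 0
  for (s in 1:20) {
    sim <- simulate_screen(
      screen_sim_params(n_genes = 80, guides_per_gene = 5,
                        n_nt_guides = 80, cells_per_guide = 100,
                        reads_per_bin = 2e5, frac_nonnull = 0.2,
                        effect_mean = 2), seed = 100 + s)
    st <- gene_stats(guide_lfc(normalize_counts(sim$counts)),
                     n_perm = 1000, seed = 200 + s)
    sc <- prerank_score(st, fdr_floor = 1 / 1001)
    regulon <- sim$truth$gene[sim$truth$true_effect > 0]
    if (length(regulon) < 5) next
    eligible <- eligible + 1
    set.seed(300 + s)
    decoys <- lapply(1:5, function(i) sample(st$gene, length(regulon)))
    sets <- c(list(regulon = regulon), setNames(decoys, paste0("d", 1:5)))
    res <- gsea_prerank(sc, sets, n_perm = 200, seed = 400 + s)
    if (res$fdr[res$set == "regulon"] <= min(res$fdr)) wins <- wins + 1
  }
  expect_gte(eligible, 15)
  expect_gte(wins / eligible, 0.9)  # 95% target with small-sample slack
})

test_that("set filtering and degenerate sets are handled", {
  scores <- data.frame(gene = sprintf("g%02d", 1:10), score = 10:1)
  expect_error(gsea_prerank(scores, list(all = scores$gene), min_size = 2),
               "covering every scored gene")
  expect_error(gsea_prerank(scores, list(tiny = c("g01", "g02"))),
               "min_size")
  expect_error(gsea_prerank(scores, list(none = c("zz1", "zz2")),
                            min_size = 2), "min_size")
})
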