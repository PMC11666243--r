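test_that("lipid R^2 matches closed-form special cases and the moment oracle", {
  x <- c(0, 1, 2, 3)
  fit <- lipid_r2(2 * x + 1, x)
  expect_equal(fit$r2, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  # orthogonal construction -> r = 0
  expect_equal(lipid_r2(c(1, -2, 1), c(-1, 0, 1))$r2, 0)

  set.seed(55)
  for (i in 1:10) {
    a <- rnorm(8)
    ph <- rnorm(8)
    expect_equal(lipid_r2(a, ph)$r2, oracle_r2(ph, a), tolerance = 1e-12)
  }
})

test_that("R^2 is symmetric and invariant to affine transforms", {
  set.seed(56)
  a <- rnorm(10)
  ph <- rnorm(10)
  expect_equal(lipid_r2(a, ph)$r2, lipid_r2(ph, a)$r2, tolerance = 1e-12)
  expect_equal(lipid_r2(3 * a + 2, ph)$r2, lipid_r2(a, ph)$r2,
               tolerance = 1e-12)
  expect_equal(lipid_r2(a, -0.5 * ph + 1)$r2, lipid_r2(a, ph)$r2,
               tolerance = 1e-12)
})

test_that("degenerate regressions error or warn as documented", {
  expect_error(lipid_r2(1:3, c(1, 1, 1)), "constant")
  expect_warning(fit <- lipid_r2(c(2, 2, 2), 1:3), "constant abundance")
  expect_equal(fit$r2, 0)
  expect_error(lipid_r2(1:2, 1:2), "at least 3")
  expect_error(lipid_r2(1:4, 1:3), "lengths differ")
})

test_that("fit_all_lipids is consistent with per-species fits and subsetting", {
  sim <- simulate_lipidome(lipid_sim_params(), seed = 61)
  fits <- fit_all_lipids(sim$lipids, sim$phenotype)
  expect_equal(nrow(fits), nrow(sim$lipids))

  # identical rows give identical R^2
  lip2 <- sim$lipids[c(1, 1), ]
  lip2$species_id <- c("s1", "s2")
  f2 <- fit_all_lipids(lip2, sim$phenotype)
  expect_equal(f2$r2[1], f2$r2[2])

  # subsetting recomputes on the subset only
  sub <- sim$phenotype$perturbation[1:5]
  fs <- fit_all_lipids(sim$lipids, sim$phenotype, subset = sub)
  manual <- lipid_r2(as.numeric(sim$lipids[1, sub]),
                     sim$phenotype$phenotype[1:5])
  expect_equal(fs$r2[1], manual$r2, tolerance = 1e-12)

  bad_ph <- sim$phenotype
  bad_ph$perturbation[1] <- "nope"
  expect_error(fit_all_lipids(sim$lipids, bad_ph), "do not match")
  expect_error(fit_all_lipids(sim$lipids, sim$phenotype, subset = "zzz"),
               "absent")
})

test_that("class K-S follows the inclusive-reference contract", {
  # class identical to the whole table -> D = 0, p = 1
  fits <- data.frame(species_id = paste0("s", 1:6),
                     class = rep("A", 6),
                     r2 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  res <- class_ks(fits)
  expect_equal(res$ks_d, 0)
  expect_equal(res$p, 1)

  # the spec's worked 2-vs-5 case against full enumeration
  fits2 <- data.frame(
    species_id = paste0("s", 1:5),
    class = c("other", "other", "other", "hot", "hot"),
    r2 = c(0.1, 0.2, 0.3, 0.90, 0.95))
  res2 <- class_ks(fits2)
  hot <- res2[res2$class == "hot", ]
  expect_equal(hot$method, "exact-enumeration")
  expect_equal(hot$p,
               oracle_ks_exact_p(c(0.90, 0.95), fits2$r2))

  # stochastic dominance: the uniformly larger class has the smaller p
  fits3 <- data.frame(
    species_id = paste0("s", 1:20),
    class = rep(c("hi", "lo"), each = 10),
    r2 = c(seq(0.8, 0.98, length.out = 10), seq(0.01, 0.2, length.out = 10)))
  res3 <- class_ks(fits3)
  expect_lt(max(res3$p), 0.2)
  expect_equal(res3$p[res3$class == "hi"], res3$p[res3$class == "lo"],
               tolerance = 1e-9)  # symmetric split is symmetric

  # classes with < 2 members are skipped with a warning
  fits4 <- rbind(fits2, data.frame(species_id = "s6", class = "solo",
                                   r2 = 0.5))
  expect_warning(res4 <- class_ks(fits4), "solo")
  expect_false("solo" %in% res4$class)
})

test_that("exclusive reference excludes the class's own members", {
  fits <- data.frame(species_id = paste0("s", 1:5),
                     class = c("a", "a", "b", "b", "b"),
                     r2 = c(0.9, 0.95, 0.1, 0.2, 0.3))
  inc <- class_ks(fits)
  exc <- class_ks(fits, exclusive_reference = TRUE)
  # excluding the class makes the contrast sharper
  expect_gte(exc$ks_d[exc$class == "a"], inc$ks_d[inc$class == "a"])
  expect_equal(exc$ks_d[exc$class == "a"], 1)  # disjoint supports
})

test_that("null K-S calibration stays within twice the nominal rate", {
  classes <- data.frame(class = paste0("c", 1:5),
                        n_species = rep(10L, 5),
                        gamma = rep(0, 5), jitter_sd = rep(0, 5))
  n_tests <- 0
  n_sig <- 0
  for (s in 1:40) {
    sim <- simulate_lipidome(
      lipid_sim_params(n_perturbations = 10, classes = classes), seed = s)
    fits <- fit_all_lipids(sim$lipids, sim$phenotype)
    res <- class_ks(fits)
    n_tests <- n_tests + nrow(res)
    n_sig <- n_sig + sum(res$p < 0.05)
  }
  expect_lte(n_sig / n_tests, 0.10)  # conservatism tolerated, inflation not
})
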