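# eco_diversity: functional distances, TD/FD/FR, f_prabs, regressions, model

test_that("weighted_jaccard matches hand computations and errors on zero rows", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), d = c(0, 0, 0.0))
  colnames(m) <- paste0("f", 1:3)
  m["d", 1] <- 0 # keep an all-zero row
  g <- gene_content(m)
  expect_equal(weighted_jaccard(g, "a", "c"), 0)        # identical rows
  expect_equal(weighted_jaccard(g, "a", "b"), 2 / 3)    # 1 - 1/3
  expect_error(weighted_jaccard(g, "a", "d"), "all-zero")
  # disjoint supports -> 1
  g2 <- gene_content(matrix(c(2, 3, 0, 0, 0, 0, 1, 5), 2, 4, byrow = TRUE,
                              dimnames = list(c("x", "y"), paste0("f", 1:4))))
  expect_equal(weighted_jaccard(g2, "x", "y"), 1)
})

test_that("functional_distance_matrix equals the pairwise definition", {
  set.seed(4)
  m <- matrix(rpois(8 * 15, 1.5), 8, 15,
              dimnames = list(paste0("t", 1:8), paste0("f", 1:15)))
  m[rowSums(m) == 0, 1] <- 1
  g <- gene_content(m)
  D <- functional_distance_matrix(g)
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(D[i, j], weighted_jaccard(g, paste0("t", i), paste0("t", j)))
  }
  expect_equal(unname(diag(D)), rep(0, 8))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  # triangle inequality of the Jaccard distance on binary data (spot check)
  Db <- functional_distance_matrix(g, binarize = TRUE)
  set.seed(9)
  for (k in 1:25) {
    ijk <- sample(8, 3)
    expect_lte(Db[ijk[1], ijk[3]],
               Db[ijk[1], ijk[2]] + Db[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("TD double-sum form equals 1 - sum(p^2)", {
  set.seed(2)
  p <- rgamma(50, 1); p <- p / sum(p)
  double_sum <- sum(outer(p, p)) - sum(p^2)
  expect_equal(taxonomic_diversity(p), double_sum, tolerance = 1e-12)
  expect_equal(taxonomic_diversity(1), 0)
  expect_equal(taxonomic_diversity(c(0.5, 0.5)), 0.5)
})

test_that("FD limits, hand case, and the FR identity", {
  p <- c(a = 0.5, b = 0.5)
  d1 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  d0 <- d1 * 0
  dh <- d1 * 0.5
  TD <- taxonomic_diversity(p)
  expect_equal(functional_diversity(p, d1), TD)           # d = 1 -> FD = TD
  expect_equal(functional_diversity(p, d0), 0)            # full redundancy
  expect_equal(functional_diversity(p, dh), 0.25)         # 2 * 0.25 * 0.5
  expect_equal(functional_redundancy(TD, functional_diversity(p, dh)), 0.25)
  expect_error(functional_redundancy(0.3, 0.4), "FD exceeds TD")
  expect_error(functional_diversity(c(a = 0.5, z = 0.5), d1), "missing")
})

test_that("FR identity and 0 <= FD <= TD hold on random compositions and GCNs", {
  for (r in 1:40) {
    cfg <- simulation_config(n_taxa = 12, n_gene_families = 60,
                             gcn_core_fraction = runif(1, 0, 0.8),
                             seed = 1000L + r)
    D <- functional_distance_matrix(generate_gcn(cfg))
    set.seed(2000L + r)
    p <- setNames(rgamma(12, 0.7), rownames(D)); p <- p / sum(p)
    TD <- taxonomic_diversity(p)
    FD <- functional_diversity(p, D)
    expect_gte(FD, 0)
    expect_lte(FD, TD + 1e-12)
    expect_equal(functional_redundancy(TD, FD), TD - FD, tolerance = 1e-12)
  }
})

test_that("fraction_prabs covers both modes and error cases", {
  p <- setNames(c(rep(0.1, 10)), paste0("t", 1:10))
  expect_equal(fraction_prabs(p, paste0("t", 1:3), "presence"), 0.3)
  expect_equal(fraction_prabs(p, "absent_taxon", "presence"), 0)
  expect_equal(fraction_prabs(p, "absent_taxon", "abundance"), 0)
  q <- c(a = 0.2, b = 0.05, c = 0.75)
  expect_equal(fraction_prabs(q, c("a", "b"), "abundance"), 0.25)
  expect_error(fraction_prabs(setNames(0.4, "a"), "a", "presence",
                              presence_threshold = 0.5), "no taxon above")
})

test_that("diversity_profiles enforces GCN coverage and computes t_post", {
  sim <- generate_cohorts(simulation_config(n_cohorts = 1,
                                            subjects_per_cohort = 6, seed = 44))
  gcn_full <- generate_gcn(simulation_config(seed = 44))
  pr <- diversity_profiles(sim$table, gcn_full, sim$planted, abx_end_day = 7)
  expect_equal(pr$FR, pr$TD - pr$FD, tolerance = 1e-12)
  expect_true(all(pr$FD <= pr$TD + 1e-12 & pr$FD >= 0))
  post <- pr$timepoint == "post"
  expect_true(all(is.na(pr$t_post[!post])))
  expect_equal(pr$t_post[post], pr$day[post] - 7)

  # taxa missing from the GCN: hard error, or renormalized restriction
  gcn_small <- gene_content(gcn_full$values[1:50, ])
  expect_error(diversity_profiles(sim$table, gcn_small, sim$planted), "sp051")
  pr2 <- suppressMessages(
    diversity_profiles(sim$table, gcn_small, sim$planted, restrict_to_gcn = TRUE))
  expect_equal(pr2$FR, pr2$TD - pr2$FD, tolerance = 1e-12)
})

test_that("regress_fprabs recovers exact coefficients and is calibrated", {
  set.seed(6)
  n <- 40
  t_post <- runif(n, 1, 60)
  TD <- runif(n, 0.3, 0.9)
  prof <- data.frame(f_prabs_presence = 0.1 + 0.02 * t_post + 0.5 * TD,
                     f_prabs_abundance = runif(n),
                     TD = TD, FD = TD * 0.8, FR = TD * 0.2, t_post = t_post)
  fit <- suppressWarnings(regress_fprabs(prof, "presence", "TD")) # perfect fit
  expect_equal(unname(fit$coefficients[, "Estimate"]), c(0.1, 0.02, 0.5),
               tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-12)
  expect_error(regress_fprabs(prof[1, ], "presence", "TD"), "at least 10")
  expect_error(regress_fprabs(transform(prof, TD = 0.5), "presence", "TD"),
               "constant")

  # null calibration: F-test rejects ~5% under pure noise
  rej <- vapply(1:500, function(r) {
    set.seed(r)
    d <- data.frame(f_prabs_presence = runif(30), f_prabs_abundance = 0,
                    TD = runif(30), FD = 0, FR = 0, t_post = runif(30, 1, 50))
    regress_fprabs(d, "presence", "TD")$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("predict_recovery reproduces the packaged equation", {
  m <- recovery_model()
  expect_equal(predict_recovery(m, 0, 0, 0)$y, -0.8204)
  expect_equal(predict_recovery(m, 1, 0, 0)$y - predict_recovery(m, 0, 0, 0)$y,
               0.4571)
  expect_equal(predict_recovery(m, 0, 1, 0)$y - predict_recovery(m, 0, 0, 0)$y,
               0.7309)
  expect_equal(predict_recovery(m, 0, 0, 1)$y - predict_recovery(m, 0, 0, 0)$y,
               0.4465)
  expect_equal(predict_recovery(m, 1, 1, 1)$y, 0.8141)
  # probability strictly increasing in each coordinate
  base <- predict_recovery(m, 0.3, 0.5, 0.2)$probability
  expect_gt(predict_recovery(m, 0.4, 0.5, 0.2)$probability, base)
  expect_gt(predict_recovery(m, 0.3, 0.6, 0.2)$probability, base)
  expect_gt(predict_recovery(m, 0.3, 0.5, 0.3)$probability, base)
})

test_that("fit_recovery_model: nulls, separability and the ridge fallback", {
  set.seed(8)
  n <- 400
  FD <- runif(n); TD <- runif(n); f <- runif(n)
  # shuffled labels -> AUC ~ 0.5
  y0 <- rbinom(n, 1, 0.5)
  fit0 <- fit_recovery_model(FD, TD, f, y0, n_repeats = 3, seed = 5)
  expect_lt(abs(fit0$auc_mean - 0.5), 0.08)
  # deterministic labels -> separable; ridge fallback flags and AUC = 1
  y1 <- as.numeric(TD > 0.5)
  fit1 <- fit_recovery_model(FD, TD, f, y1, n_repeats = 2, seed = 5)
  expect_true(fit1$ridged)
  # the finite ridge keeps a boundary point or two near 0.5, so the
  # cross-validated AUC sits a fraction of a percent below the ideal 1
  expect_equal(fit1$auc_mean, 1, tolerance = 1e-2)
})

test_that("correlate_predictors handles exact, constant and monotone cases", {
  set.seed(10)
  n <- 30
  prof <- data.frame(FD = runif(n), f_prabs_abundance = runif(n))
  prof$TD <- prof$FD                      # exact equality -> correlation 1
  prof$f_prabs_presence <- exp(prof$FD)   # monotone nonlinear
  ct <- correlate_predictors(prof)
  row_td <- ct[ct$var1 == "FD" & ct$var2 == "TD", ]
  expect_equal(row_td$pearson, 1)
  expect_equal(row_td$spearman, 1)
  row_mono <- ct[ct$var1 == "FD" & ct$var2 == "f_prabs_presence", ]
  expect_equal(row_mono$spearman, 1)
  expect_lt(row_mono$pearson, 1)
  prof$FD <- 0.5
  ct2 <- correlate_predictors(prof)
  expect_true(all(is.na(ct2$pearson[ct2$var1 == "FD"])))
})
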