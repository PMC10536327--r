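# prab_ensemble: the six selectors and the AUC-driven combiner

test_that("vectorized rank-sum p-values agree with stats::wilcox.test", {
  set.seed(11)
  for (rep in 1:5) {
    n1 <- sample(4:12, 1); n0 <- sample(4:12, 1)
    X <- matrix(rnorm((n1 + n0) * 6), n1 + n0, 6)
    if (rep > 3) X[1:3, 1] <- X[4:6, 1] # inject ties
    grp <- c(rep(TRUE, n1), rep(FALSE, n0))
    p_fast <- microrecov:::rank_sum_p(X, grp, "greater")
    p_ref <- apply(X, 2, function(col)
      suppressWarnings(wilcox.test(col[grp], col[!grp],
                                   alternative = "greater")$p.value))
    expect_equal(unname(p_fast), unname(p_ref), tolerance = 1e-12)
    p2_fast <- microrecov:::rank_sum_p(X, grp, "two.sided")
    p2_ref <- apply(X, 2, function(col)
      suppressWarnings(wilcox.test(col[grp], col[!grp])$p.value))
    expect_equal(unname(p2_fast), unname(p2_ref), tolerance = 1e-12)
  }
})

test_that("wilcoxon_select applies the consensus rule and skip contracts", {
  sim <- generate_cohorts(simulation_config(n_cohorts = 4,
                                            subjects_per_cohort = 10, seed = 31))
  sel <- wilcoxon_select(sim$table, sim$truth, timepoint = "pre")
  expect_true(all(sel$score[sel$selected] >= 2))
  # a taxon significant in exactly 1 cohort is not selected: raise threshold
  sel3 <- wilcoxon_select(sim$table, sim$truth, timepoint = "pre", min_cohorts = 4)
  expect_true(all(sel3$selected %in% sel$selected))
  expect_error(wilcoxon_select(sim$table, sim$truth, min_cohorts = 5), "at least 5")
  # one-class cohort skipped with a warning; all skipped -> error
  one <- generate_cohorts(simulation_config(n_cohorts = 2,
                                            subjects_per_cohort = 6, seed = 8))
  all_rec <- recovery_labels(one$truth$subject_id, one$truth$cohort_id,
                             rep("recoverer", nrow(one$truth)))
  expect_error(suppressWarnings(wilcoxon_select(one$table, all_rec)), "skipped")
})

test_that("wilcoxon_select has power > 0.9 for planted 1.5 log-unit effects", {
  hits <- vapply(1:15, function(r) {
    cfg <- simulation_config(n_cohorts = 4, subjects_per_cohort = 40,
                             n_taxa = 30, n_planted_prabs = 4,
                             effect_size = 1.5, seed = 900L + r)
    sim <- generate_cohorts(cfg)
    sel <- wilcoxon_select(sim$table, sim$truth, timepoint = "pre")
    mean(sim$planted %in% sel$selected)
  }, numeric(1))
  expect_gt(mean(hits), 0.9)
})

test_that("gbdt learner separates and matches a logistic baseline on easy data", {
  set.seed(5)
  n <- 60
  x <- cbind(signal = c(runif(n / 2, 1, 2), runif(n / 2, -2, -1)),
             noise = rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  fit <- gbdt_fit(x, y, n_trees = 50)
  expect_equal(auroc(predict(fit, x), y), 1)
  expect_gt(fit$importance["signal"], 0.95 * sum(fit$importance))
  # glm oracle agrees that the problem is separable
  expect_equal(auroc(predict(suppressWarnings(
    glm(y ~ x, family = binomial())), type = "response"), y), 1)
})

test_that("classifier_select keeps recoverer-direction features only", {
  set.seed(17)
  n <- 40
  up <- c(runif(n / 2, 0.5, 0.9), runif(n / 2, 0.05, 0.3))   # higher in recoverers
  down <- c(runif(n / 2, 0.05, 0.3), runif(n / 2, 0.5, 0.9)) # higher in non-recoverers
  noise <- matrix(runif(n * 4, 0.1, 0.3), ncol = 4,
                  dimnames = list(NULL, paste0("z", 1:4)))
  mk <- function(feature, name) {
    v <- t(cbind(setNames(data.frame(feature), name), noise))
    colnames(v) <- paste0("s", seq_len(n))
    make_table(v)
  }
  tb_up <- mk(up, "up")
  labs <- two_class_labels(tb_up, paste0("s", seq_len(n / 2)))
  for (lrn in c("gbdt_a", "gbdt_b")) {
    # single perfectly separating taxon, higher in recoverers -> selected
    sel <- classifier_select(tb_up, labs, learner = lrn)
    expect_true("up" %in% sel$selected)
    expect_identical(unname(sel$direction["up"]), "recoverer")
    # same taxon higher in NON-recoverers -> excluded by the direction filter
    sel2 <- classifier_select(mk(down, "down"), labs, learner = lrn)
    expect_false("down" %in% sel2$selected)
  }
})

test_that("classifier_select mostly returns planted taxa on synthetic cohorts", {
  prec <- vapply(1:6, function(r) {
    sim <- generate_cohorts(simulation_config(seed = 400L + r))
    labs <- label_recoverers(sim$table)
    sel <- classifier_select(sim$table, labs, timepoint = "pre")
    mean(sel$selected %in% sim$planted)
  }, numeric(1))
  expect_gte(mean(prec), 0.8)
})

test_that("differential_network_scores matches brute-force set arithmetic", {
  expect_error(differential_network_scores(random_table(4, 8), random_table(5, 8)),
               "taxon universe")
  # identical tables -> all zeros
  tb <- random_table(6, 10, seed = 2)
  sc0 <- differential_network_scores(tb, tb, abundance_min = 0.1, corr_min = 0.5)
  expect_equal(sc0$nesh_like, rep(0, 6))
  expect_equal(sc0$del_bet, rep(0, 6))
  expect_equal(sc0$netmoss_like, rep(0, 6))

  # constructed monotone blocks: X correlated with {A,B} in one class and
  # with {C,D} in the other -> neighbor sets disjoint, nesh_like = 1
  base <- 1:8
  mk <- function(partners) {
    v <- rbind(X = base, A = rnorm(8), B = rnorm(8), C = rnorm(8), D = rnorm(8))
    for (nm in partners) v[nm, ] <- base * runif(1, 0.5, 2) + runif(1)
    # decorrelate the rest deterministically
    make_table(abs(v) + 0.01)
  }
  set.seed(33)
  t_rec <- mk(c("A", "B")); t_non <- mk(c("C", "D"))
  sc <- differential_network_scores(t_rec, t_non, abundance_min = 0.1,
                                    corr_min = 0.9)
  x_row <- sc[sc$taxon == "X", ]
  expect_equal(x_row$nesh_like, 1)

  # brute-force oracle on random tables: recompute neighbor sets directly
  t1 <- random_table(7, 12, seed = 41); t2 <- random_table(7, 12, seed = 42)
  sc2 <- differential_network_scores(t1, t2, abundance_min = 0.1, corr_min = 0.4)
  neigh <- function(tb, tx) {
    r <- cor(t(tb$values), method = "spearman")
    names(which(abs(r[tx, ]) > 0.4 & rownames(r) != tx))
  }
  for (tx in sc2$taxon) {
    n1 <- neigh(t1, tx); n2 <- neigh(t2, tx)
    u <- union(n1, n2)
    expected <- if (length(u) == 0) 0 else 1 - length(intersect(n1, n2)) / length(u)
    expect_equal(sc2$nesh_like[sc2$taxon == tx], expected)
  }
})

test_that("netshift_like_select filters by quantile and del_bet sign", {
  mk_scores <- function(nesh, del) {
    structure(data.frame(taxon = paste0("t", seq_along(nesh)),
                         nesh_like = nesh, del_bet = del,
                         netmoss_like = 0, isolated = FALSE,
                         stringsAsFactors = FALSE),
              class = c("driver_scores", "data.frame"))
  }
  expect_length(netshift_like_select(mk_scores(rep(0, 8), rep(0, 8)))$selected, 0)
  sc <- mk_scores(c(1, rep(0, 7)), c(-0.2, rep(0, 7)))
  expect_identical(netshift_like_select(sc)$selected, "t1")
  # random scores match a direct filtering oracle
  set.seed(12)
  sc2 <- mk_scores(runif(20), runif(20, -0.5, 0.5))
  got <- netshift_like_select(sc2, nesh_quantile = 0.6)$selected
  thr <- quantile(sc2$nesh_like, 0.6, names = FALSE)
  expect_setequal(got, sc2$taxon[sc2$nesh_like > thr & sc2$del_bet < 0])
})

test_that("netmoss_like_select finds the precision-recall crossing", {
  sim <- generate_cohorts(simulation_config(n_cohorts = 1,
                                            subjects_per_cohort = 20, seed = 77))
  tb <- subset_table(sim$table,
    sample_ids = sim$table$metadata$sample_id[sim$table$metadata$timepoint == "pre"])
  lab <- sample_labels(tb <- tb, sim$truth)
  p <- microrecov:::rank_sum_p(t(tb$values), lab == "recoverer", "two.sided")
  ref <- names(p)[p < 0.05]
  # scores exactly 1 on the reference set -> P = R = 1, selection = ref
  # (up to the recoverer-direction filter, which planted taxa satisfy)
  sc <- structure(data.frame(taxon = rownames(tb$values),
                             nesh_like = 0, del_bet = 0,
                             netmoss_like = as.numeric(rownames(tb$values) %in% ref),
                             isolated = FALSE, stringsAsFactors = FALSE),
                  class = c("driver_scores", "data.frame"))
  sel <- netmoss_like_select(sc, tb, sim$truth)
  mean_rec <- rowMeans(tb$values[, lab == "recoverer"])
  mean_non <- rowMeans(tb$values[, lab == "non_recoverer"])
  expect_setequal(sel$selected,
                  intersect(ref, rownames(tb$values)[mean_rec > mean_non]))
  expect_equal(attr(sel, "threshold"), 1)
  # empty reference -> error
  null_sim <- generate_cohorts(simulation_config(n_cohorts = 1, n_taxa = 5,
                                                 n_planted_prabs = 2,
                                                 subjects_per_cohort = 4,
                                                 effect_size = 0, seed = 3))
  ntb <- subset_table(null_sim$table,
    sample_ids = null_sim$table$metadata$sample_id[
      null_sim$table$metadata$timepoint == "pre"])
  sc0 <- structure(data.frame(taxon = rownames(ntb$values), nesh_like = 0,
                              del_bet = 0, netmoss_like = 0, isolated = FALSE,
                              stringsAsFactors = FALSE),
                   class = c("driver_scores", "data.frame"))
  expect_error(netmoss_like_select(sc0, ntb, null_sim$truth),
               "reference set empty")
})

test_that("network selectors are enriched for planted taxa on synthetic data", {
  # The generator plants mean shifts, not network rewiring, so the
  # network-based stand-ins are weak; the honest contract is enrichment of
  # planted taxa over the base rate (see methods vignette).
  enrich <- c()
  for (r in 1:4) {
    sim <- generate_cohorts(simulation_config(seed = 600L + r))
    md <- sim$table$metadata
    tb <- subset_table(sim$table, sample_ids = md$sample_id[md$timepoint == "pre"])
    lab <- sample_labels(tb, sim$truth)
    sc <- differential_network_scores(
      subset_table(tb, sample_ids = names(lab)[lab == "recoverer"]),
      subset_table(tb, sample_ids = names(lab)[lab == "non_recoverer"]))
    sel <- netmoss_like_select(sc, tb, sim$truth)
    if (length(sel$selected) > 0)
      enrich <- c(enrich, mean(sel$selected %in% sim$planted))
  }
  base_rate <- 8 / 60
  expect_gt(mean(enrich), base_rate)
})

test_that("pc_corr_select honours its limiting cases", {
  set.seed(19)
  n <- 24
  sep <- c(runif(n / 2, 0.6, 0.9), runif(n / 2, 0.05, 0.2))
  v <- t(cbind(sep = sep,
               matrix(runif(n * 3, 0.2, 0.4), ncol = 3,
                      dimnames = list(NULL, paste0("z", 1:3)))))
  colnames(v) <- paste0("s", 1:n)
  tb <- make_table(v)
  labs <- two_class_labels(tb, paste0("s", 1:(n / 2)))
  # a lone separating taxon survives via self-retention at cutoff 0
  expect_true("sep" %in% pc_corr_select(tb, labs, cutoff = 0)$selected)
  # cutoff 1: no weight and no loading can exceed 1 -> empty
  expect_length(pc_corr_select(tb, labs, cutoff = 1)$selected, 0)
  expect_error(pc_corr_select(subset_table(tb, taxon_ids = "sep"), labs),
               "at least 2 taxa")

  # brute-force oracle: replicate the documented edge rule on a toy table
  sim <- generate_cohorts(simulation_config(n_cohorts = 1, n_taxa = 6,
                                            n_planted_prabs = 3,
                                            subjects_per_cohort = 12, seed = 5))
  md <- sim$table$metadata
  tbp <- subset_table(sim$table, sample_ids = md$sample_id[md$timepoint == "pre"])
  lab <- sample_labels(tbp, sim$truth)
  got <- pc_corr_select(tbp, sim$truth, cutoff = 0.1)$selected
  X <- scale(t(log10(tbp$values + 1e-5)))
  X[, attr(X, "scaled:scale") == 0] <- 0
  pca <- prcomp(X, center = FALSE)
  tt <- apply(pca$x[, 1:min(10, ncol(pca$x))], 2, function(s)
    abs(t.test(s[lab == "recoverer"], s[lab == "non_recoverer"])$statistic))
  k <- which.max(tt)
  v_load <- pca$rotation[, k] / max(abs(pca$rotation[, k]))
  r <- cor(X)
  keep <- abs(v_load) > 0.1
  nt <- length(v_load)
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    w <- min(abs(v_load[i]), abs(v_load[j]), abs(r[i, j]))
    if (sign(v_load[i]) * sign(v_load[j]) == sign(r[i, j]) && w > 0.1)
      keep[i] <- keep[j] <- TRUE
  }
  s_dir <- sign(mean(pca$x[lab == "recoverer", k]) -
                  mean(pca$x[lab == "non_recoverer", k]))
  expected <- rownames(tbp$values)[keep & sign(v_load) == s_dir]
  expect_setequal(got, expected)
})

test_that("evaluate_combination: null AUC ~ 0.5, separable AUC = 1, errors", {
  sim <- generate_cohorts(simulation_config(n_cohorts = 2,
                                            subjects_per_cohort = 20, seed = 55))
  set.seed(1)
  shuffled <- sim$truth
  shuffled$label <- sample(shuffled$label)
  ev0 <- evaluate_combination(rownames(sim$table$values)[1:10], sim$table,
                              shuffled, n_repeats = 10, seed = 2)
  # null sd of the Mann-Whitney AUC at this problem size (40 pre samples)
  sd_null <- sqrt((40 + 1) / (12 * 20 * 20))
  expect_lt(abs(ev0$auc_mean - 0.5), 2.5 * sd_null)

  # single perfectly separating feature
  n <- 20
  v <- t(cbind(good = c(runif(n / 2, 0.7, 0.9), runif(n / 2, 0.1, 0.3)),
               z1 = runif(n, 0.2, 0.4), z2 = runif(n, 0.2, 0.4)))
  colnames(v) <- paste0("s", 1:n)
  tb <- make_table(v)
  labs <- two_class_labels(tb, paste0("s", 1:(n / 2)))
  ev1 <- evaluate_combination("good", tb, labs, n_folds = 5, n_repeats = 2)
  expect_equal(ev1$auc_mean, 1)
  expect_error(evaluate_combination(character(0), tb, labs), "non-empty")
  expect_error(evaluate_combination("absent", tb, labs), "not in table")
})

test_that("select_ensemble returns the argmax union with deterministic ties", {
  n <- 24
  set.seed(23)
  good <- c(runif(n / 2, 0.7, 0.9), runif(n / 2, 0.1, 0.3))
  v <- t(cbind(alpha = good, beta = good * 0.5 + 0.01, # monotone copy: same AUC
               noise = runif(n, 0.2, 0.4)))
  colnames(v) <- paste0("s", 1:n)
  tb <- make_table(v)
  labs <- two_class_labels(tb, paste0("s", 1:(n / 2)))
  r1 <- selection_result("m1", "alpha")
  r2 <- selection_result("m2", "beta")
  ens <- select_ensemble(list(r1, r2), tb, labs, n_repeats = 2, seed = 4)
  # both singletons and the union reach AUC 1; smaller set wins, then
  # lexicographic -> {alpha}
  expect_identical(ens$final_prabs, "alpha")

  # one method supplied -> that set
  ens1 <- select_ensemble(list(r2), tb, labs, n_repeats = 2, seed = 4)
  expect_identical(ens1$final_prabs, "beta")
  expect_error(select_ensemble(list(selection_result("m", character(0))),
                               tb, labs), "empty")
})

test_that("best ensemble AUC dominates every single method on shared folds", {
  sim <- generate_cohorts(simulation_config(n_cohorts = 2,
                                            subjects_per_cohort = 16, seed = 71))
  labs <- label_recoverers(sim$table)
  sels <- list(selection_result("a", sim$planted[1:4]),
               selection_result("b", rownames(sim$table$values)[30:35]),
               selection_result("c", sim$planted))
  ens <- select_ensemble(sels, sim$table, labs, n_repeats = 2, seed = 6)
  singles <- ens$combinations[!grepl("\\+", ens$combinations$methods), ]
  expect_true(all(ens$combinations$auc_mean[1] >= singles$auc_mean))
})

test_that("selected sets are invariant to sample and taxon permutations", {
  sim <- generate_cohorts(simulation_config(n_cohorts = 2,
                                            subjects_per_cohort = 10, seed = 91))
  labs <- sim$truth
  perm_t <- sample(nrow(sim$table$values))
  perm_s <- sample(ncol(sim$table$values))
  vp <- sim$table$values[perm_t, perm_s]
  tbp <- abundance_table(vp, sim$table$metadata)
  expect_setequal(wilcoxon_select(sim$table, labs, "pre")$selected,
                  wilcoxon_select(tbp, labs, "pre")$selected)
  expect_setequal(classifier_select(sim$table, labs, "pre", seed = 3)$selected,
                  classifier_select(tbp, labs, "pre", seed = 3)$selected)
})
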