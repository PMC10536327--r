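#' Construct a selection result
#'
#' One selector's candidate set of predictive recovery-associated taxa
#' (p-RABs) with per-taxon scores and contribution direction.
#'
#' @param method selector name
#' @param selected character vector of selected taxa
#' @param score named numeric vector covering `selected`
#' @param direction named character vector (`"recoverer"` /
#'   `"non_recoverer"`) covering `selected`; defaults to all `"recoverer"`
#' @return object of class `selection_result`
#' @export
selection_result <- function(method, selected, score = NULL, direction = NULL) {
  selected <- sort(unique(as.character(selected)))
  if (is.null(score)) score <- setNames(rep(1, length(selected)), selected)
  if (is.null(direction))
    direction <- setNames(rep("recoverer", length(selected)), selected)
  if (!all(selected %in% names(score)))
    stop("every selected taxon needs a score")
  structure(list(method = method, selected = selected,
                 score = score[selected], direction = direction[selected]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d taxa\n", x$method, length(x$selected)))
  if (length(x$selected) > 0)
    cat(" ", paste(head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}

#' Cross-cohort Wilcoxon consensus selection
#'
#' Per cohort, a one-sided Wilcoxon rank-sum test of each taxon's abundance
#' (recoverers greater than non-recoverers) at the given time point. A taxon
#' is selected iff its p-value falls below `alpha` in at least `min_cohorts`
#' cohorts; the score is the number of significant cohorts. Raw per-cohort
#' p-values are used by default; `adjust = "BH"` applies
#' Benjamini-Hochberg within each cohort.
#'
#' @param table an [abundance_table()] spanning one or more cohorts
#' @param labels a [recovery_labels()] data.frame
#' @param timepoint `"pre"`, `"during"` or `"post"`
#' @param alpha per-cohort significance level
#' @param min_cohorts consensus requirement (default 2)
#' @param adjust `"none"` (default) or `"BH"`
#' @return a [selection_result()]
#' @export
wilcoxon_select <- function(table, labels, timepoint = "pre", alpha = 0.05,
                            min_cohorts = 2, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  tabs <- split_by_cohort(table)
  if (length(tabs) < min_cohorts)
    stop(sprintf("need at least %d cohorts, got %d", min_cohorts, length(tabs)))
  counts <- setNames(integer(nrow(table$values)), rownames(table$values))
  used <- 0
  for (co in names(tabs)) {
    tb <- tabs[[co]]
    keep <- tb$metadata$timepoint == timepoint
    tb <- subset_table(tb, sample_ids = tb$metadata$sample_id[keep])
    lab <- sample_labels(tb, labels)
    ok <- !is.na(lab)
    if (sum(lab[ok] == "recoverer") == 0 || sum(lab[ok] == "non_recoverer") == 0) {
      warning(sprintf("cohort '%s' skipped: one class empty at '%s'", co, timepoint))
      next
    }
    X <- t(tb$values[, ok, drop = FALSE])
    p <- rank_sum_p(X, lab[ok] == "recoverer", alternative = "greater")
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    counts[names(p)] <- counts[names(p)] + (p < alpha)
    used <- used + 1
  }
  if (used == 0) stop("all cohorts were skipped (a class empty everywhere)")
  sel <- names(counts)[counts >= min_cohorts]
  selection_result("wilcoxon", sel, score = as.numeric(counts)[match(sel, names(counts))] |>
                     setNames(sel))
}

#' Boosted-tree feature selection with direction filtering
#'
#' Fits a gradient-boosted tree classifier to abundances at one time point,
#' ranks taxa by total gain importance, retains the head of the ranking up
#' to the elbow of cumulative importance (`importance_cum`, capped at
#' `max_features`), and keeps only features whose out-of-fold contribution
#' direction points toward recoverers. The direction of a feature is the
#' sign of the Spearman correlation between its values and the out-of-fold
#' predicted recoverer probability, a monotone surrogate for per-feature
#' attribution.
#'
#' @inheritParams wilcoxon_select
#' @param learner `"gbdt_a"` or `"gbdt_b"` (see [gbdt_params()])
#' @param n_folds stratified folds for out-of-fold predictions (>= 3)
#' @param max_features cap on the retained set size
#' @param importance_cum cumulative-gain fraction defining the elbow
#' @param seed seed for fold assignment
#' @return a [selection_result()]
#' @export
classifier_select <- function(table, labels, timepoint = "pre",
                              learner = c("gbdt_a", "gbdt_b"), n_folds = 5,
                              max_features = 20, importance_cum = 0.9,
                              seed = 1L) {
  learner <- match.arg(learner)
  if (n_folds < 3) stop("n_folds must be >= 3")
  keep <- table$metadata$timepoint == timepoint
  tb <- subset_table(table, sample_ids = table$metadata$sample_id[keep])
  lab <- sample_labels(tb, labels)
  ok <- !is.na(lab)
  tb <- subset_table(tb, sample_ids = names(lab)[ok])
  lab <- lab[ok]
  y <- as.numeric(lab == "recoverer")
  if (length(unique(y)) < 2) stop("both classes must be present")

  # sort taxa and samples so the deterministic learner is order-invariant
  ord_t <- order(rownames(tb$values))
  ord_s <- order(colnames(tb$values))
  X <- t(tb$values[ord_t, ord_s, drop = FALSE])
  y <- y[ord_s]

  par <- gbdt_params(learner)
  fit <- do.call(gbdt_fit, c(list(x = X, y = y), par))
  imp <- fit$importance
  if (sum(imp) <= 0) return(selection_result(learner, character(0)))

  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  oof <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) next
    m <- do.call(gbdt_fit, c(list(x = X[tr, , drop = FALSE], y = y[tr]), par))
    oof[!tr] <- predict(m, X[!tr, , drop = FALSE])
  }

  ord <- order(-imp, names(imp))
  cum <- cumsum(imp[ord]) / sum(imp)
  k <- min(which(cum >= importance_cum)[1], max_features)
  cand <- names(imp)[ord][seq_len(k)]
  cand <- cand[imp[cand] > 0]
  dirn <- vapply(cand, function(tx) {
    r <- suppressWarnings(cor(X[, tx], oof, method = "spearman"))
    if (is.na(r)) 0 else r
  }, numeric(1))
  sel <- cand[dirn > 0]
  selection_result(learner, sel, score = imp[sel],
                   direction = setNames(rep("recoverer", length(sel)), sel))
}

#' Differential co-occurrence driver scores
#'
#' Builds one Spearman co-occurrence graph per class (taxa passing a
#' prevalence prefilter; edges with `|rho| > corr_min`) and scores every
#' taxon of the shared universe by three between-graph contrasts:
#' `nesh_like`, the Jaccard dissimilarity of its neighbour sets (0 when the
#' neighbourhoods are identical, 1 when disjoint); `del_bet`, normalized
#' betweenness in the non-recoverer graph minus the recoverer graph
#' (negative read as driving toward the recovered state); and
#' `netmoss_like`, the L1 distance between the taxon's retained-edge
#' correlation profiles, rescaled to `[0, 1]` by the maximum over taxa.
#'
#' @param table_rec,table_nonrec [abundance_table()]s for the two classes
#'   over the same taxon universe
#' @param abundance_min prefilter threshold; with
#'   `filter = "prevalence"` (default) taxa must be present in more than
#'   this fraction of a class's samples, with `filter = "mean_quantile"`
#'   taxa must exceed this quantile of mean abundance
#' @param corr_min minimum `|rho|` for a retained edge, in (0,1)
#' @param filter prefilter interpretation (see `abundance_min`)
#' @return data.frame of class `driver_scores` with columns `taxon`,
#'   `nesh_like`, `del_bet`, `netmoss_like`, `isolated`
#' @export
differential_network_scores <- function(table_rec, table_nonrec,
                                        abundance_min = 0.3, corr_min = 0.5,
                                        filter = c("prevalence", "mean_quantile")) {
  filter <- match.arg(filter)
  if (corr_min <= 0 || corr_min >= 1) stop("corr_min must lie in (0, 1)")
  if (!setequal(rownames(table_rec$values), rownames(table_nonrec$values)))
    stop("the two tables must share a taxon universe")
  universe <- sort(rownames(table_rec$values))

  class_graph <- function(tb) {
    v <- tb$values[universe, , drop = FALSE]
    keep <- if (filter == "prevalence") {
      rowMeans(v > 0) > abundance_min
    } else {
      mn <- rowMeans(v)
      mn > quantile(mn, abundance_min, names = FALSE)
    }
    kept <- universe[keep]
    adj <- matrix(0, length(universe), length(universe),
                  dimnames = list(universe, universe))
    if (length(kept) >= 2) {
      rho <- suppressWarnings(cor(t(v[kept, , drop = FALSE]), method = "spearman"))
      rho[is.na(rho)] <- 0
      diag(rho) <- 0
      rho[abs(rho) <= corr_min] <- 0
      adj[kept, kept] <- rho
    }
    list(kept = kept, adj = adj)
  }
  g_rec <- class_graph(table_rec)
  g_non <- class_graph(table_nonrec)

  neigh <- function(adj, tx) universe[adj[tx, ] != 0]
  bet <- function(g) {
    gr <- igraph::graph_from_adjacency_matrix(abs(g$adj) > 0, mode = "undirected",
                                              diag = FALSE)
    b <- igraph::betweenness(gr, normalized = TRUE)
    setNames(as.numeric(b), universe)
  }
  b_rec <- bet(g_rec); b_non <- bet(g_non)

  nesh <- del <- l1 <- numeric(length(universe))
  for (i in seq_along(universe)) {
    tx <- universe[i]
    n1 <- neigh(g_rec$adj, tx); n2 <- neigh(g_non$adj, tx)
    u <- union(n1, n2)
    nesh[i] <- if (length(u) == 0) 0 else 1 - length(intersect(n1, n2)) / length(u)
    del[i] <- b_non[tx] - b_rec[tx]
    l1[i] <- sum(abs(g_rec$adj[tx, ] - g_non$adj[tx, ]))
  }
  if (max(l1) > 0) l1 <- l1 / max(l1)
  out <- data.frame(taxon = universe, nesh_like = nesh, del_bet = del,
                    netmoss_like = l1,
                    isolated = !(universe %in% g_rec$kept) &
                               !(universe %in% g_non$kept),
                    stringsAsFactors = FALSE)
  class(out) <- c("driver_scores", "data.frame")
  out
}

#' Neighbour-shift driver selection
#'
#' Selects taxa whose `nesh_like` score exceeds the given quantile of all
#' scores and (by default) whose betweenness change is negative, i.e.
#' drivers toward the recovered state.
#'
#' @param scores a `driver_scores` data.frame from
#'   [differential_network_scores()]
#' @param nesh_quantile quantile of `nesh_like` that must be exceeded
#' @param require_delbet_negative also require `del_bet < 0`
#' @return a [selection_result()]
#' @export
netshift_like_select <- function(scores, nesh_quantile = 0.75,
                                 require_delbet_negative = TRUE) {
  if (nrow(scores) == 0) stop("empty driver scores")
  thr <- quantile(scores$nesh_like, nesh_quantile, names = FALSE)
  keep <- scores$nesh_like > thr
  if (require_delbet_negative) keep <- keep & scores$del_bet < 0
  sel <- scores$taxon[keep]
  selection_result("netshift", sel,
                   score = setNames(scores$nesh_like[keep], sel))
}

#' Threshold-swept driver selection with a precision-recall crossing
#'
#' Sweeps thresholds over `netmoss_like`; at each threshold, precision and
#' recall are computed for retrieving the in-sample reference set of taxa
#' whose abundance differs between classes (two-sided Wilcoxon p < `alpha`).
#' The operating threshold is the sweep point where the precision and recall
#' curves cross; taxa at or above it whose mean abundance is higher in
#' recoverers are selected.
#'
#' @inheritParams netshift_like_select
#' @param table an [abundance_table()] providing the in-sample reference
#' @param labels a [recovery_labels()]
#' @param alpha significance level defining the reference set
#' @return a [selection_result()]; attribute `threshold` records the
#'   crossing point
#' @export
netmoss_like_select <- function(scores, table, labels, alpha = 0.05) {
  lab <- sample_labels(table, labels)
  ok <- !is.na(lab)
  X <- t(table$values[, ok, drop = FALSE])
  p <- rank_sum_p(X, lab[ok] == "recoverer", alternative = "two.sided")
  ref <- names(p)[p < alpha]
  if (length(ref) == 0)
    stop("reference set empty (no taxon differs at alpha); more data or a larger effect is needed")

  s <- setNames(scores$netmoss_like, scores$taxon)
  cand <- sort(unique(s))
  pr <- vapply(cand, function(t0) {
    sel <- names(s)[s >= t0]
    c(precision = length(intersect(sel, ref)) / max(length(sel), 1),
      recall = length(intersect(sel, ref)) / length(ref))
  }, numeric(2))
  gap <- abs(pr["precision", ] - pr["recall", ])
  thr <- cand[which.min(gap)]

  mean_rec <- rowMeans(table$values[, ok, drop = FALSE][, lab[ok] == "recoverer", drop = FALSE])
  mean_non <- rowMeans(table$values[, ok, drop = FALSE][, lab[ok] == "non_recoverer", drop = FALSE])
  sel <- scores$taxon[s[scores$taxon] >= thr &
                        mean_rec[scores$taxon] > mean_non[scores$taxon]]
  out <- selection_result("netmoss", sel, score = s[sel])
  attr(out, "threshold") <- thr
  out
}

#' Discriminant principal-component correlation selection
#'
#' Log-transformed, standardized abundances are decomposed by PCA; the
#' component whose sample scores best separate the classes (largest
#' two-sample |t|) provides loadings `v` (rescaled to max |v| = 1). The
#' edge weight between taxa i and j is `min(|v_i|, |v_j|, |r_ij|)` when the
#' loading signs are consistent with the sign of their Pearson correlation
#' `r_ij`, zero otherwise. Nodes incident to an edge with weight above
#' `cutoff` — or carrying `|v| > cutoff` themselves (self-retention, so a
#' lone discriminative taxon is not lost) — are retained, then filtered to
#' the loading sign enriched in recoverers.
#'
#' @inheritParams wilcoxon_select
#' @param cutoff edge-weight cutoff (the study swept 0, 0.1, 0.2)
#' @param wilcoxon_postfilter additionally require a one-sided Wilcoxon
#'   p < 0.05 (recoverers greater)
#' @param pseudo pseudocount added before log10
#' @param n_pcs number of leading components searched
#' @return a [selection_result()]
#' @export
pc_corr_select <- function(table, labels, cutoff = 0,
                           wilcoxon_postfilter = FALSE, pseudo = 1e-5,
                           n_pcs = 10) {
  if (nrow(table$values) < 2) stop("need at least 2 taxa")
  lab <- sample_labels(table, labels)
  ok <- !is.na(lab)
  tb <- subset_table(table, sample_ids = names(lab)[ok])
  lab <- lab[ok]
  if (sum(lab == "recoverer") < 2 || sum(lab == "non_recoverer") < 2)
    stop("need at least 2 samples per class")

  X <- scale(t(log10(tb$values + pseudo)))
  X[, attr(X, "scaled:scale") == 0] <- 0
  pca <- prcomp(X, center = FALSE, scale. = FALSE)
  k_max <- min(n_pcs, ncol(pca$x))
  tstat <- vapply(seq_len(k_max), function(k) {
    sc <- pca$x[, k]
    if (sd(sc[lab == "recoverer"]) == 0 && sd(sc[lab == "non_recoverer"]) == 0)
      return(0)
    abs(t.test(sc[lab == "recoverer"], sc[lab == "non_recoverer"])$statistic)
  }, numeric(1))
  k <- which.max(tstat)
  v <- pca$rotation[, k]
  if (max(abs(v)) > 0) v <- v / max(abs(v))
  r <- suppressWarnings(cor(X))
  r[is.na(r)] <- 0

  taxa_ids <- rownames(tb$values)
  n <- length(taxa_ids)
  retained <- abs(v) > cutoff   # self-retention
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (v[i] == 0 || v[j] == 0 || r[i, j] == 0) next
    if (sign(v[i]) * sign(v[j]) != sign(r[i, j])) next
    w <- min(abs(v[i]), abs(v[j]), abs(r[i, j]))
    if (w > cutoff) retained[i] <- retained[j] <- TRUE
  }

  s_dir <- sign(mean(pca$x[lab == "recoverer", k]) -
                  mean(pca$x[lab == "non_recoverer", k]))
  sel <- taxa_ids[retained & sign(v) == s_dir]
  if (wilcoxon_postfilter && length(sel) > 0) {
    p <- rank_sum_p(t(tb$values[sel, , drop = FALSE]), lab == "recoverer",
                    alternative = "greater")
    sel <- sel[p[sel] < 0.05]
  }
  selection_result("pccorr", sel, score = setNames(abs(v)[match(sel, taxa_ids)], sel))
}
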