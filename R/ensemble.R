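#' Cross-validated AUC of a taxa set
#'
#' Repeated stratified cross-validation of a classifier restricted to the
#' given taxa, predicting recoverer status from abundances at one time
#' point. The AUC of each repeat is computed on the pooled out-of-fold
#' predictions; mean and sd are taken across repeats.
#'
#' @param taxa_set non-empty character vector of taxa present in `table`
#' @param table an [abundance_table()]
#' @param labels a [recovery_labels()]
#' @param learner `"logistic"` (ridge-stabilised, fast), `"gbdt_a"` or
#'   `"gbdt_b"`
#' @param timepoint samples used for prediction (default `"pre"`:
#'   predicting recovery before the outcome is observed)
#' @param n_folds,n_repeats cross-validation design
#' @param seed seed for fold assignment (same seed gives the same folds for
#'   every taxa set, making combination AUCs comparable)
#' @return list with `auc_mean`, `auc_sd`, `auc_per_repeat`
#' @export
evaluate_combination <- function(taxa_set, table, labels,
                                 learner = c("logistic", "gbdt_a", "gbdt_b"),
                                 timepoint = "pre", n_folds = 5, n_repeats = 5,
                                 seed = 1L) {
  learner <- match.arg(learner)
  taxa_set <- sort(unique(taxa_set))
  if (length(taxa_set) == 0) stop("taxa_set must be non-empty")
  missing <- setdiff(taxa_set, rownames(table$values))
  if (length(missing) > 0)
    stop("taxa not in table: ", paste(missing, collapse = ", "))

  keep <- table$metadata$timepoint == timepoint
  tb <- subset_table(table, sample_ids = table$metadata$sample_id[keep])
  lab <- sample_labels(tb, labels)
  ok <- !is.na(lab)
  ord <- order(names(lab)[ok])
  sample_ids <- names(lab)[ok][ord]
  y <- as.numeric(lab[sample_ids] == "recoverer")
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- t(tb$values[taxa_set, sample_ids, drop = FALSE])

  fit_predict <- function(tr) {
    if (learner == "logistic") {
      m <- ridge_logistic(X[tr, , drop = FALSE], y[tr], lambda = 1e-2)
      predict_ridge_logistic(m, X[!tr, , drop = FALSE])
    } else {
      par <- gbdt_params(learner)
      m <- do.call(gbdt_fit, c(list(x = X[tr, , drop = FALSE], y = y[tr]), par))
      predict(m, X[!tr, , drop = FALSE])
    }
  }
  aucs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + 1000L * r)
    fold <- stratified_folds(y, n_folds)
    oof <- numeric(length(y))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) { oof[!tr] <- mean(y[tr]); next }
      oof[!tr] <- fit_predict(tr)
    }
    aucs[r] <- auroc(oof, y)
  }
  list(auc_mean = mean(aucs), auc_sd = sd(aucs), auc_per_repeat = aucs)
}

#' Combine method-level selections by AUC-ranked union search
#'
#' Enumerates unions over subsets of the supplied selection results (all
#' `2^k - 1` subsets when `k <= 6`, greedy forward union otherwise or when
#' requested), evaluates each union with [evaluate_combination()] on shared
#' folds, and returns the ranked table with the argmax union as
#' `final_prabs`. AUC ties are broken by smaller union size, then by the
#' lexicographic order of the union's taxa.
#'
#' @param results list of [selection_result()]s (at least one non-empty)
#' @inheritParams evaluate_combination
#' @param search `"all_subsets"` or `"greedy"`
#' @return object of class `ensemble_result`: `combinations` (data.frame
#'   with methods, size, auc_mean, auc_sd), `final_prabs`, `best_methods`
#' @export
select_ensemble <- function(results, table, labels,
                            learner = c("logistic", "gbdt_a", "gbdt_b"),
                            timepoint = "pre", n_folds = 5, n_repeats = 5,
                            seed = 1L, search = c("all_subsets", "greedy")) {
  learner <- match.arg(learner)
  search <- match.arg(search)
  if (length(results) == 0) stop("no selection results supplied")
  sets <- lapply(results, function(r) r$selected)
  names(sets) <- vapply(results, function(r) r$method, character(1))
  sets <- sets[lengths(sets) > 0]
  if (length(sets) == 0) stop("all selections are empty")
  k <- length(sets)
  if (search == "all_subsets" && k > 6) search <- "greedy"

  eval_union <- local({
    cache <- new.env(parent = emptyenv())
    function(u) {
      key <- paste(u, collapse = "\r")
      if (!is.null(cache[[key]])) return(cache[[key]])
      res <- evaluate_combination(u, table, labels, learner = learner,
                                  timepoint = timepoint, n_folds = n_folds,
                                  n_repeats = n_repeats, seed = seed)
      cache[[key]] <- res
      res
    }
  })

  rows <- list()
  add_row <- function(methods) {
    u <- sort(unique(unlist(sets[methods])))
    ev <- eval_union(u)
    rows[[length(rows) + 1]] <<- data.frame(
      methods = paste(methods, collapse = "+"), size = length(u),
      auc_mean = ev$auc_mean, auc_sd = ev$auc_sd,
      taxa = paste(u, collapse = ";"), stringsAsFactors = FALSE)
  }

  if (search == "all_subsets") {
    for (m in seq_len(k)) {
      cmb <- combn(names(sets), m, simplify = FALSE)
      for (methods in cmb) add_row(methods)
    }
  } else {
    chosen <- character(0)
    remaining <- names(sets)
    for (mt in remaining) add_row(mt)   # singletons always scored
    repeat {
      best_gain <- -Inf; best_m <- NULL
      base_auc <- if (length(chosen) == 0) -Inf else {
        eval_union(sort(unique(unlist(sets[chosen]))))$auc_mean
      }
      for (mt in setdiff(remaining, chosen)) {
        u <- sort(unique(unlist(sets[c(chosen, mt)])))
        a <- eval_union(u)$auc_mean
        if (a > best_gain) { best_gain <- a; best_m <- mt }
      }
      if (is.null(best_m) || best_gain <= base_auc) break
      chosen <- c(chosen, best_m)
      add_row(chosen)
      if (length(chosen) == k) break
    }
  }

  combos <- do.call(rbind, rows)
  taxa_list <- strsplit(combos$taxa, ";", fixed = TRUE)
  lex <- vapply(taxa_list, paste, character(1), collapse = "\r")
  ord <- order(-combos$auc_mean, combos$size, lex)
  combos <- combos[ord, , drop = FALSE]
  rownames(combos) <- NULL
  structure(list(combinations = combos,
                 final_prabs = taxa_list[ord][[1]],
                 best_methods = combos$methods[1]),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: best combination [%s], %d taxa, AUC %.3f\n",
              x$best_methods, length(x$final_prabs),
              x$combinations$auc_mean[1]))
  invisible(x)
}

#' Run the full selector battery
#'
#' Runs the requested selectors at each time point and unions a method's
#' selections across time points, mirroring a design in which every method
#' examines pre-, during- and post-treatment data.
#'
#' @inheritParams evaluate_combination
#' @param methods subset of
#'   `c("wilcoxon", "gbdt_a", "gbdt_b", "netshift", "netmoss", "pccorr")`
#' @param timepoints time points analysed (default all three)
#' @param alpha significance level for Wilcoxon-based steps
#' @param min_cohorts consensus requirement for [wilcoxon_select()]
#' @param seed seed forwarded to seeded selectors
#' @return named list of [selection_result()]s
#' @export
run_selectors <- function(table, labels,
                          methods = c("wilcoxon", "gbdt_a", "gbdt_b",
                                      "netshift", "netmoss", "pccorr"),
                          timepoints = c("pre", "during", "post"),
                          alpha = 0.05, min_cohorts = 2, seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (m in methods) {
    per_tp <- list()
    for (tp in timepoints) {
      res <- tryCatch({
        keep <- table$metadata$timepoint == tp
        tb <- subset_table(table, sample_ids = table$metadata$sample_id[keep])
        switch(m,
          wilcoxon = wilcoxon_select(table, labels, timepoint = tp,
                                     alpha = alpha, min_cohorts = min_cohorts),
          gbdt_a = classifier_select(table, labels, timepoint = tp,
                                     learner = "gbdt_a", seed = seed),
          gbdt_b = classifier_select(table, labels, timepoint = tp,
                                     learner = "gbdt_b", seed = seed),
          netshift = {
            lab <- sample_labels(tb, labels)
            sc <- differential_network_scores(
              subset_table(tb, sample_ids = names(lab)[!is.na(lab) & lab == "recoverer"]),
              subset_table(tb, sample_ids = names(lab)[!is.na(lab) & lab == "non_recoverer"]))
            netshift_like_select(sc)
          },
          netmoss = {
            lab <- sample_labels(tb, labels)
            sc <- differential_network_scores(
              subset_table(tb, sample_ids = names(lab)[!is.na(lab) & lab == "recoverer"]),
              subset_table(tb, sample_ids = names(lab)[!is.na(lab) & lab == "non_recoverer"]))
            netmoss_like_select(sc, tb, labels)
          },
          pccorr = pc_corr_select(tb, labels))
      }, error = function(e) {
        warning(sprintf("selector '%s' failed at '%s': %s", m, tp,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) per_tp[[tp]] <- res
    }
    if (length(per_tp) > 0) {
      sel <- sort(unique(unlist(lapply(per_tp, function(r) r$selected))))
      score <- setNames(numeric(length(sel)), sel)
      dirn <- setNames(rep("recoverer", length(sel)), sel)
      for (r in per_tp) {
        score[r$selected] <- pmax(score[r$selected], r$score)
        dirn[r$selected] <- r$direction
      }
      out[[m]] <- selection_result(m, sel, score = score, direction = dirn)
    }
  }
  out
}
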