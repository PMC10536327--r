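#' Weighted Jaccard functional distance between two taxa
#'
#' `d_ij = 1 - sum_k min(a_ik, a_jk) / sum_k max(a_ik, a_jk)` over gene
#' families; binary incidence gives the classical Jaccard distance.
#'
#' @param gcn a [gene_content()]
#' @param i,j taxon identifiers
#' @return distance in `[0, 1]`
#' @export
weighted_jaccard <- function(gcn, i, j) {
  stopifnot(inherits(gcn, "gene_content"))
  for (tx in c(i, j)) {
    if (!tx %in% rownames(gcn$values)) stop("unknown taxon: ", tx)
    if (sum(gcn$values[tx, ]) == 0)
      stop("taxon '", tx, "' has an all-zero gene-content row")
  }
  a <- gcn$values[i, ]; b <- gcn$values[j, ]
  1 - sum(pmin(a, b)) / sum(pmax(a, b))
}

#' All pairwise weighted Jaccard distances
#'
#' @param gcn a [gene_content()]
#' @param binarize reduce copy numbers to presence/absence first
#' @return symmetric matrix of class `functional_distance` with zero
#'   diagonal and entries in `[0, 1]`
#' @export
functional_distance_matrix <- function(gcn, binarize = FALSE) {
  stopifnot(inherits(gcn, "gene_content"))
  A <- gcn$values
  if (binarize) A <- (A > 0) * 1
  zero <- rowSums(A) == 0
  if (any(zero))
    stop("all-zero gene-content row(s): ",
         paste(rownames(A)[zero], collapse = ", "))
  # sum(min) = (s_i + s_j - L1_ij)/2 ; sum(max) = (s_i + s_j + L1_ij)/2
  s <- rowSums(A)
  L1 <- as.matrix(stats::dist(A, method = "manhattan"))
  S <- outer(s, s, "+")
  d <- 1 - (S - L1) / (S + L1)
  diag(d) <- 0
  structure(d, class = c("functional_distance", "matrix"))
}

#' Taxonomic diversity (Gini-Simpson)
#'
#' `TD = sum_{i != j} p_i p_j = 1 - sum p_i^2`.
#'
#' @inheritParams gini_simpson
#' @return TD in `[0, 1)`
#' @export
taxonomic_diversity <- function(p) gini_simpson(p)

#' Functional diversity (Rao quadratic entropy)
#'
#' `FD = sum_{i != j} p_i p_j d_ij`: the abundance-weighted mean functional
#' dissimilarity of two random members.
#'
#' @param p named relative-abundance vector
#' @param d a [functional_distance_matrix()] covering all taxa of `p`
#' @return FD in `[0, TD]`
#' @export
functional_diversity <- function(p, d) {
  if (abs(sum(p) - 1) > 1e-6) stop("composition does not sum to 1; renormalize")
  if (is.null(names(p))) stop("`p` must be named by taxon")
  missing <- setdiff(names(p)[p > 0], rownames(d))
  if (length(missing) > 0)
    stop("taxa missing from the functional distance matrix: ",
         paste(missing, collapse = ", "))
  common <- intersect(names(p), rownames(d))
  q <- p[common]
  drop(t(q) %*% d[common, common] %*% q)
}

#' Functional redundancy
#'
#' `FR = TD - FD`: the share of taxonomic diversity carried by functionally
#' interchangeable taxa.
#'
#' @param TD,FD computed diversity pair
#' @return FR (>= 0)
#' @export
functional_redundancy <- function(TD, FD) {
  if (FD > TD + 1e-12)
    stop("FD exceeds TD; the distance matrix must violate d <= 1")
  TD - FD
}

#' Fraction of p-RABs in a sample
#'
#' `mode = "presence"`: number of p-RABs detected above the threshold over
#' the number of all species detected. `mode = "abundance"`: summed relative
#' abundance of p-RABs over total abundance.
#'
#' @param p named relative-abundance vector
#' @param prabs non-empty character vector of p-RAB taxa
#' @param mode `"presence"` or `"abundance"`
#' @param presence_threshold detection threshold on relative abundance
#'   (default 0: profilers emit exact zeros)
#' @return fraction in `[0, 1]`
#' @export
fraction_prabs <- function(p, prabs, mode = c("presence", "abundance"),
                           presence_threshold = 0) {
  mode <- match.arg(mode)
  if (length(prabs) == 0) stop("prabs must be non-empty")
  if (is.null(names(p))) stop("`p` must be named by taxon")
  if (mode == "presence") {
    n_all <- sum(p > presence_threshold)
    if (n_all == 0) stop("no taxon above the presence threshold in this sample")
    sum(p[intersect(prabs, names(p))] > presence_threshold) / n_all
  } else {
    if (sum(p) == 0) stop("sample has zero total abundance")
    sum(p[intersect(prabs, names(p))]) / sum(p)
  }
}

#' Per-sample diversity profiles
#'
#' Computes TD, FD, FR, both p-RAB fractions and days since the end of
#' antibiotics for every sample of a table.
#'
#' @param table an [abundance_table()]
#' @param gcn a [gene_content()] covering the table's taxa, or a
#'   precomputed [functional_distance_matrix()]
#' @param prabs character vector of p-RAB taxa
#' @param abx_end_day study day on which antibiotics ended; `t_post` is
#'   `day - abx_end_day` for post-treatment samples and `NA` otherwise
#' @param restrict_to_gcn drop (and renormalize over) taxa absent from the
#'   gene-content matrix instead of erroring; coverage is reported via a
#'   message
#' @param presence_threshold passed to [fraction_prabs()]
#' @param binarize_gcn passed to [functional_distance_matrix()]
#' @return data.frame of class `diversity_profile` with columns
#'   `sample_id`, `TD`, `FD`, `FR`, `f_prabs_presence`, `f_prabs_abundance`,
#'   `t_post` plus the sample metadata
#' @export
diversity_profiles <- function(table, gcn, prabs, abx_end_day = 7,
                               restrict_to_gcn = FALSE,
                               presence_threshold = 0, binarize_gcn = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  d <- if (inherits(gcn, "functional_distance")) gcn
       else functional_distance_matrix(gcn, binarize = binarize_gcn)
  tab_taxa <- rownames(table$values)
  uncovered <- setdiff(tab_taxa, rownames(d))
  values <- table$values
  if (length(uncovered) > 0) {
    if (!restrict_to_gcn)
      stop("taxa absent from the gene-content matrix: ",
           paste(uncovered, collapse = ", "),
           " (use restrict_to_gcn = TRUE to renormalize over covered taxa)")
    message(sprintf("restricting to GCN: %d/%d taxa covered",
                    length(tab_taxa) - length(uncovered), length(tab_taxa)))
    values <- values[setdiff(tab_taxa, uncovered), , drop = FALSE]
    values <- sweep(values, 2, colSums(values), "/")
  }
  rows <- lapply(seq_len(ncol(values)), function(k) {
    p <- values[, k]
    TD <- taxonomic_diversity(p)
    FD <- functional_diversity(p, d)
    data.frame(sample_id = colnames(values)[k], TD = TD, FD = FD,
               FR = functional_redundancy(TD, FD),
               f_prabs_presence = fraction_prabs(p, prabs, "presence",
                                                 presence_threshold),
               f_prabs_abundance = fraction_prabs(p, prabs, "abundance"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  md <- table$metadata
  out$t_post <- ifelse(md$timepoint == "post", md$day - abx_end_day, NA_real_)
  out <- cbind(out, md[setdiff(names(md), "sample_id")])
  class(out) <- c("diversity_profile", "data.frame")
  out
}

#' Regress a p-RAB fraction on recovery time and a diversity covariate
#'
#' Ordinary least squares of `f_prabs ~ t_post + covariate` over
#' post-treatment samples, with the overall F test and per-coefficient t
#' tests.
#'
#' @param profiles a [diversity_profiles()] data.frame
#' @param response `"presence"` or `"abundance"` fraction
#' @param covariate `"TD"`, `"FD"` or `"FR"`
#' @return list with `coefficients`, `f_statistic`, `p_value`, and the
#'   underlying `lm` fit
#' @export
regress_fprabs <- function(profiles, response = c("presence", "abundance"),
                           covariate = c("TD", "FD", "FR")) {
  response <- match.arg(response)
  covariate <- match.arg(covariate)
  d <- profiles[!is.na(profiles$t_post), , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 post-treatment profiles")
  ycol <- paste0("f_prabs_", response)
  if (sd(d[[covariate]]) == 0) stop("covariate '", covariate, "' is constant")
  dat <- data.frame(f = d[[ycol]], t_post = d$t_post, cov = d[[covariate]])
  fit <- lm(f ~ t_post + cov, data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(coefficients = sm$coefficients,
       f_statistic = unname(fstat[1]),
       p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
       fit = fit)
}

#' The packaged logistic recovery model
#'
#' Default coefficients are the published point estimates of the recovery
#' predictor `y = 0.4571 FD + 0.7309 TD + 0.4465 f - 0.8204`; all three
#' predictors promote recovery. Refit study-specific coefficients with
#' [fit_recovery_model()].
#'
#' @param beta_FD,beta_TD,beta_f,intercept model coefficients
#' @return object of class `recovery_model`
#' @export
recovery_model <- function(beta_FD = 0.4571, beta_TD = 0.7309,
                           beta_f = 0.4465, intercept = -0.8204) {
  stopifnot(is.finite(beta_FD), is.finite(beta_TD), is.finite(beta_f),
            is.finite(intercept))
  structure(list(beta_FD = beta_FD, beta_TD = beta_TD, beta_f = beta_f,
                 intercept = intercept), class = "recovery_model")
}

#' @export
print.recovery_model <- function(x, ...) {
  cat(sprintf("recovery_model: y = %.4f FD + %.4f TD + %.4f f %+.4f\n",
              x$beta_FD, x$beta_TD, x$beta_f, x$intercept))
  invisible(x)
}

#' Predict recovery from diversity statistics
#'
#' @param model a [recovery_model()]
#' @param FD,TD,f numeric vectors (recycled) of functional diversity,
#'   taxonomic diversity and p-RAB fraction
#' @param threshold classification threshold on the probability
#' @return data.frame with `y` (linear predictor), `probability`
#'   (`1/(1+exp(-y))`) and `predicted` label
#' @export
predict_recovery <- function(model, FD, TD, f, threshold = 0.5) {
  stopifnot(inherits(model, "recovery_model"))
  y <- model$beta_FD * FD + model$beta_TD * TD + model$beta_f * f +
    model$intercept
  prob <- 1 / (1 + exp(-y))
  data.frame(y = y, probability = prob,
             predicted = ifelse(prob >= threshold, "recoverer", "non_recoverer"),
             stringsAsFactors = FALSE)
}

#' Refit the logistic recovery model
#'
#' Maximum-likelihood logistic regression of recovery status on
#' (FD, TD, f), with repeated stratified cross-validation for AUC and
#' accuracy. Perfect separation (detected via `glm` non-convergence or
#' exploding coefficients) triggers a ridge-stabilised refit
#' (`l2` penalty), which is flagged in the result.
#'
#' @param FD,TD,f numeric predictor vectors
#' @param label 0/1 vector or `"recoverer"`/`"non_recoverer"` labels
#' @param n_folds,n_repeats cross-validation design
#' @param seed fold seed
#' @param l2 ridge strength used only for the separation fallback
#' @return list with `model` (a [recovery_model()]), `auc_mean`,
#'   `accuracy_mean`, `ridged` flag
#' @export
fit_recovery_model <- function(FD, TD, f, label, n_folds = 5, n_repeats = 5,
                               seed = 1L, l2 = 1e-2) {
  y <- if (is.numeric(label)) as.numeric(label)
       else as.numeric(label == "recoverer")
  if (length(unique(y)) < 2) stop("both classes must be present")
  dat <- data.frame(y = y, FD = FD, TD = TD, f = f)

  fit_once <- function(d) {
    g <- suppressWarnings(glm(y ~ FD + TD + f, data = d, family = binomial()))
    sep <- !g$converged || any(abs(coef(g)) > 50)
    if (sep) {
      r <- ridge_logistic(as.matrix(d[c("FD", "TD", "f")]), d$y, lambda = l2)
      list(coef = r$coefficients, ridged = TRUE)
    } else {
      list(coef = coef(g), ridged = FALSE)
    }
  }
  full <- fit_once(dat)
  cf <- full$coef

  aucs <- accs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(seed + 1000L * r)
    fold <- stratified_folds(y, n_folds)
    oof <- numeric(length(y))
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      m <- fit_once(dat[tr, , drop = FALSE])
      eta <- drop(cbind(1, as.matrix(dat[!tr, c("FD", "TD", "f")])) %*% m$coef)
      oof[!tr] <- 1 / (1 + exp(-eta))
    }
    aucs[r] <- auroc(oof, y)
    accs[r] <- mean((oof >= 0.5) == (y == 1))
  }
  list(model = recovery_model(beta_FD = unname(cf["FD"]),
                              beta_TD = unname(cf["TD"]),
                              beta_f = unname(cf["f"]),
                              intercept = unname(cf[1])),
       auc_mean = mean(aucs), accuracy_mean = mean(accs),
       ridged = full$ridged)
}

#' Pearson and Spearman correlations among diversity predictors
#'
#' @param profiles a [diversity_profiles()] data.frame (>= 5 rows used)
#' @param columns predictor columns to correlate
#' @return data.frame with one row per pair and `pearson`, `pearson_p`,
#'   `spearman`, `spearman_p` (NA for constant columns)
#' @export
correlate_predictors <- function(profiles,
                                 columns = c("FD", "TD", "f_prabs_presence",
                                             "f_prabs_abundance")) {
  columns <- intersect(columns, names(profiles))
  if (nrow(profiles) < 5) stop("need at least 5 profiles")
  prs <- combn(columns, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    x <- profiles[[pr[1]]]; y <- profiles[[pr[2]]]
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(var1 = pr[1], var2 = pr[2], pearson = NA_real_,
                        pearson_p = NA_real_, spearman = NA_real_,
                        spearman_p = NA_real_, stringsAsFactors = FALSE))
    pe <- cor.test(x, y, method = "pearson")
    sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
    data.frame(var1 = pr[1], var2 = pr[2],
               pearson = unname(pe$estimate), pearson_p = pe$p.value,
               spearman = unname(sp$estimate), spearman_p = sp$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
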