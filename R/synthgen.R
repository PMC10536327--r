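#' Configuration for the synthetic multi-cohort generator
#'
#' Defaults describe a study of four cohorts of 20 subjects sampled at three
#' time points around an antibiotic course, with 60 species, 8 planted
#' recovery-associated taxa enriched ~4.5-fold (1.5 log-units) in
#' recoverers, a 60% loss of Gini-Simpson diversity during treatment, and
#' half of the subjects recovering.
#'
#' @param n_cohorts number of cohorts
#' @param subjects_per_cohort subjects per cohort (>= 4)
#' @param n_taxa number of species
#' @param n_gene_families gene families in the gene-content matrix
#' @param n_planted_prabs number of planted recovery-associated taxa
#' @param effect_size log-scale enrichment of planted taxa in recoverers at
#'   pre and post (natural-log units)
#' @param recoverer_fraction fraction of subjects that recover, in (0,1)
#' @param disturbance_depth fraction of Gini-Simpson diversity lost during
#'   antibiotics, in (0,1)
#' @param overdispersion Dirichlet concentration scale for per-sample noise
#'   (larger = less noisy)
#' @param detection_limit relative abundances below this are set to zero and
#'   the sample renormalized, emulating a profiler's detection floor; 0
#'   keeps compositions strictly positive (useful for calibration studies
#'   that need tie-free ranks)
#' @param baseline_log_sd sd of cohort-level log baseline abundances
#' @param subject_log_sd sd of subject-level log deviations
#' @param gcn_core_fraction fraction of gene families shared by every taxon
#' @param n_gcn_clusters number of functional clusters for accessory families
#' @param gcn_within_prob probability a taxon carries a family of its own
#'   cluster block
#' @param gcn_noise_prob probability a taxon carries a family of a foreign
#'   block
#' @param seed integer root seed; all substreams derive from it by fixed
#'   offsets
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_cohorts = 4, subjects_per_cohort = 20,
                              n_taxa = 60, n_gene_families = 400,
                              n_planted_prabs = 8, effect_size = 1.5,
                              recoverer_fraction = 0.5,
                              disturbance_depth = 0.6,
                              overdispersion = 300,
                              detection_limit = 1e-4,
                              baseline_log_sd = 1.1,
                              subject_log_sd = 0.6,
                              gcn_core_fraction = 0.3,
                              n_gcn_clusters = 5,
                              gcn_within_prob = 0.8,
                              gcn_noise_prob = 0.02,
                              seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              subjects_per_cohort = as.integer(subjects_per_cohort),
              n_taxa = as.integer(n_taxa),
              n_gene_families = as.integer(n_gene_families),
              n_planted_prabs = as.integer(n_planted_prabs),
              effect_size = effect_size,
              recoverer_fraction = recoverer_fraction,
              disturbance_depth = disturbance_depth,
              overdispersion = overdispersion,
              detection_limit = detection_limit,
              baseline_log_sd = baseline_log_sd,
              subject_log_sd = subject_log_sd,
              gcn_core_fraction = gcn_core_fraction,
              n_gcn_clusters = as.integer(n_gcn_clusters),
              gcn_within_prob = gcn_within_prob,
              gcn_noise_prob = gcn_noise_prob,
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(n_cohorts, subjects_per_cohort, n_taxa, n_gene_families,
              n_gcn_clusters) <= 0))
      stop("all counts must be positive")
    if (n_planted_prabs > n_taxa) stop("n_planted_prabs must be <= n_taxa")
    if (n_planted_prabs < 0) stop("n_planted_prabs must be >= 0")
    if (recoverer_fraction <= 0 || recoverer_fraction >= 1)
      stop("recoverer_fraction must lie in (0, 1)")
    if (disturbance_depth < 0 || disturbance_depth >= 1)
      stop("disturbance_depth must lie in [0, 1)")
    if (effect_size < 0) stop("effect_size must be >= 0")
    if (overdispersion <= 0) stop("overdispersion must be positive")
    if (detection_limit < 0 || detection_limit >= 0.5)
      stop("detection_limit must lie in [0, 0.5)")
  })
  structure(cfg, class = c("simulation_config", "list"))
}

#' Planted recovery-associated taxon names for a config
#' @param config a [simulation_config()]
#' @return character vector of taxon identifiers
#' @export
planted_prabs <- function(config) {
  if (config$n_planted_prabs == 0) return(character(0))
  sprintf("sp%03d", seq_len(config$n_planted_prabs))
}

rdirichlet1 <- function(alpha, detection_limit = 0) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1 # pathological tiny alpha
  x <- x / sum(x)
  if (detection_limit > 0) {
    x[x < detection_limit] <- 0
    x <- x / sum(x)
  }
  x
}

gini_simpson_raw <- function(p) 1 - sum(p^2)

#' Generate a synthetic gene-content matrix
#'
#' A `gcn_core_fraction` share of gene families is carried by every taxon
#' (creating functional redundancy); the remaining families are split into
#' `n_gcn_clusters` blocks, and taxa assigned round-robin to clusters carry
#' families of their own block with probability `gcn_within_prob` and foreign
#' families with probability `gcn_noise_prob`. Each taxon with a non-empty
#' own block is guaranteed at least one accessory family so no row is
#' all-zero when the core is empty.
#'
#' @param config a [simulation_config()]
#' @param core_size optional explicit core size (overrides
#'   `gcn_core_fraction`); must not exceed `n_gene_families`
#' @return a [gene_content()] binary incidence matrix
#' @export
generate_gcn <- function(config, core_size = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(core_size))
    core_size <- round(config$gcn_core_fraction * config$n_gene_families)
  if (core_size > config$n_gene_families)
    stop("requested core size exceeds n_gene_families")
  set.seed(config$seed + 104729L)
  n_taxa <- config$n_taxa
  n_fam <- config$n_gene_families
  taxa <- sprintf("sp%03d", seq_len(n_taxa))
  fams <- sprintf("fam%04d", seq_len(n_fam))
  m <- matrix(0, n_taxa, n_fam, dimnames = list(taxa, fams))
  if (core_size > 0) m[, seq_len(core_size)] <- 1
  n_acc <- n_fam - core_size
  if (n_acc > 0) {
    k <- min(config$n_gcn_clusters, n_acc, n_taxa)
    block <- rep(seq_len(k), length.out = n_acc)           # family -> cluster
    cluster <- rep(seq_len(k), length.out = n_taxa)        # taxon -> cluster
    for (i in seq_len(n_taxa)) {
      own <- which(block == cluster[i]) + core_size
      foreign <- which(block != cluster[i]) + core_size
      m[i, own] <- rbinom(length(own), 1, config$gcn_within_prob)
      if (length(foreign) > 0)
        m[i, foreign] <- rbinom(length(foreign), 1, config$gcn_noise_prob)
      if (sum(m[i, own]) == 0) m[i, own[1]] <- 1
    }
  }
  gene_content(m)
}

# Diversity of the convex combination (1-l)*p + l*q, as a function of l.
mix_to_target <- function(p, q, target, tol = 1e-9) {
  f <- function(l) gini_simpson_raw((1 - l) * p + l * q) - target
  f0 <- f(0); f1 <- f(1)
  if (f0 * f1 > 0) {
    # target outside the reachable range: pick the closer endpoint
    return(if (abs(f0) <= abs(f1)) p else q)
  }
  l <- uniroot(f, c(0, 1), tol = tol)$root
  (1 - l) * p + l * q
}

#' Generate synthetic multi-cohort longitudinal data with ground truth
#'
#' Per subject, three samples (pre, during, post) are drawn. Baseline
#' compositions come from a log-normal profile (cohort-level means plus
#' subject-level deviations) with Dirichlet resampling per sample. During
#' antibiotics a subject's composition is pulled toward a single "resistant"
#' taxon until Gini-Simpson diversity drops to
#' `(1 - disturbance_depth)` of that subject's pre-treatment value. Post
#' compositions are convex combinations of the subject's pre and during
#' samples (or of pre and the uniform vector, when diversity must rise)
#' calibrated so recoverers land inside the cohort's pooled pre-treatment
#' interquartile range and non-recoverers land below its first quartile.
#' Planted taxa receive the configured log-scale enrichment in recoverers at
#' pre and post.
#'
#' @param config a [simulation_config()]
#' @return list with `table` (an [abundance_table()]), `truth` (a
#'   [recovery_labels()] data.frame of ground-truth labels) and `planted`
#'   (character vector of planted taxa)
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_taxa <- config$n_taxa
  taxa_ids <- sprintf("sp%03d", seq_len(n_taxa))
  planted <- planted_prabs(config)
  conc <- config$overdispersion
  unif <- rep(1 / n_taxa, n_taxa)

  cols <- list(); meta <- list(); truth <- list()
  for (co in seq_len(config$n_cohorts)) {
    set.seed(config$seed + 7919L * co)
    cohort_id <- sprintf("cohort%02d", co)
    mu <- rnorm(n_taxa, 0, config$baseline_log_sd)
    n_sub <- config$subjects_per_cohort
    n_rec <- max(1L, min(n_sub - 1L, round(config$recoverer_fraction * n_sub)))
    is_rec <- rep(FALSE, n_sub)
    is_rec[sample.int(n_sub, n_rec)] <- TRUE

    pre <- during <- matrix(0, n_taxa, n_sub)
    pre_comp <- during_comp <- matrix(0, n_taxa, n_sub)
    for (s in seq_len(n_sub)) {
      eta <- mu + rnorm(n_taxa, 0, config$subject_log_sd)
      if (is_rec[s] && length(planted) > 0)
        eta[seq_along(planted)] <- eta[seq_along(planted)] + config$effect_size
      comp <- exp(eta - max(eta)); comp <- comp / sum(comp)
      pre_comp[, s] <- comp
      pre[, s] <- rdirichlet1(conc * comp, config$detection_limit)
      # during: collapse toward one resistant taxon to the target diversity
      d_target <- (1 - config$disturbance_depth) * gini_simpson_raw(pre[, s])
      res <- sample.int(n_taxa, 1, prob = pre[, s])
      point <- numeric(n_taxa); point[res] <- 1
      qcomp <- mix_to_target(pre[, s], point, d_target)
      during_comp[, s] <- qcomp
      during[, s] <- rdirichlet1(conc * qcomp, config$detection_limit)
    }

    pre_div <- apply(pre, 2, gini_simpson_raw)
    q <- quantile(pre_div, c(0.25, 0.75), names = FALSE)
    iqr_w <- max(q[2] - q[1], 0.02)

    post <- matrix(0, n_taxa, n_sub)
    for (s in seq_len(n_sub)) {
      if (is_rec[s]) {
        target <- quantile(pre_div, runif(1, 0.45, 0.9), names = FALSE)
      } else {
        target <- q[1] - (0.5 + 0.4 * runif(1)) * iqr_w
        target <- max(target, 1.05 * gini_simpson_raw(during[, s]))
        target <- min(target, q[1] - 0.4 * iqr_w)
        target <- max(target, 0.01)
      }
      base <- pre[, s]
      other <- if (target > gini_simpson_raw(base)) unif else during[, s]
      comp <- mix_to_target(base, other, target)
      post[, s] <- rdirichlet1(conc * comp, config$detection_limit)
    }

    subj_ids <- sprintf("%s_s%03d", cohort_id, seq_len(n_sub))
    for (s in seq_len(n_sub)) {
      for (tp in c("pre", "during", "post")) {
        sample_id <- sprintf("%s_%s", subj_ids[s], tp)
        cols[[sample_id]] <- switch(tp, pre = pre[, s], during = during[, s],
                                    post = post[, s])
        meta[[sample_id]] <- data.frame(
          sample_id = sample_id, subject_id = subj_ids[s],
          cohort_id = cohort_id, timepoint = tp,
          day = switch(tp, pre = -3L, during = 4L,
                       post = sample(14:90, 1)),
          group = "abx", stringsAsFactors = FALSE)
      }
    }
    truth[[cohort_id]] <- data.frame(
      subject_id = subj_ids, cohort_id = cohort_id,
      label = ifelse(is_rec, "recoverer", "non_recoverer"),
      stringsAsFactors = FALSE)
  }

  values <- do.call(cbind, cols)
  rownames(values) <- taxa_ids
  metadata <- do.call(rbind, unname(meta))
  truth <- do.call(rbind, unname(truth))
  list(table = abundance_table(values, metadata),
       truth = recovery_labels(truth$subject_id, truth$cohort_id, truth$label),
       planted = planted)
}
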