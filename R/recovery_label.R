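#' Gini-Simpson diversity of a composition
#'
#' `D = 1 - sum(p^2)`: the probability that two members drawn at random from
#' the community belong to different taxa. Input must already be a relative
#' abundance vector.
#'
#' @param p non-negative numeric vector summing to 1 (tolerance 1e-6)
#' @param index `"gini_simpson"` (default) or `"inv_simpson"`
#'   (`1 / sum(p^2)`, provided for sensitivity analysis)
#' @return a single numeric value
#' @export
gini_simpson <- function(p, index = c("gini_simpson", "inv_simpson")) {
  index <- match.arg(index)
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("composition does not sum to 1 (|sum - 1| > 1e-6); renormalize first")
  s2 <- sum(p^2)
  if (index == "gini_simpson") 1 - s2 else 1 / s2
}

#' Shannon diversity (natural log), a plotting convenience
#' @inheritParams gini_simpson
#' @return a single numeric value
#' @export
shannon <- function(p) {
  if (abs(sum(p) - 1) > 1e-6) stop("composition does not sum to 1; renormalize")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample diversity of an abundance table
#' @param table an [abundance_table()]
#' @inheritParams gini_simpson
#' @return data.frame with `sample_id` and `diversity`, plus the metadata
#' @export
sample_diversity <- function(table, index = c("gini_simpson", "inv_simpson")) {
  index <- match.arg(index)
  d <- apply(table$values, 2, gini_simpson, index = index)
  cbind(table$metadata,
        data.frame(diversity = unname(d), stringsAsFactors = FALSE))
}

#' Label subjects as recoverers or non-recoverers
#'
#' Per cohort, the pooled distribution of pre-treatment Gini-Simpson
#' diversities defines an interquartile range. A subject is a recoverer iff
#' its post-treatment diversity reaches at least the first quartile of that
#' pooled pre distribution, and its during-treatment diversity fell below its
#' own pre-treatment diversity (i.e. a disturbance actually occurred).
#' Subjects with several samples at a time point contribute their mean
#' diversity.
#'
#' @param table an [abundance_table()] whose metadata carries `pre`,
#'   `during`, `post` time points
#' @param quartile_scope `"per_cohort"` (default) or `"pooled"` across
#'   cohorts
#' @param pool_during also pool during-treatment samples into the reference
#'   distribution (default FALSE; pooling depressed during-values deflates
#'   the first quartile and over-calls recovery)
#' @param index diversity index passed to [gini_simpson()]
#' @return a [recovery_labels()] data.frame with diagnostic columns
#'   `pre_diversity`, `during_diversity`, `post_diversity`, `q1_pre`
#' @export
label_recoverers <- function(table, quartile_scope = c("per_cohort", "pooled"),
                             pool_during = FALSE,
                             index = c("gini_simpson", "inv_simpson")) {
  quartile_scope <- match.arg(quartile_scope)
  index <- match.arg(index)
  stopifnot(inherits(table, "abundance_table"))
  div <- sample_diversity(table, index = index)

  per_subject <- aggregate(diversity ~ subject_id + cohort_id + timepoint,
                           data = div, FUN = mean)
  wide <- split(per_subject, per_subject$subject_id)
  rows <- lapply(wide, function(d) {
    tp <- setNames(d$diversity, d$timepoint)
    if (!all(c("pre", "during", "post") %in% names(tp))) return(NULL)
    data.frame(subject_id = d$subject_id[1], cohort_id = d$cohort_id[1],
               pre_diversity = tp[["pre"]], during_diversity = tp[["during"]],
               post_diversity = tp[["post"]], stringsAsFactors = FALSE)
  })
  dropped <- names(wide)[vapply(rows, is.null, logical(1))]
  if (length(dropped) > 0)
    warning("subjects lacking a time point excluded: ",
            paste(dropped, collapse = ", "))
  subj <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(subj) || nrow(subj) == 0) stop("no subject has all three time points")

  n_per_cohort <- table(subj$cohort_id)
  if (any(n_per_cohort < 4))
    stop("cohort(s) with fewer than 4 complete subjects (quartiles need support): ",
         paste(names(n_per_cohort)[n_per_cohort < 4], collapse = ", "))

  ref_pool <- function(d) {
    ref <- d$pre_diversity
    if (pool_during) ref <- c(ref, d$during_diversity)
    ref
  }
  if (quartile_scope == "pooled") {
    q1 <- quantile(ref_pool(subj), 0.25, names = FALSE)
    subj$q1_pre <- q1
  } else {
    q1_by <- vapply(split(subj, subj$cohort_id),
                    function(d) quantile(ref_pool(d), 0.25, names = FALSE),
                    numeric(1))
    subj$q1_pre <- q1_by[subj$cohort_id]
  }
  lab <- ifelse(subj$post_diversity >= subj$q1_pre &
                  subj$during_diversity < subj$pre_diversity,
                "recoverer", "non_recoverer")
  recovery_labels(subj$subject_id, subj$cohort_id, lab,
                  pre_diversity = subj$pre_diversity,
                  during_diversity = subj$during_diversity,
                  post_diversity = subj$post_diversity,
                  q1_pre = subj$q1_pre)
}

#' Prevalence-balance recovery index of a sample
#'
#' A GMHI-style log-ratio of the detected fraction of recovery-associated
#' taxa to the detected fraction of non-recovery-associated taxa:
#' `log10((R_p/|prabs| + eps) / (R_n/|nrabs| + eps))`, where `R_p` and `R_n`
#' count set members with abundance above `theta`. Positive values indicate a
#' recovery-like composition.
#'
#' @param p named relative-abundance vector for one sample
#' @param prabs,nrabs disjoint, non-empty character vectors of taxa
#'   associated with recovery / non-recovery
#' @param theta presence threshold on relative abundance (default 1e-4)
#' @param epsilon pseudocount keeping the index finite (default 1e-5)
#' @return a single numeric value (log10 scale)
#' @export
recovery_index <- function(p, prabs, nrabs, theta = 1e-4, epsilon = 1e-5) {
  if (length(prabs) == 0 || length(nrabs) == 0)
    stop("prabs and nrabs must be non-empty")
  if (length(intersect(prabs, nrabs)) > 0)
    stop("prabs and nrabs overlap: ",
         paste(intersect(prabs, nrabs), collapse = ", "))
  if (is.null(names(p))) stop("`p` must be a named abundance vector")
  if (theta < 0) stop("theta must be >= 0")
  present <- function(set) {
    x <- p[intersect(set, names(p))]
    sum(x > theta)
  }
  rp <- present(prabs) / length(prabs)
  rn <- present(nrabs) / length(nrabs)
  log10((rp + epsilon) / (rn + epsilon))
}
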