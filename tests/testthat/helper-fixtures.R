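# Shared in-code fixtures and independent oracles.

# Minimal abundance table: values is a taxa x samples matrix (or vector layout
# helpers below); metadata filled with one cohort unless supplied.
make_table <- function(values, timepoint = NULL, subject = NULL,
                       cohort = NULL, day = NULL, normalize = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("t%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  n <- ncol(values)
  md <- data.frame(
    sample_id = colnames(values),
    subject_id = if (is.null(subject)) colnames(values) else subject,
    cohort_id = if (is.null(cohort)) "c1" else cohort,
    timepoint = if (is.null(timepoint)) "pre" else timepoint,
    day = if (is.null(day)) -1L else day,
    group = "g", stringsAsFactors = FALSE)
  suppressWarnings(abundance_table(values, md, normalize = normalize))
}

# Table of iid continuous abundances (null data, no class signal).
random_table <- function(n_taxa, n_samples, seed = 1) {
  set.seed(seed)
  v <- matrix(rexp(n_taxa * n_samples), n_taxa, n_samples)
  make_table(v)
}

two_class_labels <- function(table, recoverers) {
  subj <- unique(table$metadata$subject_id)
  recovery_labels(subj,
                  table$metadata$cohort_id[match(subj, table$metadata$subject_id)],
                  ifelse(subj %in% recoverers, "recoverer", "non_recoverer"))
}

# ---- brute-force graph oracles (independent of igraph shortest paths) ----

# BFS distances from an adjacency matrix.
bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; depth <- 0
    visited <- rep(FALSE, n); visited[s] <- TRUE
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] > 0 & !visited)
        d[s, nb] <- depth
        visited[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
      frontier <- nxt
    }
  }
  d
}

bf_average_efficacy <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_mEDR <- function(adj) {
  n <- nrow(adj)
  ea <- bf_average_efficacy(adj)
  if (ea == 0) return(NA_real_)
  edr <- vapply(seq_len(n), function(i) {
    ea2 <- bf_average_efficacy(adj[-i, -i, drop = FALSE])
    (ea - ea2) / ea
  }, numeric(1))
  max(edr)
}

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(0, n, n)
  adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p)
  adj + t(adj)
}

igraph_from_adj <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(nrow(adj)))
  g
}
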