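#' Build a Spearman co-occurrence network
#'
#' Spearman rho and a two-sided p-value are computed for every taxon pair
#' passing a prevalence prefilter; edges with `|rho| > r_threshold` and
#' `p < p_threshold` are retained. Isolated nodes that passed the
#' prevalence filter remain in the node set. P-values use the asymptotic t
#' approximation for n >= 10 samples and the exact permutation distribution
#' (via [stats::cor.test()]) below that.
#'
#' @param table an [abundance_table()] (>= 5 samples)
#' @param r_threshold minimum `|rho|` for an edge (default 0.4)
#' @param p_threshold maximum p-value for an edge (default 0.05)
#' @param min_prevalence taxa present in at most this fraction of samples
#'   are dropped before correlation (default 0.1)
#' @param clr apply a centred log-ratio transform before correlating
#'   (sensitivity analysis; rank correlations on relative abundances are the
#'   default)
#' @return object of class `conet` wrapping an igraph graph with edge
#'   attributes `rho` and `p_value`
#' @export
build_conet <- function(table, r_threshold = 0.4, p_threshold = 0.05,
                        min_prevalence = 0.1, clr = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  n <- ncol(table$values)
  if (n < 5) stop("need at least 5 samples (rank-correlation p-values unreliable)")
  v <- table$values
  keep <- rowMeans(v > 0) >= min_prevalence
  v <- v[keep, , drop = FALSE]
  if (clr) {
    lv <- log(v + 1e-6)
    v <- sweep(lv, 2, colMeans(lv), "-")
  }
  taxa_ids <- rownames(v)
  g <- igraph::make_empty_graph(n = length(taxa_ids), directed = FALSE)
  igraph::V(g)$name <- taxa_ids
  if (length(taxa_ids) >= 2) {
    X <- t(v)
    rho <- suppressWarnings(cor(X, method = "spearman"))
    rho[is.na(rho)] <- 0
    edges <- character(0); e_rho <- e_p <- numeric(0)
    for (i in seq_len(length(taxa_ids) - 1)) {
      for (j in (i + 1):length(taxa_ids)) {
        r <- rho[i, j]
        if (abs(r) <= r_threshold) next
        p <- spearman_p(X[, i], X[, j], r)
        if (p >= p_threshold) next
        edges <- c(edges, taxa_ids[i], taxa_ids[j])
        e_rho <- c(e_rho, r); e_p <- c(e_p, p)
      }
    }
    if (length(edges) > 0) {
      g <- igraph::add_edges(g, edges)
      igraph::E(g)$rho <- e_rho
      igraph::E(g)$p_value <- e_p
    }
  }
  structure(list(graph = g), class = "conet")
}

# Two-sided Spearman p (internal): t approximation for n >= 10, exact
# permutation distribution below.
spearman_p <- function(x, y, rho = NULL) {
  n <- length(x)
  if (n < 10) {
    return(suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value))
  }
  if (is.null(rho)) rho <- cor(x, y, method = "spearman")
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t_stat), n - 2)
}

#' @export
print.conet <- function(x, ...) {
  cat(sprintf("conet: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Network topology summary
#'
#' @param network a `conet` (or bare igraph graph)
#' @return list with `n_nodes`, `n_edges`, `mean_degree` (`2E/N`; all zero
#'   for the empty network)
#' @export
topology <- function(network) {
  g <- conet_graph(network)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  list(n_nodes = n, n_edges = e,
       mean_degree = if (n > 0) 2 * e / n else 0)
}

conet_graph <- function(network) {
  g <- if (inherits(network, "conet")) network$graph
       else if (inherits(network, "igraph")) network
       else stop("expected a conet or igraph object")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Hub nodes of a co-occurrence network
#'
#' Hubs are nodes whose degree reaches the `(1 - top_fraction)` quantile of
#' the distinct degree values in the network. Working on distinct values
#' makes the rule deterministic under heavy ties: in a regular graph every
#' node ties at the threshold and all are hubs, while in a star only the
#' centre exceeds it.
#'
#' @param network a `conet` or igraph graph
#' @param top_fraction fraction of the degree range counted as hubs
#'   (default 0.2)
#' @return character vector of hub node names (empty for an empty network)
#' @export
hub_nodes <- function(network, top_fraction = 0.2) {
  g <- conet_graph(network)
  if (igraph::vcount(g) == 0) return(character(0))
  deg <- igraph::degree(g)
  thr <- quantile(sort(unique(deg)), 1 - top_fraction, names = FALSE)
  names(deg)[deg >= thr]
}

#' Average efficacy of a network
#'
#' `E_a = 1/(n(n-1)) * sum_{i != j} 1/d_ij` with `d_ij` the shortest-path
#' length in edges and `1/d_ij = 0` for disconnected pairs, so the formula
#' is total on sparse post-antibiotic networks. `E_a` is 1 for a complete
#' graph and 0 for a fully disconnected one.
#'
#' @param network a `conet` or igraph graph with >= 2 nodes
#' @return `E_a` in `[0, 1]`
#' @export
average_efficacy <- function(network) {
  g <- conet_graph(network)
  n <- igraph::vcount(g)
  if (n < 2) stop("average efficacy needs at least 2 nodes")
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability: maximal efficacy-decreasing ratio
#'
#' Each node is removed in turn, the average efficacy `E_a'` of the reduced
#' network is recomputed, and the efficacy-decreasing ratio
#' `EDR = (E_a - E_a') / E_a` is recorded; the maximum over nodes is the
#' `mEDR`, reported with its argmax node(s). By default `E_a'` is
#' normalized by the reduced node count `n - 1` (the reduced network is
#' treated as a network in its own right); `normalization = "original"`
#' keeps the original `n`.
#'
#' @param network a `conet` or igraph graph with >= 3 nodes
#' @param normalization `"reduced"` (default) or `"original"`
#' @return list with `mEDR` (NA with an explanatory `note` when `E_a = 0`),
#'   `nodes` (argmax, all ties), and `edr` (named vector over nodes)
#' @export
vulnerability_mEDR <- function(network, normalization = c("reduced", "original")) {
  normalization <- match.arg(normalization)
  g <- conet_graph(network)
  n <- igraph::vcount(g)
  if (n < 3) stop("vulnerability needs at least 3 nodes (removal must leave >= 2)")
  ea <- average_efficacy(g)
  if (ea == 0)
    return(list(mEDR = NA_real_, nodes = character(0),
                edr = setNames(rep(NA_real_, n), igraph::V(g)$name),
                note = "E_a = 0: mEDR undefined"))
  edr <- vapply(seq_len(n), function(i) {
    g2 <- igraph::delete_vertices(g, i)
    ea2 <- average_efficacy(g2)
    if (normalization == "original")
      ea2 <- ea2 * ((n - 1) * (n - 2)) / (n * (n - 1))
    (ea - ea2) / ea
  }, numeric(1))
  names(edr) <- igraph::V(g)$name
  m <- max(edr)
  list(mEDR = m, nodes = names(edr)[edr == m], edr = edr)
}

#' Full metric panel for one network
#'
#' @param network a `conet` or igraph graph
#' @param top_fraction passed to [hub_nodes()]
#' @return list combining [topology()], [hub_nodes()],
#'   [average_efficacy()] and [vulnerability_mEDR()] (the latter two NA for
#'   networks too small to support them)
#' @export
network_metrics <- function(network, top_fraction = 0.2) {
  top <- topology(network)
  g <- conet_graph(network)
  ea <- if (igraph::vcount(g) >= 2) average_efficacy(g) else NA_real_
  vul <- if (igraph::vcount(g) >= 3) vulnerability_mEDR(g)
         else list(mEDR = NA_real_, nodes = character(0))
  c(top, list(hub_nodes = hub_nodes(network, top_fraction),
              E_a = ea, mEDR = vul$mEDR, mEDR_nodes = vul$nodes))
}
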