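#' Seed set from differential-abundance and phospho calls
#'
#' The seed set is the union of proteins with abundance calls and proteins
#' owning called phosphopeptides; proteins in both lists are tagged
#' `both`.
#'
#' @param abundance_proteins protein ids dysregulated at the abundance
#'   level.
#' @param phospho_proteins protein ids owning dysregulated
#'   phosphopeptides.
#' @return data.frame `protein_id`, `change_kind` in
#'   `abundance`/`phospho`/`both`.
#' @export
build_seed_set <- function(abundance_proteins, phospho_proteins) {
  a <- unique(as.character(abundance_proteins))
  p <- unique(as.character(phospho_proteins))
  all <- union(a, p)
  if (length(all) == 0) stop("empty seed set")
  kind <- ifelse(all %in% a & all %in% p, "both",
                 ifelse(all %in% a, "abundance", "phospho"))
  data.frame(protein_id = all, change_kind = kind, stringsAsFactors = FALSE)
}

#' Expand seeds to their direct high-confidence interactors
#'
#' Node set = seeds plus all background neighbors of seeds; edge set = all
#' background edges with both endpoints in the node set. Non-seed nodes
#' are tagged `interactor_only`. Seeds missing from the background are
#' retained as isolated nodes (with a warning when none is present).
#'
#' @param seeds data.frame from [build_seed_set()] (or character vector).
#' @param background an `interaction_network` (see [read_edge_list()]),
#'   already thresholded on the confidence score.
#' @return an `interaction_network` whose `nodes` carry `is_seed` and
#'   `change_kind`.
#' @export
expand_network <- function(seeds, background) {
  if (is.character(seeds)) {
    seeds <- data.frame(protein_id = unique(seeds),
                        change_kind = "abundance", stringsAsFactors = FALSE)
  }
  g <- background$graph
  present <- intersect(seeds$protein_id, igraph::V(g)$name)
  if (length(present) == 0) {
    warning("no seed present in background; returning isolated seeds")
    node_names <- seeds$protein_id
    sub <- igraph::make_empty_graph(n = 0, directed = FALSE)
    sub <- igraph::add_vertices(sub, length(node_names), name = node_names)
  } else {
    nb_idx <- unique(unlist(igraph::adjacent_vertices(g, present)))
    nb <- igraph::V(g)$name[nb_idx]
    node_names <- union(seeds$protein_id, union(present, nb))
    sub <- igraph::induced_subgraph(g, intersect(node_names,
                                                 igraph::V(g)$name))
    lonely <- setdiff(node_names, igraph::V(sub)$name)
    if (length(lonely)) sub <- igraph::add_vertices(sub, length(lonely),
                                                    name = lonely)
  }
  nodes <- data.frame(protein_id = igraph::V(sub)$name,
                      stringsAsFactors = FALSE)
  m <- match(nodes$protein_id, seeds$protein_id)
  nodes$is_seed <- !is.na(m)
  nodes$change_kind <- ifelse(nodes$is_seed, seeds$change_kind[m],
                              "interactor_only")
  nodes$degree <- as.integer(igraph::degree(sub)[nodes$protein_id])
  new_interaction_network(sub, nodes)
}

new_interaction_network <- function(graph, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- data.frame(protein_id = igraph::V(graph)$name,
                        degree = as.integer(igraph::degree(graph)),
                        stringsAsFactors = FALSE)
  }
  structure(list(graph = graph, nodes = nodes),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  if ("is_seed" %in% names(x$nodes)) {
    cat("  seeds:", sum(x$nodes$is_seed), " interactor-only:",
        sum(!x$nodes$is_seed), "\n")
  }
  invisible(x)
}

#' Edge data frame of an interaction network
#' @param network an `interaction_network`.
#' @return data.frame `protein_a`, `protein_b`, `combined_score`.
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network$graph)
  score <- igraph::edge_attr(network$graph, "score")
  if (is.null(score)) score <- rep(NA_real_, nrow(el))
  data.frame(protein_a = el[, 1], protein_b = el[, 2],
             combined_score = score, stringsAsFactors = FALSE)
}

#' Exact Poisson test for interaction-count enrichment
#'
#' Upper-tail probability `P(X >= observed)` for `X ~ Poisson(expected)`,
#' computed with the regularized gamma function (exact, no normal
#' approximation).
#'
#' @param observed_edges observed interaction count (nonnegative integer).
#' @param expected_edges expected count under the background edge density
#'   (positive real); see [expected_edge_count()].
#' @return upper-tail p-value.
#' @examples
#' edge_enrichment(10, 10)   # ~0.542
#' edge_enrichment(849, 189) # far below 5e-13
#' @export
edge_enrichment <- function(observed_edges, expected_edges) {
  if (observed_edges < 0) stop("observed_edges must be nonnegative")
  if (expected_edges <= 0) stop("expected_edges must be positive")
  if (observed_edges == 0) return(1.0)
  stats::ppois(observed_edges - 1, expected_edges, lower.tail = FALSE)
}

#' Expected edge count for a node set under the background density
#'
#' Background density is computed over the universe of detected proteins
#' present in the background graph; the expected count is (number of node
#' pairs) times that density.
#'
#' @param n_nodes nodes in the network under test.
#' @param background an `interaction_network`.
#' @param universe detected protein ids defining the background universe;
#'   defaults to all background nodes.
#' @return expected number of edges (real).
#' @export
expected_edge_count <- function(n_nodes, background, universe = NULL) {
  g <- background$graph
  if (is.null(universe)) {
    nu <- igraph::vcount(g)
    ne <- igraph::ecount(g)
  } else {
    keep <- intersect(unique(universe), igraph::V(g)$name)
    sub <- igraph::induced_subgraph(g, keep)
    nu <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
  }
  if (nu < 2) stop("background universe has fewer than 2 nodes")
  density <- ne / (nu * (nu - 1) / 2)
  choose(n_nodes, 2) * density
}

#' Fit discrete degree distributions and select the best family
#'
#' Zero-truncated maximum-likelihood fits on the full degree support
#' (minimum degree 1) for four candidate families: power law
#' (`p(k) = k^-alpha / zeta(alpha)`), Poisson, exponential (geometric on
#' k >= 1) and lognormal discretized by probability mass on integer bins.
#' The family with the lowest BIC is selected (for equal parameter counts
#' this is the highest log-likelihood; the dimension penalty keeps the
#' selection consistent, so the generating family is recovered as the
#' sample grows -- an unpenalized or AIC comparison over-selects the
#' 2-parameter lognormal with non-vanishing probability). Per-node tail
#' p-values `P(K >= k)` come from the selected family.
#'
#' @param degrees integer degrees; nodes with degree 0 are dropped.
#' @return object of class `degree_fit`: `family`, `params`, and per-family
#'   `loglik`, `aic`, `bic`; tail probabilities via [degree_tail_p()].
#' @export
fit_degree_distribution <- function(degrees) {
  k <- as.integer(degrees[degrees >= 1])
  if (length(k) < 10) stop("need at least 10 nodes with degree >= 1")
  if (length(unique(k)) == 1) {
    stop("all degrees equal; fit degenerate - use the empirical tail instead")
  }
  fits <- list(
    poisson = fit_ztpois(k),
    exponential = fit_ztgeom(k),
    power_law = fit_zeta(k),
    lognormal = fit_dlnorm(k)
  )
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  np <- vapply(fits, `[[`, numeric(1), "n_par")
  aic <- 2 * np - 2 * ll
  bic <- log(length(k)) * np - 2 * ll
  best <- names(which.min(bic))
  structure(list(family = best, params = fits[[best]]$params,
                 loglik = ll, aic = aic, bic = bic, n = length(k),
                 fits = fits),
            class = "degree_fit")
}

#' @export
print.degree_fit <- function(x, ...) {
  cat("Degree-distribution fit on", x$n, "nodes (k >= 1)\n")
  cat("Selected family:", x$family, "(",
      paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
      ")\n")
  tab <- data.frame(loglik = round(x$loglik, 2), AIC = round(x$aic, 2),
                    BIC = round(x$bic, 2))
  print(tab)
  invisible(x)
}

# --- zero-truncated families -------------------------------------------

fit_ztpois <- function(k) {
  nll <- function(lam) {
    -sum(stats::dpois(k, lam, log = TRUE)) +
      length(k) * log1p(-stats::dpois(0, lam))
  }
  opt <- stats::optimize(nll, c(1e-3, max(mean(k) * 3, 1)))
  list(params = c(lambda = opt$minimum), loglik = -opt$objective, n_par = 1)
}

fit_ztgeom <- function(k) {
  # p(k) = q (1-q)^(k-1), k >= 1; MLE q = 1 / mean(k)
  q <- 1 / mean(k)
  ll <- sum(log(q) + (k - 1) * log1p(-q))
  list(params = c(rate = -log1p(-q)), loglik = ll, n_par = 1)
}

fit_zeta <- function(k) {
  nll <- function(alpha) {
    length(k) * log(pracma::zeta(alpha)) + alpha * sum(log(k))
  }
  opt <- stats::optimize(nll, c(1.01, 10))
  list(params = c(alpha = opt$minimum), loglik = -opt$objective, n_par = 1)
}

# lognormal mass on integer bins (k-0.5, k+0.5], truncated to k >= 1
dlnorm_bin <- function(k, mu, sigma, log = FALSE) {
  z0 <- stats::pnorm((log(pmax(k - 0.5, .Machine$double.xmin)) - mu) / sigma)
  z1 <- stats::pnorm((log(k + 0.5) - mu) / sigma)
  norm <- 1 - stats::pnorm((log(0.5) - mu) / sigma)
  p <- pmax(z1 - z0, 1e-300) / norm
  if (log) log(p) else p
}

fit_dlnorm <- function(k) {
  nll <- function(par) {
    if (par[2] <= 0) return(Inf)
    -sum(dlnorm_bin(k, par[1], par[2], log = TRUE))
  }
  init <- c(mean(log(k)), max(stats::sd(log(k)), 0.1))
  opt <- stats::optim(init, nll, method = "Nelder-Mead")
  list(params = c(meanlog = opt$par[1], sdlog = opt$par[2]),
       loglik = -opt$value, n_par = 2)
}

#' Tail probability P(K >= k) under a fitted degree distribution
#'
#' @param fit a `degree_fit`.
#' @param k degree values (vectorized).
#' @param family override the selected family.
#' @return tail probabilities.
#' @export
degree_tail_p <- function(fit, k, family = fit$family) {
  par <- fit$fits[[family]]$params
  k <- as.numeric(k)
  switch(family,
    poisson = {
      lam <- par[["lambda"]]
      stats::ppois(k - 1, lam, lower.tail = FALSE) /
        (1 - stats::dpois(0, lam))
    },
    exponential = {
      q <- 1 - exp(-par[["rate"]])
      (1 - q)^(k - 1)
    },
    power_law = {
      alpha <- par[["alpha"]]
      z <- pracma::zeta(alpha)
      vapply(k, function(ki) {
        if (ki <= 1) return(1)
        head_mass <- sum(seq_len(ceiling(ki) - 1)^(-alpha)) / z
        max(1 - head_mass, 0)
      }, numeric(1))
    },
    lognormal = {
      mu <- par[["meanlog"]]; s <- par[["sdlog"]]
      norm <- 1 - stats::pnorm((log(0.5) - mu) / s)
      pmin((1 - stats::pnorm((log(pmax(k - 0.5, 0.5)) - mu) / s)) / norm, 1)
    },
    stop("unknown family: ", family))
}

#' Hub calls from degree-distribution tail p-values
#'
#' Hubs are nodes whose probability of reaching at least their degree
#' under the fitted distribution is below `alpha`; sorted by degree
#' descending, ties broken lexicographically by protein id.
#'
#' @param nodes data.frame with `protein_id` and `degree` (e.g. the
#'   `nodes` of an expanded network, or any table carrying a `tail_p`
#'   column directly).
#' @param fit a `degree_fit` (ignored when `nodes$tail_p` is present).
#' @param alpha tail threshold.
#' @return `nodes` rows that qualify as hubs, with `tail_p`, ordered.
#' @export
hub_calls <- function(nodes, fit = NULL, alpha = 0.05) {
  if (!"tail_p" %in% names(nodes)) {
    if (is.null(fit)) stop("supply a degree_fit or a tail_p column")
    nodes$tail_p <- degree_tail_p(fit, nodes$degree)
  }
  hubs <- nodes[!is.na(nodes$tail_p) & nodes$tail_p < alpha, ]
  hubs[order(-hubs$degree, hubs$protein_id), , drop = FALSE]
}

#' Permutation test for the mean degree of a node subset
#'
#' Compares the observed mean degree of `node_subset` with the mean degree
#' of random subsets of the same size drawn without replacement from all
#' network nodes. The p-value uses the add-one correction
#' `(1 + #{perm >= obs}) / (n_perm + 1)` and therefore never returns 0.
#'
#' @param network an `interaction_network`.
#' @param node_subset protein ids (must all be network nodes).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return list `observed` (mean degree), `p`, `perm_mean` (null mean).
#' @export
subgraph_degree_permutation <- function(network, node_subset,
                                        n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  deg <- network$nodes$degree
  names(deg) <- network$nodes$protein_id
  node_subset <- unique(as.character(node_subset))
  if (!all(node_subset %in% names(deg))) {
    stop("node_subset contains nodes outside the network")
  }
  m <- length(node_subset)
  if (m > length(deg)) stop("subset larger than network")
  obs <- mean(deg[node_subset])
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm),
                 function(i) mean(deg[sample.int(length(deg), m)]),
                 numeric(1))
  list(observed = obs,
       p = (1 + sum(perm >= obs)) / (n_perm + 1),
       perm_mean = mean(perm))
}

#' Edge counts by endpoint change kind
#'
#' Counts edges of the seed-only subgraph (default) or the full network by
#' the unordered pair of endpoint change kinds: `pp` (both endpoints
#' changing phosphorylation), `aa` (both changing abundance only), `mixed`
#' otherwise (including any endpoint changing both).
#'
#' @param network an expanded `interaction_network`.
#' @param seeds_only restrict to edges between seed nodes.
#' @return named integer vector `pp`, `aa`, `mixed`, `total`.
#' @export
count_edge_types <- function(network, seeds_only = TRUE) {
  el <- igraph::as_edgelist(network$graph)
  kind <- network$nodes$change_kind
  names(kind) <- network$nodes$protein_id
  if (nrow(el) == 0) return(c(pp = 0L, aa = 0L, mixed = 0L, total = 0L))
  ka <- kind[el[, 1]]; kb <- kind[el[, 2]]
  if (seeds_only) {
    is_seed <- network$nodes$is_seed
    names(is_seed) <- network$nodes$protein_id
    keep <- is_seed[el[, 1]] & is_seed[el[, 2]]
    ka <- ka[keep]; kb <- kb[keep]
  }
  pp <- sum(ka == "phospho" & kb == "phospho")
  aa <- sum(ka == "abundance" & kb == "abundance")
  total <- length(ka)
  c(pp = pp, aa = aa, mixed = total - pp - aa, total = total)
}
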