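#' Spearman correlation of molecular features with a cognitive score
#'
#' Correlates each feature's log2 intensities with the per-animal PC1
#' score (average ranks for ties, pairwise-complete observations) and
#' flags features passing the absolute-rho cutoff.
#'
#' @param feature_matrix numeric matrix, features x animals (log2
#'   intensities, `NA` for missing), with column names matching
#'   `names(scores)`.
#' @param scores named numeric vector of PC1 scores per animal.
#' @param cutoff absolute-rho screening threshold.
#' @param min_n minimum paired observations per feature.
#' @return data.frame `feature_id`, `rho`, `n`, `passes`; features with
#'   too few pairs or a constant vector get `rho = NA` and are counted in
#'   `attr(, "n_skipped")`.
#' @export
spearman_vs_score <- function(feature_matrix, scores, cutoff = 0.4,
                              min_n = 3) {
  common <- intersect(colnames(feature_matrix), names(scores))
  if (length(common) < min_n) stop("fewer than min_n shared animals")
  fm <- feature_matrix[, common, drop = FALSE]
  sc <- scores[common]
  rho <- rep(NA_real_, nrow(fm))
  n <- integer(nrow(fm))
  for (i in seq_len(nrow(fm))) {
    ok <- !is.na(fm[i, ]) & !is.na(sc)
    n[i] <- sum(ok)
    if (n[i] >= min_n && stats::sd(fm[i, ok]) > 0 && stats::sd(sc[ok]) > 0) {
      rho[i] <- stats::cor(fm[i, ok], sc[ok], method = "spearman")
    }
  }
  out <- data.frame(
    feature_id = if (!is.null(rownames(fm))) rownames(fm) else seq_len(nrow(fm)),
    rho = rho, n = n, passes = !is.na(rho) & abs(rho) > cutoff,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- sum(is.na(rho))
  out
}

#' Hypergeometric set-overlap enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a query and a reference set drawn from a finite
#' background (the one-sided Fisher exact test), plus the 2x2-table odds
#' ratio and the Szymkiewicz-Simpson overlap coefficient
#' `|A n B| / min(|A|, |B|)`.
#'
#' @param query,reference character vectors, subsets of `background`.
#' @param background character vector: the detected-feature universe.
#' @return list `n_query`, `n_reference`, `n_background`, `overlap`,
#'   `odds_ratio`, `p`, `overlap_coefficient`.
#' @export
hypergeom_enrichment <- function(query, reference, background) {
  bg <- unique(as.character(background))
  q <- unique(as.character(query))
  r <- unique(as.character(reference))
  if (!all(q %in% bg) || !all(r %in% bg)) {
    stop("query and reference must be contained in the background")
  }
  k <- length(intersect(q, r))
  nq <- length(q); nr <- length(r); nb <- length(bg)
  p <- stats::phyper(k - 1, nr, nb - nr, nq, lower.tail = FALSE)
  a <- k; b <- nq - k; cc <- nr - k; d <- nb - nq - nr + k
  or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  coef <- if (min(nq, nr) == 0) 0 else k / min(nq, nr)
  list(n_query = nq, n_reference = nr, n_background = nb, overlap = k,
       odds_ratio = or, p = p, overlap_coefficient = coef)
}

#' Extend a protein set with its direct background interactors
#'
#' @param set protein ids.
#' @param background an `interaction_network`.
#' @return data.frame `protein_id`, `origin` (`original` / `added`); the
#'   extended set is monotone (always contains `set`).
#' @export
extend_with_interactors <- function(set, background) {
  set <- unique(as.character(set))
  g <- background$graph
  present <- intersect(set, igraph::V(g)$name)
  nb <- if (length(present)) {
    igraph::V(g)$name[unique(unlist(igraph::adjacent_vertices(g, present)))]
  } else character(0)
  added <- setdiff(nb, set)
  data.frame(protein_id = c(set, added),
             origin = c(rep("original", length(set)),
                        rep("added", length(added))),
             stringsAsFactors = FALSE)
}

#' Pairwise overlap matrices for a list of named sets
#'
#' Symmetric matrices of upper-tail hypergeometric p-values and
#' Szymkiewicz-Simpson coefficients for every pair of sets against a
#' shared background. Empty sets yield `NA` p-values (flagged).
#'
#' @param sets named list of character vectors.
#' @param background character vector universe containing every set.
#' @return list `p` (matrix), `coefficient` (matrix),
#'   `empty` (logical vector).
#' @export
overlap_matrix <- function(sets, background) {
  if (length(sets) < 2 || is.null(names(sets))) {
    stop("need >= 2 named sets")
  }
  n <- length(sets)
  pm <- cm <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  empty <- vapply(sets, function(s) length(s) == 0, logical(1))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (empty[i] || empty[j]) next
      e <- hypergeom_enrichment(sets[[i]], sets[[j]], background)
      pm[i, j] <- e$p
      cm[i, j] <- e$overlap_coefficient
    }
  }
  diag(cm)[!empty] <- 1
  list(p = pm, coefficient = cm, empty = empty)
}

#' BH-adjusted annotation-term enrichment
#'
#' Hypergeometric enrichment of a query set against every term of a
#' GMT-style term-to-members map, Benjamini-Hochberg adjusted across
#' terms. Members outside the background are dropped from each term.
#'
#' @param query protein ids (subset of background).
#' @param terms named list of member vectors ([read_annotations()]).
#' @param background detected-feature universe.
#' @return data.frame per term: sizes, overlap, `p`, `adj_p`.
#' @export
term_enrichment <- function(query, terms, background) {
  bg <- unique(as.character(background))
  rows <- lapply(names(terms), function(tn) {
    ref <- intersect(terms[[tn]], bg)
    if (length(ref) == 0) return(NULL)
    e <- hypergeom_enrichment(intersect(query, bg), ref, bg)
    data.frame(term = tn, n_term = e$n_reference, overlap = e$overlap,
               odds_ratio = e$odds_ratio, p = e$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no term overlaps the background")
  out$adj_p <- stats::p.adjust(out$p, "BH")
  out[order(out$p), ]
}
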