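# Shared fixture builders for the test suite. Everything is generated in
# code; nothing is read from disk except the packaged hub-candidate table.

# minimal long-format intensity table from a matrix of log2 means
# (features x cells), n replicates per cell, optional noise
toy_table <- function(log2_means, n = 5, noise_sd = 0, kind = "protein",
                      seed = 1) {
  set.seed(seed)
  cells <- colnames(log2_means)
  rows <- list()
  for (f in rownames(log2_means)) {
    for (cl in cells) {
      gt <- sub("\\..*$", "", cl)
      tr <- sub("^[^.]*\\.", "", cl)
      x <- log2_means[f, cl] + stats::rnorm(n, 0, noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = f, feature_kind = kind, protein_id = f,
        sample_id = paste0(cl, ".r", seq_len(n)), genotype = gt,
        treatment = tr, replicate = seq_len(n), intensity = 2^x,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# drop the intensity of chosen replicates of one feature in one cell
blank_out <- function(tab, feature, cell, replicates) {
  gt <- sub("\\..*$", "", cell)
  tr <- sub("^[^.]*\\.", "", cell)
  idx <- tab$feature_id == feature & tab$genotype == gt &
    tab$treatment == tr & tab$replicate %in% replicates
  tab$intensity[idx] <- NA_real_
  tab
}

# discrete zero-truncated samplers matching the degree-fit families
r_ztpois <- function(n, lambda) {
  k <- stats::rpois(n * 2, lambda)
  k <- k[k >= 1]
  k[seq_len(min(n, length(k)))]
}
r_ztgeom <- function(n, mean_k) stats::rgeom(n, 1 / mean_k) + 1L
r_zeta <- function(n, alpha, kmax = 1e5) {
  sample.int(kmax, n, replace = TRUE, prob = (1:kmax)^(-alpha))
}
r_dlnorm <- function(n, meanlog, sdlog) {
  pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
}

# independent brute-force hypergeometric upper tail by combinatorics
hyper_tail_bruteforce <- function(overlap, n_query, n_ref, n_bg) {
  ks <- overlap:min(n_query, n_ref)
  sum(choose(n_ref, ks) * choose(n_bg - n_ref, n_query - ks)) /
    choose(n_bg, n_query)
}

# independent Poisson upper tail by direct pmf summation
pois_tail_bruteforce <- function(x, lambda, kmax = 5000) {
  ks <- x:kmax
  sum(exp(-lambda + ks * log(lambda) - lgamma(ks + 1)))
}

path_hub_table <- function() {
  system.file("extdata", "network_hub_candidates.tsv",
              package = "phosphoRescue", mustWork = TRUE)
}
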