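#' Read a long-format intensity table
#'
#' Tab-separated with header columns `feature_id`, `feature_kind`,
#' `protein_id`, `sample_id`, `genotype`, `treatment`, `replicate`,
#' `intensity` and, for phosphopeptides, `site_position`, `residue`,
#' `loc_prob`, `window`. Missing intensities are encoded as empty or
#' `NA`; zero intensities are treated as missing (log2 undefined), with
#' the count recorded in `attr(, "n_zero_as_missing")`. No imputation is
#' ever performed.
#'
#' @param path TSV file path.
#' @return the feature table data.frame.
#' @export
read_intensity_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  required <- c("feature_id", "feature_kind", "protein_id", "sample_id",
                "genotype", "treatment", "replicate", "intensity")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("intensity table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(tab$feature_id, tab$sample_id)
  if (anyDuplicated(key)) {
    stop("duplicate (feature_id, sample_id): ", key[duplicated(key)][1])
  }
  if (any(tab$intensity < 0, na.rm = TRUE)) {
    stop("negative intensity values present")
  }
  bad_g <- setdiff(unique(tab$genotype), genotype_levels())
  if (length(bad_g)) stop("unknown genotype label(s): ",
                          paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(tab$treatment), treatment_levels())
  if (length(bad_t)) stop("unknown treatment label(s): ",
                          paste(bad_t, collapse = ", "))
  zero <- !is.na(tab$intensity) & tab$intensity == 0
  tab$intensity[zero] <- NA_real_
  if (any(tab$feature_kind == "phosphopeptide") &&
      !all(c("site_position", "residue", "loc_prob", "window") %in%
             names(tab))) {
    stop("phosphopeptide rows require site_position, residue, loc_prob, window")
  }
  attr(tab, "n_zero_as_missing") <- sum(zero)
  tab
}

#' Write a table as TSV (UTF-8, header, no quoting)
#' @param table data.frame.
#' @param path output path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a scored protein-protein edge list
#'
#' Tab-separated `protein_a`, `protein_b`, `combined_score` in \[0, 1\].
#' The graph is undirected and deduplicated (`(a,b)` equals `(b,a)`);
#' self-loops are dropped with a warning; edges with score less than or
#' equal to `min_score` are excluded (strict inequality: the confidence
#' threshold keeps only very-high-score interactions).
#'
#' @param path TSV file path.
#' @param min_score confidence threshold (edges must exceed it).
#' @return an `interaction_network`.
#' @export
read_edge_list <- function(path, min_score = 0.9) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("protein_a", "protein_b", "combined_score")
  if (!all(required %in% names(ed))) {
    stop("edge list must have columns: ", paste(required, collapse = ", "))
  }
  if (any(ed$combined_score < 0 | ed$combined_score > 1, na.rm = TRUE)) {
    stop("combined_score outside [0, 1]")
  }
  edges_to_network(ed, min_score)
}

#' Build an `interaction_network` from an edge data.frame
#' @param edges data.frame `protein_a`, `protein_b`, `combined_score`.
#' @param min_score strict lower confidence bound (0 keeps everything
#'   scored above 0).
#' @return an `interaction_network`.
#' @export
edges_to_network <- function(edges, min_score = 0) {
  loops <- edges$protein_a == edges$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, ]
  }
  edges <- edges[edges$combined_score > min_score, ]
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], score = edges$combined_score[keep]),
    directed = FALSE)
  new_interaction_network(g)
}

#' Read a GMT-style annotation file
#'
#' One term per line: term name, description, then members (tab
#' separated). Members are deduplicated; blank lines are skipped; a line
#' with fewer than three columns (i.e. an empty term) is an error.
#'
#' @param path GMT file path.
#' @return named list of member character vectors.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line with fewer than 3 columns: ", substr(ln, 1, 40))
    }
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Write / read phosphosite windows as FASTA
#'
#' Headers are feature ids; sequences are the flanking windows (padding
#' character included).
#'
#' @param windows data.frame with `feature_id` and `window`.
#' @param path FASTA path.
#' @return (read) data.frame `feature_id`, `window`.
#' @export
write_windows_fasta <- function(windows, path) {
  x <- Biostrings::BStringSet(windows$window)
  names(x) <- windows$feature_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_windows_fasta
#' @export
read_windows_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(feature_id = names(x), window = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a flat key:value YAML pipeline configuration
#'
#' Unknown keys are kept; missing thresholds fall back to the defaults in
#' [default_config()].
#'
#' @param path YAML path (flat mapping).
#' @return a config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_config(), cfg)
  validate_config(out)
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(alpha = 0.05, lfc = 0.3, loc_prob = 0.5, qc_min_fraction = 0.5,
       score = 0.9, rho = 0.4, n_perm = 1000, hub_alpha = 0.05,
       halfwidth = 7, prototypes_k = 5, seed = 1L)
}

validate_config <- function(cfg) {
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$lfc >= 0,
            cfg$loc_prob >= 0, cfg$loc_prob <= 1,
            cfg$score >= 0, cfg$score <= 1,
            cfg$rho >= 0, cfg$rho <= 1,
            cfg$n_perm >= 100, cfg$hub_alpha > 0, cfg$hub_alpha < 1)
  cfg
}
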