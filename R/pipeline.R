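#' Write a complete synthetic input bundle
#'
#' Generates the study design, proteome and phosphoproteome tables, a
#' scored background network over the simulated proteins, phosphosite
#' windows and a behavior table, and writes them (plus the ground-truth
#' tables) as plain TSV / FASTA files into `dir`.
#'
#' @param dir output directory (created if needed).
#' @param n_replicates replicates per group.
#' @param n_features,n_sites proteome / phosphoproteome sizes.
#' @param seed integer RNG seed (sub-generators derive fixed offsets).
#' @param ... passed to [generate_proteome()].
#' @return invisibly, the named list of file paths.
#' @export
simulate_inputs <- function(dir, n_replicates = 5, n_features = 1000,
                            n_sites = 600, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  design <- generate_design(n_replicates, seed)
  prot <- generate_proteome(design, n_features = n_features,
                            seed = seed, ...)
  phos <- generate_phospho(design, n_sites = n_sites, seed = seed + 1L)
  net <- generate_network(unique(prot$truth$protein_id),
                          n_extra_nodes = 200, seed = seed + 2L)
  beh <- generate_behavior(design, seed = seed + 3L)

  tab <- rbind(fill_phospho_cols(prot$table), phos$table)
  paths <- list(
    intensity = file.path(dir, "intensities.tsv"),
    edges = file.path(dir, "edges.tsv"),
    windows = file.path(dir, "windows.fasta"),
    behavior = file.path(dir, "behavior.tsv"),
    truth_proteome = file.path(dir, "truth_proteome.tsv"),
    truth_phospho = file.path(dir, "truth_phospho.tsv"),
    truth_network = file.path(dir, "truth_network.tsv")
  )
  write_tsv(tab, paths$intensity)
  write_tsv(net$edges, paths$edges)
  write_windows_fasta(phos$windows, paths$windows)
  write_tsv(beh, paths$behavior)
  write_tsv(prot$truth, paths$truth_proteome)
  write_tsv(phos$truth, paths$truth_phospho)
  write_tsv(net$truth, paths$truth_network)
  invisible(paths)
}

fill_phospho_cols <- function(tab) {
  for (col in c("site_position", "residue", "loc_prob", "window")) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  tab
}

#' Run the full downstream pipeline
#'
#' Stages, in order: replicate QC and feature filtering; per-feature
#' contrasts with BH adjustment; rescue scoring per treatment; seed-set
#' construction, network expansion, edge enrichment, degree fit, hub
#' calls and the DYRK1A-interactor permutation test (when an edge list is
#' configured — otherwise the network stage is skipped with a log line);
#' motif composition of TG-upregulated phosphosites; behavior contrasts,
#' PCA and prototype selection; Spearman correlation of features with
#' PC1; annotation enrichment (when a GMT is configured). One TSV per
#' result type is written to `config$out_dir`, plus `run_log.txt` with
#' the seed, package version and per-stage record counts.
#'
#' @param config list (see [default_config()]); file paths under keys
#'   `intensity`, `behavior` and optionally `edges`, `annotations`,
#'   `dyrk1a_interactors`, plus `out_dir`.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(utils::modifyList(default_config(), config))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(paste("phosphoRescue", as.character(utils::packageVersion("phosphoRescue"))),
                 paste("seed:", config$seed),
                 paste("started:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  logf <- function(...) log_lines <<- c(log_lines, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste("FAILED at stage:", name)), log_path)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  tab <- stage("read", read_intensity_table(config$intensity))
  logf("read: ", length(unique(tab$feature_id)), " features, ",
       length(unique(tab$sample_id)), " samples, ",
       attr(tab, "n_zero_as_missing"), " zero intensities set missing")

  tab <- stage("qc", qc_exclude_replicates(tab, config$qc_min_fraction))
  logf("qc: excluded samples: ",
       paste(attr(tab, "excluded_samples"), collapse = ", "))

  blood <- config$blood_ids %||% character(0)
  tab <- stage("filter", filter_features(tab, blood, config$loc_prob))
  fl <- attr(tab, "filter_log")
  logf("filter: blood removed ", fl["blood_removed"],
       ", loc_prob removed ", fl["loc_prob_removed"])

  res$contrasts <- stage("contrasts", {
    out <- list()
    for (kind in unique(tab$feature_kind)) {
      sub <- tab[tab$feature_kind == kind, ]
      out[[kind]] <- adjust_and_call(fit_contrasts(sub),
                                     config$alpha, config$lfc)
    }
    out
  })
  for (kind in names(res$contrasts)) {
    r <- res$contrasts[[kind]]
    write_tsv(r, file.path(out_dir, paste0("contrasts_", kind, ".tsv")))
    gsum <- de_summary(r[r$contrast == "TG.NT-WT.NT", ])
    logf("contrasts[", kind, "]: genotype DE total ", gsum["total"],
         " (up ", gsum["up_total"], ", down ", gsum["down_total"], ")")
  }

  res$rescue <- stage("rescue", {
    out <- list()
    for (kind in names(res$contrasts)) {
      r <- res$contrasts[[kind]]
      geno <- r[r$contrast == "TG.NT-WT.NT", ]
      tres <- lapply(stats::setNames(nm = treated_levels()), function(tr) {
        r[r$contrast == paste0("TG.", tr, "-WT.NT"), ]
      })
      out[[kind]] <- rescue_table(geno, tres)
    }
    out
  })
  for (kind in names(res$rescue)) {
    write_tsv(res$rescue[[kind]]$records,
              file.path(out_dir, paste0("rescue_", kind, ".tsv")))
    logf("rescue[", kind, "]: ",
         sum(res$rescue[[kind]]$records$class == "rescued", na.rm = TRUE),
         " feature x treatment rescued calls")
  }

  if (!is.null(config$edges)) {
    res$network <- stage("network", {
      bg <- read_edge_list(config$edges, config$score)
      prot_r <- res$contrasts[["protein"]]
      phos_r <- res$contrasts[["phosphopeptide"]]
      geno_prot <- if (!is.null(prot_r))
        de_features(prot_r[prot_r$contrast == "TG.NT-WT.NT", ]) else character(0)
      geno_phos_prot <- if (!is.null(phos_r)) {
        ph <- phos_r[phos_r$contrast == "TG.NT-WT.NT", ]
        de_ids <- de_features(ph)
        unique(tab$protein_id[tab$feature_id %in% de_ids])
      } else character(0)
      seeds <- build_seed_set(geno_prot, geno_phos_prot)
      net <- expand_network(seeds, bg)
      n_nodes <- nrow(net$nodes)
      exp_e <- expected_edge_count(n_nodes, bg,
                                   universe = unique(tab$protein_id))
      obs_e <- igraph::ecount(net$graph)
      fit <- tryCatch(fit_degree_distribution(net$nodes$degree),
                      error = function(e) NULL)
      hubs <- if (!is.null(fit)) {
        net$nodes$tail_p <- degree_tail_p(fit, net$nodes$degree)
        hub_calls(net$nodes, alpha = config$hub_alpha)
      } else NULL
      perm <- NULL
      if (!is.null(config$dyrk1a_interactors)) {
        ints <- readLines(config$dyrk1a_interactors, warn = FALSE)
        ints <- intersect(trimws(ints), net$nodes$protein_id)
        if (length(ints) >= 2) {
          perm <- subgraph_degree_permutation(net, ints, config$n_perm,
                                              config$seed)
        }
      }
      list(network = net, observed_edges = obs_e, expected_edges = exp_e,
           edge_p = edge_enrichment(obs_e, exp_e), fit = fit, hubs = hubs,
           interactor_perm = perm,
           edge_types = count_edge_types(net, seeds_only = TRUE))
    })
    nt <- res$network
    write_tsv(nt$network$nodes, file.path(out_dir, "network_nodes.tsv"))
    write_tsv(network_edges(nt$network), file.path(out_dir, "network_edges.tsv"))
    stats_df <- data.frame(
      statistic = c("n_nodes", "n_edges", "expected_edges", "edge_p",
                    "degree_family", "n_hubs"),
      value = c(nrow(nt$network$nodes), nt$observed_edges,
                signif(nt$expected_edges, 6), signif(nt$edge_p, 6),
                if (is.null(nt$fit)) NA else nt$fit$family,
                if (is.null(nt$hubs)) NA else nrow(nt$hubs)))
    write_tsv(stats_df, file.path(out_dir, "network_stats.tsv"))
    logf("network: ", nrow(nt$network$nodes), " nodes, ",
         nt$observed_edges, " edges (expected ",
         signif(nt$expected_edges, 4), ", p = ", signif(nt$edge_p, 3), ")")
  } else {
    logf("network: skipped (no edge list configured)")
  }

  res$motif <- stage("motif", {
    ph <- res$contrasts[["phosphopeptide"]]
    if (is.null(ph)) return(NULL)
    geno <- ph[ph$contrast == "TG.NT-WT.NT", ]
    up_ids <- de_features(geno, "up")
    win <- unique(tab[tab$feature_id %in% up_ids & !is.na(tab$window),
                      c("feature_id", "window")])
    if (nrow(win) == 0) return(NULL)
    list(counts = composition_counts(win$window),
         pxsp = match_consensus(win$window, "PXSP", win$feature_id),
         canonical = match_consensus(win$window, "RPX(S/T)P", win$feature_id),
         pfm = pfm(win$window))
  })
  if (!is.null(res$motif)) {
    write_tsv(data.frame(statistic = names(res$motif$counts),
                         count = as.integer(res$motif$counts)),
              file.path(out_dir, "motif_counts.tsv"))
    write_pfm(res$motif$pfm, file.path(out_dir, "motif_pfm.tsv"))
    logf("motif: ", res$motif$counts["n"], " TG-up windows, ",
         res$motif$counts["S_plus1_P"], " with P at +1")
  }

  res$behavior <- stage("behavior", {
    beh <- utils::read.delim(config$behavior, stringsAsFactors = FALSE)
    if (!"DI" %in% names(beh)) {
      beh$DI <- discrimination_index(beh$TN, beh$TF, beh$total)
    }
    pca <- pca_behavior(beh)
    list(table = beh, contrasts = anova_contrasts(beh), pca = pca,
         prototypes = select_prototypes(beh, config$prototypes_k,
                                        config$seed, allow_fewer = TRUE))
  })
  write_tsv(res$behavior$contrasts, file.path(out_dir, "behavior_contrasts.tsv"))
  scores <- data.frame(sample_id = res$behavior$table$sample_id,
                       res$behavior$pca$scores[, 1:2])
  write_tsv(scores, file.path(out_dir, "behavior_scores.tsv"))
  logf("behavior: ", nrow(res$behavior$table), " animals, ",
       nrow(res$behavior$prototypes), " prototypes selected")

  res$correlation <- stage("correlate", {
    proto <- res$behavior$prototypes$sample_id
    pc1 <- stats::setNames(res$behavior$pca$scores[, 1],
                           res$behavior$table$sample_id)[proto]
    sub <- tab[tab$sample_id %in% proto, ]
    fm <- tapply(log2(sub$intensity),
                 list(sub$feature_id, sub$sample_id), identity)
    spearman_vs_score(fm, pc1, cutoff = config$rho)
  })
  write_tsv(res$correlation, file.path(out_dir, "correlation.tsv"))
  logf("correlate: ", sum(res$correlation$passes), " of ",
       nrow(res$correlation), " features pass |rho| > ", config$rho)

  if (!is.null(config$annotations)) {
    res$enrichment <- stage("enrich", {
      terms <- read_annotations(config$annotations)
      prot_r <- res$contrasts[["protein"]]
      query <- de_features(prot_r[prot_r$contrast == "TG.NT-WT.NT", ])
      bg <- unique(tab$protein_id[tab$feature_kind == "protein"])
      term_enrichment(intersect(query, bg), terms, bg)
    })
    write_tsv(res$enrichment, file.path(out_dir, "enrichment.tsv"))
    logf("enrich: ", sum(res$enrichment$adj_p < config$alpha),
         " terms at adj_p < ", config$alpha)
  } else {
    logf("enrich: skipped (no annotations configured)")
  }

  logf("finished: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  writeLines(log_lines, log_path)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
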