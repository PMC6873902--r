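#' Replicate quality control by feature count
#'
#' Removes samples whose number of observed (non-missing) features falls
#' below `min_fraction` of the median count across samples of the same
#' feature kind — the operational form of dropping replicates that
#' identified substantially fewer peptides than the rest of the experiment.
#'
#' @param table long-format feature table (see [read_intensity_table()]).
#' @param min_fraction fraction of the median feature count below which a
#'   sample is excluded; strictly between 0 and 1.
#' @return the filtered table, with excluded sample ids in
#'   `attr(, "excluded_samples")`.
#' @export
qc_exclude_replicates <- function(table, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction >= 1) {
    stop("min_fraction must be in (0, 1)")
  }
  drop <- character(0)
  for (kind in unique(table$feature_kind)) {
    sub <- table[table$feature_kind == kind, ]
    counts <- tapply(!is.na(sub$intensity), sub$sample_id, sum)
    low <- names(counts)[counts < min_fraction * stats::median(counts)]
    drop <- c(drop, low)
  }
  out <- table[!(table$sample_id %in% drop), ]
  groups_left <- unique(condition_label(out$genotype, out$treatment))
  groups_all <- unique(condition_label(table$genotype, table$treatment))
  if (!all(groups_all %in% groups_left)) {
    stop("replicate QC removed every sample of group(s): ",
         paste(setdiff(groups_all, groups_left), collapse = ", "))
  }
  attr(out, "excluded_samples") <- unique(drop)
  out
}

#' Minimum observations required for quantifiability
#'
#' Three of five biological replicates; when a group retains only four
#' replicates the rule relaxes to two.
#'
#' @param n_replicates replicates available in the group.
#' @return required observation count.
#' @export
min_obs_required <- function(n_replicates) {
  ifelse(n_replicates >= 5, 3L, 2L)
}

#' Filter features: contaminants and uncertain phosphosites
#'
#' Removes blood-contaminant proteins from all analyses and drops
#' phosphopeptides whose site localization probability is below
#' `loc_prob_min`. Quantifiability per condition (the minimum-observation
#' rule) is evaluated later, per comparison, by [call_presence()] and
#' [fit_contrasts()].
#'
#' @param table long-format feature table.
#' @param blood_ids protein ids annotated to the blood-microparticle term.
#' @param loc_prob_min minimum localization probability for
#'   phosphopeptides.
#' @return filtered table; counts removed in `attr(, "filter_log")`.
#' @export
filter_features <- function(table, blood_ids = character(0),
                            loc_prob_min = 0.5) {
  n0 <- length(unique(table$feature_id))
  keep <- !(table$protein_id %in% blood_ids)
  tab <- table[keep, ]
  n_blood <- n0 - length(unique(tab$feature_id))
  is_ph <- tab$feature_kind == "phosphopeptide"
  if (any(is_ph)) {
    bad <- is_ph & (is.na(tab$loc_prob) | tab$loc_prob < loc_prob_min)
    tab <- tab[!bad, ]
  }
  n_loc <- n0 - n_blood - length(unique(tab$feature_id))
  if (nrow(tab) == 0) stop("no features left after filtering")
  attr(tab, "filter_log") <- c(blood_removed = n_blood,
                               loc_prob_removed = n_loc)
  tab
}

# observation counts per feature for one (genotype, treatment) cell;
# returns named list: obs (vector per feature) and n_rep
condition_obs <- function(table, condition) {
  cc <- split_condition(condition)
  sub <- table[table$genotype == cc$genotype &
                 table$treatment == cc$treatment, ]
  if (nrow(sub) == 0) stop("unknown condition: ", condition)
  n_rep <- length(unique(sub$sample_id))
  obs <- tapply(!is.na(sub$intensity), sub$feature_id, sum)
  list(obs = obs, n_rep = n_rep)
}

#' Presence/absence calling between two conditions
#'
#' A feature is quantifiable in a condition when observed in at least
#' [min_obs_required()] of its replicates. Features quantifiable in one
#' condition only are called `present_only` / `absent_only` (relative to
#' `condition_a`); features quantifiable in both take the quantitative
#' path; features quantifiable in neither are excluded.
#'
#' @param table filtered feature table.
#' @param condition_a,condition_b condition labels `"genotype.treatment"`.
#' @return data.frame `feature_id`, `n_obs_a`, `n_obs_b`, `call` with
#'   call in `present_only` (a only), `absent_only` (b only),
#'   `quantitative`, `excluded`.
#' @export
call_presence <- function(table, condition_a, condition_b) {
  oa <- condition_obs(table, condition_a)
  ob <- condition_obs(table, condition_b)
  ids <- sort(unique(table$feature_id))
  na <- ifelse(is.na(oa$obs[ids]), 0L, oa$obs[ids])
  nb <- ifelse(is.na(ob$obs[ids]), 0L, ob$obs[ids])
  qa <- na >= min_obs_required(oa$n_rep)
  qb <- nb >= min_obs_required(ob$n_rep)
  call <- ifelse(qa & qb, "quantitative",
          ifelse(qa & !qb, "present_only",
          ifelse(!qa & qb, "absent_only", "excluded")))
  data.frame(feature_id = ids, n_obs_a = as.integer(na),
             n_obs_b = as.integer(nb), call = call,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-feature cell-means linear-model contrasts
#'
#' For each feature, ordinary least squares is fit on log2 intensity with
#' the (genotype x treatment) cell as a fixed effect, using every observed
#' sample of that feature. A contrast is a signed combination of cell
#' means (e.g. `"TG.NT - WT.NT"`, or the difference-of-differences
#' `"(TG.greentea - TG.NT) - (WT.greentea - WT.NT)"`); its standard error
#' uses the pooled residual variance across all cells, and the p-value is
#' a two-sided t test on the residual degrees of freedom. A feature enters
#' a contrast only when quantifiable (minimum-observation rule) in every
#' condition of that contrast; features quantifiable on one side of a
#' two-condition contrast are reported via the presence/absence path
#' instead.
#'
#' @param table filtered feature table.
#' @param contrasts named list; each element is a named numeric vector of
#'   cell weights, e.g. `c("TG.NT" = 1, "WT.NT" = -1)`. See
#'   [standard_contrasts()].
#' @return data.frame with `feature_id`, `contrast`, `log2FC`, `SE`, `df`,
#'   `p`, `call` (`quantitative`, `present_only`, `absent_only`), and
#'   per-condition observation counts for two-condition contrasts.
#' @export
fit_contrasts <- function(table, contrasts = standard_contrasts()) {
  if (!is.list(contrasts) || is.null(names(contrasts))) {
    stop("contrasts must be a named list of weight vectors")
  }
  tab <- table[!is.na(table$intensity), ]
  if (any(tab$intensity <= 0)) stop("intensities must be positive")
  tab$log2 <- log2(tab$intensity)
  tab$cell <- condition_label(tab$genotype, tab$treatment)

  # per feature x cell: n, mean, within-cell sum of squares
  key <- paste(tab$feature_id, tab$cell, sep = "\r")
  n_fc <- tapply(tab$log2, key, length)
  m_fc <- tapply(tab$log2, key, mean)
  ss_fc <- tapply(tab$log2, key, function(x) sum((x - mean(x))^2))
  parts <- do.call(rbind, strsplit(names(n_fc), "\r", fixed = TRUE))
  cells <- data.frame(feature_id = parts[, 1], cell = parts[, 2],
                      n = as.integer(n_fc), m = as.numeric(m_fc),
                      ss = as.numeric(ss_fc), stringsAsFactors = FALSE)

  # replicates per cell (for the min-obs rule)
  cell_reps <- tapply(table$sample_id,
                      condition_label(table$genotype, table$treatment),
                      function(s) length(unique(s)))

  # residual variance pooled over every cell the feature is observed in
  # (the full cell-means model), with df = sum(n_c - 1)
  ss_all <- tapply(cells$ss, cells$feature_id, sum)
  df_all <- tapply(cells$n - 1L, cells$feature_id, sum)

  out <- list()
  for (cname in names(contrasts)) {
    w <- contrasts[[cname]]
    conds <- names(w)
    sub <- cells[cells$cell %in% conds, ]
    wide_n <- tapply2(sub$n, sub$feature_id, sub$cell, conds, 0L)
    wide_m <- tapply2(sub$m, sub$feature_id, sub$cell, conds, NA_real_)
    ids <- rownames(wide_n)
    need <- matrix(min_obs_required(cell_reps[conds]),
                   nrow = length(ids), ncol = length(conds), byrow = TRUE)
    quant <- rowSums(wide_n >= need) == length(conds)

    ss_tot <- ss_all[ids]
    df <- df_all[ids]
    est <- as.numeric(wide_m %*% w)
    se2 <- ifelse(df > 0, ss_tot / df, NA_real_) *
      as.numeric((1 / pmax(wide_n, 1)) %*% (w^2))
    se <- sqrt(se2)
    p <- 2 * stats::pt(abs(est / se), df, lower.tail = FALSE)

    res <- data.frame(feature_id = ids, contrast = cname,
                      log2FC = est, SE = se, df = as.integer(df), p = p,
                      call = "quantitative", stringsAsFactors = FALSE,
                      row.names = NULL)
    if (length(conds) == 2) {
      res$n_obs_a <- wide_n[, which(w > 0)]
      res$n_obs_b <- wide_n[, which(w < 0)]
      one_sided <- (wide_n[, which(w > 0)] >= need[, which(w > 0)]) !=
                   (wide_n[, which(w < 0)] >= need[, which(w < 0)])
      res$call[one_sided] <- ifelse(
        (wide_n[, which(w > 0)] >= need[, which(w > 0)])[one_sided],
        "present_only", "absent_only")
      res$log2FC[one_sided] <- NA_real_
      res$SE[one_sided] <- NA_real_
      res$p[one_sided] <- NA_real_
    } else {
      res$n_obs_a <- NA_integer_; res$n_obs_b <- NA_integer_
    }
    keep <- quant | res$call %in% c("present_only", "absent_only")
    res <- res[keep, ]
    bad <- res$call == "quantitative" & res$df < 1
    res <- res[!bad, ]
    out[[cname]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# small helper: value[feature, cell] matrix with fill for absent cells
tapply2 <- function(v, rows, cols, col_levels, fill) {
  m <- tapply(v, list(factor(rows), factor(cols, levels = col_levels)),
              identity)
  m[is.na(m)] <- fill
  storage.mode(m) <- if (is.integer(fill)) "integer" else "double"
  m
}

#' The study's standard contrasts
#'
#' Genotype at baseline, each treatment against baseline within genotype,
#' treatment gaps against untreated WT, and the genotype-by-treatment
#' interaction (difference of differences) per treatment.
#'
#' @param treatments treatment arms to include.
#' @return named list of cell-weight vectors for [fit_contrasts()].
#' @export
standard_contrasts <- function(treatments = treated_levels()) {
  ctr <- list("TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1),
              "WT.NT-TG.NT" = c("WT.NT" = 1, "TG.NT" = -1))
  for (tr in treatments) {
    tgt <- paste0("TG.", tr); wtt <- paste0("WT.", tr)
    ctr[[paste0(tgt, "-TG.NT")]] <- stats::setNames(c(1, -1), c(tgt, "TG.NT"))
    ctr[[paste0(wtt, "-WT.NT")]] <- stats::setNames(c(1, -1), c(wtt, "WT.NT"))
    ctr[[paste0(tgt, "-WT.NT")]] <- stats::setNames(c(1, -1), c(tgt, "WT.NT"))
    ctr[[paste0(wtt, "-TG.NT")]] <- stats::setNames(c(1, -1), c(wtt, "TG.NT"))
    ctr[[paste0("(", tgt, "-TG.NT)-(", wtt, "-WT.NT)")]] <-
      stats::setNames(c(1, -1, -1, 1), c(tgt, "TG.NT", wtt, "WT.NT"))
  }
  ctr
}

#' Benjamini-Hochberg adjustment and differential-abundance calls
#'
#' Adjusts p-values within each contrast across its testable features and
#' calls `up` when `adj_p < alpha` and `log2FC > lfc`, `down` when
#' `adj_p < alpha` and `log2FC < -lfc`, `ns` otherwise. Presence/absence
#' calls pass through unchanged (they carry no fold change); by the
#' list-assembly convention, features uniquely present in one condition
#' belong to that condition's up/down list alongside the quantitative
#' calls.
#'
#' @param results output of [fit_contrasts()].
#' @param alpha adjusted-p threshold.
#' @param lfc absolute log2 fold-change threshold.
#' @return `results` with `adj_p` and updated `call` in
#'   `up`, `down`, `present_only`, `absent_only`, `ns`.
#' @export
adjust_and_call <- function(results, alpha = 0.05, lfc = 0.3) {
  if (nrow(results) == 0) stop("empty result list")
  results$adj_p <- NA_real_
  for (cname in unique(results$contrast)) {
    idx <- results$contrast == cname & results$call == "quantitative"
    results$adj_p[idx] <- stats::p.adjust(results$p[idx], method = "BH")
  }
  quant <- results$call == "quantitative"
  results$call[quant] <- ifelse(
    !is.na(results$adj_p[quant]) & results$adj_p[quant] < alpha &
      results$log2FC[quant] > lfc, "up",
    ifelse(!is.na(results$adj_p[quant]) & results$adj_p[quant] < alpha &
             results$log2FC[quant] < -lfc, "down", "ns"))
  results
}

#' Summarize differential-abundance calls for one contrast
#'
#' Totals follow the list-assembly convention: the up list is the union of
#' quantitative `up` calls and `present_only` features; the down list adds
#' `absent_only` features.
#'
#' @param results adjusted results ([adjust_and_call()]) for one contrast.
#' @return named integer vector: `up`, `present_only`, `down`,
#'   `absent_only`, `up_total`, `down_total`, `total`.
#' @export
de_summary <- function(results) {
  stopifnot(length(unique(results$contrast)) <= 1)
  n <- function(k) sum(results$call == k)
  c(up = n("up"), present_only = n("present_only"),
    down = n("down"), absent_only = n("absent_only"),
    up_total = n("up") + n("present_only"),
    down_total = n("down") + n("absent_only"),
    total = n("up") + n("present_only") + n("down") + n("absent_only"))
}

#' Differentially abundant feature ids for a contrast
#'
#' @param results adjusted results for one contrast.
#' @param direction `"both"`, `"up"` or `"down"`.
#' @return character vector of feature ids (presence/absence included).
#' @export
de_features <- function(results, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- switch(direction,
                 up = c("up", "present_only"),
                 down = c("down", "absent_only"),
                 both = c("up", "present_only", "down", "absent_only"))
  results$feature_id[results$call %in% keep]
}
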