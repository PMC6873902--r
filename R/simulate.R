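#' Simulate a label-free proteome intensity table with known ground truth
#'
#' Generates log-normal feature intensities over a full factorial design,
#' plants genotype effects on a subset of features, plants treatment effects
#' on TG animals calibrated so each affected feature's true recovery
#' fraction falls inside a prescribed rescue class, applies
#' intensity-dependent missingness, and flags a subset of features as blood
#' contaminants. The returned truth table is the reference for every
#' downstream parameter-recovery check.
#'
#' The treatment effect of a feature with genotype gap `g` and drawn true
#' recovery fraction `f` is `-f * g` on TG treated samples, so that the
#' treatment gap equals `g * (1 - f)` and [recovery_fraction()] applied to
#' the noiseless gaps returns `f` exactly. True fractions are drawn
#' uniformly inside each class interval, inset by `class_margin` from the
#' class boundaries so that planted classes are well defined under finite
#' replicate noise (a feature whose truth sits on a decision boundary has
#' no recoverable class).
#'
#' Missingness is logistic in the true log2 intensity `x`:
#' `P(missing) = plogis(missing_steepness * (missing_midpoint - x))`, and
#' identically zero when `missing_steepness = 0`. Low-abundance features
#' therefore drop below detection and become "absent/low abundant" in the
#' sense of the downstream minimum-observation rule; no explicit
#' presence/absence label is planted.
#'
#' @param design sample sheet from [generate_design()].
#' @param n_features number of protein features.
#' @param frac_affected fraction of features given a genotype effect.
#' @param effect_size absolute genotype effect, log2 units (sign random).
#' @param effect_sd optional spread of planted effect magnitudes.
#' @param recovery_mix named fractions over the four rescue classes; must
#'   sum to 1. One class is drawn per affected feature and treatment.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param missing_steepness logistic steepness of the detection curve;
#'   0 disables missingness.
#' @param missing_midpoint log2 intensity at which detection odds are even.
#' @param frac_blood fraction of features flagged as blood contaminants.
#' @param baseline_mean,baseline_sd log2-scale distribution of feature
#'   baselines.
#' @param class_margin inset (recovery-fraction units) from each class
#'   boundary when drawing true fractions. The default (0.3) is 1.5 times
#'   the delta-method sampling sd of the estimated recovery fraction under
#'   the default design (|gap| 1 log2, noise sd 0.25, 5 replicates), so
#'   that planted classes remain identifiable from the data.
#' @param wt_mirror if `TRUE`, treatment effects are mirrored onto WT
#'   samples as well, exercising the WT-impairment analysis.
#' @param seed integer RNG seed.
#' @return a list with `table` (long-format feature table; `intensity` is
#'   `NA` where below detection) and `truth` (per-feature planted effects,
#'   per-treatment true class and recovery fraction, contamination flag).
#' @seealso [recovery_fraction()], [classify_recovery()]
#' @export
generate_proteome <- function(design,
                              n_features = 1000,
                              frac_affected = 0.1,
                              effect_size = 1.0,
                              effect_sd = 0,
                              recovery_mix = c(rescued = 0.5,
                                               overcorrected = 0.1,
                                               not_sufficiently_rescued = 0.3,
                                               impaired = 0.1),
                              noise_sd = 0.25,
                              missing_steepness = 1.5,
                              missing_midpoint = 16,
                              frac_blood = 0.02,
                              baseline_mean = 20,
                              baseline_sd = 2,
                              class_margin = 0.3,
                              wt_mirror = FALSE,
                              seed = 1L) {
  if (n_features < 1) stop("n_features must be >= 1")
  stopifnot(frac_affected >= 0, frac_affected <= 1,
            frac_blood >= 0, frac_blood <= 1)
  check_recovery_mix(recovery_mix)
  set.seed(as.integer(seed))

  ids <- sprintf("P%04d", seq_len(n_features))
  baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)
  n_aff <- round(frac_affected * n_features)
  affected <- c(rep(TRUE, n_aff), rep(FALSE, n_features - n_aff))
  g_effect <- numeric(n_features)
  if (n_aff > 0) {
    mag <- abs(effect_size + stats::rnorm(n_aff, 0, effect_sd))
    g_effect[affected] <- mag * sample(c(-1, 1), n_aff, replace = TRUE)
  }
  is_blood <- seq_len(n_features) %in%
    sample.int(n_features, round(frac_blood * n_features))

  truth <- data.frame(
    feature_id = ids, protein_id = ids,
    baseline = baseline, affected = affected,
    genotype_effect = g_effect, is_blood = is_blood,
    stringsAsFactors = FALSE
  )

  trts <- treated_levels()
  t_effect <- matrix(0, n_features, length(trts), dimnames = list(ids, trts))
  for (tr in trts) {
    cls <- rep(NA_character_, n_features)
    frc <- rep(NA_real_, n_features)
    if (n_aff > 0) {
      cls[affected] <- sample(names(recovery_mix), n_aff, replace = TRUE,
                              prob = recovery_mix)
      frc[affected] <- draw_recovery_fraction(cls[affected], class_margin)
      t_effect[affected, tr] <- -frc[affected] * g_effect[affected]
    }
    truth[[paste0("class_", tr)]] <- ifelse(is.na(cls), "unaffected", cls)
    truth[[paste0("fraction_", tr)]] <- frc
  }

  tab <- expand_intensities(design, truth_ids = ids, baseline = baseline,
                            g_effect = g_effect, t_effect = t_effect,
                            noise_sd = noise_sd, wt_mirror = wt_mirror)
  tab$intensity <- apply_missingness(tab$log2_true, missing_steepness,
                                     missing_midpoint, tab$intensity)
  tab$log2_true <- NULL
  tab$feature_kind <- "protein"
  tab$protein_id <- tab$feature_id
  tab <- tab[, c("feature_id", "feature_kind", "protein_id", "sample_id",
                 "genotype", "treatment", "replicate", "intensity")]
  list(table = tab, truth = truth)
}

check_recovery_mix <- function(mix) {
  classes <- c("rescued", "overcorrected", "not_sufficiently_rescued", "impaired")
  if (is.null(names(mix)) || !all(names(mix) %in% classes)) {
    stop("recovery_mix must be named with rescue classes: ",
         paste(classes, collapse = ", "))
  }
  if (abs(sum(mix) - 1) > 1e-8) stop("recovery_mix must sum to 1")
  invisible(mix)
}

# class intervals, inset by `margin`; truths are drawn strictly interior
draw_recovery_fraction <- function(classes, margin) {
  lo <- c(rescued = 0.5, overcorrected = 1.5,
          not_sufficiently_rescued = -0.5, impaired = -1.5)
  hi <- c(rescued = 1.5, overcorrected = 2.5,
          not_sufficiently_rescued = 0.5, impaired = -0.5)
  stats::runif(length(classes),
               lo[classes] + margin, hi[classes] - margin)
}

# long table of true + noisy intensities for every feature x sample
expand_intensities <- function(design, truth_ids, baseline, g_effect,
                               t_effect, noise_sd, wt_mirror) {
  n_f <- length(truth_ids); n_s <- nrow(design)
  tab <- design[rep(seq_len(n_s), times = n_f), ]
  tab$feature_id <- rep(truth_ids, each = n_s)
  fi <- rep(seq_len(n_f), each = n_s)
  mu <- baseline[fi]
  tg <- tab$genotype == "TG"
  mu[tg] <- mu[tg] + g_effect[fi[tg]]
  treated <- tab$treatment != "NT"
  idx <- treated & (tg | wt_mirror)
  if (any(idx)) {
    mu[idx] <- mu[idx] + t_effect[cbind(fi[idx], match(tab$treatment[idx],
                                                       colnames(t_effect)))]
  }
  x <- mu + stats::rnorm(length(mu), 0, noise_sd)
  tab$log2_true <- mu
  tab$intensity <- 2^x
  rownames(tab) <- NULL
  tab
}

apply_missingness <- function(log2_true, steepness, midpoint, intensity) {
  if (steepness == 0) return(intensity)
  p_miss <- stats::plogis(steepness * (midpoint - log2_true))
  intensity[stats::runif(length(intensity)) < p_miss] <- NA_real_
  intensity
}

#' Simulate a phosphopeptide table with motif-structured flanking windows
#'
#' Phosphosites get a central residue drawn S/T/Y (0.8 / 0.17 / 0.03), a
#' localization probability, and a flanking window of length
#' `2 * halfwidth + 1`. A fraction of sites receives a genotype effect
#' (split between up- and downregulation in TG); among TG-upregulated
#' serine sites, `frac_motif` carry a proline at +1, a sub-fraction of
#' those also a proline at -2, and a small fraction of TG-upregulated S/T
#' sites carry the full arginine(-3)/proline(-2)/proline(+1) context.
#'
#' @param design sample sheet from [generate_design()].
#' @param n_sites number of phosphosites.
#' @param frac_motif fraction of TG-upregulated serine sites with P at +1.
#' @param p_minus2 fraction of the +1-proline sites that also carry P at -2.
#' @param p_full fraction of TG-upregulated S/T sites with the full
#'   R(-3)/P(-2)/P(+1) context.
#' @param halfwidth flanking residues on each side of the site (>= 3 when
#'   the full motif context is planted).
#' @param frac_affected,effect_size,noise_sd,missing_steepness,missing_midpoint,seed
#'   as in [generate_proteome()].
#' @param frac_up among affected sites, fraction upregulated in TG.
#' @param loc_shape1,loc_shape2 Beta parameters for localization
#'   probabilities.
#' @return list with `table` (long feature table, `feature_kind =
#'   "phosphopeptide"`, carrying `site_position`, `residue`, `loc_prob`,
#'   `window`), `windows` (one row per site) and `truth`.
#' @export
generate_phospho <- function(design,
                             n_sites = 600,
                             frac_motif = 0.4,
                             p_minus2 = 0.3,
                             p_full = 0.02,
                             halfwidth = 7,
                             frac_affected = 0.2,
                             frac_up = 0.5,
                             effect_size = 1.0,
                             noise_sd = 0.25,
                             missing_steepness = 1.5,
                             missing_midpoint = 16,
                             loc_shape1 = 4, loc_shape2 = 1,
                             seed = 1L) {
  if (halfwidth < 2) stop("halfwidth must be >= 2")
  if (p_full > 0 && halfwidth < 3) {
    stop("halfwidth too small to host the planted R(-3)/P(-2)/P(+1) context")
  }
  stopifnot(n_sites >= 1)
  set.seed(as.integer(seed))

  ids <- sprintf("ph%04d", seq_len(n_sites))
  n_prot <- max(1L, n_sites %/% 2L)
  prot <- sprintf("PP%04d", sample.int(n_prot, n_sites, replace = TRUE))
  residue <- sample(c("S", "T", "Y"), n_sites, replace = TRUE,
                    prob = c(0.8, 0.17, 0.03))
  loc_prob <- stats::rbeta(n_sites, loc_shape1, loc_shape2)

  n_aff <- round(frac_affected * n_sites)
  affected <- c(rep(TRUE, n_aff), rep(FALSE, n_sites - n_aff))
  up <- affected & (stats::runif(n_sites) < frac_up)
  g_effect <- numeric(n_sites)
  g_effect[affected] <- ifelse(up[affected], effect_size, -effect_size)

  width <- 2L * halfwidth + 1L
  win <- matrix(sample(AA20, n_sites * width, replace = TRUE),
                nrow = n_sites)
  win[, halfwidth + 1L] <- residue
  # planted motif hierarchy on TG-upregulated sites
  full <- up & residue %in% c("S", "T") & stats::runif(n_sites) < p_full
  plus1 <- up & residue == "S" & !full & stats::runif(n_sites) < frac_motif
  minus2 <- plus1 & stats::runif(n_sites) < p_minus2
  win[plus1 | full, halfwidth + 2L] <- "P"
  win[minus2 | full, halfwidth - 1L] <- "P"
  win[full, halfwidth - 2L] <- "R"
  windows <- data.frame(
    feature_id = ids, protein_id = prot,
    site_position = sample.int(400L, n_sites, replace = TRUE) + halfwidth,
    residue = residue, loc_prob = loc_prob,
    window = apply(win, 1, paste, collapse = ""),
    stringsAsFactors = FALSE
  )

  baseline <- stats::rnorm(n_sites, 19, 2)
  t_eff <- matrix(0, n_sites, length(treated_levels()),
                  dimnames = list(ids, treated_levels()))
  tab <- expand_intensities(design, ids, baseline, g_effect, t_eff,
                            noise_sd, wt_mirror = FALSE)
  tab$intensity <- apply_missingness(tab$log2_true, missing_steepness,
                                     missing_midpoint, tab$intensity)
  tab$log2_true <- NULL
  tab$feature_kind <- "phosphopeptide"
  m <- match(tab$feature_id, ids)
  tab$protein_id <- prot[m]
  tab$site_position <- windows$site_position[m]
  tab$residue <- residue[m]
  tab$loc_prob <- loc_prob[m]
  tab$window <- windows$window[m]
  tab <- tab[, c("feature_id", "feature_kind", "protein_id", "sample_id",
                 "genotype", "treatment", "replicate", "intensity",
                 "site_position", "residue", "loc_prob", "window")]

  truth <- data.frame(
    feature_id = ids, protein_id = prot, affected = affected,
    genotype_effect = g_effect, tg_up = up,
    motif_plus1 = plus1 | full, motif_minus2 = minus2 | full,
    motif_full = full, stringsAsFactors = FALSE
  )
  list(table = tab, windows = windows, truth = truth)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a scored background interaction network
#'
#' Grows a preferential-attachment graph over the supplied feature ids plus
#' extra (undetected-interactor) nodes: the growth starts from a single
#' edge and every later node attaches to `m = 2` distinct existing nodes
#' with probability proportional to `degree^attachment_exponent`, giving a
#' heavy-tailed degree distribution with exactly `2N - 3` edges for N
#' nodes. Optionally plants additional explicit hub nodes wired to many
#' random targets. Each edge gets a confidence score uniform in
#' `score_range`.
#'
#' @param feature_ids protein identifiers to embed in the background.
#' @param n_extra_nodes additional background-only nodes.
#' @param attachment_exponent preferential-attachment power (1 = linear).
#' @param score_range edge confidence score interval.
#' @param n_planted_hubs extra nodes wired as explicit hubs.
#' @param hub_degree edges per planted hub.
#' @param seed integer RNG seed.
#' @return list with `edges` (`protein_a`, `protein_b`, `combined_score`)
#'   and `truth` (per-node final degree, planted-hub flag).
#' @export
generate_network <- function(feature_ids,
                             n_extra_nodes = 200,
                             attachment_exponent = 1,
                             score_range = c(0.9, 1),
                             n_planted_hubs = 0,
                             hub_degree = 30,
                             seed = 1L) {
  if (length(feature_ids) == 0) stop("feature_ids must be non-empty")
  set.seed(as.integer(seed))
  nodes <- c(as.character(feature_ids),
             if (n_extra_nodes > 0) sprintf("EXT%04d", seq_len(n_extra_nodes)))
  nodes <- sample(nodes)  # growth order decorrelated from identity
  n <- length(nodes)
  if (n < 2) stop("need at least 2 nodes to grow a network")

  deg <- integer(n)
  a <- integer(0); b <- integer(0)
  deg[1:2] <- 1L; a <- 1L; b <- 2L
  for (v in seq(3L, length.out = max(0L, n - 2L))) {
    w <- deg[seq_len(v - 1L)]^attachment_exponent
    tgt <- sample.int(v - 1L, size = min(2L, v - 1L), prob = w)
    a <- c(a, rep(v, length(tgt))); b <- c(b, tgt)
    deg[v] <- deg[v] + length(tgt)
    deg[tgt] <- deg[tgt] + 1L
  }
  hub_names <- character(0)
  if (n_planted_hubs > 0) {
    hub_names <- sprintf("HUB%03d", seq_len(n_planted_hubs))
    for (h in seq_len(n_planted_hubs)) {
      tgt <- sample.int(n, min(hub_degree, n))
      a <- c(a, rep(n + h, length(tgt))); b <- c(b, tgt)
      deg[tgt] <- deg[tgt] + 1L
    }
    nodes <- c(nodes, hub_names)
    deg <- c(deg, rep(min(hub_degree, n), n_planted_hubs))
  }
  edges <- data.frame(
    protein_a = nodes[a], protein_b = nodes[b],
    combined_score = stats::runif(length(a), score_range[1], score_range[2]),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(node = nodes, degree = deg,
                      is_planted_hub = nodes %in% hub_names,
                      stringsAsFactors = FALSE)
  list(edges = edges, truth = truth)
}

#' Simulate novel-object-recognition behavior with group-shifted DI
#'
#' Each animal draws a latent learning score; its discrimination index is
#' the group mean plus `di_sd` times a mixture of the latent score and
#' independent noise, so the DI, distance traveled and spontaneous
#' alternation share a common factor. Exploration times are constructed
#' from the DI so that `(TN - TF) / total * 100` reproduces it exactly.
#'
#' @param design sample sheet from [generate_design()] (one row per
#'   animal).
#' @param group_di_means named DI means (%) per `"genotype.treatment"`
#'   cell; defaults emulate a TG deficit at baseline rescued mainly by the
#'   green tea arms.
#' @param di_sd DI standard deviation within a group (DI units, >= 0).
#' @param factor_loading share of DI variance carried by the latent
#'   learning factor (0..1).
#' @param seed integer RNG seed.
#' @return data.frame with per-animal `TN`, `TF`, `total`, `distance`,
#'   `alternation` and the derived `DI`.
#' @export
generate_behavior <- function(design,
                              group_di_means = c(
                                "WT.NT" = 40, "WT.greentea" = 42,
                                "WT.EE" = 42, "WT.greentea+EE" = 40,
                                "TG.NT" = 0, "TG.greentea" = 32,
                                "TG.EE" = 15, "TG.greentea+EE" = 30),
                              di_sd = 12,
                              factor_loading = 0.7,
                              seed = 1L) {
  if (di_sd < 0) stop("di_sd must be >= 0")
  if (any(abs(group_di_means) > 100)) {
    stop("DI means must lie in [-100, 100]")
  }
  set.seed(as.integer(seed))
  cond <- condition_label(design$genotype, design$treatment)
  mu <- group_di_means[cond]
  if (anyNA(mu)) {
    stop("group_di_means missing for: ",
         paste(unique(cond[is.na(mu)]), collapse = ", "))
  }
  n <- nrow(design)
  latent <- stats::rnorm(n)
  eps <- stats::rnorm(n)
  di <- as.numeric(mu) + di_sd * (sqrt(factor_loading) * latent +
                                    sqrt(1 - factor_loading) * eps)
  di <- pmin(95, pmax(-95, di))
  total <- stats::runif(n, 20, 40)
  tn <- total * (1 + di / 100) / 2
  tf <- total - tn
  out <- design
  out$TN <- tn
  out$TF <- tf
  out$total <- total
  out$distance <- 2000 + 150 * latent + stats::rnorm(n, 0, 200)
  out$alternation <- pmin(100, pmax(0, 60 + 5 * latent + stats::rnorm(n, 0, 6)))
  out$DI <- discrimination_index(out$TN, out$TF, out$total)
  out
}
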