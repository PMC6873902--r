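#' Discrimination index from exploration times
#'
#' `DI = (TN - TF) / total * 100`, where `TN` and `TF` are the seconds
#' spent exploring the novel and the familiar object and `total` is the
#' total exploration time.
#'
#' @param TN novel-object exploration time (s).
#' @param TF familiar-object exploration time (s).
#' @param total total exploration time (s), > 0 and >= TN + TF.
#' @return DI in percent, in \[-100, 100\] (vectorized).
#' @examples
#' discrimination_index(30, 20, 50)  # 20
#' @export
discrimination_index <- function(TN, TF, total) {
  if (any(total <= 0)) stop("total exploration time must be positive")
  if (any(TN + TF > total + 1e-9)) {
    stop("TN + TF must not exceed total exploration time")
  }
  (TN - TF) / total * 100
}

#' Genotype-by-treatment contrasts on the discrimination index
#'
#' Fits the cell-means linear model `DI ~ genotype x treatment` and tests
#' the study's seven contrasts: TG.NT vs WT.NT, and each treatment against
#' the untreated arm within each genotype. Estimates are cell-mean
#' differences with pooled-variance t statistics; the family of seven
#' p-values is Holm-adjusted.
#'
#' @param table behavior data.frame with `genotype`, `treatment`, `DI`.
#' @return data.frame `contrast`, `estimate`, `SE`, `df`, `p`, `adj_p`.
#' @export
anova_contrasts <- function(table) {
  cell <- condition_label(table$genotype, table$treatment)
  n_c <- tapply(table$DI, cell, length)
  if (any(n_c < 2)) {
    stop("each (genotype, treatment) cell needs >= 2 animals")
  }
  m_c <- tapply(table$DI, cell, mean)
  ss <- sum(tapply(table$DI, cell, function(x) sum((x - mean(x))^2)))
  df <- sum(n_c) - length(n_c)
  s2 <- ss / df

  contrasts <- c(list("TG.NT-WT.NT" = c("TG.NT" = 1, "WT.NT" = -1)),
                 unlist(lapply(treated_levels(), function(tr) {
                   stats::setNames(list(
                     stats::setNames(c(1, -1), c(paste0("TG.", tr), "TG.NT")),
                     stats::setNames(c(1, -1), c(paste0("WT.", tr), "WT.NT"))),
                     c(paste0("TG.", tr, "-TG.NT"),
                       paste0("WT.", tr, "-WT.NT")))
                 }), recursive = FALSE))
  est <- se <- p <- numeric(length(contrasts))
  for (i in seq_along(contrasts)) {
    w <- contrasts[[i]]
    if (!all(names(w) %in% names(m_c))) {
      stop("empty cell for contrast ", names(contrasts)[i])
    }
    est[i] <- sum(w * m_c[names(w)])
    se[i] <- sqrt(s2 * sum(w^2 / n_c[names(w)]))
    p[i] <- 2 * stats::pt(abs(est[i] / se[i]), df, lower.tail = FALSE)
  }
  data.frame(contrast = names(contrasts), estimate = est, SE = se,
             df = df, p = p, adj_p = stats::p.adjust(p, "holm"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' PCA of novel-object-recognition variables
#'
#' Standardized (unit-variance, zero-centered) principal component
#' analysis of DI, percent time on the novel and familiar objects,
#' distance traveled and spontaneous alternation. PC1 is sign-oriented so
#' the DI loading is positive (higher PC1 = better learning).
#'
#' @param table behavior data.frame with `TN`, `TF`, `total`, `distance`,
#'   `alternation`, `DI`.
#' @return object of class `nor_pca`: `scores` (animals x PCs),
#'   `loadings`, `variance_fraction`, plus the input rows.
#' @export
pca_behavior <- function(table) {
  vars <- data.frame(
    DI = table$DI,
    pct_novel = table$TN / table$total * 100,
    pct_familiar = table$TF / table$total * 100,
    distance = table$distance,
    alternation = table$alternation
  )
  if (nrow(vars) < 3) stop("need at least 3 animals")
  if (anyNA(vars)) stop("missing values in behavior variables")
  sds <- vapply(vars, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant variable(s): ", paste(names(vars)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(vars, center = TRUE, scale. = TRUE)
  flip <- sign(pc$rotation["DI", 1])
  if (flip < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
                 table = table),
            class = "nor_pca")
}

#' @export
print.nor_pca <- function(x, ...) {
  cat("NOR behavioral PCA on", nrow(x$scores), "animals\n")
  vf <- round(100 * x$variance_fraction, 1)
  cat("Variance explained (%):", paste(vf, collapse = ", "), "\n")
  cat("PC1 loadings:\n")
  print(round(x$loadings[, 1], 3))
  invisible(x)
}

#' Select prototype animals inside the 1.5 x IQR fence
#'
#' Per (genotype, treatment) group, animals whose DI lies outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (fences computed within the group) are
#' excluded, then `k` animals are sampled uniformly without replacement.
#'
#' @param table behavior data.frame with `sample_id`, `genotype`,
#'   `treatment`, `DI`.
#' @param k animals to select per group.
#' @param seed integer RNG seed.
#' @param allow_fewer take every inlier instead of failing when a group
#'   has fewer than `k` animals inside the fence.
#' @return the selected rows of `table`.
#' @export
select_prototypes <- function(table, k = 5, seed = 1L,
                              allow_fewer = FALSE) {
  set.seed(as.integer(seed))
  cell <- condition_label(table$genotype, table$treatment)
  keep <- unlist(lapply(split(seq_len(nrow(table)), cell), function(idx) {
    di <- table$DI[idx]
    q <- stats::quantile(di, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
    inside <- idx[di >= fence[1] & di <= fence[2]]
    kk <- k
    if (length(inside) < k) {
      if (!allow_fewer) {
        stop("fewer than ", k, " non-outlier animals in group ",
             cell[idx[1]])
      }
      kk <- length(inside)
    }
    sort(sample(inside, kk))
  }))
  out <- table[sort(unname(keep)), ]
  rownames(out) <- NULL
  out
}
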