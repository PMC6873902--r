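#' Percentage of recovery
#'
#' For a feature dysregulated in the untreated genotype contrast, the
#' genotype gap `g` is the log2 fold change TG.NT - WT.NT and the
#' treatment gap `t` the log2 fold change TG.T - WT.NT. The recovery
#' fraction is `(g - t) / g`: 1 means the treatment restored the feature
#' exactly to untreated-WT level, 0 means no treatment effect, values
#' above 1 overshoot, negative values mean the gap widened.
#'
#' @param genotype_gap log2FC of TG.NT - WT.NT; must be nonzero.
#' @param treatment_gap log2FC of TG.T - WT.NT.
#' @return unitless recovery fraction (vectorized).
#' @examples
#' recovery_fraction(1.0, 0.0)   # 1: full restoration
#' recovery_fraction(0.8, -0.4)  # 1.5: overshoot
#' @export
recovery_fraction <- function(genotype_gap, treatment_gap) {
  if (any(genotype_gap == 0, na.rm = TRUE)) {
    stop("genotype_gap must be nonzero")
  }
  (genotype_gap - treatment_gap) / genotype_gap
}

#' Rescue classification of a recovery fraction
#'
#' `rescued` for fractions in \[0.5, 1.5\] (50--150% recovery, boundaries
#' included), `overcorrected` above 1.5, `not_sufficiently_rescued` in
#' \[-0.5, 0.5), `impaired` below -0.5. The four intervals partition the
#' real line.
#'
#' @param fraction finite recovery fraction (vectorized).
#' @return character vector of classes.
#' @export
classify_recovery <- function(fraction) {
  if (any(!is.finite(fraction))) stop("fraction must be finite")
  ifelse(fraction > 1.5, "overcorrected",
  ifelse(fraction >= 0.5, "rescued",
  ifelse(fraction >= -0.5, "not_sufficiently_rescued", "impaired")))
}

#' Percentage of impairment (treatment effect on WT)
#'
#' Mirror of [recovery_fraction()] with the reversed baseline contrast:
#' `wt_gap` is the log2FC of WT.NT - TG.NT and `wt_treated_gap` the log2FC
#' of WT.T - TG.NT. High values mean the treatment pushed WT levels toward
#' the TG state.
#'
#' @param wt_gap log2FC of WT.NT - TG.NT; must be nonzero.
#' @param wt_treated_gap log2FC of WT.T - TG.NT.
#' @return unitless impairment fraction.
#' @export
impairment_fraction <- function(wt_gap, wt_treated_gap) {
  if (any(wt_gap == 0, na.rm = TRUE)) stop("wt_gap must be nonzero")
  (wt_gap - wt_treated_gap) / wt_gap
}

#' Rescue table and cross-treatment accounting
#'
#' Scores every feature differentially abundant in the genotype contrast
#' against each treatment. Quantitative features use the recovery
#' fraction computed from the fitted genotype and treatment gaps (the
#' treatment gap is the directly fitted TG.T - WT.NT contrast, not a sum
#' of two estimates). Presence/absence features are scored qualitatively:
#' a feature uniquely present in TG.NT (absent in WT.NT) is rescued by a
#' treatment when it is also absent under that treatment, and vice versa
#' for features absent in TG.NT.
#'
#' @param genotype_results adjusted results ([adjust_and_call()]) of the
#'   `TG.NT-WT.NT` contrast.
#' @param treatment_results named list per treatment of adjusted results
#'   for the `TG.<treatment>-WT.NT` contrast.
#' @return list with `records` (one row per feature x treatment:
#'   `genotype_gap`, `treatment_gap`, `recovery_fraction`, `class`,
#'   `qualitative` flag), `class_counts` (treatment x class matrix), and
#'   `venn` (named counts of the rescue partition across treatments, cells
#'   keyed like `"greentea+EE&greentea"`).
#' @export
rescue_table <- function(genotype_results, treatment_results) {
  de <- genotype_results[genotype_results$call %in%
                           c("up", "down", "present_only", "absent_only"), ]
  if (is.null(names(treatment_results)) || length(treatment_results) == 0) {
    stop("treatment_results must be a named list (one element per treatment)")
  }
  recs <- list()
  for (tr in names(treatment_results)) {
    tres <- treatment_results[[tr]]
    m <- match(de$feature_id, tres$feature_id)
    quant <- de$call %in% c("up", "down")
    g <- ifelse(quant, de$log2FC, NA_real_)
    t_gap <- tres$log2FC[m]
    f <- rep(NA_real_, nrow(de))
    cls <- rep(NA_character_, nrow(de))
    ok <- quant & !is.na(t_gap) & g != 0
    f[ok] <- recovery_fraction(g[ok], t_gap[ok])
    cls[ok] <- classify_recovery(f[ok])
    # qualitative path: does the presence state flip back to the WT state?
    qual <- !quant
    t_call <- tres$call[m]
    flipped <- (de$call == "present_only" &
                  t_call %in% c("absent_only", NA)) |
               (de$call == "absent_only" & !is.na(t_call) &
                  t_call %in% c("quantitative", "up", "down", "ns",
                                "present_only"))
    # a feature absent from the treatment results entirely was seen in
    # neither condition: for a TG-present feature that counts as reverted
    flipped[is.na(m) & de$call == "present_only"] <- TRUE
    flipped[is.na(m) & de$call == "absent_only"] <- FALSE
    cls[qual] <- ifelse(flipped[qual], "rescued", "not_sufficiently_rescued")
    recs[[tr]] <- data.frame(
      feature_id = de$feature_id, treatment = tr,
      genotype_call = de$call, genotype_gap = g, treatment_gap = t_gap,
      recovery_fraction = f, class = cls, qualitative = qual,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  cc <- table(records$treatment, records$class)
  venn <- rescue_venn(records)
  list(records = records, class_counts = cc, venn = venn)
}

# partition of rescued features by the set of treatments rescuing them
rescue_venn <- function(records) {
  resc <- records[records$class == "rescued", ]
  if (nrow(resc) == 0) return(integer(0))
  by_feat <- tapply(resc$treatment, resc$feature_id,
                    function(x) paste(sort(unique(x)), collapse = "&"))
  table(unlist(by_feat))
}
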