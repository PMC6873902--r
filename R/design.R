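#' Study design: genotypes, treatments and replicates
#'
#' Builds the full factorial sample sheet for a two-genotype (WT, TG),
#' four-arm (NT, greentea, EE, greentea+EE) study with a fixed number of
#' biological replicates per cell.
#'
#' @param n_replicates replicates per (genotype, treatment) cell; must be
#'   at least 2.
#' @param seed integer kept for interface uniformity with the stochastic
#'   generators; the design itself is deterministic.
#' @return a `data.frame` with columns `sample_id`, `genotype`,
#'   `treatment`, `replicate`. Sample ids are `"<genotype>.<treatment>.r<k>"`.
#' @examples
#' d <- generate_design(5)
#' nrow(d)  # 40
#' @export
generate_design <- function(n_replicates = 5, seed = 1L) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1 ||
      is.na(n_replicates) || n_replicates < 2) {
    stop("n_replicates must be a single number >= 2")
  }
  n_replicates <- as.integer(n_replicates)
  grid <- expand.grid(
    replicate = seq_len(n_replicates),
    treatment = treatment_levels(),
    genotype  = genotype_levels(),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[, c("genotype", "treatment", "replicate")]
  grid$sample_id <- paste0(grid$genotype, ".", grid$treatment, ".r", grid$replicate)
  rownames(grid) <- NULL
  grid[, c("sample_id", "genotype", "treatment", "replicate")]
}

#' @rdname generate_design
#' @export
genotype_levels <- function() c("WT", "TG")

#' @rdname generate_design
#' @export
treatment_levels <- function() c("NT", "greentea", "EE", "greentea+EE")

#' @rdname generate_design
#' @export
treated_levels <- function() setdiff(treatment_levels(), "NT")

# "WT.NT"-style cell label
condition_label <- function(genotype, treatment) paste(genotype, treatment, sep = ".")

# split "WT.NT" back into its two factors (treatment may contain '+', not '.')
split_condition <- function(cond) {
  pos <- regexpr(".", cond, fixed = TRUE)
  if (any(pos < 0)) stop("malformed condition label: ", cond[pos < 0][1])
  data.frame(
    genotype = substr(cond, 1L, pos - 1L),
    treatment = substring(cond, pos + 1L),
    stringsAsFactors = FALSE
  )
}
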