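#' Extract phosphosite flanking windows from protein sequences
#'
#' Windows of length `2 * halfwidth + 1` centered on the phosphosite;
#' positions beyond the protein termini are padded with `"X"`. The residue
#' at the site position must be S, T or Y.
#'
#' @param sites data.frame with `feature_id`, `protein_id`,
#'   `site_position` (1-based).
#' @param protein_sequences named character vector (or `AAStringSet`) of
#'   protein sequences.
#' @param halfwidth flanking residues on each side.
#' @return data.frame `feature_id`, `protein_id`, `site_position`,
#'   `residue`, `window`.
#' @export
extract_windows <- function(sites, protein_sequences, halfwidth = 7) {
  if (halfwidth < 1) stop("halfwidth must be >= 1")
  seqs <- protein_sequences
  if (!is.character(seqs)) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("protein_sequences must be named")
  out <- sites[, c("feature_id", "protein_id", "site_position")]
  out$residue <- NA_character_
  out$window <- NA_character_
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$protein_id[i]]]
    if (is.null(s) || is.na(s)) stop("no sequence for ", sites$protein_id[i])
    pos <- sites$site_position[i]
    if (pos < 1 || pos > nchar(s)) {
      stop("site position ", pos, " outside ", sites$protein_id[i])
    }
    ctr <- substr(s, pos, pos)
    if (!ctr %in% c("S", "T", "Y")) {
      stop("site ", sites$feature_id[i], ": residue at position ", pos,
           " is '", ctr, "', not S/T/Y")
    }
    lo <- pos - halfwidth; hi <- pos + halfwidth
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- lo:hi
    win <- ifelse(idx >= 1 & idx <= length(chars), chars[pmax(idx, 1)], "X")
    out$residue[i] <- ctr
    out$window[i] <- paste(win, collapse = "")
  }
  out
}

# window string matrix: rows = windows, cols = positions -h..+h
window_matrix <- function(windows) {
  w <- as.character(windows)
  len <- unique(nchar(w))
  if (length(len) != 1) stop("windows must share one length")
  if (len %% 2 == 0) stop("window length must be odd")
  m <- do.call(rbind, strsplit(w, "", fixed = TRUE))
  h <- (len - 1L) / 2L
  colnames(m) <- as.character(seq(-h, h))
  m
}

#' Central-residue and proline-context composition counts
#'
#' Nested counts mirroring the phospho-logo hierarchy: all windows, those
#' with a central serine / threonine / tyrosine, serine windows with a
#' proline at +1, and serine windows with a proline at -2.
#'
#' @param windows character vector of odd-length windows (shared width,
#'   halfwidth >= 2).
#' @return named integer vector: `n`, `center_S`, `center_T`, `center_Y`,
#'   `S_plus1_P`, `S_minus2_P`.
#' @export
composition_counts <- function(windows) {
  if (length(windows) == 0) {
    return(c(n = 0L, center_S = 0L, center_T = 0L, center_Y = 0L,
             S_plus1_P = 0L, S_minus2_P = 0L))
  }
  m <- window_matrix(windows)
  if (!all(c("-2", "1") %in% colnames(m))) stop("halfwidth must be >= 2")
  ctr <- m[, "0"]
  s <- ctr == "S"
  c(n = length(windows),
    center_S = sum(s), center_T = sum(ctr == "T"), center_Y = sum(ctr == "Y"),
    S_plus1_P = sum(s & m[, "1"] == "P"),
    S_minus2_P = sum(s & m[, "-2"] == "P"))
}

#' Match windows against an anchored consensus pattern
#'
#' Patterns are positional constraints anchored to the central phosphosite
#' and read left to right, e.g. `"PXSP"` (proline at -2, any at -1,
#' serine center, proline at +1) or `"RPX(S/T)P"` (arginine -3, proline
#' -2, any -1, S-or-T center, proline +1). `X` matches any residue but
#' never the terminal padding character; the center token must be a
#' phospho-acceptor (S, T, Y or a class of them).
#'
#' @param windows character vector of windows (shared odd length).
#' @param pattern consensus string.
#' @param ids optional identifiers returned for matches (defaults to
#'   indices).
#' @return the ids of matching windows.
#' @export
match_consensus <- function(windows, pattern, ids = seq_along(windows)) {
  tok <- parse_consensus(pattern)
  if (length(windows) == 0) return(ids[0])
  m <- window_matrix(windows)
  h <- (ncol(m) - 1L) / 2L
  if (max(abs(tok$offset)) > h) {
    stop("pattern spans beyond the window halfwidth")
  }
  ok <- rep(TRUE, nrow(m))
  for (i in seq_along(tok$offset)) {
    col <- m[, as.character(tok$offset[i])]
    allowed <- tok$residues[[i]]
    if (identical(allowed, "X")) {
      ok <- ok & col != "X"          # any residue, but padding never matches
    } else {
      ok <- ok & col %in% allowed
    }
  }
  ids[ok]
}

# tokenize a consensus pattern; returns offsets relative to the center
parse_consensus <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tokens <- list(); i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(j)) stop("unbalanced parenthesis in pattern")
      cls <- setdiff(chars[(i + 1):(j - 1)], "/")
      tokens[[length(tokens) + 1]] <- cls
      i <- j + 1
    } else {
      tokens[[length(tokens) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  is_center <- vapply(tokens, function(t)
    all(t %in% c("S", "T", "Y")) && !identical(t, "X"), logical(1))
  if (!any(is_center)) stop("pattern without a center phospho-acceptor class")
  ctr <- which(is_center)[1]
  list(offset = seq_along(tokens) - ctr, residues = tokens)
}

#' Position frequency matrix and information content
#'
#' Per-position amino-acid frequencies over the 20 standard residues,
#' excluding the padding character from denominators so terminal sites do
#' not dilute columns. Information content per column is
#' `log2(20) - H` where `H` is the Shannon entropy (bits) of the column
#' frequencies.
#'
#' @param windows character vector of windows (shared odd length).
#' @return object of class `pfm`: list with `freq` (20 x positions
#'   matrix), `counts`, `ic` (bits per position), `n_informative`
#'   (non-padding count per column).
#' @export
pfm <- function(windows) {
  if (length(windows) == 0) stop("need at least one window")
  m <- window_matrix(windows)
  pos <- colnames(m)
  counts <- vapply(pos, function(p)
    table(factor(m[, p], levels = AA20)), integer(length(AA20)))
  rownames(counts) <- AA20
  n_inf <- colSums(counts)
  freq <- sweep(counts, 2, pmax(n_inf, 1), "/")
  ent <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  ic <- ifelse(n_inf > 0, log2(20) - ent, NA_real_)
  structure(list(freq = freq, counts = counts, ic = ic,
                 n_informative = n_inf, n = length(windows)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix:", x$n, "windows, positions",
      colnames(x$freq)[1], "..", colnames(x$freq)[ncol(x$freq)], "\n")
  cat("Information content (bits):\n")
  print(round(x$ic, 3))
  invisible(x)
}

#' Write / read a PFM as a plain TSV (positions x residues)
#' @param x a `pfm`.
#' @param path file path.
#' @return (read) the frequency matrix with positions as columns.
#' @export
write_pfm <- function(x, path) {
  df <- data.frame(residue = rownames(x$freq), x$freq, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pfm
#' @export
read_pfm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$residue
  m
}
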