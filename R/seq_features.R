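#' Read annotated modification sites into peptide windows
#'
#' Reads a multi-record protein FASTA plus a tab-separated site table and cuts
#' a fixed-length peptide window around every annotated site. Windows that
#' overhang a protein terminus are padded with `"X"`; the padding symbol never
#' contributes to downstream feature counts.
#'
#' The site table must have the header
#' `record_id  position  residue  label`, with 1-based positions, residues in
#' `K`, `R`, `T`, `P`, and labels 0 (unmodified site) or 1 (modified site).
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param sites_path Path to the tab-separated site table.
#' @param window_len Odd window length (default 21 residues).
#' @return A tibble of peptide windows with columns `window`, `label`,
#'   `source_id`, `centre_position`, `residue`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">prot1", "MKAVTKLPR"), fa)
#' st <- tempfile(fileext = ".tsv")
#' writeLines(c("record_id\tposition\tresidue\tlabel", "prot1\t2\tK\t1"), st)
#' read_sites(fa, st, window_len = 5)
#' @export
read_sites <- function(fasta_path, sites_path, window_len = 21) {
  window_len <- check_window_len(window_len)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  seq_chr <- stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))

  sites <- utils::read.delim(sites_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  need <- c("record_id", "position", "residue", "label")
  if (!all(need %in% names(sites))) {
    abort(sprintf("site table must have columns %s", paste(need, collapse = ", ")))
  }
  if (!all(sites$residue %in% CENTRE_RESIDUES)) {
    bad <- setdiff(unique(sites$residue), CENTRE_RESIDUES)
    abort(sprintf("site residues must be one of K, R, T, P; found: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(sites$label %in% c(0L, 1L))) abort("site labels must be 0 or 1")

  windows <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    id <- sites$record_id[i]
    if (!id %in% names(seq_chr)) {
      abort(sprintf("record id '%s' not found in FASTA", id))
    }
    s <- seq_chr[[id]]
    pos <- sites$position[i]
    if (pos < 1 || pos > nchar(s)) {
      abort(sprintf("position %d is outside record '%s' (length %d)",
                    pos, id, nchar(s)))
    }
    found <- substr(s, pos, pos)
    if (found != sites$residue[i]) {
      abort(sprintf(
        "residue mismatch in record '%s' at position %d: site table says '%s', sequence has '%s'",
        id, pos, sites$residue[i], found))
    }
    windows[i] <- cut_window(s, pos, window_len)
  }

  tibble(
    window = windows,
    label = as.integer(sites$label),
    source_id = sites$record_id,
    centre_position = as.integer(sites$position),
    residue = sites$residue
  )
}

check_window_len <- function(window_len) {
  window_len <- check_positive_int(window_len, "window_len")
  if (window_len %% 2L == 0L) {
    abort(sprintf("`window_len` must be odd, got %d", window_len))
  }
  window_len
}

# Cut an L-mer centred at `pos` (1-based), padding termini with 'X'.
cut_window <- function(seq, pos, window_len) {
  half <- (window_len - 1L) %/% 2L
  idx <- (pos - half):(pos + half)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(idx, 1L)], AA_PAD)
  # Any non-standard residue (B, J, O, U, Z, ...) maps to the padding symbol.
  out[!(out %in% c(AA_ALPHABET, AA_PAD))] <- AA_PAD
  paste(out, collapse = "")
}

#' Read / write peptide window files
#'
#' Plain two-column `window  label` TSV, one peptide window per line.
#'
#' @param path File path.
#' @return `read_windows()` returns a windows tibble; `write_windows()`
#'   invisibly returns `path`.
#' @export
read_windows <- function(path) {
  dat <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("window", "label") %in% names(dat))) {
    abort("windows file must have columns `window` and `label`")
  }
  tibble(window = dat$window, label = as.integer(dat$label))
}

#' @rdname read_windows
#' @param data A windows tibble (columns `window`, `label`).
#' @export
write_windows <- function(data, path) {
  utils::write.table(data[c("window", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Distance-based residue (DR) features for peptide windows
#'
#' Converts each fixed-length window into a count vector of length
#' `20 + 400 * d_max`: the first 20 entries count each amino acid
#' (alphabetical order `A, C, D, ..., Y`), and for every distance
#' `k = 1, ..., d_max` a 400-entry block counts ordered residue pairs
#' `(i, j)` occurring at positions `(p, p + k)`, pairs ordered
#' `AA, AC, ..., YY`. Pairs are counted at distance exactly `k`, so for a
#' window of length `L` without padding the single-residue block sums to `L`
#' and each distance-`k` block sums to `L - k`. Any position holding the
#' padding symbol `"X"` contributes to no counter.
#'
#' @param data A windows tibble (as from [read_sites()] or
#'   [make_peptide_dataset()]), or a character vector of windows.
#' @param d_max Maximum residue-pair distance (positive integer, smaller than
#'   the window length). Default 3.
#' @return A tibble with `20 + 400 * d_max` integer feature columns, plus a
#'   `label` column when the input carries one. Single-residue columns are
#'   named `A ... Y`; pair columns `AA_1 ... YY_1, AA_2, ...` by distance.
#' @examples
#' dr_features(c("ACA"), d_max = 2)[, c("A", "C", "AC_1", "CA_1", "AA_2")]
#' @export
dr_features <- function(data, d_max = 3) {
  d_max <- check_positive_int(d_max, "d_max")
  if (is.character(data)) data <- tibble(window = data)
  if (!is.data.frame(data) || !"window" %in% names(data)) {
    abort("`data` must be a windows tibble with a `window` column")
  }
  wins <- data$window
  if (length(wins) == 0) abort("no windows to featurise")
  lens <- nchar(wins)
  if (any(d_max >= lens)) {
    abort(sprintf("`d_max` (%d) must be smaller than the window length (%d)",
                  d_max, min(lens)))
  }

  feat_names <- dr_feature_names(d_max)
  X <- matrix(0L, nrow = length(wins), ncol = length(feat_names),
              dimnames = list(NULL, feat_names))
  for (r in seq_along(wins)) {
    X[r, ] <- dr_vector(wins[r], d_max)
  }
  out <- as_tibble(X)
  if ("label" %in% names(data)) out$label <- as.integer(data$label)
  out
}

dr_feature_names <- function(d_max) {
  pairs <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  c(AA_ALPHABET,
    unlist(lapply(seq_len(d_max), function(k) paste0(pairs, "_", k))))
}

# Count vector for one window: D0 (20) then d_max blocks of 400.
dr_vector <- function(window, d_max) {
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, c(AA_ALPHABET, AA_PAD))
  if (length(bad) > 0) {
    abort(sprintf("window '%s' contains characters outside the amino-acid alphabet: %s",
                  window, paste(bad, collapse = ", ")))
  }
  idx <- match(chars, AA_ALPHABET)  # NA for padding
  L <- length(chars)
  d0 <- tabulate(idx, nbins = 20L)
  blocks <- lapply(seq_len(d_max), function(k) {
    i <- idx[seq_len(L - k)]
    j <- idx[seq_len(L - k) + k]
    ok <- !is.na(i) & !is.na(j)
    tabulate((i[ok] - 1L) * 20L + j[ok], nbins = 400L)
  })
  c(d0, unlist(blocks))
}

#' Min-max feature scaling fitted on the training set
#'
#' Fits per-column ranges on `train` only and rescales every data set to the
#' training ranges (`(x - min) / (max - min)`). Constant columns map to 0.
#' Values outside the training range are not clipped, so held-out data can
#' fall outside `[0, 1]`.
#'
#' @param train A feature tibble (the fitting set); must not already be
#'   scaled.
#' @param others A feature tibble or list of feature tibbles to transform
#'   with the ranges fitted on `train`.
#' @return A list with elements `train` (scaled), `others` (list of scaled
#'   tibbles), and `ranges` (tibble of the fitted column minima and maxima).
#'   Scaled tibbles carry `attr(-, "scaling_state") == "minmax"`.
#' @export
minmax_scale <- function(train, others = list()) {
  if (identical(attr(train, "scaling_state"), "minmax")) {
    abort("`train` is already min-max scaled")
  }
  if (is.data.frame(others)) others <- list(others)
  tp <- feature_parts(train, require_label = FALSE)
  lo <- apply(tp$X, 2, min)
  hi <- apply(tp$X, 2, max)
  span <- hi - lo
  span[span == 0] <- Inf  # constant columns -> 0 after centring

  apply_scale <- function(d) {
    p <- feature_parts(d, require_label = FALSE)
    if (ncol(p$X) != length(lo)) {
      abort(sprintf("column count mismatch: fitting set has %d feature columns, data has %d",
                    length(lo), ncol(p$X)))
    }
    Xs <- sweep(sweep(p$X, 2, lo, "-"), 2, span, "/")
    out <- feature_tibble(Xs, p$y, p$feature_names)
    attr(out, "scaling_state") <- "minmax"
    out
  }

  list(
    train = apply_scale(train),
    others = lapply(others, apply_scale),
    ranges = tibble(feature = tp$feature_names, min = unname(lo), max = unname(hi))
  )
}
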