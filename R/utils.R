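#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows bind_cols mutate filter select arrange group_by summarise ungroup
#' @importFrom purrr map map_dbl map_int map2
NULL

# The 20 standard amino acids, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Padding symbol used at protein termini; never counted in features.
AA_PAD <- "X"

CENTRE_RESIDUES <- c("K", "R", "T", "P")

# Run `code` under a private RNG stream; the caller's .Random.seed is
# untouched afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

is_feature_df <- function(data) {
  is.data.frame(data) && "label" %in% names(data)
}

# Split a feature tibble into an X matrix and a 0/1 label vector.
feature_parts <- function(data, require_label = TRUE) {
  if (!is.data.frame(data)) {
    abort("expected a data frame of features (with a `label` column)")
  }
  has_label <- "label" %in% names(data)
  if (require_label && !has_label) {
    abort("feature data must contain a `label` column")
  }
  x_cols <- setdiff(names(data), "label")
  X <- as.matrix(data[x_cols])
  if (!is.numeric(X)) abort("feature columns must all be numeric")
  y <- if (has_label) as.integer(data$label) else NULL
  if (!is.null(y) && !all(y %in% c(0L, 1L))) {
    abort("`label` must be binary (0 = majority/negative, 1 = minority/positive)")
  }
  list(X = X, y = y, feature_names = x_cols)
}

feature_tibble <- function(X, y = NULL, feature_names = NULL) {
  feature_names <- feature_names %||% colnames(X) %||%
    sprintf("f%03d", seq_len(ncol(X)))
  colnames(X) <- feature_names
  out <- as_tibble(X)
  if (!is.null(y)) out$label <- as.integer(y)
  out
}

check_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

# Labels given as 0/1 or -1/+1; standardise to -1/+1.
as_pm1 <- function(y) {
  y <- as.integer(y)
  if (all(y %in% c(0L, 1L))) return(ifelse(y == 1L, 1L, -1L))
  if (all(y %in% c(-1L, 1L))) return(y)
  abort("labels must be coded 0/1 or -1/+1")
}
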