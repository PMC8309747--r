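# Internal helpers shared across modules.

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

# Fold assignment vector of length n with values 1..k. Stratified keeps the
# class proportions of y in every fold (required so every class appears in
# every training fold of a classification CV).
make_folds <- function(n, k, y = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  k <- as.integer(k)
  if (k < 2L) stop("fold count must be >= 2")
  fold <- integer(n)
  if (is.null(y)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    y <- as.factor(y)
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  fold
}

one_hot <- function(y) {
  y <- as.factor(y)
  m <- matrix(0, length(y), nlevels(y),
              dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' Jaccard overlap of two channel masks
#'
#' `|A intersect B| / |A union B|` on the selected (==1) channels; used to
#' score wavelength-selector recovery of the generator's known informative
#' channels.
#'
#' @param mask_a,mask_b 0/1 vectors of equal length.
#' @return numeric in `[0, 1]`; 1 for identical non-empty masks, and by
#'   convention 1 when both masks are empty.
#' @export
jaccard_mask <- function(mask_a, mask_b) {
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
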