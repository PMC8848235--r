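#' Blocked cross-validation splits
#'
#' Partitions `n_rows` ordered rows into `k` contiguous, non-overlapping
#' blocks; fold j validates on block j and trains on all remaining rows.
#' No shuffling is performed, preserving the temporal ordering inside
#' every block — the appropriate scheme for autocorrelated series.
#'
#' @param n_rows Number of rows to split.
#' @param k Number of folds (default 5).
#' @return A list of `k` elements, each `list(train =, validation =)` of
#'   integer row indices. Block sizes differ by at most one.
#' @export
#' @examples
#' blocked_cv_splits(10, 5)
blocked_cv_splits <- function(n_rows, k = 5) {
  if (k < 2) abort("`k` must be at least 2.")
  if (n_rows < k) abort("`n_rows` must be at least `k`.")
  sizes <- rep(n_rows %/% k, k)
  extra <- n_rows %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(k), function(j) {
    val <- starts[j]:ends[j]
    list(train = setdiff(seq_len(n_rows), val), validation = val)
  })
}

# Fold id vector (1..k) for glmnet-style interfaces.
blocked_foldid <- function(n_rows, k = 5) {
  splits <- blocked_cv_splits(n_rows, k)
  id <- integer(n_rows)
  for (j in seq_along(splits)) id[splits[[j]]$validation] <- j
  id
}
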