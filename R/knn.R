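# Chunked exact k-nearest-neighbour search in Euclidean space.
# Returns index and distance matrices (n_query x k) into rows of `ref`.
# `exclude` optionally maps each query row to the ref row that is itself.
nearest_neighbors <- function(ref, query, k, exclude = NULL,
                              chunk = 2000L) {
  stopifnot(is.matrix(ref), is.matrix(query), ncol(ref) == ncol(query))
  k <- min(k, nrow(ref) - if (is.null(exclude)) 0L else 1L)
  if (k < 1) stop("k must be >= 1 after self-exclusion")
  ref_norm <- rowSums(ref^2)
  nq <- nrow(query)
  idx <- matrix(NA_integer_, nq, k)
  dst <- matrix(NA_real_, nq, k)
  for (start in seq(1L, nq, by = chunk)) {
    rows <- start:min(start + chunk - 1L, nq)
    q <- query[rows, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref_norm, `+`) - 2 * tcrossprod(q, ref)
    d2[d2 < 0] <- 0
    if (!is.null(exclude)) {
      ex <- exclude[rows]
      has <- which(!is.na(ex))
      if (length(has)) d2[cbind(has, ex[has])] <- Inf
    }
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(d2[j, o])
    }
  }
  list(idx = idx, dist = dst, k = k)
}
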