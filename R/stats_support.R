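#' Cochran's C statistic for homogeneity of variances
#'
#' C = max(s_i^2) / sum(s_i^2) over k group variances: the share of the
#' total variance held by the most variable group. Bounded by 1/k (all
#' groups equal) and 1 (one group holds all variance), and invariant to a
#' common rescaling of the variances. The statistic is returned together
#' with k and the common replicate count n so it can be referred to
#' published critical-value tables; no p-value is computed.
#'
#' @param variances nonnegative group variances, one per cell (>= 2 groups,
#'   at least one positive).
#' @param n common number of replicates per group (optional, carried along
#'   for table lookup).
#' @return an object of class `cochran_c`: a list with `statistic`, `k`,
#'   `n`.
#' @export
#' @examples
#' cochran_c(c(4, 1, 1, 1, 1)) # C = 0.5
cochran_c <- function(variances, n = NULL) {
  if (length(variances) < 2) abort_domain("need at least 2 group variances")
  if (any(is.na(variances)) || any(variances < 0)) {
    abort_domain("variances must be nonnegative")
  }
  total <- sum(variances)
  if (total == 0) abort_domain("all variances are zero: C undefined")
  structure(
    list(
      statistic = max(variances) / total,
      k = length(variances),
      n = n
    ),
    class = "cochran_c"
  )
}

#' @export
print.cochran_c <- function(x, ...) {
  cat(sprintf(
    "Cochran's C = %.4f (k = %d groups%s)\n",
    x$statistic, x$k,
    if (is.null(x$n)) "" else sprintf(", n = %d replicates per group", x$n)
  ))
  invisible(x)
}
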