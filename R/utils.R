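# Numeric helpers shared across modules.

#' Compensated (Kahan) summation
#'
#' Sums a numeric vector left to right with a running compensation term so the
#' result does not depend on how a caller might have chunked the additions.
#' All hierarchical-partitioning accumulations go through this function in a
#' fixed canonical order, which is what makes the decomposition reproducible
#' to ~1e-12 regardless of predictor order.
#'
#' @param x numeric vector.
#' @return The compensated sum, a length-1 numeric.
#' @keywords internal
kahan_sum <- function(x) {
  s <- 0
  comp <- 0
  for (xi in x) {
    y <- xi - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  s
}

# Number of set bits for every mask in 0:(2^k - 1), in ascending-mask order.
popcount_table <- function(k) {
  size <- integer(bitwShiftL(1L, k))
  for (i in seq_len(k)) {
    bit <- bitwShiftL(1L, i - 1L)
    size <- size + as.integer(bitwAnd(0:(length(size) - 1L), bit) != 0L)
  }
  size
}

# All permutations of 1:k as a k! x k matrix (rows are permutations).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    shifted <- sub + (sub >= i)
    out[[i]] <- cbind(rep.int(i, nrow(sub)), shifted)
  }
  do.call(rbind, out)
}

# Derive independent substream seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  s
}
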