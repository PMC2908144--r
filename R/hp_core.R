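#' Hierarchical partition of a subset fit table
#'
#' Decomposes the full model's goodness-of-fit into one independent
#' contribution per predictor by averaging, level by level, the increase in
#' fit each predictor produces when added to every submodel that excludes it:
#' at hierarchy level `h` the increments over all subsets of size `h` are
#' averaged, and the independent contribution `I_i` is the mean of the `k`
#' level means. This level average is identical to the Shapley/LMG average
#' over all `k!` predictor orderings (see [partition_by_orderings()]).
#' The joint contribution is `J_i = T_i - I_i`, where the total contribution
#' `T_i = gof({i}) - gof(empty)` is the univariate gain; negative `J_i`
#' indicates that the other predictors act as suppressors.
#'
#' Increments are accumulated with compensated summation in ascending-bitmask
#' order, so the decomposition is reproducible to ~1e-12 and — because the fit
#' table itself is built in canonical name order — invariant to the order the
#' predictors entered the analysis.
#'
#' @param table a `subset_fit_table` from [fit_all_subsets()].
#' @return An object of class `hp_partition`: list with `names`, `I`, `J`,
#'   `T`, `I_perc` (shares, `100 * I / sum(I)`), `gof_full`, `gof_null` and
#'   the `spec`.
#' @examples
#' # k = 2 by hand: gof(empty)=0, gof(A)=.3, gof(B)=.2, gof(AB)=.4
#' p <- partition_gof(subset_fit_table(c(0, .3, .2, .4), c("A", "B")))
#' p$I  # 0.25 0.15
#' @export
partition_gof <- function(table) {
  stopifnot(inherits(table, "subset_fit_table"))
  k <- table$k
  gof <- table$gof
  if (bitwShiftL(1L, k) != length(gof))
    stop("gof table length is not 2^k")
  masks <- 0:(length(gof) - 1L)
  size <- popcount_table(k)
  I <- numeric(k)
  T_ <- numeric(k)
  for (i in seq_len(k)) {
    bit <- bitwShiftL(1L, i - 1L)
    m0 <- masks[bitwAnd(masks, bit) == 0L]          # ascending (canonical)
    inc <- gof[m0 + bit + 1L] - gof[m0 + 1L]
    h <- size[m0 + 1L]
    level_means <- vapply(0:(k - 1L), function(hh) {
      v <- inc[h == hh]
      kahan_sum(v) / length(v)
    }, numeric(1))
    I[i] <- kahan_sum(level_means) / k
    T_[i] <- gof[bit + 1L] - gof[1L]
  }
  J <- T_ - I
  if (any(I < 0))
    warning("negative independent contribution for: ",
            paste(table$names[I < 0], collapse = ", "))
  structure(
    list(names = table$names, I = I, J = J, T = T_,
         I_perc = 100 * I / kahan_sum(I),
         gof_full = gof[length(gof)], gof_null = gof[1L], spec = table$spec),
    class = "hp_partition"
  )
}

#' @export
print.hp_partition <- function(x, digits = 4, ...) {
  cat("Hierarchical partition (", x$spec$measure, ", ", x$spec$family, ")\n",
      sep = "")
  df <- data.frame(Independent = x$I, Joint = x$J, Total = x$T,
                   I_perc = x$I_perc, row.names = x$names)
  print(round(df, digits), ...)
  cat("gof(full) =", format(x$gof_full, digits = digits),
      "; gof(null) =", format(x$gof_null, digits = digits),
      "; sum(I) =", format(kahan_sum(x$I), digits = digits), "\n")
  invisible(x)
}

#' @export
as.data.frame.hp_partition <- function(x, ...) {
  data.frame(variable = x$names, I = x$I, J = x$J, T = x$T,
             I_perc = x$I_perc, stringsAsFactors = FALSE)
}

#' Brute-force partition over all predictor orderings
#'
#' Independent reference implementation of the same decomposition: the
#' contribution of predictor `i` is averaged over the fit increment it adds
#' when entering in each of the `k!` predictor orderings (the Shapley value of
#' the goodness-of-fit game). Exponentially more expensive than
#' [partition_gof()] and capped at `k <= 8`; intended as an oracle in tests.
#'
#' @inheritParams partition_gof
#' @return An `hp_partition`, agreeing with [partition_gof()] to ~1e-9.
#' @export
partition_by_orderings <- function(table) {
  stopifnot(inherits(table, "subset_fit_table"))
  k <- table$k
  if (k > 8L) stop("ordering enumeration (k!) is capped at k = 8")
  gof <- table$gof
  perms <- all_permutations(k)
  acc <- matrix(0, nrow(perms), k)
  for (p in seq_len(nrow(perms))) {
    mask <- 0L
    for (j in seq_len(k)) {
      i <- perms[p, j]
      bit <- bitwShiftL(1L, i - 1L)
      acc[p, i] <- gof[bitwOr(mask, bit) + 1L] - gof[mask + 1L]
      mask <- bitwOr(mask, bit)
    }
  }
  I <- vapply(seq_len(k), function(i) kahan_sum(acc[, i]) / nrow(perms),
              numeric(1))
  T_ <- vapply(seq_len(k), function(i)
    gof[bitwShiftL(1L, i - 1L) + 1L] - gof[1L], numeric(1))
  structure(
    list(names = table$names, I = I, J = T_ - I, T = T_,
         I_perc = 100 * I / kahan_sum(I),
         gof_full = gof[length(gof)], gof_null = gof[1L], spec = table$spec),
    class = "hp_partition"
  )
}

#' Rank variables by independent contribution
#'
#' Orders variables by decreasing independent contribution `I`. Exact ties are
#' broken by canonical (alphabetical) name order, with a warning, so rankings
#' are always deterministic.
#'
#' @param result an `hp_partition`.
#' @return An object of class `hp_ranking`: list with `order` (names sorted by
#'   decreasing `I`) and `positions` (named integer vector, 1-based rank per
#'   variable).
#' @export
rank_variables <- function(result) {
  stopifnot(inherits(result, "hp_partition"))
  if (anyDuplicated(result$I))
    warning("exact ties in independent contributions; broken alphabetically")
  ord <- order(-result$I, result$names)
  positions <- seq_along(ord)
  names(positions) <- result$names[ord]
  structure(list(order = result$names[ord],
                 positions = positions[result$names]),
            class = "hp_ranking")
}

#' @export
print.hp_ranking <- function(x, ...) {
  cat("Ranking by independent contribution:\n")
  cat(paste0(seq_along(x$order), ". ", x$order, collapse = "\n"), "\n")
  invisible(x)
}

#' Joint contribution from total and independent
#'
#' The joint contribution is simply the total univariate contribution minus
#' the independent contribution, `J = T - I` (vectorized).
#'
#' @param I independent contribution(s).
#' @param T total contribution(s).
#' @return `T - I`.
#' @examples
#' joint_from_total(10.63, 31.48)  # 20.85
#' @export
joint_from_total <- function(I, T) T - I

#' One-call hierarchical partitioning
#'
#' Convenience wrapper: fits all predictor subsets and partitions the
#' goodness-of-fit in one step.
#'
#' @inheritParams fit_all_subsets
#' @param gof goodness-of-fit measure, `"rsqu"` or `"loglik"`.
#' @return An `hp_partition`.
#' @examples
#' d <- hp_data(rnorm(20), matrix(rnorm(60), 20, 3))
#' hier_part(d)
#' @export
hier_part <- function(data, gof = c("rsqu", "loglik"), cap = 12L) {
  gof <- match.arg(gof)
  partition_gof(fit_all_subsets(data, gof_spec(gof, data$family), cap = cap))
}
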