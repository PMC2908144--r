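#' Permutation audit of ranking stability
#'
#' Reruns the hierarchical partitioning under `R` independently drawn uniform
#' permutations of the predictor order and compares each run's ranking to the
#' reference analysis, whose predictors follow alphabetical order. With the
#' exact engine every run reproduces the reference bit for bit; an
#' order-sensitive engine (supplied via `engine`, e.g. a test double) will
#' show rank changes, which the summaries below quantify.
#'
#' @param data an [hp_data()] object.
#' @param spec a [gof_spec()].
#' @param R number of reshuffles (default 100).
#' @param seed master seed; per-run seeds are derived from it and logged.
#' @param engine function `(data) -> hp_partition`; defaults to the exact
#'   engine `partition_gof(fit_all_subsets(data, spec, cap))`.
#' @param cap predictor cap passed to [fit_all_subsets()].
#' @return An object of class `hp_perm_experiment`: list with `reference`
#'   (`hp_partition`), `reference_ranking`, `runs` (each with `order`, `seed`,
#'   `result`, `ranking`), `R`, `seed`.
#' @export
run_permutation_experiment <- function(data, spec = gof_spec("rsqu", "gaussian"),
                                       R = 100L, seed = 1L, engine = NULL,
                                       cap = 12L) {
  stopifnot(inherits(data, "hp_data"))
  if (R < 1L) stop("R must be at least 1")
  if (is.null(engine))
    engine <- function(d) partition_gof(fit_all_subsets(d, spec, cap = cap))
  k <- length(data$names)
  ref_data <- permute_predictors(data, data$canonical_order)
  reference <- engine(ref_data)
  reference_ranking <- rank_variables(reference)
  run_seeds <- derive_seeds(seed, R)
  runs <- vector("list", R)
  for (r in seq_len(R)) {
    set.seed(run_seeds[r])
    perm <- sample.int(k)
    pd <- permute_predictors(data, perm)
    res <- engine(pd)
    runs[[r]] <- list(order = data$names[perm], seed = run_seeds[r],
                      result = res, ranking = rank_variables(res))
  }
  structure(list(reference = reference,
                 reference_ranking = reference_ranking,
                 runs = runs, R = R, seed = seed),
            class = "hp_perm_experiment")
}

#' @export
print.hp_perm_experiment <- function(x, ...) {
  cat("Permutation audit:", x$R, "reshuffles of",
      length(x$reference$names), "predictors (seed", x$seed, ")\n")
  cat("ranking change rate:",
      format(ranking_change_rate(x)), "%\n")
  invisible(x)
}

#' Rank-transition (change) matrix
#'
#' Builds the k x k matrix whose entry (r, c) is the percentage of permutation
#' runs in which the variable holding reference rank r appeared at rank c.
#' With an order-invariant engine this is 100 on the diagonal and 0 elsewhere;
#' every row sums to 100.
#'
#' @param experiment an `hp_perm_experiment`.
#' @return Numeric k x k matrix, rows named by the reference ranking order,
#'   columns by rank.
#' @export
change_matrix <- function(experiment) {
  stopifnot(inherits(experiment, "hp_perm_experiment"))
  ref <- experiment$reference_ranking
  k <- length(ref$order)
  M <- matrix(0, k, k, dimnames = list(ref$order, seq_len(k)))
  for (run in experiment$runs) {
    pos <- run$ranking$positions[ref$order]
    for (r in seq_len(k)) M[r, pos[r]] <- M[r, pos[r]] + 1
  }
  100 * M / experiment$R
}

#' Ranking change rate
#'
#' Percentage of permutation runs whose ranking differs anywhere from the
#' reference. With `top_m` given, the comparison is restricted to the
#' reference's top-`m` variables (a run counts as changed if any of those
#' variables holds a different rank than in the reference).
#'
#' @param experiment an `hp_perm_experiment`.
#' @param top_m number of top reference variables to compare; `NULL` compares
#'   the whole ranking.
#' @return Percentage in `[0, 100]`.
#' @export
ranking_change_rate <- function(experiment, top_m = NULL) {
  stopifnot(inherits(experiment, "hp_perm_experiment"))
  ref <- experiment$reference_ranking
  vars <- if (is.null(top_m)) ref$order else
    ref$order[seq_len(min(top_m, length(ref$order)))]
  ref_pos <- ref$positions[vars]
  changed <- vapply(experiment$runs, function(run)
    any(run$ranking$positions[vars] != ref_pos), logical(1))
  100 * mean(changed)
}

#' Variability of independent contributions across runs
#'
#' Per-variable mean, standard deviation, minimum and maximum of the
#' independent contribution `I` (and of the share `I_perc`) across the
#' permutation runs. With an order-invariant engine every range is zero.
#'
#' @param experiment an `hp_perm_experiment`.
#' @return data frame with one row per variable: `variable`, `mean_I`, `sd_I`,
#'   `min_I`, `max_I`, `mean_I_perc`, `sd_I_perc`, `min_I_perc`, `max_I_perc`.
#' @export
ive_variability <- function(experiment) {
  stopifnot(inherits(experiment, "hp_perm_experiment"))
  vars <- sort(experiment$reference$names)
  if (experiment$R < 2L)
    warning("single run: standard deviations reported as 0")
  Imat <- t(vapply(experiment$runs, function(run) {
    v <- run$result$I
    names(v) <- run$result$names
    v[vars]
  }, numeric(length(vars))))
  Pmat <- t(vapply(experiment$runs, function(run) {
    v <- run$result$I_perc
    names(v) <- run$result$names
    v[vars]
  }, numeric(length(vars))))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  data.frame(
    variable = vars,
    mean_I = apply(Imat, 2L, mean), sd_I = apply(Imat, 2L, sd0),
    min_I = apply(Imat, 2L, min), max_I = apply(Imat, 2L, max),
    mean_I_perc = apply(Pmat, 2L, mean), sd_I_perc = apply(Pmat, 2L, sd0),
    min_I_perc = apply(Pmat, 2L, min), max_I_perc = apply(Pmat, 2L, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Subsampled-variable-set audit
#'
#' For each requested subset size `m`, draws one random `m`-subset of the
#' predictors (more with `replicates`) and runs the permutation audit on it,
#' reporting per-size ranking change rates.
#'
#' @inheritParams run_permutation_experiment
#' @param sizes integer vector of subset sizes, each in `2..k`.
#' @param replicates random subsets drawn per size (default 1).
#' @param top_m also report the change rate restricted to the top `top_m`
#'   reference variables.
#' @return An object of class `hp_subsample_experiment`: list with
#'   `experiments` (nested per size/replicate) and `summary` (data frame:
#'   `size`, `replicate`, `variables`, `change_rate`, `change_rate_top`).
#' @export
run_subsample_experiment <- function(data, spec = gof_spec("rsqu", "gaussian"),
                                     sizes = 2:length(data$names), R = 100L,
                                     seed = 1L, replicates = 1L, engine = NULL,
                                     top_m = 5L, cap = 12L) {
  stopifnot(inherits(data, "hp_data"))
  k <- length(data$names)
  if (any(sizes < 2L | sizes > k))
    stop("sizes must lie in 2..k = 2..", k)
  seeds <- derive_seeds(seed, length(sizes) * replicates * 2L)
  si <- 0L
  experiments <- list()
  rows <- list()
  for (m in sizes) {
    for (rep in seq_len(replicates)) {
      si <- si + 1L
      set.seed(seeds[2L * si - 1L])
      vars <- sort(sample(data$names, m))
      sub <- hp_data(data$response,
                     data$predictors[, vars, drop = FALSE], names = vars,
                     family = data$family,
                     response_name = data$response_name)
      ex <- run_permutation_experiment(sub, spec, R = R,
                                       seed = seeds[2L * si], engine = engine,
                                       cap = cap)
      experiments[[length(experiments) + 1L]] <-
        list(size = m, replicate = rep, variables = vars, experiment = ex)
      rows[[length(rows) + 1L]] <- data.frame(
        size = m, replicate = rep,
        variables = paste(vars, collapse = "|"),
        change_rate = ranking_change_rate(ex),
        change_rate_top = ranking_change_rate(ex, top_m = top_m),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(experiments = experiments,
                 summary = do.call(rbind, rows), seed = seed),
            class = "hp_subsample_experiment")
}

#' @export
print.hp_subsample_experiment <- function(x, ...) {
  cat("Subsampled-variable-set audit (seed", x$seed, ")\n")
  print(x$summary, ...)
  invisible(x)
}
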