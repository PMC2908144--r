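#' Goodness-of-fit specification
#'
#' Pairs a goodness-of-fit measure with an error family. `"rsqu"` (least
#' squares R-squared) is only defined for the gaussian family; `"loglik"`
#' (the maximized log-likelihood) is available for all families.
#'
#' @param measure `"rsqu"` or `"loglik"`.
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @return An object of class `gof_spec`.
#' @export
gof_spec <- function(measure = c("rsqu", "loglik"),
                     family = c("gaussian", "binomial", "poisson")) {
  measure <- match.arg(measure)
  family <- match.arg(family)
  if (measure == "rsqu" && family != "gaussian")
    stop("measure 'rsqu' requires family 'gaussian'")
  structure(list(measure = measure, family = family), class = "gof_spec")
}

#' @export
print.gof_spec <- function(x, ...) {
  cat("gof_spec: measure =", x$measure, ", family =", x$family, "\n")
  invisible(x)
}

# Log-likelihood of a fitted mean vector under the given family.
family_loglik <- function(y, mu, family, n) {
  switch(family,
    gaussian = {
      rss <- sum((y - mu)^2)
      -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    },
    binomial = sum(stats::dbinom(y, 1L, mu, log = TRUE)),
    poisson  = sum(stats::dpois(y, mu, log = TRUE))
  )
}

#' Fit every predictor subset
#'
#' Fits all `2^k` submodels (including the intercept-only model) and stores
#' one goodness-of-fit value per subset, indexed by bitmask: bit `i` set means
#' the `i`-th predictor *in canonical alphabetical order* is in the model.
#' Columns are canonicalized before enumeration, so the table — and every
#' decomposition derived from it — is identical for any input column order.
#'
#' For `measure = "rsqu"` the empty model scores 0 and every submodel scores
#' its least-squares R-squared; for `measure = "loglik"` each submodel scores
#' its maximized log-likelihood (the empty model is the intercept-only fit).
#' Rank-deficient subsets (possible with collinear subsamples) are fitted at
#' their reduced rank and counted in a single warning rather than failing.
#'
#' @param data an [hp_data()] object.
#' @param spec a [gof_spec()]; its family must match `data$family`.
#' @param cap maximum number of predictors (default 12; hard limit 16, since
#'   the cost is `2^k` model fits).
#' @return An object of class `subset_fit_table`: list with `k`, `names`
#'   (canonical order), `gof` (length `2^k`, ascending bitmask), `spec`, `n`
#'   and `n_rank_deficient`.
#' @examples
#' d <- hp_data(rnorm(20), matrix(rnorm(60), 20, 3), names = c("a", "b", "c"))
#' tab <- fit_all_subsets(d, gof_spec("rsqu", "gaussian"))
#' length(tab$gof)  # 8
#' @export
fit_all_subsets <- function(data, spec = gof_spec("rsqu", "gaussian"),
                            cap = 12L) {
  stopifnot(inherits(data, "hp_data"), inherits(spec, "gof_spec"))
  if (spec$family != data$family)
    stop("gof_spec family (", spec$family, ") does not match data family (",
         data$family, ")")
  if (cap > 16L)
    stop("cap may not exceed 16 (2^k submodel fits)")
  k <- length(data$names)
  if (k > cap)
    stop("k = ", k, " predictors exceeds the cap of ", cap,
         "; raise 'cap' (hard limit 16) at a cost of 2^k fits")
  ord <- data$canonical_order
  X <- data$predictors[, ord, drop = FALSE]
  nms <- data$names[ord]
  y <- data$response
  n <- length(y)
  n_models <- bitwShiftL(1L, k)
  gof <- numeric(n_models)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  n_def <- 0L

  if (spec$measure == "rsqu") {
    tss <- sum((y - mean(y))^2)
    if (tss <= 0) stop("constant response: R-squared undefined")
    gof[1L] <- 0
    for (m in seq_len(n_models - 1L)) {
      cols <- which(bitwAnd(m, bits) != 0L)
      fit <- .lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
      if (fit$rank < length(cols) + 1L) n_def <- n_def + 1L
      gof[m + 1L] <- 1 - sum(fit$residuals^2) / tss
    }
  } else {
    fam <- switch(spec$family,
                  gaussian = stats::gaussian(),
                  binomial = stats::binomial(),
                  poisson  = stats::poisson())
    ctrl <- stats::glm.control(epsilon = 1e-10, maxit = 100L)
    for (m in 0:(n_models - 1L)) {
      cols <- which(bitwAnd(m, bits) != 0L)
      xm <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
      fit <- suppressWarnings(
        stats::glm.fit(xm, y, family = fam, control = ctrl))
      if (fit$rank < ncol(xm)) n_def <- n_def + 1L
      gof[m + 1L] <- family_loglik(y, fit$fitted.values, spec$family, n)
    }
  }
  if (n_def > 0L)
    warning(n_def, " rank-deficient subset(s) fitted at reduced rank")
  structure(
    list(k = k, names = nms, gof = gof, spec = spec, n = n,
         n_rank_deficient = n_def),
    class = "subset_fit_table"
  )
}

#' @export
print.subset_fit_table <- function(x, ...) {
  cat("subset_fit_table: k =", x$k, "(", length(x$gof), "subsets ),",
      "measure =", x$spec$measure, ", family =", x$spec$family, "\n")
  cat("gof(null) =", format(x$gof[1L]), ", gof(full) =",
      format(x$gof[length(x$gof)]), "\n")
  invisible(x)
}

# Build a subset_fit_table directly from a gof vector (tests / oracles).
subset_fit_table <- function(gof, names = NULL,
                             spec = gof_spec("rsqu", "gaussian"), n = NA_integer_) {
  k <- as.integer(round(log2(length(gof))))
  if (bitwShiftL(1L, k) != length(gof))
    stop("gof length must be a power of two")
  if (is.null(names)) names <- LETTERS[seq_len(k)]
  structure(list(k = k, names = names, gof = as.numeric(gof), spec = spec,
                 n = n, n_rank_deficient = 0L),
            class = "subset_fit_table")
}

#' Select a piecewise-linearization threshold
#'
#' Screens a candidate grid of thresholds (the distinct observed values of `x`
#' between its 10th and 90th percentiles) and, for each candidate `t`, fits
#' the model with hinge terms `min(x, t)` and `max(x - t, 0)`. The threshold
#' with the lowest residual deviance is returned. If no candidate improves on
#' the plain linear fit beyond numerical tolerance the relationship is deemed
#' linear and a "no threshold" flag is set.
#'
#' @param x numeric predictor with at least 10 distinct values.
#' @param y response vector (0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param tol minimum absolute deviance improvement over the linear fit for a
#'   threshold to count as real.
#' @return list with `threshold` (NA when flagged), `deviance`, `no_threshold`
#'   (logical) and `deviance_linear`.
#' @examples
#' x <- seq(0, 1, length.out = 50)
#' select_piecewise_threshold(x, 2 * x + 1, family = "gaussian")$no_threshold
#' @export
select_piecewise_threshold <- function(x, y,
                                       family = c("binomial", "gaussian"),
                                       tol = 1e-8) {
  family <- match.arg(family)
  ux <- sort(unique(x))
  if (length(ux) < 10L)
    stop("need at least 10 distinct values of x, got ", length(ux))
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  cand <- ux[ux >= q[1L] & ux <= q[2L]]
  if (length(cand) == 0L) cand <- ux[c(2L, length(ux) - 1L)]
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  dev_of <- function(xm) {
    fit <- suppressWarnings(stats::glm.fit(xm, y, family = fam))
    fit$deviance
  }
  dev_lin <- dev_of(cbind(1, x))
  devs <- vapply(cand, function(t)
    dev_of(cbind(1, pmin(x, t), pmax(x - t, 0))), numeric(1))
  best <- which.min(devs)
  scale <- max(1, abs(dev_lin))
  if (dev_lin - devs[best] <= tol * scale) {
    list(threshold = NA_real_, deviance = dev_lin, no_threshold = TRUE,
         deviance_linear = dev_lin)
  } else {
    list(threshold = cand[best], deviance = devs[best], no_threshold = FALSE,
         deviance_linear = dev_lin)
  }
}
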