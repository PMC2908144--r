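# Modelling the probability that a variable changes rank as a function of its
# spacing (in independent explained variance) along the reference ranking:
# feature construction, arcsine response transform, Spearman collinearity
# screen, candidate-set enumeration, mixed-model fits, AICc ranking with
# Akaike weights, and confidence-set model averaging with prediction curves.

# Spacing features for a vector v of IVE percentages sorted in decreasing
# (ranking) order. Boundary positions get NA.
spacing_features <- function(v) {
  k <- length(v)
  lag_diff <- function(off) {
    out <- rep(NA_real_, k)
    if (off > 0 && k > off)
      out[seq_len(k - off)] <- v[seq_len(k - off)] - v[seq_len(k - off) + off]
    out
  }
  DIFNEXT <- lag_diff(1L)
  DIFPREVIOUS <- c(NA_real_, v[-k] - v[-1L])
  DIFALL <- vapply(seq_len(k), function(i) sum(abs(v[i] - v[-i])), numeric(1))
  data.frame(
    DIFNEXT = DIFNEXT,
    DIFPREVIOUS = DIFPREVIOUS,
    DIFSECOND = lag_diff(2L),
    DIFTHIRD = lag_diff(3L),
    DIFNEXTPREVIOUS = DIFNEXT + DIFPREVIOUS,
    DIFALL = DIFALL
  )
}

#' Spacing features along the reference ranking
#'
#' Builds, for every variable, the spacing features used to explain the
#' probability of a rank change: differences in independent explained variance
#' (IVE) between the variable and its neighbours one, two and three positions
#' further down the ranking (`DIFNEXT`, `DIFSECOND`, `DIFTHIRD`), the spacing
#' to the previous variable (`DIFPREVIOUS`), their sum (`DIFNEXTPREVIOUS`),
#' the summed absolute spacing to all other variables (`DIFALL`), and the
#' number of variables in the analysis (`VARIABLES`). Boundary positions
#' (no previous / no next variable) are marked `NA`.
#'
#' @param x either an `hp_partition` or a named numeric vector of IVE
#'   percentages (one per variable, any order).
#' @param change_pct named numeric vector: percentage of permutation runs in
#'   which each variable changed rank (e.g. `100 - diag(change_matrix(ex))`).
#' @param dataset dataset identifier stored with the rows (grouping factor of
#'   the mixed model).
#' @param scale for an `hp_partition` input: `"gof_pct"` (default) uses
#'   `100 * I`, i.e. percent of the response variance for the R-squared
#'   measure; `"share"` uses the normalized `I_perc`.
#' @return data frame with one row per variable in ranking order: `dataset`,
#'   `variable`, `rank`, the six `DIF*` columns, `VARIABLES`, `change_pct`
#'   and `change_asin` (see [transform_response()]).
#' @examples
#' ive <- c(AUTOCOV4 = 10.63, FARMLAND = 5.98, DROOST = 4.82, FOREST = 4.59,
#'          DCOLONY10 = 3.71)
#' ft <- compute_features(ive, change_pct = c(AUTOCOV4 = 0, FARMLAND = 5,
#'   DROOST = 30, FOREST = 51, DCOLONY10 = 48))
#' ft$DIFPREVIOUS[ft$variable == "DCOLONY10"]  # 0.88
#' @export
compute_features <- function(x, change_pct, dataset = "dataset1",
                             scale = c("gof_pct", "share")) {
  scale <- match.arg(scale)
  if (inherits(x, "hp_partition")) {
    v <- if (scale == "gof_pct") 100 * x$I else x$I_perc
    names(v) <- x$names
  } else {
    v <- x
    if (is.null(names(v))) stop("IVE vector must be named")
  }
  k <- length(v)
  if (k < 4L)
    stop("need at least 4 variables (DIFTHIRD undefined everywhere for k < 4)")
  ord <- order(-v, names(v))
  v <- v[ord]
  if (!all(names(v) %in% names(change_pct)))
    stop("change_pct must be named for every variable")
  cp <- change_pct[names(v)]
  out <- cbind(
    data.frame(dataset = dataset, variable = names(v), rank = seq_len(k),
               stringsAsFactors = FALSE),
    spacing_features(unname(v)),
    data.frame(VARIABLES = k, change_pct = unname(cp),
               change_asin = transform_response(unname(cp)))
  )
  rownames(out) <- NULL
  out
}

#' Arcsine transform of a change percentage
#'
#' Transforms the percentage of runs with a rank change into `asin(p)` with
#' `p = change_pct / 100` (the study-literal transform). The conventional
#' variance-stabilizing `asin(sqrt(p))` is available behind a flag.
#'
#' @param change_pct percentages in `[0, 100]`.
#' @param variance_stabilizing use `asin(sqrt(p))` instead of `asin(p)`.
#' @return Transformed values in `[0, pi/2]`.
#' @examples
#' transform_response(c(0, 50, 100))  # 0, asin(0.5), pi/2
#' @export
transform_response <- function(change_pct, variance_stabilizing = FALSE) {
  p <- change_pct / 100
  if (any(p < 0 | p > 1)) stop("change_pct must lie in [0, 100]")
  if (variance_stabilizing) asin(sqrt(p)) else asin(p)
}

#' Spearman collinearity screen
#'
#' Computes Spearman rank correlations between all pairs of candidate
#' explanatory features and flags pairs with `|r_s|` above the threshold;
#' flagged pairs are never placed together in one candidate model.
#'
#' @param features a feature table from [compute_features()] (possibly several
#'   datasets row-bound together).
#' @param terms feature columns to screen; defaults to all `DIF*` columns plus
#'   `VARIABLES` present in `features`.
#' @param threshold absolute Spearman correlation above which a pair is
#'   forbidden (default 0.5).
#' @return data frame of forbidden pairs: `var1`, `var2`, `rho`. Zero rows
#'   when nothing is flagged.
#' @export
screen_collinearity <- function(features, terms = NULL, threshold = 0.5) {
  if (is.null(terms))
    terms <- intersect(c("DIFNEXT", "DIFPREVIOUS", "DIFSECOND", "DIFTHIRD",
                         "DIFNEXTPREVIOUS", "DIFALL", "VARIABLES"),
                       names(features))
  if (nrow(features) < 5L) stop("need at least 5 rows to screen")
  rho <- suppressWarnings(
    stats::cor(features[terms], method = "spearman",
               use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  data.frame(var1 = terms[pairs[, 1L]], var2 = terms[pairs[, 2L]],
             rho = rho[pairs], stringsAsFactors = FALSE)
}

#' Enumerate candidate models
#'
#' All non-empty subsets of the candidate terms that contain no forbidden pair,
#' plus the null (intercept-only) model.
#'
#' @param terms character vector of candidate fixed-effect terms.
#' @param forbidden forbidden-pair data frame from [screen_collinearity()]
#'   (columns `var1`, `var2`), or `NULL`.
#' @return list of character vectors (the null model is `character(0)`).
#' @examples
#' length(enumerate_models(c("A", "B")))  # 4
#' @export
enumerate_models <- function(terms, forbidden = NULL) {
  models <- list(character(0))
  ok <- function(tt) {
    if (is.null(forbidden) || nrow(forbidden) == 0L) return(TRUE)
    for (r in seq_len(nrow(forbidden)))
      if (forbidden$var1[r] %in% tt && forbidden$var2[r] %in% tt)
        return(FALSE)
    TRUE
  }
  for (sz in seq_along(terms)) {
    cmb <- utils::combn(terms, sz, simplify = FALSE)
    for (tt in cmb) if (ok(tt)) models[[length(models) + 1L]] <- tt
  }
  models
}

model_label <- function(terms) {
  if (length(terms) == 0L) "Null model" else paste(terms, collapse = " + ")
}

#' Fit one candidate model
#'
#' Fits a linear mixed model for the arcsine-transformed change probability
#' with the given fixed-effect terms and a random intercept per dataset,
#' by maximum likelihood (so AIC values are comparable across fixed-effect
#' structures). Rows with missing values in the used terms (boundary ranking
#' positions) are dropped for that model only. With a single dataset, or when
#' the random-intercept variance is estimated as singular, the fit falls back
#' to ordinary least squares with a warning.
#'
#' @param terms character vector of fixed-effect terms (`character(0)` for the
#'   null model).
#' @param features feature table with columns `change_asin`, `dataset` and the
#'   terms.
#' @param group name of the grouping column (default `"dataset"`).
#' @return list of class `hp_candidate_fit`: `terms`, `label`, `method`
#'   (`"lmm"` or `"ols"`), `coef`, `se`, `logLik`, `AIC`, `p` (parameter
#'   count), `n` (rows used), `fit`.
#' @export
fit_candidate <- function(terms, features, group = "dataset") {
  used <- c("change_asin", terms, group)
  d <- features[stats::complete.cases(features[used]), used, drop = FALSE]
  d[[group]] <- factor(d[[group]])
  rhs <- if (length(terms) == 0L) "1" else paste(terms, collapse = " + ")
  method <- "lmm"
  fit <- NULL
  if (nlevels(d[[group]]) < 2L) {
    warning("fewer than 2 datasets: falling back to ordinary least squares")
    method <- "ols"
  } else {
    fml <- stats::as.formula(
      paste0("change_asin ~ ", rhs, " + (1 | ", group, ")"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = d, REML = FALSE)))
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("singular random-intercept variance: ",
              "falling back to ordinary least squares")
      method <- "ols"
      fit <- NULL
    }
  }
  if (is.null(fit)) {
    fit <- stats::lm(stats::as.formula(paste0("change_asin ~ ", rhs)),
                     data = d)
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  ll <- stats::logLik(fit)
  structure(list(terms = terms, label = model_label(terms), method = method,
                 coef = cf, se = se, logLik = as.numeric(ll),
                 AIC = stats::AIC(fit), p = attr(ll, "df"), n = nrow(d),
                 fit = fit),
            class = "hp_candidate_fit")
}

#' Akaike weights from AICc values
#'
#' Computes `delta = AICc - min(AICc)`, Akaike weights
#' `w = exp(-delta/2) / sum(exp(-delta/2))`, AICc ranks, and the 95%
#' confidence-set flag (models added in decreasing weight until the cumulative
#' weight exceeds 0.95, including the crossing model).
#'
#' @param aicc numeric vector of AICc values.
#' @param level confidence-set level (default 0.95).
#' @return data frame in input order: `aicc`, `delta`, `weight`, `rank`,
#'   `in_confidence_set`.
#' @examples
#' akaike_weights(c(95.14, 99.21, 100.94))$weight
#' @export
akaike_weights <- function(aicc, level = 0.95) {
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  rk <- rank(aicc, ties.method = "first")
  ord <- order(rk)
  cum <- cumsum(w[ord])
  inset_ord <- seq_along(cum) <= which(cum >= level)[1L]
  inset <- logical(length(w))
  inset[ord] <- inset_ord
  data.frame(aicc = aicc, delta = delta, weight = w, rank = rk,
             in_confidence_set = inset)
}

#' Rank candidate models by AICc
#'
#' Applies the small-sample correction `AICc = AIC + 2p(p+1)/(n-p-1)` to each
#' fitted candidate (with its own parameter count and rows used) and ranks the
#' set by AICc, attaching Akaike weights and the 95% confidence-set flag.
#'
#' @param fits list of `hp_candidate_fit` objects from [fit_candidate()].
#' @param level confidence-set level (default 0.95).
#' @return Object of class `model_set_ranking`: a data frame (ordered by AICc)
#'   with `model`, `AIC`, `p`, `n`, `AICc`, `delta`, `weight`, `rank`,
#'   `in_confidence_set`, and attribute `fits` (reordered to match).
#' @export
rank_models <- function(fits, level = 0.95) {
  stopifnot(length(fits) >= 1L)
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  p <- vapply(fits, `[[`, numeric(1), "p")
  n <- vapply(fits, `[[`, numeric(1), "n")
  if (any(n - p - 1 <= 0))
    stop("AICc undefined: n - p - 1 <= 0 for model(s) ",
         paste(which(n - p - 1 <= 0), collapse = ", "))
  aicc <- aic + 2 * p * (p + 1) / (n - p - 1)
  aw <- akaike_weights(aicc, level = level)
  out <- data.frame(model = vapply(fits, `[[`, character(1), "label"),
                    AIC = aic, p = p, n = n, AICc = aicc,
                    delta = aw$delta, weight = aw$weight, rank = aw$rank,
                    in_confidence_set = aw$in_confidence_set,
                    stringsAsFactors = FALSE)
  ord <- order(out$rank)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits[ord]
  class(out) <- c("model_set_ranking", "data.frame")
  out
}

#' Average the models in the confidence set
#'
#' Shrinkage model averaging over the 95% confidence set: weights are
#' renormalized within the set, a term absent from a model contributes a zero
#' coefficient, and unconditional standard errors follow the usual
#' information-theoretic formula
#' `SE = sum_m w_m * sqrt(se_m^2 + (b_m - b_avg)^2)`.
#' When the best model alone carries weight >= the level, the average reduces
#' to that model.
#'
#' @param ranking a `model_set_ranking` from [rank_models()].
#' @return Object of class `averaged_model`: list with `coefficients` (data
#'   frame `term`, `estimate`, `se`), `weights` (renormalized, named by model
#'   label) and `terms`.
#' @export
average_models <- function(ranking) {
  stopifnot(inherits(ranking, "model_set_ranking"))
  fits <- attr(ranking, "fits")
  sel <- which(ranking$in_confidence_set)
  w <- ranking$weight[sel]
  w <- w / sum(w)
  fits <- fits[sel]
  terms <- unique(unlist(lapply(fits, function(f) names(f$coef))))
  est <- se <- setNames(numeric(length(terms)), terms)
  B <- S <- matrix(0, length(fits), length(terms),
                   dimnames = list(NULL, terms))
  for (m in seq_along(fits)) {
    B[m, names(fits[[m]]$coef)] <- fits[[m]]$coef
    S[m, names(fits[[m]]$coef)] <- fits[[m]]$se
  }
  est <- drop(w %*% B)
  for (j in seq_along(terms))
    se[j] <- sum(w * sqrt(S[, j]^2 + (B[, j] - est[j])^2))
  structure(list(
    coefficients = data.frame(term = terms, estimate = unname(est),
                              se = unname(se), stringsAsFactors = FALSE),
    weights = setNames(w, ranking$model[sel]),
    terms = setdiff(terms, "(Intercept)")),
    class = "averaged_model")
}

#' @export
print.averaged_model <- function(x, ...) {
  cat("Averaged model over", length(x$weights), "model(s):",
      paste(names(x$weights), collapse = "; "), "\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' Predict from an averaged model
#'
#' Evaluates the averaged linear predictor on new data and, on the response
#' scale, back-transforms through the inverse of the arcsine transform
#' (clamping the linear predictor to `[0, pi/2]`, so predicted change
#' probabilities always lie in `[0, 100]`). Standard errors combine the
#' unconditional coefficient SEs assuming independent coefficient errors —
#' an approximation adequate for the plotted error bands.
#'
#' @param object an `averaged_model`.
#' @param newdata data frame containing every term of the averaged model.
#' @param scale `"response"` (percentage, back-transformed) or `"link"`
#'   (arcsine scale).
#' @param variance_stabilizing must match the flag used in
#'   [transform_response()] when the response was built.
#' @param ... unused.
#' @return data frame `fit`, `se`, `lwr`, `upr` (on the requested scale;
#'   `lwr`/`upr` are `fit` plus/minus one SE, transformed).
#' @export
predict.averaged_model <- function(object, newdata,
                                   scale = c("response", "link"),
                                   variance_stabilizing = FALSE, ...) {
  scale <- match.arg(scale)
  terms <- object$terms
  missing <- setdiff(terms, names(newdata))
  if (length(missing))
    stop("newdata lacks term(s): ", paste(missing, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(newdata[, terms, drop = FALSE]))
  cf <- setNames(object$coefficients$estimate, object$coefficients$term)
  se <- setNames(object$coefficients$se, object$coefficients$term)
  cols <- colnames(X)
  eta <- drop(X %*% cf[cols])
  se_eta <- sqrt(drop((X^2) %*% (se[cols]^2)))
  if (scale == "link")
    return(data.frame(fit = eta, se = se_eta,
                      lwr = eta - se_eta, upr = eta + se_eta))
  back <- function(e) {
    e <- pmin(pmax(e, 0), pi / 2)
    p <- if (variance_stabilizing) sin(e)^2 else sin(e)
    100 * p
  }
  data.frame(fit = back(eta), se = se_eta,
             lwr = back(eta - se_eta), upr = back(eta + se_eta))
}

#' Prediction curve over a feature grid
#'
#' Expands a named list of term values into a grid and evaluates the averaged
#' model on it (response scale), producing the data behind a
#' change-probability curve with one-SE bands.
#'
#' @param object an `averaged_model`.
#' @param values named list giving the grid values of every averaged term,
#'   e.g. `list(DIFPREVIOUS = seq(0, 20, 0.5), VARIABLES = c(10, 11, 12))`.
#' @param variance_stabilizing see [predict.averaged_model()].
#' @return data frame: the grid columns plus `fit`, `se`, `lwr`, `upr`
#'   (percentages).
#' @export
prediction_curve <- function(object, values, variance_stabilizing = FALSE) {
  stopifnot(inherits(object, "averaged_model"))
  missing <- setdiff(object$terms, names(values))
  if (length(missing))
    stop("values lacks term(s): ", paste(missing, collapse = ", "))
  grid <- expand.grid(values, KEEP.OUT.ATTRS = FALSE)
  cbind(grid, predict(object, grid, scale = "response",
                      variance_stabilizing = variance_stabilizing))
}

#' Simulate a feature table with a known spacing effect
#'
#' Generates the kind of feature table the rank-change model is fitted to,
#' with a known ground truth: per dataset, a decreasing IVE profile is drawn
#' (exponential spacings scaled to a realistic total), and the arcsine-scale
#' change probability is `beta0 + beta_dif * DIFPREVIOUS` plus a dataset
#' random intercept and residual noise, clamped to `[0, pi/2]`. Used for
#' parameter-recovery checks of the model-selection and averaging machinery.
#'
#' @param k_values number of variables per dataset (one dataset per entry).
#' @param beta0 intercept on the arcsine scale (default `asin(0.9)`: a 90%
#'   change probability at zero spacing).
#' @param beta_dif true `DIFPREVIOUS` slope on the arcsine scale (default
#'   -0.085, i.e. roughly 3.7 percentage points per IVE unit near the
#'   intercept).
#' @param sd_dataset SD of the dataset random intercept.
#' @param sd_resid residual SD.
#' @param total_ive range of the summed IVE percentage per dataset.
#' @param seed integer seed.
#' @return A feature table as from [compute_features()], rows for all
#'   datasets, with attribute `truth = c(beta0, beta_dif)`.
#' @export
simulate_feature_table <- function(k_values = c(10L, 11L, 12L, 11L, 12L),
                                   beta0 = asin(0.9), beta_dif = -0.085,
                                   sd_dataset = 0.1, sd_resid = 0.15,
                                   total_ive = c(40, 70), seed = 1L) {
  set.seed(seed)
  rows <- vector("list", length(k_values))
  for (d in seq_along(k_values)) {
    k <- k_values[d]
    tot <- stats::runif(1L, total_ive[1L], total_ive[2L])
    v <- sort(stats::rexp(k), decreasing = TRUE)
    v <- tot * v / sum(v)
    names(v) <- sprintf("V%02d", seq_len(k))
    sf <- spacing_features(unname(v))
    b_d <- stats::rnorm(1L, 0, sd_dataset)
    eta <- beta0 + beta_dif * ifelse(is.na(sf$DIFPREVIOUS), 0,
                                     sf$DIFPREVIOUS) +
      b_d + stats::rnorm(k, 0, sd_resid)
    eta <- pmin(pmax(eta, 0), pi / 2)
    rows[[d]] <- cbind(
      data.frame(dataset = paste0("dataset", d), variable = names(v),
                 rank = seq_len(k), stringsAsFactors = FALSE),
      sf,
      data.frame(VARIABLES = k, change_pct = 100 * sin(eta),
                 change_asin = eta))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- c(beta0 = beta0, beta_dif = beta_dif)
  out
}
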