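# Shared fixtures: printed reference values and small hand-built objects.

# AICc column of the published candidate-model ranking (arithmetic fixture).
table2_aicc <- c(95.14, 99.21, 100.94, 106.92, 113.09, 119.74, 129.67, 133.69)
table2_models <- c("DIFPREVIOUS", "DIFPREVIOUS + VARIABLES",
                   "DIFPREVIOUS + DIFALL", "DIFPREVIOUS + VARIABLES + DIFALL",
                   "DIFALL", "VARIABLES + DIFALL", "Null model", "VARIABLES")

# Independent explained variance (percent) per variable, reference order.
kestrel_ive <- c(AUTOCOV4 = 10.63, BUILDUP = 1.75, DCOLONY10 = 3.71,
                 DROOST = 4.82, EDGE = 1.36, EFFORT = 2.37, FARMLAND = 5.98,
                 FOREST = 4.59, GRASSLAND = 1.30, SHANDIVER = 2.68,
                 WIRE = 2.13)
vulture_ive <- c(COWS = 2.49, ELEVATION = 8.94, HEIGHT = 1.45, LENGTH = 2.74,
                 LIVESTOCK = 1.67, NEIGHBOUR = 2.44, PASTURE = 2.74,
                 PATCH = 5.34, ROAD = 3.67, SHEEP = 0.37, SHRUB = 6.32,
                 SLOPE = 2.09)

make_partition <- function(I, names = base::names(I)) {
  structure(list(names = names, I = unname(I), J = rep(0, length(I)),
                 T = unname(I), I_perc = 100 * unname(I) / sum(I),
                 gof_full = sum(I), gof_null = 0,
                 spec = gof_spec("rsqu", "gaussian")),
            class = "hp_partition")
}

make_ranking <- function(order) {
  positions <- stats::setNames(seq_along(order), order)
  structure(list(order = order, positions = positions[sort(order)][order]),
            class = "hp_ranking")
}

# hp_ranking with positions indexed by variable name (any name order works
# because downstream code always subsets by name).
ranking_from_order <- function(order) {
  structure(list(order = order,
                 positions = stats::setNames(seq_along(order), order)),
            class = "hp_ranking")
}

fake_experiment <- function(reference_order, run_orders) {
  runs <- lapply(run_orders, function(o) list(ranking = ranking_from_order(o)))
  structure(list(reference_ranking = ranking_from_order(reference_order),
                 runs = runs, R = length(run_orders)),
            class = "hp_perm_experiment")
}

fake_fit <- function(label, coef, se, AIC, p, n) {
  structure(list(terms = setdiff(names(coef), "(Intercept)"), label = label,
                 method = "ols", coef = coef, se = se,
                 logLik = -(AIC - 2 * p) / 2, AIC = AIC, p = p, n = n,
                 fit = NULL),
            class = "hp_candidate_fit")
}

# Engine double that perturbs contributions by column position, so results
# depend on predictor order (used to exercise the audit's counting machinery).
order_sensitive_engine <- function(eps = 0.05) {
  function(d) {
    p <- hier_part(d)
    pos <- match(p$names, d$names)
    p$I <- p$I + eps * pos
    p$I_perc <- 100 * p$I / sum(p$I)
    p$J <- p$T - p$I
    p
  }
}
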