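#' Assemble a dataset for hierarchical partitioning
#'
#' Bundles a response vector and a predictor matrix into a validated object.
#' Predictor columns are kept in the order supplied, but the canonical
#' (alphabetical) name order is recorded: all partitioning is performed in
#' canonical order, which is what guarantees that results do not depend on the
#' order in which columns arrive.
#'
#' @param response numeric response vector; for `family = "binomial"` it must
#'   be coded 0/1.
#' @param predictors numeric matrix (or data frame) of predictors, one column
#'   per variable.
#' @param names character vector of unique predictor names; defaults to the
#'   column names of `predictors`.
#' @param family error family of the models to be fitted: `"gaussian"`,
#'   `"binomial"` or `"poisson"`.
#' @param response_name label for the response column (used when writing).
#' @return An object of class `hp_data`: a list with elements `response`,
#'   `predictors` (numeric matrix with column names), `names`, `family`,
#'   `response_name` and `canonical_order` (the alphabetical permutation).
#' @examples
#' d <- hp_data(rnorm(30), matrix(rnorm(90), 30, 3), names = c("b", "a", "c"))
#' d$names[d$canonical_order]
#' @export
hp_data <- function(response, predictors, names = colnames(predictors),
                    family = c("gaussian", "binomial", "poisson"),
                    response_name = "Y") {
  family <- match.arg(family)
  predictors <- as.matrix(predictors)
  storage.mode(predictors) <- "double"
  n <- length(response)
  k <- ncol(predictors)
  if (nrow(predictors) != n)
    stop("response length (", n, ") does not match predictor rows (",
         nrow(predictors), ")")
  if (is.null(names)) names <- paste0("X", seq_len(k))
  names <- as.character(names)
  if (length(names) != k) stop("need exactly one name per predictor column")
  if (anyDuplicated(names))
    stop("duplicate predictor names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  if (anyNA(response) || anyNA(predictors))
    stop("missing values are not supported; impute or drop rows first")
  if (family == "gaussian" && n < k + 2)
    stop("gaussian least squares needs n >= k + 2 (n = ", n, ", k = ", k, ")")
  if (family == "binomial" && !all(response %in% c(0, 1)))
    stop("binomial family requires a 0/1 response")
  if (family == "poisson" && any(response < 0))
    stop("poisson family requires a non-negative response")
  colnames(predictors) <- names
  structure(
    list(response = as.numeric(response), predictors = predictors,
         names = names, family = family, response_name = response_name,
         canonical_order = order(names)),
    class = "hp_data"
  )
}

#' @export
print.hp_data <- function(x, ...) {
  cat("hp_data: n =", length(x$response), ", k =", length(x$names),
      ", family =", x$family, "\n")
  cat("predictors:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a dataset from CSV
#'
#' Reads a header-row CSV, selects the response column by name, validates the
#' remaining columns as predictors and records the canonical alphabetical
#' name order.
#'
#' @param path path to a CSV file with a header row of unique variable names.
#' @param response name of the response column.
#' @param family model family passed on to [hp_data()].
#' @return An [hp_data()] object.
#' @export
read_hp_data <- function(path, response,
                         family = c("gaussian", "binomial", "poisson")) {
  family <- match.arg(family)
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  if (anyDuplicated(nm))
    stop("duplicate column names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!response %in% nm)
    stop("response column '", response, "' not found in ", path)
  if (anyNA(df)) {
    idx <- which(is.na(df), arr.ind = TRUE)
    cells <- apply(idx, 1L, function(z)
      paste0("row ", z[1L], ", column '", nm[z[2L]], "'"))
    stop("missing values in ", path, ": ",
         paste(utils::head(cells, 10L), collapse = "; "))
  }
  pred <- df[, setdiff(nm, response), drop = FALSE]
  hp_data(df[[response]], as.matrix(pred), names = setdiff(nm, response),
          family = family, response_name = response)
}

#' Write a dataset to CSV
#'
#' Inverse of [read_hp_data()]: writes the response (first column) and
#' predictors with a header row, so datasets round-trip without loss.
#'
#' @param data an [hp_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hp_data <- function(data, path) {
  stopifnot(inherits(data, "hp_data"))
  df <- data.frame(data$response, data$predictors, check.names = FALSE)
  names(df)[1L] <- data$response_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Reorder predictor columns; names travel with their columns.
permute_predictors <- function(data, perm) {
  stopifnot(inherits(data, "hp_data"))
  hp_data(data$response, data$predictors[, perm, drop = FALSE],
          names = data$names[perm], family = data$family,
          response_name = data$response_name)
}
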