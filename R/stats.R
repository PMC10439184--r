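#' Between-sample distance from an abundance matrix
#'
#' Bray--Curtis (default) or Euclidean distances between water samples
#' from a non-negative abundance matrix (samples in rows, groups/taxa in
#' columns). By convention, under Bray--Curtis an all-zero sample is at
#' distance 1 from any sample with signal and at distance 0 from another
#' all-zero sample.
#'
#' @param mat non-negative numeric matrix, rownames are sample labels.
#' @param metric `"bray_curtis"` or `"euclidean"`.
#' @return a `dist` object with sample labels.
#' @export
abundance_distance <- function(mat, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  if (nrow(mat) < 3) stop("at least 3 samples are required")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("S", seq_len(nrow(mat)))
  if (metric == "euclidean") return(stats::dist(mat))
  d <- withCallingHandlers(
    vegan::vegdist(mat, method = "bray"),
    warning = function(w) {
      # empty rows are handled below by the documented convention
      if (grepl("empty rows|missing values in results",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  # double-zero pairs are NaN in vegan; fix to 0 per the stated convention
  v <- as.matrix(d)
  zero <- rowSums(mat) == 0
  v[zero, zero] <- 0
  diag(v) <- 0
  stats::as.dist(v)
}

#' Environmental distance on standardized variables
#'
#' Euclidean distance between samples on the chosen environmental
#' variables, each z-scored across samples (mean 0, SD 1) so that
#' variables on different scales contribute equally. Zero-variance
#' variables are dropped with a warning.
#'
#' @param env data.frame of environmental records; rownames or a
#'   `water_sample_id` column label the samples.
#' @param variables character vector of column names to use; default all
#'   numeric columns.
#' @param standardize z-score each variable first (default `TRUE`).
#' @return a `dist` object.
#' @export
env_distance <- function(env, variables = NULL, standardize = TRUE) {
  if ("water_sample_id" %in% names(env)) {
    rownames(env) <- env$water_sample_id
    env$water_sample_id <- NULL
  }
  if (is.null(variables)) {
    variables <- names(env)[vapply(env, is.numeric, logical(1))]
  }
  missing_vars <- setdiff(variables, names(env))
  if (length(missing_vars) > 0) {
    stop("unknown environmental variable(s): ",
         paste(missing_vars, collapse = ", "))
  }
  m <- as.matrix(env[, variables, drop = FALSE])
  if (nrow(m) < 3) stop("at least 3 samples are required")
  if (anyNA(m)) stop("environmental variables contain missing values")
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning("dropping zero-variance variable(s): ",
              paste(colnames(m)[sds == 0], collapse = ", "))
      m <- m[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (ncol(m) == 0) stop("no variable with positive variance")
    m <- scale(m)
  }
  stats::dist(m)
}

check_dist_pair <- function(dx, dy) {
  if (!inherits(dx, "dist") || !inherits(dy, "dist")) {
    stop("distance inputs must be 'dist' objects")
  }
  if (attr(dx, "Size") != attr(dy, "Size")) {
    stop("distance matrices differ in size")
  }
  lx <- attr(dx, "Labels"); ly <- attr(dy, "Labels")
  if (!is.null(lx) && !is.null(ly) && !identical(lx, ly)) {
    stop("distance matrices must share the same labels in the same order")
  }
  if (attr(dx, "Size") < 4) stop("at least 4 samples are required")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    block <- cbind(i, ifelse(sub >= i, sub + 1L, sub))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Mantel permutation test
#'
#' Correlation between two distance matrices: Mantel's r is the Pearson
#' correlation of the lower-triangle vectors, and significance comes from
#' permuting the row/column order of `dy` jointly. The p-value is
#' one-tailed for positive association and uses the add-one correction,
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`, so p is never
#' zero. With `exhaustive = TRUE` all `n!` relabelings are enumerated and
#' `p` is the exact fraction with `r_perm >= r_obs` (the identity included).
#'
#' @param dx,dy `dist` objects over the same samples in the same order.
#' @param n_permutations number of random permutations (ignored when
#'   `exhaustive`).
#' @param seed integer seed for the permutation generator; `NULL` leaves
#'   the RNG state alone.
#' @param exhaustive enumerate all relabelings (requires `n <= 8`).
#' @return object of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `partial`, `exhaustive`, `seed`.
#' @export
mantel_test <- function(dx, dy, n_permutations = 999, seed = NULL,
                        exhaustive = FALSE) {
  check_dist_pair(dx, dy)
  xv <- as.vector(dx)
  M <- as.matrix(dy)
  n <- attr(dx, "Size")
  lt <- lower.tri(M)
  yv <- M[lt]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in a distance matrix; Mantel r is undefined")
  }
  r_obs <- stats::cor(xv, yv)
  eps <- 1e-12
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(p) stats::cor(xv, M[p, p][lt]))
    p_value <- mean(rs >= r_obs - eps)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (i in seq_len(n_permutations)) {
      p <- sample.int(n)
      if (stats::cor(xv, M[p, p][lt]) >= r_obs - eps) count <- count + 1L
    }
    p_value <- (1 + count) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, p_value = p_value, n_permutations = n_used,
                 partial = FALSE, exhaustive = exhaustive,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "mantel_result")
}

#' Partial Mantel permutation test
#'
#' Correlation between `dx` and `dy` controlling for `dz`: Mantel's
#' partial r is the Pearson correlation of the residuals of the two
#' triangle vectors after simple linear regression on the `dz` triangle
#' vector. Permutations relabel `dy` (jointly over rows and columns) and
#' recompute the partial statistic; the p-value is one-tailed with the
#' add-one correction as in [mantel_test].
#'
#' @inheritParams mantel_test
#' @param dz `dist` object to control for.
#' @return object of class `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(dx, dy, dz, n_permutations = 999,
                                seed = NULL, exhaustive = FALSE) {
  check_dist_pair(dx, dy)
  check_dist_pair(dx, dz)
  xv <- as.vector(dx)
  zv <- as.vector(dz)
  M <- as.matrix(dy)
  n <- attr(dx, "Size")
  lt <- lower.tri(M)
  yv <- M[lt]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0 || stats::sd(zv) == 0) {
    stop("zero variance in a distance matrix; partial Mantel r is undefined")
  }
  if (abs(stats::cor(yv, zv)) > 1 - 1e-12) {
    stop("dy and dz triangle vectors are collinear")
  }
  rx <- stats::resid(stats::lm(xv ~ zv))
  partial_r <- function(y) stats::cor(rx, stats::resid(stats::lm(y ~ zv)))
  r_obs <- partial_r(yv)
  eps <- 1e-12
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration is limited to n <= 8")
    perms <- all_permutations(n)
    rs <- apply(perms, 1, function(p) partial_r(M[p, p][lt]))
    p_value <- mean(rs >= r_obs - eps)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (i in seq_len(n_permutations)) {
      p <- sample.int(n)
      if (partial_r(M[p, p][lt]) >= r_obs - eps) count <- count + 1L
    }
    p_value <- (1 + count) / (1 + n_permutations)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, p_value = p_value, n_permutations = n_used,
                 partial = TRUE, exhaustive = exhaustive,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(if (x$partial) "Partial Mantel test" else "Mantel test",
      if (x$exhaustive) "(exhaustive)" else "", "\n")
  cat(sprintf("  r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}

#' Linear correlation between PPR expression and source-taxon abundance
#'
#' Ordinary least-squares fit of per-sample PPR transcript abundance on the
#' relative abundance of the source taxon, with the Pearson correlation
#' coefficient and its square (the R-squared reported in expression-vs-
#' abundance panels).
#'
#' @param x relative abundance of a taxon per sample.
#' @param y PPR TPM of that taxon per sample, same order.
#' @return list: `pearson_r`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
expression_abundance_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired samples are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation is undefined")
  }
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  list(pearson_r = r, r_squared = r^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x))
}
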