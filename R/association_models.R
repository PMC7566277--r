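# Standardized regression of reactor performance on environment (ENV),
# diversity (DIV) and community-composition (COM) predictor groups, with
# exhaustive AIC subset selection, plus distance-based redundancy analysis
# of community composition on the environmental variables.

#' Z-score standardization of a predictor matrix
#'
#' Centres each column to mean 0 and scales it to (sample) standard
#' deviation 1.
#'
#' @param variables numeric matrix or data frame.
#' @return standardized matrix.
#' @export
standardize <- function(variables) {
  m <- as.matrix(variables)
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(m)[zero] %||% which(zero), collapse = ", "),
         call. = FALSE)
  scale(m)[, , drop = FALSE]
}

# Gaussian AIC on the n*log(RSS/n) scale, counting p slopes, the intercept
# and sigma^2: AIC = n log(RSS/n) + 2 (p + 2). Only differences within a
# run are meaningful.
aic_rss <- function(n, rss, p) n * log(rss / n) + 2 * (p + 2)

#' Fit a standardized multiple regression
#'
#' Ordinary least squares of a (standardized) response on standardized
#' predictors with an intercept. Reports standardized coefficients,
#' adjusted R-squared, Gaussian AIC and two-sided coefficient t-tests.
#'
#' @param response numeric response vector.
#' @param predictors numeric matrix (columns named).
#' @param standardized if `FALSE`, inputs are z-scored first.
#' @return object of class `perf_model`.
#' @export
fit_standardized_ols <- function(response, predictors, standardized = TRUE) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(response)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop("need at least p + 2 observations", call. = FALSE)
  if (!standardized) {
    X <- standardize(X)
    y <- as.vector(standardize(matrix(y, dimnames = list(NULL, "y"))))
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    dropped <- qrX$pivot[(qrX$rank + 1):(p + 1)]
    dep <- colnames(X)[dropped[dropped > 1] - 1]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(predictor_names = colnames(X),
         coefficients = stats::coef(fit)[-1],
         intercept = stats::coef(fit)[1],
         r2 = sm$r.squared,
         adjusted_r2 = sm$adj.r.squared,
         aic = aic_rss(n, rss, p),
         p_values = sm$coefficients[-1, 4],
         overall_p = if (p > 0) stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                          sm$fstatistic[3],
                                          lower.tail = FALSE) else NA_real_,
         n = n, rss = rss, lm = fit),
    class = "perf_model"
  )
}

#' @export
print.perf_model <- function(x, ...) {
  cat("Standardized regression (", x$n, " obs, ",
      length(x$predictor_names), " predictors)\n", sep = "")
  cat(sprintf("  adjusted R^2 = %.3f, AIC = %.2f\n", x$adjusted_r2, x$aic))
  stars <- ifelse(x$p_values < 0.001, "***",
                  ifelse(x$p_values < 0.01, "**",
                         ifelse(x$p_values < 0.05, "*", "")))
  for (i in seq_along(x$coefficients))
    cat(sprintf("  %-14s beta = %+.3f  p = %.4f %s\n",
                x$predictor_names[i], x$coefficients[i], x$p_values[i],
                stars[i]))
  invisible(x)
}

#' @export
summary.perf_model <- function(object, ...) summary(object$lm, ...)

#' @export
coef.perf_model <- function(object, ...) object$coefficients

#' @export
predict.perf_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  nd <- as.data.frame(newdata)[, object$predictor_names, drop = FALSE]
  stats::predict(object$lm, newdata = nd, ...)
}

#' @export
residuals.perf_model <- function(object, ...) stats::residuals(object$lm)

#' Exhaustive best-subset selection by AIC
#'
#' Enumerates every non-empty subset of the predictor pool (smallest
#' subsets first, then by position of the first predictor, so AIC ties
#' resolve to the earlier-listed, more parsimonious model), fits each by
#' OLS, and returns the minimum-AIC model. Rank-deficient subsets are
#' skipped.
#'
#' @param response numeric response vector (standardized).
#' @param predictor_pool named standardized matrix, at most 15 columns.
#' @param groups optional named list mapping group labels (e.g. ENV, DIV,
#'   COM) to predictor names; the winner's group composition is reported.
#' @return a `perf_model` with extra fields `winner_groups` and
#'   `aic_table` (subset, AIC, adjusted R^2 for every candidate).
#' @export
best_subset_aic <- function(response, predictor_pool, groups = NULL) {
  X <- as.matrix(predictor_pool)
  p <- ncol(X)
  if (p == 0L) stop("empty predictor pool", call. = FALSE)
  if (p > 15L) stop("pool too large for exhaustive search (> 15)", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  y <- as.numeric(response)
  n <- length(y)
  subsets <- unlist(lapply(seq_len(p), function(sz)
    utils::combn(p, sz, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(idx) {
    Xi <- cbind(1, X[, idx, drop = FALSE])
    q <- qr(Xi)
    if (q$rank < ncol(Xi)) return(NULL)
    res <- stats::lm.fit(Xi, y)$residuals
    rss <- sum(res^2)
    k <- length(idx)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    data.frame(subset = paste(colnames(X)[idx], collapse = "+"),
               size = k, aic = aic_rss(n, rss, k),
               adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1))
  })
  keep <- !vapply(rows, is.null, logical(1))
  tab <- do.call(rbind, rows[keep])
  subsets <- subsets[keep]
  best_i <- which.min(tab$aic)
  idx <- subsets[[best_i]]
  model <- fit_standardized_ols(y, X[, idx, drop = FALSE])
  model$aic_table <- tab
  model$winner_groups <- if (!is.null(groups)) {
    names(groups)[vapply(groups, function(g)
      any(colnames(X)[idx] %in% g), logical(1))]
  } else NULL
  model
}

#' Performance-model comparison table over predictor-group combinations
#'
#' Builds the standard model-comparison table: for each combination of the
#' ENV (temperature, pH, DO), DIV (richness, Shannon, Pielou) and COM
#' (NMDS1-3) groups, the best AIC subset drawn from that combination's
#' pooled predictors is reported with its adjusted R-squared and
#' standardized coefficients.
#'
#' @param response performance index (e.g. smoothed N2/npNO3- ratio),
#'   standardized internally.
#' @param env,div,com data frames / matrices of the three predictor groups
#'   (same rows as `response`).
#' @return list with `table` (data frame: model, predictors, adjusted_r2,
#'   aic) and `models` (named list of `perf_model`s).
#' @export
performance_model_table <- function(response, env, div, com) {
  blocks <- list(ENV = as.matrix(env), DIV = as.matrix(div),
                 COM = as.matrix(com))
  ok <- stats::complete.cases(cbind(response, do.call(cbind, blocks)))
  y <- as.vector(standardize(matrix(response[ok], ncol = 1,
                                    dimnames = list(NULL, "y"))))
  blocks <- lapply(blocks, function(b) standardize(b[ok, , drop = FALSE]))
  combos <- list("ENV", "DIV", "COM", c("ENV", "DIV"), c("ENV", "COM"),
                 c("DIV", "COM"), c("ENV", "DIV", "COM"))
  models <- list()
  rows <- list()
  for (cmb in combos) {
    pool <- do.call(cbind, blocks[cmb])
    groups <- lapply(blocks[cmb], colnames)
    m <- best_subset_aic(y, pool, groups = groups)
    label <- paste(cmb, collapse = "+")
    models[[label]] <- m
    rows[[label]] <- data.frame(
      model = label,
      predictors = paste(m$predictor_names, collapse = "+"),
      adjusted_r2 = m$adjusted_r2, aic = m$aic,
      stringsAsFactors = FALSE
    )
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       models = models)
}

#' Genus-abundance performance models
#'
#' Single-genus standardized regressions of the performance index on each
#' dominant genus' relative abundance, plus the best AIC multi-genus
#' subset.
#'
#' @param response performance index.
#' @param genus_abundance samples x genera relative-abundance matrix (the
#'   dominant genera).
#' @return list with `table` (data frame: genus rows with adjusted R^2 and
#'   p, plus a `multivariate` row) and `best` (the multi-genus
#'   `perf_model`).
#' @export
genus_model_table <- function(response, genus_abundance) {
  G <- as.matrix(genus_abundance)
  ok <- stats::complete.cases(cbind(response, G))
  y <- as.vector(standardize(matrix(response[ok], ncol = 1,
                                    dimnames = list(NULL, "y"))))
  G <- standardize(G[ok, , drop = FALSE])
  rows <- lapply(colnames(G), function(g) {
    m <- fit_standardized_ols(y, G[, g, drop = FALSE])
    data.frame(model = g, predictors = g, adjusted_r2 = m$adjusted_r2,
               aic = m$aic, p_value = unname(m$p_values[1]),
               stringsAsFactors = FALSE)
  })
  best <- best_subset_aic(y, G)
  rows <- c(rows, list(data.frame(
    model = "multivariate", predictors = paste(best$predictor_names,
                                               collapse = "+"),
    adjusted_r2 = best$adjusted_r2, aic = best$aic,
    p_value = unname(best$overall_p), stringsAsFactors = FALSE)))
  list(table = do.call(rbind, rows), best = best)
}

#' Distance-based redundancy analysis
#'
#' Principal-coordinates decomposition of the Gower-centred dissimilarity
#' matrix; the axes with non-negative eigenvalues are regressed on the
#' (standardized) environmental variables, and the constrained fraction is
#' constrained inertia over total non-negative inertia. An optional
#' permutation test shuffles the environment rows.
#'
#' @param dist dissimilarity matrix or `dist` (e.g. Bray-Curtis).
#' @param env environmental variable matrix / data frame (rows match
#'   samples).
#' @param permutations permutations for the significance test (0 to skip).
#' @param seed RNG seed for the permutation test.
#' @return object of class `dbrda_result`: `constrained_fraction`,
#'   `axis_scores` (constrained axes), `env_names`, `p_value`.
#' @export
dbrda_variance <- function(dist, env, permutations = 0, seed = 1L) {
  dmat <- as.matrix(stats::as.dist(dist))
  n <- nrow(dmat)
  E <- as.matrix(env)
  if (nrow(E) != n) stop("env rows must match the dissimilarity matrix",
                         call. = FALSE)
  Ez <- standardize(E)
  if (qr(Ez)$rank < ncol(Ez))
    stop("collinear environmental variables", call. = FALSE)
  # Gower double-centring of -d^2/2, eigen-decomposition, keep
  # non-negative axes scaled to sqrt(eigenvalue)
  G <- -0.5 * dmat^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))   # sequential row/col centring = Gower
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  Y <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                sum(pos))
  total <- sum(eg$values[pos])
  H <- Ez %*% solve(crossprod(Ez), t(Ez))       # projection (Ez centred)
  frac <- function(Yp) sum((H %*% Yp)^2) / total
  constrained <- frac(Y)
  p_value <- NA_real_
  if (permutations > 0) {
    stat_perm <- with_seed(seed, vapply(seq_len(permutations), function(b) {
      frac(Y[sample.int(n), , drop = FALSE])
    }, numeric(1)))
    p_value <- (sum(stat_perm >= constrained) + 1) / (permutations + 1)
  }
  fitted_Y <- H %*% Y
  sv <- svd(fitted_Y)
  nax <- min(ncol(Ez), sum(sv$d > max(sv$d) * 1e-10))
  scores <- sv$u[, seq_len(nax), drop = FALSE] %*%
    diag(sv$d[seq_len(nax)], nax)
  colnames(scores) <- paste0("dbRDA", seq_len(nax))
  structure(list(constrained_fraction = constrained, axis_scores = scores,
                 env_names = colnames(Ez), p_value = p_value),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf(
    "db-RDA: %.1f%% of community variation constrained by %s%s\n",
    100 * x$constrained_fraction, paste(x$env_names, collapse = ", "),
    if (!is.na(x$p_value)) sprintf(" (permutation p = %.3f)", x$p_value)
    else ""))
  invisible(x)
}
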