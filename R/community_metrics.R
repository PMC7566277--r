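# Succession analytics on the count table: rarefied alpha diversity,
# Bray-Curtis beta diversity, NMDS ordination, Ward + elbow staging,
# indicator taxa, and dissimilarity structure over time.

#' Rarefied alpha-diversity profile
#'
#' Subsamples every sample to equal depth without replacement, `reps`
#' times, computes richness (observed taxa), Shannon diversity
#' (`H' = -sum p_i ln p_i`, nats) and Pielou evenness (`J = H'/ln S`;
#' defined as 0 for single-taxon samples) per replicate, and averages
#' across replicates.
#'
#' @param table a [community_table()].
#' @param depth rarefaction depth; every sample must hold at least this
#'   many reads.
#' @param reps number of rarefaction replicates.
#' @param seed RNG seed.
#' @return data frame with columns `sample`, `day`, `richness`, `shannon`,
#'   `pielou`.
#' @export
rarefy_diversity <- function(table, depth = 30000, reps = 100, seed = 1L) {
  stopifnot(inherits(table, "community_table"), reps >= 1)
  tot <- rowSums(table$counts)
  low <- tot < depth
  if (any(low))
    stop("sample(s) shallower than rarefaction depth ", depth, ": ",
         paste(rownames(table$counts)[low], collapse = ", "), call. = FALSE)
  acc <- matrix(0, nrow(table$counts), 3)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      # rrarefy warns on tables whose smallest non-zero count exceeds 1,
      # which is routine for deep simulated samples
      sub <- suppressWarnings(vegan::rrarefy(table$counts, depth))
      S <- rowSums(sub > 0)
      H <- vegan::diversity(sub, index = "shannon")
      J <- ifelse(S > 1, H / log(S), 0)
      acc <- acc + cbind(S, H, J)
    }
  })
  acc <- acc / reps
  data.frame(sample = rownames(table$counts), day = table$sample_days,
             richness = acc[, 1], shannon = acc[, 2], pielou = acc[, 3],
             row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = 1 - 2 sum min(x_i, y_i) / (sum x_i + sum y_i)`; symmetric,
#' zero-diagonal, bounded in [0, 1].
#'
#' @param table a [community_table()] or a samples x taxa numeric matrix.
#' @return a `dist` object.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("sample(s) with zero total abundance: ",
         paste(rownames(m)[tot == 0], collapse = ", "), call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Global NMDS (Kruskal stress-1 with monotone regression) run from a
#' metric-scaling start plus `restarts` random starts, keeping the
#' lowest-stress configuration. The configuration is centred at the origin
#' and, when `sample_days` is supplied, each axis is sign-fixed so that its
#' correlation with sampling day is non-negative (reproducible orientation).
#'
#' @param dist a `dist` or symmetric dissimilarity matrix.
#' @param k embedding dimensions.
#' @param restarts number of random restarts beyond the metric start.
#' @param seed RNG seed for the random starts.
#' @param sample_days optional day per sample for sign-fixing.
#' @return object of class `nmds_ordination`: `points` (samples x k),
#'   `stress` (Kruskal stress-1, in [0, 1]), `k`, `converged`.
#' @export
nmds <- function(dist, k = 3, restarts = 20, seed = 1L, sample_days = NULL) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (k >= n) stop("k must be smaller than the number of samples", call. = FALSE)
  # zero-dissimilarity samples are indistinguishable: collapse them to one
  # representative before optimisation and replicate its coordinates after
  dmat <- as.matrix(d)
  group <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(group[seq_len(i - 1)] > 0 & dmat[i, seq_len(i - 1)] == 0)
    group[i] <- if (length(hit)) group[hit[1]] else max(group) + 1L
  }
  reps <- match(seq_len(max(group)), group)
  du <- stats::as.dist(dmat[reps, reps, drop = FALSE])
  nu <- length(reps)
  if (k >= nu)
    stop("k must be smaller than the number of distinct samples", call. = FALSE)
  fits <- with_seed(seed, {
    first <- vegan::monoMDS(du, k = k, model = "global")
    rest <- lapply(seq_len(restarts), function(i) {
      y0 <- matrix(stats::rnorm(nu * k), nu, k)
      vegan::monoMDS(du, y = y0, k = k, model = "global")
    })
    c(list(first), rest)
  })
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  best <- fits[[which.min(stresses)]]
  pts <- best$points[group, , drop = FALSE]
  pts <- scale(pts, center = TRUE, scale = FALSE)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  if (!is.null(sample_days)) {
    for (j in seq_len(k)) {
      r <- suppressWarnings(stats::cor(pts[, j], sample_days))
      if (!is.na(r) && r < 0) pts[, j] <- -pts[, j]
    }
  }
  rownames(pts) <- labels(d)
  structure(list(points = pts[, , drop = FALSE], stress = best$stress,
                 k = k, converged = best$converged %||% NA),
            class = "nmds_ordination")
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d samples in %d dimensions, stress-1 = %.4f\n",
              nrow(x$points), x$k, x$stress))
  invisible(x)
}

# Total within-cluster dispersion from a dissimilarity matrix for given
# labels: sum over clusters of sum_{i<j} d_ij^2 / n_c (the distance form of
# within-cluster variance).
within_dispersion <- function(dmat, labels) {
  sum(vapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) return(0)
    sum(dmat[idx, idx]^2) / 2 / length(idx)
  }, numeric(1)))
}

#' Successional stage assignment by Ward clustering with elbow selection
#'
#' Agglomerates samples with Ward linkage (`ward.D2`, i.e. Ward on squared
#' dissimilarities) on the Bray-Curtis matrix. The number of stages is the
#' `k` in `2..k_max` maximising the second difference of the total
#' within-cluster dispersion curve (the sharpest elbow); labels are
#' renumbered in order of first appearance along the sample order, so that
#' stage 1 is the earliest.
#'
#' @param dist dissimilarity matrix or `dist`.
#' @param k_max largest candidate number of stages.
#' @param k optional forced number of stages (skips elbow selection).
#' @return object of class `stage_assignment`: `k`, `labels`,
#'   `within_dispersion` (named vector over candidate k), `hclust`.
#' @export
cluster_stages <- function(dist, k_max = 8, k = NULL) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  if (is.null(k) && k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  if (k_max >= n) {
    warning("k_max reduced to n - 1")
    k_max <- n - 1L
  }
  hc <- stats::hclust(d, method = "ward.D2")
  dmat <- as.matrix(d)
  ks <- seq_len(min(k_max + 1L, n))
  W <- vapply(ks, function(kk) within_dispersion(dmat, stats::cutree(hc, kk)),
              numeric(1))
  names(W) <- ks
  if (is.null(k)) {
    cand <- ks[ks >= 2 & ks <= k_max & ks < max(ks)]
    d2 <- vapply(cand, function(kk) {
      (W[kk - 1] - W[kk]) - (W[kk] - W[kk + 1])
    }, numeric(1))
    k <- cand[which.max(d2)]
  }
  labels <- stats::cutree(hc, k)
  labels <- match(labels, unique(labels))   # renumber in time order
  structure(list(k = as.integer(k), labels = labels, within_dispersion = W,
                 hclust = hc),
            class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat("Stage assignment:", x$k, "stages over", length(x$labels), "samples\n")
  rle_ <- rle(x$labels)
  ends <- cumsum(rle_$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  cat("  blocks:", paste(sprintf("stage %d [%d-%d]", rle_$values, starts,
                                 ends), collapse = ", "), "\n")
  invisible(x)
}

#' Indicator-taxon analysis by point-biserial correlation
#'
#' For every taxon and stage, computes the Pearson correlation between the
#' taxon's relative abundance across samples and the 0/1 stage-membership
#' vector, with a permutation p-value (fraction of label shuffles with
#' `|r| >= |r_obs|`, `(count + 1)/(permutations + 1)`). Constant abundance
#' vectors get `r = 0`, `p = 1`.
#'
#' @param table a [community_table()] (converted to relative abundance) or
#'   a samples x taxa abundance matrix.
#' @param stages a [cluster_stages()] result or an integer label vector.
#' @param permutations number of label permutations.
#' @param seed RNG seed.
#' @return data frame with columns `taxon`, `stage`, `r_pb`, `p_value`.
#' @export
indicator_taxa <- function(table, stages, permutations = 999, seed = 1L) {
  A <- if (inherits(table, "community_table")) relative_abundance(table)
       else as.matrix(table)
  labels <- if (inherits(stages, "stage_assignment")) stages$labels else stages
  if (length(labels) != nrow(A))
    stop("stage labels must match samples", call. = FALSE)
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need at least 2 stages", call. = FALSE)
  n <- nrow(A)
  # column-standardize once; correlations then reduce to cross-products,
  # which keeps the permutation loop cheap for wide tables
  sds <- apply(A, 2, stats::sd)
  const <- sds == 0
  As <- scale(A)
  As[, const] <- 0
  M <- vapply(lev, function(s) as.numeric(labels == s), numeric(n))
  Ms <- scale(M)
  r_obs <- crossprod(As, Ms) / (n - 1)              # taxa x stages
  perms <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) sample.int(n), integer(n))
  })
  exceed <- matrix(0L, ncol(A), length(lev))
  for (b in seq_len(permutations)) {
    r_p <- crossprod(As, Ms[perms[, b], , drop = FALSE]) / (n - 1)
    exceed <- exceed + (abs(r_p) >= abs(r_obs) - 1e-12)
  }
  p <- (exceed + 1) / (permutations + 1)
  p[const, ] <- 1
  data.frame(
    taxon = rep(colnames(A), times = length(lev)),
    stage = rep(lev, each = ncol(A)),
    r_pb = as.vector(r_obs),
    p_value = as.vector(p),
    row.names = NULL
  )
}

#' Dissimilarity structure over time and within stages
#'
#' Summarises the pairwise dissimilarity matrix two ways: the mean
#' dissimilarity of sample pairs per sampling-day gap (rising means the
#' community keeps drifting), and the full distribution of within-stage
#' pairwise dissimilarities per stage (stage-internal variability).
#'
#' @param dist dissimilarity matrix or `dist`.
#' @param sample_days day per sample.
#' @param stages optional [cluster_stages()] result or label vector.
#' @return list with `gap_curve` (data frame: `gap`, `mean_dissimilarity`,
#'   `n_pairs`) and `stage_dispersion` (data frame: `stage`,
#'   `dissimilarity`), the latter `NULL` without stages.
#' @export
dissimilarity_structure <- function(dist, sample_days, stages = NULL) {
  dmat <- as.matrix(stats::as.dist(dist))
  n <- nrow(dmat)
  if (length(sample_days) != n)
    stop("sample_days must match the matrix", call. = FALSE)
  ij <- which(upper.tri(dmat), arr.ind = TRUE)
  gap <- abs(sample_days[ij[, 2]] - sample_days[ij[, 1]])
  val <- dmat[ij]
  agg <- stats::aggregate(val, list(gap = gap), mean)
  cnt <- stats::aggregate(val, list(gap = gap), length)
  gap_curve <- data.frame(gap = agg$gap, mean_dissimilarity = agg$x,
                          n_pairs = cnt$x)
  stage_dispersion <- NULL
  if (!is.null(stages)) {
    labels <- if (inherits(stages, "stage_assignment")) stages$labels else stages
    same <- labels[ij[, 1]] == labels[ij[, 2]]
    stage_dispersion <- data.frame(stage = labels[ij[same, 1]],
                                   dissimilarity = val[same])
    stage_dispersion <- stage_dispersion[order(stage_dispersion$stage), ,
                                         drop = FALSE]
    rownames(stage_dispersion) <- NULL
  }
  list(gap_curve = gap_curve, stage_dispersion = stage_dispersion)
}
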