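# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. All deliberately naive (double loops, direct
# formulas) and kept separate from the package's code paths.

oracle_mann_kendall <- function(x) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      S <- S + sign(x[j] - x[i])
  ties <- table(x)
  corr <- 0
  for (t in ties) if (t > 1) corr <- corr + t * (t - 1) * (2 * t + 5)
  var_S <- (n * (n - 1) * (2 * n + 5) - corr) / 18
  list(S = S, var_S = var_S)
}

oracle_sens_slope <- function(x, d) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (d[j] != d[i]) slopes <- c(slopes, (x[j] - x[i]) / (d[j] - d[i]))
  median(slopes)
}

oracle_bray_curtis <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

oracle_point_biserial <- function(abund, membership) {
  if (sd(abund) == 0) return(0)
  cor(abund, membership)
}

oracle_ols_coef <- function(y, X) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[-1]
}

# random small community table (positive totals guaranteed)
random_table <- function(n_samples, n_taxa, max_count = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_taxa, lambda = max_count / 5),
              n_samples, n_taxa)
  m[cbind(seq_len(n_samples), sample(n_taxa, n_samples, replace = TRUE))] <-
    m[cbind(seq_len(n_samples), sample(n_taxa, n_samples, replace = TRUE))] + 1
  colnames(m) <- paste0("t", seq_len(n_taxa))
  community_table(m, seq_len(n_samples))
}

# one shared succession-scenario run, computed lazily and cached for the
# whole test session
scenario_cache <- new.env()
cached_run <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(scenario_cache[[key]]))
    scenario_cache[[key]] <- simulate_scenario("succession", seed = seed)
  scenario_cache[[key]]
}

# minimal hand-built simulation object with a fixed taxon profile, for
# testing the count emitter in isolation
fake_sim <- function(p, n_samples, seed = 1) {
  taxa <- data.frame(taxon_id = names(p), genus = names(p),
                     phylum = "unclassified", guild = "HET",
                     stringsAsFactors = FALSE)
  prof <- matrix(rep(p / sum(p), each = n_samples), n_samples,
                 dimnames = list(NULL, names(p)))
  structure(
    list(taxon_profile = prof, days = seq_len(n_samples),
         true_stage = rep(1L, n_samples),
         config = list(seed = seed), schedule = NULL,
         taxon_map = list(taxa = taxa)),
    class = "reactor_sim"
  )
}
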