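# Sequencing-count emission: maps simulated guild biomass onto an
# ASV-level taxonomic profile and draws Dirichlet-multinomial read counts
# at a fixed sequencing depth.

#' Default guild-to-taxon map
#'
#' Defines the ASV inventory of the simulated reactor: each functional
#' guild is represented by one or more genera (the dominant genera of
#' low-DO nitrification/anammox reactors: Nitrosomonas for AOB, Nitrospira
#' for NOB and comammox, Candidatus Jettenia and SM1A02 for anammox, plus a
#' heterotrophic fringe of Denitratisoma, Sideroxydans, AKYH767, OLB12,
#' OLB8, Terrimonas), each genus by several ASVs. Every ASV carries a
#' weight per successional stage; within-guild weights shift across stages
#' (ecotype turnover), which is what makes community composition — not only
#' guild biomass — track succession. A tail of `n_background` rare taxa
#' with stage-skewed weights produces the rising-richness pattern of a
#' recovering reactor.
#'
#' @param n_background number of rare background taxa.
#' @return list with `taxa` (data frame: `taxon_id`, `genus`, `phylum`,
#'   `guild`) and `weights` (taxa x 3 stage-weight matrix).
#' @export
default_taxon_map <- function(n_background = 135) {
  core <- list(
    # each guild carries a stage-1, a stage-2 and a stage-3 ecotype of
    # comparable contrast, plus a few generalists
    #      genus                 phylum            guild  w1    w2    w3
    list("Nitrosomonas",         "Proteobacteria", "AOB", 1.00, 0.15, 0.05),
    list("Nitrosomonas",         "Proteobacteria", "AOB", 0.15, 1.00, 0.15),
    list("Nitrosomonas",         "Proteobacteria", "AOB", 0.05, 0.15, 1.00),
    list("Nitrosomonas",         "Proteobacteria", "AOB", 0.40, 0.40, 0.40),
    list("Nitrospira",           "Nitrospirae",    "NOB", 1.00, 0.15, 0.05),
    list("Nitrospira",           "Nitrospirae",    "NOB", 0.15, 1.00, 0.15),
    list("Nitrospira",           "Nitrospirae",    "NOB", 0.05, 0.15, 1.00),
    list("Nitrospira",           "Nitrospirae",    "NOB", 0.50, 0.50, 0.50),
    list("Nitrospira",           "Nitrospirae",    "CMX", 1.00, 0.20, 0.10),
    list("Nitrospira",           "Nitrospirae",    "CMX", 0.15, 1.00, 0.20),
    list("Nitrospira",           "Nitrospirae",    "CMX", 0.05, 0.20, 1.00),
    list("Candidatus Jettenia",  "Planctomycetes", "AMX", 1.00, 0.15, 0.05),
    list("Candidatus Jettenia",  "Planctomycetes", "AMX", 0.15, 1.00, 0.15),
    list("Candidatus Jettenia",  "Planctomycetes", "AMX", 0.05, 0.15, 1.00),
    list("Candidatus Jettenia",  "Planctomycetes", "AMX", 0.10, 0.50, 0.80),
    list("Candidatus Jettenia",  "Planctomycetes", "AMX", 0.50, 0.50, 0.50),
    list("SM1A02",               "Planctomycetes", "AMX", 1.00, 0.20, 0.05),
    list("SM1A02",               "Planctomycetes", "AMX", 0.15, 1.00, 0.20),
    list("SM1A02",               "Planctomycetes", "AMX", 0.05, 0.20, 1.00),
    list("Denitratisoma",        "Proteobacteria", "HET", 1.00, 0.20, 0.05),
    list("Denitratisoma",        "Proteobacteria", "HET", 0.80, 0.30, 0.10),
    list("Denitratisoma",        "Proteobacteria", "HET", 0.60, 0.25, 0.15),
    list("Sideroxydans",         "Proteobacteria", "HET", 1.00, 0.20, 0.05),
    list("Sideroxydans",         "Proteobacteria", "HET", 0.70, 0.25, 0.10),
    list("AKYH767",              "Bacteroidetes",  "HET", 0.05, 0.20, 1.00),
    list("AKYH767",              "Bacteroidetes",  "HET", 0.10, 0.25, 1.00),
    list("AKYH767",              "Bacteroidetes",  "HET", 0.02, 0.15, 0.80),
    list("OLB12",                "Bacteroidetes",  "HET", 0.05, 0.25, 1.00),
    list("OLB12",                "Bacteroidetes",  "HET", 0.10, 0.15, 0.90),
    list("OLB12",                "Bacteroidetes",  "HET", 0.08, 0.20, 1.00),
    list("OLB8",                 "Chloroflexi",    "HET", 0.10, 1.00, 0.60),
    list("OLB8",                 "Chloroflexi",    "HET", 0.10, 0.60, 1.00),
    list("Terrimonas",           "Bacteroidetes",  "HET", 0.15, 1.00, 0.15),
    list("Terrimonas",           "Bacteroidetes",  "HET", 0.10, 0.90, 0.25)
  )
  taxa <- data.frame(
    genus = vapply(core, `[[`, character(1), 1),
    phylum = vapply(core, `[[`, character(1), 2),
    guild = vapply(core, `[[`, character(1), 3),
    stringsAsFactors = FALSE
  )
  w <- t(vapply(core, function(x) unlist(x[4:6]), numeric(3)))

  if (n_background > 0) {
    n_early <- round(n_background * 0.22)
    n_mid <- round(n_background * 0.30)
    n_late <- n_background - n_early - n_mid
    phyla <- c("Chloroflexi", "Proteobacteria", "Bacteroidetes",
               "Acidobacteria", "Planctomycetes", "Armatimonadetes",
               "Verrucomicrobia", "Chlorobi")
    i <- seq_len(n_background)
    mag <- 0.5 + ((i * 37L) %% 100L) / 100L    # deterministic size variation
    bw <- rbind(
      matrix(rep(c(0.020, 0.004, 0.001), each = n_early), ncol = 3),
      matrix(rep(c(0.003, 0.020, 0.004), each = n_mid), ncol = 3),
      matrix(rep(c(0.001, 0.004, 0.020), each = n_late), ncol = 3)
    ) * mag
    bg <- data.frame(
      genus = sprintf("uncultured_%03d", i),
      phylum = phyla[(i - 1L) %% length(phyla) + 1L],
      guild = "HET",
      stringsAsFactors = FALSE
    )
    taxa <- rbind(taxa, bg)
    w <- rbind(w, bw)
  }
  taxa$taxon_id <- sprintf("ASV_%04d", seq_len(nrow(taxa)))
  rownames(w) <- taxa$taxon_id
  list(taxa = taxa[, c("taxon_id", "genus", "phylum", "guild")], weights = w)
}

# Relative-abundance profile (days x taxa) from guild biomass trajectories.
# Within-guild taxon weights are blended over stages with the schedule's
# logistic weights; guild shares come from total (attached + suspended)
# biomass.
build_taxon_profile <- function(taxon_map, biomass, schedule, days) {
  n <- length(days)
  wt <- if (is.null(schedule)) {
    matrix(1 / 3, n, 3)
  } else {
    stage_weights(schedule, days)
  }
  gids <- colnames(biomass)
  share <- biomass / pmax(rowSums(biomass), .Machine$double.eps)
  prof <- matrix(0, n, nrow(taxon_map$taxa),
                 dimnames = list(sprintf("d%02d", days),
                                 taxon_map$taxa$taxon_id))
  u_all <- taxon_map$weights %*% t(wt)     # taxa x days
  for (g in gids) {
    sel <- taxon_map$taxa$guild == g
    if (!any(sel)) next
    u <- u_all[sel, , drop = FALSE]
    u <- sweep(u, 2, pmax(colSums(u), .Machine$double.eps), "/")
    prof[, sel] <- t(u) * share[, g]
  }
  rs <- rowSums(prof)
  ok <- rs > 0
  prof[ok, ] <- prof[ok, , drop = FALSE] / rs[ok]
  prof
}

#' Draw sequencing counts from a simulation
#'
#' Emulates amplicon sequencing of the simulated community: per sample, the
#' expected taxon proportions are the biomass-weighted taxon profile, and
#' counts are drawn Dirichlet-multinomial with concentration
#' `dispersion * p` at fixed `depth` reads per sample
#' (`dispersion = Inf` gives pure multinomial sampling).
#'
#' @param sim a [simulate_reactor()] result (needs a taxon profile, i.e. it
#'   was run with a `taxon_map`, or pass one here).
#' @param taxon_map optional map overriding the one stored in `sim`.
#' @param depth reads per sample (>= 1).
#' @param dispersion Dirichlet concentration parameter (> 0 or `Inf`).
#' @param seed RNG seed (defaults to a sub-seed of the simulation's).
#' @return a [community_table()] with planted stages attached.
#' @export
generate_community_counts <- function(sim, taxon_map = NULL, depth = 30000,
                                      dispersion = 300, seed = NULL) {
  stopifnot(inherits(sim, "reactor_sim"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (!is.infinite(dispersion) && dispersion <= 0)
    stop("dispersion must be > 0 or Inf", call. = FALSE)
  if (is.null(taxon_map)) taxon_map <- sim$taxon_map
  if (is.null(taxon_map))
    stop("no taxon map: run simulate_reactor() with one or supply it here",
         call. = FALSE)
  prof <- sim$taxon_profile
  if (is.null(prof))
    prof <- build_taxon_profile(taxon_map, sim$guild_biomass, sim$schedule,
                                sim$days)
  if (is.null(seed)) seed <- derive_seed(sim$config$seed, "counts")
  counts <- with_seed(seed, {
    t(vapply(seq_len(nrow(prof)), function(i) {
      p <- prof[i, ]
      if (sum(p) <= 0)
        stop("degenerate profile: all-zero biomass at day ", sim$days[i],
             call. = FALSE)
      p <- p / sum(p)
      if (is.finite(dispersion)) {
        g <- numeric(length(p))
        pos <- p > 0
        g[pos] <- stats::rgamma(sum(pos), shape = dispersion * p[pos])
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      as.numeric(stats::rmultinom(1, size = depth, prob = p))
    }, numeric(ncol(prof))))
  })
  dimnames(counts) <- dimnames(prof)
  community_table(counts, sim$days, taxon_map$taxa, stages = sim$true_stage)
}
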