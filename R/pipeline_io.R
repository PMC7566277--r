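# File formats, configuration, guild annotation and the end-to-end
# pipeline runner.

#' Write / read the chemistry CSV
#'
#' Columns: `day`, `nh4_in_mgN_d`, `nh4_out_mgN_L`, `no2_out_mgN_L`,
#' `no3_out_mgN_L`, `temp_C`, `ph`, `do_mgO2_L`. Effluent species are
#' stored as concentrations; the rate basis is recovered at load time from
#' the flow.
#'
#' @param chem a [chem_series()] (rate basis).
#' @param path output file.
#' @param flow effluent flow, L/day.
#' @export
write_chemistry <- function(chem, path, flow) {
  df <- data.frame(
    day = chem$day,
    nh4_in_mgN_d = chem$influent_nh4,
    nh4_out_mgN_L = chem$effluent_nh4 / flow,
    no2_out_mgN_L = chem$effluent_no2 / flow,
    no3_out_mgN_L = chem$effluent_no3 / flow,
    temp_C = chem$temperature, ph = chem$ph, do_mgO2_L = chem$do
  )
  utils::write.csv(format(df, digits = 10, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chemistry
#' @export
read_chemistry <- function(path, flow) {
  df <- utils::read.csv(path, check.names = FALSE)
  chem_from_concentrations(df, flow)
}

#' Write / read the counts TSV (taxa rows x sample columns)
#' @param table a [community_table()].
#' @param path output file.
#' @export
write_counts <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param taxonomy_path taxonomy TSV (`taxon_id`, `genus`, `phylum`).
#' @param sample_days day per sample column; defaults to integers parsed
#'   from the column names.
#' @export
read_counts <- function(path, taxonomy_path = NULL, sample_days = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  taxa <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- taxa
  if (is.null(sample_days)) {
    sample_days <- as.integer(gsub("\\D", "", rownames(m)))
    if (any(is.na(sample_days)))
      stop("cannot parse sample days from column names; pass sample_days",
           call. = FALSE)
  }
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  community_table(m, sample_days, taxonomy)
}

#' Write / read the taxonomy TSV
#' @param taxonomy data frame with `taxon_id`, `genus`, `phylum`.
#' @param path file path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy[, c("taxon_id", "genus", "phylum")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character")
}

#' Functional guild annotation of genera
#'
#' Static lookup of the metabolic functions reported for the dominant
#' genera of autotrophic nitrogen-removal reactors. Unknown genera return
#' an empty set.
#'
#' @param genera character vector of genus names.
#' @return named list of character vectors of functional labels.
#' @export
annotate_guilds <- function(genera) {
  lookup <- list(
    "Nitrospira" = c("aerobic nitrite oxidation (NOB)",
                     "complete ammonium oxidation (comammox)"),
    "Candidatus Jettenia" = "anaerobic ammonium oxidation (anammox)",
    "Nitrosomonas" = "aerobic ammonium oxidation (AOB)",
    "SM1A02" = c("anaerobic ammonium oxidation (anammox)",
                 "candidate lineage"),
    "Denitratisoma" = "denitrification",
    "Sideroxydans" = "iron oxidation",
    "AKYH767" = "chemoheterotrophy",
    "OLB12" = "chemoheterotrophy",
    "OLB8" = "chemoheterotrophy",
    "Terrimonas" = "chemoheterotrophy"
  )
  out <- lapply(genera, function(g) lookup[[g]] %||% character(0))
  names(out) <- genera
  out
}

#' Pipeline configuration
#'
#' Either file inputs (`chemistry`, `counts`, `taxonomy` paths plus `flow`)
#' or a packaged `scenario` name must be supplied.
#'
#' @param chemistry,counts,taxonomy input file paths.
#' @param flow effluent flow (L/day) used to convert chemistry
#'   concentrations to rates.
#' @param scenario packaged scenario name (e.g. `"succession"`).
#' @param depth,reps rarefaction depth and replicate count.
#' @param nmds_k,nmds_restarts NMDS dimensions and random restarts.
#' @param k_max largest candidate stage count.
#' @param permutations permutations for indicator and db-RDA tests.
#' @param window smoothing window, days (one HRT).
#' @param seed master seed.
#' @param outdir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(chemistry = NULL, counts = NULL, taxonomy = NULL,
                            flow = 0.72, scenario = NULL, depth = 30000,
                            reps = 100, nmds_k = 3, nmds_restarts = 20,
                            k_max = 8, permutations = 999, window = 6.25,
                            seed = 1L, outdir = tempfile("pipeline_")) {
  if (is.null(scenario) && (is.null(chemistry) || is.null(counts)))
    stop("supply either input files (chemistry + counts) or a scenario",
         call. = FALSE)
  structure(list(chemistry = chemistry, counts = counts, taxonomy = taxonomy,
                 flow = flow, scenario = scenario, depth = depth, reps = reps,
                 nmds_k = nmds_k, nmds_restarts = nmds_restarts,
                 k_max = k_max, permutations = permutations, window = window,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Load and align the pipeline inputs
#'
#' Reads (or simulates) the chemistry series and the community table and
#' aligns them on the intersection of sampling days, warning when days are
#' dropped.
#'
#' @param config a [pipeline_config()].
#' @return list with `chem`, `community`, and `truth` (non-`NULL` only for
#'   simulated scenarios).
#' @export
load_inputs <- function(config) {
  truth <- NULL
  if (!is.null(config$scenario)) {
    run <- simulate_scenario(config$scenario, seed = config$seed)
    chem <- run$chem
    community <- run$community
    truth <- run$truth
  } else {
    chem <- read_chemistry(config$chemistry, config$flow)
    community <- read_counts(config$counts, config$taxonomy)
  }
  common <- intersect(chem$day, community$sample_days)
  if (length(common) == 0L)
    stop("chemistry and community sampling days do not overlap", call. = FALSE)
  if (length(common) < length(chem$day) ||
      length(common) < length(community$sample_days))
    warning("dropping ", length(chem$day) - length(common), " chemistry and ",
            length(community$sample_days) - length(common),
            " community day(s) outside the common range", call. = FALSE)
  chem <- chem[chem$day %in% common, , drop = FALSE]
  class(chem) <- c("chem_series", "data.frame")
  keep <- community$sample_days %in% common
  community <- community_table(community$counts[keep, , drop = FALSE],
                               community$sample_days[keep],
                               community$taxonomy,
                               stages = community$stages[keep])
  list(chem = chem, community = community, truth = truth)
}

#' Run the full succession/performance analysis pipeline
#'
#' Executes, in order: nitrogen partition and HRT-window smoothing,
#' rarefied diversity, Bray-Curtis dissimilarity and NMDS ordination, Ward
#' + elbow staging, indicator taxa, per-stage Mann-Kendall/Sen trend
#' statistics, genus aggregation, the ENV/DIV/COM model-comparison table
#' and the genus-abundance models, and db-RDA of composition on the
#' environment. All result tables are written as CSV under
#' `config$outdir`, together with a `run_log.txt` recording seeds; the same
#' configuration and seed yield byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with every intermediate result.
#' @export
run_full_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config)
  chem <- inputs$chem
  community <- inputs$community

  part <- partition_nitrogen(chem)
  part$ratio_smoothed <- moving_average(part$day, part$ratio, config$window)

  div <- rarefy_diversity(community, depth = config$depth, reps = config$reps,
                          seed = derive_seed(config$seed, "rarefy"))
  bc <- bray_curtis(community)
  ord <- nmds(bc, k = config$nmds_k, restarts = config$nmds_restarts,
              seed = derive_seed(config$seed, "nmds"),
              sample_days = community$sample_days)
  stages <- cluster_stages(bc, k_max = config$k_max)
  ind <- indicator_taxa(community, stages,
                        permutations = config$permutations,
                        seed = derive_seed(config$seed, "indicators"))
  diss <- dissimilarity_structure(bc, community$sample_days, stages)

  ratio_by_day <- part$ratio_smoothed[match(community$sample_days, part$day)]
  trends <- trend_by_stage(community$sample_days, ratio_by_day,
                           stages$labels)

  genus <- aggregate_taxa(community, "genus")
  rel <- relative_abundance(genus)
  top10 <- names(sort(colMeans(rel), decreasing = TRUE))[seq_len(min(10, ncol(rel)))]

  env <- data.frame(temperature = chem$temperature, ph = chem$ph,
                    do = chem$do)[match(community$sample_days, chem$day), ,
                                  drop = FALSE]
  div_block <- div[, c("richness", "shannon", "pielou")]
  com_block <- ord$points

  tab1 <- performance_model_table(ratio_by_day, env, div_block, com_block)
  tab2 <- genus_model_table(ratio_by_day, rel[, top10, drop = FALSE])
  rda <- dbrda_variance(bc, env, permutations = config$permutations,
                        seed = derive_seed(config$seed, "dbrda"))

  w <- function(df, name) utils::write.csv(
    df, file.path(config$outdir, name), row.names = FALSE)
  w(part, "partition.csv")
  w(div, "diversity.csv")
  utils::write.csv(as.matrix(bc), file.path(config$outdir, "dissimilarity.csv"))
  w(data.frame(sample = rownames(ord$points), day = community$sample_days,
               ord$points, stress = ord$stress), "ordination.csv")
  w(data.frame(sample = rownames(community$counts),
               day = community$sample_days, stage = stages$labels,
               k = stages$k), "stages.csv")
  w(ind, "indicators.csv")
  w(trends, "trends.csv")
  w(tab1$table, "models_groups.csv")
  w(tab2$table, "models_genera.csv")
  w(data.frame(constrained_fraction = rda$constrained_fraction,
               p_value = rda$p_value), "dbrda.csv")
  writeLines(c(
    "pipeline run log",
    paste0("master_seed: ", config$seed),
    paste0("sub_seeds: rarefy=", derive_seed(config$seed, "rarefy"),
           " nmds=", derive_seed(config$seed, "nmds"),
           " indicators=", derive_seed(config$seed, "indicators"),
           " dbrda=", derive_seed(config$seed, "dbrda")),
    paste0("scenario: ", config$scenario %||% "files"),
    paste0("rarefaction: depth=", config$depth, " reps=", config$reps),
    paste0("nmds: k=", config$nmds_k, " restarts=", config$nmds_restarts),
    paste0("permutations: ", config$permutations)
  ), file.path(config$outdir, "run_log.txt"))

  invisible(list(chem = chem, community = community, partition = part,
                 diversity = div, dissimilarity = bc, ordination = ord,
                 stages = stages, indicators = ind,
                 dissimilarity_structure = diss, trends = trends,
                 group_models = tab1, genus_models = tab2, dbrda = rda,
                 truth = inputs$truth, outdir = config$outdir))
}
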