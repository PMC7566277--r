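# Packaged simulation scenarios.

#' The packaged succession scenario
#'
#' Encodes the reference operating conditions of a bench-scale autotrophic
#' nitrogen-removal CSTR: 4.5 L working volume, 6.25-day hydraulic
#' retention time, 86.4 mg NH4-N/day sole nitrogen feed, ~0.2 mg/L
#' dissolved oxygen, 56 daily samples, with a whole-reactor homogenisation
#' disturbance at day 0 and a planted three-stage community succession
#' (early nitrifier bloom, unstable middle, anammox-balanced late stage;
#' stage boundaries between days 13/14 and 34/35).
#'
#' @param seed master seed of the scenario run.
#' @param depth sequencing depth (reads per sample).
#' @param dispersion Dirichlet-multinomial concentration.
#' @return list with `config`, `guilds`, `schedule`, `taxon_map`,
#'   `disturbance_day`, `mixing_fraction`, `depth`, `dispersion`.
#' @export
succession_scenario <- function(seed = 1L, depth = 35000, dispersion = 300) {
  list(
    name = "succession",
    config = reactor_config(working_volume = 4.5, hrt = 6.25,
                            influent_nh4_load = 86.4, do_setpoint = 0.2,
                            temperature = 30, ph = 7.6, duration = 56,
                            seed = seed),
    guilds = default_guilds(),
    schedule = stage_schedule(boundaries = c(13.5, 34.5), steepness = 1.5),
    taxon_map = default_taxon_map(),
    disturbance_day = 0,
    mixing_fraction = 1,
    depth = depth,
    dispersion = dispersion
  )
}

#' Run a packaged or user scenario end to end
#'
#' Simulates the reactor and emits the sequencing counts, returning
#' everything the analysis pipeline consumes plus the planted ground truth.
#'
#' @param scenario a scenario list (see [succession_scenario()]) or the
#'   scenario name `"succession"`.
#' @param seed master seed (overrides the scenario's).
#' @return list with `chem` (measured chemistry, [chem_series()]),
#'   `community` ([community_table()]), `sim` (the full `reactor_sim`),
#'   and `truth` (planted stages, noise-free chemistry, guild biomass).
#' @export
simulate_scenario <- function(scenario = "succession", seed = NULL) {
  if (is.character(scenario)) {
    scenario <- switch(scenario,
      succession = succession_scenario(seed = seed %||% 1L),
      stop("unknown scenario: ", scenario, call. = FALSE))
  } else if (!is.null(seed)) {
    scenario$config$seed <- as.integer(seed)
  }
  sim <- simulate_reactor(
    scenario$config, scenario$guilds,
    disturbance_day = scenario$disturbance_day,
    mixing_fraction = scenario$mixing_fraction %||% 1,
    schedule = scenario$schedule, noise = sim_noise_defaults(),
    taxon_map = scenario$taxon_map
  )
  community <- generate_community_counts(
    sim, depth = scenario$depth %||% 35000,
    dispersion = scenario$dispersion %||% 300
  )
  list(
    chem = sim$chem, community = community, sim = sim,
    truth = list(stages = sim$true_stage, chem = sim$true_chem,
                 guild_biomass = sim$guild_biomass, n2_rate = sim$n2_rate)
  )
}

#' Read a scenario description from YAML or JSON
#'
#' The file may carry `reactor`, `guilds`, `schedule`, `disturbance` and
#' `emission` blocks; omitted blocks fall back to the packaged succession
#' scenario defaults.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a scenario list as accepted by [simulate_scenario()].
#' @export
load_scenario <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  base <- succession_scenario()
  if (!is.null(raw$reactor))
    base$config <- do.call(reactor_config, raw$reactor)
  if (!is.null(raw$guilds))
    base$guilds <- lapply(raw$guilds, function(g) do.call(guild_params, g))
  if (!is.null(raw$schedule))
    base$schedule <- stage_schedule(
      boundaries = raw$schedule$boundaries %||% c(13.5, 34.5),
      steepness = raw$schedule$steepness %||% 1.5,
      multipliers = if (!is.null(raw$schedule$multipliers))
        do.call(rbind, raw$schedule$multipliers) else NULL
    )
  if (!is.null(raw$disturbance)) {
    base$disturbance_day <- raw$disturbance$day %||% 0
    base$mixing_fraction <- raw$disturbance$mixing_fraction %||% 1
  }
  if (!is.null(raw$emission)) {
    base$depth <- raw$emission$depth %||% base$depth
    base$dispersion <- raw$emission$dispersion %||% base$dispersion
  }
  base$name <- raw$name %||% "custom"
  base
}
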