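# Mechanistic guild-based simulator of a continuously stirred tank reactor
# (CSTR) performing autotrophic nitrogen removal.
#
# The reactor holds three dissolved nitrogen pools (NH4-N, NO2-N, NO3-N,
# mg N/L) exchanged with the feed at dilution rate D = Q/V, and five
# functional guilds, each split into an attached (retained) and a suspended
# (washed out) biomass pool:
#   AOB  aerobic ammonia oxidizers        NH4 -> NO2
#   NOB  nitrite oxidizers                NO2 -> NO3
#   CMX  comammox (complete oxidizers)    NH4 -> NO3
#   AMX  anammox                          NH4 + 1.32 NO2 -> N2 (+ NO3)
#   HET  chemoheterotrophs (no inorganic-N turnover; grow on decay products)
# Aerobic rates are Monod in substrate times Monod in oxygen; anammox carries
# a non-competitive oxygen inhibition factor K_I/(K_I + DO). Anammox products
# are split in the fixed 0.26 : 2.04 NO3-N : N2-N stoichiometric ratio, and
# the consumed nitrogen (1 + 1.32 mol N per mol NH4) is fully recovered in
# the products, so the simulator conserves nitrogen exactly; biomass carries
# no nitrogen in the balance, matching the downstream mass-balance analysis
# that neglects assimilation.

GUILD_IDS <- c("AOB", "NOB", "CMX", "AMX", "HET")

# anammox stoichiometry per mol NH4-N consumed
AMX_NO2_PER_NH4 <- 1.32
AMX_N_IN <- 1 + AMX_NO2_PER_NH4                   # total N consumed
AMX_F_NO3 <- 0.26 / (0.26 + 2.04)                 # product split: nitrate
AMX_F_N2 <- 2.04 / (0.26 + 2.04)                  # product split: N2

#' Reactor operating configuration
#'
#' @param working_volume reactor liquid volume, L.
#' @param hrt hydraulic retention time, days; `influent_flow` defaults to
#'   `working_volume / hrt`.
#' @param influent_flow feed flow, L/day (overrides `hrt` when given).
#' @param influent_nh4_load influent ammonium-N load, mg N/day.
#' @param do_setpoint controlled dissolved-oxygen level, mg O2/L.
#' @param temperature,ph nominal operating temperature (C) and pH.
#' @param duration simulated horizon, days.
#' @param dt maximum internal integrator step, days.
#' @param seed master seed for every stochastic element of a run.
#' @return object of class `reactor_config`.
#' @export
reactor_config <- function(working_volume = 4.5, hrt = 6.25,
                           influent_flow = NULL, influent_nh4_load = 86.4,
                           do_setpoint = 0.2, temperature = 30, ph = 7.6,
                           duration = 56, dt = 0.25, seed = 1L) {
  stopifnot_scalar(working_volume, "working_volume", positive = TRUE)
  if (is.null(influent_flow)) {
    stopifnot_scalar(hrt, "hrt", positive = TRUE)
    influent_flow <- working_volume / hrt
  }
  stopifnot_scalar(influent_flow, "influent_flow", positive = TRUE)
  stopifnot_scalar(influent_nh4_load, "influent_nh4_load", nonneg = TRUE)
  stopifnot_scalar(do_setpoint, "do_setpoint", nonneg = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (duration < dt) stop("duration must be >= dt", call. = FALSE)
  structure(
    list(working_volume = working_volume, influent_flow = influent_flow,
         influent_nh4_load = influent_nh4_load, do_setpoint = do_setpoint,
         temperature = temperature, ph = ph, duration = duration, dt = dt,
         seed = as.integer(seed)),
    class = "reactor_config"
  )
}

#' @export
print.reactor_config <- function(x, ...) {
  cat(sprintf(
    "CSTR config: V = %.2f L, Q = %.3f L/d (HRT %.2f d), load %.1f mg NH4-N/d, DO %.2f mg/L, %g d horizon\n",
    x$working_volume, x$influent_flow, x$working_volume / x$influent_flow,
    x$influent_nh4_load, x$do_setpoint, x$duration))
  invisible(x)
}

#' Kinetic and partitioning parameters of one microbial guild
#'
#' Standard Monod parameterisation. `k_substrate` is the half-saturation
#' constant of the guild's electron-donor substrate (for anammox it is
#' applied to both ammonium and nitrite); `oxygen_inhibition_k` is only used
#' by anammox.
#'
#' @param guild_id one of `"AOB"`, `"NOB"`, `"CMX"`, `"AMX"`, `"HET"`.
#' @param mu_max maximum specific growth rate, 1/day.
#' @param k_substrate substrate half-saturation, mg N/L.
#' @param k_oxygen oxygen half-saturation, mg O2/L.
#' @param oxygen_inhibition_k non-competitive O2 inhibition constant, mg O2/L.
#' @param yield_biomass biomass yield, mg biomass per mg N transformed.
#' @param decay first-order decay, 1/day.
#' @param attached_fraction fraction of initial biomass in the attached pool.
#' @return object of class `guild_params`.
#' @export
guild_params <- function(guild_id, mu_max, k_substrate, k_oxygen,
                         oxygen_inhibition_k = NA_real_, yield_biomass,
                         decay, attached_fraction = 0.8) {
  guild_id <- match.arg(guild_id, GUILD_IDS)
  for (nm in c("mu_max", "k_substrate", "k_oxygen", "yield_biomass", "decay"))
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  if (attached_fraction < 0 || attached_fraction > 1)
    stop("attached_fraction must lie in [0, 1]", call. = FALSE)
  structure(
    list(guild_id = guild_id, mu_max = mu_max, k_substrate = k_substrate,
         k_oxygen = k_oxygen, oxygen_inhibition_k = oxygen_inhibition_k,
         yield_biomass = yield_biomass, decay = decay,
         attached_fraction = attached_fraction),
    class = "guild_params"
  )
}

#' Default calibrated guild set
#'
#' Kinetics typical of partial-nitritation/anammox systems at ~30 C under
#' oxygen limitation: AOB hold a lower oxygen half-saturation than NOB
#' (which is what lets anammox outcompete nitrate formation at low DO),
#' comammox is a slow oligotroph, and anammox is slow-growing, strongly
#' oxygen-inhibited and mostly attached.
#'
#' @return named list of [guild_params()] objects.
#' @export
default_guilds <- function() {
  list(
    AOB = guild_params("AOB", mu_max = 0.60, k_substrate = 0.80,
                       k_oxygen = 0.30, yield_biomass = 0.12,
                       decay = 0.04, attached_fraction = 0.70),
    NOB = guild_params("NOB", mu_max = 0.70, k_substrate = 0.40,
                       k_oxygen = 0.90, yield_biomass = 0.06,
                       decay = 0.05, attached_fraction = 0.70),
    CMX = guild_params("CMX", mu_max = 0.18, k_substrate = 0.60,
                       k_oxygen = 0.15, yield_biomass = 0.10,
                       decay = 0.035, attached_fraction = 0.80),
    AMX = guild_params("AMX", mu_max = 0.10, k_substrate = 0.10,
                       k_oxygen = 0, oxygen_inhibition_k = 0.25,
                       yield_biomass = 0.065, decay = 0.010,
                       attached_fraction = 0.90),
    HET = guild_params("HET", mu_max = 0.50, k_substrate = 1.0,
                       k_oxygen = 0.20, yield_biomass = 0.40,
                       decay = 0.05, attached_fraction = 0.50)
  )
}

#' Redistribute attached biomass into suspension
#'
#' Models the physical homogenisation of biofilms and aggregates: a fraction
#' of each guild's attached pool is resuspended; total biomass per guild is
#' conserved at the disturbance instant.
#'
#' @param state list with numeric vectors `attached` and `suspended`
#'   (mg biomass/L per guild).
#' @param mixing_fraction fraction of attached biomass resuspended, in [0,1].
#' @return state list of the same shape.
#' @export
apply_disturbance <- function(state, mixing_fraction) {
  if (!is.list(state) || is.null(state$attached) || is.null(state$suspended))
    stop("state must be a list with 'attached' and 'suspended'", call. = FALSE)
  if (!is.numeric(mixing_fraction) || length(mixing_fraction) != 1L ||
      is.na(mixing_fraction) || mixing_fraction < 0 || mixing_fraction > 1)
    stop("mixing_fraction must lie in [0, 1]", call. = FALSE)
  moved <- state$attached * mixing_fraction
  state$suspended <- state$suspended + moved
  state$attached <- state$attached - moved
  state
}

#' Successional fitness schedule
#'
#' Plants staged succession by modulating each guild's maximum growth rate
#' with stage-specific multipliers blended by logistic weights over time.
#' Stage weights are `w1 = 1 - L1`, `w3 = L2`, `w2 = 1 - w1 - w3` with
#' `L_b(t) = 1/(1 + exp(-steepness (t - b)))` at the two stage boundaries.
#'
#' @param boundaries two stage-transition days.
#' @param steepness logistic steepness, 1/day.
#' @param multipliers guilds-by-stages matrix of growth-rate multipliers
#'   (rownames must cover the simulated guilds).
#' @return object of class `stage_schedule`.
#' @export
stage_schedule <- function(boundaries = c(13.5, 34.5), steepness = 1.5,
                           multipliers = NULL) {
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    stop("boundaries must be two increasing days", call. = FALSE)
  if (is.null(multipliers)) {
    multipliers <- rbind(
      AOB = c(1.60, 1.00, 0.80),
      NOB = c(1.50, 0.70, 0.55),
      CMX = c(0.90, 1.10, 1.00),
      AMX = c(0.35, 1.00, 1.50),
      HET = c(1.00, 1.20, 1.00)
    )
  }
  structure(list(boundaries = boundaries, steepness = steepness,
                 multipliers = multipliers),
            class = "stage_schedule")
}

# Stage weight matrix for times t: rows t, columns 3 stages.
stage_weights <- function(schedule, t) {
  L1 <- stats::plogis(schedule$steepness * (t - schedule$boundaries[1]))
  L2 <- stats::plogis(schedule$steepness * (t - schedule$boundaries[2]))
  cbind(1 - L1, L1 - L2, L2)
}

# Hard stage label (nearest planted stage) for times t.
stage_labels <- function(schedule, t) {
  max.col(stage_weights(schedule, t))
}

# Build the daily environmental forcing traces (DO, temperature, pH).
# DO is a controlled setpoint with AR(1) excursions plus a decaying
# post-disturbance elevation; temperature and pH are AR(1) around nominal.
make_forcings <- function(config, noise, disturbed) {
  days <- seq(0, config$duration, by = 1)
  n <- length(days)
  ar1 <- function(n, sd, rho) {
    if (sd <= 0) return(numeric(n))
    e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
    x <- numeric(n)
    x[1] <- stats::rnorm(1, 0, sd)
    for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
    x
  }
  pulse <- if (disturbed) noise$do_pulse * exp(-days / noise$do_pulse_tau) else 0
  do <- pmax(config$do_setpoint + pulse + ar1(n, noise$do_sd, noise$ar_rho), 0)
  temp <- config$temperature + ar1(n, noise$temp_sd, noise$ar_rho)
  ph <- config$ph + ar1(n, noise$ph_sd, noise$ar_rho)
  list(days = days, do = do, temperature = temp, ph = ph)
}

#' Default simulator noise settings
#'
#' `conc_cv`: multiplicative (lognormal) measurement noise on effluent
#' concentrations; `do_sd`/`temp_sd`/`ph_sd`: AR(1) excursion scales of the
#' forcing traces with lag-1 correlation `ar_rho`; `do_pulse` and
#' `do_pulse_tau`: size (mg/L) and decay time (days) of the transient DO
#' elevation that follows a disturbance.
#' @export
sim_noise_defaults <- function() {
  list(conc_cv = 0.03, do_sd = 0.02, temp_sd = 0.25, ph_sd = 0.04,
       ar_rho = 0.7, do_pulse = 0.15, do_pulse_tau = 8)
}

sim_noise_off <- function() {
  list(conc_cv = 0, do_sd = 0, temp_sd = 0, ph_sd = 0,
       ar_rho = 0, do_pulse = 0, do_pulse_tau = 8)
}

#' Simulate the CSTR nitrogen-removal reactor
#'
#' Integrates the CSTR mass balance `dC/dt = (Q/V)(C_in - C) + reactions`
#' for the dissolved nitrogen pools together with attached/suspended biomass
#' dynamics of the supplied guilds, under an optional successional fitness
#' schedule and an optional disturbance event that resuspends attached
#' biomass. Cumulative N2 evasion and cumulative effluent nitrogen are
#' tracked as states so that the nitrogen balance can be audited exactly.
#'
#' @param config a [reactor_config()].
#' @param guilds list of [guild_params()] (may be empty for an abiotic run).
#' @param disturbance_day day of the homogenisation disturbance (`NULL` for
#'   none; day 0 disturbs the initial state).
#' @param mixing_fraction fraction of attached biomass resuspended.
#' @param schedule optional [stage_schedule()].
#' @param init optional list with `nh4`, `no2`, `no3` (mg N/L) and
#'   `attached`, `suspended` biomass vectors (mg/L per guild).
#' @param noise noise settings as from [sim_noise_defaults()];
#'   use `noise = NULL` for a fully deterministic run.
#' @param taxon_map optional taxon map (see [default_taxon_map()]) used to
#'   derive relative-abundance profiles from guild biomass.
#' @param reattachment_rate first-order re-attachment of suspended biomass,
#'   1/day.
#' @return object of class `reactor_sim`: `chem` (a [chem_series()] with
#'   measurement noise), `true_chem` (noise-free), `guild_biomass`
#'   (days x guilds, attached + suspended), `true_stage`, `taxon_profile`
#'   (days x taxa, rows sum to 1), `n2_rate` (mg N/day), `balance_error`
#'   (relative nitrogen-conservation error per day), plus inputs.
#' @export
simulate_reactor <- function(config, guilds = default_guilds(),
                             disturbance_day = NULL, mixing_fraction = 1,
                             schedule = NULL, init = NULL, noise = NULL,
                             taxon_map = NULL, reattachment_rate = 0.2) {
  stopifnot(inherits(config, "reactor_config"))
  if (length(guilds)) {
    ok <- vapply(guilds, inherits, logical(1), "guild_params")
    if (!all(ok)) stop("guilds must be guild_params objects", call. = FALSE)
    names(guilds) <- vapply(guilds, `[[`, character(1), "guild_id")
  }
  if (config$dt > config$working_volume / config$influent_flow / 2)
    stop("step size dt too large for a stable CSTR integration (must be <= HRT/2)",
         call. = FALSE)
  D <- config$influent_flow / config$working_volume
  V <- config$working_volume
  c_in <- config$influent_nh4_load / config$influent_flow
  ng <- length(guilds)
  gid <- if (ng) names(guilds) else character(0)

  noise_on <- !is.null(noise)
  nz <- if (noise_on) utils::modifyList(sim_noise_defaults(), noise) else sim_noise_off()
  forc <- with_seed(if (noise_on) config$seed else NULL,
                    make_forcings(config, nz, !is.null(disturbance_day)))
  do_fun <- stats::approxfun(forc$days, forc$do, rule = 2)

  if (is.null(init)) {
    att <- if (ng) vapply(guilds, `[[`, numeric(1), "attached_fraction") else numeric(0)
    tot <- c(AOB = 40, NOB = 25, CMX = 15, AMX = 120, HET = 40)[gid]
    tot[is.na(tot)] <- 20
    init <- list(nh4 = 5, no2 = 1, no3 = 15,
                 attached = tot * att, suspended = tot * (1 - att))
  }
  bio <- list(attached = init$attached, suspended = init$suspended)
  if (!is.null(disturbance_day) && disturbance_day <= 0) {
    bio <- apply_disturbance(bio, mixing_fraction)
    disturbance_day <- NULL
  }

  mu0 <- if (ng) vapply(guilds, `[[`, numeric(1), "mu_max") else numeric(0)
  ks <- if (ng) vapply(guilds, `[[`, numeric(1), "k_substrate") else numeric(0)
  ko <- if (ng) vapply(guilds, `[[`, numeric(1), "k_oxygen") else numeric(0)
  ki <- if (ng) vapply(guilds, `[[`, numeric(1), "oxygen_inhibition_k") else numeric(0)
  yld <- if (ng) vapply(guilds, `[[`, numeric(1), "yield_biomass") else numeric(0)
  dec <- if (ng) vapply(guilds, `[[`, numeric(1), "decay") else numeric(0)

  fit_fun <- if (is.null(schedule)) {
    function(t) rep(1, ng)
  } else {
    M <- schedule$multipliers
    if (ng && !all(gid %in% rownames(M)))
      stop("schedule multipliers must cover all guilds", call. = FALSE)
    function(t) as.vector(M[gid, , drop = FALSE] %*% stage_weights(schedule, t)[1, ])
  }

  # per-guild kinetic structure, precomputed for the vectorized derivative
  use_nh4 <- gid %in% c("AOB", "CMX", "AMX")
  use_no2 <- gid %in% c("NOB", "AMX")
  aerobic <- gid %in% c("AOB", "NOB", "CMX")
  is_amx <- gid == "AMX"
  is_het <- gid == "HET"
  q0 <- ifelse(is_het, 0, mu0 / pmax(yld, .Machine$double.eps))
  i_aob <- match("AOB", gid); i_nob <- match("NOB", gid)
  i_cmx <- match("CMX", gid); i_amx <- match("AMX", gid)

  idxA <- seq_len(ng) + 5
  idxS <- idxA + ng
  derivs <- function(t, y, parms) {
    y <- unname(y)
    nh4 <- max(y[[1]], 0); no2 <- max(y[[2]], 0); no3 <- max(y[[3]], 0)
    A <- y[idxA]; A[A < 0] <- 0
    S <- y[idxS]; S[S < 0] <- 0
    X <- A + S
    do <- do_fun(t)
    r <- numeric(ng)                    # substrate-N transformation, mg N/L/d
    if (ng) {
      fit <- fit_fun(t)
      fac <- q0 * fit * X
      fac[use_nh4] <- fac[use_nh4] * nh4 / (ks[use_nh4] + nh4)
      fac[use_no2] <- fac[use_no2] * no2 / (ks[use_no2] + no2)
      fac[aerobic] <- fac[aerobic] * do / (ko[aerobic] + do)
      fac[is_amx] <- fac[is_amx] * ki[is_amx] / (ki[is_amx] + do)
      r <- fac
    }
    r_aob <- if (is.na(i_aob)) 0 else r[i_aob]
    r_nob <- if (is.na(i_nob)) 0 else r[i_nob]
    r_cmx <- if (is.na(i_cmx)) 0 else r[i_cmx]
    r_amx <- if (is.na(i_amx)) 0 else r[i_amx]

    dnh4 <- D * (c_in - nh4) - r_aob - r_cmx - r_amx
    dno2 <- -D * no2 + r_aob - r_nob - AMX_NO2_PER_NH4 * r_amx
    dno3 <- -D * no3 + r_nob + r_cmx + AMX_N_IN * AMX_F_NO3 * r_amx
    dn2 <- V * AMX_N_IN * AMX_F_N2 * r_amx          # mg N/day evasion
    deff <- config$influent_flow * (nh4 + no2 + no3) # mg N/day effluent

    dA <- dS <- numeric(ng)
    if (ng) {
      growth <- yld * r - dec * X
      growth[is_het] <- yld[is_het] * sum(dec * X) - dec[is_het] * X[is_het]
      shareA <- rep(0.5, ng)
      pos <- X > 0
      shareA[pos] <- A[pos] / X[pos]
      dA <- growth * shareA + reattachment_rate * S
      dS <- growth * (1 - shareA) - reattachment_rate * S - D * S
    }
    list(c(dnh4, dno2, dno3, dn2 / V, deff / V, dA, dS))
  }

  run_leg <- function(y0, t0, t1) {
    grid <- if (floor(t1) >= ceiling(t0)) seq(ceiling(t0), floor(t1), by = 1) else numeric(0)
    times <- sort(unique(c(t0, grid, t1)))
    out <- deSolve::ode(y = y0, times = times, func = derivs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10,
                        hmax = config$dt)
    if (attr(out, "istate")[1] < 0)
      stop("integration failure near t = ", max(out[, 1]), call. = FALSE)
    out
  }

  bio_names <- if (ng) c(paste0("A_", gid), paste0("S_", gid)) else character(0)
  y0 <- c(nh4 = init$nh4, no2 = init$no2, no3 = init$no3,
          cum_n2 = 0, cum_eff = 0,
          stats::setNames(c(bio$attached, bio$suspended), bio_names))

  if (!is.null(disturbance_day) && disturbance_day < config$duration) {
    leg1 <- run_leg(y0, 0, disturbance_day)
    y_mid <- leg1[nrow(leg1), -1]
    st <- list(attached = y_mid[seq_len(ng) + 5],
               suspended = y_mid[seq_len(ng) + 5 + ng])
    st <- apply_disturbance(st, mixing_fraction)
    y_mid[seq_len(ng) + 5] <- st$attached
    y_mid[seq_len(ng) + 5 + ng] <- st$suspended
    leg2 <- run_leg(y_mid, disturbance_day, config$duration)
    out <- rbind(leg1[-nrow(leg1), , drop = FALSE], leg2)
  } else {
    out <- run_leg(y0, 0, config$duration)
  }

  state <- out[, -1, drop = FALSE]
  worst <- min(state)
  if (worst < -1e-6 * max(abs(state), 1)) {
    bad <- which(state == worst, arr.ind = TRUE)[1, ]
    stop(sprintf("integration failure: negative state '%s' (%.3g) at t = %g",
                 colnames(state)[bad[2]], worst, out[bad[1], 1]), call. = FALSE)
  }
  state[state < 0] <- 0

  days <- out[, 1]
  keep <- days >= 1 & abs(days - round(days)) < 1e-8
  days_out <- round(days[keep])
  nh4 <- state[keep, 1]; no2 <- state[keep, 2]; no3 <- state[keep, 3]

  # N2 evasion rate per output day: increment of the cumulative state over
  # the preceding day
  cum_n2 <- state[, 4] * V
  cumf <- stats::approxfun(days, cum_n2, rule = 2)
  n2_rate <- cumf(days_out) - cumf(days_out - 1)

  q_out <- config$influent_flow
  true_chem <- chem_series(
    day = days_out,
    influent_nh4 = rep(config$influent_nh4_load, length(days_out)),
    effluent_nh4 = nh4 * q_out, effluent_no2 = no2 * q_out,
    effluent_no3 = no3 * q_out,
    temperature = forc$temperature[match(days_out, forc$days)],
    ph = forc$ph[match(days_out, forc$days)],
    do = forc$do[match(days_out, forc$days)]
  )
  chem <- true_chem
  if (noise_on && nz$conc_cv > 0) {
    chem[, c("effluent_nh4", "effluent_no2", "effluent_no3")] <-
      with_seed(derive_seed(config$seed, "noise"), {
        m <- as.matrix(true_chem[, c("effluent_nh4", "effluent_no2",
                                     "effluent_no3")])
        m * exp(matrix(stats::rnorm(length(m), 0, nz$conc_cv), nrow(m)))
      })
  }

  biomass <- state[keep, seq_len(ng) + 5, drop = FALSE] +
    state[keep, seq_len(ng) + 5 + ng, drop = FALSE]
  colnames(biomass) <- gid

  true_stage <- if (is.null(schedule)) rep(1L, length(days_out)) else
    stage_labels(schedule, days_out)

  taxon_profile <- NULL
  if (!is.null(taxon_map))
    taxon_profile <- build_taxon_profile(taxon_map, biomass, schedule, days_out)

  # audit: reactor N + cumulative N2 + cumulative effluent vs influent load
  n0 <- (y0[1] + y0[2] + y0[3]) * V
  total <- (state[, 1] + state[, 2] + state[, 3]) * V +
    state[, 4] * V + state[, 5] * V
  expected <- n0 + config$influent_nh4_load * days
  balance_error <- (total - expected) /
    pmax(config$influent_nh4_load * pmax(days, 1), 1)

  structure(
    list(chem = chem, true_chem = true_chem, guild_biomass = biomass,
         true_stage = true_stage, taxon_profile = taxon_profile,
         n2_rate = n2_rate, days = days_out, config = config,
         guilds = guilds, schedule = schedule, taxon_map = taxon_map,
         balance_error = balance_error,
         final_state = state[nrow(state), ],
         final_derivs = unlist(derivs(max(days), state[nrow(state), ], NULL))),
    class = "reactor_sim"
  )
}

#' @export
print.reactor_sim <- function(x, ...) {
  cat("CSTR guild simulation:", length(x$days), "daily samples,",
      ncol(x$guild_biomass), "guilds\n")
  last <- nrow(x$chem)
  cat(sprintf("  final effluent (mg N/d): NH4 %.2f, NO2 %.2f, NO3 %.2f; N2 evasion %.2f\n",
              x$true_chem$effluent_nh4[last], x$true_chem$effluent_no2[last],
              x$true_chem$effluent_no3[last], x$n2_rate[last]))
  cat(sprintf("  worst nitrogen-balance error: %.2e (relative to load)\n",
              max(abs(x$balance_error))))
  invisible(x)
}

#' Steady-state nitrogen export of a configuration
#'
#' Runs the simulator (deterministically, no noise) until the state
#' derivatives fall below `tol`, then returns the total nitrogen export
#' rate: effluent NH4-N + NO2-N + NO3-N plus N2-N evasion, mg N/day. At
#' steady state this equals the influent load by conservation.
#'
#' @param config a [reactor_config()]; `duration` is the horizon tried first.
#' @param guilds guild list.
#' @param tol derivative tolerance, mg N/L/day.
#' @param max_horizon give up (with an error) beyond this many days.
#' @return list with `total_export`, `components`, `horizon`.
#' @export
steady_state_export <- function(config, guilds = default_guilds(),
                                tol = 1e-9, max_horizon = 4000) {
  horizon <- max(config$duration, 500)
  repeat {
    cfg <- config
    cfg$duration <- horizon
    sim <- simulate_reactor(cfg, guilds, noise = NULL)
    dmax <- max(abs(sim$final_derivs[c(1:3, 5 + seq_len(2 * length(guilds)))]))
    if (dmax < tol) break
    horizon <- horizon * 2
    if (horizon > max_horizon)
      stop("no steady state reached within ", max_horizon, " days", call. = FALSE)
  }
  last <- nrow(sim$true_chem)
  comp <- c(
    nh4 = sim$true_chem$effluent_nh4[last],
    no2 = sim$true_chem$effluent_no2[last],
    no3 = sim$true_chem$effluent_no3[last],
    n2 = sim$final_derivs[4] * config$working_volume
  )
  list(total_export = sum(comp), components = comp, horizon = horizon)
}

#' Mean residence time from a conservative tracer pulse
#'
#' Injects a unit pulse of conservative tracer into the abiotic reactor at
#' t = 0 and returns the first moment of the washout curve,
#' `integral(t C dt) / integral(C dt)`, which for an ideal CSTR equals the
#' hydraulic retention time V/Q.
#'
#' @param config a [reactor_config()].
#' @param horizon integration horizon in units of HRT.
#' @return mean residence time, days.
#' @export
tracer_mean_residence_time <- function(config, horizon = 10) {
  stopifnot(inherits(config, "reactor_config"))
  hrt <- config$working_volume / config$influent_flow
  Tend <- horizon * hrt
  times <- seq(0, Tend, by = min(config$dt, hrt / 200))
  out <- deSolve::ode(
    y = c(C = 1), times = times, parms = NULL,
    func = function(t, y, p) list(-config$influent_flow /
                                    config$working_volume * y),
    rtol = 1e-10, atol = 1e-12
  )
  C <- out[, 2]
  if (C[length(C)] > 0.01)
    stop("washout horizon too short: ", round(100 * C[length(C)], 1),
         "% of tracer mass remains", call. = FALSE)
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  trapz(times, times * C) / trapz(times, C)
}
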