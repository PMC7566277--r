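# Stoichiometric nitrogen mass balance of the autotrophic removal system.
#
# In a reactor fed solely with ammonium, nitrification (AOB: NH4+ -> NO2-;
# NOB: NO2- -> NO3-) and anammox (NH4+ + NO2- -> N2, with a small NO3-
# by-product) account for the nitrogen speciation of the effluent. Because
# N2 escapes to the gas phase, it is inferred as the deficit between the
# influent ammonium-nitrogen load and the summed effluent nitrogen species.
# Measured nitrate is then split by the anammox reaction stoichiometry:
# about 0.26 mol NO3- is formed per 1.02 mol N2 produced, so the
# anammox-derived pool is N2-N * 0.26/2.04 (mol-N and mass-N bases agree,
# both pools being nitrogen) and the remainder is nitrification-derived.

#' Nitrate yield of anammox relative to dinitrogen production
#'
#' Mass ratio of anammox-derived nitrate-N to dinitrogen-N: 0.26 mol NO3-
#' is produced per 1.02 mol N2 (2.04 mol N).
#' @export
anammox_no3_per_n2 <- 0.26 / 2.04

#' Assemble a chemistry time series on the rate basis
#'
#' Daily nitrogen loads in and out of the reactor plus the operational
#' variables. All nitrogen fields are rates in mg N/day; use
#' [chem_from_concentrations()] when the effluent is recorded as
#' concentrations.
#'
#' @param day sampling day (strictly increasing).
#' @param influent_nh4 influent ammonium-N load, mg N/day.
#' @param effluent_nh4,effluent_no2,effluent_no3 effluent species export
#'   rates, mg N/day.
#' @param temperature reactor temperature, degrees C.
#' @param ph reactor pH.
#' @param do dissolved oxygen, mg O2/L.
#' @return a `data.frame` of class `chem_series`.
#' @export
chem_series <- function(day, influent_nh4, effluent_nh4, effluent_no2,
                        effluent_no3, temperature = NA_real_, ph = NA_real_,
                        do = NA_real_) {
  n <- length(day)
  if (n == 0L) stop("empty chemistry series", call. = FALSE)
  if (any(diff(day) <= 0)) stop("day must be strictly increasing", call. = FALSE)
  rates <- cbind(influent_nh4, effluent_nh4, effluent_no2, effluent_no3)
  if (any(!is.finite(rates))) stop("nitrogen rates must be finite", call. = FALSE)
  if (any(rates < 0)) stop("nitrogen rates must be >= 0", call. = FALSE)
  out <- data.frame(
    day = day, influent_nh4 = influent_nh4, effluent_nh4 = effluent_nh4,
    effluent_no2 = effluent_no2, effluent_no3 = effluent_no3,
    temperature = rep_len(temperature, n), ph = rep_len(ph, n),
    do = rep_len(do, n)
  )
  class(out) <- c("chem_series", "data.frame")
  out
}

#' Convert effluent concentrations to a rate-basis chemistry series
#'
#' @param df data frame with columns `day`, `nh4_in_mgN_d`, `nh4_out_mgN_L`,
#'   `no2_out_mgN_L`, `no3_out_mgN_L`, `temp_C`, `ph`, `do_mgO2_L`.
#' @param flow effluent flow, L/day (equal to influent flow in a CSTR).
#' @return a [chem_series()] on the mg N/day basis.
#' @export
chem_from_concentrations <- function(df, flow) {
  stopifnot_scalar(flow, "flow", positive = TRUE)
  need <- c("day", "nh4_in_mgN_d", "nh4_out_mgN_L", "no2_out_mgN_L",
            "no3_out_mgN_L")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing chemistry columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  chem_series(
    day = df$day,
    influent_nh4 = df$nh4_in_mgN_d,
    effluent_nh4 = df$nh4_out_mgN_L * flow,
    effluent_no2 = df$no2_out_mgN_L * flow,
    effluent_no3 = df$no3_out_mgN_L * flow,
    temperature = if ("temp_C" %in% names(df)) df$temp_C else NA_real_,
    ph = if ("ph" %in% names(df)) df$ph else NA_real_,
    do = if ("do_mgO2_L" %in% names(df)) df$do_mgO2_L else NA_real_
  )
}

#' Partition effluent nitrogen by reaction origin
#'
#' Infers the dinitrogen evasion rate from the nitrogen deficit
#' (influent NH4-N minus summed effluent NH4-N, NO2-N, NO3-N), attributes
#' `n2 * 0.26/2.04` of the measured nitrate to anammox (`ap_no3`) and the
#' remainder to nitrification (`np_no3`), and forms the performance index
#' `ratio = n2 / np_no3`.
#'
#' A negative inferred deficit (measurement noise) is floored at zero; a
#' warning is raised when it falls below `-tol * influent`. The ratio is
#' reported as `NA` when `np_no3` is not positive (no nitrification-derived
#' nitrate to normalise by).
#'
#' @param chem a [chem_series()] (or any data frame with its rate columns).
#' @param tol relative tolerance on a negative deficit before warning.
#' @return a `data.frame` of class `nitrogen_partition` with columns
#'   `day`, `n2`, `ap_no3`, `np_no3`, `ratio` (rates in mg N/day).
#' @export
partition_nitrogen <- function(chem, tol = 0.05) {
  need <- c("day", "influent_nh4", "effluent_nh4", "effluent_no2",
            "effluent_no3")
  miss <- setdiff(need, names(chem))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  rates <- cbind(chem$influent_nh4, chem$effluent_nh4, chem$effluent_no2,
                 chem$effluent_no3)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("nitrogen rates must be finite and >= 0", call. = FALSE)
  deficit <- chem$influent_nh4 -
    (chem$effluent_nh4 + chem$effluent_no2 + chem$effluent_no3)
  bad <- deficit < -tol * pmax(chem$influent_nh4, .Machine$double.eps)
  if (any(bad))
    warning(sum(bad), " day(s) with effluent nitrogen exceeding the influent ",
            "load beyond tolerance; inferred N2 floored at 0", call. = FALSE)
  n2 <- pmax(deficit, 0)
  ap <- n2 * anammox_no3_per_n2
  np <- chem$effluent_no3 - ap
  ratio <- ifelse(np > 1e-9, n2 / np, NA_real_)
  out <- data.frame(day = chem$day, n2 = n2, ap_no3 = ap, np_no3 = np,
                    ratio = ratio)
  class(out) <- c("nitrogen_partition", "data.frame")
  out
}

#' Centred moving average over a day window
#'
#' Mean over all points whose day lies within `window/2` of the focal day
#' (inclusive). `NA` values are excluded from each window's mean; the output
#' has the same length as the input. The conventional window is one
#' hydraulic retention time.
#'
#' @param day strictly increasing day coordinates.
#' @param value series values (may contain `NA`).
#' @param window full window width in days (> 0).
#' @return numeric vector of smoothed values, `NA` where a window holds no
#'   defined value.
#' @export
moving_average <- function(day, value, window) {
  if (length(day) == 0L) stop("empty series", call. = FALSE)
  if (length(day) != length(value)) stop("day/value length mismatch", call. = FALSE)
  if (any(diff(day) <= 0)) stop("day must be strictly increasing", call. = FALSE)
  stopifnot_scalar(window, "window", positive = TRUE)
  half <- window / 2
  vapply(seq_along(day), function(i) {
    sel <- abs(day - day[i]) <= half
    v <- value[sel]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' @export
print.nitrogen_partition <- function(x, ...) {
  cat("Nitrogen partition over", nrow(x), "days (mg N/day)\n")
  cat(sprintf("  mean N2 %.2f | mean npNO3- %.2f | mean apNO3- %.2f\n",
              mean(x$n2), mean(x$np_no3), mean(x$ap_no3)))
  ok <- !is.na(x$ratio)
  if (any(ok))
    cat(sprintf("  N2/npNO3- ratio: mean %.3f (defined on %d/%d days)\n",
                mean(x$ratio[ok]), sum(ok), nrow(x)))
  invisible(x)
}
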