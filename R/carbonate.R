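#' Seawater carbonate-system equilibrium constants
#'
#' Evaluates the full set of equilibrium constants needed to solve the marine
#' CO2 system from an NBS-scale pH / total-alkalinity pair, at surface
#' pressure. The formulations mirror the classic CO2SYS configuration used in
#' ocean-acidification husbandry work: carbonic-acid constants from the
#' Mehrbach data as refit by Dickson and Millero (seawater pH scale), boric
#' acid from Dickson, water from Millero, CO2 solubility from Weiss, bisulfate
#' from Dickson, hydrogen fluoride from Dickson and Riley, borate-to-salinity
#' ratio from Uppström, and the NBS activity coefficient fH from
#' Takahashi. All hydrogen-ion constants are returned on the seawater (SWS)
#' pH scale in mol/kg-SW, so that a single scale is used throughout the solve.
#'
#' @param temperature Water temperature, degrees C. Accepted without warning
#'   in (15, 35); values in (0, 45) are accepted with a warning.
#' @param salinity Practical salinity, psu, in (0, 45).
#' @return An object of class `carb_constants`: a list with components `k0`
#'   (mol kg-1 atm-1), `k1`, `k2`, `kb`, `kw`, `ks`, `kf` (mol/kg-SW; `ks`,
#'   `kf` on the free scale, the others on SWS), `total_boron`,
#'   `total_sulfate`, `total_fluoride` (mol/kg-SW), `fh` (NBS activity
#'   coefficient), `fugacity_factor`, and the inputs `temperature`,
#'   `salinity`.
#' @examples
#' k <- compute_constants(28.8, 35.5)
#' -log10(k$k1)  # pK1 on the seawater scale
#' @export
compute_constants <- function(temperature, salinity) {
  stopifnot(length(temperature) == 1L, length(salinity) == 1L)
  if (!is.finite(temperature) || temperature <= 0 || temperature >= 45) {
    stop("temperature out of range (0, 45) degC: ", temperature, call. = FALSE)
  }
  if (!is.finite(salinity) || salinity <= 0 || salinity >= 45) {
    stop("salinity out of range (0, 45) psu: ", salinity, call. = FALSE)
  }
  if (temperature <= 15 || temperature >= 35) {
    warning("temperature ", temperature,
            " degC is outside the routinely validated range (15, 35)")
  }
  TK <- temperature + 273.15
  lTK <- log(TK)
  S <- salinity

  # Weiss 1974 CO2 solubility, mol/kg-SW/atm
  k0 <- exp(-60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
              S * (0.023517 - 0.023656 * (TK / 100) +
                     0.0047036 * (TK / 100)^2))

  # Mehrbach refit (Dickson & Millero 1987), SWS scale
  pk1 <- 3670.7 / TK - 62.008 + 9.7944 * lTK - 0.0118 * S + 0.000116 * S^2
  pk2 <- 1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2
  k1 <- 10^(-pk1)
  k2 <- 10^(-pk2)

  ion_s <- 19.924 * S / (1000 - 1.005 * S)

  # Dickson 1990 bisulfate, free scale, converted to mol/kg-SW
  ks <- exp(-4276.1 / TK + 141.328 - 23.093 * lTK +
              (-13856 / TK + 324.57 - 47.986 * lTK) * sqrt(ion_s) +
              (35474 / TK - 771.54 + 114.723 * lTK) * ion_s -
              (2698 / TK) * ion_s^1.5 + (1776 / TK) * ion_s^2) *
    (1 - 0.001005 * S)

  # Dickson & Riley 1979 hydrogen fluoride, free scale, mol/kg-SW
  kf <- exp(1590.2 / TK - 12.641 + 1.525 * sqrt(ion_s)) * (1 - 0.001005 * S)

  total_boron <- 0.0004157 * S / 35                 # Uppstrom 1974
  total_sulfate <- (0.14 / 96.062) * (S / 1.80655)  # Morris & Riley 1966
  total_fluoride <- (0.000067 / 18.998) * (S / 1.80655)

  sws_to_tot <- (1 + total_sulfate / ks) /
    (1 + total_sulfate / ks + total_fluoride / kf)

  # Dickson 1990 boric acid (total scale), moved onto SWS
  kb <- exp((-8966.9 - 2890.53 * sqrt(S) - 77.942 * S + 1.728 * S^1.5 -
               0.0996 * S^2) / TK +
              148.0248 + 137.1942 * sqrt(S) + 1.62142 * S +
              (-24.4344 - 25.085 * sqrt(S) - 0.2474 * S) * lTK +
              0.053105 * sqrt(S) * TK) / sws_to_tot

  # Millero 1995 water dissociation, SWS
  kw <- exp(148.9802 - 13847.26 / TK - 23.6521 * lTK +
              (118.67 / TK - 5.977 + 1.0495 * lTK) * sqrt(S) - 0.01615 * S)

  # Takahashi et al. 1982 NBS activity coefficient
  fh <- 1.2948 - 0.002036 * TK + (0.0004607 - 0.000001475 * TK) * S^2

  # CO2 fugacity coefficient at 1 atm total pressure
  delta <- 57.7 - 0.118 * TK
  bvir <- -1636.75 + 12.0408 * TK - 0.0327957 * TK^2 + 3.16528e-5 * TK^3
  fugacity_factor <- exp((bvir + 2 * delta) * 1.01325 / (83.1451 * TK))

  structure(
    list(k0 = k0, k1 = k1, k2 = k2, kb = kb, kw = kw, ks = ks, kf = kf,
         total_boron = total_boron, total_sulfate = total_sulfate,
         total_fluoride = total_fluoride, fh = fh,
         fugacity_factor = fugacity_factor,
         temperature = temperature, salinity = salinity),
    class = "carb_constants")
}

#' Convert NBS-scale pH to the working (seawater) scale
#'
#' The equilibrium constants used by the solver live on the seawater (SWS)
#' hydrogen-ion scale, while husbandry pH meters calibrated against standard
#' buffers report NBS pH. The conversion divides the NBS hydrogen-ion
#' activity by the activity coefficient fH: `[H+]_SWS = 10^(-pH_NBS) / fH`.
#'
#' @param ph_nbs pH measured on the NBS scale.
#' @param constants A [compute_constants()] object holding `fh`.
#' @return pH on the seawater scale (numeric, same length as `ph_nbs`).
#' @export
convert_ph_scale <- function(ph_nbs, constants) {
  fh <- .get_fh(constants)
  ph_nbs + log10(fh)
}

#' @rdname convert_ph_scale
#' @export
convert_ph_scale_inverse <- function(ph_sws, constants) {
  fh <- .get_fh(constants)
  ph_sws - log10(fh)
}

.get_fh <- function(constants) {
  if (!inherits(constants, "carb_constants") || is.null(constants$fh) ||
      !is.finite(constants$fh)) {
    stop("constants must be a carb_constants object carrying fH", call. = FALSE)
  }
  constants$fh
}

.validate_seawater <- function(temperature, salinity, ph_nbs, total_alkalinity) {
  if (!is.finite(ph_nbs) || ph_nbs < 7.0 || ph_nbs > 8.6) {
    stop("ph_nbs out of range [7.0, 8.6]: ", ph_nbs, call. = FALSE)
  }
  if (!is.finite(total_alkalinity) || total_alkalinity <= 0) {
    stop("total_alkalinity must be positive (umol/kg-SW): ", total_alkalinity,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Solve the CO2 system from NBS pH and total alkalinity
#'
#' Given temperature, salinity, NBS-scale pH and total alkalinity, solves the
#' alkalinity balance for dissolved inorganic carbon and returns the partial
#' pressure of CO2 together with the full carbonate speciation. The pH fixes
#' every non-carbonate alkalinity term (borate, hydroxide, free hydrogen,
#' bisulfate, hydrogen fluoride), so carbonate alkalinity follows by
#' subtraction and DIC in closed form:
#' \deqn{DIC = CA \frac{H^2 + K_1 H + K_1 K_2}{K_1 (H + 2 K_2)}}
#' with \eqn{pCO_2 = [CO_2^*]/K_0} (optionally divided by the fugacity
#' coefficient). Nutrient alkalinity is taken as zero and pressure as surface.
#'
#' @param temperature,salinity See [compute_constants()].
#' @param ph_nbs pH on the NBS scale, in \[7.0, 8.6\].
#' @param total_alkalinity Total alkalinity, umol per kg seawater (> 0).
#' @param apply_fugacity If `TRUE`, report pCO2 = fCO2 / fugacity factor;
#'   default `FALSE` reports the partial pressure without the (~0.3%)
#'   fugacity correction.
#' @param constants Optionally, a precomputed [compute_constants()] object.
#' @return A one-row `data.frame` with columns `pco2_uatm`, `dic_umol_kg`,
#'   `co2_star_umol_kg`, `bicarbonate_umol_kg`, `carbonate_umol_kg`,
#'   `ph_sws`, plus the inputs; the constant set is attached as attribute
#'   `"constants"` for provenance.
#' @examples
#' solve_from_ph_ta(28.8, 35.5, 8.15, 2284)$pco2_uatm
#' @export
solve_from_ph_ta <- function(temperature, salinity, ph_nbs, total_alkalinity,
                             apply_fugacity = FALSE, constants = NULL) {
  .validate_seawater(temperature, salinity, ph_nbs, total_alkalinity)
  k <- if (is.null(constants)) compute_constants(temperature, salinity) else constants
  ta <- total_alkalinity * 1e-6            # mol/kg-SW

  h <- 10^(-ph_nbs) / k$fh                 # [H+] on SWS
  h_free <- h / (1 + k$total_sulfate / k$ks + k$total_fluoride / k$kf)

  borate <- k$total_boron * k$kb / (k$kb + h)
  oh <- k$kw / h
  hso4 <- k$total_sulfate / (1 + k$ks / h_free)
  hf <- k$total_fluoride / (1 + k$kf / h_free)

  carb_alk <- ta - borate - oh + h_free + hso4 + hf
  if (carb_alk <= 0) {
    stop("implied carbonate alkalinity is non-positive (", signif(carb_alk, 4),
         " mol/kg); inputs are inconsistent", call. = FALSE)
  }

  denom <- h^2 + k$k1 * h + k$k1 * k$k2
  dic <- carb_alk * denom / (k$k1 * (h + 2 * k$k2))
  co2_star <- dic * h^2 / denom
  bicarbonate <- dic * k$k1 * h / denom
  carbonate <- dic * k$k1 * k$k2 / denom

  pco2 <- co2_star / k$k0 * 1e6            # uatm (fugacity-uncorrected)
  if (apply_fugacity) pco2 <- pco2 / k$fugacity_factor

  out <- data.frame(
    temperature_c = temperature, salinity_psu = salinity, ph_nbs = ph_nbs,
    ta_umol_kg = total_alkalinity,
    pco2_uatm = pco2,
    dic_umol_kg = dic * 1e6,
    co2_star_umol_kg = co2_star * 1e6,
    bicarbonate_umol_kg = bicarbonate * 1e6,
    carbonate_umol_kg = carbonate * 1e6,
    ph_sws = convert_ph_scale(ph_nbs, k))
  attr(out, "constants") <- k
  out
}

#' Forward pH solve from total alkalinity and DIC
#'
#' Inverts the system solved by [solve_from_ph_ta()]: given total alkalinity
#' and dissolved inorganic carbon, finds the NBS pH at which the alkalinity
#' balance closes, by bounded root-finding on pH. Used for round-trip
#' validation of the closed-form solve.
#'
#' @param temperature,salinity See [compute_constants()].
#' @param total_alkalinity Total alkalinity, umol/kg-SW.
#' @param dic Dissolved inorganic carbon, umol/kg-SW.
#' @param tol Convergence tolerance on pH.
#' @return pH on the NBS scale.
#' @export
ph_from_ta_dic <- function(temperature, salinity, total_alkalinity, dic,
                           tol = 1e-10) {
  k <- compute_constants(temperature, salinity)
  ta <- total_alkalinity * 1e-6
  dic_mol <- dic * 1e-6
  resid <- function(ph_nbs) {
    h <- 10^(-ph_nbs) / k$fh
    h_free <- h / (1 + k$total_sulfate / k$ks + k$total_fluoride / k$kf)
    denom <- h^2 + k$k1 * h + k$k1 * k$k2
    carb_alk <- dic_mol * (k$k1 * h + 2 * k$k1 * k$k2) / denom
    borate <- k$total_boron * k$kb / (k$kb + h)
    carb_alk + borate + k$kw / h - h_free -
      k$total_sulfate / (1 + k$ks / h_free) -
      k$total_fluoride / (1 + k$kf / h_free) - ta
  }
  stats::uniroot(resid, c(6, 9.5), tol = tol)$root
}

#' Solve a batch of seawater samples
#'
#' Batch interface over [solve_from_ph_ta()] matching the tabular layout of
#' treatment-chemistry summaries: one row per sample with columns
#' `temperature_c`, `salinity_psu`, `ph_nbs`, `ta_umol_kg`. The solved
#' columns (`pco2_uatm` and companions) are appended.
#'
#' @param samples A `data.frame` with the four input columns above.
#' @param apply_fugacity Passed to [solve_from_ph_ta()].
#' @return `samples` with solution columns appended.
#' @export
solve_carbonate_batch <- function(samples, apply_fugacity = FALSE) {
  needed <- c("temperature_c", "salinity_psu", "ph_nbs", "ta_umol_kg")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("samples is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  res <- lapply(seq_len(nrow(samples)), function(i) {
    solve_from_ph_ta(samples$temperature_c[i], samples$salinity_psu[i],
                     samples$ph_nbs[i], samples$ta_umol_kg[i],
                     apply_fugacity = apply_fugacity)
  })
  res <- do.call(rbind, res)
  cbind(samples, res[, setdiff(names(res), needed), drop = FALSE])
}
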