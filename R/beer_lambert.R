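# Modified Beer-Lambert law: DPF, extinction coefficients, and the
# forward (concentration -> optical density) and inverse conversions.

#' Differential pathlength factor as a function of wavelength and age
#'
#' Evaluates the general DPF equation
#' \deqn{DPF(\lambda, A) = 223.3 + 0.05624 A^{0.8493}
#'   - 5.723\times 10^{-7}\lambda^3 + 0.001245\lambda^2 - 0.9025\lambda}
#' with age \eqn{A} in years and wavelength \eqn{\lambda} in nm. For a
#' neonate (age 0) this gives 5.31 at 695 nm and 4.67 at 830 nm (2 d.p.).
#'
#' @param wavelength wavelength(s) in nm, within 650--900.
#' @param age age in years, >= 0 (default 0, neonate).
#' @return dimensionless DPF, vectorized over `wavelength`.
#' @examples
#' round(compute_dpf(c(695, 830), age = 0), 2)
#' @export
compute_dpf <- function(wavelength, age = 0) {
  if (any(!is.finite(wavelength)) || any(wavelength < 650) || any(wavelength > 900))
    stop("wavelength must lie in [650, 900] nm", call. = FALSE)
  if (!is_scalar_num(age) || age < 0)
    stop("age must be a finite scalar >= 0 years", call. = FALSE)
  223.3 + 0.05624 * age^0.8493 -
    5.723e-7 * wavelength^3 + 0.001245 * wavelength^2 - 0.9025 * wavelength
}

#' Hemoglobin extinction coefficients shipped with the package
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at the two
#' probe wavelengths, in cm^-1 per micromolar (1e-3 x the conventional
#' cm^-1/mM values). The simulator and the inverse Beer-Lambert step use
#' this same table, so forward/inverse round trips are self-consistent;
#' absolute concentration scale depends on the compilation used, which
#' only matters up to a common factor here.
#'
#' @param wavelengths wavelengths (nm) to look up; must be present in
#'   the table.
#' @return a matrix with rows = wavelengths, columns `hbo`, `hbr`,
#'   units cm^-1/uM.
#' @export
extinction_coefficients <- function(wavelengths = c(695, 830)) {
  tab <- matrix(
    c(695, 0.320e-3, 1.820e-3,
      760, 0.586e-3, 1.548e-3,
      830, 0.974e-3, 0.693e-3),
    ncol = 3, byrow = TRUE,
    dimnames = list(NULL, c("wavelength_nm", "hbo", "hbr"))
  )
  idx <- match(wavelengths, tab[, "wavelength_nm"])
  if (anyNA(idx))
    stop("no extinction coefficients for wavelength(s) ",
         paste(wavelengths[is.na(idx)], collapse = ", "), " nm", call. = FALSE)
  out <- tab[idx, c("hbo", "hbr"), drop = FALSE]
  rownames(out) <- as.character(wavelengths)
  out
}

# 2x2 pathlength-scaled extinction system A such that
#   dOD[lambda] = A %*% c(dHbO, dHbR)   (concentrations in uM)
bl_system <- function(layout, age = 0, extinction = NULL) {
  wl <- layout_wavelengths(layout)
  if (length(wl) != 2)
    stop("modified Beer-Lambert inversion needs exactly two wavelengths",
         call. = FALSE)
  eps <- if (is.null(extinction)) extinction_coefficients(wl) else extinction
  d <- layout$distance_cm[1]
  dpf <- compute_dpf(wl, age)
  A <- eps * (d * dpf)         # row-wise scaling: rows are wavelengths
  if (abs(det(A)) < 1e-12)
    abort_config("extinction matrix is singular; cannot separate HbO/HbR")
  A
}

#' Convert optical-density changes to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per channel and sample:
#' solves the 2x2 system
#' \eqn{\Delta OD(\lambda) = [\epsilon_{HbO}(\lambda)\Delta HbO +
#' \epsilon_{HbR}(\lambda)\Delta HbR] \, d \, DPF(\lambda)}
#' for \eqn{(\Delta HbO, \Delta HbR)} in micromolar.
#'
#' @param od an `od_series` (see [intensity_to_od()]).
#' @param layout the `probe_layout`; supplies distance and wavelengths.
#' @param age subject age in years for the DPF (default 0).
#' @param extinction optional 2x2 extinction matrix (rows = wavelengths,
#'   columns hbo/hbr, cm^-1/uM); default the shipped table.
#' @return a `conc_series`: list with matrices `hbo`, `hbr`
#'   (samples x channels, uM), `fs`, `layout`, `channel_id`.
#' @export
od_to_conc <- function(od, layout = od$layout, age = 0, extinction = NULL) {
  A <- bl_system(layout, age, extinction)
  Ainv <- solve(A)
  # od$dod is samples x channels x 2 wavelengths
  d1 <- od$dod[, , 1L, drop = FALSE][, , 1L]
  d2 <- od$dod[, , 2L, drop = FALSE][, , 1L]
  hbo <- Ainv[1, 1] * d1 + Ainv[1, 2] * d2
  hbr <- Ainv[2, 1] * d1 + Ainv[2, 2] * d2
  structure(list(hbo = as.matrix(hbo), hbr = as.matrix(hbr),
                 fs = od$fs, layout = layout,
                 channel_id = od$channel_id),
            class = "conc_series")
}

# Forward model: concentration (uM) -> optical-density change.
# hbo/hbr: samples x channels. Returns samples x channels x 2 array.
conc_to_od <- function(hbo, hbr, layout, age = 0, extinction = NULL) {
  A <- bl_system(layout, age, extinction)
  dod <- array(0, dim = c(nrow(hbo), ncol(hbo), 2L))
  dod[, , 1L] <- A[1, 1] * hbo + A[1, 2] * hbr
  dod[, , 2L] <- A[2, 1] * hbo + A[2, 2] * hbr
  dod
}
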