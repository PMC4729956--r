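#' Electrospray ion-beam deposition dose bookkeeping
#'
#' During soft landing the integrated ion current on the sample (the
#' charge dose, in picoampere hours) together with the charge state gives
#' the number of deposited molecules:
#' `N = (Q[pAh] * 3.6e-9 C/pAh) / (z * e)`.
#' Sticking probability is assumed 1 and re-desorption 0.  The published
#' doses are 43 pAh at z = +2 (octapeptide) and 60 pAh at z = +3
#' (decapeptide), both landed at 10 eV.
#'
#' @param charge_dose Integrated current, pAh (>= 0).
#' @param z Charge state, positive integer.
#' @param landing_energy Landing energy, eV (recorded only).
#' @param sample_area Sample area, mm^2 (optional, for coverage).
#' @param molecular_footprint Area of one flat-lying molecule, nm^2.
#' @return `dose_record()` returns a `dose_record`;
#'   `molecules_from_dose()` a molecule count; `coverage_fraction()` a
#'   dimensionless monolayer fraction.
#' @examples
#' molecules_from_dose(dose_record(43, 2))  # ~4.8e11 molecules
#' @export
dose_record <- function(charge_dose, z, landing_energy = 10,
                        sample_area = NA_real_,
                        molecular_footprint = NA_real_) {
  if (charge_dose < 0) stop("charge_dose must be >= 0", call. = FALSE)
  if (z != round(z) || z <= 0) stop("z must be a positive integer", call. = FALSE)
  structure(list(charge_dose = charge_dose, z = as.integer(z),
                 landing_energy = landing_energy, sample_area = sample_area,
                 molecular_footprint = molecular_footprint),
            class = "dose_record")
}

#' @export
print.dose_record <- function(x, ...) {
  cat(sprintf("<dose_record> %.1f pAh at z = +%d, %.0f eV landing\n",
              x$charge_dose, x$z, x$landing_energy))
  invisible(x)
}

coulomb_per_pAh <- 3.6e-9
elementary_charge <- 1.602176634e-19

#' @rdname dose_record
#' @param rec A `dose_record` (or a dose in pAh when `z` is also given).
#' @export
molecules_from_dose <- function(rec, z = NULL) {
  if (!inherits(rec, "dose_record")) rec <- dose_record(rec, z)
  rec$charge_dose * coulomb_per_pAh / (rec$z * elementary_charge)
}

#' @rdname dose_record
#' @param count Number of molecules.
#' @param footprint_nm2 Molecular footprint, nm^2.
#' @param area_mm2 Deposition area, mm^2 (> 0); 1 mm^2 = 1e12 nm^2.
#' @export
coverage_fraction <- function(count, footprint_nm2, area_mm2) {
  if (area_mm2 <= 0) stop("area must be positive", call. = FALSE)
  count * footprint_nm2 / (area_mm2 * 1e12)
}

#' @rdname dose_record
#' @export
deposition_summary <- function(charge_dose, z, footprint_nm2 = NA_real_,
                               area_mm2 = NA_real_) {
  n <- molecules_from_dose(dose_record(charge_dose, z))
  tibble::tibble(
    charge_dose_pAh = charge_dose, z = as.integer(z), molecules = n,
    coverage = if (is.finite(footprint_nm2) && is.finite(area_mm2))
      coverage_fraction(n, footprint_nm2, area_mm2) else NA_real_)
}
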