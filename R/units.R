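#' Cell compartment geometry
#'
#' Compartment volumes of the modeled yeast cell and the Avogadro constant
#' used for all concentration/molecule-count conversions. The whole cell is
#' 58 fL, of which the cytoplasm occupies 50% (29 fL) and the nucleus 7%
#' (4.06 fL). The Avogadro constant is fixed at 6.022e23 1/mol so that the
#' shipped molecule-count tables round to the documented integers.
#'
#' @param v_cell whole-cell volume in femtoliters.
#' @param v_cyt cytoplasmic volume in femtoliters.
#' @param v_nuc nuclear volume in femtoliters.
#'
#' @return An object of class `cell_geometry`: a list with elements `v_cell`,
#'   `v_cyt`, `v_nuc` (fL) and `avogadro` (1/mol).
#' @export
#' @examples
#' geom <- cell_geometry()
#' geom$v_nuc / geom$v_cyt
cell_geometry <- function(v_cell = 58, v_cyt = 29, v_nuc = 4.06) {
  stopifnot(v_cell > 0, v_cyt > 0, v_nuc > 0)
  if (!(v_nuc < v_cyt && v_cyt < v_cell)) {
    stop("cell geometry requires v_nuc < v_cyt < v_cell", call. = FALSE)
  }
  structure(
    list(v_cell = v_cell, v_cyt = v_cyt, v_nuc = v_nuc, avogadro = 6.022e23),
    class = "cell_geometry"
  )
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("cell geometry: cell", x$v_cell, "fL | cytoplasm", x$v_cyt,
      "fL | nucleus", x$v_nuc, "fL\n")
  invisible(x)
}

# molecules per (mmol/ml) in a compartment of `volume_fL` femtoliters.
# mmol/ml is numerically mol/L, and 1 fL = 1e-15 L.
.count_per_conc <- function(volume_fL, geometry = cell_geometry()) {
  volume_fL * 1e-15 * geometry$avogadro
}

#' Convert a concentration to a molecule count
#'
#' Converts a nanomolar concentration in a compartment of given volume to the
#' (rounded) number of molecules, and back. `count_to_concentration` is the
#' inverse up to rounding error.
#'
#' @param conc_nM concentration in nM (vectorised).
#' @param volume_fL compartment volume in femtoliters.
#' @param geometry a [cell_geometry()].
#'
#' @return `concentration_to_count`: integer-valued molecule counts.
#'   `count_to_concentration`: concentrations in nM.
#' @export
#' @examples
#' concentration_to_count(406, 29)   # cytoplasmic Fus3, 7090 molecules
#' concentration_to_count(340.5, 4.06) # nuclear Hog1, 832 molecules
concentration_to_count <- function(conc_nM, volume_fL,
                                   geometry = cell_geometry()) {
  if (any(conc_nM < 0)) stop("negative concentration", call. = FALSE)
  if (any(volume_fL <= 0)) stop("volume must be positive", call. = FALSE)
  round(conc_nM * 1e-9 * .count_per_conc(volume_fL, geometry))
}

#' @rdname concentration_to_count
#' @param count molecule count (need not be integer).
#' @export
count_to_concentration <- function(count, volume_fL,
                                   geometry = cell_geometry()) {
  if (any(count < 0)) stop("negative count", call. = FALSE)
  if (any(volume_fL <= 0)) stop("volume must be positive", call. = FALSE)
  count / .count_per_conc(volume_fL, geometry) * 1e9
}

#' Convert a deterministic rate constant to a stochastic propensity constant
#'
#' Converts a rate constant expressed in canonical concentration units
#' (mmol/ml, numerically mol/L; time in seconds) to the per-molecule
#' propensity constant (1/s) used by the stochastic simulation engine.
#'
#' * order 2 (`ml/(mmol s)`): divided by `N_A * V` with `V` the compartment
#'   volume in liters;
#' * order 0 (`mmol/(ml s)`): multiplied by `N_A * V`, giving molecules/s;
#' * order 1 within one compartment: unchanged;
#' * order 1 where a species in one compartment drives a rate producing
#'   molecules in another (e.g. nuclear kinase driving cytoplasmic
#'   transcription): multiplied by `v_target/v_source`.
#'
#' @param k deterministic rate constant (canonical units).
#' @param order reaction order: 0, 1 or 2.
#' @param volume_fL compartment volume in fL (orders 0 and 2).
#' @param v_source,v_target source/target compartment volumes in fL for
#'   compartment-crossing first-order rates; leave `NULL` for a rate confined
#'   to one compartment.
#' @param geometry a [cell_geometry()].
#'
#' @return propensity constant in 1/s (order 0: molecules/s).
#' @export
#' @examples
#' det_to_stoch_rate(8e11, order = 2, volume_fL = 29)      # ~45.8
#' det_to_stoch_rate(6.95e-12, order = 0, volume_fL = 29)  # ~0.1214
#' det_to_stoch_rate(4e-6, order = 1, v_source = 4.06, v_target = 29)
det_to_stoch_rate <- function(k, order, volume_fL = NULL,
                              v_source = NULL, v_target = NULL,
                              geometry = cell_geometry()) {
  stopifnot(length(order) == 1)
  if (!order %in% c(0, 1, 2)) {
    stop("unsupported reaction order: ", order, call. = FALSE)
  }
  if (order == 2) {
    stopifnot(!is.null(volume_fL))
    return(k / .count_per_conc(volume_fL, geometry))
  }
  if (order == 0) {
    stopifnot(!is.null(volume_fL))
    return(k * .count_per_conc(volume_fL, geometry))
  }
  if (!is.null(v_source) && !is.null(v_target)) {
    return(k * v_target / v_source)
  }
  k
}
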