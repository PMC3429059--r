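#' Kinetic parameter set for the consortium models
#'
#' All rate constants of the four cell models, in canonical units: time in
#' seconds, concentrations in mmol/ml (numerically mol/L). Second-order
#' constants are ml/(mmol s), zero-order production terms mmol/(ml s).
#'
#' The set covers the salt-cell HOG module (`w`, `k20`-`k30`, `Ki30`),
#' alpha-factor expression (`k31`, `k31_deg`, `k32`, `k33`), the Tet-Off
#' dox-cell (`k38`, `Ki38`), the GAL1 gal-cell (`k37`), the reporter-cell
#' pheromone pathway (`k1`-`k10`, `v_Ste2_production`, `k_nuc_imp`,
#' `k_nuc_exp`, `k_small`) and the GFP expression module (`k34`, `k34_deg`,
#' `k35`, `k36`).
#'
#' @param ... named overrides of individual constants (e.g. `k1 = 4e11` for
#'   the low-affinity Ste2-F262A receptor variant).
#'
#' @return named list of class `parameter_set`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$k38 / p$k31_deg * 1e9   # basal Tet-Off mRNA steady state, nM
default_parameters <- function(...) {
  p <- list(
    # salt-cell: osmostress gain and HOG cascade
    w     = 2.39,
    k20   = 758,        # Pbs2 activation, ml/(mmol s)
    k21   = 235,        # Pbs2 deactivation, 1/s
    k22   = 113543,     # Hog1 phosphorylation, ml/(mmol s)
    k23   = 8.84e-5,    # cytoplasmic Hog1 dephosphorylation, 1/s
    k24   = 0.0148,     # nuclear Hog1 dephosphorylation, 1/s
    k25   = 34.5,       # nuclear export of Hog1-PP, 1/s
    k26   = 87.8,       # nuclear import of Hog1-PP, 1/s
    k27   = 5.76,       # nuclear import of Hog1, 1/s
    k28   = 45.2,       # nuclear export of Hog1, 1/s
    k29   = 8170,       # osmolyte synthesis, 1/s
    k30   = 0.0035,     # osmolyte leakage, 1/s
    Ki30  = 100,        # leakage inhibition by osmostress, ml/mmol
    k31   = 1.5e-6,     # transcription from PSTL1, 1/s
    # shared alpha-factor expression module
    k31_deg = 0.00231,  # MFalpha1-mRNA degradation (t1/2 = 5 min), 1/s
    k32   = 3,          # prepro-alpha translation, 1/s
    k33   = 0.00315,    # processing and export of alpha, 1/s
    # dox-cell (Tet-Off) and gal-cell (GAL1)
    k38   = 2e-12,      # Tet-Off transcription, mmol/(ml s)
    Ki38  = 1e7,        # doxycycline repression, ml/mmol
    k37   = 1.2e-11,    # GAL1 transcription, ml/(mmol s) applied to [Gal]
    # reporter cell: pheromone pathway
    k1    = 8e11,       # Ste2-alpha binding, ml/(mmol s)
    k2    = 3250,       # alpha release from Ste2, 1/s
    v_Ste2_production = 6.95e-12, # Ste2 synthesis, mmol/(ml s)
    k4    = 1.84e-5,    # Ste2 degradation, 1/s
    k5    = 2.1e-5,     # Ste2-alpha degradation, 1/s
    k6    = 18000,      # Ste5 complex activation, ml/(mmol s)
    k7    = 0.0042,     # Ste5 complex inactivation, 1/s
    k8    = 3.2e10,     # Fus3 phosphorylation, ml/(mmol s)
    k9    = 680,        # cytoplasmic Fus3 dephosphorylation, 1/s
    k10   = 0.28,       # nuclear Fus3 dephosphorylation, 1/s
    k_nuc_imp = 16.8,   # nuclear import of Fus3 / Fus3-PP, 1/s
    k_nuc_exp = 85.7,   # nuclear export of Fus3, 1/s
    k_small  = 0.5,     # Fus3-PP export = k_small * k_nuc_exp
    # GFP expression module
    k34   = 4e-6,       # transcription from PFUS1, 1/s
    k34_deg = 0.00214,  # GFP-mRNA degradation, 1/s
    k35   = 2,          # GFP translation, 1/s
    k36   = 9.625e-5    # GFP folding/maturation, 1/s
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(dots)] <- dots
  }
  if (any(unlist(p) < 0)) stop("rate constants must be >= 0", call. = FALSE)
  if (p$k_small <= 0 || p$k_small > 1) stop("k_small must be in (0, 1]",
                                            call. = FALSE)
  class(p) <- "parameter_set"
  p
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter set (", length(unclass(x)), " constants)\n", sep = "")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Initial protein concentrations
#'
#' Initial concentrations (nM) of the proteins present before stimulation,
#' with their compartments and the corresponding per-cell molecule numbers
#' used by the stochastic engine. All other species start at zero.
#'
#' @return data.frame with columns `species`, `compartment`, `conc_nM`,
#'   `count` (molecules per cell, used verbatim by the stochastic models).
#' @export
initial_concentrations <- function() {
  data.frame(
    species = c("Pbs2", "Hog1n", "Hog1c", "Ste2", "inactive_Ste5complex",
                "Fus3n", "Fus3c"),
    compartment = c("cytoplasm", "nucleus", "cytoplasm", "cytoplasm",
                    "cytoplasm", "nucleus", "cytoplasm"),
    conc_nM = c(123.7, 340.5, 340.5, 378, 38.5, 568.4, 406),
    count = c(2160, 832, 5948, 6600, 672, 1390, 7090),
    stringsAsFactors = FALSE
  )
}

#' Stochastic propensity constants for the reporter cell
#'
#' Per-molecule propensity constants (1/s; the Ste2 production term `k3` in
#' molecules/s) of the stochastic reporter-cell model. Most entries follow
#' from the deterministic constants via [det_to_stoch_rate()]; the nuclear
#' import/export pair `k_nuc_imp`/`k_nuc_exp` does not follow any simple
#' volume scaling of the deterministic constants and is stored verbatim --
#' see [reporter_stochastic_model()] for how the model treats it (the
#' flux-consistent rates are the default).
#'
#' @return named numeric vector.
#' @export
#' @examples
#' stochastic_parameters()[["k1"]]
stochastic_parameters <- function() {
  c(
    k1 = 45.82, k2 = 3250, k3 = 0.12144, k4 = 1.84e-5, k5 = 2.1e-5,
    k6 = 1.031e-6, k7 = 0.0042, k8 = 1.833, k9 = 680, k10 = 0.28,
    k_nuc_imp = 21.423, k_nuc_exp = 8.4,
    k34 = 2.86e-5, k34_deg = 0.00214, k35 = 2, k36 = 9.625e-5
  )
}

#' Recompute stochastic constants from the deterministic parameter set
#'
#' Applies the [det_to_stoch_rate()] volume rules to the deterministic
#' constants that have a direct stochastic counterpart. Used to check the
#' internal consistency of the two parameter tables (the anomalous
#' `k_nuc_imp`/`k_nuc_exp` pair is excluded).
#'
#' @param params a [default_parameters()] set.
#' @param geometry a [cell_geometry()].
#' @return named numeric vector of recomputed propensity constants.
#' @export
derive_stochastic_parameters <- function(params = default_parameters(),
                                         geometry = cell_geometry()) {
  vc <- geometry$v_cyt
  c(
    k1 = det_to_stoch_rate(params$k1, 2, vc, geometry = geometry),
    k2 = det_to_stoch_rate(params$k2, 1),
    k3 = det_to_stoch_rate(params$v_Ste2_production, 0, vc,
                           geometry = geometry),
    k4 = det_to_stoch_rate(params$k4, 1),
    k5 = det_to_stoch_rate(params$k5, 1),
    k6 = det_to_stoch_rate(params$k6, 2, vc, geometry = geometry),
    k7 = det_to_stoch_rate(params$k7, 1),
    k8 = det_to_stoch_rate(params$k8, 2, vc, geometry = geometry),
    k9 = det_to_stoch_rate(params$k9, 1),
    k10 = det_to_stoch_rate(params$k10, 1),
    # nuclear Fus3-PP count drives cytoplasmic transcription
    k34 = det_to_stoch_rate(params$k34, 1, v_source = geometry$v_nuc,
                            v_target = geometry$v_cyt),
    k34_deg = det_to_stoch_rate(params$k34_deg, 1),
    k35 = det_to_stoch_rate(params$k35, 1),
    k36 = det_to_stoch_rate(params$k36, 1)
  )
}

# ---- input-signal unit conventions ------------------------------------------
# Canonical internal unit for all chemical signals is mmol/ml (= mol/L).
# User-facing units: NaCl in M (numerically equal to mmol/ml), doxycycline in
# ug/ml (molecular weight 444.4 g/mol), galactose in % w/v where 2% w/v
# corresponds to 0.11 mmol/ml.

#' Convert user-facing input units to canonical mmol/ml
#'
#' @param nacl_M NaCl concentration in mol/L.
#' @param dox_ug_ml doxycycline in micrograms per ml (MW 444.4 g/mol).
#' @param gal_percent galactose in percent w/v (2% corresponds to
#'   0.11 mmol/ml).
#' @return concentration in mmol/ml.
#' @export
#' @examples
#' dox_to_canonical(1)   # ~2.25e-6 mmol/ml
#' gal_to_canonical(2)   # 0.11 mmol/ml
nacl_to_canonical <- function(nacl_M) {
  stopifnot(all(nacl_M >= 0))
  nacl_M  # 1 M = 1 mol/L = 1 mmol/ml
}

#' @rdname nacl_to_canonical
#' @export
dox_to_canonical <- function(dox_ug_ml) {
  stopifnot(all(dox_ug_ml >= 0))
  # 1 ug/ml = 1e-6 g/ml; /444.4 g/mol = 2.2502e-9 mol/ml = 2.2502e-6 mmol/ml
  dox_ug_ml * 1e-3 / 444.4
}

#' @rdname nacl_to_canonical
#' @export
gal_to_canonical <- function(gal_percent) {
  stopifnot(all(gal_percent >= 0))
  gal_percent / 2 * 0.11
}
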