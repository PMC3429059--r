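# Single-cell kinetic models: salt-, dox-, gal- (sender) and reporter cells.
# Canonical units throughout: concentrations in mmol/ml (= mol/L), time in
# seconds; the dilution law is parameterised in hours.

#' Osmotic stress level
#'
#' Effective osmostress experienced by the salt-cell: the gain-scaled external
#' salt concentration minus the internal osmolyte pool, clamped at zero.
#'
#' @param salt external NaCl, mmol/ml.
#' @param int_osmo internal osmolyte concentration, mmol/ml.
#' @param w dimensionless osmostress gain.
#' @return stress level in mmol/ml (never negative).
#' @export
#' @examples
#' osmostress(0.4, 0, 2.39)
osmostress <- function(salt, int_osmo, w) {
  stopifnot(all(salt >= 0), all(int_osmo >= 0))
  pmax(w * salt - int_osmo, 0)
}

#' Culture settings and the dilution law
#'
#' The per-cell export flux of alpha-factor is divided by a time-decreasing
#' dilution factor `coeff * exp(-rate * t)` that models the growing culture:
#' the factor halves every doubling time (`rate = ln(2)/doubling_h`) and its
#' coefficient scales inversely with the initial culture density (13,800 at
#' the reference density of 5e6 cells/ml).
#'
#' @param density initial culture density, cells/ml, per population.
#' @param doubling_h cell doubling time in hours.
#' @param dilution_coeff dilution factor at time zero for the reference
#'   density of 5e6 cells/ml.
#' @return object of class `culture_config`.
#' @export
#' @examples
#' dilution_factor(0, culture_config())    # 13800
#' dilution_factor(4, culture_config())    # ~ half of that
culture_config <- function(density = 5e6, doubling_h = 4,
                           dilution_coeff = 13800) {
  stopifnot(density > 0, doubling_h > 0, dilution_coeff > 0)
  structure(
    list(density = density, doubling_h = doubling_h,
         dilution_coeff = dilution_coeff,
         dilution_rate = log(2) / doubling_h,          # 1/h
         coeff = dilution_coeff * (5e6 / density)),
    class = "culture_config"
  )
}

#' @export
print.culture_config <- function(x, ...) {
  cat("culture:", format(x$density, big.mark = ","), "cells/ml, doubling",
      x$doubling_h, "h, dilution", x$coeff, "* exp(-",
      round(x$dilution_rate, 4), "* t[h])\n")
  invisible(x)
}

#' @rdname culture_config
#' @param t_h time in hours.
#' @param culture a `culture_config`.
#' @export
dilution_factor <- function(t_h, culture = culture_config()) {
  if (any(t_h < 0)) stop("negative time", call. = FALSE)
  culture$coeff * exp(-culture$dilution_rate * t_h)
}

# ---- model constructors ------------------------------------------------------

.nM <- 1e-9  # nM in mmol/ml

new_cell_model <- function(name, species, initial, rhs,
                           params, geometry, culture, extra = list()) {
  stopifnot(setequal(names(initial), species))
  structure(
    c(list(name = name, species = species, initial = initial[species],
           rhs = rhs, params = params, geometry = geometry,
           culture = culture), extra),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat("cell model <", x$name, ">: ", length(x$species), " species (",
      paste(x$species, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Sender and reporter cell models
#'
#' Constructors for the four single-cell kinetic models.
#'
#' * `salt_cell()`: HOG-pathway model (Pbs2, Hog1 with nuclear shuttling,
#'   internal osmolytes) driving MFalpha1 expression from the STL1 promoter;
#'   input `NaCl` (mmol/ml).
#' * `dox_cell()`: constitutive Tet-Off expression of MFalpha1, repressed by
#'   doxycycline; input `DOX` (mmol/ml).
#' * `gal_cell()`: GAL1-driven MFalpha1 expression; input `Gal` (mmol/ml).
#'   Unless `precultured = TRUE`, GAL gene induction only starts 3 h after
#'   the galactose shift.
#' * `reporter_cell()`: pheromone pathway (Ste2 receptor, Ste5 complex, Fus3
#'   with nuclear shuttling) driving GFP expression from the FUS1 promoter;
#'   input `alpha` (medium alpha-factor, mmol/ml), treated as an external
#'   driving concentration when the cell is simulated on its own.
#'
#' Intracellular mRNA and protein concentrations refer to the cytoplasm,
#' `Hog1n`/`Hog1ppn`/`Fus3n`/`Fus3ppn` to the nucleus, and `Alpha_in_medium`
#' to the culture medium; the export flux of alpha is divided by the
#' [dilution_factor()] of the sender's culture.
#'
#' @param params a [default_parameters()] set.
#' @param geometry a [cell_geometry()].
#' @param culture a [culture_config()] (senders only).
#' @param precultured logical; were the gal-cells grown in galactose before
#'   the simulation (no induction delay)?
#'
#' @return a `cell_model` object with fields `name`, `species`, `initial`
#'   (mmol/ml), `rhs` and the configuration used.
#' @export
#' @name cell_models
salt_cell <- function(params = default_parameters(),
                      geometry = cell_geometry(),
                      culture = culture_config()) {
  species <- c("Pbs2", "Pbs2pp", "Hog1c", "Hog1ppc", "Hog1n", "Hog1ppn",
               "Int_osmo", "MFalpha1_mRNA", "prepro_Alpha", "Alpha_in_medium")
  initial <- stats::setNames(numeric(length(species)), species)
  initial["Pbs2"]  <- 123.7 * .nM
  initial["Hog1c"] <- 340.5 * .nM
  initial["Hog1n"] <- 340.5 * .nM

  vn_vc <- geometry$v_nuc / geometry$v_cyt
  vc_vn <- geometry$v_cyt / geometry$v_nuc

  rhs <- function(t, state, inputs) {
    p <- params
    s <- state
    os <- osmostress(inputs$NaCl, s[["Int_osmo"]], p$w)
    phos <- p$k22 * s[["Hog1c"]] * s[["Pbs2pp"]]
    d <- c(
      Pbs2    = -p$k20 * s[["Pbs2"]] * os + p$k21 * s[["Pbs2pp"]],
      Pbs2pp  =  p$k20 * s[["Pbs2"]] * os - p$k21 * s[["Pbs2pp"]],
      Hog1c   = -phos + p$k23 * s[["Hog1ppc"]] -
                 p$k27 * s[["Hog1c"]] + p$k28 * s[["Hog1n"]] * vn_vc,
      Hog1ppc =  phos - p$k23 * s[["Hog1ppc"]] -
                 p$k26 * s[["Hog1ppc"]] + p$k25 * s[["Hog1ppn"]] * vn_vc,
      Hog1n   =  p$k24 * s[["Hog1ppn"]] + p$k27 * s[["Hog1c"]] * vc_vn -
                 p$k28 * s[["Hog1n"]],
      Hog1ppn = -p$k24 * s[["Hog1ppn"]] + p$k26 * s[["Hog1ppc"]] * vc_vn -
                 p$k25 * s[["Hog1ppn"]],
      Int_osmo = p$k29 * s[["Hog1ppc"]] -
                 p$k30 * s[["Int_osmo"]] / (1 + p$Ki30 * os),
      MFalpha1_mRNA = p$k31 * s[["Hog1ppn"]] - p$k31_deg * s[["MFalpha1_mRNA"]],
      prepro_Alpha  = p$k32 * s[["MFalpha1_mRNA"]] - p$k33 * s[["prepro_Alpha"]],
      Alpha_in_medium = p$k33 * s[["prepro_Alpha"]] /
                        dilution_factor(t / 3600, culture)
    )
    d
  }
  new_cell_model("salt_cell", species, initial, rhs, params, geometry, culture)
}

#' @rdname cell_models
#' @export
dox_cell <- function(params = default_parameters(),
                     geometry = cell_geometry(),
                     culture = culture_config()) {
  species <- c("MFalpha1_mRNA", "prepro_Alpha", "Alpha_in_medium")
  initial <- stats::setNames(numeric(3), species)
  rhs <- function(t, state, inputs) {
    p <- params
    c(
      MFalpha1_mRNA = p$k38 / (1 + p$Ki38 * inputs$DOX) -
                      p$k31_deg * state[["MFalpha1_mRNA"]],
      prepro_Alpha  = p$k32 * state[["MFalpha1_mRNA"]] -
                      p$k33 * state[["prepro_Alpha"]],
      Alpha_in_medium = p$k33 * state[["prepro_Alpha"]] /
                        dilution_factor(t / 3600, culture)
    )
  }
  new_cell_model("dox_cell", species, initial, rhs, params, geometry, culture)
}

#' @rdname cell_models
#' @export
gal_cell <- function(params = default_parameters(),
                     geometry = cell_geometry(),
                     culture = culture_config(),
                     precultured = FALSE) {
  species <- c("MFalpha1_mRNA", "prepro_Alpha", "Alpha_in_medium")
  initial <- stats::setNames(numeric(3), species)
  delay_s <- if (precultured) 0 else 3 * 3600
  rhs <- function(t, state, inputs) {
    p <- params
    k_gal <- if (t < delay_s) 0 else p$k37
    c(
      MFalpha1_mRNA = k_gal * inputs$Gal -
                      p$k31_deg * state[["MFalpha1_mRNA"]],
      prepro_Alpha  = p$k32 * state[["MFalpha1_mRNA"]] -
                      p$k33 * state[["prepro_Alpha"]],
      Alpha_in_medium = p$k33 * state[["prepro_Alpha"]] /
                        dilution_factor(t / 3600, culture)
    )
  }
  new_cell_model("gal_cell", species, initial, rhs, params, geometry, culture,
                 extra = list(switch_times = if (delay_s > 0) delay_s else NULL,
                              precultured = precultured))
}

#' @rdname cell_models
#' @export
reporter_cell <- function(params = default_parameters(),
                          geometry = cell_geometry()) {
  species <- c("Ste2", "Ste2_Ph", "inactive_Ste5complex", "active_Ste5complex",
               "Fus3c", "Fus3ppc", "Fus3n", "Fus3ppn",
               "GFP_mRNA", "nascent_GFP", "mature_GFP")
  initial <- stats::setNames(numeric(length(species)), species)
  initial["Ste2"]  <- 378 * .nM
  initial["inactive_Ste5complex"] <- 38.5 * .nM
  initial["Fus3c"] <- 406 * .nM
  initial["Fus3n"] <- 568.4 * .nM

  vn_vc <- geometry$v_nuc / geometry$v_cyt
  vc_vn <- geometry$v_cyt / geometry$v_nuc

  rhs <- function(t, state, inputs) {
    p <- params
    s <- state
    alpha <- inputs$alpha
    bind  <- p$k1 * s[["Ste2"]] * alpha
    act   <- p$k6 * s[["inactive_Ste5complex"]] * s[["Ste2_Ph"]]
    phos  <- p$k8 * s[["Fus3c"]] * s[["active_Ste5complex"]]
    c(
      Ste2    = p$v_Ste2_production - bind + p$k2 * s[["Ste2_Ph"]] -
                p$k4 * s[["Ste2"]],
      Ste2_Ph = bind - p$k2 * s[["Ste2_Ph"]] - p$k5 * s[["Ste2_Ph"]],
      inactive_Ste5complex = -act + p$k7 * s[["active_Ste5complex"]],
      active_Ste5complex   =  act - p$k7 * s[["active_Ste5complex"]],
      Fus3c   = -p$k_nuc_imp * s[["Fus3c"]] +
                 p$k_nuc_exp * s[["Fus3n"]] * vn_vc - phos +
                 p$k9 * s[["Fus3ppc"]],
      Fus3ppc =  p$k_small * p$k_nuc_exp * s[["Fus3ppn"]] * vn_vc -
                 p$k_nuc_imp * s[["Fus3ppc"]] + phos - p$k9 * s[["Fus3ppc"]],
      Fus3n   =  p$k_nuc_imp * s[["Fus3c"]] * vc_vn -
                 p$k_nuc_exp * s[["Fus3n"]] + p$k10 * s[["Fus3ppn"]],
      Fus3ppn = -p$k_small * p$k_nuc_exp * s[["Fus3ppn"]] +
                 p$k_nuc_imp * s[["Fus3ppc"]] * vc_vn - p$k10 * s[["Fus3ppn"]],
      GFP_mRNA    = p$k34 * s[["Fus3ppn"]] - p$k34_deg * s[["GFP_mRNA"]],
      nascent_GFP = p$k35 * s[["GFP_mRNA"]] - p$k36 * s[["nascent_GFP"]],
      mature_GFP  = p$k36 * s[["nascent_GFP"]]
    )
  }
  new_cell_model("reporter_cell", species, initial, rhs, params, geometry,
                 culture = NULL)
}
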