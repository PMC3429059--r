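# Finite-difference parameter sensitivity of the gate's GFP output.

#' Time-dependent parameter sensitivity of the GFP output
#'
#' Scaled (relative) sensitivity coefficients of mature GFP with respect to
#' every kinetic parameter of the cells involved in the gate, every non-zero
#' initial concentration, the dilution coefficient and the cell doubling
#' time. For each quantity `p` the gate is re-integrated with `p` perturbed
#' by `h = max(delta * |p|, min_delta)` (forward difference) and
#'
#'   `S(t) = (p / GFP(t)) * (GFP_perturbed(t) - GFP(t)) / h`
#'
#' i.e. `d log GFP / d log p`. Where the baseline GFP is 0 the coefficient is
#' reported as 0.
#'
#' @param gate a [gate_spec()] (single-reporter gates).
#' @param inputs logical inputs in user units, as in [run_gate()]; the
#'   baseline must produce GFP by the last report time.
#' @param times_min report times in minutes (9 points in the 15-240 min
#'   range by default).
#' @param delta relative perturbation (1e-3).
#' @param min_delta absolute floor for the perturbation (1e-12).
#' @param ... passed to [run_gate()] (e.g. `preculture`).
#' @return object of class `sensitivity_table`: matrix of scaled
#'   coefficients, rows = parameters/initial conditions, columns = report
#'   times (minutes).
#' @export
#' @examples
#' \donttest{
#' st <- sensitivity_scan(gate_spec("identity"), list(nacl_M = 0.4))
#' rank_parameters(st, 240)[1:5, ]
#' }
sensitivity_scan <- function(gate, inputs,
                             times_min = c(15, 30, 60, 90, 120, 150, 180,
                                           210, 240),
                             delta = 1e-3, min_delta = 1e-12, ...) {
  stopifnot(inherits(gate, "gate_spec"), length(gate$reporters) == 1)
  hours <- max(times_min) / 60
  gfp_at <- function(g) {
    run <- run_gate(g, inputs, hours = hours, report_dt = 60, ...)
    tr <- run$trajectory
    col <- paste0(names(g$reporters)[1], ".mature_GFP")
    tr[[col]][match(times_min * 60, tr$time_s)]
  }
  base <- gfp_at(gate)
  # require a detectable baseline: 1e-6 nM is far below a single molecule
  if (base[length(base)] <= 1e-6) {
    stop("baseline mature GFP is 0 at the last report time; ",
         "sensitivities are undefined", call. = FALSE)
  }

  # quantities to perturb: kinetic parameters used by the involved cells,
  # non-zero initial concentrations, dilution coefficient, doubling time
  par_names <- .gate_parameter_names(gate)
  init <- initial_concentrations()
  init_names <- init$species[.gate_species_mask(gate, init$species)]

  perturb <- function(p0, apply_fun) {
    h <- max(delta * abs(p0), min_delta)
    gfp <- gfp_at(apply_fun(p0 + h))
    s <- ifelse(base == 0, 0, (p0 / base) * (gfp - base) / h)
    s
  }

  rows <- list()
  for (nm in par_names) {
    p0 <- gate$params[[nm]]
    rows[[nm]] <- perturb(p0, function(v) {
      g <- gate
      g$params[[nm]] <- v
      g
    })
  }
  for (nm in init_names) {
    conc0 <- init$conc_nM[init$species == nm]
    rows[[paste0("init.", nm)]] <- perturb(conc0, function(v) {
      g <- gate
      g$initial_override <- c(g$initial_override,
                              stats::setNames(v * 1e-9, nm))
      g
    })
  }
  rows[["dilution_coeff"]] <- perturb(gate$culture$dilution_coeff,
    function(v) {
      g <- gate
      g$culture <- culture_config(g$culture$density, g$culture$doubling_h, v)
      g
    })
  rows[["doubling_time_h"]] <- perturb(gate$culture$doubling_h,
    function(v) {
      g <- gate
      g$culture <- culture_config(g$culture$density, v,
                                  g$culture$dilution_coeff)
      g
    })

  tab <- do.call(rbind, rows)
  colnames(tab) <- times_min
  class(tab) <- c("sensitivity_table", class(tab))
  tab
}

# kinetic parameters that can influence the given gate's output
.gate_parameter_names <- function(gate) {
  shared <- c("k31_deg", "k32", "k33")
  by_sender <- list(
    salt = c("w", paste0("k", 20:31), "Ki30"),
    dox  = c("k38", "Ki38"),
    gal  = "k37"
  )
  reporter <- c(paste0("k", c(1, 2, 4:10)), "v_Ste2_production",
                "k_nuc_imp", "k_nuc_exp", "k_small",
                "k34", "k34_deg", "k35", "k36")
  unique(c(unlist(by_sender[gate$senders]), shared, reporter))
}

.gate_species_mask <- function(gate, species) {
  salt_species <- c("Pbs2", "Hog1n", "Hog1c")
  rep_species <- c("Ste2", "inactive_Ste5complex", "Fus3n", "Fus3c")
  species %in% c(if ("salt" %in% gate$senders) salt_species, rep_species)
}

#' Rank parameters by influence at a time point
#'
#' @param table a [sensitivity_scan()] result.
#' @param t_min time point (minutes; must be a column of the table).
#' @return data.frame sorted by decreasing `|S|`, ties broken by name. An
#'   all-zero column yields an empty ranking with a warning.
#' @export
rank_parameters <- function(table, t_min) {
  col <- as.character(t_min)
  if (!col %in% colnames(table)) {
    stop("t = ", t_min, " min is not in the table", call. = FALSE)
  }
  s <- table[, col]
  if (all(s == 0)) {
    warning("all sensitivity coefficients are zero at t = ", t_min, " min",
            call. = FALSE)
    return(data.frame(parameter = character(0), s = numeric(0)))
  }
  ord <- order(-abs(s), names(s))
  data.frame(parameter = names(s)[ord], s = unname(s[ord]),
             row.names = NULL)
}
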