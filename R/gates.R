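# Logic-gate assembly: sender + reporter populations coupled through the
# shared alpha-factor concentration in the medium.

.gate_defs <- list(
  identity    = list(senders = "salt",            inputs = "nacl_M"),
  not         = list(senders = "dox",             inputs = "dox_ug_ml"),
  or          = list(senders = c("salt", "gal"),  inputs = c("nacl_M", "gal_percent")),
  implies     = list(senders = c("dox", "gal"),   inputs = c("dox_ug_ml", "gal_percent")),
  # gate "reprogramming": the IMPLIES assembly read with glucose (which shuts
  # off GAL1 transcription) as the second input computes NAND
  nand        = list(senders = c("dox", "gal"),   inputs = c("dox_ug_ml", "glucose")),
  three_value = list(senders = "salt",            inputs = "nacl_M")
)

#' Define a logic gate
#'
#' A gate couples one or two sender populations to one (or, for the
#' three-value gate, two) reporter populations through the alpha-factor
#' concentration in the shared medium. Built-in gates:
#'
#' | gate | senders | logical inputs |
#' |------|---------|----------------|
#' | `identity` | salt-cell | `nacl_M` |
#' | `not` | dox-cell | `dox_ug_ml` |
#' | `or` | salt-cell, gal-cell | `nacl_M`, `gal_percent` |
#' | `implies` | dox-cell, gal-cell | `dox_ug_ml`, `gal_percent` |
#' | `nand` | dox-cell, gal-cell | `dox_ug_ml`, `glucose` (0/1) |
#' | `three_value` | salt-cell | `nacl_M` |
#'
#' `nand` is the IMPLIES assembly "reprogrammed" by treating glucose as the
#' second input: glucose present means no galactose induction (`Gal = 0`),
#' glucose absent means growth on 2% galactose. The `three_value` gate adds a
#' second reporter population carrying the low-affinity Ste2-F262A receptor
#' (`k1 = 4e11 ml/(mmol s)`, half the wild-type affinity) and is read out
#' after 5 h.
#'
#' A reporter cell is scored GFP-positive when its cytoplasmic mature-GFP
#' concentration reaches `threshold_uM` (default 4.5 uM; comparison is `>=`).
#'
#' @param gate gate name (see table above).
#' @param threshold_uM GFP positivity threshold, micromolar.
#' @param readout_h readout time in hours (4 by default, 5 for the
#'   three-value gate).
#' @param params kinetic parameters, see [default_parameters()].
#' @param geometry a [cell_geometry()].
#' @param culture a [culture_config()] applied to every sender population.
#' @param mutant_k1 receptor-binding constant of the second reporter
#'   population of the three-value gate, ml/(mmol s).
#'
#' @return object of class `gate_spec`.
#' @export
#' @examples
#' gate_spec("identity")
gate_spec <- function(gate = names(.gate_defs), threshold_uM = 4.5,
                      readout_h = if (match.arg(gate) == "three_value") 5 else 4,
                      params = default_parameters(),
                      geometry = cell_geometry(),
                      culture = culture_config(),
                      mutant_k1 = 4e11) {
  gate <- match.arg(gate)
  def <- .gate_defs[[gate]]
  reporters <- if (gate == "three_value") {
    list(reporter_wt = params$k1, reporter_mut = mutant_k1)
  } else {
    list(reporter = params$k1)
  }
  structure(
    list(gate = gate, senders = def$senders, input_names = def$inputs,
         reporters = reporters, threshold_uM = threshold_uM,
         readout_h = readout_h, params = params, geometry = geometry,
         culture = culture),
    class = "gate_spec"
  )
}

#' @export
print.gate_spec <- function(x, ...) {
  cat("gate <", toupper(x$gate), ">: senders {",
      paste(x$senders, collapse = ", "), "}, reporters {",
      paste(names(x$reporters), collapse = ", "), "}\n  inputs: ",
      paste(x$input_names, collapse = ", "), "; threshold ", x$threshold_uM,
      " uM GFP at ", x$readout_h, " h\n", sep = "")
  invisible(x)
}

# map user-facing logical inputs to canonical chemical signals (mmol/ml)
.canonical_inputs <- function(gate, inputs) {
  bad <- setdiff(names(inputs), gate$input_names)
  if (length(bad)) {
    stop("unknown input(s) for ", toupper(gate$gate), " gate: ",
         paste(bad, collapse = ", "), " (expected: ",
         paste(gate$input_names, collapse = ", "), ")", call. = FALSE)
  }
  get0 <- function(nm) if (is.null(inputs[[nm]])) 0 else inputs[[nm]]
  gal <- if (gate$gate == "nand") {
    # glucose input: 1 = glucose medium (GAL1 off), 0 = 2% galactose
    glc <- get0("glucose")
    stopifnot(glc %in% c(0, 1, FALSE, TRUE))
    gal_to_canonical(if (as.logical(glc)) 0 else 2)
  } else {
    gal_to_canonical(get0("gal_percent"))
  }
  list(NaCl = nacl_to_canonical(get0("nacl_M")),
       DOX = dox_to_canonical(get0("dox_ug_ml")),
       Gal = gal)
}

.sender_model <- function(type, params, geometry, culture, precultured) {
  switch(type,
         salt = salt_cell(params, geometry, culture),
         dox  = dox_cell(params, geometry, culture),
         gal  = gal_cell(params, geometry, culture, precultured = precultured),
         stop("unknown sender type: ", type, call. = FALSE))
}

#' Pre-culture conditioning of sender populations
#'
#' Establishes the intracellular state of the sender cells before the gate is
#' started. Gal-cells are pre-grown in medium with 2% galactose and dox-cells
#' in medium without doxycycline, both simulated for `hours`; the resulting
#' MFalpha1-mRNA and prepro-alpha pools become the senders' initial
#' conditions. Any alpha-factor excreted during pre-culturing is removed by
#' the media exchange, so `Alpha_in_medium` always starts at 0.
#'
#' Modes:
#' * `"simulated"`: pools from the pre-simulation (the default);
#' * `"zero"`: pools reset to zero (models a handling period long enough for
#'   the short-lived mRNA and precursor to decay completely);
#' * `"none"`: no pre-culture; gal-cells then incur the 3-h GAL induction
#'   delay during the gate run.
#'
#' A `handling_delay_min > 0` lets the pre-accumulated mRNA and precursor
#' decay exponentially (rates `k31_deg` and `k33`) for that many minutes
#' between the media exchange and the start of the gate.
#'
#' @param gate a [gate_spec()].
#' @param hours pre-culture duration (16 h by default).
#' @param mode `"simulated"`, `"zero"` or `"none"`.
#' @param handling_delay_min decay period between pre-culture and gate start.
#' @return named list mapping sender type to its initial state (canonical
#'   mmol/ml), with attribute `mode`.
#' @export
#' @examples
#' pc <- precondition(gate_spec("implies"))
#' pc$gal[["MFalpha1_mRNA"]] * 1e9  # 0.571 nM
precondition <- function(gate, hours = 16,
                         mode = c("simulated", "zero", "none"),
                         handling_delay_min = 0) {
  mode <- match.arg(mode)
  stopifnot(hours > 0, handling_delay_min >= 0)
  p <- gate$params
  out <- list()
  for (type in gate$senders) {
    model <- .sender_model(type, p, gate$geometry, gate$culture,
                           precultured = TRUE)
    init <- model$initial
    if (type == "salt") {
      if (mode == "simulated" && !any(c("gal", "dox") %in% gate$senders)) {
        warning("pre-culturing a salt-cell is a no-op: without osmostress ",
                "it converges to the zero expression state", call. = FALSE)
      }
      out[[type]] <- init
      next
    }
    if (mode == "simulated") {
      pre_inputs <- list(Gal = gal_to_canonical(2), DOX = 0)
      tr <- simulate_cell(model, pre_inputs, hours = hours,
                          report_dt = hours * 3600)
      fin <- utils::tail(tr, 1)
      init["MFalpha1_mRNA"] <- fin[["MFalpha1_mRNA"]] * 1e-9
      init["prepro_Alpha"]  <- fin[["prepro_Alpha"]] * 1e-9
      if (handling_delay_min > 0) {
        dt <- handling_delay_min * 60
        init["MFalpha1_mRNA"] <- init[["MFalpha1_mRNA"]] * exp(-p$k31_deg * dt)
        init["prepro_Alpha"]  <- init[["prepro_Alpha"]] * exp(-p$k33 * dt)
      }
    }
    init["Alpha_in_medium"] <- 0  # media exchange removes excreted alpha
    out[[type]] <- init
  }
  attr(out, "mode") <- mode
  out
}

# Build the coupled ODE system: each sender population contributes its own
# intracellular species plus an export flux into the single shared
# Alpha_in_medium pool; reporter populations read that pool without depleting
# it (per-cell consumption is negligible at culture scale), so one
# representative cell per reporter variant suffices.
.build_assembly <- function(gate, preculture) {
  p <- gate$params
  precultured <- attr(preculture, "mode") != "none"
  senders <- lapply(gate$senders, function(type) {
    m <- .sender_model(type, p, gate$geometry, gate$culture, precultured)
    m$initial <- preculture[[type]]
    m
  })
  names(senders) <- gate$senders
  # reporter variants differ only in the receptor-binding constant
  reporters <- lapply(gate$reporters, function(k1) {
    pr <- p
    pr$k1 <- k1
    reporter_cell(pr, gate$geometry)
  })

  species <- character(0)
  idx <- list()
  for (nm in names(senders)) {
    intra <- setdiff(senders[[nm]]$species, "Alpha_in_medium")
    idx[[nm]] <- length(species) + seq_along(intra)
    species <- c(species, paste(nm, intra, sep = "."))
  }
  alpha_i <- length(species) + 1L
  species <- c(species, "Alpha_in_medium")
  for (nm in names(reporters)) {
    idx[[nm]] <- length(species) + seq_along(reporters[[nm]]$species)
    species <- c(species, paste(nm, reporters[[nm]]$species, sep = "."))
  }

  initial <- stats::setNames(numeric(length(species)), species)
  for (nm in names(senders)) {
    intra <- setdiff(senders[[nm]]$species, "Alpha_in_medium")
    initial[idx[[nm]]] <- senders[[nm]]$initial[intra]
  }
  for (nm in names(reporters)) {
    initial[idx[[nm]]] <- reporters[[nm]]$initial
  }
  # per-species initial-concentration overrides (sensitivity analysis):
  # names are bare species names, applied to every population carrying them
  if (!is.null(gate$initial_override)) {
    for (nm in names(gate$initial_override)) {
      hit <- grep(paste0("\\.", nm, "$"), species)
      if (!length(hit)) stop("initial override for unknown species: ", nm,
                             call. = FALSE)
      initial[hit] <- gate$initial_override[[nm]]
    }
  }

  sender_species <- lapply(senders, function(m)
    setdiff(m$species, "Alpha_in_medium"))

  rhs <- function(t, state, inputs) {
    d <- numeric(length(state))
    alpha <- state[[alpha_i]]
    d_alpha <- 0
    for (nm in names(senders)) {
      loc <- stats::setNames(c(state[idx[[nm]]], alpha),
                             c(sender_species[[nm]], "Alpha_in_medium"))
      dl <- senders[[nm]]$rhs(t, loc, inputs)
      d[idx[[nm]]] <- dl[sender_species[[nm]]]
      d_alpha <- d_alpha + dl[["Alpha_in_medium"]]
    }
    d[alpha_i] <- d_alpha
    for (nm in names(reporters)) {
      loc <- stats::setNames(state[idx[[nm]]], reporters[[nm]]$species)
      d[idx[[nm]]] <- reporters[[nm]]$rhs(t, loc, list(alpha = alpha))
    }
    stats::setNames(d, species)
  }

  switch_times <- unique(unlist(lapply(senders, function(m) m$switch_times)))
  list(species = species, initial = initial, rhs = rhs,
       switch_times = switch_times, reporter_names = names(reporters))
}

#' Run a logic gate
#'
#' Preconditions the sender populations, integrates the coupled
#' sender/reporter system over `[0, hours]` and scores each reporter
#' population against the GFP threshold at the readout time.
#'
#' @param gate a [gate_spec()].
#' @param inputs named list of logical inputs in user-facing units (see
#'   [gate_spec()]), e.g. `list(nacl_M = 0.4)` or
#'   `list(dox_ug_ml = 10, gal_percent = 2)`. Missing inputs default to 0.
#' @param preculture either the result of [precondition()] or a list of
#'   arguments for it, e.g. `list(mode = "zero")`.
#' @param hours simulation length (defaults to the gate's readout time).
#' @param report_dt report grid spacing, seconds.
#' @param rtol,atol integration tolerances.
#' @return object of class `gate_run`: list with elements `trajectory`
#'   (species in nM, sender species prefixed by sender type, reporter species
#'   by reporter name), `gfp_uM` (named, at readout), `verdict` (named
#'   logical), `gate`, `inputs`.
#' @export
#' @examples
#' run <- run_gate(gate_spec("identity"), list(nacl_M = 0.4))
#' run$gfp_uM
#' run$verdict
run_gate <- function(gate, inputs = list(), preculture = list(),
                     hours = gate$readout_h, report_dt = 60,
                     rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(gate, "gate_spec"))
  canon <- .canonical_inputs(gate, inputs)
  if (!is.list(preculture) || is.null(attr(preculture, "mode"))) {
    if (is.null(preculture$mode) && !any(c("gal", "dox") %in% gate$senders)) {
      # nothing to pre-accumulate in salt-only gates
      preculture$mode <- "none"
    }
    preculture <- do.call(precondition, c(list(gate = gate), preculture))
  }
  asm <- .build_assembly(gate, preculture)
  mat <- .integrate_rhs(asm$rhs, asm$initial, canon, hours * 3600,
                        report_dt = report_dt,
                        switch_times = asm$switch_times,
                        rtol = rtol, atol = atol)
  tr <- new_trajectory(mat, paste0("gate:", gate$gate), inputs)
  t_read <- min(gate$readout_h, hours) * 3600
  row <- which.min(abs(tr$time_s - t_read))
  gfp <- vapply(asm$reporter_names, function(nm)
    tr[[paste0(nm, ".mature_GFP")]][row] / 1000, numeric(1))  # nM -> uM
  structure(
    list(trajectory = tr, gfp_uM = gfp, verdict = gfp >= gate$threshold_uM,
         gate = gate$gate, inputs = inputs, threshold_uM = gate$threshold_uM,
         readout_h = t_read / 3600),
    class = "gate_run"
  )
}

#' @export
print.gate_run <- function(x, ...) {
  cat("gate <", toupper(x$gate), "> at ",
      paste(names(x$inputs), unlist(x$inputs), sep = "=", collapse = ", "),
      "\n  GFP at ", x$readout_h, " h: ",
      paste(names(x$gfp_uM), sprintf("%.3f uM", x$gfp_uM), sep = ": ",
            collapse = ", "),
      "\n  verdict (>= ", x$threshold_uM, " uM): ",
      paste(names(x$verdict), ifelse(x$verdict, "POSITIVE", "negative"),
            sep = ": ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Truth table of a gate
#'
#' Evaluates the gate over a grid of input levels and returns the verdicts.
#'
#' @param gate a [gate_spec()].
#' @param levels named list of input levels (user-facing units), one entry
#'   per logical input; the grid is their cross product.
#' @param ... passed on to [run_gate()].
#' @return data.frame with one row per input combination: the inputs, the
#'   GFP concentration (uM) per reporter, and the verdicts.
#' @export
#' @examples
#' \donttest{
#' truth_table(gate_spec("or"),
#'             levels = list(nacl_M = c(0, 0.4), gal_percent = c(0, 2)))
#' }
truth_table <- function(gate, levels, ...) {
  stopifnot(length(levels) > 0, !is.null(names(levels)))
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    run <- run_gate(gate, as.list(grid[i, , drop = FALSE]), ...)
    c(as.list(grid[i, , drop = FALSE]),
      stats::setNames(as.list(run$gfp_uM),
                      paste0("gfp_uM.", names(run$gfp_uM))),
      stats::setNames(as.list(run$verdict),
                      paste0("positive.", names(run$verdict))))
  })
  out <- do.call(rbind, lapply(res, as.data.frame))
  names(out) <- sub("^(gfp_uM|positive)\\.reporter$", "\\1", names(out))
  rownames(out) <- NULL
  out
}

#' Deterministic three-value gate readout
#'
#' Runs the three-value IDENTITY gate (wild-type and Ste2-F262A reporter
#' populations) for each salt level and reports both populations' GFP at the
#' 5-h readout. The intended response: no population positive without salt,
#' only the wild-type reporter positive at 0.1 M, both positive at 0.4 M.
#'
#' @param salt_M NaCl levels in mol/L.
#' @param gate a `three_value` [gate_spec()].
#' @param ... passed on to [run_gate()].
#' @return data.frame with one row per salt level: GFP (uM) and verdict for
#'   each reporter population.
#' @export
three_value_gate <- function(salt_M = c(0, 0.1, 0.4),
                             gate = gate_spec("three_value"), ...) {
  stopifnot(gate$gate == "three_value")
  rows <- lapply(salt_M, function(s) {
    run <- run_gate(gate, list(nacl_M = s), ...)
    data.frame(nacl_M = s,
               gfp_uM.reporter_wt = run$gfp_uM[["reporter_wt"]],
               gfp_uM.reporter_mut = run$gfp_uM[["reporter_mut"]],
               positive.reporter_wt = run$verdict[["reporter_wt"]],
               positive.reporter_mut = run$verdict[["reporter_mut"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
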