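# Deterministic integration of cell models and gate assemblies (deSolve).

# Wraps a model rhs (named-vector in/out, canonical units) for deSolve and
# integrates over [0, t_end_s], splitting at any switch times (the 3-h GAL
# induction delay) so the stiff solver never steps across a discontinuity.
.integrate_rhs <- function(rhs, initial, inputs, t_end_s, report_dt = 60,
                           switch_times = NULL, rtol = 1e-8, atol = 1e-12) {
  stopifnot(t_end_s > 0)
  times <- unique(c(seq(0, t_end_s, by = report_dt), t_end_s))
  func <- function(t, y, parms) {
    names(y) <- names(initial)
    list(unname(rhs(t, y, inputs)))
  }
  segs <- sort(unique(c(0, switch_times[switch_times > 0 &
                                        switch_times < t_end_s], t_end_s)))
  out <- NULL
  y <- initial
  for (i in seq_len(length(segs) - 1)) {
    tt <- times[times >= segs[i] & times <= segs[i + 1]]
    tt <- unique(c(segs[i], tt, segs[i + 1]))
    # tcrit pins the solver inside the segment so the right-hand side is
    # never evaluated beyond a regime switch (e.g. the 3-h GAL induction)
    sol <- deSolve::lsoda(y = unname(y), times = tt, func = func, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 200000,
                          tcrit = segs[i + 1])
    if (attr(sol, "istate")[1] < 0) {
      stop("integration failed at t = ", utils::tail(sol[, 1], 1),
           " s (segment ", i, ")", call. = FALSE)
    }
    y <- stats::setNames(sol[nrow(sol), -1], names(initial))
    keep <- sol[, 1] %in% times
    if (!is.null(out)) keep[1] <- FALSE  # drop duplicated segment boundary
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  colnames(out) <- c("time_s", names(initial))
  out[!duplicated(out[, "time_s"]), , drop = FALSE]
}

new_trajectory <- function(mat, model_id, inputs) {
  df <- as.data.frame(mat)
  # species columns from canonical mmol/ml to nM
  df[, -1] <- df[, -1, drop = FALSE] * 1e9
  attr(df, "model_id") <- model_id
  attr(df, "inputs") <- inputs
  class(df) <- c("trajectory", "data.frame")
  df
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory <", attr(x, "model_id"), ">: ", nrow(x), " time points, ",
      x$time_s[nrow(x)], " s; species in nM\n", sep = "")
  print(utils::head(as.data.frame(x), 3))
  cat("...\n")
  invisible(x)
}

#' Integrate a cell model
#'
#' Solves the model ODEs with a stiff-capable integrator (`deSolve::lsoda`)
#' and returns the solution on a regular report grid. Species values are
#' reported in nM.
#'
#' @param model a `cell_model` (see [salt_cell()]).
#' @param inputs named list of input signals in canonical mmol/ml, e.g.
#'   `list(NaCl = 0.4)`, `list(DOX = 0)`, `list(Gal = 0.11)`,
#'   `list(alpha = 5e-9)`. Missing inputs default to 0.
#' @param hours simulation end time in hours.
#' @param report_dt report grid spacing in seconds (default 60).
#' @param rtol,atol relative/absolute integration tolerances (canonical
#'   concentration units).
#'
#' @return a `trajectory`: data.frame with column `time_s` followed by one
#'   column per species (nM).
#' @export
#' @examples
#' tr <- simulate_cell(dox_cell(), list(DOX = 0), hours = 16)
#' tail(tr, 1)[, c("MFalpha1_mRNA", "prepro_Alpha")]
simulate_cell <- function(model, inputs = list(), hours, report_dt = 60,
                          rtol = 1e-8, atol = 1e-12) {
  inputs <- .fill_inputs(inputs)
  mat <- .integrate_rhs(model$rhs, model$initial, inputs, hours * 3600,
                        report_dt = report_dt,
                        switch_times = model$switch_times,
                        rtol = rtol, atol = atol)
  new_trajectory(mat, model$name, inputs)
}

.fill_inputs <- function(inputs) {
  base <- list(NaCl = 0, DOX = 0, Gal = 0, alpha = 0)
  if (any(unlist(inputs) < 0)) stop("input signals must be >= 0",
                                    call. = FALSE)
  base[names(inputs)] <- inputs
  base
}

#' Steady state of a single-cell model under constant inputs
#'
#' Finds the steady state by long integration with convergence detection:
#' integration proceeds in chunks until the largest right-hand-side entry
#' falls below `tol` (mmol/ml per second). Species without a steady state
#' (`Alpha_in_medium`, `mature_GFP`: pure accumulators with no sink) are
#' excluded from the residual and reported as `NA`.
#'
#' @param model a `cell_model`.
#' @param inputs named list of constant inputs (canonical units).
#' @param tol convergence tolerance on `max |d/dt|`, mmol/ml/s.
#' @param chunk_h chunk length in hours.
#' @param max_h give up after this many hours.
#' @return named numeric vector of steady-state concentrations in nM, with
#'   attribute `residual` (mmol/ml/s).
#' @export
#' @examples
#' ss <- steady_state(dox_cell(), list(DOX = 0))
#' ss[["MFalpha1_mRNA"]]  # 0.866 nM
steady_state <- function(model, inputs = list(), tol = 1e-15,
                         chunk_h = 24, max_h = 2000) {
  if (!is.null(model$switch_times)) {
    stop("steady_state requires an autonomous model; use precultured ",
         "gal-cells (no induction delay)", call. = FALSE)
  }
  inputs <- .fill_inputs(inputs)
  accum <- intersect(c("Alpha_in_medium", "mature_GFP"), model$species)
  # accumulator species have no sink: freeze the dilution-driven export by
  # evaluating the residual on the remaining species only
  y <- model$initial
  elapsed <- 0
  repeat {
    mat <- .integrate_rhs(model$rhs, y, inputs, chunk_h * 3600,
                          report_dt = chunk_h * 3600,
                          rtol = 1e-10, atol = 1e-15)
    y <- stats::setNames(mat[nrow(mat), -1], model$species)
    elapsed <- elapsed + chunk_h
    d <- model$rhs(0, y, inputs)
    resid <- max(abs(d[setdiff(model$species, accum)]))
    if (resid < tol) break
    if (elapsed >= max_h) {
      stop("no steady state within ", max_h, " h (residual ",
           signif(resid, 3), " mmol/ml/s)", call. = FALSE)
    }
  }
  out <- y * 1e9
  out[accum] <- NA_real_
  attr(out, "residual") <- resid
  attr(out, "hours") <- elapsed
  out
}

#' Write a trajectory to CSV
#'
#' Plain comma-separated output: column `time_s` (seconds, integer grid)
#' followed by species concentrations in nM; header row included.
#'
#' @param trajectory a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
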