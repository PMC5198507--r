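#' Read a model configuration file
#'
#' Parses a YAML (or JSON, a YAML subset) model configuration into a
#' [viral_model()].  The schema has five sections:
#' \preformatted{
#' growth:    {form: logistic, params: {lambda: 10, d: 0.01, r1: 0.6, K: 500}}
#' incidence: {form: exp_shift, params: {beta: 0.3, b1: 0.01, c1: 0.01}}
#' removals:  {g1: identity, g2: identity, g3: identity, g4: identity}
#' rates:     {a: 0.5, b: 0.15, c: 0.1, k: 0.4, u: 3, p: 1, q: 1,
#'             r: 1.5, h: 1, m1: 0.01, m2: 0.01}
#' delays:    {tau1: 2, tau2: 5, tau3: 0}
#' }
#' Removal entries may be a bare form name or `{form: ..., params: ...}`.
#' Unknown top-level keys, unknown form names, missing rates and negative
#' delays are schema errors; all violations found are reported together.
#'
#' @param path path to the configuration file.
#' @return A validated [viral_model()].
#' @examples
#' cfg <- system.file("extdata", "example18.yaml", package = "viraldelay")
#' read_model_config(cfg)
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(...) errs <<- c(errs, paste0(...))

  wanted <- c("growth", "incidence", "removals", "rates", "delays")
  extra <- setdiff(names(cfg), wanted)
  if (length(extra)) note("unknown section(s): ", paste(extra, collapse = ", "))
  for (sec in wanted) if (is.null(cfg[[sec]]))
    note("missing section: ", sec)
  if (length(errs)) stop("config schema errors:\n  ",
                         paste(errs, collapse = "\n  "))

  build_form <- function(ctor, spec, what) {
    tryCatch(do.call(ctor, c(list(form = spec$form), spec$params)),
             error = function(e) {
               note(what, ": ", conditionMessage(e))
               NULL
             })
  }
  check_sec <- function(spec, what) {
    extra <- setdiff(names(spec), c("form", "params"))
    if (length(extra))
      note(what, ": unknown key(s) ", paste(extra, collapse = ", "))
    if (is.null(spec$form)) note(what, ": missing 'form'")
  }
  check_sec(cfg$growth, "growth")
  check_sec(cfg$incidence, "incidence")
  growth <- build_form(growth_form, cfg$growth, "growth")
  incid <- build_form(incidence_form, cfg$incidence, "incidence")

  rnames <- paste0("g", 1:4)
  extra <- setdiff(names(cfg$removals), rnames)
  if (length(extra))
    note("removals: unknown key(s) ", paste(extra, collapse = ", "))
  removals <- lapply(rnames, function(nm) {
    spec <- cfg$removals[[nm]]
    if (is.null(spec)) {
      note("removals: missing ", nm)
      return(NULL)
    }
    if (is.character(spec)) spec <- list(form = spec)
    check_sec(spec, paste0("removals$", nm))
    build_form(removal_form, spec, paste0("removals$", nm))
  })

  if (length(errs)) stop("config schema errors:\n  ",
                         paste(errs, collapse = "\n  "))
  mod <- tryCatch(
    viral_model(growth, incid, removals, rates = cfg$rates,
                delays = unlist(cfg$delays)),
    error = function(e) stop("config schema errors:\n  ",
                             conditionMessage(e))
  )
  mod
}

#' Worked example models
#'
#' The two benchmark parameterisations shipped with the package (as
#' `inst/extdata/example17.yaml` and `example18.yaml`):
#' \describe{
#'   \item{17 (`"ctl"`)}{logistic target-cell growth with an
#'     exponential-shift incidence; the CTL-only equilibrium E3 is the
#'     stable regime at \eqn{\tau_3 = 0} (R2 > 1, R4 < 1).}
#'   \item{18 (`"coexistence"`)}{linear growth with Crowley-Martin
#'     incidence; the coexistence equilibrium E4 is the stable regime at
#'     \eqn{\tau_3 = 0} (R3 > 1, R4 > 1).}
#' }
#' Both use identity removals.  Sweeping \eqn{\tau_3} through
#' \{0.2, 2, 4, 15\} (example 17) or \{0.1, 2.5, 6, 16\} (example 18)
#' alternates convergence and sustained oscillation: stability switches and
#' Hopf bifurcations driven by the immune delay.
#'
#' @param which `17`/`"ctl"` or `18`/`"coexistence"`.
#' @param tau3 immune-response delay to install (default 0).
#' @return A [viral_model()].
#' @export
example_model <- function(which = 17, tau3 = 0) {
  which <- as.character(which)
  file <- switch(which,
    "17" = , "ctl" = "example17.yaml",
    "18" = , "coexistence" = "example18.yaml",
    stop("unknown example: ", which)
  )
  path <- system.file("extdata", file, package = "viraldelay")
  set_tau3(read_model_config(path), tau3)
}

#' Write analysis outputs
#'
#' Structured writers for the package's result objects: trajectories and
#' delay sweeps as CSV (full precision), thresholds/equilibria/stability
#' reports as JSON.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @name write_outputs
NULL

#' @rdname write_outputs
#' @export
write_trajectory_csv <- function(x, path) {
  stopifnot(inherits(x, "viral_trajectory"))
  df <- data.frame(t = x$times, x$states)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outputs
#' @export
write_scan_csv <- function(x, path) {
  stopifnot(inherits(x, "tau3_scan"))
  utils::write.csv(x$grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outputs
#' @export
read_scan_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Thresholds, equilibria and regime as a JSON-ready report
#'
#' @param model a [viral_model()].
#' @param path optional path; when given, the report is written as JSON.
#' @return The report list (invisibly when written to file): `R0..R4`,
#'   `equilibria` (label, components, existence, residual) and `regime`.
#' @export
threshold_report <- function(model, path = NULL) {
  th <- reproduction_numbers(model)
  eqs <- equilibria(model)
  reg <- classify_regime(model, th)
  rep <- list(
    R0 = th$R0, R1 = th$R1, R2 = th$R2, R3 = th$R3, R4 = th$R4,
    equilibria = lapply(eqs, function(e)
      c(list(label = e$label), as.list(e$state),
        list(exists = e$exists, residual = e$residual))),
    regime = reg$label
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
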