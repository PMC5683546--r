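# Scenario configuration: a named bundle of region, UBT, hidden parameters,
# constants, uterotonic coverage and the population filter, round-trippable
# through YAML. Shipped fixtures under inst/extdata encode the published
# Table 1/Table 2 values verbatim.

#' Assemble a scenario configuration
#'
#' @param name Scenario name (must be unique within a scenario set).
#' @param region A [region_inputs()] object.
#' @param ubt A [ubt_spec()] object or `NULL` for a no-UBT scenario.
#' @param hidden A [hidden_params()] object.
#' @param constants A [model_constants()] object.
#' @param ut_coverage Per-setting uterotonic coverage.
#' @param filter `"all"` or `"nonsevere_only"`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(name = "base",
                            region = region_inputs(),
                            ubt = ubt_spec(),
                            hidden = hidden_params(),
                            constants = model_constants(),
                            ut_coverage = uterotonic_coverage(),
                            filter = c("all", "nonsevere_only")) {
  filter <- match.arg(filter)
  stopifnot(inherits(region, "region_inputs"), inherits(hidden, "hidden_params"),
            inherits(constants, "model_constants"))
  if (!is.null(ubt)) stopifnot(inherits(ubt, "ubt_spec"))
  ut_coverage <- assert_setting_map(ut_coverage, "ut_coverage")
  structure(list(name = as.character(name), region = region, ubt = ubt,
                 hidden = hidden, constants = constants,
                 ut_coverage = ut_coverage, filter = filter),
            class = "scenario_config")
}

# Re-run constructor validation after raw in-place edits (set_path).
revalidate_config <- function(config) {
  scenario_config(
    name = config$name,
    region = do.call(region_inputs, unclass(config$region)),
    ubt = if (is.null(config$ubt)) NULL else do.call(ubt_spec, unclass(config$ubt)),
    hidden = do.call(hidden_params, unclass(config$hidden)),
    constants = do.call(model_constants, unclass(config$constants)),
    ut_coverage = config$ut_coverage,
    filter = config$filter
  )
}

#' Read and validate a scenario configuration from YAML
#'
#' Unknown filter values, probabilities outside \[0, 1\] and setting shares
#' not summing to one raise validation errors naming the offending field.
#' Omitted blocks fall back to the package defaults (published base-case
#' values; placeholder hidden parameters).
#'
#' @param path Path to a YAML file.
#' @return An object of class `scenario_config`.
#' @seealso [write_scenario_config()]
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_val("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  config_from_list(raw, default_name = sub("\\.ya?ml$", "", basename(path)))
}

config_from_list <- function(raw, default_name = "scenario") {
  known_top <- c("name", "region", "ubt", "hidden", "constants",
                 "ut_coverage", "scenario")
  bad_top <- setdiff(names(raw), known_top)
  if (length(bad_top)) {
    stop_val("not a scenario config: unknown top-level field(s) ",
             paste(bad_top, collapse = ", "))
  }
  build <- function(block, fun) {
    if (is.null(block)) return(fun())
    known <- names(formals(fun))
    bad <- setdiff(names(block), known)
    if (length(bad)) stop_val("unknown config field(s): ",
                              paste(bad, collapse = ", "))
    do.call(fun, block)
  }
  ubt <- if (is.null(raw$ubt)) ubt_spec() else if (identical(raw$ubt, "none"))
    NULL else build(raw$ubt, ubt_spec)
  filter <- raw$scenario$filter %||% "all"
  if (!filter %in% c("all", "nonsevere_only")) {
    stop_val("unknown population filter '", filter,
             "' (expected 'all' or 'nonsevere_only')")
  }
  cf <- scenario_config(
    name = raw$name %||% default_name,
    region = build(raw$region, region_inputs),
    ubt = ubt,
    hidden = build(raw$hidden, hidden_params),
    constants = build(raw$constants, model_constants),
    ut_coverage = if (is.null(raw$ut_coverage)) uterotonic_coverage()
                  else unlist(raw$ut_coverage),
    filter = filter
  )
  # scenario-level efficacy overrides (used by sensitivity configs)
  ov <- raw$scenario$efficacy_overrides
  if (!is.null(ov)) {
    for (nm in names(ov)) {
      cf <- set_path(cf, paste0("ubt.", nm), ov[[nm]])
    }
    cf <- revalidate_config(cf)
  }
  cf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration to YAML
#'
#' @param config A [scenario_config()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  raw <- list(
    name = config$name,
    region = lapply(unclass(config$region), strip_names_if_map),
    ubt = if (is.null(config$ubt)) "none"
          else lapply(unclass(config$ubt), strip_names_if_map),
    hidden = lapply(unclass(config$hidden), strip_names_if_map),
    constants = unclass(config$constants),
    ut_coverage = as.list(config$ut_coverage),
    scenario = list(filter = config$filter)
  )
  yaml::write_yaml(raw, path, precision = 15L)
  invisible(path)
}

strip_names_if_map <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
}

#' Path to a shipped scenario configuration
#'
#' The package ships the five published scenarios as YAML fixtures:
#' `base`, `optimistic`, `pessimistic` (severe-stratum UBT efficacy 0.70,
#' 0.80, 0.60), `nonsevere_only` (device withheld above 1000 mL) and
#' `nonsevere_eff95` (nonsevere efficacy raised to 0.95), plus
#' `fitted_params` (hidden parameters fitted to the published outputs).
#'
#' @param name Fixture name without extension.
#' @return Absolute path to the installed YAML file.
#' @export
shipped_config <- function(name = c("base", "optimistic", "pessimistic",
                                    "nonsevere_only", "nonsevere_eff95",
                                    "fitted_params", "targets")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "ubtimpact")
  if (!nzchar(path)) stop_val("shipped config '", name, "' not found")
  path
}

#' Read a fitted hidden-parameter file
#'
#' @param path YAML file as written by [write_hidden_params()]; defaults to
#'   the shipped reference fit.
#' @return A [hidden_params()] object.
#' @export
read_hidden_params <- function(path = shipped_config("fitted_params")) {
  raw <- yaml::read_yaml(path)
  raw <- raw[names(raw) %in% names(formals(hidden_params))]
  do.call(hidden_params, raw)
}

#' Write hidden parameters to YAML
#'
#' @param hidden A [hidden_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hidden_params <- function(hidden, path) {
  stopifnot(inherits(hidden, "hidden_params"))
  yaml::write_yaml(lapply(unclass(hidden), strip_names_if_map), path,
                   precision = 15L)
  invisible(path)
}
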