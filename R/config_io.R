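#' Write an experiment configuration to JSON
#'
#' Serialises every sub-configuration (population, perturbation, retention,
#' extraction, scheme weights/territories, seed) so a full experiment can be
#' reproduced from one file.
#'
#' @param cfg An [experiment_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  pop <- unclass(cfg$population)
  pop$extraction <- unclass(pop$extraction)
  payload <- list(
    population = pop,
    perturbation = unclass(cfg$perturbation),
    retention = unclass(cfg$retention),
    extraction = unclass(cfg$extraction),
    scheme = cfg$scheme[c("segment", "territory", "weight")],
    min_rest_mbf = cfg$min_rest_mbf, dt_s = cfg$dt_s, seed = cfg$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read an experiment configuration from JSON
#'
#' Inverse of [write_config_json()]. Fields absent from the file keep their
#' defaults; unknown fields are an error (typo guard).
#'
#' @param path JSON file.
#' @return An [experiment_config()].
#' @export
read_config_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("population", "perturbation", "retention", "extraction",
             "scheme", "min_rest_mbf", "dt_s", "seed")
  extra <- setdiff(names(j), known)
  if (length(extra) > 0)
    abort_input("unknown config field(s): %s", paste(extra, collapse = ", "))
  build <- function(fn, args, drop = character(0)) {
    if (is.null(args)) return(fn())
    args <- args[setdiff(names(args), drop)]
    ok <- intersect(names(args), names(formals(fn)))
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad) > 0)
      abort_input("unknown field(s) in config: %s", paste(bad, collapse = ", "))
    do.call(fn, args[ok])
  }
  extraction <- function(x) {
    if (is.null(x)) extraction_model() else extraction_model(x$form, x$ps %||% 1.0)
  }
  pop_args <- j$population
  if (!is.null(pop_args$extraction)) {
    pop_ext <- extraction(pop_args$extraction)
    pop_args$extraction <- NULL
  } else pop_ext <- NULL
  pop <- build(population_config, pop_args)
  if (!is.null(pop_ext)) pop$extraction <- pop_ext
  scheme <- if (is.null(j$scheme)) aha17_scheme() else {
    sc <- aha17_scheme(weights = j$scheme$weight)
    sc$territory <- j$scheme$territory[match(sc$segment, j$scheme$segment)]
    validate_scheme(sc)
  }
  experiment_config(
    population = pop,
    perturbation = build(perturbation_config, j$perturbation),
    retention = build(retention_config, lapply(j$retention, unlist)),
    extraction = extraction(j$extraction),
    scheme = scheme,
    min_rest_mbf = j$min_rest_mbf %||% 0.05,
    dt_s = j$dt_s %||% 0.5,
    seed = j$seed %||% 1L)
}
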