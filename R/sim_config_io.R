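# JSON (de)serialization of simulation configurations. The packaged
# default, extdata/study1_fixture.json, mirrors the discovery study's group
# sizes and draws each group at its published genotype frequencies.

#' Read a simulation configuration from JSON
#'
#' The JSON carries everything but the seed, which is supplied at run time
#' so that one config can drive many replicates.
#'
#' @param path File path, or `NULL` for the packaged default config
#'   (discovery-study group sizes, empirical frequencies, calibrated
#'   performance effects).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @examples
#' cfg <- read_sim_config(seed = 1)
#' @export
read_sim_config <- function(path = NULL, seed) {
  if (is.null(path))
    path <- system.file("extdata", "study1_fixture.json",
                        package = "tgslift", mustWork = TRUE)
  x <- jsonlite::read_json(path)
  eff <- if (is.null(x$effects)) NULL else
    effect_model(baseline = x$effects$baseline, sd = x$effects$sd,
                 shifts = lapply(x$effects$shifts, unlist))
  sim_config(n = unlist(x$n),
             source = x$source %||% "empirical",
             enrichment = isTRUE(x$enrichment %||% TRUE),
             effects = eff, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
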