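#' Default experiment configuration
#'
#' The shipped defaults reproduce the published study design: 100 studies per
#' data set, 10 replicates of each kind, 4 scenarios, 16 deletion fractions
#' spanning 10%-90%, all 14 options, 100 imputations, SD bounds
#' `[0.01, 1]`, sample-size lower bound 5, bootstrap-EM cap 60%.
#'
#' @return A named list understood by [run_factorial_config()].
#' @export
default_config <- function() {
  list(
    n_studies = 100,
    n_replicates = 10,
    scenarios = c("MCAR", "MAR", "MNAR", "corMCAR"),
    fractions = default_fractions(),
    options = 1:14,
    m = 100,
    master_seed = 1,
    md_params = md_params(),
    cor_params = cor_params()
  )
}

#' Read an experiment configuration from YAML
#'
#' Unspecified fields fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg$fractions <- as.numeric(cfg$fractions)
  cfg$options <- as.integer(cfg$options)
  cfg
}

#' Run the factorial experiment from a configuration list
#'
#' @param config A list as returned by [default_config()] or [read_config()].
#' @param ... Overrides passed to [run_factorial()].
#' @return Deviation records, see [run_factorial()].
#' @export
run_factorial_config <- function(config = default_config(), ...) {
  run_factorial(scenarios = config$scenarios,
                n_replicates = config$n_replicates,
                fractions = config$fractions,
                options = config$options,
                n_studies = config$n_studies,
                m = config$m,
                master_seed = config$master_seed,
                md_params = config$md_params,
                cor_params = config$cor_params,
                ...)
}
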