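#' Deterministic fixtures with known oracle values
#'
#' Small, seeded objects used across the test suite and as quick-start demo
#' inputs. Every expected value is either forced by construction (symmetry,
#' identities) or hand-computed from the defining formulas:
#' \describe{
#'   \item{`two_study_symmetric`}{`yi = {0.5, 1.5}`, `vi = {0.1, 0.1}`; by
#'     symmetry the grand mean is exactly 1.}
#'   \item{`rubin_hand`}{`mu = {0.9, 1.0, 1.1}`, `se = 0.2` each; Rubin's
#'     rules give within 0.04, between 0.01 and total se
#'     `sqrt(0.04 + (4/3) 0.01) = 0.2309401`.}
#'   \item{`default_md_seed1`}{the 100-row mean-difference data set at seed 1
#'     with its column means frozen at build time.}
#' }
#'
#' @param name Fixture name.
#' @return A list with `name`, `dataset` (or `yi`/`vi` style inputs) and
#'   `expected` named oracle values.
#' @export
build_fixture <- function(name) {
  switch(name,
    two_study_symmetric = list(
      name = name,
      yi = c(0.5, 1.5), vi = c(0.1, 0.1),
      expected = list(mu = 1.0)
    ),
    rubin_hand = list(
      name = name,
      estimates = data.frame(mu = c(0.9, 1.0, 1.1), se = rep(0.2, 3)),
      expected = list(mu = 1.0, within_var = 0.04, between_var = 0.01,
                      se_total = sqrt(0.04 + (4 / 3) * 0.01))
    ),
    default_md_seed1 = list(
      name = name,
      dataset = simulate_md_data(100, seed = 1),
      # column means frozen from the seed-1 generation run
      expected = list(column_means = c(
        mean_c = 1.01307239392105, mean_t = 2.03729453619725,
        sd_c = 0.235718965917171, sd_t = 0.512580330796665,
        n_c = 10.29, n_t = 10.49
      ))
    ),
    stop("unknown fixture: ", name)
  )
}
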