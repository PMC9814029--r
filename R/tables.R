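# Predicted-power reproduction grids for the Connect-Home design study:
# the simulation-study prediction grid, the six-design comparison restricted
# to Design A (the Connect-Home layout), and the cluster-period-size
# (sample-size) grid.

#' Predicted-power tables for the Connect-Home design
#'
#' Deterministically regenerates the fast-GEE predicted-power grids for the
#' Connect-Home incomplete stepped wedge design with binary outcomes
#' (`beta0 = 0.85`, `beta1 = -0.01`):
#'
#' * `"simulation-grid"`: z- and t-test predicted power for 6 and 12
#'   clusters, average effects model with `delta` in (-1.2, -1.4), all five
#'   correlation structures (EX/ED/NE/BE/PD with the study parameters
#'   `alpha0 = 0.03`, `alpha1 = 0.015`, `alpha2 = 0.2`, `rho = 0.8` for ED
#'   and `0.7` for PD).
#' * `"design-a"`: t-test predicted power for the average (`delta = -1.2`)
#'   and incremental (`delta = -2.4`, `q = 10`) models, 6 and 12 clusters,
#'   cross-sectional structures EX/ED/NE.
#' * `"cluster-period-size"`: t-test predicted power for 6 clusters with
#'   cluster-period sizes 4 to 9, average model (`delta` = -1.2, -1.4) and
#'   incremental model (`delta` = -1.8, -2.4), structures EX/ED/NE.
#'
#' @param which One of `"simulation-grid"`, `"design-a"`,
#'   `"cluster-period-size"`.
#' @return A tibble of scenarios with predicted-power columns appended by
#'   [sw_power_grid()]; rerunning is byte-identical (no randomness).
#' @examples
#' connect_home_power_table("design-a")
#' @export
connect_home_power_table <- function(which = c("simulation-grid", "design-a",
                                               "cluster-period-size")) {
  which <- match.arg(which)
  structures <- function(tags) {
    tibble(
      structure = tags,
      alpha0 = 0.03,
      alpha1 = dplyr::if_else(tags %in% c("NE", "BE"), 0.015, NA_real_),
      alpha2 = dplyr::if_else(tags == "BE", 0.2, NA_real_),
      rho = dplyr::case_when(tags == "ED" ~ 0.8, tags == "PD" ~ 0.7,
                             .default = NA_real_)
    )
  }
  grid <- switch(which,
    "simulation-grid" = tidyr::expand_grid(
      clusters = c(6, 12), delta = c(-1.2, -1.4),
      structures(c("EX", "ED", "NE", "BE", "PD"))
    ),
    "design-a" = tidyr::expand_grid(
      effect_model = c("average", "incremental"), clusters = c(6, 12),
      structures(c("EX", "ED", "NE"))
    ) |>
      dplyr::mutate(delta = dplyr::if_else(.data$effect_model == "average",
                                           -1.2, -2.4)),
    "cluster-period-size" = tidyr::expand_grid(
      effect_model = c("average", "incremental"),
      delta_ix = 1:2,
      structures(c("EX", "ED", "NE")),
      cluster_period_size = 4:9
    ) |>
      dplyr::mutate(
        clusters = 6,
        delta = dplyr::case_when(
          .data$effect_model == "average" & .data$delta_ix == 1 ~ -1.2,
          .data$effect_model == "average" & .data$delta_ix == 2 ~ -1.4,
          .data$effect_model == "incremental" & .data$delta_ix == 1 ~ -1.8,
          .default = -2.4
        )
      ) |>
      dplyr::select(-"delta_ix")
  )
  sw_power_grid(grid)
}
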