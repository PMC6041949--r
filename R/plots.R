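# ggplot2 views of sweep tables and experiment analyses.

#' Plot compensation across a sweep
#'
#' For fixed-damage sweeps, draws lnRR against the damage fraction, one
#' panel per tissue, coloured by nitrogen availability, with the
#' `log(1 - D)` no-compensation floor as a reference line in the attacked
#' tissue's panel. For dynamic sweeps, draws lnRR and realized damage
#' against nitrogen.
#'
#' @param object A `herbgame_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' sw <- sweep_fixed(env_grid = c(20, 80), damage_grid = c(0, 0.3, 0.6))
#' autoplot(sw)
#' @method autoplot herbgame_sweep
#' @export
autoplot.herbgame_sweep <- function(object, ...) {
  long <- object |>
    dplyr::filter(.data$converged) |>
    tidyr::pivot_longer(dplyr::all_of(c("lnRR_fruit", "lnRR_shoot",
                                        "lnRR_root")),
                        names_to = "tissue", values_to = "lnRR",
                        names_prefix = "lnRR_")
  attacked <- object$location[1]
  floor_dat <- long |>
    dplyr::filter(.data$tissue == ifelse(attacked == "shoot", "shoot",
                                         "root"))
  if (identical(attr(object, "sweep_type"), "dynamic")) {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$N, y = .data$lnRR,
                                            colour = .data$damage_mode)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_wrap(~tissue) +
      ggplot2::labs(x = "nitrogen availability (gN)", y = "lnRR",
                    colour = NULL)
  } else {
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$D, y = .data$lnRR,
                                            colour = .data$N,
                                            group = .data$N)) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_line(data = floor_dat,
                         ggplot2::aes(y = .data$null_floor, group = .data$N),
                         colour = "red", linetype = 2) +
      ggplot2::facet_wrap(~tissue) +
      ggplot2::labs(x = "damage fraction D", y = "lnRR",
                    colour = "N (gN)")
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::theme_minimal()
}

#' Plot block-paired lnRR against damage
#'
#' Raw block-paired lnRR per treatment with the `log(1 - d)` floor for the
#' clipped tissue, the classic view of compensatory regrowth in clipping
#' experiments.
#'
#' @param object An `lnrr_table` from [block_ln_rr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' tab <- block_ln_rr(generate_experiment(experiment_spec(n_blocks = 6)))
#' autoplot(tab)
#' @method autoplot lnrr_table
#' @export
autoplot.lnrr_table <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(c("lnRR_fruit", "lnRR_shoot",
                                        "lnRR_root")),
                        names_to = "tissue", values_to = "lnRR",
                        names_prefix = "lnRR_")
  floor_dat <- dplyr::distinct(object, .data$d, .data$expected_floor) |>
    dplyr::mutate(tissue = "shoot")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$d, y = .data$lnRR)) +
    ggplot2::geom_jitter(width = 0.01, height = 0, alpha = 0.5, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "line", colour = "blue") +
    ggplot2::geom_line(data = floor_dat,
                       ggplot2::aes(y = .data$expected_floor),
                       colour = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "clipping fraction d", y = "lnRR") +
    ggplot2::theme_minimal()
}
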