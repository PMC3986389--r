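# ggplot2 visualisation of simulation output

#' Plot a simulation run
#'
#' @param object A `stent_run`.
#' @param type `"area"` (percent lumen-area change vs day),
#'   `"populations"` (SMC and EC census curves), or `"cytokines"`
#'   (max local and serum concentrations).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stent_run
#' @export
autoplot.stent_run <- function(object,
                               type = c("area", "populations", "cytokines"),
                               ...) {
  type <- match.arg(type)
  s <- object$series
  if (type == "area") {
    ggplot2::ggplot(s, ggplot2::aes(.data$day, .data$percent_area_change)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
      ggplot2::labs(x = "Day post-intervention",
                    y = "Lumen area change (%)",
                    title = "Neointimal lumen-area loss") +
      ggplot2::theme_minimal()
  } else if (type == "populations") {
    long <- tidyr::pivot_longer(s[, c("day", "smc", "ec")],
                                cols = c("smc", "ec"),
                                names_to = "cell", values_to = "count")
    ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$count,
                                       colour = .data$cell)) +
      ggplot2::geom_line() +
      ggplot2::scale_colour_manual(values = c(smc = "darkgreen",
                                              ec = "deeppink")) +
      ggplot2::labs(x = "Day post-intervention", y = "Agent count") +
      ggplot2::theme_minimal()
  } else {
    cols <- c("tgfb_max_local_ngml", "tnfa_max_local_ngml",
              "tgfb_serum_ngml", "tnfa_serum_ngml")
    long <- tidyr::pivot_longer(s[, c("day", cols)], cols = dplyr::all_of(cols),
                                names_to = "series", values_to = "ngml")
    ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$ngml,
                                       colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
      ggplot2::labs(x = "Day post-intervention",
                    y = "Concentration (ng/ml)") +
      ggplot2::theme_minimal()
  }
}

#' Plot the cross-section of a simulation state
#'
#' A colour-coded map of the vessel cross-section: SMCs green, ECs pink,
#' struts grey, plaque violet, activated platelets red, leukocytes
#' blue/cyan.
#'
#' @param state A `sim_state`.
#' @return A ggplot object.
#' @export
plot_cross_section <- function(state) {
  n <- state$frame$n
  lab <- matrix(NA_character_, n, n)
  lab[(state$S_int + state$S_med + state$S_adv + state$S_mig) > 0] <- "SMC"
  lab[state$plaque] <- "plaque"
  ep <- unique(state$frontier_idx[state$ec_present &
                                    !is.na(state$frontier_idx)])
  lab[ep] <- "EC"
  lab[state$platelets$pos[state$platelets$active]] <- "platelet"
  if (length(state$leuk$kind) > 0) {
    lp <- leuk_patch(state)
    lab[lp[state$leuk$kind == 1L]] <- "monocyte"
    lab[lp[state$leuk$kind == 2L]] <- "neutrophil"
    lab[lp[state$leuk$kind >= 3L]] <- "macrophage"
  }
  lab[state$strut] <- "strut"
  df <- tibble::tibble(
    x = rep(seq_len(n), each = n),
    y = rep(seq_len(n), times = n),
    agent = as.vector(lab))
  df <- df[!is.na(df$agent), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$agent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      SMC = "green4", EC = "deeppink", strut = "grey40", plaque = "violet",
      platelet = "red", monocyte = "blue", neutrophil = "skyblue",
      macrophage = "cyan3")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Day %.1f", state$step /
                                    state$cfg$steps_per_day)) +
    ggplot2::theme_void()
}

#' Compare single- and overlapping-stent area-loss trajectories
#'
#' @param single,overlap `stent_run` objects (or `replicate_summary`
#'   objects, in which case the first run of each is used).
#' @return A ggplot object.
#' @export
plot_overlap_comparison <- function(single, overlap) {
  pick <- function(x) if (inherits(x, "replicate_summary")) x$details[[1]] else x
  s1 <- pick(single)$series
  s2 <- pick(overlap)$series
  df <- dplyr::bind_rows(
    dplyr::mutate(s1[, c("day", "percent_area_change")], arm = "single"),
    dplyr::mutate(s2[, c("day", "percent_area_change")], arm = "overlap"))
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$percent_area_change,
                                   linetype = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day post-intervention", y = "Lumen area change (%)") +
    ggplot2::theme_minimal()
}
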