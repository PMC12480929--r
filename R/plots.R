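# Overlay plots of prior, MLE and posterior densities, one panel per
# coefficient.

overlay_frame <- function(curves, variable) {
  lo <- min(vapply(curves, function(g) g$mean - 4 * g$sd, numeric(1)))
  hi <- max(vapply(curves, function(g) g$mean + 4 * g$sd, numeric(1)))
  grid <- seq(lo, hi, length.out = 400)
  do.call(rbind, lapply(names(curves), function(nm) {
    g <- curves[[nm]]
    data.frame(variable = variable, distribution = nm, theta = grid,
               density = stats::dnorm(grid, g$mean, g$sd),
               stringsAsFactors = FALSE)
  }))
}

overlay_gg <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$density,
                                   colour = .data$distribution)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "coefficient", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay plot of prior, MLE and (optionally) posterior densities
#'
#' Single panel with labelled Gaussian density curves over a range covering
#' +/- 4 sd of every curve. When a file is given, the plotted coordinates are
#' also dumped alongside as delimited text (`<file>.csv`) so the figure is
#' reproducible independently of the rendering library.
#'
#' @param prior,mle [gaussian1d()] densities; `posterior` may be `NULL` for
#'   the two-curve variant.
#' @param posterior optional [gaussian1d()].
#' @param variable panel title.
#' @param file optional output image path (`.png` or `.pdf`).
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_overlay <- function(prior, mle, posterior = NULL, variable = "coefficient",
                         file = NULL) {
  curves <- list(Prior = prior, MLE = mle)
  if (!is.null(posterior)) curves$Posterior <- posterior
  for (g in curves) stopifnot(inherits(g, "gaussian1d"))
  df <- overlay_frame(curves, variable)
  p <- overlay_gg(df) + ggplot2::ggtitle(variable)
  if (is.null(file)) return(p)
  save_plot_with_coords(p, df, file)
  invisible(p)
}

#' Grid of overlay panels, one per coefficient
#'
#' Faceted version of [plot_overlay()] for a whole fit: per variable, the
#' set's prior, the MLE marginal, and optionally the posterior marginal.
#'
#' @param mle an `mle_approx`.
#' @param priors a [prior_set()] covering the fitted variables.
#' @param posterior optional `posterior_approx`.
#' @param file optional output image path.
#' @return the ggplot object, invisibly when written to file.
#' @export
plot_overlay_grid <- function(mle, priors, posterior = NULL, file = NULL) {
  stopifnot(inherits(mle, "mle_approx"), inherits(priors, "prior_set"))
  vars <- coef_variables(mle)
  check_alignment(names(priors$entries), vars, priors$label)
  df <- do.call(rbind, lapply(vars, function(v) {
    curves <- list(Prior = priors$entries[[v]]$prior, MLE = marginal(mle, v))
    if (!is.null(posterior)) curves$Posterior <- marginal(posterior, v)
    overlay_frame(curves, v)
  }))
  p <- overlay_gg(df) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::ggtitle(priors$label)
  if (is.null(file)) return(p)
  save_plot_with_coords(p, df, file)
  invisible(p)
}

save_plot_with_coords <- function(p, df, file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    grDevices::png(file, width = 1600, height = 1000, res = 150,
                   type = "cairo")
  } else if (ext == "pdf") {
    grDevices::pdf(file, width = 10, height = 6.5)
  } else {
    pe_stop("plot output must be .png or .pdf (got .%s)", ext)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  utils::write.csv(df, paste0(file, ".csv"), row.names = FALSE)
  invisible(file)
}
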