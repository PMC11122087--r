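#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the iteration trace of a reconstruction
#'
#' @param x A `ct_recon` object from [run_solver()].
#' @param ... Unused.
#' @return A tibble with one row per recorded iterate: `iteration`,
#'   `objective`, `rel_error` (NA without ground truth), `step`.
#' @method tidy ct_recon
#' @export
tidy.ct_recon <- function(x, ...) {
  x$trace
}

#' One-row summary of a reconstruction
#'
#' @param x A `ct_recon` object.
#' @param ... Unused.
#' @return A one-row tibble: variant, iteration count, step size, final and
#'   best objective, best iteration and relative error, convergence flags.
#' @method glance ct_recon
#' @export
glance.ct_recon <- function(x, ...) {
  tr <- x$trace
  tibble::tibble(
    variant = x$config$variant,
    iterations = max(tr$iteration, 0),
    omega = x$omega,
    objective = if (nrow(tr)) utils::tail(tr$objective, 1) else NA_real_,
    best_iteration = x$best_iteration,
    best_rel_error = if (all(is.na(tr$rel_error))) NA_real_
                     else min(tr$rel_error, na.rm = TRUE),
    converged = x$converged,
    diverged = x$diverged
  )
}

#' Plot the convergence history of a reconstruction
#'
#' Objective (and, when ground truth was tracked, relative error) against
#' the iteration index, on a log scale.
#'
#' @param object A `ct_recon` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ct_recon
#' @export
autoplot.ct_recon <- function(object, ...) {
  tr <- object$trace
  df <- rbind(
    data.frame(iteration = tr$iteration, value = tr$objective,
               quantity = "objective"),
    if (!all(is.na(tr$rel_error))) {
      data.frame(iteration = tr$iteration, value = tr$rel_error,
                 quantity = "relative error")
    }
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = sprintf("%s convergence", object$config$variant))
}

#' Plot material density channels
#'
#' Renders an `Nx x M` image matrix as one raster panel per material.
#'
#' @param X `Nx x M` material image matrix.
#' @param n Image side length.
#' @param materials Optional channel names.
#' @return A ggplot object.
#' @export
plot_material_image <- function(X, n, materials = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == n * n)
  M <- ncol(X)
  materials <- materials %||% colnames(X) %||%
    paste0("material_", seq_len(M))
  df <- data.frame(
    x = rep(rep(seq_len(n), times = n), times = M),
    y = rep(rep(seq_len(n), each = n), times = M),
    material = factor(rep(materials, each = n * n), levels = materials),
    density = as.vector(X)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~material) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "density")
}

#' @importFrom ggplot2 .data
NULL
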