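#' Robinson-projected site map
#'
#' Plots connection sites on the Robinson projection of the idealized
#' vesicle sphere, colored by class and shaped by surface.
#'
#' @param sites tibble with `lat`/`lon` (from [sphere_map()]) or local unit
#'   directions `ux`,`uy`,`uz` (converted internally).
#' @return a ggplot object.
#' @export
plot_robinson <- function(sites) {
  if (!all(c("lat", "lon") %in% names(sites))) {
    stopifnot(all(c("ux", "uy", "uz") %in% names(sites)))
    sites$lat <- asin(pmin(1, pmax(-1, sites$uz))) * 180 / pi
    sites$lon <- atan2(sites$uy, sites$ux) * 180 / pi
  }
  rxy <- robinson_xy(sites$lat, sites$lon)
  sites$rx <- rxy$x; sites$ry <- rxy$y
  grat_lat <- do.call(rbind, lapply(seq(-90, 90, 30), function(la) {
    lo <- seq(-180, 180, 5)
    g <- robinson_xy(rep(la, length(lo)), lo)
    data.frame(x = g$x, y = g$y, id = paste0("lat", la))
  }))
  grat_lon <- do.call(rbind, lapply(seq(-180, 180, 30), function(lo) {
    la <- seq(-90, 90, 5)
    g <- robinson_xy(la, rep(lo, length(la)))
    data.frame(x = g$x, y = g$y, id = paste0("lon", lo))
  }))
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$rx, y = .data$ry)) +
    ggplot2::geom_path(data = rbind(grat_lat, grat_lon),
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
                       color = "grey85", linewidth = 0.3, inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(color = .data$class,
                                     shape = .data$surface), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Connection sites (Robinson projection)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_robinson
#' @param object a `composite_map`.
#' @param ... ignored.
#' @method autoplot composite_map
#' @export
autoplot.composite_map <- function(object, ...) {
  plot_robinson(object$sites) +
    ggplot2::labs(subtitle = sprintf("%d vesicles, overlap score %.3f",
                                     object$N, tail(object$score_trace, 1)))
}

#' Distance profiles by macromolecule class
#'
#' Frequency distributions of connection-site distances from the presynaptic
#' membrane, normalized to the average rib position per vesicle.
#'
#' @param distances tibble from [distance_profile()].
#' @param binwidth histogram bin width (nm).
#' @return a ggplot object.
#' @export
plot_distance_profile <- function(distances, binwidth = 2.5) {
  df <- distances %>% filter(is.finite(.data$norm_distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$norm_distance, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.6) +
    ggplot2::facet_wrap(~ surface, ncol = 1) +
    ggplot2::labs(x = "distance from average rib position (nm)",
                  y = "sites") +
    ggplot2::theme_minimal()
}

#' Plot a virtual slice
#'
#' @param img matrix from [virtual_slice()].
#' @return a ggplot object (gray scale, 0 = black).
#' @export
plot_slice <- function(img) {
  df <- expand.grid(x = seq_len(nrow(img)), y = seq_len(ncol(img)))
  df$gray <- as.vector(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1000)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' @method tidy alignment_model
#' @export
tidy.alignment_model <- function(x, ...) {
  tibble(member = x$members,
         ax = vapply(x$transforms, function(t) rot_to_euler(t$R)[1], 1),
         ay = vapply(x$transforms, function(t) rot_to_euler(t$R)[2], 1),
         az = vapply(x$transforms, function(t) rot_to_euler(t$R)[3], 1),
         tx = vapply(x$transforms, function(t) t$t[1], 1),
         ty = vapply(x$transforms, function(t) t$t[2], 1),
         tz = vapply(x$transforms, function(t) t$t[3], 1))
}

#' @method glance alignment_model
#' @export
glance.alignment_model <- function(x, ...) {
  tibble(method = x$method, members = length(x$members), rounds = x$rounds,
         volume_nm3 = model_volume(x),
         final_score = if (length(x$score_trace)) tail(x$score_trace, 1)
                       else NA_real_)
}

#' @method tidy report_bundle
#' @export
tidy.report_bundle <- function(x, ...) x$headline

#' @method tidy composite_map
#' @export
tidy.composite_map <- function(x, ...) x$sites

#' @method glance composite_map
#' @export
glance.composite_map <- function(x, ...) {
  tibble(n_vesicles = x$N, n_sites = nrow(x$sites),
         overlap = tail(x$score_trace, 1), sweeps = length(x$score_trace) - 1)
}
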