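## Weight topography ("geometry") maps: backtrack the FC weights of each
## joint onto the two 4 x 4 electrode panels to show which channels the
## model relies on, and with which sign.

#' Backtrack a joint's FC weight vector to per-channel contributions
#'
#' The 192-long FC weight row of one joint concatenates six 32-long
#' blocks, one per feature map, aligned with the flatten order.  The
#' per-channel contribution is the superposition of the six blocks —
#' elementwise sum by default, the unique choice under which the map
#' times a uniform feature perturbation reproduces the FC output change;
#' `mean` and `abssum` are offered for exploration.
#'
#' @param w Numeric vector of length n_filters * 32 (one row of `W`).
#' @param n_channels Channels per feature-map block.
#' @param superposition `"sum"`, `"mean"`, or `"abssum"`.
#' @return Signed numeric 32-vector of per-channel weights.
#' @export
backtrack_fc_weights <- function(w, n_channels = 32,
                                 superposition = c("sum", "mean", "abssum")) {
  superposition <- match.arg(superposition)
  if (length(w) %% n_channels != 0)
    stop_data("weight length ", length(w), " is not a multiple of ", n_channels)
  blocks <- matrix(w, nrow = n_channels)
  switch(superposition,
         sum = rowSums(blocks),
         mean = rowMeans(blocks),
         abssum = rowSums(abs(blocks)))
}

#' Normalize a channel map to \[-1, 1\]
#'
#' Divides by the maximum absolute value, preserving signs; an all-zero
#' map stays all-zero.
#'
#' @param v Numeric vector.
#' @export
normalize_map <- function(v) {
  if (!all(is.finite(v))) stop_data("map contains non-finite values")
  m <- max(abs(v))
  if (m == 0) v else v / m
}

#' Arrange a 32-channel vector on the two electrode panels
#'
#' @param v Numeric 32-vector indexed by channel id.
#' @param layout A [channel_layout()] data frame.
#' @return List with `flexor` and `extensor` 4 x 4 matrices (rows/cols as
#'   worn, cells named by channel number) and the input `values`.
#' @export
arrange_panels <- function(v, layout = channel_layout()) {
  if (length(v) != 32) stop_data("v must have 32 entries")
  panel <- function(side) {
    g <- layout_grid(side, layout)
    m <- matrix(v[g], 4, 4)
    dimnames(m) <- list(NULL, NULL)
    attr(m, "channels") <- g
    m
  }
  list(flexor = panel("flexor"), extensor = panel("extensor"), values = v)
}

#' Per-joint weight topography of a fitted model
#'
#' @param model A fitted `fpcnn` (or `fpcnn_params`).
#' @param joints Which joints to map (subset of 1:3).
#' @param superposition Passed to [backtrack_fc_weights()].
#' @param normalize Scale each joint's map to \[-1, 1\] by its own
#'   maximum absolute value.
#' @return An object of class `geometry_map`: named list (per joint) of
#'   [arrange_panels()] results, with the rendering conventions recorded
#'   in attributes.
#' @export
geometry_map <- function(model, joints = NULL,
                         superposition = c("sum", "mean", "abssum"),
                         normalize = TRUE) {
  superposition <- match.arg(superposition)
  p <- as_fpcnn_params(model)
  joints <- joints %||% seq_len(p$n_out)
  maps <- lapply(joints, function(i) {
    v <- backtrack_fc_weights(p$W[i, ], n_channels = p$n_channels,
                              superposition = superposition)
    if (normalize) v <- normalize_map(v)
    arrange_panels(v)
  })
  names(maps) <- JOINT_NAMES[joints]
  structure(maps, class = "geometry_map",
            superposition = superposition, normalized = normalize)
}

#' Channels with the largest absolute map weight
#'
#' @param map One joint's entry of a [geometry_map()] (or a 32-vector).
#' @param n How many channels.
#' @return Integer channel ids.
#' @export
top_channels <- function(map, n = 8) {
  v <- if (is.list(map)) map$values else map
  order(abs(v), decreasing = TRUE)[seq_len(n)]
}

diverging_palette <- function(n = 255) {
  grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(n)
}

plot_panel <- function(m, main) {
  ## image() draws x along rows; flip so panel row 1 appears on top.
  z <- t(m[4:1, , drop = FALSE])
  graphics::image(1:4, 1:4, z, zlim = c(-1, 1), col = diverging_palette(),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  chans <- attr(m, "channels")
  for (r in 1:4) for (c in 1:4)
    graphics::text(c, 5 - r, chans[r, c], cex = 0.8)
  graphics::box()
}

#' Plot a weight-topography map
#'
#' One row per joint, flexor panel left and extensor panel right, on a
#' diverging blue-white-red scale centred at 0: red channels push the
#' joint toward positive angles (WF, P, HG), blue toward negative (WE,
#' S, HO), white channels do not contribute.
#'
#' @param x A `geometry_map`.
#' @param ... Unused.
#' @export
plot.geometry_map <- function(x, ...) {
  nj <- length(x)
  op <- graphics::par(mfrow = c(nj, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (joint in names(x)) {
    plot_panel(x[[joint]]$flexor, paste(joint, "flexor"))
    plot_panel(x[[joint]]$extensor, paste(joint, "extensor"))
    ## colour bar
    graphics::image(1, seq(-1, 1, length.out = 255),
                    matrix(seq(-1, 1, length.out = 255), 1),
                    zlim = c(-1, 1), col = diverging_palette(),
                    axes = FALSE, xlab = "", ylab = "", main = "weight")
    graphics::axis(4, at = c(-1, 0, 1), las = 1)
    graphics::box()
  }
  invisible(x)
}

#' @export
plot.fpcnn <- function(x, ...) plot(geometry_map(x), ...)

#' Render a geometry plot to an image file
#'
#' @param maps A `geometry_map` (or a fitted `fpcnn`).
#' @param file Output path; format chosen by extension (`.png` or
#'   `.svg`).
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return The file path, invisibly.
#' @export
render_geometry_plot <- function(maps, file, width = NULL, height = NULL) {
  if (inherits(maps, "fpcnn")) maps <- geometry_map(maps)
  if (!inherits(maps, "geometry_map")) stop_config("maps must be a geometry_map")
  ext <- tolower(tools::file_ext(file))
  nj <- length(maps)
  if (ext == "png") {
    grDevices::png(file, width = width %||% 700, height = height %||% (220 * nj))
  } else if (ext == "svg") {
    grDevices::svg(file, width = width %||% 8, height = height %||% (2.5 * nj))
  } else stop_config("unsupported extension '", ext, "' (use png or svg)")
  ok <- FALSE
  tryCatch({ plot(maps); ok <- TRUE }, finally = grDevices::dev.off())
  if (!ok || !file.exists(file)) stop("failed to write ", file)
  invisible(file)
}

#' Export map values as a table
#'
#' @param maps A `geometry_map`.
#' @return Data frame with channel, side, row, col and one value column
#'   per joint.
#' @export
geometry_table <- function(maps) {
  lay <- channel_layout()
  for (joint in names(maps)) lay[[joint]] <- maps[[joint]]$values
  lay
}
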