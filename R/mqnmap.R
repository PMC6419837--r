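# Chemical-space maps: PCA of raw MQN fingerprints, pixel bucketing, and
# HSV colouring (hue = mean descriptor, value driven by pixel occupancy so
# sparse pixels fade into the black background).

# Default count -> value rule. The intent: empty pixels are background,
# low-count pixels dim (floor 0.25), the max-count pixel reaches full
# value. 1 + log10 maps count_norm in [0.1, 1] onto [0, 1] smoothly.
default_value_rule <- function(count_norm) {
  pmin(1, pmax(0.25, 1 + log10(count_norm)))
}

# Hue ramp: dark blue -> cyan -> green -> yellow -> orange -> red -> magenta,
# i.e. an HSV sweep downwards from 2/3 wrapping into magenta.
default_hue_ramp <- function(d) (2 / 3 - d * 5 / 6) %% 1

#' Build an MQN/PCA chemical-space map
#'
#' Computes 42-dimension MQN fingerprints, fits a PCA on the raw
#' (uncentered-scale, unstandardized) fingerprint matrix, projects onto the
#' first two components, and buckets molecules into a `w x h` pixel grid.
#' Each bucket records its occupancy and the mean of a per-molecule
#' descriptor; both are normalized to `[0, 1]` for colouring. Component
#' signs are fixed by convention (the loading of largest magnitude is made
#' positive) so maps are reproducible across platforms and input orderings.
#'
#' @param smiles character vector of valid SMILES (>= 3).
#' @param descriptor per-molecule numeric vector to colour by, or one of
#'   the built-ins `"carbons"` (carbon count) and `"cyclic_bonds"` (cyclic
#'   bond count), both read off the MQN vector.
#' @param w,h map dimensions in pixels.
#' @return object of class `mqn_map`: `loadings` (42 x 2),
#'   `explained_variance` (fractions for PC1/PC2), `buckets` (data.frame
#'   x, y, count, mean_descriptor, count_norm, descriptor_norm), `w`, `h`.
#' @export
build_mqn_map <- function(smiles, descriptor = "carbons", w = 64, h = 64) {
  stopifnot(length(smiles) >= 3, w >= 2, h >= 2)
  fp <- mqn_fingerprint(smiles)
  if (is.character(descriptor)) {
    descriptor <- switch(descriptor,
      carbons = fp[, "c"],
      cyclic_bonds = fp[, "csb"] + fp[, "cdb"] + fp[, "ctb"],
      stop("unknown built-in descriptor: ", descriptor))
  }
  stopifnot(length(descriptor) == length(smiles), all(is.finite(descriptor)))
  if (all(apply(fp, 2, function(col) length(unique(col)) == 1)))
    stop("degenerate input: all fingerprints identical, PCA undefined")
  # PCA on the raw MQN matrix: centered (PCA is on covariance) but never
  # scaled/standardized.
  pc <- stats::prcomp(fp, center = TRUE, scale. = FALSE)
  load2 <- pc$rotation[, 1:2, drop = FALSE]
  flip <- vapply(1:2, function(j) sign(load2[which.max(abs(load2[, j])), j]), 1)
  load2 <- sweep(load2, 2, flip, `*`)
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, `*`)
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  to_pix <- function(v, m) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(0L, length(v)))
    pmin(m - 1L, as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * m)))
  }
  x <- to_pix(scores[, 1], w)
  y <- to_pix(scores[, 2], h)
  keyed <- paste(x, y)
  agg_count <- tapply(descriptor, keyed, length)
  agg_mean <- tapply(descriptor, keyed, mean)
  xy <- do.call(rbind, strsplit(names(agg_count), " ", fixed = TRUE))
  buckets <- data.frame(x = as.integer(xy[, 1]), y = as.integer(xy[, 2]),
                        count = as.integer(agg_count),
                        mean_descriptor = as.numeric(agg_mean))
  stopifnot(sum(buckets$count) == length(smiles))
  buckets$count_norm <- buckets$count / max(buckets$count)
  drng <- range(buckets$mean_descriptor)
  buckets$descriptor_norm <- if (drng[1] == drng[2]) rep(0.5, nrow(buckets)) else
    (buckets$mean_descriptor - drng[1]) / (drng[2] - drng[1])
  structure(list(loadings = load2, explained_variance = ev,
                 buckets = buckets, w = as.integer(w), h = as.integer(h)),
            class = "mqn_map")
}

#' @export
print.mqn_map <- function(x, ...) {
  cat(sprintf("MQN/PCA map %dx%d: %d occupied pixels, %d molecules\n",
              x$w, x$h, nrow(x$buckets), sum(x$buckets$count)))
  cat(sprintf("  explained variance: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  invisible(x)
}

# RGB array (h x w x 3) for a map under the HSV colouring scheme.
.map_rgb <- function(map, value_rule = default_value_rule,
                     hue_ramp = default_hue_ramp) {
  img <- array(0, dim = c(map$h, map$w, 3))
  b <- map$buckets
  hue <- hue_ramp(b$descriptor_norm)
  val <- ifelse(b$count > 0, value_rule(b$count_norm), 0)
  cols <- grDevices::hsv(hue, 1, val)
  rgb <- grDevices::col2rgb(cols) / 255
  for (i in seq_len(nrow(b))) {
    # pixel (0,0) bottom-left -> array row h - y
    img[map$h - b$y[i], b$x[i] + 1L, ] <- rgb[, i]
  }
  img
}

#' Render a map to a PNG file
#'
#' Writes the `w x h` image on a black background: hue encodes the bucket's
#' normalized mean descriptor, saturation is fixed at 1, and value follows
#' the count rule (empty pixels black, sparse pixels dim, the fullest pixel
#' at full value; value is monotone in count).
#'
#' @param map an [build_mqn_map()] result.
#' @param path output PNG path.
#' @param value_rule function mapping normalized counts (0, 1] to value in
#'   \[0, 1\]; pluggable.
#' @param hue_ramp function mapping normalized descriptor to hue.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path, value_rule = default_value_rule,
                       hue_ramp = default_hue_ramp) {
  stopifnot(inherits(map, "mqn_map"))
  png::writePNG(.map_rgb(map, value_rule, hue_ramp), path)
  invisible(path)
}

#' Plot an MQN/PCA map on the active device
#' @param x an `mqn_map`.
#' @param ... passed to [graphics::plot()].
#' @inheritParams render_map
#' @export
plot.mqn_map <- function(x, value_rule = default_value_rule,
                         hue_ramp = default_hue_ramp, ...) {
  img <- .map_rgb(x, value_rule, hue_ramp)
  graphics::plot(c(0, x$w), c(0, x$h), type = "n", asp = 1,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]), ...)
  graphics::rasterImage(img, 0, 0, x$w, x$h, interpolate = FALSE)
  invisible(x)
}
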