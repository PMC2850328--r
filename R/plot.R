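#' Similarity surface over the V/H plane
#'
#' Contour-style raster of the expected parent--offspring similarity
#' (with `I = 1`) as a function of the variable fraction `V` and the
#' heritable fraction `H <= V`, at fixed lifetime-change and copy-error
#' probabilities. Useful for seeing how the loss of similarity is
#' governed by the non-heritable variable part at high `upsilon` and by
#' the heritable part at high `mu`.
#'
#' @param upsilon,mu per-module change and miscopy probabilities.
#' @param epsilon backmutation probability (default 0).
#' @param n grid resolution per axis.
#' @return A ggplot object.
#' @examples
#' plot_similarity_surface(upsilon = 0.2, mu = 0.05)
#' @export
plot_similarity_surface <- function(upsilon = 0.1, mu = 0.05, epsilon = 0,
                                    n = 51L) {
  v <- seq(0, 1, length.out = n)
  grid <- tidyr::expand_grid(V = v, H = v)
  grid <- dplyr::filter(grid, .data$H <= .data$V)
  grid$similarity <- purrr::map2_dbl(grid$V, grid$H, function(V, H) {
    expected_similarity(vh_params(1000L, V, H, upsilon, mu, epsilon)) / 1000
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$V, y = .data$H,
                                     fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(ggplot2::aes(z = .data$similarity),
                          colour = "white", bins = 10, linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "V (variable fraction)", y = "H (heritable fraction)",
      fill = "similarity",
      title = sprintf("Expected similarity, upsilon = %g, mu = %g",
                      upsilon, mu)) +
    ggplot2::theme_minimal()
}
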