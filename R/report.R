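#' Per-class voxel counts of a TCA result
#'
#' @param result A `tca_result`.
#' @return Named integer vector over the four classes (zero-filled).
#' @export
class_counts <- function(result) {
  levels <- c("non_responsive", "non_selective", "red_selective",
              "blue_selective")
  tab <- table(factor(result$class, levels = levels))
  setNames(as.integer(tab), levels)
}

#' Seed-red versus seed-blue correlation scatter
#'
#' The diagnostic scatter of each voxel's correlation with the red
#' reference against its correlation with the blue reference, coloured by
#' the signed t value, with FDR survivors outlined.  Voxels on the
#' diagonal respond to both dimensions alike (responsive, non-selective);
#' voxels pulled toward either axis are selective for that dimension.
#'
#' @param result A `tca_result`.
#' @param file Optional output path (png or pdf, by extension); when
#'   `NULL` the ggplot object is returned for on-screen use.
#' @return The ggplot object, invisibly when written to file.
#' @export
tca_scatter <- function(result, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("tca_scatter needs the 'ggplot2' package", call. = FALSE)
  }
  keep <- which(result$valid)
  df <- data.frame(r_sr = result$triple$r_sr[keep],
                   r_sb = result$triple$r_sb[keep],
                   t = result$t[keep],
                   survives = result$survives[keep])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = r_sb, y = r_sr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = t), size = 1.2,
                        alpha = 0.8) +
    ggplot2::geom_point(data = df[df$survives, , drop = FALSE],
                        shape = 21, size = 1.8, colour = "black",
                        fill = NA, stroke = 0.5) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey80",
                                    high = "red", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "correlation with blue reference (r_sb)",
                  y = "correlation with red reference (r_sr)",
                  colour = "t") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

utils::globalVariables(c("r_sb", "r_sr"))
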