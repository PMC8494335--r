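#' Bar plot of a 119-channel signature or spectrum
#'
#' Draws per-channel bars coloured by mutation class (the six substitution
#' types, DNV/MNV, indels, SVs), in scheme order. Pass a device (e.g.
#' `png()` or `svg()`) before calling to write a file.
#'
#' @param x Numeric vector of length 119 (counts or rates in scheme order),
#'   or a `signature_fit` whose wild-type radiation signature is drawn.
#' @param main Plot title.
#' @param ylab Y-axis label.
#' @param scheme A `channel_scheme`.
#' @return Invisibly, the bar midpoints.
#' @export
plot_signature <- function(x, main = "", ylab = "mutations per 80 Gy",
                           scheme = channel_scheme()) {
  if (inherits(x, "signature_fit")) x <- x$ir_mean
  stopifnot(length(x) == 119L)
  sub6 <- substr(scheme$labels[1:96], 3, 5)
  class_of <- c(sub6, "DNV", "MNV", rep("indel", 14), rep("SV", 7))
  palette <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
               "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4",
               DNV = "#8B5CF6", MNV = "#5B21B6", indel = "#F59E0B",
               SV = "#374151")
  mids <- graphics::barplot(as.numeric(x), col = palette[class_of],
                            border = NA, main = main, ylab = ylab,
                            names.arg = rep("", 119), space = 0.2)
  blocks <- c(seq(1, 96, by = 16), 97, 99, 113)
  labs <- c(unique(sub6), "DNV/MNV", "indel", "SV")
  ends <- c(blocks[-1] - 1, 119)
  graphics::axis(1, at = (mids[blocks] + mids[ends]) / 2, labels = labs,
                 tick = FALSE, cex.axis = 0.7, line = -0.5)
  invisible(mids)
}
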