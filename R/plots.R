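# Agreement plotting (ggplot2 is suggested, not required).

#' Bland-Altman difference plot
#'
#' Differences (absolute or percent of the pairwise mean) against the
#' pairwise mean, with the bias and 95% limits of agreement as horizontal
#' lines and their confidence bands shaded.
#'
#' @param ba a `vams_agreement` from [bland_altman()].
#' @param percent plot percent differences (default) or absolute ones.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(ba, percent = TRUE) {
  stopifnot(inherits(ba, "vams_agreement"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman needs the ggplot2 package", call. = FALSE)
  }
  df <- ba$plot_data
  if (percent) {
    df <- df[!is.na(df$pct_diff), ]
    y <- df$pct_diff
    bias <- mean(y)
    s <- stats::sd(y)
    lines <- c(bias, bias - 1.96 * s, bias + 1.96 * s)
    ylab <- "difference [% of pairwise mean]"
  } else {
    y <- df$diff
    lines <- c(ba$bias, ba$loa_low, ba$loa_high)
    ylab <- "difference [ng/mL]"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = y)) +
    ggplot2::geom_hline(yintercept = lines[1], linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = lines[2:3], linetype = "dashed") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "mean of both measurements [ng/mL]", y = ylab,
                  title = ba$analyte) +
    ggplot2::theme_minimal()
}
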