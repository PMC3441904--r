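#' Assemble funnel-plot limit series on the SMR scale
#'
#' Builds the long-format data behind a funnel plot: for each requested
#' method and level, count-scale limits along a grid of expected counts and
#' their SMR-scale counterparts (count limit divided by `lambda`, so the
#' target line sits at SMR = 1).  When `smooth_prediction` is on, the
#' prediction series uses the interpolated limits of
#' [interpolated_prediction_limits()]; classification never does.
#'
#' @param lambda Ascending positive grid of expected counts.
#' @param methods Methods to include (default all three).
#' @param levels Two-sided levels (default 0.95 and 0.998).
#' @param tail_rule Tail rule for prediction limits.
#' @param smooth_prediction Smooth the prediction step curves for display
#'   (default `TRUE`).
#' @return A data frame with columns `lambda`, `method`, `level`, `side`
#'   (`"lower"`/`"upper"`), `count_limit`, `smr_limit`.
#' @examples
#' build_funnel(1:50, methods = "exact", levels = 0.95)
#' @export
build_funnel <- function(lambda, methods = limit_methods(),
                         levels = c(0.95, 0.998),
                         tail_rule = "conservative",
                         smooth_prediction = TRUE) {
  lambda <- check_lambda(lambda)
  if (is.unsorted(lambda, strictly = FALSE)) {
    stop("'lambda' grid must be ascending", call. = FALSE)
  }
  methods <- match.arg(methods, limit_methods(), several.ok = TRUE)
  if (length(levels) == 0L) stop("'levels' must be non-empty", call. = FALSE)

  pieces <- list()
  for (level in levels) {
    for (method in methods) {
      lim <- if (method == "prediction" && smooth_prediction) {
        interpolated_prediction_limits(lambda, level)
      } else {
        poisson_limits(lambda, method, level, tail_rule)
      }
      for (side in c("lower", "upper")) {
        cl <- if (side == "lower") lim$lower else lim$upper
        pieces[[length(pieces) + 1L]] <- data.frame(
          lambda = lambda, method = method, level = level, side = side,
          count_limit = cl, smr_limit = cl / lambda,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Draw a funnel plot for the SMR
#'
#' Renders limit series from [build_funnel()] and, optionally, providers
#' from [classify_providers()] as a funnel plot: expected events on the x
#' axis, SMR on the y axis, the target line at 1, nested control limits,
#' and outlying providers highlighted.  Negative Wald lower limits are
#' clamped to zero for display only; stored series are never altered.
#'
#' @param series Data frame from [build_funnel()].
#' @param providers Optional data frame with columns `expected` and `smr`
#'   (and, if present, a `flag` column used to colour points) -- typically
#'   the output of [classify_providers()] with `flag` taken from one of its
#'   flag columns.
#' @param path Optional output file; written with [ggplot2::ggsave()], the
#'   format chosen by the extension (`.png`, `.svg`, `.pdf`).
#' @param width,height Figure size in inches when `path` is given.
#' @return The ggplot object, invisibly.
#' @export
render_funnel <- function(series, providers = NULL, path = NULL,
                          width = 7, height = 5) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("'series' must be a non-empty data frame from build_funnel()",
         call. = FALSE)
  }
  series$smr_display <- pmax(series$smr_limit, 0)
  series$curve <- interaction(series$method, series$level, series$side)

  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(
      data = series,
      ggplot2::aes(x = .data$lambda, y = .data$smr_display,
                   group = .data$curve, colour = .data$method,
                   linetype = factor(.data$level))
    ) +
    ggplot2::labs(
      x = "Expected number of events",
      y = "SMR (observed / expected)",
      colour = "Method", linetype = "Level",
      caption = "Negative lower limits clamped to 0 for display"
    ) +
    ggplot2::theme_bw()

  if (!is.null(providers) && nrow(providers) > 0L) {
    if (!all(c("expected", "smr") %in% names(providers))) {
      stop("'providers' must have columns 'expected' and 'smr'", call. = FALSE)
    }
    if ("flag" %in% names(providers)) {
      p <- p + ggplot2::geom_point(
        data = providers,
        ggplot2::aes(x = .data$expected, y = .data$smr,
                     shape = .data$flag != "inside"),
        size = 2
      ) + ggplot2::scale_shape_manual(
        values = c(`FALSE` = 1, `TRUE` = 17), name = "Outlier"
      )
    } else {
      p <- p + ggplot2::geom_point(
        data = providers,
        ggplot2::aes(x = .data$expected, y = .data$smr), shape = 1, size = 2
      )
    }
  }

  if (!is.null(path)) {
    ggplot2::ggsave(path, plot = p, width = width, height = height)
  }
  invisible(p)
}
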