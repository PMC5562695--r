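#' @export
print.mserg_registration <- function(x, ...) {
  lv <- attr(x$similarity_trace, "level_lengths")
  cat(sprintf("<mserg_registration> method '%s'%s, similarity '%s'\n",
              x$method,
              if (is.null(x$scales)) ""
              else sprintf(" (kappa = %s)", paste(x$scales, collapse = ",")),
              x$similarity))
  n <- field_norms(x$field)
  cat(sprintf("  field: mean |u| %.3f px, max %.3f px\n", mean(n), max(n)))
  cat(sprintf("  iterations run per level: %s\n",
              paste(lv, collapse = ", ")))
  invisible(x)
}

#' @export
summary.mserg_registration <- function(object, ...) {
  tr <- object$similarity_trace
  lv <- attr(tr, "level_lengths")
  n <- field_norms(object$field)
  starts <- cumsum(c(1, head(lv, -1)))
  ends <- cumsum(lv)
  out <- list(method = object$method, similarity = object$similarity,
              scales = object$scales,
              levels = object$config_echo$resolution_levels,
              iterations = lv,
              trace_first = tr[starts], trace_last = tr[ends],
              field_mean = mean(n), field_max = max(n),
              coef_range = range(object$transform$coefficients))
  class(out) <- "summary.mserg_registration"
  out
}

#' @export
print.summary.mserg_registration <- function(x, ...) {
  cat(sprintf("Registration method: %s (similarity %s)\n", x$method,
              x$similarity))
  if (!is.null(x$scales))
    cat(sprintf("Length scales: %s\n", paste(x$scales, collapse = ", ")))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  level eta = %g: %d iterations, similarity %.5g -> %.5g\n",
                x$levels[i], x$iterations[i], x$trace_first[i],
                x$trace_last[i]))
  }
  cat(sprintf("Recovered field: mean |u| %.3f px, max %.3f px\n",
              x$field_mean, x$field_max))
  invisible(x)
}

#' @export
coef.mserg_registration <- function(object, ...) {
  object$transform$coefficients
}

#' Warp a new image with a fitted registration
#'
#' @param object an `mserg_registration`.
#' @param newdata a [gray_image()] (or matrix) on the registration domain;
#'   defaults to returning the stored warped moving image.
#' @param ... unused.
#' @return the warped [gray_image()].
#' @export
predict.mserg_registration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$warped_moving)
  if (!inherits(newdata, "gray_image")) newdata <- gray_image(newdata)
  warp_image(newdata, object$transform)
}

#' Plot a fitted registration
#'
#' Left: the similarity trace over iterations (level boundaries dashed).
#' Right: the magnitude of the recovered displacement field.
#'
#' @param x an `mserg_registration`.
#' @param ... passed to [graphics::image()].
#' @export
plot.mserg_registration <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  tr <- x$similarity_trace
  lv <- attr(tr, "level_lengths")
  graphics::plot(seq_along(tr), tr, type = "l", xlab = "iteration",
                 ylab = "similarity", main = x$method)
  graphics::abline(v = cumsum(lv)[-length(lv)] + 0.5, lty = 2,
                   col = "gray50")
  n <- field_norms(x$field)
  graphics::image(t(n)[, nrow(n):1], col = grDevices::hcl.colors(64),
                  axes = FALSE, main = "|u| (px)", ...)
  invisible(x)
}

#' @importFrom stats coef predict
#' @importFrom utils head
NULL
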