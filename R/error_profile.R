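#' Sequencing error profiles
#'
#' An error profile holds five per-base event probabilities: insertion,
#' deletion, mismatch, plus elevated mismatch rates applied within windows at
#' the read start and end. Presets mirror the common quality regimes:
#'
#' * `"none"`  — error-free: (0, 0, 0, 0, 0)
#' * `"q20"`   — roughly one error per 1,000 bp:
#'   (0.001, 0.001, 0.006, 0.001, 0.001)
#' * `"q30"`   — roughly one error per 10,000 bp:
#'   (0.0001, 0.0001, 0.0006, 0.0001, 0.0001)
#'
#' Each base suffers at most one event, drawn from a single categorical
#' distribution; within the start (end) window the mismatch probability is
#' `p_mm + p_mm_start` (`p_mm + p_mm_end`).
#'
#' @param preset One of `"none"`, `"q20"`, `"q30"`, `"custom"`.
#' @param probs For `preset = "custom"`: numeric length-5 vector
#'   `(p_ins, p_del, p_mm, p_mm_start, p_mm_end)`.
#' @param start_window,end_window Window sizes in bp for the elevated
#'   start/end mismatch rates (default 10 bp each).
#' @return An object of class `error_profile`.
#' @examples
#' error_profile("q20")
#' error_profile("custom", probs = c(0.002, 0, 0.01, 0, 0))
#' @export
error_profile <- function(preset = c("none", "q20", "q30", "custom"),
                          probs = NULL, start_window = 10L, end_window = 10L) {
  preset <- match.arg(preset)
  p <- switch(preset,
    none = c(0, 0, 0, 0, 0),
    q20  = c(0.001, 0.001, 0.006, 0.001, 0.001),
    q30  = c(0.0001, 0.0001, 0.0006, 0.0001, 0.0001),
    custom = {
      if (is.null(probs) || length(probs) != 5L || !is.numeric(probs))
        stop("custom profile requires 'probs' of length 5: ",
             "(p_ins, p_del, p_mm, p_mm_start, p_mm_end)")
      as.numeric(probs)
    })
  if (any(p < 0) || any(p >= 1) || sum(p) >= 1)
    stop("event probabilities must each lie in [0,1) and sum to < 1")
  stopifnot_scalar_num(start_window, "start_window", lower = 0, integer = TRUE)
  stopifnot_scalar_num(end_window, "end_window", lower = 0, integer = TRUE)
  structure(list(name = preset, p_ins = p[1], p_del = p[2], p_mm = p[3],
                 p_mm_start = p[4], p_mm_end = p[5],
                 start_window = as.integer(start_window),
                 end_window = as.integer(end_window)),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "<error_profile> %s: ins %g, del %g, mm %g (+%g first %d bp, +%g last %d bp)\n",
    x$name, x$p_ins, x$p_del, x$p_mm, x$p_mm_start, x$start_window,
    x$p_mm_end, x$end_window))
  invisible(x)
}
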