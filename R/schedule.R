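#' Construct a CEE phase schedule
#'
#' A CEE consists of three contiguous phases — pre-exposure, exposure and
#' post-exposure — each analysed on a common grid of short time blocks
#' (default 5 s). The standard design uses three 10 min phases, giving 360
#' blocks of 5 s.
#'
#' @param pre_dur,exp_dur,post_dur Phase durations in seconds. Each must be a
#'   positive multiple of `block_dur`.
#' @param block_dur Block duration in seconds (default 5).
#' @return An object of class `"cee_schedule"`: a list with phase boundaries
#'   (`pre`, `exposure`, `post`, each `c(start, end)` in seconds from CEE
#'   start), `block_dur`, `n_blocks`, the per-block phase factor `phase` and
#'   block start times `block_start`.
#' @examples
#' sched <- make_phase_schedule(600, 600, 600, 5)
#' sched$n_blocks  # 360
#' table(sched$phase)
#' @export
make_phase_schedule <- function(pre_dur = 600, exp_dur = 600, post_dur = 600,
                                block_dur = 5) {
  durs <- c(pre = pre_dur, exposure = exp_dur, post = post_dur)
  if (block_dur <= 0) stop("block_dur must be positive")
  for (ph in names(durs)) {
    d <- durs[[ph]]
    if (!is.finite(d) || d <= 0)
      stop(sprintf("phase '%s' must have positive duration", ph))
    if (abs(d / block_dur - round(d / block_dur)) > 1e-9)
      stop(sprintf("duration of phase '%s' (%g s) is not a multiple of block_dur (%g s)",
                   ph, d, block_dur))
  }
  b <- cumsum(c(0, durs))
  n_blocks <- as.integer(round(sum(durs) / block_dur))
  block_start <- seq(0, by = block_dur, length.out = n_blocks)
  phase <- cut(block_start, breaks = b, right = FALSE,
               labels = c("pre", "exposure", "post"))
  structure(list(
    pre = c(b[[1]], b[[2]]),
    exposure = c(b[[2]], b[[3]]),
    post = c(b[[3]], b[[4]]),
    block_dur = block_dur,
    n_blocks = n_blocks,
    block_start = block_start,
    phase = phase
  ), class = "cee_schedule")
}

#' @export
print.cee_schedule <- function(x, ...) {
  cat("CEE phase schedule\n")
  for (ph in c("pre", "exposure", "post"))
    cat(sprintf("  %-9s [%g, %g) s\n", ph, x[[ph]][1], x[[ph]][2]))
  cat(sprintf("  %d blocks of %g s\n", x$n_blocks, x$block_dur))
  invisible(x)
}

is_schedule <- function(x) inherits(x, "cee_schedule")

stopifnot_schedule <- function(x) {
  if (!is_schedule(x)) stop("expected a 'cee_schedule' (see make_phase_schedule)")
  invisible(x)
}
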