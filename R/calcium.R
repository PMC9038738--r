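#' Calcium-transient quantification: dF/F0
#'
#' Normalizes a fluorescence time series to its pre-stimulus baseline:
#' `dF/F0 = (F(t) - F0) / F0`, where `F0` is the mean fluorescence over the
#' baseline window. A windowed baseline (rather than the single sample at
#' time zero) is used because a one-sample `F0` is fragile to acquisition
#' noise; by default the window is every sample strictly before the
#' annotated stimulus time. Peak amplitude and time-to-peak (from stimulus
#' to the dF/F0 maximum) are reported.
#'
#' @param trace a `calcium_trace` (see [make_calcium_trace()],
#'   [read_trace_csv()]) or a data.frame with columns `time_s`, `F`.
#' @param baseline_window length-2 numeric `(t_start, t_end)` in seconds;
#'   default `c(0, stimulus_time)` (all pre-stimulus samples). Must contain
#'   at least one sample and end no later than the stimulus.
#' @param stimulus_time_s stimulus time; taken from the trace annotation if
#'   absent.
#' @return The trace augmented with `F0`, `dFF0`, `peak_dFF0`,
#'   `peak_time_s`, `time_to_peak_s`, class `calcium_trace`.
#' @examples
#' tr <- make_calcium_trace(baseline = 1, amplitude = 0.8, noise_sd = 0)
#' q <- delta_f_over_f0(tr)
#' q$peak_dFF0
#' @export
delta_f_over_f0 <- function(trace, baseline_window = NULL,
                            stimulus_time_s = NULL) {
  if (is.data.frame(trace)) {
    trace <- structure(list(time_s = trace$time_s, F = trace$F,
                            stimulus_time_s = stimulus_time_s),
                       class = "calcium_trace")
  }
  stopifnot(inherits(trace, "calcium_trace"))
  if (is.null(stimulus_time_s)) stimulus_time_s <- trace$stimulus_time_s
  t <- trace$time_s
  if (is.unsorted(t, strictly = TRUE)) stop("time grid must be increasing")
  if (is.null(baseline_window)) {
    if (is.null(stimulus_time_s))
      stop("need a baseline_window or an annotated stimulus time")
    baseline_window <- c(t[1], stimulus_time_s)
    in_bw <- t < stimulus_time_s  # strictly pre-stimulus
  } else {
    if (!is.null(stimulus_time_s) && baseline_window[2] > stimulus_time_s)
      stop("baseline window must precede the stimulus")
    in_bw <- t >= baseline_window[1] & t <= baseline_window[2]
  }
  if (!any(in_bw)) stop("empty baseline window")
  f0 <- mean(trace$F[in_bw])
  if (f0 <= 0) stop("baseline F0 must be positive")
  dff0 <- (trace$F - f0) / f0
  post <- if (!is.null(stimulus_time_s)) t >= stimulus_time_s else rep(TRUE, length(t))
  ipk <- which(post)[which.max(dff0[post])]
  trace$F0 <- f0
  trace$dFF0 <- dff0
  trace$baseline_window <- baseline_window
  trace$stimulus_time_s <- stimulus_time_s
  trace$peak_dFF0 <- dff0[ipk]
  trace$peak_time_s <- t[ipk]
  trace$time_to_peak_s <- if (!is.null(stimulus_time_s))
    t[ipk] - stimulus_time_s else NA_real_
  trace
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d samples over %.1f s", length(x$time_s),
              diff(range(x$time_s))))
  if (!is.null(x$F0))
    cat(sprintf("; F0 = %.4g, peak dF/F0 = %.4g at %.2f s", x$F0,
                x$peak_dFF0, x$peak_time_s))
  cat("\n")
  invisible(x)
}
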