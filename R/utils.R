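# Shared internal helpers.

# Centered moving average whose window shrinks near the edges, so constant
# input is returned unchanged and no NAs are introduced.
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  stopifnot(window >= 1L)
  if (window == 1L || length(x) <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Least-squares slope of y on x (no aggregation), via the standard
# sums-of-deviations formula; used for rolling-window rates.
ls_slope <- function(x, y) {
  xd <- x - mean(x)
  sum(xd * y) / sum(xd * xd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_cq <- function(msg, class) {
  stop(structure(class = c(class, "clotquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
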