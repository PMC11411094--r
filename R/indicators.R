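#' Indicator series container
#'
#' Holds one technical indicator evaluated on the bin grid. Leading bins
#' inside the warm-up region (where the indicator's window is not yet
#' full) are `NA`.
#'
#' @param name Indicator name (`"SMA"`, `"EMA"`, `"MAD"`, `"MACD"`,
#'   `"RSI"`, ...).
#' @param time Bin start times (hours).
#' @param value Indicator values (`NA` during warm-up).
#' @param params Named list of the settings used.
#' @param warm_up Number of leading undefined bins.
#' @return An object of class `indicator_series`.
#' @export
indicator_series <- function(name, time, value, params = list(),
                             warm_up = sum(cumprod(is.na(value)))) {
  stopifnot(length(time) == length(value))
  structure(list(name = name, time = as.numeric(time),
                 value = as.numeric(value), params = params,
                 warm_up = as.integer(warm_up)),
            class = "indicator_series")
}

#' @export
#' @method print indicator_series
print.indicator_series <- function(x, ...) {
  cat(sprintf("<indicator_series> %s: %d bins, warm-up %d\n",
              x$name, length(x$value), x$warm_up))
  invisible(x)
}

# Accept a numeric vector, a binned_series, an rr_decomposition (trend), or
# an indicator_series; return list(time, value).
indicator_input <- function(x, column = "trend") {
  if (inherits(x, "rr_decomposition")) {
    list(time = x$time, value = x[[column]])
  } else if (inherits(x, "binned_series")) {
    list(time = x$bin_start_h, value = x$rr_ms)
  } else if (inherits(x, "indicator_series")) {
    list(time = x$time, value = x$value)
  } else {
    v <- as.numeric(x)
    list(time = (seq_along(v) - 1L) * 0.5, value = v)
  }
}

check_window <- function(n, len, name) {
  if (!is_count(n)) stop(name, " must be a positive count", call. = FALSE)
  if (n > len) {
    warning(sprintf("%s window (%d) exceeds series length (%d): all values undefined",
                    name, as.integer(n), len), call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Simple moving average
#'
#' Value at bin t is the unweighted mean of the `n` most recent values
#' (the current bin and the n-1 before it). The first n-1 bins are the
#' warm-up and are undefined. The default n = 12 spans 6 h of 30-min bins.
#'
#' @param x Input series (numeric vector, [binned_series()], or
#'   [stl_decompose()] result, whose trend is used).
#' @param n Window length in bins.
#' @return An [indicator_series()] named `"SMA"`.
#' @export
ind_sma <- function(x, n = 12L) {
  inp <- indicator_input(x)
  len <- length(inp$value)
  v <- rep(NA_real_, len)
  if (check_window(n, len, "SMA")) {
    v <- as.numeric(stats::filter(inp$value, rep(1 / n, n), sides = 1))
  }
  indicator_series("SMA", inp$time, v, params = list(n = as.integer(n)),
                   warm_up = min(as.integer(n) - 1L, len))
}

#' Exponential moving average
#'
#' `EMA_t = alpha * P_t + (1 - alpha) * EMA_{t-1}` with
#' `alpha = 2 / (n + 1)`. By default the recursion is initialized at bin n
#' with the simple mean of the first n values (warm-up n-1 bins);
#' `init = "first"` starts at the first value with no warm-up.
#'
#' @inheritParams ind_sma
#' @param init Initialization convention: `"sma"` (default) or `"first"`.
#' @return An [indicator_series()] named `"EMA"`.
#' @export
ind_ema <- function(x, n = 12L, init = c("sma", "first")) {
  init <- match.arg(init)
  inp <- indicator_input(x)
  len <- length(inp$value)
  v <- rep(NA_real_, len)
  if (check_window(n, len, "EMA")) {
    n <- as.integer(n)
    alpha <- 2 / (n + 1)
    p <- inp$value
    if (init == "sma") {
      start <- n
      e <- mean(p[1:n])
    } else {
      start <- 1L
      e <- p[1]
    }
    v[start] <- e
    if (start < len) {
      for (t in (start + 1L):len) {
        e <- alpha * p[t] + (1 - alpha) * e
        v[t] <- e
      }
    }
  }
  indicator_series("EMA", inp$time, v,
                   params = list(n = as.integer(n), init = init),
                   warm_up = if (init == "sma") min(as.integer(n) - 1L, len) else 0L)
}

#' Moving average deviation rate
#'
#' Deviation of the current value from its own simple moving average:
#' percent mode (default) `100 * (P_t - SMA_t) / SMA_t`; difference mode
#' `P_t - SMA_t`. Positive values mean the series runs above its moving
#' average (rising trend); the sign flip from + to - accompanies the sharp
#' pre-calving decline.
#'
#' @inheritParams ind_sma
#' @param mode `"percent"` (default) or `"difference"`.
#' @return An [indicator_series()] named `"MAD"`.
#' @export
ind_mad <- function(x, n = 12L, mode = c("percent", "difference")) {
  mode <- match.arg(mode)
  inp <- indicator_input(x)
  s <- ind_sma(x, n)$value
  d <- inp$value - s
  v <- if (mode == "percent") {
    ifelse(is.na(s) | s == 0, NA_real_, 100 * d / s)
  } else {
    d
  }
  indicator_series("MAD", inp$time, v,
                   params = list(n = as.integer(n), mode = mode),
                   warm_up = min(as.integer(n) - 1L, length(v)))
}

#' Moving average convergence/divergence
#'
#' Difference between a short and a long exponential moving average;
#' percent mode (default) normalizes by the long EMA:
#' `100 * (EMA_short - EMA_long) / EMA_long`. Defaults 12/26 bins
#' (6 h / 13 h at 30-min bins). Warm-up is `long - 1` bins.
#'
#' @inheritParams ind_sma
#' @param short Short EMA window (bins).
#' @param long Long EMA window (bins); must exceed `short`.
#' @param mode `"percent"` (default) or `"difference"`.
#' @return An [indicator_series()] named `"MACD"`.
#' @export
ind_macd <- function(x, short = 12L, long = 26L,
                     mode = c("percent", "difference")) {
  mode <- match.arg(mode)
  if (!is_count(short) || !is_count(long) || short >= long) {
    stop("MACD requires integer windows with short < long", call. = FALSE)
  }
  inp <- indicator_input(x)
  es <- ind_ema(x, short)$value
  el <- ind_ema(x, long)$value
  d <- es - el
  v <- if (mode == "percent") {
    ifelse(is.na(el) | el == 0, NA_real_, 100 * d / el)
  } else {
    d
  }
  indicator_series("MACD", inp$time, v,
                   params = list(short = as.integer(short),
                                 long = as.integer(long), mode = mode),
                   warm_up = min(as.integer(long) - 1L, length(v)))
}

#' Relative strength index
#'
#' Over the last `n` bin-to-bin changes, `Upward` is the sum of positive
#' changes and `Downward` the sum of absolute negative changes;
#' `RSI = 100 * Upward / (Upward + Downward)`. The default uses simple
#' unweighted sums (Cutler's form); `method = "wilder"` applies Wilder's
#' recursive smoothing instead. A window with no change at all gives 50
#' (balance). Values lie in [0, 100]; warm-up is `n` bins. Default n = 14.
#'
#' @inheritParams ind_sma
#' @param method `"simple"` (unweighted sums, default) or `"wilder"`.
#' @return An [indicator_series()] named `"RSI"`.
#' @export
ind_rsi <- function(x, n = 14L, method = c("simple", "wilder")) {
  method <- match.arg(method)
  inp <- indicator_input(x)
  len <- length(inp$value)
  v <- rep(NA_real_, len)
  if (len >= 2L && check_window(n + 1, len, "RSI")) {
    n <- as.integer(n)
    ch <- diff(inp$value)
    up <- pmax(ch, 0)
    dn <- pmax(-ch, 0)
    if (method == "simple") {
      U <- as.numeric(stats::filter(up, rep(1, n), sides = 1))
      D <- as.numeric(stats::filter(dn, rep(1, n), sides = 1))
    } else {
      U <- D <- rep(NA_real_, length(ch))
      u <- mean(up[1:n]); d <- mean(dn[1:n])
      U[n] <- u; D[n] <- d
      if (length(ch) > n) {
        for (j in (n + 1L):length(ch)) {
          u <- (u * (n - 1) + up[j]) / n
          d <- (d * (n - 1) + dn[j]) / n
          U[j] <- u; D[j] <- d
        }
      }
    }
    tot <- U + D
    r <- ifelse(!is.na(tot) & tot == 0, 50, 100 * U / tot)
    v[(n + 1L):len] <- r[n:length(ch)]
  }
  indicator_series("RSI", inp$time, v,
                   params = list(n = as.integer(n), method = method),
                   warm_up = min(as.integer(n), len))
}

#' Compute the standard indicator panel on a trend series
#'
#' Convenience wrapper returning SMA, MAD, MACD and RSI with the study's
#' default windows (12, 12, 12/26, 14).
#'
#' @param x Input series (typically the trend of [stl_decompose()]).
#' @param sma_n,mad_n,macd_short,macd_long,rsi_n Window lengths.
#' @param mode Percent or difference mode for MAD and MACD.
#' @return Named list of [indicator_series()]: `SMA`, `MAD`, `MACD`, `RSI`.
#' @export
indicator_panel <- function(x, sma_n = 12L, mad_n = 12L,
                            macd_short = 12L, macd_long = 26L, rsi_n = 14L,
                            mode = c("percent", "difference")) {
  mode <- match.arg(mode)
  list(SMA = ind_sma(x, sma_n),
       MAD = ind_mad(x, mad_n, mode = mode),
       MACD = ind_macd(x, macd_short, macd_long, mode = mode),
       RSI = ind_rsi(x, rsi_n))
}
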