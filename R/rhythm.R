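.check_uniform <- function(t) {
  if (length(t) < 3L || is.unsorted(t, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  dt <- diff(t)
  if (max(abs(dt - dt[1L])) > 1e-9 * max(abs(t))) {
    stop("trace sampling must be uniform", call. = FALSE)
  }
  dt[1L]
}

#' Detrend a luminescence trace with a centred moving average
#'
#' Subtracts, from each sample, the weighted mean of all samples within
#' `window / 2` hours on either side, truncated at the record edges so output
#' length equals input length. When the sampling interval divides the
#' half-window exactly, the two samples sitting precisely at +/- window/2
#' receive weight 1/2 — the classical centred moving average over an
#' even-length span. This makes the operator exact on the signals it must
#' annihilate: a linear ramp gives interior residuals of exactly zero, and a
#' cosine whose period equals the window has an interior discrete mean of
#' exactly zero. Samples closer than `window / 2` to either edge are flagged
#' `edge`.
#'
#' @param trace data.frame with columns `time_h`, `value`; strictly
#'   increasing uniform sampling.
#' @param window moving-average span in hours (default 24); must be smaller
#'   than the record span.
#' @return data.frame with columns `time_h`, `value` (detrended),
#'   `baseline`, `edge`.
#' @examples
#' tr <- data.frame(time_h = 0:100, value = 5 + 2 * (0:100))
#' d <- detrendTrace(tr)
#' all(d$value[!d$edge] == 0)
#' @export
detrendTrace <- function(trace, window = 24) {
  stopifnot(all(c("time_h", "value") %in% names(trace)))
  t <- trace$time_h
  v <- trace$value
  dt <- .check_uniform(t)
  span <- t[length(t)] - t[1L]
  if (window >= span) {
    stop("window (", window, " h) must be smaller than the record span (",
         span, " h)", call. = FALSE)
  }
  half <- window / 2
  m <- floor(half / dt + 1e-9)
  boundary_exact <- abs(m * dt - half) <= 1e-9 * window
  n <- length(v)
  wts <- rep(1, 2L * m + 1L)
  if (boundary_exact && m >= 1L) wts[c(1L, 2L * m + 1L)] <- 0.5
  baseline <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - m):(i + m)
    keep <- j >= 1L & j <= n
    baseline[i] <- sum(wts[keep] * v[j[keep]]) / sum(wts[keep])
  }
  data.frame(time_h = t, value = v - baseline, baseline = baseline,
             edge = t - t[1L] < half | t[length(t)] - t < half)
}

# profiled residual sum of squares: for fixed (period, damping) the
# amplitude/phase enter linearly through a*cos + b*sin
.profiled_sse <- function(par, t, v) {
  Tt <- par[1L]; lam <- par[2L]
  om <- 2 * pi / Tt
  e <- exp(-lam * t)
  X <- cbind(e * cos(om * t), e * sin(om * t))
  fit <- stats::lm.fit(X, v)
  sum(fit$residuals^2)
}

.periodogram_candidates <- function(t, v, band, n_cand = 3L) {
  dt <- t[2L] - t[1L]
  x <- v - mean(v)
  nfft <- 2^ceiling(log2(length(x) * 8L))
  P <- Mod(stats::fft(c(x, rep(0, nfft - length(x)))))^2
  half <- seq_len(nfft %/% 2L)
  freq <- (half - 1L) / (nfft * dt)
  per <- ifelse(freq > 0, 1 / freq, Inf)
  in_band <- per >= band[1L] & per <= band[2L]
  if (!any(in_band)) return(mean(band))
  Pb <- P[half][in_band]
  pb <- per[in_band]
  # local maxima of the in-band power, strongest first
  loc <- which(diff(sign(diff(c(-Inf, Pb, -Inf)))) < 0)
  cand <- pb[loc[order(Pb[loc], decreasing = TRUE)]]
  utils::head(cand, n_cand)
}

#' Fit a damped cosine to a (detrended) luminescence trace
#'
#' Least-squares fit of `A exp(-lambda t) cos(2 pi t / T + phi)`. The period
#' is initialised from up to three dominant periodogram peaks inside the
#' search band; for each candidate the nonlinear profile over (T, lambda) is
#' minimised with bounded L-BFGS-B (amplitude and phase are profiled out
#' linearly), and the best start wins — deterministic, no random restarts.
#' Edge-affected samples of the detrending window are excluded from the fit.
#' Non-convergence yields a flagged (non-rhythmic) result, not an error.
#'
#' @param trace data.frame with `time_h`, `value`.
#' @param band period search band in hours (default 18-32, covering
#'   circadian periods).
#' @param detrend detrend internally first (default TRUE; set FALSE if the
#'   trace is already detrended).
#' @param window detrending window in hours.
#' @param r2_min minimum variance explained to call the trace rhythmic
#'   (default 0.5).
#' @return a [RhythmFit-class].
#' @examples
#' t <- seq(0, 120, by = 0.25)
#' tr <- data.frame(time_h = t, value = dampedCosine(t, period = 24))
#' fitDampedCosine(tr, detrend = FALSE)
#' @export
fitDampedCosine <- function(trace, band = c(18, 32), detrend = TRUE,
                            window = 24, r2_min = 0.5) {
  stopifnot(all(c("time_h", "value") %in% names(trace)))
  if (detrend) {
    d <- detrendTrace(trace, window = window)
    t <- d$time_h[!d$edge]
    v <- d$value[!d$edge]
  } else {
    t <- trace$time_h
    v <- trace$value
  }
  cand <- .periodogram_candidates(t, v, band)
  best <- NULL
  best_init <- cand[1L]
  for (T0 in cand) {
    for (l0 in c(0, 0.02)) {
      fit <- tryCatch(
        stats::optim(c(T0, l0), .profiled_sse, t = t, v = v,
                     method = "L-BFGS-B",
                     lower = c(band[1L], 0), upper = c(band[2L], 1),
                     control = list(factr = 1e5)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$value < best$value)) {
        best <- fit
        best_init <- T0
      }
    }
  }
  if (is.null(best)) {
    return(new("RhythmFit", period_h = NA_real_, amplitude = NA_real_,
               damping_rate = NA_real_, phase_rad = NA_real_,
               r_squared = NA_real_, rhythmic = FALSE, converged = FALSE,
               band = as.numeric(band), init_period_h = best_init,
               n_points = length(v)))
  }
  Tt <- best$par[1L]; lam <- best$par[2L]
  om <- 2 * pi / Tt
  e <- exp(-lam * t)
  ab <- stats::lm.fit(cbind(e * cos(om * t), e * sin(om * t)), v)$coefficients
  A <- sqrt(sum(ab^2))
  phi <- atan2(-ab[2L], ab[1L])
  sst <- sum((v - mean(v))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - best$value / sst)) else NA_real_
  converged <- best$convergence == 0L
  new("RhythmFit",
      period_h = Tt, amplitude = unname(A), damping_rate = lam,
      phase_rad = unname(phi), r_squared = r2,
      rhythmic = isTRUE(converged && !is.na(r2) && r2 >= r2_min &&
                        Tt >= band[1L] && Tt <= band[2L]),
      converged = converged, band = as.numeric(band),
      init_period_h = best_init, n_points = length(v))
}

#' Locate peaks in a detrended trace
#'
#' Local maxima whose topographic prominence (height above the higher of the
#' two flanking key saddles) reaches `prominence_frac * max(abs(value))`,
#' returned in time order. Of two equal adjacent samples forming a plateau
#' peak, the earlier time is reported.
#'
#' @param trace detrended data.frame with `time_h`, `value`.
#' @param prominence_frac prominence threshold as a fraction of the largest
#'   absolute value (default 0.25).
#' @return numeric vector of peak times (hours); empty for monotone traces.
#' @examples
#' t <- seq(0, 48, by = 0.25)
#' peakTimes(data.frame(time_h = t, value = cos(2 * pi * (t - 12) / 24)))
#' @export
peakTimes <- function(trace, prominence_frac = 0.25) {
  v <- trace$value
  n <- length(v)
  if (n < 3L) return(numeric(0))
  cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                v[2:(n - 1L)] >= v[3:n]) + 1L
  if (!length(cand)) return(numeric(0))
  thr <- prominence_frac * max(abs(v))
  prom <- vapply(cand, function(i) {
    j <- i
    minL <- v[i]
    while (j > 1L && v[j] <= v[i]) { j <- j - 1L; minL <- min(minL, v[j]) }
    j <- i
    minR <- v[i]
    while (j < n && v[j] <= v[i]) { j <- j + 1L; minR <- min(minR, v[j]) }
    v[i] - max(minL, minR)
  }, numeric(1))
  trace$time_h[cand[prom >= thr]]
}
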