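# Independent reference implementations used to check the package's
# detectors and tests. Deliberately written with different mechanisms
# (vector scans, closed forms, exhaustive enumeration) than the
# implementations they verify.

# Delta-commit peak detection by phase-wise vector scanning with
# cummax/cummin instead of a per-frame state machine.
oracle_peakdet <- function(v, delta, x = seq_along(v)) {
  n <- length(v)
  maxima <- list(); minima <- list()
  pos <- 1L
  phase <- "max"
  while (pos <= n) {
    seg <- v[pos:n]
    if (phase == "max") {
      run <- cummax(seg)
      commit <- which(seg < run - delta)
    } else {
      run <- cummin(seg)
      commit <- which(seg > run + delta)
    }
    if (length(commit) == 0L) break
    j <- commit[1]
    ext_rel <- which.max(if (phase == "max") seg[1:j] else -seg[1:j])
    ext <- pos + ext_rel - 1L
    rec <- data.frame(pos = as.numeric(x[ext]), value = v[ext])
    if (phase == "max") maxima[[length(maxima) + 1L]] <- rec
    else minima[[length(minima) + 1L]] <- rec
    pos <- pos + j - 1L
    phase <- if (phase == "max") "min" else "max"
  }
  bind <- function(l) {
    if (length(l) == 0L) data.frame(pos = numeric(), value = numeric())
    else do.call(rbind, l)
  }
  list(maxima = bind(maxima), minima = bind(minima))
}

# Stop periods by painting short supra-threshold gaps over and then
# run-length scanning, instead of merging run tables.
oracle_stops <- function(tailspeed, thresh, min_dur_s, max_gap_s, fps) {
  sub <- tailspeed < thresh
  n <- length(sub)
  if (n == 0L || !any(sub)) {
    return(data.frame(start = integer(), end = integer()))
  }
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    interior <- i > 1L && i < length(r$values)
    if (!r$values[i] && interior && r$lengths[i] <= max_gap_s * fps) {
      sub[starts[i]:ends[i]] <- TRUE
    }
  }
  r2 <- rle(sub)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  keep <- r2$values & (r2$lengths / fps >= min_dur_s)
  data.frame(start = s2[keep], end = e2[keep])
}

# Exact Fisher p by explicit enumeration of all margin-preserving tables
# with factorial-formula probabilities.
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  logp <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - lfactorial(aa) - lfactorial(bb) - lfactorial(cc) -
      lfactorial(dd)
  }
  avals <- max(0, c1 - r2):min(c1, r1)
  probs <- exp(vapply(avals, logp, numeric(1)))
  p_obs <- exp(logp(a))
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

# Per-frame finite-difference speed by an explicit loop.
oracle_speed <- function(pts, fps, ppm) {
  n <- nrow(pts)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      d <- pts[2, ] - pts[1, ]; dt <- 1 / fps
    } else if (i == n) {
      d <- pts[n, ] - pts[n - 1, ]; dt <- 1 / fps
    } else {
      d <- pts[i + 1, ] - pts[i - 1, ]; dt <- 2 / fps
    }
    out[i] <- sqrt(sum(d^2)) / dt / ppm
  }
  out
}

# Unwrap-then-difference signed angular speed.
oracle_omega <- function(theta, fps) {
  dw <- diff(theta)
  dw <- (dw + pi) %% (2 * pi) - pi
  u <- cumsum(c(theta[1], dw))
  n <- length(u)
  out <- numeric(n)
  out[1] <- (u[2] - u[1]) * fps
  out[n] <- (u[n] - u[n - 1]) * fps
  if (n > 2) {
    i <- 2:(n - 1)
    out[i] <- (u[i + 1] - u[i - 1]) * fps / 2
  }
  out
}
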