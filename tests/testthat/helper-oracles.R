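# Independent oracles and fixture builders used across the suite.
# Oracles are written naively (explicit loops, full rescans) on purpose so
# they share no code path with the package implementation.

# brute-force amplitude-threshold extremum finder: segment-rescan
# formulation. In ridge-seeking state, find the first sample lying strictly
# more than thr below the running segment maximum; the first attainment of
# that maximum is the committed ridge (plateau-midpoint position). Then
# switch to groove-seeking and repeat. Shares no code with the package
# implementation.
oracle_find_extrema <- function(profile, thr) {
  s <- profile$samples
  s <- s[!is.na(s$elevation), ]
  dist <- s$distance; elev <- s$elevation
  n <- length(elev)
  out <- data.frame(distance = numeric(0), elevation = numeric(0),
                    type = character(0))
  plateau_mid <- function(k) {
    j <- k
    while (j < n && elev[j + 1] == elev[k]) j <- j + 1
    mean(dist[k:j])
  }
  i <- 1; seeking <- "max"
  repeat {
    if (i >= n) break
    committed <- FALSE
    for (j in (i + 1):n) {
      seg <- elev[i:j]
      if (seeking == "max") {
        if (elev[j] < max(seg) - thr) {
          k <- i + which.max(seg) - 1
          out <- rbind(out, data.frame(distance = plateau_mid(k),
                                       elevation = max(seg), type = "max"))
          i <- j; seeking <- "min"; committed <- TRUE
          break
        }
      } else {
        if (elev[j] > min(seg) + thr) {
          k <- i + which.min(seg) - 1
          out <- rbind(out, data.frame(distance = plateau_mid(k),
                                       elevation = min(seg), type = "min"))
          i <- j; seeking <- "max"; committed <- TRUE
          break
        }
      }
    }
    if (!committed) break
  }
  out
}

# wrap bare (distance, elevation) vectors as a profile2d-shaped object
make_profile <- function(distance, elevation) {
  structure(
    list(samples = tibble::tibble(distance = distance, elevation = elevation),
         transect = NULL, provenance = "test"),
    class = "profile2d"
  )
}

# random piecewise-smooth profile with occasional quantisation (creates
# plateaus and ties)
random_profile <- function(n, quantize = FALSE) {
  x <- seq(0, n - 1) * 1.0
  z <- cumsum(rnorm(n)) + 3 * sin(x / runif(1, 2, 20))
  if (quantize) z <- round(z * 2) / 2
  make_profile(x, z)
}

# small flat-crown spec used by several tests
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(extent = c(120, 800), pixel_pitch = 2, crown_radius = Inf,
                   apex_frac = 0.5,
                   defects = data.frame(center = 400, width = 150, depth = 30),
                   noise_sd = 0, spike_rate = 0, dropout_rate = 0, seed = 1)
  defaults[names(args)] <- args  # plain replacement (no recursive merging)
  do.call(synthetic_spec, defaults)
}
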