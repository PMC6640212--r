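# Independent brute-force oracles and random-instance generators used by
# the unit and acceptance tests. Every oracle recomputes the quantity by a
# different route than the package (explicit loops over the definition).

random_grid <- function(f = 2L, h = 4L, w = 4L, t_max = 4L,
                        p_silent = 0.3) {
  times <- sample.int(t_max, f * h * w, replace = TRUE) - 1L
  times[stats::runif(f * h * w) < p_silent] <- NA_integer_
  array(times, dim = c(f, h, w))
}

random_wave <- function(f = 2L, h = 4L, w = 4L, t_max = 4L,
                        p_silent = 0.3) {
  spike_times_to_wave(random_grid(f, h, w, t_max, p_silent), t_max)
}

# per-step convolution of the instantaneous (non-accumulative) spikes,
# cumulatively summed over time
oracle_conv <- function(wave, layer) {
  d <- dim(wave)
  kh <- layer$kernel_size[1L]; kw <- layer$kernel_size[2L]
  h_out <- d[3L] - kh + 1L; w_out <- d[4L] - kw + 1L
  f_out <- layer$out_features
  inst <- wave
  if (d[1L] > 1L)
    inst[-1L, , , ] <- wave[-1L, , , ] - wave[-d[1L], , , ]
  out <- array(0, dim = c(d[1L], f_out, h_out, w_out))
  for (t in seq_len(d[1L])) {
    for (fo in seq_len(f_out)) {
      for (r in seq_len(h_out)) {
        for (c in seq_len(w_out)) {
          patch <- inst[t, , r:(r + kh - 1L), c:(c + kw - 1L)]
          out[t, fo, r, c] <- sum(layer$weights[fo, , , ] * patch)
        }
      }
    }
  }
  if (d[1L] == 1L) out else apply(out, c(2L, 3L, 4L), cumsum)
}

# naive window maximum per time-step/feature with explicit border handling
oracle_pool <- function(x, spec) {
  d <- dim(x)
  dh <- spec$padding[1L]; dw <- spec$padding[2L]
  hp <- d[3L] + 2L * dh; wp <- d[4L] + 2L * dw
  xp <- array(0, dim = c(d[1L], d[2L], hp, wp))
  xp[, , dh + seq_len(d[3L]), dw + seq_len(d[4L])] <- x
  h_out <- hp %/% spec$stride[1L]; w_out <- wp %/% spec$stride[2L]
  out <- array(0, dim = c(d[1L], d[2L], h_out, w_out))
  for (t in seq_len(d[1L])) for (f in seq_len(d[2L])) {
    for (i in seq_len(h_out)) for (j in seq_len(w_out)) {
      rs <- (i - 1L) * spec$stride[1L] + 1L
      cs <- (j - 1L) * spec$stride[2L] + 1L
      re <- min(rs + spec$window[1L] - 1L, hp)
      ce <- min(cs + spec$window[2L] - 1L, wp)
      out[t, f, i, j] <- max(xp[t, f, rs:re, cs:ce])
    }
  }
  out
}

# first step with a nonzero entry, scanned explicitly
oracle_first_step <- function(col) {
  hit <- which(col != 0)
  if (length(hit) == 0L) NA_integer_ else hit[1L] - 1L
}

# per-location argmin(step)/argmax(final potential) feature competition
oracle_pointwise <- function(tp) {
  d <- dim(tp)
  times <- array(NA_integer_, dim = d[-1L])
  for (r in seq_len(d[3L])) for (c in seq_len(d[4L])) {
    best <- NULL
    for (f in seq_len(d[2L])) {
      s <- oracle_first_step(tp[, f, r, c])
      if (is.na(s)) next
      p <- tp[d[1L], f, r, c]
      if (is.null(best) || s < best$s || (s == best$s && p > best$p))
        best <- list(f = f, s = s, p = p)
    }
    if (!is.null(best)) times[best$f, r, c] <- best$s
  }
  spike_times_to_wave(times, d[1L])
}

# exhaustive iterative winner selection with explicit suppression
oracle_winners <- function(tp, k, radius) {
  d <- dim(tp)
  cand <- expand.grid(f = seq_len(d[2L]), r = seq_len(d[3L]),
                      c = seq_len(d[4L]))
  cand$step <- mapply(function(f, r, c) oracle_first_step(tp[, f, r, c]),
                      cand$f, cand$r, cand$c)
  cand$pot <- mapply(function(f, r, c) tp[d[1L], f, r, c],
                     cand$f, cand$r, cand$c)
  cand <- cand[!is.na(cand$step), , drop = FALSE]
  winners <- list()
  while (length(winners) < k && nrow(cand) > 0L) {
    o <- order(cand$step, -cand$pot, cand$f, cand$r, cand$c)
    w <- cand[o[1L], , drop = FALSE]
    winners[[length(winners) + 1L]] <- w
    keep <- cand$f != w$f &
      !(abs(cand$r - w$r) <= radius & abs(cand$c - w$c) <= radius)
    cand <- cand[keep, , drop = FALSE]
  }
  if (length(winners) == 0L)
    return(data.frame(feature = integer(), row = integer(),
                      col = integer(), step = integer(),
                      potential = numeric()))
  out <- do.call(rbind, winners)
  data.frame(feature = out$f, row = out$r, col = out$c, step = out$step,
             potential = out$pot)
}

# per-pixel truncated-neighbourhood mean normalization
oracle_local_norm <- function(map, region, eps = 1e-12) {
  d <- dim(map)
  half <- (region - 1L) %/% 2L
  out <- map
  for (f in seq_len(d[1L])) for (r in seq_len(d[2L])) {
    for (c in seq_len(d[3L])) {
      rs <- max(1L, r - half):min(d[2L], r + half)
      cs <- max(1L, c - half):min(d[3L], c + half)
      out[f, r, c] <- map[f, r, c] / (mean(map[f, rs, cs]) + eps)
    }
  }
  out
}

# brute-force sliding-window filtering with explicit padding
oracle_filter <- function(image, bank) {
  size <- bank$window_size
  pd <- bank$padding
  padded <- matrix(0, nrow(image) + 2L * pd, ncol(image) + 2L * pd)
  padded[pd + seq_len(nrow(image)), pd + seq_len(ncol(image))] <- image
  h_out <- nrow(padded) - size + 1L
  w_out <- ncol(padded) - size + 1L
  out <- array(0, dim = c(length(bank$kernels), h_out, w_out))
  for (f in seq_along(bank$kernels)) {
    for (r in seq_len(h_out)) for (c in seq_len(w_out)) {
      v <- sum(bank$kernels[[f]] *
                 padded[r:(r + size - 1L), c:(c + size - 1L)])
      out[f, r, c] <- if (v < bank$clip_threshold) 0 else v
    }
  }
  out
}

random_potentials <- function(f = 3L, h = 5L, w = 5L, t_max = 4L) {
  p <- array(stats::runif(t_max * f * h * w, 0, 2),
             dim = c(t_max, f, h, w))
  apply(p, c(2L, 3L, 4L), cumsum)
}
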