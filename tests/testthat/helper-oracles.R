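# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementation.

# Maximal closed runs of a logical mask (NA terminates a run).
oracle_events <- function(mask) {
  out <- list()
  start <- NA
  for (i in seq_along(mask)) {
    v <- mask[i]
    if (isTRUE(v)) {
      if (is.na(start)) start <- i
    } else {
      if (!is.na(start)) {
        out[[length(out) + 1]] <- c(start = start - 1L, len = i - start)
        start <- NA
      }
    }
  }
  if (!is.na(start)) {
    out[[length(out) + 1]] <- c(start = start - 1L,
                                len = length(mask) - start + 1L)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), len = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# Window indicators recomputed from scratch from the raw mask.
oracle_indicators <- function(mask, fps = 60, window_s = 30,
                              blink_max_ms = 200) {
  blink_max <- round(blink_max_ms * fps / 1000)
  ev <- oracle_events(mask)
  qual <- ev[ev$len > blink_max, , drop = FALSE]
  win_n <- round(window_s * fps)
  n_win <- ceiling(length(mask) / win_n)
  res <- data.frame(window = seq_len(n_win) - 1L, closed = 0L,
                    n_clusters = 0L, total_dur = 0L)
  if (nrow(qual) > 0) {
    for (i in seq_len(nrow(qual))) {
      frames <- qual$start[i]:(qual$start[i] + qual$len[i] - 1L)
      for (f in frames) {
        w <- f %/% win_n + 1L
        res$closed[w] <- res$closed[w] + 1L
      }
      w0 <- qual$start[i] %/% win_n + 1L
      res$n_clusters[w0] <- res$n_clusters[w0] + 1L
      res$total_dur[w0] <- res$total_dur[w0] + qual$len[i]
    }
  }
  res$n_frames <- pmin(win_n, length(mask) - res$window * win_n)
  res$perclos <- res$closed / res$n_frames
  res$ecd_frames <- ifelse(res$n_clusters > 0,
                           res$total_dur / res$n_clusters, NA_real_)
  res$fec <- res$n_clusters
  res
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Random closed/open mask with geometric-ish runs.
random_mask <- function(n, p_closed = 0.15, p_na = 0) {
  mask <- runif(n) < p_closed
  if (p_na > 0) mask[runif(n) < p_na] <- NA
  mask
}

# Rendered calibration + classification of a synthetic aperture signal.
classify_rendered <- function(aperture, seed = 1, noise_sd = 0.02,
                              fps = 60) {
  r <- render_frames(aperture, noise_sd = noise_sd, seed = seed)
  open_idx <- which(aperture > 0.8)
  sel <- render_selection(r, open_idx[seq_len(min(3, length(open_idx)))] - 1L)
  cal <- build_templates(r$frames, sel)
  classify_sequence(r$frames, cal, r$landmarks, fps = fps)
}
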