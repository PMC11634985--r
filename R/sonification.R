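# Distance-to-audio perceptual code: the forward wall distance is mapped to
# a tone frequency (closer wall -> higher pitch) and a clear passage ahead
# is signalled by a footstep sound.

#' Sonifier configuration
#'
#' Parameters of the distance-to-frequency perceptual code. A wall at
#' distance 0 sounds at `f_max`; distances at or beyond `d_max` sound at
#' `f_min`. The default two-octave musical range (220-880 Hz) with a linear
#' map keeps equal distance differences equally discriminable.
#'
#' @param f_min,f_max Frequency range in Hz (`0 < f_min < f_max`).
#' @param d_max Distance (cell units, >= 1) at which the tone bottoms out.
#' @param mapping `"LINEAR"` or `"LOG"` (logarithmic distance compression).
#' @return An object of class `sonifier_config`.
#' @export
sonifier_config <- function(f_min = 220, f_max = 880, d_max = 5,
                            mapping = c("LINEAR", "LOG")) {
  mapping <- match.arg(mapping)
  stopifnot(f_min > 0, f_max > f_min, d_max >= 1)
  structure(list(f_min = f_min, f_max = f_max, d_max = d_max,
                 mapping = mapping),
            class = "sonifier_config")
}

#' Map a wall distance to a tone frequency
#'
#' Strictly decreasing on `[0, d_max]`: distance 0 maps to `f_max`
#' (imminent wall), `d >= d_max` maps to `f_min`. The `LINEAR` map is
#' `f_max - (d/d_max) (f_max - f_min)`; the `LOG` map substitutes
#' `ln(1+d)/ln(1+d_max)` for `d/d_max`.
#'
#' @param d Distance in cell units (vectorized, must be >= 0).
#' @param cfg A [sonifier_config()].
#' @return Frequency in Hz, in `[f_min, f_max]`.
#' @export
distance_to_frequency <- function(d, cfg = sonifier_config()) {
  if (any(d < 0)) stop("distance must be non-negative", call. = FALSE)
  u <- pmin(d, cfg$d_max)
  frac <- switch(cfg$mapping,
                 LINEAR = u / cfg$d_max,
                 LOG = log1p(u) / log1p(cfg$d_max))
  cfg$f_max - frac * (cfg$f_max - cfg$f_min)
}

#' Invert the distance-to-frequency map
#'
#' @param f Frequency in Hz within `[f_min, f_max]`.
#' @param cfg A [sonifier_config()].
#' @return The distance in `[0, d_max]` mapping to `f`.
#' @export
frequency_to_distance <- function(f, cfg = sonifier_config()) {
  if (any(f < cfg$f_min - 1e-9 | f > cfg$f_max + 1e-9)) {
    stop("frequency outside [f_min, f_max]", call. = FALSE)
  }
  frac <- (cfg$f_max - f) / (cfg$f_max - cfg$f_min)
  switch(cfg$mapping,
         LINEAR = frac * cfg$d_max,
         LOG = expm1(frac * log1p(cfg$d_max)))
}

audio_cue <- function(kind, onset, duration, frequency = NA_real_) {
  list(kind = kind, onset = onset, duration = duration,
       frequency = frequency)
}

#' Sonify the agent's current state
#'
#' Emits one TONE whose frequency encodes the forward-ray wall distance at
#' the agent's heading. When the edge immediately ahead is open
#' (distance >= 1) a FOOTSTEP cue signalling clear passage is emitted as
#' well; an imminent wall (distance 0) yields only the maximum-proximity
#' tone.
#'
#' @param state An `hw_agent_state`.
#' @param m The `hw_maze`.
#' @param cfg A [sonifier_config()].
#' @param tone_duration,footstep_duration Cue durations in seconds.
#' @return List of audio cues (`kind`, `onset`, `duration`, `frequency`).
#' @export
sonify_state <- function(state, m, cfg = sonifier_config(),
                         tone_duration = 0.3, footstep_duration = 0.05) {
  d <- wall_distance(m, state$position, state$heading)
  onset <- state$elapsed
  cues <- list(audio_cue("TONE", onset, tone_duration,
                         distance_to_frequency(d, cfg)))
  if (d >= 1) {
    cues <- c(list(audio_cue("FOOTSTEP", onset, footstep_duration)), cues)
  }
  cues
}

#' Sonify a full trial trajectory
#'
#' Produces the trial's cue stream: at every step, a TONE for the wall
#' distance at the resulting pose, plus one FOOTSTEP per successful forward
#' step (clear passage). Cue onsets follow the discrete trial clock.
#'
#' @param trial An `hw_trial` from [run_trial()].
#' @param m The maze the trial was run on.
#' @param cfg A [sonifier_config()].
#' @param tone_duration,footstep_duration Cue durations in seconds.
#' @return Data frame with columns `onset_s, duration_s, kind,
#'   frequency_hz` (the cue stream CSV layout).
#' @export
sonify_trajectory <- function(trial, m, cfg = sonifier_config(),
                              tone_duration = 0.3, footstep_duration = 0.05) {
  if (trial$maze_id != m$id) {
    stop("trial was recorded on maze '", trial$maze_id, "', not '",
         m$id, "'", call. = FALSE)
  }
  tr <- trial$trajectory
  out <- vector("list", 2L * nrow(tr))
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    onset <- (tr$step[i]) * trial$dt
    if (!is.na(tr$action[i]) && tr$event[i] %in% c("FOOTSTEP", "GOAL_REACHED")) {
      k <- k + 1L
      out[[k]] <- data.frame(onset_s = onset, duration_s = footstep_duration,
                             kind = "FOOTSTEP", frequency_hz = NA_real_)
    }
    d <- wall_distance(m, list(row = tr$row[i], col = tr$col[i]),
                       tr$heading[i])
    k <- k + 1L
    out[[k]] <- data.frame(onset_s = onset, duration_s = tone_duration,
                           kind = "TONE",
                           frequency_hz = distance_to_frequency(d, cfg))
  }
  do.call(rbind, out[seq_len(k)])
}

#' Render a cue stream to a PCM waveform
#'
#' Tones are pure sines at the stated frequency with 10 ms linear on/off
#' ramps; footsteps are 50 ms broadband clicks (fixed pseudo-random noise
#' burst with an exponential decay). Cues of the same kind must not overlap
#' (each kind is one channel); the two kinds are mixed into one mono track.
#'
#' @param cues Data frame with `onset_s, duration_s, kind, frequency_hz`
#'   (as produced by [sonify_trajectory()]).
#' @param sample_rate Samples per second (default 44100).
#' @param amplitude Peak amplitude per cue in `[0, 1]`.
#' @return Numeric waveform vector; total length covers the last cue
#'   offset. Zero-length for an empty cue list.
#' @export
render_audio <- function(cues, sample_rate = 44100, amplitude = 0.8) {
  if (is.null(cues) || nrow(cues) == 0L) return(numeric(0))
  for (kind in unique(cues$kind)) {
    sub <- cues[cues$kind == kind, , drop = FALSE]
    sub <- sub[order(sub$onset_s), , drop = FALSE]
    if (nrow(sub) > 1L) {
      ends <- sub$onset_s[-nrow(sub)] + sub$duration_s[-nrow(sub)]
      if (any(ends > sub$onset_s[-1L] + 1e-12)) {
        stop(structure(
          class = c("hwnav_layout_error", "error", "condition"),
          list(message = paste0("overlapping ", kind, " cues"), call = NULL)))
      }
    }
  }
  total <- max(cues$onset_s + cues$duration_s)
  wave <- numeric(ceiling(total * sample_rate))
  for (i in seq_len(nrow(cues))) {
    n <- round(cues$duration_s[i] * sample_rate)
    if (n < 1L) next
    t <- (seq_len(n) - 1L) / sample_rate
    if (cues$kind[i] == "TONE") {
      x <- sin(2 * pi * cues$frequency_hz[i] * t)
      ramp_n <- min(round(0.010 * sample_rate), floor(n / 2))
      if (ramp_n > 0) {
        env <- rep(1, n)
        env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
        env[n - ramp_n + seq_len(ramp_n)] <- seq(1, 0, length.out = ramp_n)
        x <- x * env
      }
    } else {
      # deterministic broadband click: seeded noise with exponential decay
      noise <- with_local_seed(20260101L, function() stats::runif(n, -1, 1))
      x <- noise * exp(-t / (cues$duration_s[i] / 5))
    }
    i0 <- round(cues$onset_s[i] * sample_rate)
    idx <- i0 + seq_len(n)
    wave[idx] <- wave[idx] + amplitude * x
  }
  wave
}

#' Write a waveform as a 16-bit mono RIFF/WAV file
#'
#' Minimal canonical WAV container (PCM, one channel). Samples are clipped
#' to `[-1, 1]` before quantization.
#'
#' @param wave Numeric waveform in `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Samples per second.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
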