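# Synthetic eight-channel strain recordings.
#
# Emulates the structure of facial strain-gauge word recordings: four sensor
# sites, each carrying a horizontal and a vertical gauge (channels 2s-1 and 2s
# for site s), sampled at 300 Hz for 2 s per utterance. Each word class has a
# characteristic smooth multi-bump dR/R waveform per channel; repetitions vary
# by a shared timing shift, a multiplicative amplitude factor, slow baseline
# drift and additive white noise; subjects get independently perturbed copies
# of the class templates (sensor placement and user dependency).

#' Simulation configuration
#'
#' Defaults mirror the study conditions this generator emulates: 100 word
#' classes, two subjects contributing 100 repetitions per word in total, 2-s
#' utterances sampled at 300 Hz. Jitter, drift and noise magnitudes are fixed
#' desk-scale choices producing realistically overlapping repetitions; see the
#' methods vignette for the rationale.
#'
#' @param n_classes number of word classes (>= 2).
#' @param reps_per_class repetitions per class per subject.
#' @param n_subjects number of subjects.
#' @param sampling_rate samples per second (default 300).
#' @param duration seconds per utterance (default 2); `sampling_rate*duration`
#'   must be an integer.
#' @param noise_sd white-noise standard deviation, dR/R units.
#' @param time_jitter_sd sd of the per-record timing shift in seconds, shared
#'   across channels (a whole utterance starts early or late).
#' @param amp_jitter_sd sd of the per-record relative amplitude factor.
#' @param drift_amplitude bound on slow sinusoidal baseline drift, dR/R units.
#' @param subject_amp_sd sd of the per-subject, per-channel multiplicative
#'   amplitude factor (subject effect).
#' @param subject_shift_sd sd of the per-subject, per-site bump-center offset
#'   in seconds (sensor placement effect).
#' @param n_bumps bumps per channel in a class template.
#' @param seed root seed; the whole dataset is a pure function of this config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_classes = 100,
                       reps_per_class = 50,
                       n_subjects = 2,
                       sampling_rate = 300,
                       duration = 2.0,
                       noise_sd = 0.02,
                       time_jitter_sd = 0.05,
                       amp_jitter_sd = 0.10,
                       drift_amplitude = 0.05,
                       subject_amp_sd = 0.15,
                       subject_shift_sd = 0.03,
                       n_bumps = 3,
                       seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  if (reps_per_class < 1 || n_subjects < 1) {
    stop("reps_per_class and n_subjects must be >= 1", call. = FALSE)
  }
  n_t <- sampling_rate * duration
  if (abs(n_t - round(n_t)) > 1e-9) {
    stop("sampling_rate * duration must be an integer number of samples",
         call. = FALSE)
  }
  sds <- c(noise_sd, time_jitter_sd, amp_jitter_sd, drift_amplitude,
           subject_amp_sd, subject_shift_sd)
  if (any(sds < 0)) stop("all noise/jitter magnitudes must be >= 0", call. = FALSE)
  if (n_bumps < 1) stop("n_bumps must be >= 1", call. = FALSE)
  structure(
    list(
      n_classes = as.integer(n_classes),
      reps_per_class = as.integer(reps_per_class),
      n_subjects = as.integer(n_subjects),
      sampling_rate = sampling_rate,
      duration = duration,
      noise_sd = noise_sd,
      time_jitter_sd = time_jitter_sd,
      amp_jitter_sd = amp_jitter_sd,
      drift_amplitude = drift_amplitude,
      subject_amp_sd = subject_amp_sd,
      subject_shift_sd = subject_shift_sd,
      n_bumps = as.integer(n_bumps),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

n_samples <- function(config) as.integer(round(config$sampling_rate * config$duration))

record_times <- function(config) {
  (seq_len(n_samples(config)) - 1) / config$sampling_rate
}

new_word_template <- function(class_id, duration, channels) {
  structure(list(class_id = as.integer(class_id), duration = duration,
                 channels = channels),
            class = "word_template")
}

# Draw one class template: per site, shared bump centers/widths for the
# horizontal (2s-1) and vertical (2s) gauges; amplitudes differ but keep the
# same sign so biaxial channels of one site co-vary.
draw_template <- function(class_id, config, rng_seed,
                          center_range = NULL, amp_range = c(0.3, 1.0)) {
  dur <- config$duration
  k <- config$n_bumps
  if (is.null(center_range)) {
    lo <- min(0.3, dur / 4); hi <- dur - lo
    center_range <- c(lo, hi)
  }
  with_seed(rng_seed, {
    channels <- vector("list", 8L)
    for (s in 1:4) {
      mu <- sort(stats::runif(k, center_range[1], center_range[2]))
      sigma <- stats::runif(k, 0.05, 0.2)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      a_h <- sgn * stats::runif(k, amp_range[1], amp_range[2])
      a_v <- a_h * stats::runif(k, 0.3, 0.9)
      channels[[2L * s - 1L]] <- list(mu = mu, sigma = sigma, a = a_h)
      channels[[2L * s]] <- list(mu = mu, sigma = sigma, a = a_v)
    }
    new_word_template(class_id, dur, channels)
  })
}

#' Generate class templates
#'
#' One noiseless multi-bump waveform description per class, drawn reproducibly
#' from the configuration seed. Paired channels of one site share bump centers
#' and widths (both gauges of a biaxial sensor deform together).
#'
#' @param config a [sim_config()].
#' @return list of `word_template` objects with class ids `0..n_classes-1`.
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lapply(seq_len(config$n_classes) - 1L, function(cid) {
    draw_template(cid, config, derive_seed(config$seed, 1L, cid))
  })
}

#' Evaluate a template's noiseless waveform
#'
#' @param template a `word_template`.
#' @param times numeric vector of sample times in seconds.
#' @return an 8 x length(times) matrix of dR/R values.
#' @export
eval_template <- function(template, times) {
  stopifnot(inherits(template, "word_template"))
  w <- matrix(0, nrow = 8L, ncol = length(times))
  for (c in 1:8) {
    ch <- template$channels[[c]]
    for (j in seq_along(ch$mu)) {
      w[c, ] <- w[c, ] +
        ch$a[j] * exp(-(times - ch$mu[j])^2 / (2 * ch$sigma[j]^2))
    }
  }
  w
}

new_strain_record <- function(waveform, class_id, subject_id = 1L,
                              session_id = 1L, rep_index = 1L) {
  stopifnot(is.matrix(waveform), nrow(waveform) == 8L, all(is.finite(waveform)))
  structure(
    list(waveform = waveform, class_id = as.integer(class_id),
         subject_id = as.integer(subject_id), session_id = as.integer(session_id),
         rep_index = as.integer(rep_index)),
    class = "strain_record"
  )
}

#' Synthesize one utterance record
#'
#' Evaluates the template with one shared timing shift per record, one
#' multiplicative amplitude factor, per-channel slow sinusoidal drift and
#' white noise. With all jitter/noise magnitudes at zero the waveform equals
#' the template evaluation exactly.
#'
#' @param template a `word_template`.
#' @param config a [sim_config()].
#' @param rng_seed integer seed for this record's private stream.
#' @param subject_id,session_id,rep_index metadata stored on the record.
#' @return a `strain_record` with an 8 x T waveform.
#' @export
synth_record <- function(template, config, rng_seed,
                         subject_id = 1L, session_id = 1L, rep_index = 1L) {
  stopifnot(inherits(template, "word_template"), inherits(config, "sim_config"))
  times <- record_times(config)
  with_seed(rng_seed, {
    delta <- stats::rnorm(1, 0, config$time_jitter_sd)
    amp <- 1 + stats::rnorm(1, 0, config$amp_jitter_sd)
    base <- eval_template(shift_template(template, delta), times)
    w <- amp * base
    for (c in 1:8) {
      if (config$drift_amplitude > 0) {
        u <- stats::runif(1, 0, config$drift_amplitude)
        f <- stats::runif(1, 0.1, 0.5)
        phi <- stats::runif(1, 0, 2 * pi)
        w[c, ] <- w[c, ] + u * sin(2 * pi * f * times + phi)
      }
      if (config$noise_sd > 0) {
        w[c, ] <- w[c, ] + stats::rnorm(length(times), 0, config$noise_sd)
      }
    }
    new_strain_record(w, template$class_id, subject_id, session_id, rep_index)
  })
}

shift_template <- function(template, delta) {
  if (delta == 0) return(template)
  channels <- lapply(template$channels, function(ch) {
    ch$mu <- ch$mu + delta
    ch
  })
  new_word_template(template$class_id, template$duration, channels)
}

# Subject effect: per-channel amplitude factors and per-site center offsets,
# drawn from a subject-specific stream. Offsets are shared within a site so
# paired channels keep common centers.
perturb_template_for_subject <- function(template, config, subject_id) {
  if (config$subject_amp_sd == 0 && config$subject_shift_sd == 0) {
    return(template)
  }
  with_seed(derive_seed(config$seed, 2L, subject_id, template$class_id), {
    amp <- stats::rnorm(8, 1, config$subject_amp_sd)
    site_shift <- stats::rnorm(4, 0, config$subject_shift_sd)
    channels <- template$channels
    for (c in 1:8) {
      s <- (c + 1L) %/% 2L
      channels[[c]]$a <- channels[[c]]$a * amp[c]
      channels[[c]]$mu <- channels[[c]]$mu + site_shift[s]
    }
    new_word_template(template$class_id, template$duration, channels)
  })
}

#' Synthesize a labelled dataset
#'
#' Produces `n_classes * reps_per_class * n_subjects` records with exactly
#' balanced labels. Each subject uses independently perturbed template copies;
#' each record draws from a seed derived from the root seed and the record
#' index, so the dataset is a pure function of the configuration.
#'
#' @param config a [sim_config()].
#' @param templates optionally, templates to use instead of
#'   [make_templates()] output (e.g. planted-window templates).
#' @return list of `strain_record` objects.
#' @export
synth_dataset <- function(config, templates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(templates)) templates <- make_templates(config)
  stopifnot(length(templates) == config$n_classes)
  records <- vector("list",
                    config$n_classes * config$reps_per_class * config$n_subjects)
  i <- 0L
  for (subj in seq_len(config$n_subjects)) {
    subj_templates <- lapply(templates, perturb_template_for_subject,
                             config = config, subject_id = subj)
    for (rep in seq_len(config$reps_per_class)) {
      for (cid in seq_len(config$n_classes) - 1L) {
        i <- i + 1L
        records[[i]] <- synth_record(
          subj_templates[[cid + 1L]], config,
          rng_seed = derive_seed(config$seed, 3L, i),
          subject_id = subj, session_id = 1L, rep_index = rep
        )
      }
    }
  }
  records
}

#' Templates differing only inside a planted time window
#'
#' Builds templates that share one waveform everywhere except for
#' class-specific bumps confined to `window` on the given channels. The
#' shared background carries anchor bumps outside the window that pin each
#' channel's min-max normalization constants, and each class receives
#' positive bumps on its own evenly spaced slots inside the window, so after
#' preprocessing all class information lives in the window. Used to test that
#' classifiers and relevance maps pick up the only region carrying class
#' information.
#'
#' @param config a [sim_config()].
#' @param window numeric `c(t0, t1)` in seconds, `0 <= t0 < t1 <= duration`.
#' @param channels integer subset of 1..8 carrying the discriminative bumps
#'   (default all eight).
#' @return list of `word_template` objects.
#' @export
plant_discriminative_window <- function(config, window, channels = 1:8) {
  stopifnot(inherits(config, "sim_config"))
  if (length(window) != 2 || !(window[1] < window[2]) ||
      window[1] < 0 || window[2] > config$duration) {
    stop("window must be c(t0, t1) with 0 <= t0 < t1 <= duration", call. = FALSE)
  }
  if (!all(channels %in% 1:8) || length(channels) < 1) {
    stop("channels must be a non-empty subset of 1..8", call. = FALSE)
  }
  # One shared background template for all classes, deliberately quieter than
  # the planted bumps (0.5-1.0) so the discriminative structure dominates the
  # waveform inside the window while the background still exercises the
  # pipeline.
  base <- draw_template(0L, config, derive_seed(config$seed, 4L, 0L),
                        amp_range = c(0.1, 0.3))
  # Anchor bumps outside the window pin every channel's extreme values to the
  # shared background, so per-channel min-max normalization constants are
  # class-independent and no class information leaks out of the window
  # through rescaling.
  seg_pre <- c(0, window[1])
  seg_post <- c(window[2], config$duration)
  seg <- if (diff(seg_pre) >= diff(seg_post)) seg_pre else seg_post
  if (diff(seg) > 0.05 * config$duration) {
    a_sig <- min(diff(seg) / 10, config$duration / 100)
    a_mu <- seg[1] + diff(seg) * c(0.25, 0.75)
    for (c in 1:8) {
      ch <- base$channels[[c]]
      base$channels[[c]] <- list(mu = c(ch$mu, a_mu),
                                 sigma = c(ch$sigma, rep(a_sig, 2)),
                                 a = c(ch$a, 2.5, -2.5))
    }
  }
  # Class-specific bumps sit on evenly spaced slots inside the window,
  # assigned round-robin to classes, with positive amplitudes: every class
  # owns positive in-window landmarks (rather than being encodable as the
  # absence of another class's features), and slots of different classes
  # never coincide.
  width <- window[2] - window[1]
  k <- config$n_bumps
  n_slots <- k * config$n_classes
  margin <- width / 8
  slot_mu <- window[1] + margin +
    (seq_len(n_slots) - 0.5) * (width - 2 * margin) / n_slots
  sigma_w <- min(width / 16, (width - 2 * margin) / (4 * n_slots))
  lapply(seq_len(config$n_classes) - 1L, function(cid) {
    channels_out <- base$channels
    mu <- slot_mu[(seq_len(n_slots) - 1L) %% config$n_classes == cid]
    with_seed(derive_seed(config$seed, 4L, cid + 1L), {
      for (s in 1:4) {
        pair <- c(2L * s - 1L, 2L * s)
        if (!any(pair %in% channels)) next
        amp_site <- stats::runif(k, 0.5, 1.0)
        for (c in pair) {
          if (!(c %in% channels)) next
          ch <- channels_out[[c]]
          channels_out[[c]] <- list(mu = c(ch$mu, mu),
                                    sigma = c(ch$sigma, rep(sigma_w, k)),
                                    a = c(ch$a, amp_site))
        }
      }
    })
    new_word_template(cid, config$duration, channels_out)
  })
}
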