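#' Parameters of an ideal Archimedean spiral drawing
#'
#' The clinical spiral task asks the subject to trace an Archimedean spiral
#' \eqn{r = a + b\theta}. The simulator draws it at approximately constant
#' tangential (pen-tip) speed, which is how practiced subjects execute the
#' task, so the angular rate is fast near the center and slows outward.
#'
#' @param a inner radius offset, device units.
#' @param b radial growth per radian, device units (must be positive).
#' @param n_turns number of full turns; the total swept angle is
#'   `2 * pi * n_turns`.
#' @param duration drawing time in seconds.
#' @param sampling_rate tablet rate in Hz. The defaults (20.48 s at 200 Hz)
#'   give exactly 4096 samples, the canonical series length used downstream.
#' @return a `spiral_params` list.
#' @export
spiral_params <- function(a = 0.5, b = 1, n_turns = 5, duration = 20.48,
                          sampling_rate = 200) {
  check_number(a, "a", lower = 0)
  check_number(b, "b", lower = 0, strict_lower = TRUE)
  check_number(n_turns, "n_turns", lower = 0, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  structure(list(a = a, b = b, n_turns = n_turns, duration = duration,
                 sampling_rate = sampling_rate),
            class = "spiral_params")
}

#' Parameters of an additive oscillatory tremor
#'
#' Action tremor in essential tremor is an oscillation in the 4--12 Hz band
#' whose displacement amplitude scales with clinical severity. The simulator
#' injects it along the local radial direction of the spiral with a slowly
#' wandering amplitude envelope.
#'
#' @param amplitude displacement amplitude in device units (0 disables).
#' @param frequency tremor frequency in Hz; must lie in \[4, 12\] whenever
#'   `amplitude > 0`.
#' @param phase oscillation phase in radians.
#' @param amp_jitter fractional slow modulation of the amplitude envelope.
#' @param drift_sd standard deviation of an additional smooth low-frequency
#'   drift added by [add_tremor()]; baseline motor noise shared by all
#'   subjects is injected separately via [add_motor_noise()].
#' @return a `tremor_params` list.
#' @export
tremor_params <- function(amplitude, frequency = 6, phase = 0,
                          amp_jitter = 0.1, drift_sd = 0) {
  check_number(amplitude, "amplitude", lower = 0)
  check_number(frequency, "frequency", lower = 0, strict_lower = TRUE)
  if (amplitude > 0 && (frequency < 4 || frequency > 12)) {
    rlang::abort("`frequency` must lie in [4, 12] Hz when amplitude > 0.")
  }
  check_number(phase, "phase")
  check_number(amp_jitter, "amp_jitter", lower = 0)
  check_number(drift_sd, "drift_sd", lower = 0)
  structure(list(amplitude = amplitude, frequency = frequency, phase = phase,
                 amp_jitter = amp_jitter, drift_sd = drift_sd),
            class = "tremor_params")
}

#' Generate a noise-free Archimedean spiral record
#'
#' Produces `duration * sampling_rate` samples of the ideal spiral
#' \eqn{x = (a + b\theta)\cos\theta}, \eqn{y = (a + b\theta)\sin\theta}, with
#' \eqn{\theta(t)} chosen by inverting the arc-length integral so the pen
#' speed is approximately constant. The pen stays down throughout, pressure
#' follows a smooth positive profile, and the sample radius equals
#' \eqn{a + b\theta} to machine precision by construction.
#'
#' @param params a [spiral_params()].
#' @param subject_id,hand identity stamped on the record.
#' @return a [spiral_record()].
#' @export
make_clean_spiral <- function(params = spiral_params(), subject_id = "sim",
                              hand = "right") {
  stopifnot(inherits(params, "spiral_params"))
  n <- round(params$duration * params$sampling_rate)
  if (n < 2L) {
    rlang::abort("duration * sampling_rate must give at least 2 samples.")
  }
  theta_max <- 2 * pi * params$n_turns
  # arc length s(theta) = integral of sqrt((a + b*theta)^2 + b^2); invert on a
  # fine grid so uniform time steps give uniform arc-length steps
  grid <- seq(0, theta_max, length.out = max(8L * n, 4096L))
  ds <- sqrt((params$a + params$b * grid)^2 + params$b^2)
  s <- cumsum(c(0, (ds[-1] + ds[-length(ds)]) / 2 * diff(grid)))
  s_target <- seq(0, s[length(s)], length.out = n)
  theta <- stats::approx(s, grid, xout = s_target, ties = "ordered")$y
  theta[1L] <- 0
  theta[n] <- theta_max

  t <- (seq_len(n) - 1L) / params$sampling_rate
  r <- params$a + params$b * theta
  rec <- spiral_record(
    x = r * cos(theta),
    y = r * sin(theta),
    t = t,
    pen_state = rep(1, n),
    azimuth = (theta * 180 / pi + 90) %% 360,
    altitude = 60 + 5 * sin(2 * pi * t / params$duration),
    pressure = 512 + 160 * sin(pi * t / params$duration),
    subject_id = subject_id,
    hand = hand,
    sampling_rate = params$sampling_rate
  )
  attr(rec, "theta") <- theta
  rec
}

#' Inject oscillatory tremor into a drawing
#'
#' Adds `A(t) * sin(2 * pi * f * t + phase)` along the local radial direction,
#' where the envelope `A(t)` is the nominal amplitude modulated by a smooth
#' fractional jitter, plus (optionally) an independent smooth low-frequency
#' drift on each coordinate. With `amplitude = 0` the input is returned
#' unchanged. Deterministic given `seed`.
#'
#' @param record a [spiral_record()].
#' @param tremor a [tremor_params()].
#' @param seed integer seed for the jitter and drift noise.
#' @return a [spiral_record()] with tremor superimposed.
#' @export
add_tremor <- function(record, tremor, seed = 1) {
  validate_spiral_record(record)
  stopifnot(inherits(tremor, "tremor_params"))
  if (tremor$frequency > sampling_rate(record) / 2) {
    rlang::abort(sprintf(
      "tremor frequency %.3g Hz exceeds the Nyquist limit %.3g Hz.",
      tremor$frequency, sampling_rate(record) / 2))
  }
  if (tremor$amplitude == 0) {
    return(record)
  }
  n <- nrow(record)
  fs <- sampling_rate(record)
  with_seed(seed, {
    envelope <- tremor$amplitude *
      pmax(0, 1 + tremor$amp_jitter * smooth_noise(n, fs, cutoff_hz = 1))
    osc <- envelope * sin(2 * pi * tremor$frequency * record$t + tremor$phase)
    drift_x <- tremor$drift_sd * smooth_noise(n, fs, cutoff_hz = 0.5)
    drift_y <- tremor$drift_sd * smooth_noise(n, fs, cutoff_hz = 0.5)
    ang <- atan2(record$y, record$x)
    ang[record$x == 0 & record$y == 0] <- 0
    record_update(record,
      x = .data$x + osc * cos(ang) + drift_x,
      y = .data$y + osc * sin(ang) + drift_y
    )
  })
}

#' Add baseline motor noise to a drawing
#'
#' Every subject, tremulous or not, shows slow motor wander around the ideal
#' trace. This adds independent smooth low-frequency (< 0.5 Hz, well below the
#' tremor band) Gaussian drift of standard deviation `drift_sd` to each
#' coordinate. `drift_sd = 0` returns the input unchanged.
#'
#' @param record a [spiral_record()].
#' @param drift_sd drift standard deviation in device units.
#' @param seed integer seed.
#' @return a [spiral_record()].
#' @export
add_motor_noise <- function(record, drift_sd = 0.3, seed = 1) {
  validate_spiral_record(record)
  check_number(drift_sd, "drift_sd", lower = 0)
  if (drift_sd == 0) return(record)
  n <- nrow(record)
  fs <- sampling_rate(record)
  with_seed(seed, {
    record_update(record,
      x = .data$x + drift_sd * smooth_noise(n, fs, cutoff_hz = 0.5),
      y = .data$y + drift_sd * smooth_noise(n, fs, cutoff_hz = 0.5)
    )
  })
}

#' Set a contiguous pen-up burst in a drawing
#'
#' Marks a random contiguous block of samples as pen-up (`pen_state = 0`),
#' emulating a brief pen lift during the task.
#'
#' @param record a [spiral_record()].
#' @param fraction fraction of samples in the burst, in \[0, 1).
#' @param seed integer seed for the burst position.
#' @return a [spiral_record()].
#' @export
add_pen_up_burst <- function(record, fraction = 0.05, seed = 1) {
  validate_spiral_record(record)
  check_number(fraction, "fraction", lower = 0, upper = 1)
  n <- nrow(record)
  len <- round(fraction * n)
  if (len == 0L) return(record)
  with_seed(seed, {
    start <- sample.int(n - len + 1L, 1L)
    pen <- record$pen_state
    pen[start:(start + len - 1L)] <- 0
    record_update(record, pen_state = pen)
  })
}

#' Configuration of a synthetic tremor cohort
#'
#' Defines the study conditions of a simulated cohort: group sizes matching a
#' control / low-tremor / high-tremor stratification, a monotone mapping from
#' severity level to tremor amplitude, a monotone truncated-normal mapping
#' from level to clinical TRS score (controls score exactly 0; truncation at 0
#' reproduces the right-skew typical of TRS distributions), and an age model
#' in which severity increases with age (a deliberate confound that can be
#' switched off by giving all levels the same age distribution).
#'
#' @param n_control,n_low,n_high group sizes. Defaults 29/12/12 mirror a
#'   29-control / 24-patient clinical sample split evenly across the two
#'   severity levels.
#' @param amplitude_by_level numeric length-3 vector of tremor displacement
#'   amplitudes for levels 0/1/2 in device units; level 0 must be 0 and the
#'   values must be strictly increasing. The default is 0, 0.5% and 3% of the
#'   outer spiral radius: low tremor is deliberately close to the control
#'   condition ("very mild"), high tremor is conspicuous.
#' @param trs_map list of `c(mean, sd)` per level for the truncated-normal TRS
#'   draw; means must be strictly increasing.
#' @param age_model list of `c(mean, sd)` per level for the age draw (years,
#'   clamped to \[10, 90\]).
#' @param freq_range range of per-subject tremor frequencies (Hz), uniform.
#' @param amp_jitter fractional amplitude envelope jitter.
#' @param amp_subject_sd log-normal sd of per-subject amplitude scaling.
#' @param drift_sd baseline motor drift sd applied to every subject.
#' @param pen_up_fraction fraction of samples in a random pen-up burst per
#'   drawing (0 disables).
#' @param spiral a [spiral_params()] shared by all drawings.
#' @param seed cohort seed; cohorts are pure functions of this configuration.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_control = 29, n_low = 12, n_high = 12,
                          amplitude_by_level = NULL,
                          trs_map = list(c(0, 0), c(6, 3), c(25, 8)),
                          age_model = list(c(45, 15), c(55, 12), c(65, 10)),
                          freq_range = c(4, 10),
                          amp_jitter = 0.1,
                          amp_subject_sd = 0.2,
                          drift_sd = 0.3,
                          pen_up_fraction = 0,
                          spiral = spiral_params(),
                          seed = 1) {
  for (nm in c("n_control", "n_low", "n_high")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      rlang::abort(sprintf("`%s` must be a nonnegative integer.", nm))
    }
  }
  stopifnot(inherits(spiral, "spiral_params"))
  if (is.null(amplitude_by_level)) {
    r_max <- spiral$a + spiral$b * 2 * pi * spiral$n_turns
    amplitude_by_level <- c(0, 0.005, 0.03) * r_max
  }
  if (length(amplitude_by_level) != 3L || amplitude_by_level[1L] != 0 ||
      any(diff(amplitude_by_level) <= 0)) {
    rlang::abort(paste0("`amplitude_by_level` must be length 3, start at 0 ",
                        "and be strictly increasing."))
  }
  trs_means <- vapply(trs_map, `[`, numeric(1), 1L)
  if (length(trs_map) != 3L || any(diff(trs_means) <= 0)) {
    rlang::abort("`trs_map` means must be strictly increasing over levels.")
  }
  check_number(amp_jitter, "amp_jitter", lower = 0)
  check_number(amp_subject_sd, "amp_subject_sd", lower = 0)
  check_number(drift_sd, "drift_sd", lower = 0)
  check_number(pen_up_fraction, "pen_up_fraction", lower = 0, upper = 1)
  structure(list(
    n_control = as.integer(n_control), n_low = as.integer(n_low),
    n_high = as.integer(n_high),
    amplitude_by_level = amplitude_by_level, trs_map = trs_map,
    age_model = age_model, freq_range = freq_range,
    amp_jitter = amp_jitter, amp_subject_sd = amp_subject_sd,
    drift_sd = drift_sd, pen_up_fraction = pen_up_fraction,
    spiral = spiral, seed = as.integer(seed)
  ), class = "cohort_config")
}

# truncated-normal draw, lower bound 0, via inverse-CDF sampling
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Simulate a tremor-graded spiral cohort
#'
#' Generates one drawing per simulated subject: a clean constant-speed
#' Archimedean spiral, plus baseline motor drift for everyone, plus
#' severity-scaled radial tremor for levels 1 and 2. Subject metadata (TRS
#' score, age, sex, hand) is drawn from the configured level-wise models.
#' The result is a pure function of `config` (same seed, same cohort).
#'
#' @param config a [cohort_config()].
#' @return a [spiral_dataset()].
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  levels_vec <- rep(0:2, times = c(config$n_control, config$n_low,
                                   config$n_high))
  n <- length(levels_vec)
  if (n == 0L) rlang::abort("cohort is empty.")
  with_seed(config$seed, {
    ids <- sprintf("S%03d", seq_len(n))
    trs <- numeric(n)
    age <- numeric(n)
    for (lv in 0:2) {
      idx <- which(levels_vec == lv)
      if (length(idx) == 0L) next
      tm <- config$trs_map[[lv + 1L]]
      am <- config$age_model[[lv + 1L]]
      trs[idx] <- if (lv == 0L) 0 else rtruncnorm0(length(idx), tm[1L], tm[2L])
      age[idx] <- pmin(90, pmax(10, stats::rnorm(length(idx), am[1L], am[2L])))
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    hand <- sample(c("right", "left"), n, replace = TRUE)
    freq <- stats::runif(n, config$freq_range[1L], config$freq_range[2L])
    phase <- stats::runif(n, 0, 2 * pi)
    amp_scale <- exp(stats::rnorm(n, 0, config$amp_subject_sd))
    sub_seeds <- sample.int(2^30, 3L * n)

    records <- vector("list", n)
    for (i in seq_len(n)) {
      rec <- make_clean_spiral(config$spiral, subject_id = ids[i],
                               hand = hand[i])
      rec <- add_motor_noise(rec, config$drift_sd, seed = sub_seeds[3L * i - 2L])
      amp <- config$amplitude_by_level[levels_vec[i] + 1L] * amp_scale[i]
      if (amp > 0) {
        rec <- add_tremor(rec,
          tremor_params(amplitude = amp, frequency = freq[i],
                        phase = phase[i], amp_jitter = config$amp_jitter,
                        drift_sd = 0),
          seed = sub_seeds[3L * i - 1L])
      }
      if (config$pen_up_fraction > 0) {
        rec <- add_pen_up_burst(rec, config$pen_up_fraction,
                                seed = sub_seeds[3L * i])
      }
      records[[i]] <- rec
    }

    meta <- tibble::tibble(
      subject_id = ids,
      group = ifelse(levels_vec == 0L, "control", "ET"),
      trs_score = trs,
      tremor_level = levels_vec,
      age = age,
      sex = sex,
      hand = hand
    )
    spiral_dataset(records, meta)
  })
}
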