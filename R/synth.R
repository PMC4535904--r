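#' Configuration for the synthetic running-cohort generator
#'
#' Defines a cohort of labelled single-cycle angle waveforms with four
#' additive variance components, each a smooth (low-order Fourier) cyclic
#' waveform:
#'
#' * a fixed population template per angle, loosely shaped like sagittal
#'   running kinematics;
#' * a per-subject offset (scale `sigma_subject`, degrees) giving every
#'   runner a unique movement pattern;
#' * a per-subject-by-condition perturbation (scale `delta_cond`) — the small,
#'   consistent, subject-specific effect of each jaw-splint condition;
#' * a side asymmetry added to the right side only, with magnitude
#'   `alpha_neutral` in the reference (no-splint) condition and `alpha_splint`
#'   in all splint conditions (by default the reference condition is the more
#'   asymmetric one);
#' * smooth trial-to-trial noise (scale `sigma_trial`).
#'
#' All scales are the pointwise standard deviation, in degrees, of the
#' corresponding random waveform component.
#'
#' @param n_subjects Number of subjects (default 20).
#' @param conditions Condition labels; the first is the reference condition
#'   (default `Neutral, Centric, DPS, Max`).
#' @param n_trials Trials per subject x condition x side (default 5).
#' @param n_time Samples per time-normalized cycle (default 201).
#' @param n_harmonics Fourier order of the random components (default 4).
#' @param sigma_subject Subject-offset scale in degrees (default 4).
#' @param delta_cond Condition-effect scale in degrees (default 1).
#' @param alpha_neutral,alpha_splint Side-asymmetry scales in degrees for the
#'   reference and the splint conditions (defaults 1.5 and 0.5).
#' @param sigma_trial Trial-noise scale in degrees (default 0.75).
#' @param seed Integer RNG seed; the same seed reproduces the cohort
#'   bit-identically.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 20L,
                         conditions = c("Neutral", "Centric", "DPS", "Max"),
                         n_trials = 5L,
                         n_time = 201L,
                         n_harmonics = 4L,
                         sigma_subject = 4,
                         delta_cond = 1,
                         alpha_neutral = 1.5,
                         alpha_splint = 0.5,
                         sigma_trial = 0.75,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              conditions = as.character(conditions),
              n_trials = as.integer(n_trials),
              n_time = as.integer(n_time),
              n_harmonics = as.integer(n_harmonics),
              sigma_subject = as.numeric(sigma_subject),
              delta_cond = as.numeric(delta_cond),
              alpha_neutral = as.numeric(alpha_neutral),
              alpha_splint = as.numeric(alpha_splint),
              sigma_trial = as.numeric(sigma_trial),
              seed = as.integer(seed))
  counts <- c(cfg$n_subjects, length(cfg$conditions), cfg$n_trials,
              cfg$n_harmonics)
  if (any(counts < 1L)) {
    stop("configuration error: all counts must be >= 1", call. = FALSE)
  }
  if (cfg$n_time < 2L) {
    stop("configuration error: n_time must be >= 2", call. = FALSE)
  }
  scales <- c(cfg$sigma_subject, cfg$delta_cond, cfg$alpha_neutral,
              cfg$alpha_splint, cfg$sigma_trial)
  if (any(!is.finite(scales)) || any(scales < 0)) {
    stop("configuration error: all scales must be finite and >= 0",
         call. = FALSE)
  }
  if (anyDuplicated(cfg$conditions)) {
    stop("configuration error: duplicate condition labels", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# Fixed population templates: mean + first two harmonics per angle, in
# degrees, loosely shaped like sagittal running angles (large knee/hip
# excursions, small trunk/head motion). Any smooth cyclic template works.
angle_templates <- function(n_time) {
  t <- seq(0, 1, length.out = n_time)
  coef <- rbind(  # mean, c1, s1, c2, s2
    foot   = c(  0, -15,  25,  -8,  5),
    ankle  = c(  5,  -8,  12,   6, -4),
    knee   = c( 40, -25, -15,  12,  8),
    hip    = c( 20,  22,   8,  -4,  2),
    pelvis = c( 10,   2,   1,   1,  0.5),
    spine  = c(  5,   2,  -1,   1,  0.5),
    thorax = c(  8,   3,   2,  -1,  0.5),
    neck   = c(  3,   2,   1,   1, -0.5),
    head   = c(  2,   1.5, 1,   0.5, 0.5))
  out <- matrix(0, nrow(coef), n_time,
                dimnames = list(rownames(coef), NULL))
  for (a in seq_len(nrow(coef))) {
    out[a, ] <- coef[a, 1] +
      coef[a, 2] * cos(2 * pi * t) + coef[a, 3] * sin(2 * pi * t) +
      coef[a, 4] * cos(4 * pi * t) + coef[a, 5] * sin(4 * pi * t)
  }
  out
}

# One random smooth cyclic waveform: Fourier series of order `H` with
# N(0, scale^2/k) coefficients (k = number of components incl. optional DC),
# so the pointwise SD is exactly `scale` at every time point.
random_fourier <- function(cosb, sinb, scale, dc) {
  H <- nrow(cosb)
  k <- H + as.integer(dc)
  # always consume the same RNG draws so that scale = 0 keeps the stream
  a <- rnorm(H)
  b <- rnorm(H)
  a0 <- rnorm(1L)
  if (scale == 0) return(numeric(ncol(cosb)))
  v <- scale / sqrt(k)
  w <- drop(v * a %*% cosb + v * b %*% sinb)
  if (dc) w <- w + v * a0
  w
}

#' Generate a synthetic running cohort
#'
#' Draws a full labelled cohort under a [synth_config()]: for every subject,
#' condition, side (`L`, `R`) and trial, each of the nine angle waveforms is
#' the population template plus the subject offset, the subject-by-condition
#' perturbation, the side asymmetry (right side only; magnitude
#' `alpha_neutral` for the reference condition, `alpha_splint` otherwise) and
#' smooth trial noise. All components are cyclic, so the noiseless waveform
#' has equal first and last samples.
#'
#' Subject sex (about one quarter female, mirroring typical recreational
#' running cohorts) and per-trial running speeds (condition-independent,
#' around 3.2 m/s) are attached as metadata.
#'
#' @param config A [synth_config()].
#' @return A list with elements `trials` (a [trial_set()] of
#'   `n_subjects * n_conditions * n_trials * 2` trials) and `truth`
#'   (a `synth_truth` holding every noiseless component; see
#'   [noiseless_waveforms()]).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("configuration error: `config` must be a synth_config",
         call. = FALSE)
  }
  nS <- config$n_subjects
  conds <- config$conditions
  nC <- length(conds)
  nTr <- config$n_trials
  nT <- config$n_time
  H <- config$n_harmonics
  nA <- length(ANGLE_NAMES)

  t <- seq(0, 1, length.out = nT)
  cosb <- t(sapply(seq_len(H), function(h) cos(2 * pi * h * t)))
  sinb <- t(sapply(seq_len(H), function(h) sin(2 * pi * h * t)))
  if (H == 1L) { cosb <- matrix(cosb, 1L); sinb <- matrix(sinb, 1L) }
  template <- angle_templates(nT)

  subjects <- sprintf("S%02d", seq_len(nS))
  alpha <- stats::setNames(
    c(config$alpha_neutral, rep(config$alpha_splint, nC - 1L)), conds)

  subj_off <- array(0, c(nS, nA, nT))
  asym_shape <- array(0, c(nS, nA, nT))
  cond_eff <- array(0, c(nS, nC, nA, nT))

  rows <- vector("list", nS * nC * 2L * nTr)
  speed_rows <- vector("list", length(rows))
  r <- 0L

  with_seed(config$seed, {
    # fixed draw order: per subject, offsets and asymmetry shapes, then
    # condition effects, then all trial noise, then speeds
    for (s in seq_len(nS)) {
      for (a in seq_len(nA)) {
        subj_off[s, a, ] <- random_fourier(cosb, sinb, config$sigma_subject,
                                           dc = TRUE)
        asym_shape[s, a, ] <- random_fourier(cosb, sinb, 1, dc = TRUE)
      }
      for (ci in seq_len(nC)) {
        for (a in seq_len(nA)) {
          cond_eff[s, ci, a, ] <- random_fourier(cosb, sinb,
                                                 config$delta_cond, dc = TRUE)
        }
      }
    }
    for (s in seq_len(nS)) {
      for (ci in seq_len(nC)) {
        for (side in c("L", "R")) {
          base <- template +
            subj_off[s, , ] + cond_eff[s, ci, , ] +
            (side == "R") * alpha[[ci]] * asym_shape[s, , ]
          for (tr in seq_len(nTr)) {
            w <- base
            for (a in seq_len(nA)) {
              w[a, ] <- w[a, ] + random_fourier(cosb, sinb,
                                                config$sigma_trial,
                                                dc = FALSE)
            }
            r <- r + 1L
            df <- data.frame(subject = subjects[s], condition = conds[ci],
                             side = side, trial = tr,
                             time_index = seq_len(nT) - 1L,
                             stringsAsFactors = FALSE)
            df[ANGLE_NAMES] <- as.data.frame(t(w))
            rows[[r]] <- df
            speed_rows[[r]] <- data.frame(subject = subjects[s],
                                          condition = conds[ci],
                                          side = side, trial = tr,
                                          speed = NA_real_,
                                          stringsAsFactors = FALSE)
          }
        }
      }
    }
    base_speed <- rnorm(nS, mean = 3.2, sd = 0.25)
    names(base_speed) <- subjects
    speed <- do.call(rbind, speed_rows)
    speed$speed <- base_speed[speed$subject] + rnorm(nrow(speed), 0, 0.05)
    n_female <- max(1L, round(nS * 0.25))
    sex <- stats::setNames(c(rep("F", n_female), rep("M", nS - n_female)),
                           subjects)
    data <- do.call(rbind, rows)
    rownames(data) <- NULL
    trials <- trial_set(data, meta = list(seed = config$seed,
                                          source = "synthetic",
                                          sex = sex, speed = speed))
    truth <- structure(list(template = template, subject_offset = subj_off,
                            condition_effect = cond_eff,
                            asymmetry_shape = asym_shape, alpha = alpha,
                            subjects = subjects, config = config),
                       class = "synth_truth")
    list(trials = trials, truth = truth)
  })
}

#' Noiseless waveforms implied by the generator ground truth
#'
#' Reconstructs the trial-noise-free mean waveforms (template + subject
#' offset + condition effect + side asymmetry) for one subject, condition and
#' side from a `synth_truth`.
#'
#' @param truth `synth_truth` from [generate_cohort()].
#' @param subject Subject id (e.g. `"S01"`).
#' @param condition Condition label.
#' @param side `"L"` or `"R"`.
#' @return Numeric matrix, angles x time points, in degrees.
#' @export
noiseless_waveforms <- function(truth, subject, condition, side) {
  stopifnot(inherits(truth, "synth_truth"), side %in% c("L", "R"))
  s <- match(subject, truth$subjects)
  ci <- match(condition, truth$config$conditions)
  if (is.na(s) || is.na(ci)) stop("unknown subject or condition",
                                  call. = FALSE)
  w <- truth$template + truth$subject_offset[s, , ] +
    truth$condition_effect[s, ci, , ] +
    (side == "R") * truth$alpha[[ci]] * truth$asymmetry_shape[s, , ]
  rownames(w) <- ANGLE_NAMES
  w
}

#' Randomly drop trials from a cohort
#'
#' Removes a uniformly random subset of trials while always retaining at
#' least one trial per subject x condition x side cell (one randomly chosen
#' trial per cell is protected before sampling). Emulates real cohorts where
#' some recorded trials are excluded.
#'
#' @param trials A [trial_set()].
#' @param fraction Proportion of trials to drop, in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return A `trial_set` with `round(fraction * n)` fewer trials.
#' @export
drop_trials <- function(trials, fraction, seed = 1L) {
  stopifnot(inherits(trials, "trial_set"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("`fraction` must be in [0, 1)", call. = FALSE)
  }
  if (fraction == 0) return(trials)
  keys <- trial_keys(trials)
  n <- nrow(keys)
  n_drop <- round(fraction * n)
  if (n_drop == 0L) return(trials)
  cell <- interaction(keys$subject, keys$condition, keys$side, drop = TRUE)
  with_seed(seed, {
    protected <- unlist(lapply(split(seq_len(n), cell), function(idx) {
      if (length(idx) == 1L) idx else sample(idx, 1L)
    }))
    pool <- setdiff(seq_len(n), protected)
    if (n_drop > length(pool)) {
      stop("infeasible: dropping ", n_drop, " trials would empty a ",
           "subject x condition x side cell", call. = FALSE)
    }
    drop_idx <- if (length(pool) == 1L) pool else sample(pool, n_drop)
    keep <- keys[-drop_idx, , drop = FALSE]
    key_all <- paste(trials$data$subject, trials$data$condition,
                     trials$data$side, trials$data$trial, sep = "\r")
    key_keep <- paste(keep$subject, keep$condition, keep$side, keep$trial,
                      sep = "\r")
    d <- trials$data[key_all %in% key_keep, , drop = FALSE]
    rownames(d) <- NULL
    trial_set(d, angles = trials$angles, meta = trials$meta)
  })
}
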