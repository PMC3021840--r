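# Seeded synthetic-data generators: dipolar sources passed through the
# package's own sphere forward models, phase-jittered oscillations, MVAR
# processes with known coupling, and injected artifacts (SQUID-jump steps,
# blink-like rank-1 transients).  Every generator is a pure function of its
# arguments including the mandatory seed; ground truth is always returned
# alongside the data.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(expr)
}

#' Default synthetic magnetometer array on a sphere cap
#'
#' `n` point magnetometers on an upper-hemisphere Fibonacci lattice of the
#' given radius, radially oriented.
#'
#' @param n number of sensors.
#' @param radius meters (default 0.12).
#' @return `sensor_array` of kind "meg".
#' @export
default_meg_sensors <- function(n = 64, radius = 0.12) {
  k <- seq_len(n)
  # Fibonacci lattice on the upper hemisphere
  z <- (k - 0.5) / n                 # in (0,1): upper half
  phi <- 2 * pi * k * (1 + sqrt(5)) / 2
  s <- sqrt(1 - z^2)
  pos <- radius * cbind(s * cos(phi), s * sin(phi), z)
  ori <- pos / radius
  sensor_array("meg", pos, ori, sprintf("MEG%03d", k))
}

#' Simulation recipe for forward-model data
#'
#' @param sensors `sensor_array`.
#' @param model `sphere_model`.
#' @param sources list of sources, each a list with `position` (3-vector,
#'   inside the model), `moment` (3-vector, A*m) and `timecourse` (a
#'   function(t) or a list like `list(type="sine", freq=, amplitude=,
#'   phase=)`).
#' @param noise_sd sensor noise standard deviation (same unit as the data).
#' @param noise_correlated logical: add a shared (rank-1) noise component.
#' @param trials number of trials.
#' @param sample_rate Hz.
#' @param trial_length seconds.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_recipe`.
#' @export
sim_recipe <- function(sensors, model, sources, noise_sd = 1e-13,
                       noise_correlated = FALSE, trials = 10,
                       sample_rate = 500, trial_length = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  for (src in sources) {
    rel <- src$position - model$center
    if (sqrt(sum(rel^2)) >= model$radii[1])
      stop("source outside the innermost model compartment")
  }
  structure(list(sensors = sensors, model = model, sources = sources,
                 noise_sd = noise_sd, noise_correlated = noise_correlated,
                 trials = trials, sample_rate = sample_rate,
                 trial_length = trial_length, seed = seed),
            class = "sim_recipe")
}

timecourse_fun <- function(spec) {
  if (is.function(spec)) return(spec)
  switch(spec$type,
    sine = function(t) (spec$amplitude %||% 1) *
      sin(2 * pi * spec$freq * t + (spec$phase %||% 0)),
    burst = function(t) {
      on <- t >= (spec$onset %||% 0.5)
      (spec$amplitude %||% 1) * on * sin(2 * pi * spec$freq * t)
    },
    stop("unknown timecourse type: ", spec$type)
  )
}

#' Simulate sensor data from dipolar sources
#'
#' `data = sum_sources leadfield(position) . moment . timecourse(t) +
#' noise`; identical seed gives identical data.
#'
#' @param recipe `sim_recipe`.
#' @return list: data (`meeg_raw`), truth (positions, moments, timecourses
#'   per trial, leadfields).
#' @export
simulate_raw <- function(recipe) {
  stopifnot(inherits(recipe, "sim_recipe"))
  fs <- recipe$sample_rate
  ns <- round(recipe$trial_length * fs)
  tvec <- (0:(ns - 1)) / fs
  lf_fun <- if (recipe$sensors$kind == "meg") meg_single_sphere else
    eeg_concentric_spheres
  lfs <- lapply(recipe$sources, function(src)
    lf_fun(src$position, recipe$sensors, recipe$model))
  gains <- lapply(seq_along(recipe$sources), function(i)
    lfs[[i]]$gain %*% recipe$sources[[i]]$moment)   # nch x 1
  nch <- nrow(recipe$sensors$positions)
  sim <- with_seed(recipe$seed, {
    lapply(seq_len(recipe$trials), function(k) {
      X <- matrix(0, nch, ns)
      tcs <- matrix(0, length(recipe$sources), ns)
      for (i in seq_along(recipe$sources)) {
        tc <- timecourse_fun(recipe$sources[[i]]$timecourse)(tvec)
        tcs[i, ] <- tc
        X <- X + gains[[i]] %*% matrix(tc, 1)
      }
      if (recipe$noise_sd > 0) {
        X <- X + matrix(stats::rnorm(nch * ns, sd = recipe$noise_sd), nch, ns)
        if (recipe$noise_correlated) {
          shared <- stats::rnorm(ns, sd = recipe$noise_sd)
          X <- X + rep(1, nch) %o% shared
        }
      }
      list(X = X, tcs = tcs)
    })
  })
  trials <- lapply(sim, `[[`, "X")
  truth_tc <- lapply(sim, `[[`, "tcs")
  data <- raw_data(trials, rep(list(tvec), recipe$trials),
                   channel_info(recipe$sensors$labels,
                                recipe$sensors$positions,
                                kind = if (recipe$sensors$kind == "meg") "meg_mag" else "eeg",
                                unit = if (recipe$sensors$kind == "meg") "T" else "V"),
                   fs,
                   append_provenance(list(), "simulate_raw",
                                     list(seed = recipe$seed,
                                          trials = recipe$trials,
                                          noise_sd = recipe$noise_sd)))
  truth <- list(positions = t(vapply(recipe$sources, `[[`, numeric(3), "position")),
                moments = t(vapply(recipe$sources, `[[`, numeric(3), "moment")),
                timecourses = truth_tc, leadfields = lfs)
  list(data = data, truth = truth)
}

#' Simulate phase-jittered oscillations
#'
#' Per-trial sinusoid at a fixed frequency with a trial-specific phase drawn
#' uniformly from `[0, phase_jitter]`, plus white noise.
#'
#' @param trials,sample_rate,freq,amplitude as named.
#' @param phase_jitter radians (0 = perfectly phase locked across trials;
#'   `2*pi` = uniform random phase).
#' @param noise_sd white-noise standard deviation.
#' @param n_channels channels (all carry the same oscillation with
#'   independent noise).
#' @param trial_length seconds.
#' @param seed mandatory.
#' @return list: data (`meeg_raw`), truth (phases per trial).
#' @export
simulate_oscillation <- function(trials, sample_rate, freq, amplitude = 1,
                                 phase_jitter = 0, noise_sd = 1,
                                 n_channels = 2, trial_length = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(freq < sample_rate / 2)
  ns <- round(trial_length * sample_rate)
  tvec <- (0:(ns - 1)) / sample_rate
  sim <- with_seed(seed, {
    phases <- if (phase_jitter > 0) stats::runif(trials, 0, phase_jitter) else
      rep(0, trials)
    trl <- lapply(seq_len(trials), function(k) {
      sig <- amplitude * sin(2 * pi * freq * tvec + phases[k])
      M <- matrix(rep(sig, each = n_channels), n_channels, ns)
      M + matrix(stats::rnorm(n_channels * ns, sd = noise_sd), n_channels, ns)
    })
    list(phases = phases, trl = trl)
  })
  phases <- sim$phases
  trl <- sim$trl
  data <- raw_data(trl, rep(list(tvec), trials),
                   sprintf("ch%02d", seq_len(n_channels)), sample_rate,
                   append_provenance(list(), "simulate_oscillation",
                                     list(seed = seed, freq = freq,
                                          amplitude = amplitude,
                                          phase_jitter = phase_jitter,
                                          noise_sd = noise_sd,
                                          trials = trials,
                                          n_channels = n_channels,
                                          sample_rate = sample_rate,
                                          trial_length = trial_length)))
  list(data = data, truth = list(phases = phases))
}

#' Simulate a (stable) MVAR process
#'
#' Gaussian innovations with the model's noise covariance; a burn-in is
#' discarded per trial.
#'
#' @param model `mvar_model` (must be stable).
#' @param trials number of trials.
#' @param samples samples per trial after burn-in.
#' @param burn_in discarded initial samples per trial.
#' @param seed mandatory.
#' @return `meeg_raw`.
#' @export
simulate_mvar <- function(model, trials, samples, burn_in = 200, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(model, "mvar_model"))
  comp <- companion_matrix(model$A)
  if (max(Mod(eigen(comp, only.values = TRUE)$values)) >= 1)
    stop("unstable MVAR model")
  nch <- nrow(model$A[[1]])
  p <- model$order
  ch <- chol(model$noise_cov)
  fs <- model$sample_rate
  trl <- with_seed(seed, {
    lapply(seq_len(trials), function(k) {
      n_tot <- samples + burn_in
      E <- t(ch) %*% matrix(stats::rnorm(nch * n_tot), nch, n_tot)
      X <- matrix(0, nch, n_tot)
      for (t in seq_len(n_tot)) {
        acc <- E[, t]
        for (kk in seq_len(min(p, t - 1))) {
          acc <- acc + model$A[[kk]] %*% X[, t - kk]
        }
        X[, t] <- acc
      }
      X[, (burn_in + 1):n_tot, drop = FALSE]
    })
  })
  tvec <- (0:(samples - 1)) / fs
  raw_data(trl, rep(list(tvec), trials),
           sprintf("ch%02d", seq_len(nch)), fs,
           append_provenance(list(), "simulate_mvar",
                             list(seed = seed, order = p, trials = trials,
                                  samples = samples, burn_in = burn_in,
                                  sample_rate = fs,
                                  A = lapply(model$A, function(m)
                                    lapply(seq_len(nrow(m)),
                                           function(r) as.numeric(m[r, ]))),
                                  noise_cov = lapply(seq_len(nch), function(r)
                                    as.numeric(model$noise_cov[r, ])))))
}

#' Construct an MVAR model from coefficient matrices
#'
#' @param A list of channel x channel coefficient matrices (lag 1..p).
#' @param noise_cov innovation covariance.
#' @param sample_rate Hz.
#' @return `mvar_model`.
#' @export
mvar_model <- function(A, noise_cov, sample_rate) {
  if (is.matrix(A)) A <- list(A)
  comp <- companion_matrix(A)
  stable <- max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
  structure(list(order = length(A), A = A, noise_cov = noise_cov,
                 sample_rate = sample_rate, stable = stable,
                 labels = sprintf("ch%02d", seq_len(nrow(A[[1]])))),
            class = "mvar_model")
}

#' Inject artifacts into raw data
#'
#' "jump": a step (SQUID flux jump) added to one random channel at a random
#' sample of a random trial.  "blink": a fixed frontal-weighted topography
#' (Gaussian fall-off from a nominal frontal point, spatial scale 0.06 m)
#' times a smooth temporal bump, added across channels.
#'
#' @param data `meeg_raw` (channels need positions for "blink").
#' @param kind "jump" or "blink".
#' @param count number of injected artifacts.
#' @param magnitude artifact amplitude (data units).
#' @param seed mandatory.
#' @param blink_tau spatial scale of the blink topography, meters.
#' @return list: data (`meeg_raw`), truth (data.frame trial, channel,
#'   sample; plus the blink topography when kind = "blink").
#' @export
inject_artifacts <- function(data, kind = c("jump", "blink"), count,
                             magnitude, seed, blink_tau = 0.06) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(data, "meeg_raw"))
  if (count > 0 && magnitude <= 0) stop("magnitude must be > 0")
  truth <- data.frame(trial = integer(0), channel = integer(0),
                      sample = integer(0))
  topo <- NULL
  if (kind == "blink") {
    pos <- channel_positions(data$channels)
    if (anyNA(pos)) stop("blink injection needs channel positions")
    frontal <- c(0, 0.09, 0.04)
    d2 <- rowSums(sweep(pos, 2, frontal)^2)
    topo <- exp(-d2 / blink_tau^2)
  }
  res <- with_seed(seed, {
    for (i in seq_len(count)) {
      k <- sample.int(length(data$trials), 1)
      ns <- ncol(data$trials[[k]])
      s <- sample.int(ns - 20, 1) + 10
      if (kind == "jump") {
        ch <- sample.int(n_channels(data), 1)
        data$trials[[k]][ch, s:ns] <- data$trials[[k]][ch, s:ns] + magnitude
        truth <- rbind(truth, data.frame(trial = k, channel = ch, sample = s - 1L))
      } else {
        len <- min(round(0.3 * data$sample_rate), ns - s)
        bump <- sin(pi * seq_len(len) / len)^2
        data$trials[[k]][, s:(s + len - 1)] <-
          data$trials[[k]][, s:(s + len - 1)] + magnitude * topo %o% bump
        truth <- rbind(truth, data.frame(trial = k, channel = NA_integer_,
                                         sample = s - 1L))
      }
    }
    list(data = data, truth = truth)
  })
  data <- res$data
  truth <- res$truth
  data$provenance <- append_provenance(list(data$provenance),
                                       "inject_artifacts",
                                       list(kind = kind, count = count,
                                            magnitude = magnitude, seed = seed))
  list(data = data, truth = truth, topography = topo)
}

#' Write a synthetic fixture dataset to disk
#'
#' Simulates a continuous recording from the recipe (trials concatenated),
#' writes it as a BrainVision triplet with one stimulus event per trial
#' onset, and stores the ground truth as JSON.
#'
#' @param recipe `sim_recipe`.
#' @param path base path (no extension).
#' @return invisible list of file paths (vhdr, vmrk, eeg, truth_json) plus
#'   the trial table the written events imply.
#' @export
write_fixture_dataset <- function(recipe, path) {
  sim <- simulate_raw(recipe)
  cont <- do.call(cbind, sim$data$trials)
  ns <- ncol(sim$data$trials[[1]])
  onsets <- (seq_len(recipe$trials) - 1L) * ns
  events <- data.frame(kind = "Stimulus", value = "S  1",
                       sample = onsets, duration = 1L)
  files <- write_brainvision(cont, events, path,
                             sample_rate = recipe$sample_rate,
                             labels = recipe$sensors$labels)
  truth_path <- paste0(sub("\\.(vhdr|vmrk|eeg)$", "", path), "_truth.json")
  jsonlite::write_json(list(
    seed = recipe$seed, trials = recipe$trials,
    sample_rate = recipe$sample_rate, trial_length = recipe$trial_length,
    positions = sim$truth$positions, moments = sim$truth$moments
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, list(truth_json = truth_path,
                          trial_table = data.frame(
                            begin_sample = onsets,
                            end_sample = onsets + ns,
                            offset_samples = 0L))))
}
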