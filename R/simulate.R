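#' Simulator configuration
#'
#' Study conditions for the synthetic pose-track generator: a top-down
#' 10-keypoint pigeon silhouette on a 1280 x 960 canvas filmed at
#' 119.88 fps. The defaults encode the statistical structure the classifier
#' has to cope with — static postural classes, brief oscillatory classes,
#' per-point tracking jitter and a frequently occluded beak — not
#' anatomical realism.
#'
#' @param fps frame rate in frames per second.
#' @param noise_sd standard deviation of i.i.d. Gaussian tracking jitter
#'   per keypoint coordinate, pixels.
#' @param head_shake_period,head_shake_amp lateral head oscillation period
#'   (frames) and amplitude (pixels).
#' @param tail_shake_period,tail_shake_amp tail oscillation period and
#'   amplitude.
#' @param walk_speed global translation speed while walking, pixels/frame.
#' @param occlusion_rate fraction of frames on which the beak is occluded.
#' @param occluded_likelihood beak likelihood on occluded frames (< 0.5).
#' @param baseline_likelihood tracking likelihood on clean frames.
#' @param canvas image width and height in pixels.
#' @param random_placement give every behavior segment a random global
#'   position and heading (a bird moving around the arena); when `FALSE`
#'   the bird sits at the canvas center, heading fixed.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list (includes the 10-part `template` matrix,
#'   body-frame pixels, body at the origin).
#' @export
sim_config <- function(fps = 119.88, noise_sd = 2.5,
                       head_shake_period = 8, head_shake_amp = 25,
                       tail_shake_period = 12, tail_shake_amp = 30,
                       look_around_amp = 10, look_around_period = c(80, 160),
                       walk_speed = 3, occlusion_rate = 0.6,
                       occluded_likelihood = 0.1,
                       baseline_likelihood = 0.95,
                       canvas = c(1280, 960), random_placement = FALSE,
                       seed = 1L) {
  stopifnot(fps > 0, noise_sd >= 0, occlusion_rate >= 0, occlusion_rate <= 1)
  template <- rbind(
    head = c(0, 45), beak = c(0, 60),
    left_neck = c(-15, 25), right_neck = c(15, 25),
    body = c(0, 0),
    left_wing_up = c(-25, 10), left_wing_down = c(-30, -20),
    right_wing_up = c(25, 10), right_wing_down = c(30, -20),
    tail = c(0, -55)
  )
  colnames(template) <- c("x", "y")
  structure(
    list(fps = fps, noise_sd = noise_sd,
         head_shake_period = head_shake_period,
         head_shake_amp = head_shake_amp,
         tail_shake_period = tail_shake_period,
         tail_shake_amp = tail_shake_amp,
         look_around_amp = look_around_amp,
         look_around_period = look_around_period,
         walk_speed = walk_speed, occlusion_rate = occlusion_rate,
         occluded_likelihood = occluded_likelihood,
         baseline_likelihood = baseline_likelihood,
         canvas = canvas, random_placement = random_placement,
         seed = as.integer(seed), template = template),
    class = "sim_config"
  )
}

#' Behaviors the simulator knows
#' @return character vector of the seven behavior names.
#' @export
sim_behaviors <- function() {
  c("eating", "standing", "walking", "head_shake", "tail_shake",
    "preening", "fluffing")
}

# Body-frame keypoint coordinates of one segment of a behavior:
# returns frames x parts x 2 deterministic kinematics (no noise).
# t is the 0-based frame index within the segment. `wander` (period, phase)
# drives the slow look-around head sway of behaviors with a free head; it
# shares the shakes' amplitude scale but not their frequency, so single
# frames are ambiguous while windows are not.
behavior_kinematics <- function(behavior, duration, config, wander = NULL) {
  tpl <- config$template
  np <- nrow(tpl)
  t <- seq_len(duration) - 1L
  X <- matrix(rep(tpl[, "x"], each = duration), duration, np)
  Y <- matrix(rep(tpl[, "y"], each = duration), duration, np)
  colnames(X) <- colnames(Y) <- rownames(tpl)
  sway <- if (is.null(wander)) rep(0, duration) else
    config$look_around_amp * sin(2 * pi * t / wander$period + wander$phase)
  switch(
    behavior,
    standing = {
      X[, "head"] <- X[, "head"] + sway
      X[, "beak"] <- X[, "beak"] + 1.2 * sway
    },
    walking = {
      # distinct gait posture: head and beak extended forward, tail raised
      X[, "head"] <- 0; Y[, "head"] <- 52
      X[, "beak"] <- 0; Y[, "beak"] <- 70
      Y[, "tail"] <- -48
    },
    eating = {
      # head and beak lowered toward the feeder, periodic dipping
      dip <- 8 * sin(2 * pi * t / 30)
      Y[, "head"] <- 28 + dip
      Y[, "beak"] <- 36 + 1.3 * dip
    },
    head_shake = {
      osc <- config$head_shake_amp * sin(2 * pi * t / config$head_shake_period)
      X[, "head"] <- X[, "head"] + osc
      X[, "beak"] <- X[, "beak"] + 1.3 * osc
    },
    tail_shake = {
      osc <- config$tail_shake_amp * sin(2 * pi * t / config$tail_shake_period)
      X[, "tail"] <- X[, "tail"] + osc
    },
    preening = {
      # beak buried in the left wing, head following; slow contact episodes
      X[, "head"] <- -21 + 2 * sin(2 * pi * t / 40)
      Y[, "head"] <- -14
      X[, "beak"] <- -30 + 2 * sin(2 * pi * t / 40)
      Y[, "beak"] <- -20 + 2 * cos(2 * pi * t / 40)
    },
    fluffing = {
      # wings extended outward from the body, head still free to sway
      wings <- c("left_wing_up", "left_wing_down",
                 "right_wing_up", "right_wing_down")
      X[, wings] <- 1.4 * X[, wings]
      Y[, wings] <- 1.4 * Y[, wings]
      X[, "head"] <- X[, "head"] + sway
      X[, "beak"] <- X[, "beak"] + 1.2 * sway
    },
    stop("unknown behavior name: '", behavior, "'")
  )
  list(x = X, y = Y)
}

#' Generate a synthetic labeled pose track
#'
#' Renders a behavior script — an ordered list of (behavior, duration)
#' segments — into a 10-keypoint pose track plus the exactly matching
#' frame-range label set. Per-behavior kinematics: standing is the static
#' template plus jitter; walking translates the whole bird at
#' `walk_speed` px/frame in a distinct gait posture (so egocentric
#' normalization reduces it to a constant posture); eating lowers head and
#' beak with periodic dips; head/tail shake add lateral sinusoidal
#' oscillation; preening moves beak and head onto the left wing; fluffing
#' extends the wing points outward with amplified jitter. Likelihoods sit
#' at the baseline except for the beak, which is occluded (likelihood
#' dropped below 0.5) on a random fraction of frames. Fully deterministic
#' given `config$seed`.
#'
#' @param script data frame with columns `behavior` and `duration`
#'   (frames, >= 1), behaviors from [sim_behaviors()].
#' @param config a [sim_config()].
#' @return list with elements `track` (a [pose_track()]) and `labels`
#'   (a [label_set()] whose slices mirror the script).
#' @export
generate_track <- function(script, config = sim_config()) {
  script <- as.data.frame(script)
  stopifnot(all(c("behavior", "duration") %in% names(script)))
  if (any(script$duration < 1)) stop("segment durations must be >= 1")
  bad <- setdiff(script$behavior, sim_behaviors())
  if (length(bad)) stop("unknown behavior name: '", bad[1], "'")

  set.seed(config$seed)
  parts <- rownames(config$template)
  np <- length(parts)
  total <- sum(script$duration)
  xs <- vector("list", nrow(script))
  ys <- vector("list", nrow(script))

  center <- config$canvas / 2
  for (i in seq_len(nrow(script))) {
    d <- as.integer(script$duration[i])
    wander <- NULL
    if (config$look_around_amp > 0 &&
        script$behavior[i] %in% c("standing", "fluffing"))
      wander <- list(period = stats::runif(1, config$look_around_period[1],
                                           config$look_around_period[2]),
                     phase = stats::runif(1, 0, 2 * pi))
    kin <- behavior_kinematics(script$behavior[i], d, config, wander)
    if (config$random_placement) {
      heading <- stats::runif(1, 0, 360)
      origin <- c(stats::runif(1, 0.25, 0.75) * config$canvas[1],
                  stats::runif(1, 0.25, 0.75) * config$canvas[2])
    } else {
      heading <- 0
      origin <- center
    }
    R <- rotation_matrix(heading)
    wx <- kin$x * R[1, 1] + kin$y * R[1, 2]
    wy <- kin$x * R[2, 1] + kin$y * R[2, 2]
    if (script$behavior[i] == "walking") {
      step <- R %*% c(0, config$walk_speed)   # walks along its heading
      tt <- seq_len(d) - 1L
      wx <- wx + tt * step[1]
      wy <- wy + tt * step[2]
    }
    wx <- wx + origin[1]
    wy <- wy + origin[2]
    if (config$noise_sd > 0) {
      nx <- matrix(stats::rnorm(d * np, 0, config$noise_sd), d, np)
      ny <- matrix(stats::rnorm(d * np, 0, config$noise_sd), d, np)
      if (script$behavior[i] == "fluffing") {
        wings <- match(c("left_wing_up", "left_wing_down",
                         "right_wing_up", "right_wing_down"), parts)
        nx[, wings] <- 2.5 * nx[, wings]   # ruffling
        ny[, wings] <- 2.5 * ny[, wings]
      }
      wx <- wx + nx
      wy <- wy + ny
    }
    xs[[i]] <- wx
    ys[[i]] <- wy
  }
  X <- do.call(rbind, xs)
  Y <- do.call(rbind, ys)
  colnames(X) <- colnames(Y) <- parts

  lik <- matrix(config$baseline_likelihood, total, np,
                dimnames = list(NULL, parts))
  occluded <- stats::runif(total) < config$occlusion_rate
  lik[occluded, "beak"] <- config$occluded_likelihood

  ends <- cumsum(script$duration)
  starts <- c(0L, ends[-length(ends)])
  labels <- label_set(starts, ends - 1L, script$behavior,
                      vocabulary = sim_behaviors())
  list(track = pose_track(X, Y, lik, parts = parts, fps = config$fps),
       labels = labels)
}

#' Default class-imbalance profile
#'
#' Frame shares per behavior mimicking a naturally skewed ethogram: common
#' postural behaviors dominate while the brief comfort behaviors (head and
#' tail shake) are rare (< 5% of frames each).
#'
#' @return named numeric vector of shares summing to 1.
#' @export
default_imbalance_profile <- function() {
  c(standing = 0.40, eating = 0.25, walking = 0.15, preening = 0.10,
    fluffing = 0.06, head_shake = 0.02, tail_shake = 0.02)
}

#' Generate an imbalanced benchmark track
#'
#' Builds a long interleaved behavior script whose expected frame shares
#' follow the given imbalance profile, then renders it with
#' [generate_track()] using random per-segment placement. Shake segments
#' are short bursts (16–32 frames); the other behaviors run 80–240 frames
#' per bout. One bout of each behavior is always present.
#'
#' @param n_frames approximate total length in frames.
#' @param profile named shares over [sim_behaviors()], all positive.
#' @param config a [sim_config()]; `random_placement` is forced on.
#' @return list with `track`, `labels` and the generated `script`.
#' @export
make_benchmark <- function(n_frames = 50000,
                           profile = default_imbalance_profile(),
                           config = sim_config()) {
  if (!all(sim_behaviors() %in% names(profile)))
    stop("profile must assign a share to every behavior")
  if (any(profile <= 0)) stop("profile shares must all be positive")
  profile <- profile[sim_behaviors()] / sum(profile[sim_behaviors()])

  set.seed(config$seed + 1000L)
  dur <- function(b) {
    if (b %in% c("head_shake", "tail_shake"))
      sample(24:48, 1L)
    else
      sample(80:240, 1L)
  }
  # expected bout length per behavior, to convert frame shares into
  # per-segment selection probabilities
  mean_dur <- vapply(sim_behaviors(), function(b)
    if (b %in% c("head_shake", "tail_shake")) 36 else 160, numeric(1))
  seg_prob <- profile / mean_dur
  seg_prob <- seg_prob / sum(seg_prob)

  behaviors <- sample(sim_behaviors())   # one bout of each, random order
  durations <- vapply(behaviors, dur, numeric(1))
  while (sum(durations) < n_frames) {
    b <- sample(sim_behaviors(), 1L, prob = seg_prob)
    behaviors <- c(behaviors, b)
    durations <- c(durations, dur(b))
  }
  over <- sum(durations) - n_frames
  if (over > 0 && durations[length(durations)] - over >= 16)
    durations[length(durations)] <- durations[length(durations)] - over
  script <- data.frame(behavior = behaviors, duration = durations,
                       stringsAsFactors = FALSE)
  cfg <- config
  cfg$random_placement <- TRUE
  out <- generate_track(script, cfg)
  out$script <- script
  out
}
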