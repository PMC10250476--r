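# Shared fixtures and independent oracles, built in code at test time.

# Small deterministic labeled track covering several behaviors.
small_sim <- function(seed = 7, durations = c(standing = 60, eating = 50,
                                              head_shake = 30)) {
  script <- data.frame(behavior = names(durations),
                       duration = as.integer(durations))
  generate_track(script, sim_config(seed = seed))
}

# A random single frame as a parts x 2 matrix with the required parts.
random_frame <- function(parts = c("head", "beak", "left_neck", "right_neck",
                                   "body", "tail")) {
  m <- matrix(stats::rnorm(2 * length(parts), sd = 50), ncol = 2,
              dimnames = list(parts, c("x", "y")))
  m
}

# A random pose track with the required parts (uniform likelihoods).
random_track <- function(n = 20, parts = c("head", "beak", "left_neck",
                                           "right_neck", "body", "tail")) {
  pose_track(matrix(stats::rnorm(n * length(parts), 600, 100), n),
             matrix(stats::rnorm(n * length(parts), 400, 100), n),
             parts = parts)
}

# Brute-force per-class precision/recall/F1: explicit frame-by-frame tally,
# independent of the package's vectorised implementation.
oracle_prf <- function(truth, pred, class) {
  tp <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    if (pred[i] == class && truth[i] == class) tp <- tp + 1
    if (pred[i] == class && truth[i] != class) fp <- fp + 1
    if (pred[i] != class && truth[i] == class) fn <- fn + 1
  }
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 / (1 / p + 1 / r)
  c(precision = p, recall = r, f1 = f)
}

oracle_weighted_f1 <- function(truth, pred) {
  total <- 0
  for (cl in unique(truth)) {
    f <- oracle_prf(truth, pred, cl)[["f1"]]
    total <- total + f * sum(truth == cl)
  }
  total / length(truth)
}

# Random multi-class label pair for metric property tests.
random_label_pair <- function(n = 50, k = 4) {
  classes <- letters[seq_len(k)]
  list(truth = sample(classes, n, replace = TRUE),
       pred = sample(classes, n, replace = TRUE))
}
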