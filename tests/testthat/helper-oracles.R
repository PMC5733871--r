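# Independent oracles and small fixture builders used across the suite.

# 4x4 real matrix representation of left-multiplication by p:
# p * q == L(p) %*% q for quaternions as column vectors (w, x, y, z).
quat_left_matrix <- function(p) {
  w <- p[1]; x <- p[2]; y <- p[3]; z <- p[4]
  matrix(c(w, -x, -y, -z,
           x,  w, -z,  y,
           y,  z,  w, -x,
           z, -y,  x,  w), 4, 4, byrow = TRUE)
}

# Rodrigues rotation matrix for angle theta about unit axis a.
rodrigues_matrix <- function(axis, theta) {
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Brute-force loop over the four feature sums.
brute_features <- function(q_mod) {
  ns <- length(q_mod)
  s <- s2 <- h <- 0
  for (v in q_mod) {
    s <- s + v; s2 <- s2 + v^2; h <- h + 1 / (1 + v^2)
  }
  c(mean = s / ns, variance = s2 / ns - (s / ns)^2, contrast = s2 / ns,
    homogeneity = h)
}

# Enumerate window starts by brute force.
count_windows_oracle <- function(len, ns, t_disp) {
  starts <- integer(0)
  s <- 0L
  while (s + ns <= len) {
    starts <- c(starts, s)
    s <- s + t_disp
  }
  starts
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# A minimal labelled 4-channel recording with the given per-sample labels.
toy_recording <- function(label, seed = 1) {
  set.seed(seed)
  n <- length(label)
  data <- matrix(stats::rnorm(n * 4), n, 4,
                 dimnames = list(NULL, c("F3", "F4", "FC5", "FC6")))
  eeg_recording(data, sampling_rate = 128, label = label)
}

# Small separable synthetic session for pipeline-level tests.
small_session <- function(contrast = 2, seed = 42, arrows = 12L, runs = 1L) {
  generate_session(
    paradigm_config(arrows_per_run = arrows, crosses_per_run = arrows + 1L,
                    runs = runs),
    signal_model(contrast = contrast), seed = seed
  )
}
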