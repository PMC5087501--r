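# Shared fixtures built in code.

# Published summed confusion matrix of the eight-activity
# leave-one-subject-out experiment (rows = true label).
table1_confusion <- function() {
  labels <- c("BR", "CL", "CW", "DK", "ET", "RD", "ST", "SD")
  m <- matrix(c(
    301, 66, 0, 10, 0, 0, 1, 22,
    16, 348, 0, 0, 2, 3, 0, 31,
    0, 9, 355, 0, 12, 8, 16, 0,
    1, 1, 18, 321, 37, 12, 7, 3,
    0, 1, 15, 29, 327, 17, 11, 0,
    0, 1, 10, 20, 30, 318, 21, 0,
    2, 5, 14, 13, 11, 11, 335, 9,
    7, 9, 0, 0, 0, 0, 2, 382
  ), nrow = 8, byrow = TRUE, dimnames = list(labels, labels))
  as_confusion_matrix(m)
}

table1_f1 <- c(BR = 0.828, CL = 0.829, CW = 0.874, DK = 0.810,
               ET = 0.799, RD = 0.827, ST = 0.845, SD = 0.902)

# A small sensor window data frame with the six channels.
toy_window <- function(n = 300, seed = 1) {
  withr::with_seed(seed, {
    tibble::as_tibble(setNames(
      as.data.frame(matrix(rnorm(n * 6), n, 6)),
      c("ax", "ay", "az", "gx", "gy", "gz")))
  })
}

# A one-frame skeleton with hip centre at `hip` and one extra joint.
toy_skeleton_frame <- function(joint = "head", at = c(0, 1, 0),
                               hip = c(0, 0, 0), time = 0) {
  skeleton_stream(dplyr::bind_rows(
    tibble::tibble(time = time, joint = "hip_center",
                   x = hip[1], y = hip[2], z = hip[3]),
    tibble::tibble(time = time, joint = joint,
                   x = hip[1] + at[1], y = hip[2] + at[2], z = hip[3] + at[3])
  ))
}

# Brute-force reference implementations used as independent oracles.
brute_dft_energy <- function(x) {
  n <- length(x)
  k <- seq_len(n - 1)            # non-DC bins
  total <- 0
  for (kk in k) {
    re <- sum(x * cos(-2 * pi * kk * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * kk * (seq_len(n) - 1) / n))
    total <- total + re^2 + im^2
  }
  total / n^2
}

brute_absolute_change <- function(x, y, z) {
  n <- length(x)
  s <- 0
  for (i in 2:n) {
    s <- s + abs(x[i] - x[i - 1]) + abs(y[i] - y[i - 1]) + abs(z[i] - z[i - 1])
  }
  s / n
}

brute_threshold_objective <- function(gv, iv, tg, ti) {
  gt <- ifelse(gv > tg, 1, 0)
  it <- ifelse(iv > ti, 1, 0)
  matches <- sum(gt * it)
  top <- max(sum(gt), sum(it))
  (if (top == 0) 0 else matches / top) - matches / length(gv)
}
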