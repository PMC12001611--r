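# Small deterministic fixtures used across the suite.
#
# F1: two flat lines, level 1 pre and 2 post        -> beta_B = (1, 0, 1, 0)
# F2: one straight line y = 2 + 0.5 T, no break     -> beta   = (2, 0.5, 0, 0)
# F3: slope change only; pre y = T, post y = 2T - 3 -> beta_B = (0, 1, -3, 1)
#     (lines meet at delta = 3: immediate effect 0, intercept gap -3)
# F4: six fixed noisy points; expected values come from the lm() oracle.

fixture_f1 <- function() {
  new_its_data(0:5, c(1, 1, 1, 2, 2, 2), delta = 3)
}

fixture_f2 <- function() {
  new_its_data(0:5, 2 + 0.5 * (0:5), delta = 3)
}

fixture_f3 <- function() {
  t <- 0:5
  y <- ifelse(t < 3, t, 2 * t - 3)
  new_its_data(t, y, delta = 3)
}

fixture_f4 <- function() {
  new_its_data(0:5, c(1.93, 2.31, 1.88, 3.10, 2.74, 3.55), delta = 3)
}

# independent oracle: lm() on an explicitly built model frame
oracle_lm <- function(data, parametrization) {
  delta <- attr(data, "delta")
  df <- data.frame(
    y = data$outcome, t = data$time, x = data$post,
    z = if (parametrization == "bernal") data$post * data$time
        else data$post * (data$time - delta)
  )
  stats::lm(y ~ t + x + z, data = df)
}

# random valid dataset generator for property-style tests
random_its <- function(m = sample(3:60, 1), n = sample(3:60, 1),
                       sigma = runif(1, 0, 5)) {
  times <- sort(sample(seq(0, 200, by = 0.5), m + n))
  delta <- (times[m] + times[m + 1]) / 2
  beta <- rnorm(4, 0, 2)
  x <- as.numeric(times >= delta)
  mu <- beta[1] + beta[2] * times + beta[3] * x + beta[4] * x * (times - delta)
  new_its_data(times, mu + rnorm(m + n, 0, sigma), delta = delta)
}

rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1))
}
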