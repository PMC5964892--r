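# Independent oracles and fixture builders shared across test files.

# Exhaustive pair-counting AUC: every responder/non-responder pair,
# ties counting one half. Kept deliberately naive.
brute_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Random small two-class instance with ties (integer-ish scores).
random_instance <- function() {
  n1 <- sample(2:12, 1)
  n0 <- sample(2:12, 1)
  scores <- c(sample(0:10, n1, replace = TRUE) + 0.5 * stats::rbinom(n1, 1, 0.5),
              sample(0:10, n0, replace = TRUE) + 0.5 * stats::rbinom(n0, 1, 0.5))
  list(scores = scores, labels = rep(c(TRUE, FALSE), c(n1, n0)))
}

# Well-separated fixture: responders clearly above non-responders.
separable_fixture <- function() {
  list(scores = c(16, 18, 20, 10, 12, 14),
       labels = rep(c(TRUE, FALSE), each = 3))
}

# Overlapping two-class fixture drawn from a binormal model.
binormal_fixture <- function(n1 = 15, n0 = 15, a = 1.5, b = 1) {
  list(scores = c(stats::rnorm(n1, mean = a, sd = 1),
                  stats::rnorm(n0, mean = 0, sd = b)),
       labels = rep(c(TRUE, FALSE), c(n1, n0)))
}
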