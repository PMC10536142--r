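# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Training conditions of the synthetic study: 5 subjects, 50 reps per action.
fixture_train <- function() {
  memo("train", function() generate_dataset(5, 50, seed = 11))
}

# 5 unseen subjects for held-out evaluation.
fixture_test <- function() {
  memo("test", function() generate_dataset(5, 20, seed = 202))
}

fixture_pipeline <- function() {
  memo("pipeline", function()
    rehab_pipeline(fixture_train(), epochs = 1500, seed = 7))
}

# Ground-truth piecewise-linear force curve through the given knots.
pl_curve <- function(ad_knots, force_knots) {
  stats::approxfun(ad_knots, force_knots, rule = 2)
}

# Build an ensemble with fixed hyperplanes (w, b per pair) for vote algebra
# tests; decision w . x + b > 0 votes the lower class of the pair.
fixed_ensemble <- function(b_by_pair, code_dim = 2L) {
  members <- Map(function(pr, b) list(pair = pr, w = numeric(code_dim), b = b),
                 rehabband:::class_pairs(4L), b_by_pair)
  structure(list(members = members, cost = 1, n_classes = 4L,
                 code_dim = code_dim),
            class = "svm_vote_ensemble")
}

# A schedule of n actions separated by rest, preceded by an initialization
# rest block long enough for reference initialization plus window fill.
action_schedule <- function(labels, rest_n = 40L, init_n = 60L) {
  sch <- list(list(type = "rest", n = init_n))
  for (lab in labels)
    sch <- c(sch, list(list(type = "action", label = lab),
                       list(type = "rest", n = rest_n)))
  sch
}

# Independent brute-force oracle for the streaming detector: materialize
# every full window of the normalized stream, apply the two gate rules, vote,
# and honor the refractory contract sequentially.
batch_detect_oracle <- function(pipe, stream, n_init = 30L) {
  m <- t(as.matrix(stream[, c("ch1", "ch2", "ch3")]))
  ref <- rowMeans(m[, 1:n_init, drop = FALSE])
  u <- m[, (n_init + 1):ncol(m), drop = FALSE] / ref
  cfg <- pipe$config
  ws <- cfg$window_size
  out <- data.frame(sample_index = integer(0), label = integer(0))
  last_accept <- -Inf
  for (e in ws:ncol(u)) {
    if (e - last_accept <= cfg$refractory) next
    w <- u[, (e - ws + 1):e, drop = FALSE]
    prefix <- w[, 1:cfg$prefix_len, drop = FALSE]
    r1 <- max(apply(prefix, 1, max) - apply(prefix, 1, min)) > cfg$t1
    r2 <- min(abs(w[, 1] - w[, ws])) < cfg$t2
    if (r1 && r2) {
      lab <- predict(pipe, flatten_sample(w))
      out <- rbind(out, data.frame(sample_index = n_init + e, label = lab))
      last_accept <- e
    }
  }
  out
}
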