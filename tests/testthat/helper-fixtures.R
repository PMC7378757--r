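# shared fixtures, built in code

make_recording <- function(data, fs = 50, subject_id = 1L) {
  colnames(data) <- c("x", "y", "z")
  structure(list(subject_id = subject_id, fs = fs, data = data),
            class = "triaxial_recording")
}

make_segment <- function(x, y, z, fs = 50, label = "Fall", subject_id = 1L) {
  make_segment_data(cbind(x = x, y = y, z = z), fs, label, subject_id)
}

make_segment_data <- function(data, fs = 50, label = "Fall", subject_id = 1L) {
  structure(list(subject_id = subject_id, label = label, fs = fs,
                 data = data), class = "event_segment")
}

# one small simulated study, computed once per test run
.fixture_env <- new.env()

tiny_study_features <- function() {
  if (is.null(.fixture_env$feats)) {
    cfg <- simulation_config(n_subjects = 6, seed = 424242L)
    segs <- segment_study(simulate_study(cfg))
    .fixture_env$feats <- extract_study_features(segs)
  }
  .fixture_env$feats
}

# binary dataset with exactly 3 informative features, each marking a
# disjoint subgroup of the Fall class; all other features are pure noise
planted_signal_dataset <- function(seed, n_subj = 8, per = 15, d = 20) {
  set.seed(seed)
  n <- n_subj * per
  x <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", 1:d)))
  informative <- c("f3", "f9", "f17")
  y <- rep("No Fall", n)
  y[seq(1, n, by = 2)] <- "Fall"
  thirds <- split(which(y == "Fall"), rep(1:3, length.out = sum(y == "Fall")))
  for (j in 1:3)
    x[thirds[[j]], informative[j]] <- x[thirds[[j]], informative[j]] + 5
  structure(data.frame(subject = rep(1:n_subj, each = per), label = y, x,
                       check.names = FALSE),
            informative = informative)
}

# brute-force moment statistics by explicit summation (independent oracle)
brute_moments <- function(x) {
  n <- length(x)
  mu <- 0; for (v in x) mu <- mu + v; mu <- mu / n
  v2 <- 0; for (v in x) v2 <- v2 + (v - mu)^2; v2 <- v2 / n
  s <- sqrt(v2)
  ms <- 0; for (v in x) ms <- ms + v^2
  rms <- sqrt(ms / n)
  if (s > 0) {
    m3 <- 0; for (v in x) m3 <- m3 + (v - mu)^3
    m4 <- 0; for (v in x) m4 <- m4 + (v - mu)^4
    skew <- m3 / (n * s^3); kurt <- m4 / (n * s^4)
  } else skew <- kurt <- 0
  c(mean = mu, var = v2, sd = s, rms = rms, skew = skew, kurt = kurt)
}

# brute-force per-class precision/recall/F1 from a counts matrix
brute_metrics <- function(m) {
  K <- nrow(m)
  prec <- rec <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- m[k, k]
    pred_k <- sum(m[, k]); true_k <- sum(m[k, ])
    prec[k] <- if (pred_k > 0) tp / pred_k else 0
    rec[k] <- if (true_k > 0) tp / true_k else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = sum(diag(m)) / sum(m), macro_f1 = mean(f1[rowSums(m) > 0]),
       f1 = f1)
}
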