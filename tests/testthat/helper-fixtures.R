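# Shared fixtures, built in code.

# Small labelled table: two Gaussian blobs in 2-D.
toy_labelled <- function(n_per_class = 30, sep = 3, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(cbind(rnorm(n_per_class, -sep / 2), rnorm(n_per_class)),
               cbind(rnorm(n_per_class, sep / 2), rnorm(n_per_class)))
  })
  score_table(x, label = rep(0:1, each = n_per_class))
}

# Wild table with scores spread over (0, 1].
toy_wild <- function(n = 120, seed = 7) {
  withr::with_seed(seed, {
    x <- cbind(rnorm(n), rnorm(n))
    s <- runif(n)
  })
  score_table(x, score = s, id = paste0("w", seq_len(n)))
}

# A small, fully scored/labelled simulated world shared by several tests.
small_world <- function(seed = 11) {
  sc <- generate_scenario(scenario_spec("clean", seed = seed))
  scorer <- fit_base_scorer(sc$train)
  sc$wild$score <- predict(scorer, sc$wild)
  sc$scorer <- scorer
  sc
}

# Brute-force pairwise-concordance AUROC (independent oracle; ties count
# one half).
auc_bruteforce <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  total / (length(pos) * length(neg))
}
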