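# Shared fixtures, built in code at test time.

# pair_set from explicit disease/control id vectors
make_pairs <- function(disease, control, distance = 0) {
  structure(data.frame(pair_id = sprintf("pair%03d", seq_along(disease)),
                       disease_sample = disease, control_sample = control,
                       score_distance = rep_len(distance, length(disease)),
                       stringsAsFactors = FALSE),
            class = c("pair_set", "data.frame"))
}

# small abundance table with given dims, deterministic values
toy_table <- function(n_samples = 6, n_features = 4, seed = 1,
                      scale_tag = "count") {
  set.seed(seed)
  m <- matrix(stats::rexp(n_samples * n_features), n_samples, n_features,
              dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                              sprintf("f%02d", seq_len(n_features))))
  abundance_table(m, scale_tag = scale_tag)
}

# default simulated cohort, cached across tests in one run
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(sim_config(seed = 1))
    cache
  }
})

# fake metabolic_background carrying explicit retained scores
fake_background <- function(scores) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores, explained = rep(1 / ncol(scores), ncol(scores)),
                 n_retained = ncol(scores), ev_threshold = 0.85),
            class = "metabolic_background")
}

# independent mutual-information oracle from the explicit contingency table
mi_oracle <- function(a, b) {
  lv_a <- sort(unique(a)); lv_b <- sort(unique(b))
  n <- length(a)
  mi <- 0
  for (x in lv_a) for (y in lv_b) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / (sum(a == x) / n * sum(b == y) / n))
  }
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log(p))
  }
  list(mi = mi, ha = ent(a), hb = ent(b))
}

# all permutations of 1..n (independent of the package's internal enumerator)
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1L))
  }))
}
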