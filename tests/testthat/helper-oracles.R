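# Independent oracles and small fixture builders shared across tests.

# Exhaustive O(n^2) pair-counting oracle for partition agreement.
pair_count_oracle <- function(c_lab, p_lab) {
  n <- length(c_lab)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_c <- c_lab[i] == c_lab[j]
      same_p <- p_lab[i] == p_lab[j]
      if (same_c && same_p) a <- a + 1
      else if (!same_c && !same_p) b <- b + 1
      else if (same_c && !same_p) cc <- cc + 1
      else d <- d + 1
    }
  }
  list(a = a, b = b, c = cc, d = d,
       ri = (a + b) / choose(n, 2))
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    pos <- length(labels) + 1
    if (pos > n) {
      out[[length(out) + 1]] <<- labels
      return()
    }
    for (lab in seq_len(next_max + 1)) {
      recurse(c(labels, lab), max(next_max, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Monte-Carlo joint-order-statistic probability P(U_(k) <= r_k for all k),
# computed without per-row sorting: U_(k) <= r_k iff at least k draws
# fall below r_k.
mc_joint_order_prob <- function(r_sorted, n_draws, seed) {
  n <- length(r_sorted)
  withr::with_seed(seed, {
    u <- matrix(runif(n_draws * n), n_draws, n)
    ok <- rep(TRUE, n_draws)
    for (k in seq_len(n)) {
      ok <- ok & (rowSums(u <= r_sorted[k]) >= k)
    }
    mean(ok)
  })
}

# Two well-separated Gaussian clouds pointing in different directions (so
# separation survives unit-norm row scaling) with gene rownames.
two_cloud_matrix <- function(n_per = 20, p = 4, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    m1 <- c(sep, rep(0, p - 1))
    m2 <- c(rep(0, p - 1), sep)
    x <- rbind(matrix(rnorm(n_per * p), n_per, p, byrow = TRUE) +
                 matrix(m1, n_per, p, byrow = TRUE),
               matrix(rnorm(n_per * p), n_per, p, byrow = TRUE) +
                 matrix(m2, n_per, p, byrow = TRUE))
    rownames(x) <- sprintf("g%03d", seq_len(2 * n_per))
    x
  })
}

two_cloud_truth <- function(n_per = 20) rep(1:2, each = n_per)

# Tiny two-document corpus used by the indexing tests.
tiny_corpus <- function() {
  corpus(
    documents = list(
      docA = c(muscle = 3L, zzz = 1L),
      docB = c(heart = 2L, muscle = 1L),
      docC = c(heart = 2L)
    ),
    gene_doc_map = list(g1 = c("docA"), g2 = c("docB", "docC"),
                        g3 = character(0))
  )
}

# Small multi-view benchmark used where full-size generation is overkill.
small_benchmark <- function(seed = 1, relevance = c(1, 0.8, 0, 0),
                            n_diseases = 3, genes = 12, unlabeled = 40) {
  generate_benchmark(
    n_diseases = n_diseases, genes_per_disease = genes,
    n_views = length(relevance), relevance = relevance,
    vocab_sizes = 50, n_unlabeled = unlabeled, seed = seed
  )
}
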