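# Shared fixtures, all built in code.

# Tiny association matrix: 3 diseases x 4 miRNAs.
tiny_assoc <- function() {
  bm <- rbind(c(1, 0, 1, 0),
              c(0, 1, 0, 0),
              c(1, 1, 0, 1))
  assoc_matrix(bm,
               entity_index(c("d1", "d2", "d3"), "disease"),
               entity_index(c("m1", "m2", "m3", "m4"), "mirna"))
}

# Two-node chain DAG: root r -> child c.
chain_forest <- function() {
  dag_forest(data.frame(dag_id = "g1", parent = "r", child = "c"))
}

# Small planted dataset used across model tests.
small_dataset <- function(seed = 7) {
  gen_dataset(synthetic_spec(nm = 16, nd = 12, latent_rank = 2,
                             density = 0.15, n_dags = 2, seed = seed))
}

# Reduced-scale training configuration for fast tests.
fast_params <- function(...) {
  args <- utils::modifyList(
    list(latent_dim = 4, hidden_dims = c(16, 8), epochs = 50,
         batch_size = 16, lr = 1e-3, n_repetitions = 1, seed = 1),
    list(...))
  do.call(bganmda_params, args)
}

# Independent recursive edit-script oracle (no DP table shared with the
# implementation path).
oracle_edit <- function(a, b, sub, indel) {
  if (nchar(a) == 0) return(nchar(b) * indel)
  if (nchar(b) == 0) return(nchar(a) * indel)
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  rest_a <- substr(a, 2, nchar(a)); rest_b <- substr(b, 2, nchar(b))
  min(oracle_edit(rest_a, rest_b, sub, indel) +
        if (a1 == b1) 0 else sub,
      oracle_edit(rest_a, b, sub, indel) + indel,
      oracle_edit(a, rest_b, sub, indel) + indel)
}

# Brute-force O(n^2) concordance oracle for the AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

expect_similarity_valid <- function(m) {
  expect_lt(max(abs(m - t(m))), 1e-9)
  expect_true(all(diag(m) == 1))
  expect_gte(min(m), 0)
  expect_lte(max(m), 1)
}
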