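test_that("weighted edit distance matches the exhaustive edit-script oracle", {
  expect_equal(weighted_edit_distance("ACGU", "ACGU"), 0)
  expect_equal(weighted_edit_distance("ACGU", "", sub_cost = 2, indel_cost = 1), 4)
  expect_equal(weighted_edit_distance("ACGU", "AGGU", 2, 1), 2)
  strings <- unlist(lapply(0:4, function(n)
    if (n == 0) "" else
      apply(expand.grid(rep(list(c("A", "C")), n)), 1, paste, collapse = "")))
  for (a in strings) for (b in strings) {
    expect_equal(weighted_edit_distance(a, b, 2, 1), oracle_edit(a, b, 2, 1),
                 info = paste(a, b))
    expect_equal(weighted_edit_distance(a, b, 3, 2), oracle_edit(a, b, 3, 2),
                 info = paste(a, b, "(3,2)"))
  }
})

test_that("edit distance is symmetric and satisfies the triangle inequality", {
  set.seed(42)
  alph <- c("A", "C", "G", "U")
  for (i in 1:25) {
    s <- replicate(3, paste(sample(alph, sample(0:8, 1), TRUE), collapse = ""))
    d12 <- weighted_edit_distance(s[1], s[2])
    d13 <- weighted_edit_distance(s[1], s[3])
    d23 <- weighted_edit_distance(s[2], s[3])
    expect_equal(d12, weighted_edit_distance(s[2], s[1]))
    expect_lte(d13, d12 + d23)
  }
})

test_that("sequence similarity reproduces the hand-computed 3-sequence fixture", {
  seqs <- structure(c(m1 = "ACGU", m2 = "AGGU", m3 = "UUUU"),
                    class = "sequence_set")
  idx <- entity_index(c("m1", "m2", "m3"), "mirna")
  mss <- sequence_similarity(seqs, idx)
  # raw: 1-2/8=0.75 (m1,m2), 1-6/8=0.25 (m1,m3), 0.25 (m2,m3);
  # off-diagonal min-max then maps 0.75->1 and 0.25->0
  expect_equal(mss["m1", "m2"], 1)
  expect_equal(mss["m1", "m3"], 0)
  expect_equal(mss["m2", "m3"], 0)
  expect_equal(diag(mss), c(m1 = 1, m2 = 1, m3 = 1))
})

test_that("sequence similarity handles missing sequences and degenerate input", {
  seqs <- structure(c(m1 = "ACGU", m2 = "ACGA"), class = "sequence_set")
  idx <- entity_index(c("m1", "m2", "m3"), "mirna")
  mss <- sequence_similarity(seqs, idx)
  expect_equal(mss["m1", "m3"], 0)
  expect_equal(mss["m3", "m3"], 1)
  empty <- structure(character(0), class = "sequence_set")
  expect_error(sequence_similarity(empty, idx), "sequence")
})

test_that("model-1 semantic values decay by mu along the chain", {
  sv <- dag_semantic_values(chain_forest(), model = 1)
  expect_equal(sv$contrib[["c"]], c(c = 1, r = 0.5))
  expect_equal(sv$sv[["c"]], 1.5)
  expect_equal(sv$contrib[["r"]], c(r = 1))
  # self-contribution is always 1
  expect_true(all(vapply(names(sv$contrib),
                         function(d) sv$contrib[[d]][[d]] == 1, logical(1))))
})

test_that("model-2 contributions vanish for terms present in every DAG", {
  forest <- dag_forest(data.frame(dag_id = c("g1", "g2"),
                                  parent = c("a", "b"),
                                  child = c("b", "a")))
  sv <- dag_semantic_values(forest, model = 2)
  expect_equal(unname(sv$contrib[["a"]]), c(0, 0))
  expect_equal(sv$sv[["a"]], 0)
})

test_that("disease semantic similarity matches the 2-node chain hand value", {
  dss1 <- disease_semantic_similarity(chain_forest(), model = 1)
  expect_equal(dss1["c", "r"], 0.6, tolerance = 1e-12)
  expect_equal(diag(dss1), c(r = 1, c = 1)[rownames(dss1)])
  # disjoint DAGs share no ancestors
  f2 <- dag_forest(data.frame(dag_id = c("g1", "g2"),
                              parent = c("r1", "r2"),
                              child = c("c1", "c2")))
  d2 <- disease_semantic_similarity(f2, model = 1)
  expect_equal(d2["c1", "c2"], 0)
})

test_that("out-of-forest diseases get zero rows with unit diagonal", {
  idx <- entity_index(c("r", "c", "orphan"), "disease")
  dss <- disease_semantic_similarity(chain_forest(), model = 1, index = idx)
  expect_equal(dss["orphan", "r"], 0)
  expect_equal(dss["orphan", "orphan"], 1)
})

test_that("the disease network is the elementwise mean of both models", {
  f <- chain_forest()
  dss1 <- disease_semantic_similarity(f, 1)
  dss2 <- disease_semantic_similarity(f, 2)
  dsn <- disease_similarity_network(dss1, dss2)
  expect_equal(dsn["c", "r"], (dss1["c", "r"] + dss2["c", "r"]) / 2)
  expect_equal(disease_similarity_network(dss1, dss1), dss1,
               ignore_attr = "kind")
  expect_error(disease_similarity_network(dss1, dss1[2:1, 2:1]), "mismatch")
})

test_that("functional similarity agrees with a direct formula evaluation in both modes", {
  a <- tiny_assoc()
  set.seed(3)
  v <- matrix(runif(9, 0.1, 0.9), 3)
  dsn <- (v + t(v)) / 2; diag(dsn) <- 1
  dimnames(dsn) <- list(a$disease_index$names, a$disease_index$names)
  for (mode in c("intersection", "union_max")) {
    mfs <- functional_similarity(a, dsn, mode)
    dsets <- apply(a$bm, 2, function(col) which(col == 1), simplify = FALSE)
    for (i in 1:4) for (j in 1:4) {
      di <- dsets[[i]]; dj <- dsets[[j]]
      expected <- if (i == j) 1 else if (!length(di) || !length(dj)) 0 else {
        s <- if (mode == "intersection") {
          sum(vapply(intersect(di, dj), function(d)
            max(dsn[d, di]) + max(dsn[d, dj]), numeric(1)))
        } else {
          sum(vapply(di, function(d) max(dsn[d, dj]), numeric(1))) +
            sum(vapply(dj, function(d) max(dsn[d, di]), numeric(1)))
        }
        s / (length(di) + length(dj))
      }
      expect_equal(mfs[i, j], expected, info = paste(mode, i, j))
    }
  }
})

test_that("functional similarity limiting cases hold", {
  a <- tiny_assoc()
  dsn <- diag(3); dimnames(dsn) <- list(a$disease_index$names,
                                        a$disease_index$names)
  mfs <- functional_similarity(a, dsn, "intersection")
  # m2 and m4 share exactly disease d3: Dice = 2*1/(2+1)
  expect_equal(mfs["m2", "m4"], 2 / 3)
  # disjoint disease sets give 0 under intersection mode
  expect_equal(mfs["m3", "m4"], 0)
})

test_that("the miRNA network is the convex blend of MFS and MSS", {
  n <- c("m1", "m2")
  mfs <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(n, n))
  mss <- matrix(c(1, 1, 1, 1), 2, dimnames = list(n, n))
  msn <- mirna_similarity_network(mfs, mss, alpha = 0.6)
  expect_equal(msn["m1", "m2"], 0.7)
  expect_equal(mirna_similarity_network(mfs, mss, 1)[1, 2], 0.5)
  expect_equal(mirna_similarity_network(mfs, mss, 0)[1, 2], 1)
  expect_error(mirna_similarity_network(mfs, mss, 1.2), "alpha")
})

test_that("GIP kernel reproduces the 2-profile hand computation", {
  bm <- diag(2)
  a <- assoc_matrix(bm, entity_index(c("d1", "d2"), "disease"),
                    entity_index(c("m1", "m2"), "mirna"))
  k <- gip_kernel(a, "mirna")
  expect_equal(k["m1", "m2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(k), c(m1 = 1, m2 = 1))
  # doubling lambda_prime squares the off-diagonal entries
  k2 <- gip_kernel(a, "mirna", bganmda_params(lambda_prime = 2))
  expect_equal(k2["m1", "m2"], k["m1", "m2"]^2, tolerance = 1e-12)
  # linear and squared conventions agree when all profile norms are 1
  kl <- gip_kernel(a, "mirna", bganmda_params(gip_norm = "linear"))
  expect_equal(kl, k, ignore_attr = TRUE)
  zero <- assoc_matrix(matrix(0, 2, 2),
                       entity_index(c("d1", "d2"), "disease"),
                       entity_index(c("m1", "m2"), "mirna"))
  expect_error(gip_kernel(zero, "mirna"), "zero")
})

test_that("GIP kernel is invariant to permutation of the non-axis dimension", {
  dat <- small_dataset()
  perm <- sample(nrow(dat$assoc$bm))
  a2 <- assoc_matrix(dat$assoc$bm[perm, ],
                     entity_index(dat$assoc$disease_index$names[perm],
                                  "disease"),
                     dat$assoc$mirna_index)
  expect_equal(gip_kernel(dat$assoc, "mirna"), gip_kernel(a2, "mirna"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("similarity integration matches the elementwise fallback oracle", {
  set.seed(11)
  n <- 8
  nm <- paste0("e", 1:n)
  mk <- function(zero_frac) {
    v <- matrix(runif(n * n), n)
    v <- (v + t(v)) / 2
    v[v < zero_frac] <- 0
    diag(v) <- 1
    dimnames(v) <- list(nm, nm)
    v
  }
  for (rep in 1:10) {
    net <- mk(0.4); gip <- mk(0)
    ms <- integrate_similarity(net, gip, net, gip)$ms
    for (i in 1:n) for (j in 1:n) {
      expected <- if (net[i, j] > 0) net[i, j] else gip[i, j]
      if (i == j) expected <- 1
      expect_equal(ms[i, j], expected)
    }
  }
})

test_that("an explicit existence mask overrides the positivity rule", {
  n <- c("a", "b")
  net <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(n, n))
  gip <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(n, n))
  masked <- bganmda:::integrate_one(net, gip, matrix(FALSE, 2, 2), "DS")
  expect_equal(masked["a", "b"], 0.9)
})

test_that("pair features concatenate the right similarity rows with labels", {
  a <- tiny_assoc()
  p <- bganmda_params()
  sims <- similarity_pipeline(a, params = p)
  pf <- build_pair_features(sims$ms, sims$ds, a)
  expect_equal(ncol(pf$x), 4 + 3)
  expect_equal(nrow(pf$x), 12)
  k <- which(pf$mirna == "m2" & pf$disease == "d3")
  expect_equal(pf$x[k, 1:4], sims$ms["m2", ])
  expect_equal(pf$x[k, 4 + (1:3)], sims$ds["d3", ])
  expect_equal(pf$label[k], 1)
  expect_equal(sum(pf$label), sum(a$bm))
  sub <- build_pair_features(sims$ms, sims$ds, a,
                             pairs = data.frame(mirna = "m1", disease = "d2"))
  expect_equal(nrow(sub$x), 1)
  expect_equal(sub$label, a$bm["d2", "m1"])
  expect_error(build_pair_features(sims$ms, sims$ds, a,
                                   pairs = data.frame(mirna = "nope",
                                                      disease = "d1")),
               "unknown")
})
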