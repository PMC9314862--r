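#' Specification of a synthetic miRNA-disease benchmark dataset
#'
#' Describes a planted-block benchmark: miRNAs and diseases are assigned
#' to `latent_rank` latent blocks, positive associations concentrate in
#' matched block pairs, miRNA sequences within a block are mutated
#' copies of a shared ancestor, and diseases of a block share a DAG
#' subtree.  This makes the guilt-by-association premise of the method
#' true by construction, so planted signal is recoverable and
#' parameter-recovery tests are meaningful.
#'
#' @param nm,nd Numbers of miRNAs and diseases.
#' @param latent_rank Number of planted blocks.
#' @param density Fraction of the `nm * nd` pairs set positive.
#' @param seq_length_range Length range (nt) of generated sequences.
#' @param n_dags Number of disease DAGs.
#' @param dag_depth Maximum DAG depth.
#' @param noise_rate Label-flip probability applied after planting.
#' @param mut_rate Per-base substitution rate within a sequence block.
#' @param seed Integer seed; every generator is a pure function of the
#'   spec including this seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(nm = 60L, nd = 40L, latent_rank = 4L,
                           density = 0.08, seq_length_range = c(18L, 25L),
                           n_dags = 4L, dag_depth = 4L, noise_rate = 0,
                           mut_rate = 0.05, seed = 7L) {
  stopifnot(density > 0, density < 1,
            latent_rank >= 1, latent_rank <= min(nm, nd),
            noise_rate >= 0, noise_rate < 0.5,
            length(seq_length_range) == 2L,
            seq_length_range[1] >= 1,
            diff(seq_length_range) >= 0,
            n_dags >= 1, dag_depth >= 1)
  structure(list(nm = as.integer(nm), nd = as.integer(nd),
                 latent_rank = as.integer(latent_rank), density = density,
                 seq_length_range = as.integer(seq_length_range),
                 n_dags = as.integer(n_dags),
                 dag_depth = as.integer(dag_depth),
                 noise_rate = noise_rate, mut_rate = mut_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

syn_mirna_names <- function(nm) sprintf("syn-mir-%03d", seq_len(nm))
syn_disease_names <- function(nd) sprintf("synthetic disease %03d",
                                          seq_len(nd))

# Round-robin block assignment keeps block sizes balanced and is a pure
# function of the counts.
block_of <- function(n, k) rep_len(seq_len(k), n)

#' Generate block-structured miRNA sequences
#'
#' One random ancestor sequence per planted block; each member is a copy
#' with per-base substitutions at `mut_rate`, so expected within-block
#' edit distance is below the between-block distance.
#'
#' @param spec A [synthetic_spec()].
#' @return A named `sequence_set` over `{A,C,G,U}`.
#' @export
gen_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  alph <- c("A", "C", "G", "U")
  blocks <- block_of(spec$nm, spec$latent_rank)
  anc <- lapply(seq_len(spec$latent_rank), function(b) {
    len <- sample(seq(spec$seq_length_range[1], spec$seq_length_range[2]), 1)
    sample(alph, len, replace = TRUE)
  })
  seqs <- vapply(seq_len(spec$nm), function(i) {
    s <- anc[[blocks[i]]]
    mut <- runif(length(s)) < spec$mut_rate
    s[mut] <- sample(alph, sum(mut), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  structure(setNames(seqs, syn_mirna_names(spec$nm)), class = "sequence_set")
}

#' Generate a block-structured disease DAG forest
#'
#' Builds `n_dags` rooted random trees of depth at most `dag_depth`.
#' Blocks are cycled over the DAGs so diseases of one planted block land
#' in the same DAG; every disease appears in at least one DAG.
#'
#' @param spec A [synthetic_spec()].
#' @return A [dag_forest()].
#' @export
gen_dag_forest <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  dnames <- syn_disease_names(spec$nd)
  blocks <- block_of(spec$nd, spec$latent_rank)
  dag_of_block <- rep_len(seq_len(spec$n_dags), spec$latent_rank)
  # an edge-list DAG needs at least two nodes; fold undersized DAGs into
  # the first one
  sizes <- vapply(seq_len(spec$n_dags), function(g)
    sum(blocks %in% which(dag_of_block == g)), integer(1))
  small <- which(sizes < 2L)
  if (length(small) > 0L)
    dag_of_block[dag_of_block %in% small] <- setdiff(seq_len(spec$n_dags),
                                                     small)[1]
  edges <- list()
  for (g in unique(dag_of_block)) {
    members <- dnames[blocks %in% which(dag_of_block == g)]
    if (length(members) == 0L) next
    depth <- setNames(integer(length(members)), members)
    for (i in seq_along(members)) {
      if (i == 1L) { depth[1] <- 1L; next }       # first member is the root
      ok <- members[seq_len(i - 1L)][depth[seq_len(i - 1L)] < spec$dag_depth]
      parent <- if (length(ok) == 1L) ok else sample(ok, 1)
      depth[i] <- depth[parent] + 1L
      edges[[length(edges) + 1L]] <-
        data.frame(dag_id = sprintf("g%d", g), parent = parent,
                   child = members[i], stringsAsFactors = FALSE)
    }
  }
  dag_forest(do.call(rbind, edges))
}

#' Generate a planted low-rank association matrix
#'
#' A block affinity score (high for matched miRNA/disease blocks, low
#' otherwise, plus a small uniform jitter to break ties) is thresholded
#' so that exactly `ceiling(density * nm * nd)` entries are positive;
#' labels are then flipped independently with probability `noise_rate`.
#' The returned truth object records block memberships and a held-out
#' set of planted (in-block) pairs that just missed the density cut --
#' the natural test set for enrichment checks.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `assoc` (an [assoc_matrix()]) and `truth` (list
#'   with `mirna_block`, `disease_block`, `score`, `heldout`, a data
#'   frame of planted-but-unobserved pairs).
#' @export
gen_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  mb <- block_of(spec$nm, spec$latent_rank)
  db <- block_of(spec$nd, spec$latent_rank)
  affinity <- outer(db, mb, function(a, b) ifelse(a == b, 1, 0))
  score <- affinity + matrix(runif(spec$nd * spec$nm, 0, 0.5),
                             spec$nd, spec$nm)
  q <- ceiling(spec$density * spec$nm * spec$nd)
  if (q > spec$nd * spec$nm)
    stop("requested density unreachable", call. = FALSE)
  ord <- order(score, decreasing = TRUE)
  bm <- matrix(0, spec$nd, spec$nm)
  bm[ord[seq_len(q)]] <- 1
  n_held <- ceiling(0.25 * q)
  held_idx <- ord[q + seq_len(min(n_held, length(ord) - q))]
  held_idx <- held_idx[affinity[held_idx] == 1]  # only truly planted pairs
  if (spec$noise_rate > 0) {
    flip <- runif(length(bm)) < spec$noise_rate
    bm[flip] <- 1 - bm[flip]
  }
  mi <- entity_index(syn_mirna_names(spec$nm), "mirna")
  di <- entity_index(syn_disease_names(spec$nd), "disease")
  heldout <- data.frame(
    mirna = mi$names[(held_idx - 1L) %/% spec$nd + 1L],
    disease = di$names[(held_idx - 1L) %% spec$nd + 1L],
    stringsAsFactors = FALSE)
  list(assoc = assoc_matrix(bm, di, mi),
       truth = list(mirna_block = setNames(mb, mi$names),
                    disease_block = setNames(db, di$names),
                    score = score, heldout = heldout))
}

#' Generate a complete synthetic benchmark dataset
#'
#' Composes [gen_associations()], [gen_sequences()] and
#' [gen_dag_forest()] under the spec's single seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `assoc`, `seqs`, `forest`, `truth`, `spec`.
#' @export
gen_dataset <- function(spec = synthetic_spec()) {
  ga <- gen_associations(spec)
  list(assoc = ga$assoc,
       seqs = gen_sequences(spec),
       forest = gen_dag_forest(spec),
       truth = ga$truth,
       spec = spec)
}

#' Write a synthetic dataset to standard-format files
#'
#' Emits `associations.tsv`, `sequences.fasta`, `dag_edges.tsv`,
#' `dag_membership.tsv` and `truth.json` into a directory, in the same
#' dialects the readers consume.
#'
#' @param dataset Result of [gen_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bm <- dataset$assoc$bm
  pos <- which(bm == 1)
  pairs <- data.frame(
    mirna = dataset$assoc$mirna_index$names[(pos - 1L) %/% nrow(bm) + 1L],
    disease = dataset$assoc$disease_index$names[(pos - 1L) %% nrow(bm) + 1L])
  write.table(pairs, file.path(dir, "associations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", names(dataset$seqs), "\n",
                    as.character(dataset$seqs)),
             file.path(dir, "sequences.fasta"))
  edges <- do.call(rbind, lapply(dataset$forest$dags, function(d)
    cbind(dag_id = d$id, d$edges)))
  write.table(edges, file.path(dir, "dag_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mem <- do.call(rbind, lapply(names(dataset$forest$membership), function(d)
    data.frame(disease = d, dag_id = dataset$forest$membership[[d]])))
  write.table(mem, file.path(dir, "dag_membership.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(dataset$spec),
         mirna_block = as.list(dataset$truth$mirna_block),
         disease_block = as.list(dataset$truth$disease_block),
         heldout = dataset$truth$heldout),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
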