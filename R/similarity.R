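#' Weighted Levenshtein distance between two sequences
#'
#' Minimum total cost of converting `s1` into `s2` with unit operations
#' priced separately: substitutions cost `sub_cost`, insertions and
#' deletions cost `indel_cost`.  With the defaults (2, 1) a substitution
#' is never cheaper than a delete-insert pair, so the distance between
#' sequences of lengths `L1` and `L2` is bounded by `L1 + L2`.
#'
#' @param s1,s2 Character strings (empty strings allowed).
#' @param sub_cost,indel_cost Positive integer costs.
#' @return A single non-negative number, symmetric in `(s1, s2)`.
#' @export
weighted_edit_distance <- function(s1, s2, sub_cost = 2L, indel_cost = 1L) {
  as.numeric(adist(s1, s2, costs = list(insertions = indel_cost,
                                        deletions = indel_cost,
                                        substitutions = sub_cost)))
}

# Validate + finalise a similarity matrix: symmetry to 1e-9, entries in
# [0,1] (tiny float excursions are clipped), unit diagonal, dimnames set.
as_similarity <- function(v, names, kind) {
  v <- as.matrix(v)
  stopifnot(nrow(v) == ncol(v))
  if (max(abs(v - t(v))) > 1e-9)
    stop("similarity matrix `", kind, "` is not symmetric", call. = FALSE)
  v <- (v + t(v)) / 2
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    stop("similarity matrix `", kind, "` has entries outside [0, 1]",
         call. = FALSE)
  v[v < 0] <- 0
  v[v > 1] <- 1
  diag(v) <- 1
  dimnames(v) <- list(names, names)
  attr(v, "kind") <- kind
  v
}

#' miRNA sequence similarity matrix
#'
#' Pairwise similarity `1 - x / (Len(i) + Len(j))` where `x` is the
#' weighted Levenshtein distance, followed by min-max rescaling of the
#' off-diagonal entries so the least similar pair maps to 0 and the most
#' similar to 1.  The diagonal is pinned to 1 and pairs involving a
#' miRNA without a sequence are set to 0.
#'
#' @param seqs A `sequence_set` (named sequences) from [read_fasta()] or
#'   [gen_sequences()].
#' @param index `entity_index` of miRNAs defining row/column order.
#' @param params [bganmda_params()] supplying the edit costs.
#' @return Symmetric matrix in `[0,1]` with unit diagonal, tagged `"MSS"`.
#' @export
sequence_similarity <- function(seqs, index, params = bganmda_params()) {
  nm <- length(index)
  seq_of <- as.character(seqs)[match(index$names, normalize_name(names(seqs)))]
  present <- which(!is.na(seq_of) & nzchar(seq_of))
  if (length(present) == 0L)
    stop("no indexed miRNA has a sequence", call. = FALSE)
  v <- matrix(0, nm, nm)
  s <- seq_of[present]
  d <- adist(s, s, costs = list(insertions = params$indel_cost,
                                deletions = params$indel_cost,
                                substitutions = params$sub_cost))
  len <- nchar(s)
  raw <- 1 - d / outer(len, len, `+`)
  if (length(present) > 1L) {
    off <- raw[upper.tri(raw) | lower.tri(raw)]
    rng <- range(off)
    if (diff(rng) > 0)
      raw <- (raw - rng[1]) / diff(rng)  # off-diagonal min-max rescale
  }
  v[present, present] <- pmin(pmax(raw, 0), 1)
  as_similarity(v, index$names, "MSS")
}

# Union of all DAG edges as one igraph (used for ancestor queries).
forest_graph <- function(forest) {
  edges <- unique(do.call(rbind, lapply(forest$dags, `[[`, "edges")))
  igraph::graph_from_data_frame(edges,
                                vertices = names(forest$membership))
}

#' Semantic contribution values of diseases in a DAG forest
#'
#' Two semantic models over the ancestor closure `G(d)` of each disease.
#' Model 1 propagates a decayed contribution up the DAG: a disease
#' contributes 1 to itself, and an ancestor's contribution is `mu` times
#' the maximum contribution among its children on paths toward the
#' disease.  Model 2 weights each term by its information content,
#' `-log(NG(k) / nd)` with `NG(k)` the number of DAGs containing term
#' `k` (natural logarithm), identically for every disease.  The semantic
#' value `SV(d)` is the sum of contributions over `G(d)`.
#'
#' @param forest A [dag_forest()].
#' @param model 1 or 2.
#' @param params [bganmda_params()] supplying `mu`.
#' @param nd Denominator for model 2; defaults to the number of distinct
#'   diseases in the forest.
#' @return List with `model`, `contrib` (per disease, named numeric
#'   vector over its ancestor closure) and `sv` (named numeric).
#' @export
dag_semantic_values <- function(forest, model = 1, params = bganmda_params(),
                                nd = NULL) {
  stopifnot(model %in% c(1, 2))
  g <- forest_graph(forest)
  diseases <- names(forest$membership)
  if (is.null(nd)) nd <- length(diseases)
  c2 <- if (model == 2) {
    ng <- vapply(forest$membership, length, integer(1))
    -log(ng / nd)
  }
  contrib <- setNames(vector("list", length(diseases)), diseases)
  for (d in diseases) {
    anc <- names(igraph::subcomponent(g, d, mode = "in"))
    if (model == 1) {
      sub <- igraph::induced_subgraph(g, anc)
      ord <- rev(names(igraph::topo_sort(sub, mode = "out")))
      cv <- setNames(numeric(length(anc)), anc)
      cv[d] <- 1
      for (a in ord) {
        if (a == d) next
        kids <- names(igraph::neighbors(sub, a, mode = "out"))
        cv[a] <- params$mu * max(cv[kids])
      }
      contrib[[d]] <- cv
    } else {
      contrib[[d]] <- c2[anc]
    }
  }
  list(model = model,
       contrib = contrib,
       sv = vapply(contrib, sum, numeric(1)))
}

#' Disease semantic similarity matrix
#'
#' For diseases `i`, `j` with ancestor closures `G(i)`, `G(j)`, the
#' similarity is the summed contribution of shared ancestors from both
#' sides, normalised by the total semantic values:
#' `sum_{x in G(i) ∩ G(j)} (C_i(x) + C_j(x)) / (SV(i) + SV(j))`.
#' Model-2 values are clipped into `[0,1]` (with a message when clipping
#' occurs); diseases absent from the forest get zero rows apart from the
#' unit diagonal.
#'
#' @param forest A [dag_forest()].
#' @param model 1 or 2.
#' @param params,nd Passed to [dag_semantic_values()].
#' @param index Optional disease `entity_index` defining the matrix
#'   order; defaults to the forest's diseases.
#' @return Symmetric matrix tagged `"DSS1"` or `"DSS2"`.
#' @export
disease_semantic_similarity <- function(forest, model = 1,
                                        params = bganmda_params(),
                                        index = NULL, nd = NULL) {
  sv_tab <- dag_semantic_values(forest, model, params, nd = nd)
  names_out <- if (is.null(index)) names(forest$membership) else index$names
  n <- length(names_out)
  v <- matrix(0, n, n)
  inf <- which(names_out %in% names(sv_tab$contrib))
  clipped <- 0L
  for (a in seq_along(inf)) {
    for (b in seq_len(a)) {
      i <- inf[a]; j <- inf[b]
      ci <- sv_tab$contrib[[names_out[i]]]
      cj <- sv_tab$contrib[[names_out[j]]]
      common <- intersect(names(ci), names(cj))
      val <- if (length(common) == 0L) 0 else
        sum(ci[common] + cj[common]) /
          (sv_tab$sv[names_out[i]] + sv_tab$sv[names_out[j]])
      if (is.nan(val)) val <- if (i == j) 1 else 0  # SV can be 0 in model 2
      if (val > 1) { val <- 1; clipped <- clipped + 1L }
      v[i, j] <- v[j, i] <- val
    }
  }
  if (clipped > 0L)
    message(clipped, " semantic similarity value(s) clipped to 1")
  as_similarity(v, names_out, paste0("DSS", model))
}

#' Combined disease semantic similarity network
#'
#' Elementwise mean of the two semantic similarity matrices.
#'
#' @param dss1,dss2 Matrices from [disease_semantic_similarity()] with
#'   identical dimnames.
#' @return Symmetric matrix tagged `"DSN"`.
#' @export
disease_similarity_network <- function(dss1, dss2) {
  if (!identical(dimnames(dss1), dimnames(dss2)))
    stop("disease similarity matrices have mismatched indices", call. = FALSE)
  as_similarity((dss1 + dss2) / 2, rownames(dss1), "DSN")
}

#' miRNA functional similarity from shared disease associations
#'
#' Functional similarity of two miRNAs induced by the semantic similarity
#' of their associated disease sets `D(i)`, `D(j)`.  `DSS(d, S)` is the
#' best semantic match of disease `d` within set `S`.  In
#' `"intersection"` mode the sum runs over the shared diseases only
#' (each term is then a pair of exact self-matches, so the score reduces
#' to the Dice overlap of the two disease sets); in `"union_max"` mode it
#' is the classical best-match average over both sets.  Either sum is
#' divided by `|D(i)| + |D(j)|`.  miRNAs with no known disease get zero
#' rows apart from the unit diagonal.
#'
#' @param bm An [assoc_matrix()].
#' @param dsn Disease similarity network over the same disease index.
#' @param mode `"intersection"` or `"union_max"`.
#' @return Symmetric matrix tagged `"MFS"`.
#' @export
functional_similarity <- function(bm, dsn,
                                  mode = c("intersection", "union_max")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bm, "assoc_matrix"))
  if (!identical(rownames(dsn), bm$disease_index$names))
    stop("disease network does not match association matrix", call. = FALSE)
  nm <- length(bm$mirna_index)
  dsets <- apply(bm$bm, 2, function(col) which(col == 1), simplify = FALSE)
  v <- matrix(0, nm, nm)
  for (i in seq_len(nm)) {
    di <- dsets[[i]]
    if (length(di) == 0L) next
    for (j in seq_len(i)) {
      dj <- dsets[[j]]
      if (length(dj) == 0L) next
      denom <- length(di) + length(dj)
      s <- if (mode == "intersection") {
        shared <- intersect(di, dj)
        if (length(shared) == 0L) 0 else
          sum(apply(dsn[shared, di, drop = FALSE], 1, max) +
                apply(dsn[shared, dj, drop = FALSE], 1, max))
      } else {
        sum(apply(dsn[di, dj, drop = FALSE], 1, max)) +
          sum(apply(dsn[dj, di, drop = FALSE], 1, max))
      }
      v[i, j] <- v[j, i] <- s / denom
    }
  }
  as_similarity(v, bm$mirna_index$names, "MFS")
}

#' Blended miRNA similarity network
#'
#' Convex combination `alpha * MFS + (1 - alpha) * MSS` of functional and
#' sequence similarity.
#'
#' @param mfs,mss Matrices over the same miRNA index.
#' @param alpha Mixing weight in `[0,1]`.
#' @return Symmetric matrix tagged `"MSN"`.
#' @export
mirna_similarity_network <- function(mfs, mss, alpha = 0.6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!identical(dimnames(mfs), dimnames(mss)))
    stop("miRNA similarity matrices have mismatched indices", call. = FALSE)
  as_similarity(alpha * mfs + (1 - alpha) * mss, rownames(mfs), "MSN")
}

#' Gaussian interaction profile kernel similarity
#'
#' Radial-basis similarity `exp(-lambda * ||p_i - p_j||^2)` between
#' interaction profiles (columns of the association matrix for miRNAs,
#' rows for diseases).  The bandwidth is `lambda_prime` divided by the
#' mean squared profile norm (or the mean norm under
#' `gip_norm = "linear"`).  Two entities with identical profiles --
#' including two all-zero profiles -- have kernel value 1 by
#' construction; this is a documented property of the kernel, not a
#' special case.
#'
#' @param bm An [assoc_matrix()].
#' @param axis `"mirna"` or `"disease"`.
#' @param params [bganmda_params()] supplying `lambda_prime`, `gip_norm`.
#' @return Symmetric matrix in `(0,1]` tagged `"MGS"` or `"DGS"`.
#' @export
gip_kernel <- function(bm, axis = c("mirna", "disease"),
                       params = bganmda_params()) {
  axis <- match.arg(axis)
  stopifnot(inherits(bm, "assoc_matrix"))
  p <- if (axis == "mirna") t(bm$bm) else bm$bm
  sq <- rowSums(p^2)
  denom <- if (params$gip_norm == "squared") mean(sq) else mean(sqrt(sq))
  if (denom == 0)
    stop("association matrix is all zero; GIP bandwidth undefined",
         call. = FALSE)
  lambda <- params$lambda_prime / denom
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0
  kind <- if (axis == "mirna") "MGS" else "DGS"
  names <- if (axis == "mirna") bm$mirna_index$names else bm$disease_index$names
  as_similarity(exp(-lambda * d2), names, kind)
}

#' Integrate a similarity network with its GIP kernel fallback
#'
#' The integrated miRNA similarity takes the network value where one
#' exists and falls back to the Gaussian kernel where it does not:
#' `MS(i,j) = MSN(i,j)` if the network similarity exists, else
#' `MGS(i,j)`; likewise `DS` from `DSN`/`DGS`.  By default a similarity
#' "exists" when the network value is positive; `exists_disease` can
#' supply an explicit logical mask (the pipeline passes joint DAG
#' coverage for diseases).
#'
#' @param msn,mgs miRNA network and kernel matrices (same index).
#' @param dsn,dgs Disease network and kernel matrices (same index).
#' @param exists_mirna,exists_disease Optional logical matrices marking
#'   where the network value is authoritative; default `value > 0`.
#' @return List with integrated matrices `ms` and `ds`.
#' @export
integrate_similarity <- function(msn, mgs, dsn, dgs,
                                 exists_mirna = NULL, exists_disease = NULL) {
  list(ms = integrate_one(msn, mgs, exists_mirna, "MS"),
       ds = integrate_one(dsn, dgs, exists_disease, "DS"))
}

integrate_one <- function(net, gip, exists = NULL, kind) {
  if (!identical(dimnames(net), dimnames(gip)))
    stop("network and kernel matrices have mismatched indices", call. = FALSE)
  if (is.null(exists)) exists <- net > 0
  stopifnot(identical(dim(exists), dim(net)))
  v <- ifelse(exists, net, gip)
  as_similarity(v, rownames(net), kind)
}

#' Per-pair concatenated similarity feature vectors
#'
#' The feature vector of pair `(m_i, d_j)` is row `i` of the integrated
#' miRNA similarity `MS` concatenated with row `j` of the integrated
#' disease similarity `DS`, giving length `nm + nd`; its label is the
#' association matrix entry.
#'
#' @param ms,ds Integrated similarity matrices.
#' @param bm An [assoc_matrix()] providing the labels.
#' @param pairs Optional data frame with columns `mirna` and `disease`
#'   (names); all `nm * nd` pairs when omitted.
#' @return A `pair_features` list: `x` (features, one row per pair),
#'   `label`, `mirna`, `disease`, `nm`, `nd`.
#' @export
build_pair_features <- function(ms, ds, bm, pairs = NULL) {
  stopifnot(inherits(bm, "assoc_matrix"))
  nm <- length(bm$mirna_index); nd <- length(bm$disease_index)
  stopifnot(identical(rownames(ms), bm$mirna_index$names),
            identical(rownames(ds), bm$disease_index$names))
  if (is.null(pairs)) {
    pairs <- expand.grid(mirna = bm$mirna_index$names,
                         disease = bm$disease_index$names,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  mi <- index_of(bm$mirna_index, pairs$mirna)
  di <- index_of(bm$disease_index, pairs$disease)
  x <- cbind(ms[mi, , drop = FALSE], ds[di, , drop = FALSE])
  rownames(x) <- NULL
  structure(list(x = x,
                 label = bm$bm[cbind(di, mi)],
                 mirna = bm$mirna_index$names[mi],
                 disease = bm$disease_index$names[di],
                 nm = nm, nd = nd),
            class = "pair_features")
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("<pair_features: %d pairs, feature length %d (%d+%d), %d positive>\n",
              nrow(x$x), ncol(x$x), x$nm, x$nd, sum(x$label)))
  invisible(x)
}

#' Run the full similarity-construction pipeline
#'
#' Computes every similarity matrix from the raw inputs: sequence (MSS),
#' functional (MFS) and blended (MSN) miRNA similarity, the two DAG
#' semantic models (DSS1, DSS2) and their mean (DSN), both Gaussian
#' interaction profile kernels (MGS, DGS), and the integrated networks
#' (MS, DS).  Missing inputs degrade gracefully: without sequences MSS
#' is zero off the diagonal, without a DAG forest DSN is, and the GIP
#' fallback covers the gaps through the integration rule.  For diseases
#' the network similarity is taken to exist when both diseases appear in
#' at least one DAG.
#'
#' @param assoc An [assoc_matrix()].
#' @param seqs Optional `sequence_set`.
#' @param forest Optional [dag_forest()].
#' @param params [bganmda_params()].
#' @return List of all ten matrices plus the input indices.
#' @export
similarity_pipeline <- function(assoc, seqs = NULL, forest = NULL,
                                params = bganmda_params()) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  mi <- assoc$mirna_index; di <- assoc$disease_index
  mss <- if (is.null(seqs)) {
    as_similarity(diag(length(mi)), mi$names, "MSS")
  } else sequence_similarity(seqs, mi, params)
  if (is.null(forest)) {
    dss1 <- dss2 <- as_similarity(diag(length(di)), di$names, "DSS1")
    in_forest <- rep(FALSE, length(di))
  } else {
    dss1 <- disease_semantic_similarity(forest, 1, params, index = di)
    dss2 <- disease_semantic_similarity(forest, 2, params, index = di)
    in_forest <- di$names %in% names(forest$membership)
  }
  dsn <- disease_similarity_network(dss1, dss2)
  mfs <- functional_similarity(assoc, dsn, params$functional_mode)
  msn <- mirna_similarity_network(mfs, mss, params$alpha)
  mgs <- gip_kernel(assoc, "mirna", params)
  dgs <- gip_kernel(assoc, "disease", params)
  integ <- integrate_similarity(msn, mgs, dsn, dgs,
                                exists_disease = outer(in_forest, in_forest,
                                                       `&`))
  list(mss = mss, mfs = mfs, msn = msn, mgs = mgs,
       dss1 = dss1, dss2 = dss2, dsn = dsn, dgs = dgs,
       ms = integ$ms, ds = integ$ds,
       mirna_index = mi, disease_index = di)
}
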