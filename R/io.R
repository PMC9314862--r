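#' @importFrom utils read.delim write.table adist head
#' @importFrom stats rnorm runif setNames sd median predict simulate
NULL

# Canonical name normalisation used for every entity identifier:
# case-fold, strip leading/trailing whitespace, collapse internal runs.
normalize_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Ordered entity index
#'
#' An ordered list of unique (normalised) entity names; the position of a
#' name is its integer id everywhere in the package.
#'
#' @param names Character vector of identifiers (normalised and
#'   deduplicated in first-appearance order).
#' @param kind `"mirna"` or `"disease"`.
#' @return An `entity_index` object.
#' @export
entity_index <- function(names, kind = c("mirna", "disease")) {
  kind <- match.arg(kind)
  names <- normalize_name(names)
  names <- names[!duplicated(names)]
  if (any(!nzchar(names)))
    stop("empty entity name after normalisation", call. = FALSE)
  structure(list(names = names, kind = kind), class = "entity_index")
}

#' @export
length.entity_index <- function(x) length(x$names)

#' @export
print.entity_index <- function(x, ...) {
  cat(sprintf("<entity_index: %d %s names>\n", length(x$names), x$kind))
  invisible(x)
}

index_of <- function(index, names) {
  i <- match(normalize_name(names), index$names)
  if (anyNA(i))
    stop("unknown ", index$kind, " name(s): ",
         paste(unique(names[is.na(i)]), collapse = ", "), call. = FALSE)
  i
}

#' Binary association matrix
#'
#' Wraps a disease-by-miRNA 0/1 matrix together with its two entity
#' indices.  Rows are diseases, columns are miRNAs.
#'
#' @param bm Binary matrix, diseases in rows and miRNAs in columns.
#' @param disease_index,mirna_index `entity_index` objects matching the
#'   matrix dimensions.
#' @param n_duplicates Number of duplicated input pairs that were collapsed.
#' @return An `assoc_matrix` object.
#' @export
assoc_matrix <- function(bm, disease_index, mirna_index, n_duplicates = 0L) {
  bm <- as.matrix(bm)
  if (!all(bm %in% c(0, 1)))
    stop("association matrix entries must be 0 or 1", call. = FALSE)
  if (nrow(bm) != length(disease_index) || ncol(bm) != length(mirna_index))
    stop("association matrix shape does not match entity indices",
         call. = FALSE)
  storage.mode(bm) <- "double"
  dimnames(bm) <- list(disease_index$names, mirna_index$names)
  structure(list(bm = bm,
                 disease_index = disease_index,
                 mirna_index = mirna_index,
                 n_duplicates = as.integer(n_duplicates)),
            class = "assoc_matrix")
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix: %d diseases x %d miRNAs, %d known associations>\n",
              nrow(x$bm), ncol(x$bm), sum(x$bm)))
  invisible(x)
}

#' Read a miRNA-disease association table
#'
#' Reads a tab-delimited table with (at least) `mirna` and `disease`
#' columns, one experimentally verified association per row, and builds
#' the binary association matrix.  Duplicate pairs are collapsed (their
#' count is reported via a message), names are case-folded and
#' whitespace-normalised, rows with an empty field are dropped, and the
#' entity indices are built in first-appearance order.
#'
#' @param path Path to a TSV/CSV file; `#` lines are ignored.  Column
#'   names are matched case-insensitively (`mirna`/`mir`/`microrna` and
#'   `disease`).
#' @return An [assoc_matrix()].
#' @export
read_association_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  cols <- tolower(names(tab))
  mcol <- which(cols %in% c("mirna", "mir", "microrna"))[1]
  dcol <- which(cols == "disease")[1]
  if (is.na(mcol) || is.na(dcol))
    stop("association table must have `mirna` and `disease` columns",
         call. = FALSE)
  if (nrow(tab) == 0L)
    stop("association table is empty", call. = FALSE)
  pairs <- data.frame(mirna = normalize_name(tab[[mcol]]),
                      disease = normalize_name(tab[[dcol]]),
                      stringsAsFactors = FALSE)
  empty <- !nzchar(pairs$mirna) | !nzchar(pairs$disease)
  if (any(empty)) {
    message(sum(empty), " row(s) with empty fields dropped")
    pairs <- pairs[!empty, , drop = FALSE]
  }
  if (nrow(pairs) == 0L)
    stop("association table has no usable rows", call. = FALSE)
  dup <- duplicated(pairs)
  n_dup <- sum(dup)
  if (n_dup > 0L) message(n_dup, " duplicate association(s) collapsed")
  pairs <- pairs[!dup, , drop = FALSE]
  mi <- entity_index(pairs$mirna, "mirna")
  di <- entity_index(pairs$disease, "disease")
  bm <- matrix(0, length(di), length(mi))
  bm[cbind(match(pairs$disease, di$names), match(pairs$mirna, mi$names))] <- 1
  assoc_matrix(bm, di, mi, n_duplicates = n_dup)
}

#' Read miRNA sequences from a FASTA file
#'
#' Sequences are upper-cased and DNA-style `T` is normalised to `U`.  The
#' first whitespace-delimited token of each header is the miRNA name
#' (normalised like all entity names).  Duplicate headers keep the first
#' record with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (name -> RNA sequence) of class
#'   `sequence_set`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  nm <- normalize_name(vapply(strsplit(names(set), "[[:space:]]+"),
                              `[`, character(1), 1))
  seqs <- chartr("acgtun", "ACGUUN", tolower(as.character(set)))
  if (anyDuplicated(nm)) {
    warning("duplicate FASTA headers; keeping first occurrence of: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
    keep <- !duplicated(nm)
    nm <- nm[keep]; seqs <- seqs[keep]
  }
  if (any(!nzchar(seqs))) stop("empty sequence record", call. = FALSE)
  structure(setNames(seqs, nm), class = "sequence_set")
}

#' Disease DAG forest
#'
#' A set of rooted directed acyclic graphs over disease names plus a
#' membership map from each disease to the DAG ids containing it.
#'
#' @param edges Data frame with columns `dag_id`, `parent`, `child`
#'   (names normalised).
#' @return A `dag_forest` object with elements `dags` (per-DAG list with
#'   `id`, `edges`, `root`, `nodes`) and `membership` (named list,
#'   disease -> character vector of DAG ids).
#' @export
dag_forest <- function(edges) {
  edges <- data.frame(dag_id = as.character(edges$dag_id),
                      parent = normalize_name(edges$parent),
                      child = normalize_name(edges$child),
                      stringsAsFactors = FALSE)
  dags <- lapply(split(edges, edges$dag_id), function(e) {
    g <- igraph::graph_from_data_frame(e[, c("parent", "child")])
    if (!igraph::is_dag(g))
      stop("cycle detected in DAG `", e$dag_id[1], "`", call. = FALSE)
    roots <- names(which(igraph::degree(g, mode = "in") == 0))
    if (length(roots) != 1L)
      stop("DAG `", e$dag_id[1], "` must have exactly one root, found ",
           length(roots), call. = FALSE)
    reach <- names(igraph::subcomponent(g, roots, mode = "out"))
    nodes <- igraph::V(g)$name
    if (!setequal(reach, nodes))
      stop("DAG `", e$dag_id[1],
           "` has nodes unreachable from its root", call. = FALSE)
    list(id = e$dag_id[1], edges = e[, c("parent", "child")],
         root = roots, nodes = nodes)
  })
  membership <- list()
  for (d in dags)
    for (node in d$nodes)
      membership[[node]] <- c(membership[[node]], d$id)
  structure(list(dags = dags, membership = membership), class = "dag_forest")
}

#' @export
print.dag_forest <- function(x, ...) {
  cat(sprintf("<dag_forest: %d DAG(s), %d disease(s)>\n",
              length(x$dags), length(x$membership)))
  invisible(x)
}

#' Read a disease DAG forest from flat edge lists
#'
#' @param edges_path TSV with columns `dag_id`, `parent`, `child`.
#' @param membership_path Optional TSV with columns `disease`, `dag_id`;
#'   when omitted, membership is derived from the edge lists.
#' @return A [dag_forest()].
#' @export
read_dag_forest <- function(edges_path, membership_path = NULL) {
  edges <- read.delim(edges_path, comment.char = "#",
                      stringsAsFactors = FALSE)
  need <- c("dag_id", "parent", "child")
  if (!all(need %in% tolower(names(edges))))
    stop("edge list must have columns dag_id, parent, child", call. = FALSE)
  names(edges) <- tolower(names(edges))
  forest <- dag_forest(edges)
  if (!is.null(membership_path)) {
    mem <- read.delim(membership_path, comment.char = "#",
                      stringsAsFactors = FALSE)
    names(mem) <- tolower(names(mem))
    if (!all(c("disease", "dag_id") %in% names(mem)))
      stop("membership table must have columns disease, dag_id",
           call. = FALSE)
    mm <- split(as.character(mem$dag_id), normalize_name(mem$disease))
    forest$membership <- lapply(mm, unique)
  }
  forest
}

#' Write a ranked association score table
#'
#' Writes a TSV with columns `mirna`, `disease`, `score` (and `label` if
#' present), sorted by descending score with ties broken lexicographically
#' by (disease, mirna) for determinism.
#'
#' @param scores Data frame with columns `mirna`, `disease`, `score` and
#'   optionally `label`.
#' @param path Output path.
#' @return Invisibly, the sorted data frame that was written.
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores),
            all(c("mirna", "disease", "score") %in% names(scores)))
  if (nrow(scores) == 0L) stop("empty score list", call. = FALSE)
  if (any(!is.finite(scores$score))) stop("non-finite score", call. = FALSE)
  ord <- order(-scores$score, scores$disease, scores$mirna)
  out <- scores[ord, intersect(c("mirna", "disease", "score", "label"),
                               names(scores)), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `mirna`, `disease`, `score` and,
#'   if present, `label`.
#' @export
read_scores <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
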