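# Comparison layer: pairwise protein alignment and percent identity,
# identity/distance matrices, Saitou-Nei neighbor joining, Newick IO.

#' Pairwise protein alignment with percent identity
#'
#' Optimal affine-gap alignment (BLOSUM62, gap open 11, extend 1 by
#' default, matching common protein-search defaults).  Percent identity is
#' identical columns over aligned columns with gap columns excluded.
#'
#' @param a,b Residue strings.
#' @param mode `"global"` (Needleman-Wunsch) or `"local"`
#'   (Smith-Waterman).  Local identity over the aligned region is the
#'   headline value for homology percentages; global is used for species
#'   demarcation.
#' @param matrix Substitution matrix (defaults to BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (positive).
#' @return A `vs_alignment` list: `aligned_a`, `aligned_b` (gapped strings
#'   of equal length), `score`, `percent_identity`, `mode`.
#' @export
align_pair <- function(a, b, mode = c("local", "global"), matrix = NULL,
                       gap_open = 11, gap_extend = 1) {
  mode <- match.arg(mode)
  if (is.null(matrix)) matrix <- scoring_model()$matrix
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = if (mode == "global") "global" else "local",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  no_gap <- ca != "-" & cb != "-"
  pid <- if (any(no_gap)) 100 * sum(ca[no_gap] == cb[no_gap]) / sum(no_gap)
         else 0
  structure(list(aligned_a = pa, aligned_b = pb,
                 score = Biostrings::score(aln),
                 percent_identity = pid, mode = mode),
            class = "vs_alignment")
}

#' All-pairs percent identity and distance matrices
#'
#' @param seqs Named character vector of residue strings.
#' @param mode Alignment mode (see [align_pair()]).
#' @param matrix,gap_open,gap_extend Passed to [align_pair()].
#' @return List: `identity` (symmetric percent matrix, diagonal 100) and
#'   `distance` (`1 - identity/100`, class `dist`-compatible matrix).
#' @export
identity_matrix <- function(seqs, mode = "local", matrix = NULL,
                            gap_open = 11, gap_extend = 1) {
  n <- length(seqs)
  stopifnot(n >= 2, !is.null(names(seqs)))
  idm <- diag(100, n)
  dimnames(idm) <- list(names(seqs), names(seqs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- align_pair(seqs[[i]], seqs[[j]], mode = mode, matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)$percent_identity
      idm[i, j] <- idm[j, i] <- pid
    }
  }
  dm <- 1 - idm / 100
  diag(dm) <- 0
  list(identity = idm, distance = dm)
}

#' Saitou-Nei neighbor joining
#'
#' Standard Q-criterion agglomeration.  Negative branch lengths are
#' clamped to zero with the deficit shifted to the sibling branch; ties in
#' the Q matrix break deterministically by label order.  The result is an
#' unrooted tree stored with a trifurcating root (an `ape` `phylo`
#' object), or a single edge for two taxa.
#'
#' @param dm Symmetric distance matrix with labeled dimnames (or `dist`).
#' @return An `ape` `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 2,
            !is.null(rownames(dm)))
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(dm)
  n_leaves <- length(labels)
  if (n_leaves == 2) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
               edge.length = rep(dm[1, 2] / 2, 2),
               tip.label = labels, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  # active nodes carry ape node ids: tips 1..n, internals n+1, n+2, ...
  ids <- seq_len(n_leaves)
  D <- dm
  next_internal <- n_leaves + 1L
  edges <- NULL
  elens <- NULL
  ord <- order(labels)  # deterministic tie-break: first by label order
  D <- D[ord, ord, drop = FALSE]
  ids <- ids[ord]
  while (nrow(D) > 3) {
    r <- nrow(D)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- min(best)
    j <- max(best)
    d_ij <- D[i, j]
    li <- d_ij / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d_ij - li
    # clamp negatives, shifting the deficit to the sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0)
    lj <- max(lj, 0)
    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, ids[i]), c(u, ids[j]))
    elens <- c(elens, li, lj)
    d_new <- (D[i, -c(i, j), drop = TRUE] + D[j, -c(i, j), drop = TRUE] - d_ij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], d_new),
                c(d_new, 0))
    ids <- c(ids[keep], u)
    D <- D2
  }
  # final three nodes join a trifurcating root (closed form)
  u <- next_internal
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  edges <- rbind(edges, c(u, ids[1]), c(u, ids[2]), c(u, ids[3]))
  elens <- c(elens, max(l1, 0), max(l2, 0), max(l3, 0))
  # renumber internals to ape's convention: root (created last) = n + 1
  max_int <- max(edges)
  e2 <- edges
  sel <- e2 > n_leaves
  e2[sel] <- n_leaves + 1L + (max_int - e2[sel])
  tr <- list(edge = matrix(as.integer(e2), ncol = 2),
             edge.length = as.numeric(elens),
             tip.label = labels, Nnode = max_int - n_leaves)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Write a tree as Newick text
#'
#' @param tree A `phylo` tree.
#' @param path Optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' @param x Newick string or path to a file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' Patristic (path-length) distances of a tree
#'
#' @param tree A `phylo` tree.
#' @return Symmetric matrix of leaf-to-leaf path lengths.
#' @export
tree_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
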