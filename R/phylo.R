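#' Pairwise difference counts over a concatenated alignment
#'
#' Counts Hamming differences between taxa. Under `complete_deletion` every
#' column containing `N` or a gap in any taxon is removed before counting (a
#' single shared site set, as used for the fixed-position concatenated
#' analyses); under `pairwise` columns are removed per pair only.
#'
#' @param aln named character vector of equal-length aligned sequences, or a
#'   character matrix (taxa x columns).
#' @param mode `"complete_deletion"` (default) or `"pairwise"`.
#' @return list with `d` (symmetric integer matrix of difference counts) and
#'   `sites_used` (scalar, or matrix for `pairwise`).
#' @export
pairwise_differences <- function(aln, mode = c("complete_deletion", "pairwise")) {
  mode <- match.arg(mode)
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa")
  ok <- !(m %in% c("N", "-", "?"))
  dim(ok) <- dim(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (mode == "complete_deletion") {
    keep <- colSums(ok) == n
    if (!any(keep)) stop("no usable sites after complete deletion")
    mm <- m[, keep, drop = FALSE]
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(mm[i, ] != mm[j, ])
    }
    return(list(d = d, sites_used = sum(keep)))
  }
  su <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use)) stop("no usable sites for pair ", rownames(m)[i], "/",
                        rownames(m)[j])
    d[i, j] <- d[j, i] <- sum(m[i, use] != m[j, use])
    su[i, j] <- su[j, i] <- sum(use)
  }
  list(d = d, sites_used = su)
}

as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) stop("aligned sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln) %||% paste0("t", seq_along(aln))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration (Saitou-Nei as reformulated by Studier
#' and Keppler). Negative intermediate branch lengths are clamped to zero with
#' the deficit shifted to the sister edge, so total path lengths are
#' preserved. Consistent: an additive matrix returns its generating tree
#' exactly.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#'   (a `dist` or a matrix), in any units (difference counts work).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (any(abs(d - t(d)) > 1e-9) || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # node bookkeeping: tips 1..n, internal nodes numbered from n+1
  active <- seq_len(n)          # indices into D
  node_id <- seq_len(n)         # phylo node id per active row
  D <- d
  next_internal <- 2L * n - 2L  # phylo internal ids count down as we build
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  internal_counter <- n + 1L
  # we will assign internal ids in creation order then let ape reorder
  while (length(active) > 2) {
    k <- length(active)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]  # deterministic tie-break
    i <- min(ij); j <- max(ij)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    # clamp negatives, shifting the deficit to the sister edge
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- internal_counter; internal_counter <- internal_counter + 1L
    edges <- rbind(edges, c(u, node_id[i]), c(u, node_id[j]))
    lens <- c(lens, li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    node_id <- c(node_id[keep], u)
    active <- seq_len(length(node_id))
  }
  # join the last two nodes with a single edge
  li <- max(D[1, 2], 0)
  if (node_id[1] > n && node_id[2] > n) {
    # connect two internal nodes directly
    edges <- rbind(edges, c(node_id[1], node_id[2]))
    lens <- c(lens, li)
  } else {
    # at least one tip: attach tip under the other node
    tip <- if (node_id[1] <= n) 1L else 2L
    other <- 3L - tip
    edges <- rbind(edges, c(node_id[other], node_id[tip]))
    lens <- c(lens, li)
  }
  nnode <- internal_counter - 1L - n
  # renumber internal nodes to ape's convention: the root is n+1
  root_old <- setdiff(edges[, 1], edges[, 2])
  stopifnot(length(root_old) == 1L)
  others <- setdiff(seq(n + 1L, internal_counter - 1L), root_old)
  map <- integer(internal_counter - 1L)
  map[seq_len(n)] <- seq_len(n)
  map[root_old] <- n + 1L
  if (length(others)) map[others] <- n + 1L + seq_along(others)
  edges[] <- map[edges]
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = as.integer(max(nnode, 1L)))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Bootstrap supports for the neighbor-joining tree of an alignment
#'
#' Columns are resampled with replacement `reps` times; a neighbor-joining
#' tree is built per replicate from difference counts, and the support of
#' each internal edge of the full-alignment tree is the fraction of
#' replicates containing that bipartition.
#'
#' @param aln as in [pairwise_differences()].
#' @param reps bootstrap replicates (default 500).
#' @param seed integer seed (resampling is deterministic given the seed).
#' @param mode site-filter mode passed to [pairwise_differences()].
#' @return list with `tree` (the full-data tree, `node.label` holding
#'   support), `support` (per internal node, in `[0, 1]`; NA for the root
#'   node of the unrooted representation), `reps`.
#' @export
bootstrap_support <- function(aln, reps = 500, seed = 1,
                              mode = "complete_deletion") {
  m <- as_aln_matrix(aln)
  pd <- pairwise_differences(m, mode)
  full <- nj_tree(pd$d)
  if (all(pd$d == 0)) {
    full$node.label <- rep(NA, full$Nnode)
    return(list(tree = full, support = rep(NA_real_, full$Nnode),
                reps = as.integer(reps),
                note = "identical sequences: no resolved splits"))
  }
  set.seed(seed)
  nc <- ncol(m)
  btrees <- vector("list", reps)
  for (b in seq_len(reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    db <- pairwise_differences(m[, cols, drop = FALSE], mode)$d
    btrees[[b]] <- nj_tree(db)
  }
  class(btrees) <- "multiPhylo"
  counts <- ape::prop.clades(full, btrees, rooted = FALSE)
  support <- counts / reps
  full$node.label <- support
  list(tree = full, support = support, reps = as.integer(reps))
}
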