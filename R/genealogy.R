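# Distance-based genealogy inference: partial-deletion masking, pairwise
# Jukes-Cantor distances, Saitou-Nei neighbor joining with deterministic
# tie-breaking, nonparametric bootstrap supports, outgroup rooting and the
# concordance verdict between the molecular genealogy and the cytological
# phylogeny.

#' Partial-deletion column mask
#'
#' Keeps the columns whose fraction of unambiguous bases (A/C/G/T) is at
#' least `coverage` (the classic "95% site coverage" filter).
#'
#' @param aln A [labeled_alignment()] or character matrix.
#' @param coverage Required coverage in `(0, 1]`; default 0.95.
#' @return Logical vector over columns.
#' @export
partial_deletion_mask <- function(aln, coverage = 0.95) {
  if (!(is.numeric(coverage) && length(coverage) == 1L &&
        coverage > 0 && coverage <= 1)) {
    stop("coverage must lie in (0, 1]")
  }
  M <- seq_matrix(aln)
  if (ncol(M) == 0L) stop("empty alignment")
  colMeans(matrix(M %in% VALID_BASES, nrow = nrow(M))) >= coverage
}

#' Pairwise Jukes-Cantor distance matrix
#'
#' Raw p-distances on the masked columns, compared pairwise-complete (each
#' pair over the columns where both sequences are unambiguous), then
#' corrected with [jc_correct()].
#'
#' @param aln A [labeled_alignment()] or character matrix.
#' @param mask Logical column mask (default: all columns).
#' @return Symmetric matrix with zero diagonal, dimnames = sample names.
#'   Errors (naming the pair) for saturated pairs (`p >= 0.75`) or pairs
#'   with no comparable sites.
#' @export
jc_distance_matrix <- function(aln, mask = NULL) {
  M <- seq_matrix(aln)
  if (is.null(mask)) mask <- rep(TRUE, ncol(M))
  M <- M[, mask, drop = FALSE]
  n <- nrow(M)
  if (n < 2L) stop("at least two sequences are required")
  V <- matrix(M %in% VALID_BASES, nrow = n)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    ok <- V[i, ] & V[j, ]
    m <- sum(ok)
    if (m == 0L) stop("no comparable sites between ", rownames(M)[i], " and ", rownames(M)[j])
    p <- sum(M[i, ok] != M[j, ok]) / m
    if (p >= 0.75) {
      stop("saturated pair (p = ", round(p, 3), "): ", rownames(M)[i], " / ", rownames(M)[j])
    }
    D[i, j] <- D[j, i] <- jc_correct(p)
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Exact ties in Q
#' are broken by the lexicographically smallest pair of cluster labels
#' (each cluster labelled by its smallest member), so the output is
#' deterministic.  Negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' nj_tree(d)
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least three taxa")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  D <- unname(dm)
  nwk <- labels          # newick substring per active node
  rep_lab <- labels      # representative (smallest) member label per node
  clamped <- FALSE
  fmt <- function(x) sprintf("%.12g", x)

  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    u <- pick[1]; v <- pick[2]
    du <- D[u, v] / 2 + (r[u] - r[v]) / (2 * (m - 2))
    dv <- D[u, v] - du
    if (du < 0 || dv < 0) { clamped <- TRUE; du <- max(du, 0); dv <- max(dv, 0) }
    newd <- (D[u, ] + D[v, ] - D[u, v]) / 2
    new_nwk <- paste0("(", nwk[u], ":", fmt(du), ",", nwk[v], ":", fmt(dv), ")")
    new_rep <- min(rep_lab[u], rep_lab[v])
    keep <- setdiff(seq_len(m), c(u, v))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (any(c(la, lb, lc) < 0)) { clamped <- TRUE; la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  text <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb), ",",
                 nwk[3], ":", fmt(lc), ");")
  if (clamped) warning("negative branch length(s) clamped to zero", call. = FALSE)
  ape::read.tree(text = text)
}

# tip-label sets for every node (tips and internals), by postorder sweep
clade_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  eo <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# normalized bipartition keys for the internal (non-basal) nodes
bipartition_keys <- function(phy) {
  ntip <- length(phy$tip.label)
  all_tips <- sort(phy$tip.label)
  anchor <- all_tips[1]
  sets <- clade_tip_sets(phy)
  root <- ntip + 1L
  nodes <- setdiff(seq(ntip + 1L, ntip + phy$Nnode), root)
  keys <- vapply(nodes, function(v) {
    s <- sort(sets[[v]])
    if (anchor %in% s) s <- setdiff(all_tips, s)
    if (length(s) < 2L || length(s) > ntip - 2L) return(NA_character_)
    paste(s, collapse = "|")
  }, character(1))
  names(keys) <- nodes
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data NJ tree on the masked columns, then resamples
#' masked columns with replacement `n` times, rebuilds the tree, and scores
#' each internal bipartition of the full-data tree by the percentage of
#' replicates recovering it.  Within replicates, saturated resampled pairs
#' are capped at `p = 0.7499` rather than raising an error.
#'
#' @param aln A [labeled_alignment()] or character matrix.
#' @param mask Logical column mask (default all columns); fixed across
#'   replicates.
#' @param n Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return The full-data unrooted `phylo` with `node.label` set to integer
#'   support percentages (the basal node is blank).
#' @export
bootstrap_support <- function(aln, mask = NULL, n = 1000, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  M <- seq_matrix(aln)
  if (is.null(mask)) mask <- rep(TRUE, ncol(M))
  M <- M[, mask, drop = FALSE]
  base <- suppressWarnings(nj_tree(jc_distance_matrix(M)))
  nseq <- nrow(M); ncols <- ncol(M)
  pair_idx <- utils::combn(nseq, 2)
  npair <- ncol(pair_idx)
  V <- matrix(M %in% VALID_BASES, nrow = nseq)
  diffM <- matrix(FALSE, npair, ncols)
  validM <- matrix(FALSE, npair, ncols)
  for (k in seq_len(npair)) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    validM[k, ] <- V[i, ] & V[j, ]
    diffM[k, ] <- validM[k, ] & (M[i, ] != M[j, ])
  }
  base_keys <- bipartition_keys(base)
  counts <- stats::setNames(rep(0L, length(base_keys)), base_keys)
  if (!is.null(seed)) set.seed(seed)
  for (b in seq_len(n)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    nd <- rowSums(diffM[, cols, drop = FALSE])
    nv <- rowSums(validM[, cols, drop = FALSE])
    p <- ifelse(nv > 0, nd / pmax(nv, 1L), 0.7499)
    p <- pmin(p, 0.7499)
    d <- jc_correct(p)
    Db <- matrix(0, nseq, nseq, dimnames = list(rownames(M), rownames(M)))
    Db[t(pair_idx)] <- d
    Db <- Db + t(Db)
    rep_tree <- suppressWarnings(nj_tree(Db))
    rk <- bipartition_keys(rep_tree)
    hit <- base_keys[!is.na(base_keys)] %in% rk
    counts[!is.na(base_keys)][hit] <- counts[!is.na(base_keys)][hit] + 1L
  }
  support <- round(100 * counts / n)
  node.label <- rep("", base$Nnode)
  ntip <- length(base$tip.label)
  node.label[as.integer(names(base_keys)) - ntip] <-
    ifelse(is.na(base_keys), "", as.character(support))
  base$node.label <- node.label
  base
}

#' Root a tree on its outgroup edge
#'
#' @param tree An `ape::phylo`.
#' @param label Tip label(s) of the outgroup.
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, label) {
  miss <- setdiff(label, tree$tip.label)
  if (length(miss)) stop("outgroup tip(s) not in tree: ", paste(miss, collapse = ", "))
  ape::root(tree, outgroup = label, resolve.root = TRUE)
}

#' Concordance verdict between molecular genealogy and cytological phylogeny
#'
#' Finds the smallest clade containing every AK and AH2 leaf (the two
#' youngest arrangements) on the rooted ingroup tree.  If those leaves are
#' not monophyletic the verdict is `"unresolved"`.  Otherwise the clade's
#' sister is inspected: AB leaves and no AG leaves gives `"discordant"`
#' (the molecular genealogy contradicts the sequential cytology, the
#' heterokaryotype-origin signature); AG leaves and no AB leaves gives
#' `"concordant"`; anything else `"unresolved"`.  GAL leaves are excluded
#' from the test (their predicted affinity is to AG under every model) and
#' outgroup leaves are used for rooting, then dropped.
#'
#' @param tree A `phylo`; if unrooted it is rooted on the outgroup leaf
#'   (required in that case).
#' @param regions Named character vector mapping tip labels to region names
#'   (`NA` or `"outgroup"` marks outgroup tips).  Default: parsed from tip
#'   labels of the form `sample_<region>_<arrangement>_<idx>`.
#' @return One of `"discordant"`, `"concordant"`, `"unresolved"`.
#' @export
#' @examples
#' t <- ape::read.tree(text = "(((sample_AK_x_1:1,sample_AH2_x_1:1):1,sample_AB_x_1:1):1,(sample_AG_x_1:1,sample_GAL_x_1:1):1);")
#' concordance_verdict(t)
concordance_verdict <- function(tree, regions = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(regions)) {
    lab <- parse_sample_labels(tree$tip.label)
    regions <- stats::setNames(ifelse(lab$outgroup, "outgroup", lab$region), lab$sample)
  } else {
    regions <- regions[tree$tip.label]
  }
  regions[is.na(regions)] <- "outgroup"
  og <- names(regions)[regions == "outgroup"]
  if (!ape::is.rooted(tree)) {
    if (length(og) == 0L) stop("an unrooted tree needs an outgroup leaf for the verdict")
    tree <- root_with_outgroup(tree, og)
  }
  drop <- c(og, names(regions)[regions == "GAL"])
  if (length(drop)) {
    if (length(setdiff(tree$tip.label, drop)) < 2L) stop("too few ingroup leaves")
    tree <- ape::drop.tip(tree, drop)
  }
  regions <- regions[tree$tip.label]
  need <- c("AB", "AG", "AK", "AH2")
  miss <- setdiff(need, unique(regions))
  if (length(miss)) stop("missing region(s) on the tree: ", paste(miss, collapse = ", "))

  focal <- names(regions)[regions %in% c("AK", "AH2")]
  ntip <- length(tree$tip.label)
  sets <- clade_tip_sets(tree)
  node <- if (length(focal) == 1L) {
    match(focal, tree$tip.label)
  } else {
    ape::getMRCA(tree, focal)
  }
  if (!setequal(sets[[node]], focal)) return("unresolved")
  root <- ntip + 1L
  if (node == root) return("unresolved")
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  sibs <- tree$edge[tree$edge[, 1] == parent & tree$edge[, 2] != node, 2]
  sister_tips <- unlist(sets[sibs], use.names = FALSE)
  sr <- regions[sister_tips]
  if (any(sr == "AB") && !any(sr == "AG")) return("discordant")
  if (any(sr == "AG") && !any(sr == "AB")) return("concordant")
  "unresolved"
}
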