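# Synthetic-data generator: breakpoint-flanking alignments simulated under a
# chosen origin model's lineage history.
#
# Each arrangement's samples form a neutral Kingman coalescent tree grafted
# at the arrangement's single-haplotype origin (the inversion bottleneck);
# founder lineages attach to their source lineage exactly at the origin-event
# times (a clean-split genealogy: no incomplete lineage sorting).  Mutations
# are Poisson on branches with Jukes-Cantor substitution.

SIM_REGIONS <- c("AB", "AG", "GAL", "AK", "AH2")

# arrangement codes used in sample names (underscore-free so that headers
# sample_<region>_<arrangement>_<idx> split cleanly on "_")
REGION_ARRANGEMENTS <- list(
  AB = "Est",
  AG = "E1+2",
  GAL = c("E1+2+9", "E1+2+9+3", "E1+2+9+12"),
  AK = c("E1+2+9", "E1+2+9+12"),
  AH2 = "E1+2+9+3"
)

#' Simulation parameters
#'
#' Defaults emulate the study conditions: five region classes with sample
#' sizes 18/6/10/11/5, ~2-kb sequences, an outgroup at Jukes-Cantor
#' divergence ~0.09, and per-region nucleotide diversity in the
#' 0.006--0.015 range.  Times are in arbitrary coalescent-style units;
#' only products `time x mu` are observable.
#'
#' @param seq_length Sites per sequence (default 2000).
#' @param mu Substitution rate per site per time unit (default 0.015).
#' @param origin_times Named vector of event times (before present):
#'   `outgroup` split, `E_1+2`, `E_9`, `E_3` and `E_12` origins; must
#'   satisfy `outgroup > E_1+2 > E_9 > E_3 > 0` and `E_12 < E_9`.
#' @param sample_sizes Named vector of per-region sample counts
#'   (`AB`, `AG`, `GAL`, `AK`, `AH2`).
#' @param model Origin model name (see [predict_clade_constraints()]);
#'   heterokaryotype models route the AK/AH2 A-window ancestor through the
#'   standard lineage, single-chromosome models through the doubly inverted
#'   one.
#' @param Ne Within-arrangement coalescent time scale (single knob, equal
#'   across arrangements; default 0.25).
#' @param gene_conversion_rate Expected conversion-tract events per lineage
#'   per time unit (default 0 = off).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Object of class `"sim_params"` (a validated list).
#' @export
sim_params <- function(seq_length = 2000,
                       mu = 0.015,
                       origin_times = c(outgroup = 3, "E_1+2" = 2, E_9 = 1.2,
                                        E_3 = 0.6, E_12 = 0.4),
                       sample_sizes = c(AB = 18, AG = 6, GAL = 10, AK = 11, AH2 = 5),
                       model = "nhej3",
                       Ne = 0.25,
                       gene_conversion_rate = 0,
                       seed = NULL) {
  stopifnot(seq_length >= 1, mu >= 0, Ne > 0, gene_conversion_rate >= 0)
  need <- c("outgroup", "E_1+2", "E_9", "E_3")
  if (!all(need %in% names(origin_times))) {
    stop("origin_times must name: ", paste(need, collapse = ", "))
  }
  t <- origin_times
  if (!(t[["outgroup"]] > t[["E_1+2"]] && t[["E_1+2"]] > t[["E_9"]] &&
        t[["E_9"]] > t[["E_3"]] && t[["E_3"]] > 0)) {
    stop("origin times must be strictly ordered: outgroup > E_1+2 > E_9 > E_3 > 0")
  }
  if ("E_12" %in% names(t) && !(t[["E_12"]] < t[["E_9"]] && t[["E_12"]] > 0)) {
    stop("the E_12 origin must postdate E_9 (0 < E_12 < E_9)")
  }
  if (!(is.character(model) && length(model) == 1L && model %in% ORIGIN_MODELS)) {
    stop("unknown origin model: ", paste(model, collapse = ", "))
  }
  miss <- setdiff(SIM_REGIONS, names(sample_sizes))
  if (length(miss)) stop("sample_sizes must name region(s): ", paste(miss, collapse = ", "))
  if (any(sample_sizes < 0)) stop("sample sizes must be >= 0")
  structure(list(seq_length = as.integer(seq_length), mu = mu,
                 origin_times = t, sample_sizes = sample_sizes[SIM_REGIONS],
                 model = model, Ne = Ne,
                 gene_conversion_rate = gene_conversion_rate, seed = seed),
            class = "sim_params")
}

#' Lineage history implied by an origin model
#'
#' Builds the event graph joining the sampled region pools: the outgroup
#' split, the origin bottleneck of the doubly inverted arrangement, the
#' third-inversion origin (where the AK/AH2 ancestor attaches -- to the
#' standard lineage under heterokaryotype models, to the doubly inverted
#' lineage under single-chromosome models, while the GAL copy always
#' attaches to the doubly inverted lineage) and the fourth-inversion
#' bottleneck separating AH2 from AK.
#'
#' @param model Origin model name.
#' @param params A [sim_params()] object (its `origin_times` are used).
#' @return Object of class `"history_graph"`: list with `nodes` (data frame
#'   `node`, `time`, `parent`, `region`), `attachments` (named vector giving
#'   the source lineage of the AK/AH2 and GAL founders) and `model`.
#' @export
build_history <- function(model, params) {
  stopifnot(inherits(params, "sim_params"))
  if (!(is.character(model) && length(model) == 1L && model %in% ORIGIN_MODELS)) {
    stop("unknown origin model: ", paste(model, collapse = ", "))
  }
  t <- params$origin_times
  het <- model %in% HETEROKARYOTYPE_MODELS
  n <- function(node, time, parent, region = NA_character_) {
    data.frame(node = node, time = time, parent = parent, region = region,
               stringsAsFactors = FALSE)
  }
  if (het) {
    nodes <- rbind(
      n("root", t[["outgroup"]], NA_character_),
      n("outgroup", 0, "root", "outgroup"),
      n("split_E12", t[["E_1+2"]], "root"),
      n("capture_E9", t[["E_9"]], "split_E12"),   # on the standard lineage
      n("AB", 0, "capture_E9", "AB"),
      n("split_E3", t[["E_3"]], "capture_E9"),
      n("AK", 0, "split_E3", "AK"),
      n("AH2", 0, "split_E3", "AH2"),
      n("dup_E9", t[["E_9"]], "split_E12"),       # on the doubly inverted lineage
      n("AG", 0, "dup_E9", "AG"),
      n("GAL", 0, "dup_E9", "GAL")
    )
    attachments <- c(AKAH2 = "E_st", GAL = "E_1+2")
  } else {
    delta <- 0.1 * (t[["E_1+2"]] - t[["E_9"]])
    nodes <- rbind(
      n("root", t[["outgroup"]], NA_character_),
      n("outgroup", 0, "root", "outgroup"),
      n("split_E12", t[["E_1+2"]], "root"),
      n("AB", 0, "split_E12", "AB"),
      n("coal_E12", t[["E_9"]] + delta, "split_E12"),  # inverted founder joins AG lineage
      n("AG", 0, "coal_E12", "AG"),
      n("origin_E9", t[["E_9"]], "coal_E12"),
      n("GAL", 0, "origin_E9", "GAL"),
      n("split_E3", t[["E_3"]], "origin_E9"),
      n("AK", 0, "split_E3", "AK"),
      n("AH2", 0, "split_E3", "AH2")
    )
    attachments <- c(AKAH2 = "E_1+2", GAL = "E_1+2")
  }
  # acyclicity / time monotonicity along descent
  pt <- nodes$time[match(nodes$parent, nodes$node)]
  stopifnot(all(is.na(pt) | pt >= nodes$time))
  structure(list(nodes = nodes, attachments = attachments, model = model),
            class = "history_graph")
}

#' @export
print.history_graph <- function(x, ...) {
  cat("Lineage history for model", x$model, "\n")
  cat("  AK/AH2 A-window founder attaches to the", x$attachments[["AKAH2"]], "lineage\n")
  cat("  GAL founder attaches to the", x$attachments[["GAL"]], "lineage\n")
  invisible(x)
}

# Standard Kingman coalescent for one region pool.  Returns a nested node
# list (leaf: label/time; internal: children/time).  The TMRCA is rescaled
# into 0.9 x the stem to the pool's origin if the draw exceeds it, keeping
# the single-haplotype bottleneck at the origin.
pool_coalescent <- function(labels, t_origin, Ne) {
  n <- length(labels)
  active <- lapply(labels, function(l) list(label = l, time = 0))
  if (n == 1L) return(active[[1]])
  t <- 0
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + rexp(1, rate = k * (k - 1) / 2 / Ne)
    pick <- sample.int(k, 2L)
    merged <- list(children = active[pick], time = t)
    active <- c(active[-pick], list(merged))
  }
  root <- active[[1]]
  if (root$time > 0.9 * t_origin) {
    root <- scale_times(root, 0.9 * t_origin / root$time)
  }
  root
}

scale_times <- function(node, f) {
  node$time <- node$time * f
  if (!is.null(node$children)) node$children <- lapply(node$children, scale_times, f = f)
  node
}

node_newick <- function(node) {
  if (is.null(node$children)) return(node$label)
  parts <- vapply(node$children, function(ch) {
    paste0(node_newick(ch), ":", sprintf("%.10f", node$time - ch$time))
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Simulate a labelled breakpoint-flanking alignment
#'
#' Draws the full genealogy (per-region coalescent trees grafted on the
#' [build_history()] backbone), evolves sequences down it with Poisson
#' mutation counts per branch and Jukes-Cantor substitution, and optionally
#' applies gene-conversion tract copies between sequences of different
#' regions.  Reproducible given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `"sim_dataset"`: list with `alignment` (a
#'   [labeled_alignment()] of all samples plus one outgroup sequence),
#'   `tree` (the true genealogy as an `ape::phylo` with branch lengths in
#'   time units), `history` (the [build_history()] graph) and `params`.
#' @export
#' @examples
#' ds <- simulate_alignment(sim_params(seq_length = 300, seed = 1))
#' ds$alignment
simulate_alignment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  history <- build_history(params$model, params)
  t <- params$origin_times
  sizes <- params$sample_sizes

  tip_labels <- list()
  for (r in SIM_REGIONS) {
    nr <- sizes[[r]]
    if (nr == 0) { tip_labels[[r]] <- character(0); next }
    arrs <- rep_len(REGION_ARRANGEMENTS[[r]], nr)
    tip_labels[[r]] <- paste("sample", r, arrs, seq_len(nr), sep = "_")
  }

  nodes <- history$nodes
  children_of <- split(nodes$node, factor(nodes$parent, levels = nodes$node))
  build_node <- function(id) {
    row <- nodes[nodes$node == id, ]
    if (!is.na(row$region)) {
      if (row$region == "outgroup") return(list(label = "outgroup", time = 0))
      labs <- tip_labels[[row$region]]
      if (length(labs) == 0L) return(NULL)
      origin <- nodes$time[nodes$node == row$parent]
      return(pool_coalescent(labs, origin, params$Ne))
    }
    kids <- Filter(Negate(is.null), lapply(children_of[[id]], build_node))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    list(children = kids, time = row$time)
  }
  root <- build_node("root")
  phy <- ape::read.tree(text = paste0(node_newick(root), ";"))

  L <- params$seq_length
  mu <- params$mu
  phy2 <- stats::reorder(phy, "cladewise")
  ntip <- length(phy2$tip.label)
  nnode <- phy2$Nnode
  seqs <- matrix(0L, nrow = ntip + nnode, ncol = L)
  seqs[ntip + 1L, ] <- sample.int(4L, L, replace = TRUE)
  for (e in seq_len(nrow(phy2$edge))) {
    par <- phy2$edge[e, 1]; chd <- phy2$edge[e, 2]
    x <- seqs[par, ]
    nmut <- rpois(1, phy2$edge.length[e] * mu * L)
    if (nmut > 0) {
      pos <- sample.int(L, nmut, replace = TRUE)
      x[pos] <- ((x[pos] - 1L + sample.int(3L, nmut, replace = TRUE)) %% 4L) + 1L
    }
    seqs[chd, ] <- x
  }
  bases <- c("A", "C", "G", "T")
  mat <- matrix(bases[seqs[seq_len(ntip), ]], nrow = ntip)
  rownames(mat) <- phy2$tip.label

  order_names <- c(unlist(tip_labels, use.names = FALSE), "outgroup")
  mat <- mat[order_names, , drop = FALSE]

  if (params$gene_conversion_rate > 0) {
    mat <- apply_gene_conversion(mat, tip_labels, t, params$gene_conversion_rate)
  }

  structure(list(alignment = labeled_alignment(mat), tree = phy,
                 history = history, params = params),
            class = "sim_dataset")
}

# Post-hoc gene conversion: each sample receives a Poisson number of tract
# copies (rate x age of its arrangement) from a random sequence of another
# region; a simplification of conversion along lineages.
apply_gene_conversion <- function(mat, tip_labels, times, rate) {
  L <- ncol(mat)
  pool_age <- c(AB = times[["outgroup"]], AG = times[["E_1+2"]],
                GAL = times[["E_9"]], AK = times[["E_9"]], AH2 = times[["E_3"]])
  for (r in names(tip_labels)) {
    donors_all <- unlist(tip_labels[setdiff(names(tip_labels), r)], use.names = FALSE)
    if (length(donors_all) == 0L) next
    for (s in tip_labels[[r]]) {
      nev <- rpois(1, rate * pool_age[[r]])
      for (i in seq_len(nev)) {
        donor <- sample(donors_all, 1L)
        len <- sample(100:500, 1L)
        len <- min(len, L)
        start <- sample.int(L - len + 1L, 1L)
        idx <- start:(start + len - 1L)
        mat[s, idx] <- mat[donor, idx]
      }
    }
  }
  mat
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset (model:", x$params$model, ", seed:",
      if (is.null(x$params$seed)) "none" else x$params$seed, ")\n")
  print(x$alignment)
  invisible(x)
}
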