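# Polymorphism, divergence and differentiation statistics, implemented from
# first principles: nucleotide diversity, segregating sites, singleton and
# multiple-hit sites, haplotype counts, Jukes-Cantor corrected divergence,
# and Hudson-style F_ST (1 - pi_within/pi_between) with a label-permutation
# test.

VALID_BASES <- c("A", "C", "G", "T")

seq_matrix <- function(x) {
  if (inherits(x, "labeled_alignment")) return(x$seqs)
  if (inherits(x, "sim_dataset")) return(x$alignment$seqs)
  stopifnot(is.matrix(x))
  x
}

#' Complete-deletion column mask
#'
#' Keeps exactly the columns with no gap or ambiguous base in any of the
#' given sequences.
#'
#' @param aln A [labeled_alignment()] or character matrix.
#' @return Logical vector over columns (`TRUE` = keep).  Warns when every
#'   column is removed.
#' @export
complete_deletion <- function(aln) {
  M <- seq_matrix(aln)
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty alignment")
  mask <- colSums(!matrix(M %in% VALID_BASES, nrow = nrow(M))) == 0L
  if (!any(mask)) warning("complete deletion removed every column", call. = FALSE)
  mask
}

# n x n matrix of per-site difference proportions.  complete: one shared
# mask; pairwise: each pair compared over its own unambiguous columns.
diff_prop_matrix <- function(M, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  if (deletion == "complete") {
    mask <- suppressWarnings(complete_deletion(M))
    m <- sum(mask)
    if (m == 0L) stop("no sites left after complete deletion")
    Mc <- M[, mask, drop = FALSE]
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      D[i, j] <- D[j, i] <- sum(Mc[i, ] != Mc[j, ]) / m
    }
  } else {
    V <- matrix(M %in% VALID_BASES, nrow = n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      ok <- V[i, ] & V[j, ]
      m <- sum(ok)
      if (m == 0L) stop("no comparable sites between ", rownames(M)[i], " and ", rownames(M)[j])
      D[i, j] <- D[j, i] <- sum(M[i, ok] != M[j, ok]) / m
    }
  }
  D
}

mean_upper <- function(D, idx) {
  if (length(idx) < 2L) return(NA_real_)
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Jukes-Cantor distance correction
#'
#' `K = -(3/4) log(1 - 4p/3)` for a raw proportion of differing sites `p`.
#'
#' @param p Numeric vector of raw difference proportions, `0 <= p < 0.75`.
#' @return Corrected distance(s).
#' @export
#' @examples
#' jc_correct(0.09)
jc_correct <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 0.75)) stop("p >= 0.75: Jukes-Cantor correction saturates")
  -0.75 * log(1 - 4 * p / 3)
}

resolve_group <- function(aln, g) {
  if (is.character(g) && length(g) == 1L && g %in% aln$labels$region) {
    return(region_samples(aln, g))
  }
  miss <- setdiff(g, aln$labels$sample)
  if (length(miss)) stop("unknown sample(s) or region: ", paste(miss, collapse = ", "))
  g
}

#' Summarise polymorphism and divergence for a set of sequences
#'
#' Computes, over the complete-deletion columns of the selected ingroup
#' sequences: segregating sites `S`, singleton sites (sites whose minor
#' variant occurs in exactly one sequence), multiple-hit sites (more than
#' two observed states), nucleotide diversity `pi` (mean pairwise
#' differences per site), and the haplotype count `h`.  Divergence `K` is
#' the mean Jukes-Cantor corrected distance from each ingroup sequence to
#' the outgroup, over columns additionally clean in the outgroup.
#'
#' @param aln A [labeled_alignment()].
#' @param group Region name or character vector of sample names; default all
#'   ingroup sequences.
#' @param outgroup Outgroup sample name(s); default the alignment's flagged
#'   outgroup.  `K` is `NA` when absent.
#' @param deletion `"complete"` (default) or `"pairwise"`; with pairwise
#'   deletion `pi` and `K` are computed per pair over each pair's
#'   unambiguous columns, while per-site counts use sites with at least two
#'   unambiguous states.
#' @return Object of class `"polymorphism_summary"`.
#' @export
summarize_polymorphism <- function(aln, group = NULL, outgroup = NULL,
                                   deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "labeled_alignment"))
  samples <- if (is.null(group)) ingroup_samples(aln) else resolve_group(aln, group)
  if (length(samples) < 2L) stop("at least two ingroup sequences are required")
  if (is.null(outgroup)) outgroup <- outgroup_samples(aln)
  M <- aln$seqs[samples, , drop = FALSE]

  if (deletion == "complete") {
    mask <- complete_deletion(M)
    Mc <- M[, mask, drop = FALSE]
    m <- sum(mask)
    site_stats <- site_counts(Mc)
    pi <- if (m == 0L) NA_real_ else mean_upper(diff_count_matrix(Mc), seq_along(samples)) / m
    h <- length(unique(apply(Mc, 1, paste, collapse = "")))
  } else {
    m <- ncol(M)
    site_stats <- site_counts(M, ignore_ambiguous = TRUE)
    D <- diff_prop_matrix(M, "pairwise")
    pi <- mean_upper(D, seq_along(samples))
    mask_h <- suppressWarnings(complete_deletion(M))
    h <- length(unique(apply(M[, mask_h, drop = FALSE], 1, paste, collapse = "")))
  }

  K <- NA_real_; sites_K <- NA_integer_
  if (length(outgroup) >= 1L) {
    og <- aln$seqs[outgroup[1], , drop = TRUE]
    if (deletion == "complete") {
      maskK <- complete_deletion(rbind(M, og))
      sites_K <- sum(maskK)
      if (sites_K > 0L) {
        ogc <- og[maskK]
        pvec <- apply(M[, maskK, drop = FALSE], 1, function(s) mean(s != ogc))
        K <- mean(jc_correct(pvec))
      }
    } else {
      V <- M %in% VALID_BASES
      dim(V) <- dim(M)
      vo <- og %in% VALID_BASES
      pvec <- vapply(seq_along(samples), function(i) {
        ok <- V[i, ] & vo
        sum(M[i, ok] != og[ok]) / sum(ok)
      }, numeric(1))
      sites_K <- NA_integer_
      K <- mean(jc_correct(pvec))
    }
  }

  structure(list(group = if (is.null(group)) "all" else paste(group, collapse = "+"),
                 n = length(samples), sites_used = m,
                 S = site_stats$S, singletons = site_stats$singletons,
                 multihit = site_stats$multihit, pi = pi, h = h,
                 K = K, sites_K = sites_K, deletion = deletion),
            class = "polymorphism_summary")
}

# integer pairwise difference counts (no normalisation)
diff_count_matrix <- function(M) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq(i + 1L, n)) {
    D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
  }
  D
}

site_counts <- function(M, ignore_ambiguous = FALSE) {
  if (ncol(M) == 0L) return(list(S = 0L, singletons = 0L, multihit = 0L))
  S <- 0L; singles <- 0L; multi <- 0L
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    if (ignore_ambiguous) col <- col[col %in% VALID_BASES]
    if (length(col) < 2L) next
    tab <- table(col)
    if (length(tab) >= 2L) {
      S <- S + 1L
      if (any(tab[-which.max(tab)] == 1L)) singles <- singles + 1L
      if (length(tab) > 2L) multi <- multi + 1L
    }
  }
  list(S = S, singletons = singles, multihit = multi)
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat("Polymorphism summary (", x$group, ", ", x$deletion, " deletion)\n", sep = "")
  cat(sprintf("  n = %d, sites = %d, S = %d, singletons = %d, multi-hit = %d\n",
              x$n, x$sites_used, x$S, x$singletons, x$multihit))
  cat(sprintf("  pi = %.4f, haplotypes = %d, K(outgroup) = %s\n",
              x$pi, x$h, ifelse(is.na(x$K), "NA", sprintf("%.4f", x$K))))
  invisible(x)
}

#' Per-region polymorphism table
#'
#' Applies [summarize_polymorphism()] to each region and to all ingroup
#' sequences jointly.
#'
#' @param aln A [labeled_alignment()].
#' @param deletion Passed to [summarize_polymorphism()].
#' @return Data frame (class `"polymorphism_table"`), one row per region
#'   plus `"Overall"`.
#' @export
polymorphism_table <- function(aln, deletion = "complete") {
  regions <- intersect(SIM_REGIONS, unique(aln$labels$region[!aln$labels$outgroup]))
  if (length(regions) == 0L) regions <- unique(aln$labels$region[!aln$labels$outgroup])
  groups <- c(as.list(regions), list(NULL))
  rows <- lapply(groups, function(g) {
    s <- summarize_polymorphism(aln, group = g, deletion = deletion)
    data.frame(region = if (is.null(g)) "Overall" else g, n = s$n,
               sites = s$sites_used, S = s$S, singletons = s$singletons,
               multihit = s$multihit, pi = s$pi, h = s$h, K = s$K,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("polymorphism_table", class(out))
  out
}

#' @export
print.polymorphism_table <- function(x, digits = 4, ...) {
  cat("Nucleotide polymorphism and divergence by breakpoint region\n")
  y <- x
  class(y) <- "data.frame"
  y$pi <- round(y$pi, digits); y$K <- round(y$K, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Hudson-style F_ST between two groups
#'
#' `F_ST = 1 - pi_within / pi_between`, with `pi_within` the unweighted
#' mean of the two within-group diversities and `pi_between` the mean
#' pairwise diversity across groups.
#'
#' @param aln A [labeled_alignment()].
#' @param group_a,group_b Region names or character vectors of sample names;
#'   at least two sequences each.
#' @param deletion `"complete"` (default, one mask over both groups) or
#'   `"pairwise"`.
#' @return F_ST (numeric scalar).  Errors when `pi_between` is zero (no
#'   variation to apportion).
#' @export
fst_hudson <- function(aln, group_a, group_b, deletion = "complete") {
  ga <- resolve_group(aln, group_a)
  gb <- resolve_group(aln, group_b)
  if (length(ga) < 2L || length(gb) < 2L) stop("each group needs at least two sequences")
  if (length(intersect(ga, gb))) stop("groups overlap")
  M <- aln$seqs[c(ga, gb), , drop = FALSE]
  D <- diff_prop_matrix(M, deletion)
  fst_from_D(D, seq_along(ga), length(ga) + seq_along(gb))
}

fst_from_D <- function(D, ia, ib) {
  piw <- mean(c(mean_upper(D, ia), mean_upper(D, ib)))
  pib <- mean(D[ia, ib])
  if (pib == 0) stop("pi_between is zero: F_ST undefined for identical groups")
  1 - piw / pib
}

#' Permutation test for F_ST
#'
#' Shuffles group labels over the pooled sequences `n_perm` times without
#' replacement and reports the fraction of permuted F_ST values at least as
#' large as the observed one (no +1 correction, so a value never reached
#' reports `p = 0`).
#'
#' @inheritParams fst_hudson
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed for reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @return Object of class `"fst_result"`: list with `fst`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
fst_permutation_p <- function(aln, group_a, group_b, n_perm = 10000,
                              seed = NULL, deletion = "complete") {
  if (n_perm <= 0) stop("n_perm must be positive")
  ga <- resolve_group(aln, group_a)
  gb <- resolve_group(aln, group_b)
  if (length(ga) < 2L || length(gb) < 2L) stop("each group needs at least two sequences")
  M <- aln$seqs[c(ga, gb), , drop = FALSE]
  D <- diff_prop_matrix(M, deletion)
  na <- length(ga); ntot <- na + length(gb)
  obs <- fst_from_D(D, seq_len(na), seq(na + 1L, ntot))
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    idx <- sample.int(ntot)
    f <- tryCatch(fst_from_D(D, idx[seq_len(na)], idx[seq(na + 1L, ntot)]),
                  error = function(e) NA_real_)
    if (!is.na(f) && f >= obs - 1e-12) hits <- hits + 1L
  }
  structure(list(fst = obs, p_value = hits / n_perm, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST = %.5f, permutation P = %.4f (%d permutations)\n",
              x$fst, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise F_ST matrix with permutation P-values
#'
#' Applies [fst_hudson()] and [fst_permutation_p()] to every pair of region
#' groups.
#'
#' @param aln A [labeled_alignment()] with region labels.
#' @param n_perm Permutations per pair (default 10000).
#' @param seed Base seed; pair `k` uses `seed + k` so results are
#'   reproducible yet independent across pairs.
#' @param deletion Passed through.
#' @return Object of class `"fst_matrix"`: list with symmetric `fst` and
#'   `p` matrices (diagonal `NA`), `n_perm`, `seed`.
#' @export
fst_matrix <- function(aln, n_perm = 10000, seed = NULL, deletion = "complete") {
  regions <- intersect(SIM_REGIONS, unique(aln$labels$region[!aln$labels$outgroup]))
  if (length(regions) == 0L) regions <- unique(aln$labels$region[!aln$labels$outgroup])
  if (length(regions) < 2L) stop("at least two region groups are required")
  k <- length(regions)
  Fm <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  Pm <- Fm
  pair_id <- 0L
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    pair_id <- pair_id + 1L
    res <- fst_permutation_p(aln, regions[i], regions[j], n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else seed + pair_id,
                             deletion = deletion)
    Fm[i, j] <- Fm[j, i] <- res$fst
    Pm[i, j] <- Pm[j, i] <- res$p_value
  }
  structure(list(fst = Fm, p = Pm, n_perm = as.integer(n_perm), seed = seed),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("Pairwise F_ST (lower triangle) and permutation P-values (upper),",
      x$n_perm, "permutations\n")
  k <- nrow(x$fst)
  out <- matrix("", k, k, dimnames = dimnames(x$fst))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i > j) out[i, j] <- sprintf("%.*f", digits, x$fst[i, j])
    if (i < j) out[i, j] <- sprintf("%.*f", digits, x$p[i, j])
    if (i == j) out[i, j] <- "-"
  }
  print(as.data.frame(out), right = TRUE)
  invisible(x)
}
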