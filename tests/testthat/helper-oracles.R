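# Independent brute-force oracles and fixture builders.  The oracles are
# deliberately naive (explicit double loops over columns and pairs) and share
# no code with the package implementation.

oracle_pi <- function(M) {
  n <- nrow(M); L <- ncol(M)
  total <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0
    for (s in 1:L) if (M[i, s] != M[j, s]) d <- d + 1
    total <- total + d / L
    pairs <- pairs + 1
  }
  total / pairs
}

oracle_site_table <- function(M) {
  S <- 0L; singles <- 0L; multi <- 0L
  for (s in 1:ncol(M)) {
    states <- table(M[, s])
    if (length(states) >= 2) {
      S <- S + 1L
      counts <- sort(as.integer(states), decreasing = TRUE)
      if (any(counts[-1] == 1L)) singles <- singles + 1L
      if (length(states) > 2) multi <- multi + 1L
    }
  }
  list(S = S, singletons = singles, multihit = multi)
}

oracle_h <- function(M) {
  length(unique(apply(M, 1, paste, collapse = "")))
}

# draw one integer from lo..hi without R's scalar-sample pitfall
draw_between <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

oracle_fst <- function(M, ia, ib) {
  pair_pi <- function(i, j) mean(M[i, ] != M[j, ])
  within <- function(idx) {
    vals <- c()
    for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1):length(idx)) {
      vals <- c(vals, pair_pi(idx[i], idx[j]))
    }
    mean(vals)
  }
  between <- c()
  for (i in ia) for (j in ib) between <- c(between, pair_pi(i, j))
  1 - mean(c(within(ia), within(ib))) / mean(between)
}

# random gap-free alignment: shared ancestor plus a few mutations per
# sequence, so pairwise p stays far from Jukes-Cantor saturation
random_alignment <- function(n, L, nmut = max(3L, L %/% 20L)) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  M <- matrix(rep(anc, each = n), nrow = n)
  for (i in 1:n) {
    pos <- sample.int(L, nmut)
    M[i, pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
  }
  rownames(M) <- paste0("s", 1:n)
  M
}

# labelled alignment from named sequence strings with explicit regions
make_aln <- function(seqs, regions, outgroup = rep(FALSE, length(seqs))) {
  labeled_alignment(seqs, labels = data.frame(
    sample = names(seqs), region = regions, arrangement = "x",
    outgroup = outgroup, stringsAsFactors = FALSE))
}

canon <- canonical_arrangements()
het_st_12 <- karyotype(canon[["E_st"]], canon[["E_1+2"]])

chromatid_break <- function(boundary) break_spec("E_1+2", boundary, "chromatid")
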