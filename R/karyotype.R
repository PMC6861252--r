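# Karyotypes: pairs of homologous arrangements.

#' Build a karyotype from two homologous arrangements
#'
#' @param homolog_1,homolog_2 [arrangement()] objects.
#' @return Object of class `"karyotype"` with fields `homolog_1`,
#'   `homolog_2` and `is_heterokaryotypic` (`TRUE` iff the homolog names
#'   differ).
#' @export
#' @examples
#' arrs <- canonical_arrangements()
#' karyotype(arrs[["E_st"]], arrs[["E_1+2"]])
karyotype <- function(homolog_1, homolog_2) {
  stopifnot(inherits(homolog_1, "arrangement"), inherits(homolog_2, "arrangement"))
  structure(
    list(homolog_1 = homolog_1, homolog_2 = homolog_2,
         is_heterokaryotypic = !identical(homolog_1$name, homolog_2$name)),
    class = "karyotype"
  )
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype ", x$homolog_1$name, "/", x$homolog_2$name,
      if (x$is_heterokaryotypic) " (heterokaryotypic)" else " (homokaryotypic)",
      "\n", sep = "")
  invisible(x)
}

#' Number of sequenced A fragments carried by a karyotype
#'
#' Sums [count_a_fragments()] over the two homologs.
#'
#' @param kt A [karyotype()].
#' @return Integer.
#' @export
karyotype_a_fragments <- function(kt) {
  stopifnot(inherits(kt, "karyotype"))
  count_a_fragments(kt$homolog_1) + count_a_fragments(kt$homolog_2)
}

#' Synthetic sample of 29 heterokaryotypic individuals
#'
#' A synthetic stand-in for the study's sampled karyotype table (which lives
#' in supplementary material and is not redistributed here).  It satisfies
#' every published constraint on that sample: 29 individuals, each
#' heterokaryotypic for a pair of the five E-chromosome arrangements, with
#' 36 chromosomes carrying a single A-fragment copy (standard or doubly
#' inverted) and 22 carrying two copies (the triple-inversion arrangement
#' and its derivatives), so that the expected number of A fragments over
#' the sample -- computed from arrangement anatomy via
#' [expected_a_fragments()] -- is 80.
#'
#' @return Data frame with columns `individual`, `homolog_1`, `homolog_2`.
#' @export
synthetic_heterokaryotype_sample <- function() {
  pairs <- rbind(
    cbind("E_st",  "E_1+2",       7L),
    cbind("E_st",  "E_1+2+9",     8L),
    cbind("E_st",  "E_1+2+9+3",   4L),
    cbind("E_st",  "E_1+2+9+12",  3L),
    cbind("E_1+2", "E_1+2+9",     4L),
    cbind("E_1+2", "E_1+2+9+3",   2L),
    cbind("E_1+2", "E_1+2+9+12",  1L)
  )
  h1 <- rep(pairs[, 1], times = as.integer(pairs[, 3]))
  h2 <- rep(pairs[, 2], times = as.integer(pairs[, 3]))
  data.frame(individual = seq_along(h1), homolog_1 = h1, homolog_2 = h2,
             stringsAsFactors = FALSE)
}

#' Expected A-fragment count over a sample of karyotypes
#'
#' For each individual, builds the karyotype from the canonical arrangement
#' map and counts the A-fragment copies its two homologs expose
#' ([karyotype_a_fragments()]).
#'
#' @param sample_table Data frame with columns `homolog_1`, `homolog_2`
#'   naming canonical arrangements; defaults to
#'   [synthetic_heterokaryotype_sample()].
#' @return Integer total expected A fragments over the sample.
#' @export
#' @examples
#' expected_a_fragments()  # 80 over the 29 synthetic individuals
expected_a_fragments <- function(sample_table = synthetic_heterokaryotype_sample()) {
  arrs <- canonical_arrangements()
  copies <- vapply(arrs, count_a_fragments, integer(1))
  bad <- setdiff(unique(c(sample_table$homolog_1, sample_table$homolog_2)), names(copies))
  if (length(bad)) stop("unknown arrangement name(s): ", paste(bad, collapse = ", "))
  sum(copies[sample_table$homolog_1] + copies[sample_table$homolog_2])
}
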