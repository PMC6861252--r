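# Arrangements as ordered, oriented, provenance-tagged fragments.
#
# Fragments are atomic: breaks only happen at fragment boundaries, mirroring
# how breakpoint anatomy is described cytologically ("between sections A_p
# and A_d").  The proximal end (row 1) is the centromere side.

FRAGMENT_ALPHABET <- c("A_p", "A_d", "B_p", "B_d", "G", "K", "L", "H2", "F")
PROVENANCE_LEVELS <- c("ancestral", "E_st", "E_1+2", "BIR_copy")

#' Default fragment lengths (nt)
#'
#' The sequenced A window is ~2 kb, split evenly between `A_p` and `A_d`
#' (the full `A_d` section is ~9 kb but only the sequenced window is ever
#' simulated); `B_p` is the ~500-nt captured fragment; all other named
#' fragments and the neutral fillers `W1..Wn` default to 1 kb.
#'
#' @return Named numeric vector of default lengths in nucleotides.
#' @export
default_fragment_lengths <- function() {
  c(A_p = 1000, A_d = 1000, B_p = 500, B_d = 1000, G = 1000, K = 1000,
    L = 1000, H2 = 1000, F = 1000, W = 1000)
}

fragment_length_for <- function(name, lengths) {
  key <- if (grepl("^W[0-9]*$", name)) "W" else name
  len <- lengths[[key]]
  if (is.null(len) || is.na(len)) len <- 1000
  len
}

is_filler <- function(name) grepl("^W[0-9]*$", name)

#' Build an arrangement from a compact fragment specification
#'
#' @param name Arrangement name (e.g. `"E_st"`).
#' @param fragments Character vector of fragment tokens in proximal-to-distal
#'   order; a trailing `"-"` marks minus orientation (e.g. `"B_p-"`).
#' @param provenance Lineage label(s), recycled along fragments; one of
#'   `"ancestral"`, `"E_st"`, `"E_1+2"`, `"BIR_copy"`.
#' @param lengths Named vector of fragment lengths, see
#'   [default_fragment_lengths()].
#' @param bir_copy Logical vector, recycled: marks fragments created as
#'   break-induced-replication copies.
#'
#' @return An object of class `"arrangement"`: a list with `name` and a
#'   `fragments` data frame (columns `name`, `length_nt`, `orientation`,
#'   `provenance`, `copy_id`, `bir_copy`).  `copy_id` numbers repeated
#'   fragment names in proximal-to-distal order so `(name, copy_id)` is
#'   unique.
#' @export
#' @examples
#' arrangement("toy", c("A_p", "A_d", "G-"))
arrangement <- function(name, fragments, provenance = "ancestral",
                        lengths = default_fragment_lengths(),
                        bir_copy = FALSE) {
  if (length(fragments) == 0L) stop("an arrangement needs at least one fragment")
  orientation <- ifelse(grepl("-$", fragments), "-", "+")
  frag_names <- sub("[-+]$", "", fragments)
  bad <- !(frag_names %in% FRAGMENT_ALPHABET | is_filler(frag_names))
  if (any(bad)) {
    stop("unknown fragment name(s): ", paste(unique(frag_names[bad]), collapse = ", "))
  }
  provenance <- rep_len(provenance, length(frag_names))
  if (!all(provenance %in% PROVENANCE_LEVELS)) {
    stop("provenance must be one of: ", paste(PROVENANCE_LEVELS, collapse = ", "))
  }
  length_nt <- vapply(frag_names, fragment_length_for, numeric(1), lengths = lengths)
  if (any(length_nt <= 0)) stop("fragment lengths must be positive")
  copy_id <- stats::ave(seq_along(frag_names), frag_names, FUN = seq_along)
  frags <- data.frame(
    name = frag_names,
    length_nt = unname(length_nt),
    orientation = orientation,
    provenance = provenance,
    copy_id = as.integer(copy_id),
    bir_copy = rep_len(bir_copy, length(frag_names)),
    stringsAsFactors = FALSE
  )
  new_arrangement(name, frags)
}

new_arrangement <- function(name, frags) {
  stopifnot(is.data.frame(frags), nrow(frags) >= 1L)
  if (anyDuplicated(frags[, c("name", "copy_id")])) {
    stop("(name, copy_id) must be unique within an arrangement")
  }
  structure(list(name = name, fragments = frags), class = "arrangement")
}

renumber_copies <- function(frags) {
  frags$copy_id <- as.integer(stats::ave(seq_len(nrow(frags)), frags$name, FUN = seq_along))
  frags
}

#' @export
print.arrangement <- function(x, ...) {
  cat("Arrangement", x$name, "(", nrow(x$fragments), "fragments, proximal -> distal )\n")
  cat(" ", paste0(x$fragments$name,
                  ifelse(x$fragments$orientation == "-", "-", ""),
                  collapse = " "), "\n")
  prov <- unique(x$fragments$provenance)
  if (!identical(prov, "ancestral")) {
    cat("  provenance:", paste(prov, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.arrangement <- function(x, ...) {
  cbind(arrangement = x$name, position = seq_len(nrow(x$fragments)), x$fragments)
}

#' Fragment order signature
#'
#' Compact `name` + orientation representation used to compare derived
#' products across origin models.
#'
#' @param arr An [arrangement()].
#' @return Character vector, one token per fragment (minus orientation as a
#'   trailing `"-"`).
#' @export
fragment_signature <- function(arr) {
  paste0(arr$fragments$name, ifelse(arr$fragments$orientation == "-", "-", ""))
}

#' The five canonical E-chromosome arrangements
#'
#' Hard-coded fragment maps for the standard arrangement and the four derived
#' arrangements generated by the sequential overlapping inversions.  The maps
#' are one fixed choice satisfying the documented adjacency constraints: the
#' standard arrangement begins `(A_p, A_d, B_p, B_d)`; the doubly inverted
#' arrangement begins `(A_p, A_d, G)`, keeps `K|L` adjacent and carries a
#' `B_p|F` junction; the triple-inversion arrangement carries the `B_p|K`
#' (AK) junction and the duplicated distal A section in its `(G, A_d, L)`
#' (GAL) window; its two derivatives respectively replace AK by `B_p|H2`
#' (AH2) and retain both AK and GAL.  Neutral `W` fillers space the named
#' fragments; no analysis depends on filler order.
#'
#' In the three derived arrangements the proximal `A_d`/`B_p` copies are
#' tagged with provenance `"E_st"` and the central inverted block (including
#' GAL's `A_d`) with `"E_1+2"`, encoding the capture of proximal material
#' from the standard homologue at the third inversion's origin.
#'
#' @param lengths Named fragment lengths, see [default_fragment_lengths()].
#' @return Named list of five [arrangement()] objects:
#'   `E_st`, `E_1+2`, `E_1+2+9`, `E_1+2+9+3`, `E_1+2+9+12`.
#' @export
#' @examples
#' arrs <- canonical_arrangements()
#' fragment_signature(arrs[["E_1+2+9"]])
canonical_arrangements <- function(lengths = default_fragment_lengths()) {
  e_st <- arrangement(
    "E_st",
    c("A_p", "A_d", "B_p", "B_d", "W1", "G", "W2", "F", "W6", "H2", "W3", "K", "L", "W4", "W5"),
    lengths = lengths
  )
  e_12 <- arrangement(
    "E_1+2",
    c("A_p", "A_d", "G", "W2", "H2", "W3", "B_d-", "B_p-", "F", "W6", "W1", "K", "L", "W4", "W5"),
    lengths = lengths
  )
  e_129 <- arrangement(
    "E_1+2+9",
    c("A_p", "A_d", "B_p", "K-", "W1-", "W6-", "F-", "B_p", "B_d", "W3-", "H2-", "W2-", "G-", "A_d-", "L", "W4", "W5"),
    provenance = c(rep("E_st", 3), rep("E_1+2", 11), rep("E_st", 3)),
    lengths = lengths
  )
  # E_3 inverts between the B_p|K junction and past H2 (fragments 4..11).
  e_1293 <- invert_segment(e_129, 4L, 11L)
  e_1293$name <- "E_1+2+9+3"
  # E_12 does not touch the E_9 breakpoints: modelled as a distal filler
  # inversion past the GAL window.
  e_12912 <- invert_segment(e_129, 16L, 17L)
  e_12912$name <- "E_1+2+9+12"
  list("E_st" = e_st, "E_1+2" = e_12, "E_1+2+9" = e_129,
       "E_1+2+9+3" = e_1293, "E_1+2+9+12" = e_12912)
}

#' Invert a segment of an arrangement
#'
#' Reverses the order of fragments `i..j` and flips each fragment's
#' orientation; all other fragments (and every fragment's provenance and
#' copy id) are untouched, so the fragment multiset is conserved and the
#' operation is an involution.
#'
#' @param arr An [arrangement()].
#' @param i,j 1-based fragment indices, `1 <= i <= j <= n`.
#' @return A new [arrangement()] (name suffixed with `".inv"` unless `i..j`
#'   is renamed by the caller).
#' @export
invert_segment <- function(arr, i, j) {
  stopifnot(inherits(arr, "arrangement"))
  n <- nrow(arr$fragments)
  if (!(is.numeric(i) && is.numeric(j) && length(i) == 1L && length(j) == 1L)) {
    stop("i and j must be single indices")
  }
  if (i < 1L || j > n || i > j) {
    stop("invert_segment: indices out of range (i=", i, ", j=", j, ", n=", n, ")")
  }
  frags <- arr$fragments
  seg <- frags[j:i, , drop = FALSE]
  seg$orientation <- ifelse(seg$orientation == "+", "-", "+")
  frags <- rbind(
    if (i > 1L) frags[seq_len(i - 1L), , drop = FALSE],
    seg,
    if (j < n) frags[seq(j + 1L, n), , drop = FALSE]
  )
  rownames(frags) <- NULL
  new_arrangement(arr$name, frags)
}

# Canonical naming vocabulary: junction pairs expected between named
# fragments; anything else between two named fragments is unknown.
KNOWN_JUNCTIONS <- list(
  c("A_p", "A_d"), c("A_d", "B_p"), c("B_p", "B_d"), c("A_d", "G"),
  c("A_d", "L"), c("B_p", "K"), c("B_p", "H2"), c("B_p", "F"), c("K", "L")
)

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Extract named breakpoint regions from an arrangement
#'
#' Scans fragment adjacencies and returns every named junction present,
#' using the canonical naming table: `AB` (contiguous `A_d, B_p, B_d` with
#' the A section), `AG` (`A_p, A_d, G`), `GAL` (`A_d` flanked by `G` and
#' `L`), `AK` (`A_d, B_p, K`), `AH2` (`A_d, B_p, H2`), `BF` (`B_p`
#' adjacent to `F`) and `KL` (`K` adjacent to `L`).  Junctions between two
#' named fragments that match no table entry are omitted with a warning;
#' junctions involving neutral `W` fillers are structural spacers and are
#' skipped silently.
#'
#' @param arr An [arrangement()] built from the canonical fragment alphabet.
#' @return A list of `"breakpoint_region"` objects (fields `name`,
#'   `fragments` window data frame in stored proximal-to-distal order, and
#'   `arrangement`), named by region.
#' @export
#' @examples
#' region_names(canonical_arrangements()[["E_1+2+9"]])
breakpoint_regions <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  frags <- arr$fragments
  nm <- frags$name
  n <- length(nm)
  regions <- list()
  consumed <- character(0)
  window <- function(idx) {
    list(name = NULL, fragments = frags[idx, , drop = FALSE], arrangement = arr$name)
  }
  add_region <- function(name, idx, pairs) {
    r <- window(idx)
    r$name <- name
    regions[[length(regions) + 1L]] <<- structure(r, class = "breakpoint_region")
    consumed <<- c(consumed, pairs)
  }
  neighbors <- function(i) nm[c(i - 1L, i + 1L)[c(i > 1L, i < n)]]

  for (i in seq_len(n)) {
    if (nm[i] == "A_d") {
      nb <- neighbors(i)
      if (all(c("G", "L") %in% nb)) {
        # duplicated distal A copy between G and L
        idx <- sort(c(i - 1L, i, i + 1L))
        add_region("GAL", idx, c(pair_key("A_d", "G"), pair_key("A_d", "L")))
      } else if (all(c("A_p", "G") %in% nb)) {
        idx <- sort(c(i - 1L, i, i + 1L))
        add_region("AG", idx, c(pair_key("A_p", "A_d"), pair_key("A_d", "G")))
      }
    }
    if (nm[i] == "B_p") {
      nb <- neighbors(i)
      if ("A_d" %in% nb && "B_d" %in% nb) {
        lo <- i - 1L; hi <- i + 1L
        if (lo > 1L && nm[lo] == "A_d" && nm[lo - 1L] == "A_p") lo <- lo - 1L
        if (hi < n && nm[hi] == "A_d" && nm[hi + 1L] == "A_p") hi <- hi + 1L
        add_region("AB", lo:hi, c(pair_key("A_d", "B_p"), pair_key("B_p", "B_d")))
      } else if ("A_d" %in% nb && "K" %in% nb) {
        lo <- min(i - 1L, i + 1L); hi <- max(i - 1L, i + 1L)
        if (lo > 1L && nm[lo] == "A_d" && nm[lo - 1L] == "A_p") lo <- lo - 1L
        if (hi < n && nm[hi] == "A_d" && nm[hi + 1L] == "A_p") hi <- hi + 1L
        add_region("AK", lo:hi, c(pair_key("A_d", "B_p"), pair_key("B_p", "K")))
      } else if ("A_d" %in% nb && "H2" %in% nb) {
        lo <- min(i - 1L, i + 1L); hi <- max(i - 1L, i + 1L)
        if (lo > 1L && nm[lo] == "A_d" && nm[lo - 1L] == "A_p") lo <- lo - 1L
        if (hi < n && nm[hi] == "A_d" && nm[hi + 1L] == "A_p") hi <- hi + 1L
        add_region("AH2", lo:hi, c(pair_key("A_d", "B_p"), pair_key("B_p", "H2")))
      } else if ("F" %in% nb) {
        lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
        add_region("BF", lo:hi, pair_key("B_p", "F"))
      }
    }
    if (nm[i] == "K" && i < n && nm[i + 1L] == "L") {
      add_region("KL", i:(i + 1L), pair_key("K", "L"))
    }
    if (nm[i] == "L" && i < n && nm[i + 1L] == "K") {
      add_region("KL", i:(i + 1L), pair_key("K", "L"))
    }
  }

  # unknown junctions between two named fragments
  known <- vapply(KNOWN_JUNCTIONS, function(p) pair_key(p[1], p[2]), character(1))
  for (i in seq_len(n - 1L)) {
    if (is_filler(nm[i]) || is_filler(nm[i + 1L])) next
    key <- pair_key(nm[i], nm[i + 1L])
    if (!(key %in% known)) {
      warning("unknown junction ", nm[i], "|", nm[i + 1L], " in ", arr$name,
              ": region omitted", call. = FALSE)
    }
  }
  names(regions) <- vapply(regions, function(r) r$name, character(1))
  regions
}

#' @export
print.breakpoint_region <- function(x, ...) {
  cat("Region", x$name, "in", x$arrangement, ":",
      paste0(x$fragments$name,
             ifelse(x$fragments$orientation == "-", "-", ""), collapse = " "), "\n")
  invisible(x)
}

#' Names of breakpoint regions present in an arrangement
#'
#' @param arr An [arrangement()].
#' @return Character vector of region names (see [breakpoint_regions()]).
#' @export
region_names <- function(arr) {
  unname(vapply(breakpoint_regions(arr), function(r) r$name, character(1)))
}

#' Count sequenced A-fragment copies carried by an arrangement
#'
#' An A fragment is sequenced from each breakpoint region that spans the
#' shared A part: AB, AG, AK, AH2 and GAL.  The standard and doubly inverted
#' arrangements carry one such region; the triple-inversion arrangement and
#' its derivatives carry two (their proximal region plus the duplicated GAL
#' window).
#'
#' @param arr An [arrangement()].
#' @return Integer count of A-fragment copies.
#' @export
count_a_fragments <- function(arr) {
  sum(region_names(arr) %in% c("AB", "AG", "AK", "AH2", "GAL"))
}
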