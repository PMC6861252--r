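# Origin mechanisms for an inversion whose proximal breakpoint captured
# material from the homologous chromosome.
#
# Single-chromosome mechanisms (cut-and-paste, isochromatid, chromatid)
# operate on one arrangement; the three heterokaryotype mechanisms (NHEJ-4,
# NHEJ-3, BIR-NHEJ) require a standard/doubly-inverted heterokaryotype and
# differ in break count, repair pathway, provenance and side products while
# producing the same derived fragment order.

ORIGIN_MODELS <- c("cut_and_paste", "isochromatid", "chromatid",
                   "nhej4", "nhej3", "bir_nhej")
HETEROKARYOTYPE_MODELS <- c("nhej4", "nhej3", "bir_nhej")

#' Specify a double-strand break at a fragment boundary
#'
#' Breaks are modelled at fragment boundaries only; a boundary is the ordered
#' pair of fragment names flanking the break.
#'
#' @param homolog Name of the arrangement carrying the break.
#' @param boundary Character vector of length 2: the fragment names left and
#'   right of the break (orientation ignored).
#' @param scope `"chromosome"` (both chromatids) or `"chromatid"` (a single
#'   sister chromatid); sister-chromatid bookkeeping is implicit.
#' @return Object of class `"break_spec"`.
#' @export
break_spec <- function(homolog, boundary, scope = c("chromosome", "chromatid")) {
  scope <- match.arg(scope)
  if (length(boundary) != 2L) stop("boundary must name the two flanking fragments")
  structure(list(homolog = homolog, boundary = as.character(boundary), scope = scope),
            class = "break_spec")
}

# Index i such that the junction between fragments i and i+1 matches the
# boundary pair (first match, proximal to distal).
find_boundary <- function(arr, boundary) {
  nm <- arr$fragments$name
  for (i in seq_len(length(nm) - 1L)) {
    if (nm[i] == boundary[1] && nm[i + 1L] == boundary[2]) return(i)
  }
  stop("boundary ", boundary[1], "|", boundary[2], " not found in ", arr$name)
}

new_origin_outcome <- function(model, derived, side_products, n_breaks, pathways) {
  stopifnot(n_breaks >= 2L)
  structure(list(model = model, derived = derived, side_products = side_products,
                 n_breaks = as.integer(n_breaks), pathways = pathways),
            class = "origin_outcome")
}

#' @export
print.origin_outcome <- function(x, ...) {
  cat("Origin outcome (model:", x$model, ")\n")
  cat("  double-strand breaks:", x$n_breaks,
      "| repair pathways:", paste(x$pathways, collapse = "+"), "\n")
  cat("  derived:", x$derived$name, "=",
      paste(fragment_signature(x$derived), collapse = " "), "\n")
  for (sp in x$side_products) {
    cat("  side product", if (isFALSE(sp$surviving)) "[non-surviving]" else "[surviving]",
        ":", paste(fragment_signature(sp), collapse = " "), "\n")
  }
  invisible(x)
}

slice_frags <- function(arr, idx, provenance = NULL, bir_copy = NULL) {
  f <- arr$fragments[idx, , drop = FALSE]
  if (!is.null(provenance)) f$provenance <- provenance
  if (!is.null(bir_copy)) f$bir_copy <- bir_copy
  f
}

flip_frags <- function(f) {
  f <- f[rev(seq_len(nrow(f))), , drop = FALSE]
  f$orientation <- ifelse(f$orientation == "+", "-", "+")
  f
}

assemble_arrangement <- function(name, ..., surviving = TRUE) {
  frags <- do.call(rbind, Filter(function(x) !is.null(x) && nrow(x) > 0, list(...)))
  rownames(frags) <- NULL
  arr <- new_arrangement(name, renumber_copies(frags))
  arr$surviving <- surviving
  arr
}

# provenance label for single-chromosome products: the source arrangement
# name when it is a recognised lineage, otherwise left untouched
lineage_label <- function(arr) {
  if (arr$name %in% PROVENANCE_LEVELS) arr$name else NULL
}

check_single_homolog <- function(arr, specs) {
  homs <- unique(vapply(specs, function(b) b$homolog, character(1)))
  if (length(homs) != 1L || homs != arr$name) {
    stop("all breaks must be on the same homolog (", arr$name, ")")
  }
}

#' Simple cut-and-paste inversion
#'
#' Two breaks on the same chromosome; the central segment is excised,
#' inverted and rejoined.  No duplication occurs.
#'
#' @param arr The [arrangement()] carrying both breaks.
#' @param b1,b2 [break_spec()]s on `arr`, at distinct boundaries.
#' @return An `"origin_outcome"` with `n_breaks = 2`, pathway NHEJ, and no
#'   side products.
#' @export
apply_cut_and_paste <- function(arr, b1, b2) {
  check_single_homolog(arr, list(b1, b2))
  i1 <- find_boundary(arr, b1$boundary)
  i2 <- find_boundary(arr, b2$boundary)
  if (i1 == i2) stop("the two breaks must be at distinct boundaries")
  lo <- min(i1, i2); hi <- max(i1, i2)
  lab <- lineage_label(arr)
  prox <- slice_frags(arr, seq_len(lo), provenance = lab)
  central <- flip_frags(slice_frags(arr, seq(lo + 1L, hi), provenance = lab))
  dist <- if (hi < nrow(arr$fragments)) {
    slice_frags(arr, seq(hi + 1L, nrow(arr$fragments)), provenance = lab)
  }
  derived <- assemble_arrangement(paste0(arr$name, ".inv"), prox, central, dist)
  new_origin_outcome("cut_and_paste", derived, list(), 2L, "NHEJ")
}

iso_like_product <- function(arr, p1, p2, d, model, n_breaks) {
  n <- nrow(arr$fragments)
  if (p1 > p2) stop("staggered pair not nested/ordered (", p1, " > ", p2, ")")
  if (d <= p2) stop("distal break must lie distal to the staggered pair")
  lab <- lineage_label(arr)
  prox <- slice_frags(arr, seq_len(p1), provenance = lab)
  stagger <- if (p2 > p1) slice_frags(arr, seq(p1 + 1L, p2), provenance = lab)
  central <- flip_frags(slice_frags(arr, seq(p2 + 1L, d), provenance = lab))
  stagger_copy <- if (!is.null(stagger)) flip_frags(stagger)
  dist <- if (d < n) slice_frags(arr, seq(d + 1L, n), provenance = lab)
  derived <- assemble_arrangement(paste0(arr$name, ".inv"),
                                  prox, stagger, central, stagger_copy, dist)
  new_origin_outcome(model, derived, list(), n_breaks, "NHEJ")
}

#' Isochromatid model: staggered breaks on a single chromatid
#'
#' Two staggered breaks in the proximal region of one chromatid plus a
#' distal break; repair duplicates the inter-staggered stretch, which ends
#' up at both breakpoints of the inverted chromosome in opposite
#' orientations.  Both copies keep the provenance of the single carrying
#' chromosome.  A zero-width stagger (both proximal breaks at the same
#' boundary) degenerates to the cut-and-paste product.
#'
#' @param arr The [arrangement()] carrying the breaks.
#' @param proximal_staggered List of two [break_spec()]s (chromatid scope) in
#'   proximal-to-distal order.
#' @param distal A [break_spec()] (chromatid scope) distal to the stagger.
#' @return An `"origin_outcome"` with `n_breaks = 3` and no side products.
#' @export
apply_isochromatid <- function(arr, proximal_staggered, distal) {
  specs <- c(proximal_staggered, list(distal))
  check_single_homolog(arr, specs)
  if (!all(vapply(specs, function(b) b$scope, character(1)) == "chromatid")) {
    stop("isochromatid breaks must have chromatid scope")
  }
  p1 <- find_boundary(arr, proximal_staggered[[1]]$boundary)
  p2 <- find_boundary(arr, proximal_staggered[[2]]$boundary)
  d <- find_boundary(arr, distal$boundary)
  iso_like_product(arr, p1, p2, d, "isochromatid", 3L)
}

#' Chromatid model: two breaks in each of two sister chromatids
#'
#' Four breaks in total (two per sister chromatid) during meiotic prophase;
#' resolution leaves one chromatid with the inverted order and the
#' inter-break stretch duplicated at both breakpoints, exactly as in the
#' isochromatid product.  All fragments keep the provenance of the single
#' carrying homolog; sister-chromatid bookkeeping is implicit.
#'
#' @param arr The [arrangement()] carrying the breaks.
#' @param breaks List of three [break_spec()]s with chromatid scope: the two
#'   staggered proximal breaks (proximal-to-distal) and the distal break.
#' @return An `"origin_outcome"` with `n_breaks = 4` and no side products.
#' @export
apply_chromatid <- function(arr, breaks) {
  if (length(breaks) != 3L) stop("chromatid model takes the two staggered proximal breaks and one distal break")
  check_single_homolog(arr, breaks)
  if (!all(vapply(breaks, function(b) b$scope, character(1)) == "chromatid")) {
    stop("chromatid-model breaks must have chromatid scope")
  }
  p1 <- find_boundary(arr, breaks[[1]]$boundary)
  p2 <- find_boundary(arr, breaks[[2]]$boundary)
  d <- find_boundary(arr, breaks[[3]]$boundary)
  iso_like_product(arr, p1, p2, d, "chromatid", 4L)
}

check_het <- function(het) {
  if (!inherits(het, "karyotype") || !het$is_heterokaryotypic) {
    stop("a heterokaryotypic karyotype is required")
  }
  nms <- c(het$homolog_1$name, het$homolog_2$name)
  if (!setequal(nms, c("E_st", "E_1+2"))) {
    stop("the heterokaryotype models require an E_st/E_1+2 karyotype, got ",
         paste(nms, collapse = "/"))
  }
  list(est = if (het$homolog_1$name == "E_st") het$homolog_1 else het$homolog_2,
       e12 = if (het$homolog_1$name == "E_1+2") het$homolog_1 else het$homolog_2)
}

het_pieces <- function(est, e12) {
  # staggered proximal breaks: past B_p on the standard homolog, between
  # A_p and A_d on the doubly inverted one; distal breaks at the K|L junction
  i_est_prox <- find_boundary(est, c("B_p", "B_d"))
  i_est_dist <- find_boundary(est, c("K", "L"))
  i_e12_prox <- find_boundary(e12, c("A_p", "A_d"))
  i_e12_dist <- find_boundary(e12, c("K", "L"))
  list(
    est_prox = slice_frags(est, seq_len(i_est_prox), provenance = "E_st"),
    est_central = slice_frags(est, seq(i_est_prox + 1L, i_est_dist), provenance = "E_st"),
    est_dist = slice_frags(est, seq(i_est_dist + 1L, nrow(est$fragments)), provenance = "E_st"),
    e12_prox = slice_frags(e12, seq_len(i_e12_prox), provenance = "E_1+2"),
    e12_central = slice_frags(e12, seq(i_e12_prox + 1L, i_e12_dist), provenance = "E_1+2"),
    e12_dist = slice_frags(e12, seq(i_e12_dist + 1L, nrow(e12$fragments)), provenance = "E_1+2")
  )
}

#' NHEJ-4 heterokaryotype model (four breaks on both homologs)
#'
#' Both homologs break at the distal junction and, staggered, in the
#' proximal region (past `B_p` on the standard homolog; between `A_p` and
#' `A_d` on the doubly inverted one).  The excised central part of the
#' doubly inverted homolog is rejoined in inverted orientation to the
#' external standard-homolog pieces.  The reciprocal joint of the remaining
#' pieces is emitted as a non-surviving side product.
#'
#' @param het A heterokaryotypic [karyotype()] of the standard and doubly
#'   inverted arrangements.
#' @return An `"origin_outcome"`: `n_breaks = 4`, pathway NHEJ, derived
#'   arrangement with proximal `A_p`/`A_d`/`B_p` of standard-homolog
#'   provenance and the GAL `A_d` of doubly-inverted provenance.
#' @export
#' @examples
#' arrs <- canonical_arrangements()
#' apply_nhej4(karyotype(arrs[["E_st"]], arrs[["E_1+2"]]))
apply_nhej4 <- function(het) {
  h <- check_het(het)
  p <- het_pieces(h$est, h$e12)
  derived <- assemble_arrangement("E_1+2+9",
                                  p$est_prox, flip_frags(p$e12_central), p$est_dist)
  side <- assemble_arrangement("reciprocal_product",
                               p$e12_prox, flip_frags(p$est_central), p$e12_dist,
                               surviving = FALSE)
  new_origin_outcome("nhej4", derived, list(side), 4L, "NHEJ")
}

#' NHEJ-3 heterokaryotype model (three breaks)
#'
#' As [apply_nhej4()] but the distal break occurs only on the doubly
#' inverted homolog; the derived chromosome keeps that homolog's distal
#' piece, and the side product is a broken standard chromosome lacking its
#' `A_d` and `B_p` sections (it received the orphan proximal `A_p` of the
#' doubly inverted homolog).
#'
#' @inheritParams apply_nhej4
#' @return An `"origin_outcome"` with `n_breaks = 3`, pathway NHEJ.
#' @export
apply_nhej3 <- function(het) {
  h <- check_het(het)
  p <- het_pieces(h$est, h$e12)
  derived <- assemble_arrangement("E_1+2+9",
                                  p$est_prox, flip_frags(p$e12_central), p$e12_dist)
  side <- assemble_arrangement("E_st_lacking_Ad_Bp",
                               p$e12_prox, p$est_central, p$est_dist,
                               surviving = FALSE)
  new_origin_outcome("nhej3", derived, list(side), 3L, "NHEJ")
}

#' BIR-NHEJ heterokaryotype model (two breaks on one chromatid)
#'
#' Two breaks on a single sister chromatid of the doubly inverted homolog
#' (between `A_p` and `A_d`, and at the distal `K|L` junction).  The
#' proximal break is repaired by break-induced replication using the
#' standard homolog as template, inserting fresh copies of its `A_d` and
#' `B_p` sections (provenance `"E_st"`, flagged `bir_copy`); the distal
#' break is repaired by NHEJ.  The standard homolog is returned intact among
#' the side products.
#'
#' @inheritParams apply_nhej4
#' @return An `"origin_outcome"` with `n_breaks = 2`, pathways BIR and NHEJ.
#' @export
apply_bir_nhej <- function(het) {
  h <- check_het(het)
  p <- het_pieces(h$est, h$e12)
  i_ad <- which(h$est$fragments$name == "A_d")[1]
  i_bp <- which(h$est$fragments$name == "B_p")[1]
  bir_copies <- slice_frags(h$est, c(i_ad, i_bp), provenance = "E_st", bir_copy = TRUE)
  derived <- assemble_arrangement("E_1+2+9",
                                  p$e12_prox, bir_copies,
                                  flip_frags(p$e12_central), p$e12_dist)
  est_intact <- h$est
  est_intact$surviving <- TRUE
  new_origin_outcome("bir_nhej", derived, list(est_intact), 2L, c("BIR", "NHEJ"))
}

#' Predicted sister-clade constraints for an origin model
#'
#' Under any heterokaryotype model the proximal A-window copies of the
#' inverted chromosome descend from the standard homolog, so the AK and AH2
#' sequences are predicted sister to AB, while the duplicated distal copy
#' (GAL) descends from the doubly inverted homolog and groups with AG.  (For
#' BIR-NHEJ the `A_p` section stays with the doubly inverted lineage, but
#' the sequenced window lies in `A_d`, so all three heterokaryotype models
#' make the same prediction for it.)  Under a single-chromosome model every
#' A-window copy descends from the doubly inverted chromosome and groups
#' with AG.
#'
#' @param model One of `"cut_and_paste"`, `"isochromatid"`, `"chromatid"`,
#'   `"nhej4"`, `"nhej3"`, `"bir_nhej"`.
#' @return List of `"clade_constraint"` objects (fields `focal_regions`,
#'   `predicted_sister`, `basis`).
#' @export
predict_clade_constraints <- function(model) {
  if (!(is.character(model) && length(model) == 1L && model %in% ORIGIN_MODELS)) {
    stop("unknown origin model: ", paste(model, collapse = ", "))
  }
  cc <- function(focal, sister, basis) {
    stopifnot(!sister %in% focal)
    structure(list(focal_regions = focal, predicted_sister = sister, basis = basis),
              class = "clade_constraint")
  }
  if (model %in% HETEROKARYOTYPE_MODELS) {
    list(
      cc(c("AK", "AH2"), "AB",
         "proximal A-window copies descend from the standard (E_st) homolog"),
      cc("GAL", "AG",
         "duplicated distal A_d copy descends from the doubly inverted (E_1+2) homolog")
    )
  } else {
    list(
      cc(c("AK", "AH2", "GAL"), "AG",
         "all A-window copies descend from the single E_1+2 chromosome")
    )
  }
}

#' @export
print.clade_constraint <- function(x, ...) {
  cat("{", paste(x$focal_regions, collapse = ","), "} sister to ",
      x$predicted_sister, " -- ", x$basis, "\n", sep = "")
  invisible(x)
}
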