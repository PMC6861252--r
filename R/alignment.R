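# Labelled multiple alignments over {A,C,G,T,-,N}.

ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a labelled alignment
#'
#' @param seqs Character matrix of single characters (rows = sequences,
#'   rownames = sample names) or a named character vector of equal-length
#'   strings.  Lowercase is upper-cased and `U` normalised to `T`.
#' @param labels Optional data frame with columns `sample`, `region`,
#'   `arrangement`, `outgroup`.  When missing, labels are parsed from sample
#'   names of the form `sample_<region>_<arrangement>_<idx>`; any other name
#'   is treated as an outgroup sequence.
#' @return Object of class `"labeled_alignment"`: list with `seqs` (character
#'   matrix) and `labels` (data frame).
#' @export
labeled_alignment <- function(seqs, labels = NULL) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    }
    nm <- names(seqs)
    if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
    seqs <- do.call(rbind, strsplit(seqs, ""))
    rownames(seqs) <- nm
  }
  stopifnot(is.matrix(seqs), nrow(seqs) >= 1L)
  if (is.null(rownames(seqs))) rownames(seqs) <- paste0("seq", seq_len(nrow(seqs)))
  seqs[] <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  bad <- which(!(seqs %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(seqs))
    stop("unknown symbol '", seqs[bad[1]], "' in sequence ", rownames(seqs)[i[1]],
         " at position ", i[2])
  }
  if (is.null(labels)) labels <- parse_sample_labels(rownames(seqs))
  labels <- validate_labels(labels, rownames(seqs))
  structure(list(seqs = seqs, labels = labels), class = "labeled_alignment")
}

parse_sample_labels <- function(nm) {
  pat <- "^sample_([^_]+)_([^_]+)_([0-9]+)$"
  hit <- grepl(pat, nm)
  data.frame(
    sample = nm,
    region = ifelse(hit, sub(pat, "\\1", nm), NA_character_),
    arrangement = ifelse(hit, sub(pat, "\\2", nm), NA_character_),
    outgroup = !hit,
    stringsAsFactors = FALSE
  )
}

validate_labels <- function(labels, nm) {
  need <- c("sample", "region", "arrangement", "outgroup")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels lack column(s): ", paste(miss, collapse = ", "))
  labels <- labels[match(nm, labels$sample), need]
  if (anyNA(labels$sample)) stop("labels must cover every sequence")
  labels$outgroup <- as.logical(labels$outgroup)
  rownames(labels) <- NULL
  labels
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("Labelled alignment:", nrow(x$seqs), "sequences x", ncol(x$seqs), "sites\n")
  ing <- x$labels[!x$labels$outgroup, ]
  if (nrow(ing)) {
    tab <- table(ing$region)
    cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (any(x$labels$outgroup)) {
    cat("  outgroup:", paste(x$labels$sample[x$labels$outgroup], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset an alignment by sample name
#'
#' @param aln A [labeled_alignment()].
#' @param samples Character vector of sample names to keep (in this order).
#' @return A [labeled_alignment()] restricted to `samples`.
#' @export
subset_alignment <- function(aln, samples) {
  stopifnot(inherits(aln, "labeled_alignment"))
  miss <- setdiff(samples, rownames(aln$seqs))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  labeled_alignment(aln$seqs[samples, , drop = FALSE],
                    aln$labels[match(samples, aln$labels$sample), ])
}

#' Sample names of the ingroup / outgroup
#'
#' @param aln A [labeled_alignment()].
#' @return Character vector of sample names.
#' @export
ingroup_samples <- function(aln) aln$labels$sample[!aln$labels$outgroup]

#' @rdname ingroup_samples
#' @export
outgroup_samples <- function(aln) aln$labels$sample[aln$labels$outgroup]

#' Sample names belonging to a region
#'
#' @param aln A [labeled_alignment()].
#' @param region Region name (e.g. `"AB"`).
#' @return Character vector of sample names.
#' @export
region_samples <- function(aln, region) {
  aln$labels$sample[!aln$labels$outgroup & aln$labels$region %in% region]
}
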