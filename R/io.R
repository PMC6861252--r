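# FASTA / TSV / JSON interfaces.  Sequence labels travel in FASTA headers
# (sample_<region>_<arrangement>_<idx>) with an optional sidecar TSV
# override, since real archive records carry no structured labels.

#' Read a labelled alignment from FASTA
#'
#' Sequences are upper-cased with `U` normalised to `T`; a ragged input or
#' an unknown symbol raises an error (the latter naming the position).
#'
#' @param path FASTA file.
#' @param labels Optional label sidecar: a data frame or the path of a
#'   tab-separated file with columns `sample`, `region`, `arrangement`,
#'   `outgroup`; overrides header parsing.
#' @return A [labeled_alignment()].
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  seq_lines <- !startsWith(lines, ">")
  if (any(grepl("[Uu]", lines[seq_lines]))) {
    # RNA-style input: normalise U -> T before handing to the DNA parser
    lines[seq_lines] <- chartr("Uu", "Tt", lines[seq_lines])
    path <- tempfile(fileext = ".fasta")
    writeLines(lines, path)
    on.exit(unlink(path), add = TRUE)
  }
  dna <- ape::read.FASTA(path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment in ", path, ": lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  M <- toupper(as.character(as.matrix(dna)))
  if (is.character(labels) && length(labels) == 1L) labels <- read_labels(labels)
  labeled_alignment(M, labels)
}

#' Write a labelled alignment to FASTA
#'
#' @param aln A [labeled_alignment()] or character matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  M <- seq_matrix(aln)
  ape::write.FASTA(ape::as.DNAbin(M), path)
  invisible(path)
}

#' Read / write a label sidecar TSV
#'
#' @param path Tab-separated file with columns `sample`, `region`,
#'   `arrangement`, `outgroup`.
#' @return Data frame of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = c("NA", ""))
}

#' @rdname read_labels
#' @param aln A [labeled_alignment()].
#' @export
write_labels <- function(aln, path) {
  stopifnot(inherits(aln, "labeled_alignment"))
  write.table(aln$labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise arrangements and origin outcomes
#'
#' Tab-separated and JSON dumps of the fragment-level structures, for use
#' from scripts and the command line.
#'
#' @param arr An [arrangement()].
#' @param path Output file for the TSV variant.
#' @return The JSON string / `path`, invisibly for writers.
#' @export
arrangement_json <- function(arr) {
  stopifnot(inherits(arr, "arrangement"))
  jsonlite::toJSON(list(name = arr$name, fragments = arr$fragments),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname arrangement_json
#' @export
write_arrangement_tsv <- function(arr, path) {
  write.table(as.data.frame(arr), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname arrangement_json
#' @param outcome An `"origin_outcome"`.
#' @export
origin_outcome_json <- function(outcome) {
  stopifnot(inherits(outcome, "origin_outcome"))
  jsonlite::toJSON(list(
    model = outcome$model,
    n_breaks = outcome$n_breaks,
    pathways = outcome$pathways,
    derived = list(name = outcome$derived$name, fragments = outcome$derived$fragments),
    side_products = lapply(outcome$side_products, function(sp) {
      list(name = sp$name, surviving = isTRUE(sp$surviving), fragments = sp$fragments)
    })
  ), auto_unbox = TRUE, digits = NA)
}
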