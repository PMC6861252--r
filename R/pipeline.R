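# Pipeline orchestration: simulate (or read) -> polymorphism table ->
# F_ST matrix -> pooling check -> NJ tree with bootstrap -> verdict.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (simulate under an origin model; the default)
#'   or `"real"` (analyse a user-supplied alignment).
#' @param sim A [sim_params()] object (synthetic mode).
#' @param input_fasta,labels Real mode inputs: alignment FASTA and optional
#'   label sidecar (see [read_fasta()]).
#' @param n_perm Permutations per F_ST test (default 10000).
#' @param n_bootstrap Bootstrap replicates for the tree (default 1000).
#' @param coverage Partial-deletion coverage for tree building (default
#'   0.95).
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional output directory; when given, all stage outputs
#'   and a JSON run manifest are written there.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), sim = sim_params(),
                            input_fasta = NULL, labels = NULL,
                            n_perm = 10000, n_bootstrap = 1000,
                            coverage = 0.95, seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "real" && is.null(input_fasta)) stop("real mode requires input_fasta")
  stopifnot(n_perm > 0, n_bootstrap >= 1, coverage > 0, coverage <= 1)
  structure(list(mode = mode, sim = sim, input_fasta = input_fasta,
                 labels = labels, n_perm = n_perm, n_bootstrap = n_bootstrap,
                 coverage = coverage, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

# differentiation between arrangements pooled within one region (tests
# whether a later inversion that left the focal breakpoints untouched
# warrants pooling its carriers)
pooling_check <- function(aln, region, n_perm, seed) {
  lab <- aln$labels[!aln$labels$outgroup & aln$labels$region == region, ]
  tab <- sort(table(lab$arrangement), decreasing = TRUE)
  tab <- tab[tab >= 2]
  if (length(tab) < 2L) return(NULL)
  ga <- lab$sample[lab$arrangement == names(tab)[1]]
  gb <- lab$sample[lab$arrangement == names(tab)[2]]
  res <- fst_permutation_p(aln, ga, gb, n_perm = n_perm, seed = seed)
  res$region <- region
  res$arrangements <- names(tab)[1:2]
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> per-region polymorphism summaries -> pairwise
#' F_ST with permutation tests -> within-region pooling check -> NJ tree
#' with bootstrap supports, rooted on the outgroup -> concordance verdict.
#' Deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"inv_pipeline"`: list with `alignment`,
#'   `dataset` (synthetic mode), `stats` ([polymorphism_table()]), `fst`
#'   ([fst_matrix()]), `pooling` (list of pooling-check results), `tree`
#'   (rooted, with bootstrap node labels), `verdict`, `manifest` and
#'   `config`.
#' @export
#' @examples
#' cfg <- pipeline_config(sim = sim_params(seq_length = 300),
#'                        n_perm = 100, n_bootstrap = 20, seed = 7)
#' res <- run_pipeline(cfg)
#' res$verdict
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  dataset <- NULL
  if (config$mode == "synthetic") {
    params <- config$sim
    if (is.null(params$seed)) params$seed <- seed
    dataset <- stage("simulate", simulate_alignment(params))
    aln <- dataset$alignment
  } else {
    aln <- stage("read", read_fasta(config$input_fasta, config$labels))
  }

  stats_tab <- stage("stats", polymorphism_table(aln))
  fstm <- stage("fst", fst_matrix(aln, n_perm = config$n_perm, seed = seed + 101L))
  regions_present <- unique(aln$labels$region[!aln$labels$outgroup])
  pooling <- stage("pooling", {
    out <- list()
    k <- 0L
    for (r in intersect(c("AK", "GAL"), regions_present)) {
      k <- k + 1L
      pc <- pooling_check(aln, r, config$n_perm, seed + 300L + k)
      if (!is.null(pc)) out[[r]] <- pc
    }
    out
  })

  tree <- stage("tree", {
    mask <- partial_deletion_mask(aln, config$coverage)
    tr <- bootstrap_support(aln, mask, n = config$n_bootstrap, seed = seed + 202L)
    og <- outgroup_samples(aln)
    if (length(og)) root_with_outgroup(tr, og) else tr
  })
  verdict <- stage("verdict", concordance_verdict(tree))

  manifest <- list(
    package = "invorigin",
    version = as.character(packageVersion("invorigin")),
    r_version = R.version.string,
    mode = config$mode,
    seed = seed,
    stage_seeds = list(fst = seed + 101L, bootstrap = seed + 202L,
                       pooling = seed + 301L),
    n_perm = config$n_perm, n_bootstrap = config$n_bootstrap,
    coverage = config$coverage,
    sim = if (config$mode == "synthetic") unclass(dataset$params),
    verdict = verdict
  )

  res <- structure(list(alignment = aln, dataset = dataset, stats = stats_tab,
                        fst = fstm, pooling = pooling, tree = tree,
                        verdict = verdict, manifest = manifest, config = config),
                   class = "inv_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(out_dir, x)
  write_fasta(res$alignment, f("alignment.fasta"))
  write_labels(res$alignment, f("labels.tsv"))
  tab <- res$stats; class(tab) <- "data.frame"
  write.table(tab, f("polymorphism.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$fst$fst, f("fst.tsv"), sep = "\t", quote = FALSE, col.names = NA)
  write.table(res$fst$p, f("fst_pvalues.tsv"), sep = "\t", quote = FALSE, col.names = NA)
  ape::write.tree(res$tree, f("tree.nwk"))
  writeLines(res$verdict, f("verdict.txt"))
  jsonlite::write_json(res$manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.inv_pipeline <- function(x, ...) {
  cat("Breakpoint-genealogy pipeline (", x$config$mode, " mode, seed ",
      x$config$seed, ")\n", sep = "")
  if (x$config$mode == "synthetic") {
    cat("  origin model:", x$dataset$params$model, "\n")
  }
  cat("  sequences:", nrow(x$alignment$seqs), "x", ncol(x$alignment$seqs), "sites\n")
  cat("  verdict: molecular genealogy is", toupper(x$verdict),
      "with the cytological phylogeny\n")
  invisible(x)
}

#' @export
summary.inv_pipeline <- function(object, ...) {
  print(object)
  cat("\n"); print(object$stats)
  cat("\n"); print(object$fst)
  for (pc in object$pooling) {
    cat(sprintf("\nPooling check %s (%s vs %s): F_ST = %.4f, P = %.4f\n",
                pc$region, pc$arrangements[1], pc$arrangements[2],
                pc$fst, pc$p_value))
  }
  invisible(object)
}
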