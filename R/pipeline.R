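# End-to-end pipeline: simulate -> reconstruct -> evaluate, with a
# provenance record. Priors and configs are JSON; matrices and reports TSV;
# trees newick.

#' Read / write a prior set
#'
#' JSON mapping character name -> {state: probability}; probabilities are
#' the conditional indel-outcome distribution per character.
#'
#' @param path file path.
#' @param priors list of named numeric vectors, one per character.
#' @return [read_priors()] returns the list form used by [select_split()].
#' @export
read_priors <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) unlist(x))
}

#' @rdname read_priors
#' @export
write_priors <- function(priors, path) {
  jsonlite::write_json(lapply(priors, as.list), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Reconstruct a tree by a named method
#'
#' Dispatch helper shared by the pipeline and the command-line interface.
#'
#' @param m a [character_matrix()].
#' @param method "greedy", "ilp", "hybrid" or "nj".
#' @param priors optional priors (greedy/hybrid).
#' @param cutoff hybrid cell-count cutoff.
#' @param max_neighborhood_size,time_limit,gap_tolerance ILP controls.
#' @return an annotated \code{lineage_tree}.
#' @export
reconstruct <- function(m, method = c("greedy", "ilp", "hybrid", "nj"),
                        priors = NULL, cutoff = 200L,
                        max_neighborhood_size = 10000,
                        time_limit = 12600, gap_tolerance = 0) {
  method <- match.arg(method)
  tr <- switch(method,
    greedy = build_greedy(m, priors),
    nj = build_nj(m),
    ilp = {
      g <- optimize_neighborhood(m, max_neighborhood_size)
      solve_steiner(g, time_limit = time_limit,
                    gap_tolerance = gap_tolerance)
    },
    hybrid = build_hybrid(m, cutoff = cutoff, priors = priors,
                          max_neighborhood_size = max_neighborhood_size,
                          time_limit = time_limit,
                          gap_tolerance = gap_tolerance))
  annotate_ancestral_states(tr, m)
}

#' Run a simulate/reconstruct/evaluate pipeline
#'
#' @param config list with elements \code{seed}, \code{params} (a
#'   [sim_params()] or argument list for it), \code{methods} (character
#'   vector of reconstruction methods), and optional ILP controls
#'   (\code{cutoff}, \code{max_neighborhood_size}, \code{time_limit},
#'   \code{gap_tolerance}); \code{use_priors} applies the generating state
#'   probabilities as reconstruction priors.
#' @param outdir optional directory: matrices (TSV), trees (newick), a
#'   metrics report (TSV) and a provenance record (JSON) are written there.
#' @return list: \code{experiment}, \code{trees} (per method),
#'   \code{metrics} (data.frame: method, triplets thresholded and
#'   unthresholded, parsimony), \code{provenance}.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  set.seed(seed)
  params <- config$params
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  exp <- simulate_lineage(params)
  methods <- config$methods %||% "greedy"
  priors <- NULL
  if (isTRUE(config$use_priors)) {
    priors <- lapply(exp$state_probs, function(v) {
      q <- v / sum(v); names(q) <- seq_along(q); q
    })
  }
  trees <- list(); rows <- list()
  for (meth in methods) {
    tr <- reconstruct(exp$observed, method = meth, priors = priors,
                      cutoff = config$cutoff %||% 200L,
                      max_neighborhood_size =
                        config$max_neighborhood_size %||% 10000,
                      time_limit = config$time_limit %||% 12600,
                      gap_tolerance = config$gap_tolerance %||% 0)
    trees[[meth]] <- tr
    tc <- triplets_correct(exp$tree, tr,
                           n_triplets = config$n_triplets %||% 10000L)
    rows[[meth]] <- data.frame(
      method = meth, triplets_thresholded = tc$thresholded,
      triplets_unthresholded = tc$unthresholded,
      parsimony = parsimony_score(tr))
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  prov <- list(seed = seed, params = unclass(params), methods = methods,
               package_version = as.character(utils::packageVersion("lintree")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_character_matrix(exp$observed, file.path(outdir, "observed.tsv"))
    write_character_matrix(exp$truth, file.path(outdir, "truth.tsv"))
    write_newick(exp$tree, file.path(outdir, "true_tree.nwk"))
    for (meth in names(trees))
      write_newick(trees[[meth]], file.path(outdir,
                                            paste0("tree_", meth, ".nwk")))
    write.table(metrics, file.path(outdir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(experiment = exp, trees = trees, metrics = metrics, provenance = prov)
}
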