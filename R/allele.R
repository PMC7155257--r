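# Allele-table utilities. An allele table relates each (cell barcode,
# integration barcode) pair to its called indel allele and the number of
# supporting molecules (UMIs); it is the contract boundary downstream of
# read processing and upstream of the character matrix.

#' Construct / read / write an allele table
#'
#' Columns: \code{cellBC} (cell barcode), \code{intBC} (integration
#' barcode), \code{allele} (comma-joined per-cut-site states), \code{UMI}
#' (positive molecule count). Tab-separated on disk.
#'
#' @param df data.frame with the four columns above.
#' @return a data.frame of class \code{allele_table}.
#' @export
allele_table <- function(df) {
  need <- c("cellBC", "intBC", "allele", "UMI")
  if (!all(need %in% names(df))) stop("allele table needs columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$UMI < 1)) stop("UMI counts must be >= 1")
  df <- df[, need]
  class(df) <- c("allele_table", "data.frame")
  df
}

#' @param path file path.
#' @rdname allele_table
#' @export
read_allele_table <- function(path) {
  allele_table(read.delim(path, colClasses = c("character", "character",
                                               "character", "integer")))
}

#' @param tab an \code{allele_table}.
#' @rdname allele_table
#' @export
write_allele_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate indel prior probabilities from allele tables
#'
#' The prior of indel state s is q_s = f(s) / |I|: the number of
#' integration barcodes in which s was observed in at least one cell,
#' divided by the total number of integration barcodes. Low-prior indels
#' observed at high frequency are strong greedy-split candidates.
#'
#' @param tab an [allele_table()] (may span several clones).
#' @return named numeric vector q_s over distinct indel states (uncut "0"
#'   excluded), each in (0, 1].
#' @export
estimate_indel_priors <- function(tab) {
  if (!nrow(tab)) stop("empty allele table")
  intbcs <- unique(tab$intBC)
  states <- lapply(strsplit(tab$allele, ",", fixed = TRUE), trimws)
  rows <- rep(seq_len(nrow(tab)), lengths(states))
  long <- data.frame(intBC = tab$intBC[rows], state = unlist(states))
  long <- long[long$state != "0" & long$state != "-", ]
  f <- tapply(long$intBC, long$state, function(x) length(unique(x)))
  q <- as.numeric(f) / length(intbcs)
  names(q) <- names(f)
  q
}

#' Estimate the per-character mutation rate from a character matrix
#'
#' Under independent per-generation cutting at rate p over d generations,
#' the expected fraction of mutated characters per cell is
#' K/n = 1 - (1 - p)^d; inverting gives p = 1 - (1 - K/n)^(1/d). K is the
#' mean number of mutated (nonzero, non-missing) characters per cell.
#'
#' @param m a [character_matrix()].
#' @param d number of generations.
#' @return estimated p in [0, 1] (warning at saturation K = n).
#' @export
estimate_mutation_rate <- function(m, d) {
  m <- unclass(character_matrix(unclass(m)))
  K <- mean(rowSums(m > 0L))
  n <- ncol(m)
  if (K == 0) return(0)
  if (K >= n) {
    warning("all characters mutated in every cell; rate saturated at 1")
    return(1)
  }
  1 - (1 - K / n)^(1 / d)
}

#' Call independent clones from integration-barcode sets
#'
#' Iteratively selects the integration barcode shared among the most
#' unassigned cells, assigns every cell containing it to a new clone, and
#' repeats until at most \code{junk_fraction} of cells remain (these form
#' the "junk" clone). Within each clone, integration barcodes present in
#' fewer than \code{min_prevalence} of the clone's cells are dropped from
#' the clone's set.
#'
#' @param tab an [allele_table()].
#' @param junk_fraction stop threshold on the unassigned fraction
#'   (default 0.005).
#' @param min_prevalence intBC prevalence filter within a clone
#'   (default 0.1).
#' @return a \code{clone_assignment} list: \code{clones} (named vector,
#'   cell -> clone id; junk cells get "junk"), \code{intbc_sets} (per clone,
#'   named prevalence vector), \code{junk_cells}.
#' @export
call_clones <- function(tab, junk_fraction = 0.005, min_prevalence = 0.1) {
  if (!nrow(tab)) stop("empty allele table")
  cells <- unique(tab$cellBC)
  cell_bcs <- split(tab$intBC, tab$cellBC)
  cell_bcs <- lapply(cell_bcs, unique)
  unassigned <- cells
  assign <- setNames(rep(NA_character_, length(cells)), cells)
  clone_id <- 0L
  while (length(unassigned) > junk_fraction * length(cells)) {
    tallies <- table(unlist(cell_bcs[unassigned]))
    if (!length(tallies)) break
    best <- sort(names(tallies)[tallies == max(tallies)])[1L]
    members <- unassigned[vapply(cell_bcs[unassigned],
                                 function(s) best %in% s, logical(1))]
    clone_id <- clone_id + 1L
    assign[members] <- paste0("clone", clone_id)
    unassigned <- setdiff(unassigned, members)
  }
  assign[is.na(assign)] <- "junk"
  sets <- list()
  for (cl in setdiff(unique(assign), "junk")) {
    mem <- names(assign)[assign == cl]
    prev <- table(unlist(cell_bcs[mem])) / length(mem)
    prev <- prev[prev >= min_prevalence]
    sets[[cl]] <- setNames(as.numeric(prev), names(prev))
  }
  structure(list(clones = assign, intbc_sets = sets,
                 junk_cells = names(assign)[assign == "junk"]),
            class = "clone_assignment")
}

#' Detect doublets from allele conflicts and clone membership
#'
#' Intra-clone doublets report conflicting alleles on shared integration
#' barcodes: the intra score is the fraction of a cell's UMIs supporting
#' non-plurality alleles of their intBC. Inter-clone doublets blend two
#' clones' intBC sets: the membership m_{i,k} of cell i in clone k is the
#' prevalence-weighted fraction of clone k's intBCs observed in the cell,
#' normalized across clones to m'_{i,k}; a low m' for the assigned clone
#' flags a doublet.
#'
#' @param tab an [allele_table()].
#' @param clones a [call_clones()] result (needed for the inter score).
#' @param intra_threshold flag cells with intra score >= this (default 0.35).
#' @param inter_threshold flag cells whose assigned-clone m' < this
#'   (default 0.6).
#' @return data.frame per cell: \code{cellBC}, \code{intra_score},
#'   \code{inter_score} (assigned-clone m'), \code{flag_intra},
#'   \code{flag_inter}.
#' @export
detect_doublets <- function(tab, clones = NULL, intra_threshold = 0.35,
                            inter_threshold = 0.6) {
  cells <- unique(tab$cellBC)
  intra <- vapply(cells, function(cb) {
    rows <- tab[tab$cellBC == cb, ]
    if (!sum(rows$UMI)) stop("cell with zero UMIs: ", cb)
    conflicting <- 0
    for (ib in unique(rows$intBC)) {
      r <- rows[rows$intBC == ib, ]
      umis <- tapply(r$UMI, r$allele, sum)
      conflicting <- conflicting + sum(umis) - max(umis)
    }
    conflicting / sum(rows$UMI)
  }, numeric(1))
  out <- data.frame(cellBC = cells, intra_score = intra,
                    flag_intra = intra >= intra_threshold,
                    stringsAsFactors = FALSE)
  if (!is.null(clones)) {
    sets <- clones$intbc_sets
    cl_names <- names(sets)
    cell_bcs <- lapply(split(tab$intBC, tab$cellBC), unique)
    mship <- t(vapply(cells, function(cb) {
      obs <- cell_bcs[[cb]]
      m <- vapply(cl_names, function(k) {
        p <- sets[[k]]
        sum(p[names(p) %in% obs]) / sum(p)
      }, numeric(1))
      tot <- sum(m)
      if (tot > 0) m / tot else m
    }, numeric(length(cl_names))))
    colnames(mship) <- cl_names
    assigned <- clones$clones[cells]
    inter <- vapply(seq_along(cells), function(i) {
      if (assigned[i] %in% cl_names) mship[i, assigned[i]] else NA_real_
    }, numeric(1))
    out$inter_score <- inter
    out$flag_inter <- !is.na(inter) & inter < inter_threshold
    attr(out, "membership") <- mship
  }
  out
}

#' Inject synthetic doublets into an allele table
#'
#' Forms \code{n} doublets by combining the UMIs (rows) of two randomly
#' chosen cells under a new cell barcode; intra-mode parents come from the
#' same clone, inter-mode parents from two different clones.
#'
#' @param tab an [allele_table()].
#' @param n number of doublets (default 200).
#' @param mode "intra" or "inter".
#' @param clones a [call_clones()] result (required for mode selection).
#' @return list: \code{table} (augmented \code{allele_table}),
#'   \code{labels} (named logical: TRUE for injected doublets).
#' @export
simulate_doublets <- function(tab, n = 200L, mode = c("intra", "inter"),
                              clones = NULL) {
  mode <- match.arg(mode)
  if (is.null(clones)) clones <- call_clones(tab)
  asg <- clones$clones
  real <- names(asg)[asg != "junk"]
  if (mode == "inter" && length(unique(asg[real])) < 2L)
    stop("inter-mode doublet simulation needs >= 2 clones")
  rows <- tab
  labels <- setNames(rep(FALSE, length(unique(tab$cellBC))),
                     unique(tab$cellBC))
  tallies <- table(asg[real])
  big <- names(tallies)[tallies >= 2L]
  if (mode == "intra" && !length(big))
    stop("intra-mode doublet simulation needs a clone with >= 2 cells")
  if (n > 0L) for (i in seq_len(n)) {
    if (mode == "intra") {
      cl <- if (length(big) == 1L) big else sample(big, 1L)
      pool <- real[asg[real] == cl]
      pair <- sample(pool, 2L)
    } else {
      cls <- sample(unique(asg[real]), 2L)
      pair <- c(sample(real[asg[real] == cls[1L]], 1L),
                sample(real[asg[real] == cls[2L]], 1L))
    }
    newid <- paste0("doublet", i)
    dbl <- tab[tab$cellBC %in% pair, ]
    dbl$cellBC <- newid
    rows <- rbind(rows, dbl)
    labels[newid] <- TRUE
  }
  list(table = allele_table(rows), labels = labels)
}

#' Tune the doublet decision rule on labeled datasets
#'
#' Grid-searches thresholds 0, 0.05, ..., 1.0 (21 points) and returns the
#' threshold maximizing the F-measure (harmonic mean of precision and
#' recall), averaged across datasets. Scores are compared with
#' \code{score >= threshold} flagging a doublet (pass \code{1 - m'} style
#' scores for the inter detector so that higher means more doublet-like).
#'
#' @param datasets list of lists with elements \code{scores} (named numeric)
#'   and \code{labels} (named logical, TRUE = doublet).
#' @return list(threshold, precision, recall, F, grid) where \code{grid}
#'   holds the per-threshold averaged metrics.
#' @export
tune_doublet_threshold <- function(datasets) {
  if (!length(datasets)) stop("no labeled datasets")
  grid <- seq(0, 1, by = 0.05)
  per <- vapply(grid, function(th) {
    pr <- vapply(datasets, function(ds) {
      sc <- ds$scores; lb <- ds$labels[names(sc)]
      if (!any(lb)) stop("no positives in labels")
      called <- sc >= th
      tp <- sum(called & lb)
      prec <- if (sum(called)) tp / sum(called) else 0
      rec <- tp / sum(lb)
      f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      c(prec, rec, f)
    }, numeric(3))
    rowMeans(pr)
  }, numeric(3))
  best <- which.max(per[3L, ])
  list(threshold = grid[best], precision = per[1L, best],
       recall = per[2L, best], F = per[3L, best],
       grid = data.frame(threshold = grid, precision = per[1L, ],
                         recall = per[2L, ], F = per[3L, ]))
}

#' Simulate a synthetic allele table with known clone structure
#'
#' Generates clones with disjoint integration-barcode sets (optionally
#' leaking a fraction of intBCs across clones), per-cut-site indel states
#' drawn from a shared skewed state distribution, per-intBC detection
#' dropout, and log-normal-ish UMI counts. All operations in this module
#' are testable against the generating truth.
#'
#' @param n_clones number of clones.
#' @param cells_per_clone cells per clone.
#' @param intbc_per_clone integration barcodes per clone.
#' @param n_sites cut sites per integration barcode (allele length).
#' @param n_states possible indel states per site.
#' @param mutate_prob probability a site is mutated in a founder allele.
#' @param dropout per-(cell, intBC) detection failure rate.
#' @param leak_rate fraction of intBCs additionally shared with another
#'   clone.
#' @return list: \code{table} ([allele_table()]), \code{clones} (true cell
#'   -> clone map), \code{state_probs} (generating per-state probabilities).
#' @export
simulate_allele_table <- function(n_clones = 3L, cells_per_clone = 60L,
                                  intbc_per_clone = 8L, n_sites = 3L,
                                  n_states = 20L, mutate_prob = 0.5,
                                  dropout = 0.1, leak_rate = 0) {
  state_probs <- draw_state_distribution(n_states, family = "negbin",
                                         theta = 0, p = 1)
  rows <- list()
  clone_of <- character(0)
  for (k in seq_len(n_clones)) {
    ibcs <- sprintf("iBC%02d_%02d", k, seq_len(intbc_per_clone))
    if (leak_rate > 0 && n_clones > 1L) {
      n_leak <- rbinom(1L, intbc_per_clone, leak_rate)
      if (n_leak > 0) {
        other <- sample(setdiff(seq_len(n_clones), k), 1L)
        ibcs[seq_len(n_leak)] <- sprintf("iBC%02d_%02d", other,
                                         seq_len(n_leak))
      }
    }
    # clone-founder alleles per intBC: cells inherit them (clonal), with
    # some per-cell extra editing
    founder <- lapply(ibcs, function(ib) {
      s <- ifelse(runif(n_sites) < mutate_prob,
                  sample.int(n_states, n_sites, replace = TRUE,
                             prob = state_probs), 0L)
      as.integer(s)
    })
    for (cidx in seq_len(cells_per_clone)) {
      cb <- sprintf("cell%02d_%03d", k, cidx)
      clone_of[cb] <- paste0("trueclone", k)
      for (j in seq_along(ibcs)) {
        if (runif(1) < dropout) next
        al <- founder[[j]]
        extra <- al == 0L & runif(n_sites) < mutate_prob / 2
        al[extra] <- sample.int(n_states, sum(extra), replace = TRUE,
                                prob = state_probs)
        rows[[length(rows) + 1L]] <- data.frame(
          cellBC = cb, intBC = ibcs[j],
          allele = paste(al, collapse = ","),
          UMI = max(1L, round(exp(rnorm(1, log(8), 0.6)))),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = allele_table(do.call(rbind, rows)), clones = clone_of,
       state_probs = setNames(state_probs, seq_len(n_states)))
}
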