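# Character matrices: cells x target-site characters, integer indel states.
# 0 = uncut, MISSING_STATE (-1) = dropout. State labels are namespaced per
# character: state 3 in character 1 is unrelated to state 3 in character 2.

#' Construct a character matrix
#'
#' @param x integer matrix (cells in rows, characters in columns). Row names
#'   are cell identifiers and must be unique; column names are character
#'   names (generated as \code{c1..cm} when absent). Entries are nonnegative
#'   integer states or [MISSING_STATE].
#' @return an integer matrix of class \code{character_matrix}.
#' @export
character_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) && nrow(x) > 0)
    rownames(x) <- paste0("cell", seq_len(nrow(x)))
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("c", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate cell ids in character matrix")
  if (any(is.na(x))) stop("NA entries; use MISSING_STATE (-1) for missing data")
  if (any(x < -1L)) stop("states must be nonnegative integers or -1 (missing)")
  class(x) <- c("character_matrix", class(x))
  x
}

#' Validate a character matrix
#'
#' Checks the structural invariants (unique cell ids, rectangular shape,
#' no negative states other than the missing sentinel) and summarises
#' missingness.
#'
#' @param m a [character_matrix()] (or coercible matrix).
#' @return a list with elements \code{valid}, \code{n_cells},
#'   \code{n_characters}, \code{missing_fraction} (per character) and
#'   \code{overall_missing}.
#' @export
validate_matrix <- function(m) {
  m <- character_matrix(unclass(m))
  miss <- colMeans(m == MISSING_STATE)
  list(
    valid = TRUE,
    n_cells = nrow(m),
    n_characters = ncol(m),
    missing_fraction = miss,
    overall_missing = mean(m == MISSING_STATE)
  )
}

#' One-hot binarize a multi-state character matrix
#'
#' Factorizes each multi-state character into one binary character per
#' observed (character, nonzero state) pair. A cell carries 1 exactly in the
#' column of its observed state; a missing entry expands to missing across
#' all of that character's columns.
#'
#' @param m a [character_matrix()].
#' @return a \code{character_matrix} with binary states (plus missing); the
#'   attribute \code{"origin"} maps output columns to (character, state).
#' @export
binarize_matrix <- function(m) {
  m <- character_matrix(unclass(m))
  cols <- list(); origin <- list()
  for (i in seq_len(ncol(m))) {
    v <- m[, i]
    states <- sort(unique(v[v > 0L]))
    for (s in states) {
      b <- ifelse(v == MISSING_STATE, MISSING_STATE, as.integer(v == s))
      cols[[length(cols) + 1L]] <- b
      origin[[length(origin) + 1L]] <- c(char = i, state = s)
    }
  }
  if (!length(cols)) {
    out <- matrix(integer(0), nrow = nrow(m), ncol = 0,
                  dimnames = list(rownames(m), NULL))
  } else {
    out <- do.call(cbind, cols)
    rownames(out) <- rownames(m)
    colnames(out) <- vapply(origin, function(o)
      paste0(colnames(m)[o[["char"]]], "_s", o[["state"]]), character(1))
  }
  out <- character_matrix(out)
  attr(out, "origin") <- do.call(rbind, origin)
  out
}

#' Character compatibility (set criterion)
#'
#' Two binary characters with mutated-cell sets O1 and O2 are compatible iff
#' O1 is a subset of O2, O2 a subset of O1, or the sets are disjoint; a pair
#' of compatible characters can coexist in a perfect phylogeny.
#'
#' @param o1,o2 vectors of cell identifiers (the cells mutated for each
#'   character).
#' @return logical.
#' @export
characters_compatible <- function(o1, o2) {
  o1 <- unique(o1); o2 <- unique(o2)
  inter <- length(intersect(o1, o2))
  inter == 0L || inter == length(o1) || inter == length(o2)
}

# cells to remove for one binary pair: min(|O1&O2|, |O1\O2|, |O2\O1|) if all
# three nonempty, else 0.
.pair_removal <- function(o1, o2) {
  ab <- length(intersect(o1, o2))
  a <- length(setdiff(o1, o2)); b <- length(setdiff(o2, o1))
  if (ab == 0L || a == 0L || b == 0L) 0L else min(ab, a, b)
}

#' Minimum compatibility distance between two characters
#'
#' The minimum number of cells whose removal makes every pair of
#' (state-of-i, state-of-j) mutated-cell sets compatible, after one-hot
#' binarization. Missing cells are excluded from the sets. Exhaustive search
#' over removal subsets is used up to \code{exact_max} cells; above that, a
#' greedy heuristic removes the cell participating in the most violated
#' pairs until compatibility.
#'
#' @param m a [character_matrix()].
#' @param char_i,char_j character column indices.
#' @param exact_max exhaustive-search cell-count limit (default 12).
#' @return list with \code{distance} (integer) and \code{method}
#'   ("exact" or "greedy").
#' @export
min_compatibility_distance <- function(m, char_i, char_j, exact_max = 12L) {
  m <- character_matrix(unclass(m))
  if (char_i < 1L || char_i > ncol(m) || char_j < 1L || char_j > ncol(m))
    stop("character index out of range")
  vi <- m[, char_i]; vj <- m[, char_j]
  sets_i <- lapply(sort(unique(vi[vi > 0L])), function(s)
    rownames(m)[!is.na(vi) & vi == s])
  sets_j <- lapply(sort(unique(vj[vj > 0L])), function(s)
    rownames(m)[!is.na(vj) & vj == s])
  all_ok <- function(keep) {
    for (a in sets_i) for (b in sets_j) {
      if (!characters_compatible(intersect(a, keep), intersect(b, keep)))
        return(FALSE)
    }
    TRUE
  }
  if (all_ok(rownames(m))) return(list(distance = 0L, method = "exact"))
  involved <- unique(c(unlist(sets_i), unlist(sets_j)))
  if (length(involved) <= exact_max) {
    for (k in seq_along(involved)) {
      subs <- combn(involved, k, simplify = FALSE)
      for (rm in subs) {
        if (all_ok(setdiff(rownames(m), rm)))
          return(list(distance = k, method = "exact"))
      }
    }
    return(list(distance = length(involved), method = "exact"))
  }
  # greedy: repeatedly drop the cell in the most violated pairs
  keep <- rownames(m); removed <- 0L
  repeat {
    if (all_ok(keep)) break
    score <- setNames(numeric(length(keep)), keep)
    for (a in sets_i) for (b in sets_j) {
      ka <- intersect(a, keep); kb <- intersect(b, keep)
      if (!characters_compatible(ka, kb)) {
        cells <- union(ka, kb)
        score[cells] <- score[cells] + 1
      }
    }
    drop <- names(which.max(score))
    keep <- setdiff(keep, drop); removed <- removed + 1L
  }
  list(distance = removed, method = "greedy")
}

#' Read / write a character matrix
#'
#' Tab-separated text: header row of character names, first column
#' \code{cell_id}, entries integer states with \code{"-"} (also accepted:
#' \code{"NA"}, \code{"?"}) for missing.
#'
#' @param path file path.
#' @return [read_character_matrix()] returns a \code{character_matrix}.
#' @export
read_character_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = NULL)
  if (ncol(df) < 2L) stop("expected a cell_id column plus >=1 character column")
  ids <- df[[1L]]
  x <- as.matrix(df[, -1L, drop = FALSE])
  x[x %in% c("-", "NA", "?")] <- "-1"
  suppressWarnings(xi <- matrix(as.integer(x), nrow = nrow(x),
                                dimnames = list(ids, colnames(x))))
  if (any(is.na(xi))) {
    bad <- which(is.na(xi), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer state at row %d (cell '%s'), column '%s'",
                 bad[1L], ids[bad[1L]], colnames(x)[bad[2L]]))
  }
  character_matrix(xi)
}

#' @param m a [character_matrix()].
#' @rdname read_character_matrix
#' @export
write_character_matrix <- function(m, path) {
  m <- character_matrix(unclass(m))
  out <- matrix(as.character(unclass(m)), nrow = nrow(m),
                dimnames = dimnames(m))
  out[unclass(m) == MISSING_STATE] <- "-"
  df <- data.frame(cell_id = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
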