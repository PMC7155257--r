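# Forward simulation of lineage-tracing experiments. A full binary tree of D
# divisions is grown; after each division every still-uncut character of each
# daughter mutates independently with probability p, choosing its indel state
# from the per-character state distribution; mutated characters never change
# again (Cas9 irreversibility). Leaves are subsampled and dropout masks
# entries to MISSING_STATE.

#' Simulation parameters
#'
#' @param num_characters C, number of recording target sites.
#' @param num_states S, number of possible indel states per character.
#' @param p per-character, per-generation mutation probability (total cutting
#'   probability; the uncut probability each generation is 1 - p). May be a
#'   vector of length C for per-character rates (phased recorders).
#' @param depth D, number of binary cell divisions (generations).
#' @param subsample M, fraction of the 2^D final cells that are sampled;
#'   round(2^D * M) leaves are drawn uniformly without replacement.
#' @param dropout per-character dropout rates d_c. Either a vector of length
#'   C, or a single mean rate from which per-character rates are drawn from a
#'   Beta distribution with that mean (see \code{dropout_concentration}).
#' @param state_family state-distribution family for indel outcome
#'   probabilities: "negbin" (negative-binomial-shaped, NB(5, 0.5) mass on
#'   1..S, a skewed distribution like empirical indel spectra) or "uniform".
#' @param theta mixture weight between Unif(0,1) draws (theta = 1) and the
#'   skewed family (theta = 0) when generating per-state probabilities.
#' @param unique_states if TRUE, simulate in perfect-phylogeny mode: at every
#'   division each daughter edge receives exactly one mutation, in a
#'   uniformly chosen character not yet mutated along that lineage, with a
#'   globally novel state. The resulting matrix always admits a perfect
#'   phylogeny and every division is identifiable.
#' @param dropout_concentration Beta concentration used when \code{dropout}
#'   is a scalar mean (default 10).
#' @return a \code{sim_params} list.
#' @export
sim_params <- function(num_characters = 40L, num_states = 40L, p = 0.025,
                       depth = 11L, subsample = 400 / 2^11,
                       dropout = 0.17, state_family = c("negbin", "uniform"),
                       theta = 0, unique_states = FALSE,
                       dropout_concentration = 10) {
  state_family <- match.arg(state_family)
  stopifnot(num_characters >= 1L, num_states >= 1L, depth >= 1L,
            all(p >= 0 & p <= 1), subsample > 0, subsample <= 1,
            all(dropout >= 0 & dropout <= 1), theta >= 0, theta <= 1)
  if (round(2^depth * subsample) < 1) stop("subsample * 2^depth < 1 cell")
  structure(list(num_characters = as.integer(num_characters),
                 num_states = as.integer(num_states), p = p,
                 depth = as.integer(depth), subsample = subsample,
                 dropout = dropout, state_family = state_family,
                 theta = theta, unique_states = unique_states,
                 dropout_concentration = dropout_concentration),
            class = "sim_params")
}

#' Draw a per-state probability distribution for one character
#'
#' Draws S raw values from the mixture theta * Unif(0,1) + (1 - theta) * F,
#' where F is the skewed surrogate family (normalized NB(5, 0.5) probability
#' mass shuffled over states), then normalizes the values to sum to the total
#' mutation probability p. The conditional state distribution given a
#' mutation is the returned vector divided by p.
#'
#' @param S number of states.
#' @param family "negbin" or "uniform" skewed component.
#' @param theta mixture weight on the uniform component.
#' @param p total per-generation mutation probability.
#' @return numeric vector of S positive values summing to p.
#' @export
draw_state_distribution <- function(S, family = c("negbin", "uniform"),
                                    theta = 0, p = 1) {
  family <- match.arg(family)
  if (S < 1L) stop("S must be >= 1")
  u <- runif(S)
  skew <- switch(family,
    negbin = {
      w <- stats::dnbinom(seq_len(S) - 1L, size = 5, prob = 0.5)
      w <- w / sum(w)
      # invert the NB cdf at uniform draws: skewed, heavy on few states
      w[sample.int(S)] * S * runif(S, 0.5, 1.5)
    },
    uniform = runif(S))
  raw <- theta * u + (1 - theta) * skew
  raw <- pmax(raw, .Machine$double.eps)
  raw / sum(raw) * p
}

.dropout_rates <- function(params) {
  C <- params$num_characters
  d <- params$dropout
  if (length(d) == C) return(d)
  if (length(d) != 1L) stop("dropout must be scalar or length C")
  if (d == 0) return(rep(0, C))
  k <- params$dropout_concentration
  rbeta(C, shape1 = d * k, shape2 = (1 - d) * k)
}

#' Simulate a lineage-tracing experiment
#'
#' Grows a full binary tree of \code{depth} divisions under the
#' irreversible-mutation model, samples leaves, applies dropout, and returns
#' the ground truth alongside the observed data. All randomness flows from
#' the R random number generator (set a seed beforehand for
#' reproducibility).
#'
#' @param params a [sim_params()] object.
#' @return a \code{sim_experiment} list: \code{tree} (true
#'   \code{lineage_tree} over sampled leaves, single-child chains collapsed,
#'   edge lengths = divisions, annotated with character strings),
#'   \code{truth} (pre-dropout [character_matrix()]), \code{observed}
#'   (post-dropout), \code{params}, \code{state_probs} (per-character list
#'   of generated state probabilities summing to p) and \code{dropout_rates}.
#' @export
simulate_lineage <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  C <- params$num_characters; S <- params$num_states; D <- params$depth
  p <- rep(params$p, length.out = C)
  state_probs <- lapply(seq_len(C), function(i)
    draw_state_distribution(S, params$state_family, params$theta, p[i]))
  cond_probs <- lapply(state_probs, function(v) v / sum(v))

  n_final <- 2^D
  # states of the current generation, cells x characters
  cur <- matrix(0L, nrow = 1L, ncol = C)
  next_state <- 1L  # global novel-state counter for unique_states mode
  for (gen in seq_len(D)) {
    cur <- cur[rep(seq_len(nrow(cur)), each = 2L), , drop = FALSE]
    if (params$unique_states) {
      for (r in seq_len(nrow(cur))) {
        free <- which(cur[r, ] == 0L)
        if (length(free)) {
          ch <- if (length(free) == 1L) free else sample(free, 1L)
          cur[r, ch] <- next_state
          next_state <- next_state + 1L
        }
      }
    } else {
      for (i in seq_len(C)) {
        unmut <- cur[, i] == 0L
        hit <- unmut & (runif(nrow(cur)) < p[i])
        if (any(hit)) {
          cur[hit, i] <- sample.int(S, sum(hit), replace = TRUE,
                                    prob = cond_probs[[i]])
        }
      }
    }
  }
  n_samp <- round(n_final * params$subsample)
  samp <- sort(sample.int(n_final, n_samp))
  truth <- cur[samp, , drop = FALSE]
  rownames(truth) <- paste0("cell", seq_len(n_samp))
  colnames(truth) <- paste0("c", seq_len(C))
  truth <- character_matrix(truth)

  d_c <- .dropout_rates(params)
  obs <- unclass(truth)
  for (i in seq_len(C)) {
    mask <- runif(n_samp) < d_c[i]
    obs[mask, i] <- MISSING_STATE
  }
  obs <- character_matrix(obs)

  tree <- .true_tree_from_indices(samp, D, truth)
  structure(list(tree = tree, truth = truth, observed = obs, params = params,
                 state_probs = state_probs, dropout_rates = d_c),
            class = "sim_experiment")
}

# Reconstruct the true (collapsed) tree over sampled leaf indices of a full
# binary tree of depth D. Leaf i (1-based) has ancestor path given by its
# bit representation. Edge lengths = number of divisions merged.
.true_tree_from_indices <- function(samp, D, truth) {
  n <- length(samp)
  # ancestor code of leaf i at generation g: (i-1) >> (D - g)
  # Build the collapsed tree recursively over sorted leaf indices.
  build <- function(lo, hi, gen) {
    # leaves samp[lo..hi] all share the ancestor at generation 'gen'
    if (lo == hi) {
      return(list(label = rownames(truth)[lo], edge_len = NA_real_,
                  gen_born = gen, children = list(),
                  states = unclass(truth)[lo, ]))
    }
    g <- gen
    repeat {
      g <- g + 1L
      if (g > D) break
      # split leaves by the bit at generation g
      bits <- bitwAnd(bitwShiftR(samp[lo:hi] - 1L, D - g), 1L)
      if (any(bits == 0L) && any(bits == 1L)) break
    }
    mid <- lo + sum(bitwAnd(bitwShiftR(samp[lo:hi] - 1L, D - g), 1L) == 0L) - 1L
    left <- build(lo, mid, g)
    right <- build(mid + 1L, hi, g)
    left$edge_len <- (left$gen_born %||% D) - g
    right$edge_len <- (right$gen_born %||% D) - g
    # leaves live at generation D
    if (!length(left$children)) left$edge_len <- D - g
    if (!length(right$children)) right$edge_len <- D - g
    list(label = "", edge_len = NA_real_, gen_born = g,
         children = list(left, right), states = NULL)
  }
  node <- build(1L, n, 0L)
  g0 <- if (length(node$children)) node$gen_born else 0L
  tr <- flatten_tree(node)
  # root label and zero-length root edge
  tr$label[tree_root(tr)] <- "root"
  tr$edge_len[tree_root(tr)] <- 0
  # generation depth: divisions before the first split plus path lengths
  tr$depth_gen <- .gen_depths(tr) + g0
  tr
}

# accumulated edge-length depth per node
.gen_depths <- function(tr) {
  d <- numeric(length(tr$parent))
  for (v in tree_preorder(tr)) {
    p <- tr$parent[v]
    d[v] <- if (is.na(p)) 0 else d[p] + tr$edge_len[v]
  }
  d
}

#' Inject parallel-evolution events into a perfect phylogeny
#'
#' Starting from a perfect-phylogeny experiment simulated with
#' \code{40 - k} characters (no dropout), repeats \code{k} times: picks a
#' node at generation \code{d} of the true tree, picks one grandchild
#' through each of its two children, and places the identical mutation of a
#' fresh character on both child-to-grandchild paths. The output has the
#' original characters plus \code{k} new ones, each mutated on exactly two
#' independent branches (homoplasy).
#'
#' @param base a \code{sim_experiment} from [simulate_lineage()] with
#'   \code{unique_states = TRUE} and no dropout.
#' @param k number of parallel events to inject.
#' @param d generation (division depth) at which events are placed; must be
#'   < depth - 1.
#' @return a \code{sim_experiment} with augmented matrices and a
#'   \code{parallel_events} record (character, state, and the two clades).
#' @export
inject_parallel_evolution <- function(base, k, d) {
  stopifnot(inherits(base, "sim_experiment"))
  D <- base$params$depth
  if (d >= D - 1L) stop("d must be < depth - 1")
  tr <- base$tree
  if (k == 0L) return(base)
  gen <- tr$depth_gen %||% node_depths(tr)
  below <- leaves_below(tr)
  truth <- unclass(base$truth)
  C0 <- ncol(truth)
  newcols <- matrix(0L, nrow = nrow(truth), ncol = k)
  events <- vector("list", k)
  # candidate nodes: internal, born at generation <= d, with a split at or
  # below d such that two grandchild branches exist
  cand <- which(!tr$is_leaf & gen <= d & lengths(tr$children) >= 2L)
  if (!length(cand)) stop("insufficient nodes at depth d")
  for (e in seq_len(k)) {
    v <- if (length(cand) == 1L) cand else sample(cand, 1L)
    kids <- tr$children[[v]]
    two <- sample(kids, 2L)
    pick_grandchild <- function(ch) {
      gk <- tr$children[[ch]]
      if (!length(gk)) ch else if (length(gk) == 1L) gk else sample(gk, 1L)
    }
    g1 <- pick_grandchild(two[1L]); g2 <- pick_grandchild(two[2L])
    leaves1 <- match(tr$label[below[[g1]]], rownames(truth))
    leaves2 <- match(tr$label[below[[g2]]], rownames(truth))
    newcols[c(leaves1, leaves2), e] <- 1L
    events[[e]] <- list(character = C0 + e, state = 1L,
                        clade1 = rownames(truth)[leaves1],
                        clade2 = rownames(truth)[leaves2])
  }
  colnames(newcols) <- paste0("c", C0 + seq_len(k))
  truth2 <- character_matrix(cbind(truth, newcols))
  base$truth <- truth2
  base$observed <- truth2   # no dropout in this regime
  base$parallel_events <- events
  base
}

#' Base-editor simulation preset
#'
#' Simulated base-editing recorders: the product of characters and states is
#' held at 400, dropout is 10 percent, the per-character mutation rate is
#' 1.04 percent, and 400 cells are sampled from a tree of depth 10, with a
#' negative-binomial-shaped editing-outcome distribution.
#'
#' @param num_characters one of 40, 50, 80, 100 (must divide 400).
#' @return a [sim_params()] object.
#' @export
preset_base_editor <- function(num_characters = 40L) {
  if (400L %% num_characters != 0L)
    stop("num_characters must divide 400")
  sim_params(num_characters = num_characters,
             num_states = 400L %/% num_characters,
             p = 0.0104, depth = 10L, subsample = 400 / 2^10,
             dropout = 0.10, state_family = "negbin", theta = 0)
}

#' Phased-recorder simulation preset
#'
#' 50 characters, 10 states; per-character mutation rates are staggered in
#' blocks of five: m_i = p0 * (1 + e_j * floor(i / 5)) with characters
#' indexed i = 1..50 and p0 = 0.025, so the max/min rate ratio is
#' 1 + 10 * e_j.
#'
#' @param e_j experiment scalar, one of 0, 0.05, 0.1, 0.25, 0.5 (any
#'   nonnegative value accepted).
#' @return a [sim_params()] object with vector-valued \code{p}.
#' @export
preset_phased_recorder <- function(e_j = 0) {
  p0 <- 0.025
  i <- 1:50
  rates <- p0 * (1 + e_j * (i %/% 5L))
  sim_params(num_characters = 50L, num_states = 10L, p = rates,
             depth = 11L, subsample = 400 / 2^11, dropout = 0.17,
             state_family = "negbin", theta = 0)
}
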