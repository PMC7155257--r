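# Parallel-evolution theory: moments of X (number of independent occurrences
# of a particular mutation in a full binary tree of height h) and Y (the
# fraction of leaves carrying it), under per-generation mutation probability
# p and conditional state probability q. Mutation occurs after division and
# is irreversible: an edge into a depth-t node mutates with probability
# p*q*(1-p)^(t-1), and such an event fixes 2^(h-t) of the 2^h leaves, so
# Y = sum_t 2^(-t) B_t where B_t counts the generation-t events.
#
# E(X), E(Y) and the Var(X) bound follow the closed forms; E(XY), Var(Y) and
# exact Var(X) are computed by O(h) moment recursions on the unmutated-cell
# Markov chain N_t (N_1 = 1, A_t ~ Bin(2 N_t, p), B_t ~ Bin(A_t, q),
# N_{t+1} = 2 N_t - A_t), verified against exhaustive enumeration at small h.

#' Theory parameters
#' @param p per-generation mutation probability of the character.
#' @param q conditional probability of the particular mutated state.
#' @param h tree height in generations.
#' @return a \code{theory_params} list.
#' @export
theory_params <- function(p, q, h) {
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1, h >= 1)
  structure(list(p = p, q = q, h = as.integer(h)), class = "theory_params")
}

# moment recursions for N_t (E N, Var N) and the covariances of the B_t.
# Working with Cov(B_s, B_t) directly avoids the catastrophic cancellation
# of E(B_s B_t) - E(B_s) E(B_t), whose common (2-2p)^(s+t) leading term
# dwarfs the covariance at large h.
#   Var N_{t+1} = (2-2p)^2 Var N_t + 2 p (1-p) E N_t
#   Var B_t     = 2pq(1-q) E N_t + 2p(1-p) q^2 E N_t + 4 p^2 q^2 Var N_t
#   Cov(B_s,B_t) = 4 p^2 q^2 (1-p) (2-2p)^(t-s-1) (2 Var N_s - E N_s), s < t
.bt_moments <- function(p, q, h) {
  EN <- numeric(h); VN <- numeric(h)
  EN[1L] <- 1; VN[1L] <- 0
  if (h > 1L) for (t in 1:(h - 1L)) {
    EN[t + 1L] <- (2 - 2 * p) * EN[t]
    VN[t + 1L] <- (2 - 2 * p)^2 * VN[t] + 2 * p * (1 - p) * EN[t]
  }
  EB <- 2 * p * q * EN
  VB <- 2 * p * q * (1 - q) * EN + 2 * p * (1 - p) * q^2 * EN +
    4 * p^2 * q^2 * VN
  covB <- function(s, t) {
    if (s == t) return(VB[s])
    lo <- min(s, t); hi <- max(s, t)
    4 * p^2 * q^2 * (1 - p) * (2 - 2 * p)^(hi - lo - 1L) *
      (2 * VN[lo] - EN[lo])
  }
  list(EN = EN, VN = VN, EB = EB, VB = VB, covB = covB)
}

# Cov(X, Y) = sum_s sum_t 2^(-t) Cov(B_s, B_t). The naive double sum is
# numerically unstable at large h: the s > t block carries a (2-2p)^h
# component whose coefficient S = sum_t (2 Var N_t - E N_t) (2(2-2p))^(-t)
# cancels exactly in the infinite sum (verified symbolically), leaving only
# the (2(1-p)^2)^h behavior. We therefore evaluate that block through the
# closed-form tail of S. With r = 2-2p and alpha = 4p(1-p)/(1-2p),
# 2 Var N_t - E N_t = alpha r^(2t-3) - (alpha + r) r^(t-2), and
# S(n) = -alpha r^(-3) (1-p)^(n+1)/p + (alpha + r) r^(-2) 2^(-n).
.cov_xy_stable <- function(p, q, h, mom) {
  if (p == 0 || q == 0) return(0)
  r <- 2 - 2 * p
  G <- 4 * p^2 * q^2 * (1 - p) * (2 * mom$VN - mom$EN)
  # diagonal
  D <- sum(2^-(1:h) * mom$VB)
  # s < t block: sum_s G[s] * 2^(-(s+1)) (1 - (1-p)^(h-s)) / p
  A <- sum(G * 2^-(seq_len(h) + 1L) * (1 - (1 - p)^(h - seq_len(h))) / p)
  # s > t block via the stable tail of S
  C <- 0
  if (h >= 2L) {
    if (abs(1 - 2 * p) < 1e-9) {
      # near the p = 0.5 singularity fall back to the direct sum (r ~ 1,
      # no large powers, the direct sum is stable here)
      for (t in 1:(h - 1L)) for (s in (t + 1L):h) {
        C <- C + 2^-t * 4 * p^2 * q^2 * (1 - p) * r^(s - t - 1L) *
          (2 * mom$VN[t] - mom$EN[t])
      }
    } else {
      alpha <- 4 * p * (1 - p) / (1 - 2 * p)
      n <- h - 1L
      S_n <- -alpha * r^-3 * (1 - p)^(n + 1L) / p +
        (alpha + r) * r^-2 * 2^-n
      ts <- seq_len(n)
      U_n <- sum(2^-ts * (alpha * r^(2 * ts - 3L) -
                            (alpha + r) * r^(ts - 2L)))
      K <- 4 * p^2 * q^2 * (1 - p) / (r - 1)
      C <- K * (r^h * S_n - U_n)
    }
  }
  A + D + C
}

#' Closed-form moments of mutation count and leaf frequency
#'
#' Returns E(X), a variance bound for X, E(Y), E(XY), Cov(X, Y) and Var(Y)
#' for the binary-tree mutation model. E(X) uses the printed closed form
#' 2pq((2-2p)^h - 1)/(1-2p), with the limit 2pqh at p = 0.5.
#'
#' @param params a [theory_params()] object.
#' @return named list with elements \code{E_X}, \code{Var_X_bound},
#'   \code{Var_X}, \code{E_Y}, \code{E_XY}, \code{Cov_XY}, \code{Var_Y}.
#' @export
closed_form_moments <- function(params) {
  p <- params$p; q <- params$q; h <- params$h
  tol <- 1e-9
  E_X <- if (abs(1 - 2 * p) < tol) 2 * p * q * h else
    2 * p * q * ((2 - 2 * p)^h - 1) / (1 - 2 * p)
  E_Y <- q * (1 - (1 - p)^h)
  mom <- .bt_moments(p, q, h)
  wy <- 2^-(1:h)
  Var_Y <- 0; Var_X <- 0
  for (s in 1:h) for (t in 1:h) {
    cst <- mom$covB(s, t)
    Var_Y <- Var_Y + wy[s] * wy[t] * cst
    Var_X <- Var_X + cst
  }
  Cov_XY <- .cov_xy_stable(p, q, h, mom)
  E_XY <- Cov_XY + E_X * E_Y
  # printed bound (valid away from p = 0.5)
  Var_X_bound <- if (abs(1 - 2 * p) < tol) Inf else
    2 * p^2 * q^2 * (2 * p - 2)^(2 * h + 1) / (2 * p - 1)^3 +
    2 * p * q * (1 - (2 - 2 * p)^h) / (2 * p - 1) -
    4 * p^2 * q^2 * (1 - (2 - 2 * p)^h)^2 / (2 * p - 1)^2
  list(E_X = E_X, Var_X_bound = Var_X_bound, Var_X = Var_X, E_Y = E_Y,
       E_XY = E_XY, Cov_XY = Cov_XY, Var_Y = Var_Y)
}

#' Least-squares linear estimate of X given observed frequency Y
#'
#' L(X | Y = y) = E(X) + Cov(X, Y) / Var(Y) * (y - E(Y)). For realistic
#' mutation probabilities the slope is negative: mutations observed at
#' higher leaf frequency are expected to have occurred fewer times,
#' justifying the greedy split criterion.
#'
#' @param y observed leaf frequency of the mutation.
#' @param params a [theory_params()] object.
#' @return estimated occurrence count.
#' @export
llse_x_given_y <- function(y, params) {
  mm <- closed_form_moments(params)
  if (mm$Var_Y <= 0) stop("degenerate Var(Y)")
  mm$E_X + mm$Cov_XY / mm$Var_Y * (y - mm$E_Y)
}

#' Markov-chain simulation of a mutation's occurrence count and frequency
#'
#' Simulates the unmutated-cell chain N_t (N_1 = 1,
#' A_t ~ Bin(2 N_t, p) mutations after division, B_t ~ Bin(A_t, q) taking
#' the particular state, N_{t+1} = 2 N_t - A_t) and returns per replicate
#' X = sum B_t and Y = sum 2^(-t) B_t (the fraction of the 2^h leaves fixed
#' by each generation-t event).
#'
#' @param params a [theory_params()] object.
#' @param reps number of replicates.
#' @return data.frame with columns \code{X} (integer) and \code{Y} in [0, 1].
#' @export
simulate_markov <- function(params, reps) {
  stopifnot(reps >= 1L)
  p <- params$p; q <- params$q; h <- params$h
  N <- rep(1, reps)
  X <- numeric(reps); Y <- numeric(reps)
  for (t in 1:h) {
    A <- rbinom(reps, 2 * N, p)
    B <- rbinom(reps, A, q)
    X <- X + B
    Y <- Y + B * 2^(-t)
    N <- 2 * N - A
  }
  data.frame(X = X, Y = Y)
}

# exhaustive enumeration oracle for tiny h: exact joint moments of (X, Y)
# by dynamic programming over the full binary tree. Used in tests only.
enumerate_moments <- function(p, q, h) {
  # distribution over (X, K) where K = Y * 2^h, for a subtree of height hh
  # whose root-edge character is still unmutated.
  subtree <- function(hh) {
    if (hh == 0L) return(list(`0:0` = 1))
    sub <- subtree(hh - 1L)
    # one child branch: edge mutates (prob p*q -> all 2^(hh-1) leaves fixed;
    # prob p*(1-q) -> other state, subtree contributes nothing;
    # prob 1-p -> recurse)
    branch <- new.env()
    addp <- function(env, key, pr) {
      env[[key]] <- (env[[key]] %||% 0) + pr
    }
    br <- list()
    add <- function(key, pr) br[[key]] <<- (br[[key]] %||% 0) + pr
    add(paste(1, 2^(hh - 1L), sep = ":"), p * q)
    add("0:0", p * (1 - q))
    for (k in names(sub)) add(k, (1 - p) * sub[[k]])
    # two independent branches: convolve
    out <- list()
    for (k1 in names(br)) for (k2 in names(br)) {
      a <- as.integer(strsplit(k1, ":")[[1]])
      b <- as.integer(strsplit(k2, ":")[[1]])
      key <- paste(a + b, collapse = ":")
      out[[key]] <- (out[[key]] %||% 0) + br[[k1]] * br[[k2]]
    }
    out
  }
  dist <- subtree(h)
  EX <- 0; EY <- 0; EXY <- 0; EX2 <- 0; EY2 <- 0
  for (k in names(dist)) {
    v <- as.numeric(strsplit(k, ":")[[1]])
    x <- v[1]; y <- v[2] / 2^h; pr <- dist[[k]]
    EX <- EX + x * pr; EY <- EY + y * pr; EXY <- EXY + x * y * pr
    EX2 <- EX2 + x^2 * pr; EY2 <- EY2 + y^2 * pr
  }
  list(E_X = EX, E_Y = EY, E_XY = EXY, Var_X = EX2 - EX^2,
       Var_Y = EY2 - EY^2, Cov_XY = EXY - EX * EY)
}

#' Critical mutation probability for diverging frequency-count covariance
#'
#' Scans p over a grid and reports, to two decimals, the largest p for which
#' the magnitude of Cov(X, Y) still grows with tree height (evaluated at a
#' sequence of heights). The theoretical boundary is 1 - 1/sqrt(2) ~ 0.29:
#' below it, frequency and occurrence count become exponentially more
#' negatively correlated with depth.
#'
#' Divergence is distinguished from saturation (above the boundary the
#' covariance converges to a constant, which also increases in magnitude at
#' small heights) by a geometric-growth test: the magnitude must keep
#' growing by at least \code{growth_factor} between consecutive heights,
#' and the covariance must be negative at the largest height.
#'
#' @param q conditional state probability (default 0.5).
#' @param p_grid probabilities to scan.
#' @param heights tree heights at which the covariance is evaluated.
#' @param growth_factor minimum consecutive-height magnitude ratio counted
#'   as growth (default 1.05).
#' @return the boundary probability (two-decimal grid value).
#' @export
critical_p_scan <- function(q = 0.5, p_grid = seq(0.01, 0.49, by = 0.01),
                            heights = c(40L, 80L, 120L, 160L, 200L),
                            growth_factor = 1.05) {
  grows <- vapply(p_grid, function(p) {
    cv <- vapply(heights, function(h)
      closed_form_moments(theory_params(p, q, h))$Cov_XY, numeric(1))
    acv <- abs(cv)
    all(acv[-1L] / acv[-length(acv)] > growth_factor) &&
      cv[length(cv)] < 0
  }, logical(1))
  if (!any(grows)) return(NA_real_)
  max(p_grid[grows])
}
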