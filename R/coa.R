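#' Parameters for the coot optimization algorithm
#'
#' @param n_coots Population size `N` (leaders included).
#' @param n_leaders Number of leaders `NL`, `1 <= NL < N`; default
#'   `ceiling(0.1 * N)`.
#' @param p Probability governing the vector-vs-scalar random draws in the
#'   leader update, in `[0, 1]`.
#' @param iter_max Number of iterations (0 = return the best of the initial
#'   population).
#' @param lower,upper Per-dimension box bounds (recycled to the problem
#'   dimension), `lower < upper`.
#' @param seed RNG seed; all randomness in one run flows from it.
#' @return A `coa_params` list.
#' @export
coa_params <- function(n_coots = 30, n_leaders = NULL, p = 0.5,
                       iter_max = 50, lower = -1, upper = 1, seed = 1) {
  if (is.null(n_leaders)) n_leaders <- ceiling(0.1 * n_coots)
  stopifnot(n_leaders >= 1, n_leaders < n_coots, p >= 0, p <= 1,
            iter_max >= 0, all(lower < upper))
  structure(list(n_coots = as.integer(n_coots),
                 n_leaders = as.integer(n_leaders),
                 p = p, iter_max = as.integer(iter_max),
                 lower = lower, upper = upper, seed = seed),
            class = "coa_params")
}

#' Leader assignment for a follower coot
#'
#' `Lind = 1 + (i mod NL)` with a 0-based follower index `i`, giving a
#' stable 1-based leader index in `[1, NL]`.
#'
#' @param i 0-based follower index.
#' @param NL Number of leaders.
#' @return Integer leader index.
#' @export
assign_leader <- function(i, NL) {
  stopifnot(NL >= 1)
  as.integer(1L + (i %% NL))
}

coa_bounds <- function(params, dim) {
  lb <- rep_len(params$lower, dim)
  ub <- rep_len(params$upper, dim)
  list(lb = lb, ub = ub)
}

coa_clamp <- function(x, b) pmin(pmax(x, b$lb), b$ub)

safe_fitness <- function(fitness) {
  function(x) {
    v <- fitness(x)
    if (!is.finite(v)) Inf else v
  }
}

#' Initialize a coot population
#'
#' Positions are i.i.d. uniform on the box; the first `NL` coots (a random
#' ordering, so the selection is random) act as leaders.
#'
#' @param fitness Objective function mapping a numeric vector to a scalar.
#' @param params [coa_params()].
#' @param dim Problem dimension.
#' @return A `coot_state` list: follower/leader positions and fitnesses,
#'   the incumbent `gBest`, and an empty history.
#' @export
coa_init <- function(fitness, params, dim) {
  stopifnot(dim >= 1)
  set.seed(params$seed)
  fit <- safe_fitness(fitness)
  b <- coa_bounds(params, dim)
  N <- params$n_coots
  NL <- params$n_leaders
  pos <- matrix(stats::runif(N * dim), N, dim)
  pos <- sweep(sweep(pos, 2L, b$ub - b$lb, `*`), 2L, b$lb, `+`)
  f <- apply(pos, 1L, fit)
  lead_idx <- sample.int(N, NL)
  best <- which.min(f)
  structure(
    list(followers = pos[-lead_idx, , drop = FALSE],
         follower_fit = f[-lead_idx],
         leaders = pos[lead_idx, , drop = FALSE],
         leader_fit = f[lead_idx],
         gBest = pos[best, ],
         gBest_fitness = f[best],
         history = numeric(0),
         dim = dim,
         bounds = b),
    class = "coot_state"
  )
}

#' Minimize a function with the coot optimization algorithm
#'
#' Population metaheuristic imitating coot-bird flock movement.  Each
#' iteration a follower either circles its assigned leader
#' (`pos <- L + 2 R1 cos(2 pi R) (L - pos)`, probability 1/2), moves in a
#' chain towards its predecessor (`pos <- (pos + pos_prev) / 2`), or
#' wanders towards a random point in the box
#' (`pos <- pos + A * RN2 * (Q - pos)`); leaders spiral around the
#' incumbent best (`L <- B R3 cos(2 pi R) (gBest - L) + gBest`).  `A` and
#' `B` shrink linearly over the run.  A follower that beats its leader
#' swaps roles with it, and `gBest` is elitist, so the best-so-far curve is
#' non-increasing.  Positions are clamped to the box after every move.
#'
#' @inheritParams coa_init
#' @return List of class `coa_fit`: `gBest`, `gBest_fitness`, `history`
#'   (per-iteration best-so-far), `n_evals`, and the params used.
#' @export
coa_minimize <- function(fitness, params, dim) {
  st <- coa_init(fitness, params, dim)
  fit <- safe_fitness(fitness)
  b <- st$bounds
  NL <- params$n_leaders
  Nf <- nrow(st$followers)
  P <- params$p
  iter_max <- params$iter_max
  n_evals <- params$n_coots

  for (t in seq_len(iter_max)) {
    A <- 1 - t / iter_max
    B <- 2 - t / iter_max
    vector_mode <- stats::runif(1) < P

    for (i in seq_len(Nf)) {
      k <- assign_leader(i - 1L, NL)
      r_branch <- stats::runif(1)
      if (r_branch > 0.5) {
        # circle the assigned leader
        if (vector_mode) {
          R1 <- stats::runif(st$dim)
          R <- stats::runif(st$dim, -1, 1)
        } else {
          R1 <- stats::runif(1)
          R <- stats::runif(1, -1, 1)
        }
        L <- st$leaders[k, ]
        cand <- L + 2 * R1 * cos(2 * pi * R) * (L - st$followers[i, ])
      } else if (i > 1L && stats::runif(1) < 0.5) {
        # chain movement: average with the previous coot
        cand <- 0.5 * (st$followers[i - 1L, ] + st$followers[i, ])
      } else {
        # random wandering towards a fresh uniform point
        Q <- stats::runif(st$dim) * (b$ub - b$lb) + b$lb
        RN2 <- stats::runif(1)
        cand <- st$followers[i, ] + A * RN2 * (Q - st$followers[i, ])
      }
      cand <- coa_clamp(cand, b)
      fc <- fit(cand)
      n_evals <- n_evals + 1L
      st$followers[i, ] <- cand
      st$follower_fit[i] <- fc
      if (fc < st$leader_fit[k]) {
        tmp <- st$leaders[k, ]
        tmpf <- st$leader_fit[k]
        st$leaders[k, ] <- cand
        st$leader_fit[k] <- fc
        st$followers[i, ] <- tmp
        st$follower_fit[i] <- tmpf
      }
    }

    for (k in seq_len(NL)) {
      R4 <- stats::runif(1)
      if (R4 < P) {
        R3 <- stats::runif(st$dim)
        R <- stats::runif(st$dim, -1, 1)
      } else {
        R3 <- stats::runif(1)
        R <- stats::runif(1, -1, 1)
      }
      cand <- B * R3 * cos(2 * pi * R) * (st$gBest - st$leaders[k, ]) +
        st$gBest
      cand <- coa_clamp(cand, b)
      fc <- fit(cand)
      n_evals <- n_evals + 1L
      st$leaders[k, ] <- cand
      st$leader_fit[k] <- fc
      if (fc < st$gBest_fitness) {
        st$leaders[k, ] <- st$gBest
        st$leader_fit[k] <- st$gBest_fitness
        st$gBest <- cand
        st$gBest_fitness <- fc
      }
    }
    st$history <- c(st$history, st$gBest_fitness)
  }

  structure(
    list(gBest = st$gBest, gBest_fitness = st$gBest_fitness,
         history = st$history, n_evals = n_evals, params = params,
         dim = st$dim),
    class = "coa_fit"
  )
}

#' @export
print.coa_fit <- function(x, ...) {
  cat("<coa_fit> dim ", x$dim, ", ", length(x$history), " iterations, ",
      x$n_evals, " evaluations\n  best fitness: ",
      format(x$gBest_fitness), "\n", sep = "")
  invisible(x)
}

#' Tidy the convergence trace of a COA run
#'
#' @param x A `coa_fit`.
#' @param ... Unused.
#' @return Tibble with columns `iteration` and `best_fitness`.
#' @export
tidy.coa_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history),
                 best_fitness = x$history)
}

#' One-row summary of a COA run
#'
#' @inheritParams tidy.coa_fit
#' @return Tibble with the final fitness, evaluation count and dimensions.
#' @export
glance.coa_fit <- function(x, ...) {
  tibble::tibble(best_fitness = x$gBest_fitness,
                 iterations = length(x$history),
                 n_evals = x$n_evals, dim = x$dim)
}

#' Random-search baseline with the same evaluation budget
#'
#' Uniform i.i.d. sampling of the box, used as the control arm when judging
#' whether the coot search beats blind sampling.
#'
#' @inheritParams coa_init
#' @param n_evals Evaluation budget.
#' @return List with `best`, `best_fitness`, `n_evals`.
#' @export
random_search <- function(fitness, params, dim, n_evals) {
  set.seed(params$seed)
  fit <- safe_fitness(fitness)
  b <- coa_bounds(params, dim)
  best <- NULL
  best_f <- Inf
  for (j in seq_len(n_evals)) {
    x <- stats::runif(dim) * (b$ub - b$lb) + b$lb
    fx <- fit(x)
    if (fx < best_f) {
      best_f <- fx
      best <- x
    }
  }
  list(best = best, best_fitness = best_f, n_evals = n_evals)
}
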