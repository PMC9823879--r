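# Mayfly optimization algorithm (MOA).
#
# Two sexed swarms explore a box-bounded continuous space under a
# maximization convention.  Males are attracted to their personal best
# and the global best with exponentially distance-damped coefficients;
# the current best male performs a "nuptial dance" perturbation.  Females
# are attracted to their rank-paired male when he outranks them and
# otherwise take a random walk.  Rank-paired crossover produces offspring
# that replace worse same-sex individuals (elitist), so the best-so-far
# trace is monotone non-decreasing.

#' Mayfly optimizer parameters
#'
#' @param bounds per-dimension box bounds: a matrix with columns
#'   `lower`, `upper` (one row per dimension), or a list with `lower` and
#'   `upper` vectors.
#' @param n_flies flies per sex.
#' @param max_iter iteration budget (the only termination criterion).
#' @param c1,c2 local (personal-best) and global (global-best) learning
#'   coefficients.
#' @param beta visibility exponent damping attraction with squared
#'   Cartesian distance.
#' @param dance nuptial dance coefficient of the best male.
#' @param dance_decay geometric per-iteration decay of the dance (and
#'   female random-walk) scale, in (0, 1]; undamped jitter of size
#'   `dance` prevents convergence on unit-scale problems.
#' @param walk_scale initial female random-walk step scale (defaults to
#'   `dance`, decayed by `dance_decay`).
#' @param seed integer seed used by [mayfly_optimize()].
#' @return a `mayfly_params` list.
#' @export
mayfly_params <- function(bounds,
                          n_flies = 30L,
                          max_iter = 3000L,
                          c1 = 1,
                          c2 = 1.5,
                          beta = 2,
                          dance = 5,
                          dance_decay = 0.99,
                          walk_scale = dance,
                          seed = 1L) {
  if (is.list(bounds) && !is.matrix(bounds)) {
    bounds <- cbind(lower = bounds$lower, upper = bounds$upper)
  }
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2) stop("bounds must have lower and upper columns")
  colnames(bounds) <- c("lower", "upper")
  if (any(bounds[, 1] >= bounds[, 2])) stop("bounds must satisfy lower < upper")
  if (n_flies < 2) stop("n_flies must be >= 2")
  if (beta <= 0) stop("beta must be > 0")
  if (any(c(c1, c2, dance, walk_scale) < 0)) {
    stop("c1, c2, dance, walk_scale must be >= 0")
  }
  if (dance_decay <= 0 || dance_decay > 1) stop("dance_decay must be in (0, 1]")
  structure(list(bounds = bounds, n_flies = as.integer(n_flies),
                 max_iter = as.integer(max_iter), c1 = c1, c2 = c2,
                 beta = beta, dance = dance, dance_decay = dance_decay,
                 walk_scale = walk_scale, seed = as.integer(seed)),
            class = "mayfly_params")
}

eval_objective <- function(objective, pos) {
  v <- objective(pos)
  if (length(v) != 1 || !is.finite(v)) {
    stop("objective returned a non-finite value at position (",
         paste(signif(pos, 6), collapse = ", "), ")")
  }
  as.numeric(v)
}

eval_rows <- function(objective, p) {
  vapply(seq_len(nrow(p)), function(i) eval_objective(objective, p[i, ]), 0)
}

# clamp positions to bounds, zeroing velocity on clamped dimensions
clamp_state <- function(p, v, bounds) {
  lo <- matrix(bounds[, 1], nrow(p), ncol(p), byrow = TRUE)
  hi <- matrix(bounds[, 2], nrow(p), ncol(p), byrow = TRUE)
  out <- p < lo | p > hi
  p <- pmin(pmax(p, lo), hi)
  v[out] <- 0
  list(p = p, v = v)
}

#' Initialize a mayfly swarm state
#'
#' Positions are uniform in the bounds, velocities zero.  Uses the
#' ambient RNG stream; [mayfly_optimize()] seeds it from `params$seed`.
#'
#' @param objective function: position vector -> finite scalar
#'   (maximized).
#' @param params a [mayfly_params()].
#' @return a `mayfly_state` list.
#' @export
mayfly_init <- function(objective, params) {
  d <- nrow(params$bounds)
  n <- params$n_flies
  runif_box <- function() {
    sapply(seq_len(d), function(j)
      stats::runif(n, params$bounds[j, 1], params$bounds[j, 2]))
  }
  mp <- matrix(runif_box(), n, d)
  fp <- matrix(runif_box(), n, d)
  mv <- matrix(0, n, d)
  fv <- matrix(0, n, d)
  mval <- eval_rows(objective, mp)
  fval <- eval_rows(objective, fp)
  all_val <- c(mval, fval)
  all_pos <- rbind(mp, fp)
  gi <- which.max(all_val)
  structure(list(
    male = list(p = mp, v = mv, val = mval),
    female = list(p = fp, v = fv, val = fval),
    pbest = list(p = mp, val = mval),
    gbest = all_pos[gi, ], gbest_val = all_val[gi],
    t = 0L,
    dance_scale = params$dance,
    walk_scale = params$walk_scale), class = "mayfly_state")
}

refresh_gbest <- function(state, pos, val) {
  gi <- which.max(val)
  if (val[gi] > state$gbest_val) {
    state$gbest <- pos[gi, ]
    state$gbest_val <- val[gi]
  }
  state
}

#' One male-swarm update
#'
#' Velocity gains distance-damped attraction toward the personal and
#' global bests; the currently best male dances instead (velocity kick
#' `dance_scale * R`, one random scalar R in \[-1, 1\] per dance).
#' Positions advance by the new velocity and are clamped to the bounds
#' (velocity zeroed on clamped dimensions); personal/global bests refresh
#' on improvement.
#'
#' @param state a `mayfly_state`.
#' @param objective maximized objective.
#' @param params a [mayfly_params()].
#' @return updated state.
#' @export
mayfly_male_update <- function(state, objective, params) {
  m <- state$male
  n <- nrow(m$p)
  best <- which.max(m$val)
  for (i in seq_len(n)) {
    if (i == best) {
      m$v[i, ] <- m$v[i, ] + state$dance_scale * stats::runif(1, -1, 1)
    } else {
      dp2 <- sum((m$p[i, ] - state$pbest$p[i, ])^2)
      dg2 <- sum((m$p[i, ] - state$gbest)^2)
      m$v[i, ] <- m$v[i, ] +
        params$c1 * exp(-params$beta * dp2) * (state$pbest$p[i, ] - m$p[i, ]) +
        params$c2 * exp(-params$beta * dg2) * (state$gbest - m$p[i, ])
    }
  }
  cl <- clamp_state(m$p + m$v, m$v, params$bounds)
  m$p <- cl$p; m$v <- cl$v
  m$val <- eval_rows(objective, m$p)
  imp <- m$val > state$pbest$val
  state$pbest$p[imp, ] <- m$p[imp, , drop = FALSE]
  state$pbest$val[imp] <- m$val[imp]
  state$male <- m
  refresh_gbest(state, m$p, m$val)
}

# rank-based best-to-best pairing: i-th best female with i-th best male
pair_by_rank <- function(state) {
  list(male = order(state$male$val, decreasing = TRUE),
       female = order(state$female$val, decreasing = TRUE))
}

#' One female-swarm update
#'
#' Females pair with males by fitness rank (best to best).  A female
#' whose paired male outranks her is attracted toward him with
#' coefficient `c2 * exp(-beta * Dmf^2)`; otherwise (including ties) she
#' random-walks with step `walk_scale * r`, r uniform in \[-1, 1\] per
#' dimension.
#'
#' @inheritParams mayfly_male_update
#' @return updated state.
#' @export
mayfly_female_update <- function(state, objective, params) {
  f <- state$female
  pairs <- pair_by_rank(state)
  for (k in seq_along(pairs$female)) {
    i <- pairs$female[k]   # female index
    j <- pairs$male[k]     # paired male index
    if (state$male$val[j] > f$val[i]) {
      dmf2 <- sum((state$male$p[j, ] - f$p[i, ])^2)
      f$v[i, ] <- f$v[i, ] +
        params$c2 * exp(-params$beta * dmf2) * (state$male$p[j, ] - f$p[i, ])
    } else {
      f$v[i, ] <- state$walk_scale * stats::runif(ncol(f$p), -1, 1)
    }
  }
  cl <- clamp_state(f$p + f$v, f$v, params$bounds)
  f$p <- cl$p; f$v <- cl$v
  f$val <- eval_rows(objective, f$p)
  state$female <- f
  refresh_gbest(state, f$p, f$val)
}

#' Rank-paired uniform crossover with elitist replacement
#'
#' Each rank pair produces two offspring `L * male + (1 - L) * female`
#' and `(1 - L) * male + L * female`, L uniform(0, 1) per dimension.  The
#' first offspring of each pair competes for male slots, the second for
#' female slots; offspring replace the worst same-sex individuals only
#' when strictly better.
#'
#' @inheritParams mayfly_male_update
#' @return updated state.
#' @export
mayfly_mate <- function(state, objective, params) {
  pairs <- pair_by_rank(state)
  n <- length(pairs$male)
  d <- ncol(state$male$p)
  off_m <- matrix(0, n, d); off_f <- matrix(0, n, d)
  for (k in seq_len(n)) {
    pm <- state$male$p[pairs$male[k], ]
    pf <- state$female$p[pairs$female[k], ]
    l <- stats::runif(d)
    off_m[k, ] <- l * pm + (1 - l) * pf
    off_f[k, ] <- (1 - l) * pm + l * pf
  }
  val_m <- eval_rows(objective, off_m)
  val_f <- eval_rows(objective, off_f)

  replace_into <- function(pop, off_p, off_val, pbest = NULL) {
    ord <- order(off_val, decreasing = TRUE)
    for (k in ord) {
      worst <- which.min(pop$val)
      if (off_val[k] > pop$val[worst]) {
        pop$p[worst, ] <- off_p[k, ]
        pop$v[worst, ] <- 0
        pop$val[worst] <- off_val[k]
        if (!is.null(pbest) && off_val[k] > pbest$val[worst]) {
          pbest$p[worst, ] <- off_p[k, ]
          pbest$val[worst] <- off_val[k]
        }
      } else break
    }
    list(pop = pop, pbest = pbest)
  }
  rm_ <- replace_into(state$male, off_m, val_m, state$pbest)
  state$male <- rm_$pop; state$pbest <- rm_$pbest
  rf_ <- replace_into(state$female, off_f, val_f)
  state$female <- rf_$pop
  state <- refresh_gbest(state, off_m, val_m)
  refresh_gbest(state, off_f, val_f)
}

#' Run the mayfly optimizer
#'
#' Loops male update, female update and mating for `max_iter` iterations
#' (the sole stopping rule) with all randomness drawn from
#' `params$seed`.
#'
#' @param objective function mapping a position vector to a finite scalar;
#'   maximized.
#' @param params a [mayfly_params()].
#' @return list with `gbest` (best position), `value` (its objective),
#'   `trace` (per-iteration best-so-far values, non-decreasing) and the
#'   final `state`.
#' @export
mayfly_optimize <- function(objective, params) {
  with_seed(params$seed, {
    state <- mayfly_init(objective, params)
    trace <- numeric(params$max_iter)
    for (t in seq_len(params$max_iter)) {
      state$t <- t
      state <- mayfly_male_update(state, objective, params)
      state <- mayfly_female_update(state, objective, params)
      state <- mayfly_mate(state, objective, params)
      state$dance_scale <- state$dance_scale * params$dance_decay
      state$walk_scale <- state$walk_scale * params$dance_decay
      trace[t] <- state$gbest_val
    }
    list(gbest = state$gbest, value = state$gbest_val,
         trace = trace, state = state)
  })
}

#' Export an optimizer trace as CSV
#' @param trace numeric vector of per-iteration best values.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(iteration = seq_along(trace),
                              best_value = trace),
                   path, row.names = FALSE)
  invisible(path)
}
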