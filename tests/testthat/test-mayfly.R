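quad_obj <- function(x) -(x[1] - 2)^2

make_state <- function(mp, fp, objective, params, mv = NULL, fv = NULL) {
  # hand-built swarm state for step-level tests
  n <- nrow(mp); d <- ncol(mp)
  if (is.null(mv)) mv <- matrix(0, n, d)
  if (is.null(fv)) fv <- matrix(0, n, d)
  mval <- apply(mp, 1, objective)
  fval <- apply(fp, 1, objective)
  all_pos <- rbind(mp, fp); all_val <- c(mval, fval)
  gi <- which.max(all_val)
  structure(list(male = list(p = mp, v = mv, val = mval),
                 female = list(p = fp, v = fv, val = fval),
                 pbest = list(p = mp, val = mval),
                 gbest = all_pos[gi, ], gbest_val = all_val[gi],
                 t = 0L, dance_scale = params$dance,
                 walk_scale = params$walk_scale),
            class = "mayfly_state")
}

test_that("male velocity update matches the printed attraction terms", {
  # 1-D: P=0, V=0, pbest=1, Gbest=2, c1=1, c2=1.5, beta=2
  params <- mayfly_params(bounds = cbind(-10, 10), n_flies = 2,
                          dance = 1e-12)
  obj <- function(x) -sum(x^2)  # values irrelevant to the velocity formula
  st <- make_state(rbind(0, 5), rbind(9, 9.5), obj, params)
  st$pbest$p <- rbind(1, 5)
  st$pbest$val <- c(obj(1), obj(5))
  st$gbest <- 2; st$gbest_val <- obj(2)
  st$male$val <- c(-101, -100)  # male 2 is "best" and dances; male 1 attracts
  out <- withr::with_seed(1, mayfly_male_update(st, obj, params))
  v_expected <- exp(-2 * 1) * (1 - 0) + 1.5 * exp(-2 * 4) * (2 - 0)
  expect_equal(out$male$p[1, ] - st$male$p[1, ], v_expected,
               tolerance = 1e-12)
})

test_that("a male at both bests keeps its velocity (attractions vanish)", {
  params <- mayfly_params(bounds = cbind(-100, 100), n_flies = 2,
                          dance = 1e-12)
  obj <- function(x) -sum((x - 50)^2)
  st <- make_state(rbind(3, 90), rbind(-3, -9), obj, params,
                   mv = rbind(0.5, 0))
  # male 1: P = pbest = Gbest = 3; male 2 is best by value and dances
  st$pbest$p <- rbind(3, 90)
  st$pbest$val <- apply(st$pbest$p, 1, obj)
  st$gbest <- 3
  st$male$val <- c(-1, 0)  # male 2 best
  out <- withr::with_seed(1, mayfly_male_update(st, obj, params))
  expect_equal(out$male$p[1, ], 3.5)   # moved by its own velocity only
})

test_that("optimizer solves 1-D quadratic and 5-D sphere problems", {
  params <- mayfly_params(bounds = cbind(0, 5), max_iter = 500L, seed = 3)
  res <- mayfly_optimize(quad_obj, params)
  expect_lt(abs(res$gbest - 2), 0.01)
  p5 <- mayfly_params(bounds = cbind(rep(-5, 5), rep(5, 5)),
                      max_iter = 500L, seed = 3)
  r5 <- mayfly_optimize(function(x) -sum(x^2), p5)
  expect_gt(r5$value, -1e-3)
})

test_that("best-so-far trace is monotone and constant objectives stay flat", {
  params <- mayfly_params(bounds = cbind(c(-1, -1), c(1, 1)),
                          n_flies = 5, max_iter = 40, seed = 9)
  res <- mayfly_optimize(function(x) sum(x * 0) + 4.25, params)
  expect_equal(res$value, 4.25)
  expect_true(all(res$trace == 4.25))
  res2 <- mayfly_optimize(function(x) -sum((x - 0.3)^2), params)
  expect_true(all(diff(res2$trace) >= 0))
})

test_that("quadratic optimum is reached in at least 95% of seeded runs", {
  hits <- vapply(1:20, function(s) {
    p <- mayfly_params(bounds = cbind(0, 5), n_flies = 10, max_iter = 200,
                       seed = s)
    abs(mayfly_optimize(quad_obj, p)$gbest - 2) < 1e-2
  }, TRUE)
  expect_gte(sum(hits), 19)
})

test_that("female update takes attraction vs random-walk branches correctly", {
  params <- mayfly_params(bounds = cbind(c(-10, -10), c(10, 10)),
                          n_flies = 2, dance = 1e-9, walk_scale = 1e-9)
  obj <- function(x) -sum(x^2)
  # pair ranks: male 1 (0,0) best male; female 1 at the same position
  mp <- rbind(c(0, 0), c(5, 5))
  fp <- rbind(c(0, 0), c(6, 6))
  st <- make_state(mp, fp, obj, params)
  # coincident pair with equal objective: tie -> random walk branch,
  # walk scale ~0 so the position is unchanged
  out <- withr::with_seed(1, mayfly_female_update(st, obj, params))
  expect_equal(out$female$p[1, ], c(0, 0), tolerance = 1e-6)

  # paired male strictly better, female coincident: Dmf = 0 and the
  # attraction displacement is exactly zero
  st2 <- make_state(mp, fp, obj, params)
  st2$male$val <- c(10, -90)     # male 1 better than female 1
  out2 <- withr::with_seed(1, mayfly_female_update(st2, obj, params))
  expect_equal(out2$female$p[1, ], c(0, 0))

  # male worse than female: position changes only by the walk term
  params3 <- mayfly_params(bounds = cbind(c(-10, -10), c(10, 10)),
                           n_flies = 2, walk_scale = 0.5)
  st3 <- make_state(mp, fp, obj, params3)
  st3$male$val <- c(-100, -101)  # both males worse than their females
  st3$female$v <- rbind(c(0.3, 0.3), c(0, 0))  # memory must be discarded
  out3 <- withr::with_seed(5, mayfly_female_update(st3, obj, params3))
  step <- withr::with_seed(5, 0.5 * stats::runif(2, -1, 1))
  expect_equal(out3$female$p[1, ], step)
})

test_that("crossover is exact arithmetic and a fixed point for twins", {
  params <- mayfly_params(bounds = cbind(c(0, 0), c(1, 1)), n_flies = 2)
  obj <- function(x) sum(x)
  # identical parents: offspring equal parents (population unchanged)
  mp <- rbind(c(0.4, 0.4), c(0.4, 0.4))
  st <- make_state(mp, mp, obj, params)
  out <- withr::with_seed(2, mayfly_mate(st, obj, params))
  expect_equal(out$male$p, mp)
  expect_equal(out$female$p, mp)

  # parents (0,0) and (1,1) with blend L: offspring are exactly
  # L*male + (1-L)*female and its mirror, landing in the worst slots
  mp2 <- rbind(c(0, 0), c(0, 0))
  fp2 <- rbind(c(1, 1), c(0, 0))
  st2 <- make_state(mp2, fp2, obj, params)
  st2$male$val <- c(5, -5)   # rank pairing: male 1 with female 1
  st2$female$val <- c(4, -4)
  l <- withr::with_seed(8, stats::runif(2))
  out2 <- withr::with_seed(8, mayfly_mate(st2, obj, params))
  expect_equal(out2$male$p[2, ], 1 - l)   # l*(0,0) + (1-l)*(1,1)
  expect_equal(out2$female$p[2, ], l)     # (1-l)*(0,0) + l*(1,1)
})

test_that("offspring worse than the whole population change nothing", {
  params <- mayfly_params(bounds = cbind(c(-2, -2), c(2, 2)), n_flies = 2)
  obj <- function(x) -sum(abs(x))
  mp <- rbind(c(0, 0), c(0.1, -0.1))
  fp <- rbind(c(-0.1, 0.1), c(0.05, 0))
  # force "worse than everyone" with an objective that penalizes every
  # point that is not one of the four parents
  obj2 <- function(x) if (max(abs(x)) < 0.2 && !any(apply(rbind(mp, fp), 1,
                        function(r) isTRUE(all.equal(r, x))))) -100 else -sum(abs(x))
  st2 <- make_state(mp, fp, obj2, params)
  out <- withr::with_seed(3, mayfly_mate(st2, obj2, params))
  expect_equal(out$male$p, mp)
  expect_equal(out$female$p, fp)
})

test_that("motion is ballistic when attraction, dance and walk are off", {
  params <- mayfly_params(bounds = cbind(c(-100, -100), c(100, 100)),
                          n_flies = 2, c1 = 0, c2 = 0, dance = 0,
                          walk_scale = 0)
  obj <- function(x) 1  # constant: tie -> walk branch (scale 0)
  mp <- rbind(c(0, 0), c(1, 1))
  st <- make_state(mp, mp, obj, params, mv = rbind(c(1, -2), c(0.5, 0)))
  for (i in 1:3) st <- mayfly_male_update(st, obj, params)
  expect_equal(st$male$p[1, ], c(3, -6))
  expect_equal(st$male$p[2, ], c(2.5, 1))
})

test_that("positions clamp to bounds with velocity zeroing", {
  params <- mayfly_params(bounds = cbind(c(0, 0), c(1, 1)), n_flies = 2,
                          c1 = 0, c2 = 0, dance = 0, walk_scale = 0)
  obj <- function(x) 1
  st <- make_state(rbind(c(0.5, 0.5), c(0.2, 0.2)),
                   rbind(c(0.5, 0.5), c(0.2, 0.2)), obj, params,
                   mv = rbind(c(10, 0.1), c(0, 0)))
  st <- mayfly_male_update(st, obj, params)
  expect_equal(st$male$p[1, ], c(1, 0.6))
  expect_equal(st$male$v[1, ], c(0, 0.1))  # clamped dim zeroed
})

test_that("non-finite objectives abort with the offending position", {
  params <- mayfly_params(bounds = cbind(0, 1), n_flies = 3, seed = 1)
  expect_error(mayfly_optimize(function(x) NaN, params), "non-finite")
  expect_error(mayfly_optimize(function(x) Inf, params), "non-finite")
})

test_that("parameter validation rejects malformed configurations", {
  expect_error(mayfly_params(bounds = cbind(1, 0)), "lower < upper")
  expect_error(mayfly_params(bounds = cbind(0, 1), n_flies = 1), "n_flies")
  expect_error(mayfly_params(bounds = cbind(0, 1), dance_decay = 0),
               "dance_decay")
})
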