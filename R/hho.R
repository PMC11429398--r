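#' Optimizer configuration for Harris Hawks optimization
#'
#' @param dim Problem dimension.
#' @param n_hawks Population size N (default 20); at least 4, and at least 5
#'   for the `ihho` variant (its third-elite update samples two further
#'   distinct members).
#' @param max_iters Number of iterations s (default 100).
#' @param lower,upper Per-dimension box bounds (scalars, recycled; default
#'   unit hypercube).
#' @param variant `"hho"` for the original algorithm or `"ihho"` for the
#'   improved variant in which the three best-ranked individuals (alpha,
#'   beta, gamma) follow dedicated elite update rules.
#' @param levy_beta Stability index of the Levy flight, in (1, 2]
#'   (default 1.5).
#' @param seed Integer seed; runs are bit-reproducible per seed.
#' @return An object of class `hho_config`.
#' @export
hho_config <- function(dim, n_hawks = 20L, max_iters = 100L,
                       lower = 0, upper = 1,
                       variant = c("ihho", "hho"),
                       levy_beta = 1.5, seed = 1L) {
  variant <- match.arg(variant)
  cfg <- list(dim = as.integer(dim), n_hawks = as.integer(n_hawks),
              max_iters = as.integer(max_iters),
              lower = as.numeric(lower), upper = as.numeric(upper),
              variant = variant, levy_beta = levy_beta,
              seed = as.integer(seed))
  if (cfg$dim < 1L) hawkfs_abort("dim must be >= 1", "hawkfs_error_bad_config")
  if (cfg$n_hawks < 4L)
    hawkfs_abort("n_hawks must be >= 4", "hawkfs_error_bad_config")
  if (variant == "ihho" && cfg$n_hawks < 5L)
    hawkfs_abort("ihho needs n_hawks >= 5", "hawkfs_error_bad_config")
  if (cfg$max_iters < 1L)
    hawkfs_abort("max_iters must be >= 1", "hawkfs_error_bad_config")
  if (any(cfg$lower >= cfg$upper))
    hawkfs_abort("lower must be < upper", "hawkfs_error_bad_config")
  if (levy_beta <= 1 || levy_beta > 2)
    hawkfs_abort("levy_beta must lie in (1, 2]", "hawkfs_error_bad_config")
  structure(cfg, class = "hho_config")
}

#' Prey escaping energy schedule
#'
#' The decaying scalar that switches the hawks between exploration and
#' exploitation: `E = 2 * e0 * (1 - t/s)`. The caller redraws `e0`
#' uniformly in (-1, 1) each iteration.
#'
#' @param e0 Initial energy draw in (-1, 1).
#' @param t Current iteration, `0 <= t <= s`.
#' @param s Total iterations, >= 1.
#' @return The energy value.
#' @export
prey_energy <- function(e0, t, s) {
  if (s < 1 || t < 0 || t > s)
    hawkfs_abort("need 0 <= t <= s and s >= 1", "hawkfs_error_bad_iteration")
  2 * e0 * (1 - t / s)
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Exploration move
#'
#' Perching based on random locations: with `q >= 0.5` the hawk moves
#' relative to a random population member,
#' `m_rand - r1 * |m_rand - 2 * r2 * m_i|`; otherwise relative to the prey
#' and the population average,
#' `(m_rab - m_avg) - r1 * (lower + r2 * (upper - lower))`. The result is
#' clipped to the box.
#'
#' @param m_i Current position (numeric vector).
#' @param m_rand Position of a randomly chosen member.
#' @param m_rab Best-so-far (prey/rabbit) position.
#' @param m_avg Population mean position.
#' @param lower,upper Box bounds.
#' @param q Branch random in [0, 1].
#' @param r1,r2 Uniform randoms in [0, 1].
#' @return New position, clipped.
#' @export
hho_exploration <- function(m_i, m_rand, m_rab, m_avg, lower, upper,
                            q, r1, r2) {
  pos <- if (q >= 0.5) {
    m_rand - r1 * abs(m_rand - 2 * r2 * m_i)
  } else {
    (m_rab - m_avg) - r1 * (lower + r2 * (upper - lower))
  }
  clip_box(pos, lower, upper)
}

#' Soft or hard besiege move
#'
#' Exploitation without dives: soft besiege
#' (`0.5 <= |E| < 1`) moves by
#' `(m_rab - m_i) - E * |2 * (1 - r_e) * m_rab - m_i|`; hard besiege
#' (`|E| < 0.5`) collapses towards the prey by
#' `m_rab - E * |m_rab - m_i|`. Clipped to the box.
#'
#' @param m_i Current position.
#' @param m_rab Prey (best-so-far) position.
#' @param E Escaping energy.
#' @param r_e Uniform random in [0, 1].
#' @param lower,upper Box bounds.
#' @return New position, clipped.
#' @export
hho_besiege <- function(m_i, m_rab, E, r_e, lower, upper) {
  pos <- if (abs(E) >= 0.5) {
    (m_rab - m_i) - E * abs(2 * (1 - r_e) * m_rab - m_i)
  } else {
    m_rab - E * abs(m_rab - m_i)
  }
  clip_box(pos, lower, upper)
}

#' First candidate of a progressive rapid dive
#'
#' `A = m_rab - E * |2 * (1 - r_e) * m_rab - base|`, where `base` is the
#' hawk's own position in the soft-dive regime and the population average in
#' the hard-dive regime.
#'
#' @param base Reference position (own position or population mean).
#' @param m_rab Prey position.
#' @param E Escaping energy.
#' @param r_e Uniform random in [0, 1].
#' @param lower,upper Box bounds.
#' @return Candidate position A, clipped.
#' @export
hho_dive_candidate <- function(base, m_rab, E, r_e, lower, upper) {
  clip_box(m_rab - E * abs(2 * (1 - r_e) * m_rab - base), lower, upper)
}

#' Progressive rapid dive with greedy acceptance
#'
#' The exploitation move with Levy-flight excursions: a first candidate
#' `A = m_rab - E * |2 * (1 - r_e) * m_rab - base|` is accepted if it
#' improves on the hawk's current fitness; otherwise a Levy-perturbed
#' candidate `B = A + rand(dim) * levy(dim)` is tried; if neither improves,
#' the hawk keeps its position. `B` is only evaluated when `A` fails
#' (short-circuit), so a dive costs one or two objective evaluations.
#' `base` is the hawk's own position for the soft dive (`0.5 <= |E| < 1`)
#' and the population average for the hard dive (`|E| < 0.5`).
#'
#' @param m_i Current position.
#' @param f_i Current fitness of the hawk.
#' @param base Reference position (own position or population mean).
#' @param m_rab Prey position.
#' @param E Escaping energy.
#' @param r_e Uniform random in [0, 1].
#' @param objective Objective function.
#' @param lower,upper Box bounds.
#' @param levy_beta Levy stability index.
#' @param levy_scale Levy step scale (default 0.01); 0 degenerates B to A.
#' @return List with `position`, `fitness`, and `n_evals` (1 or 2). Draws
#'   `rand(dim)` and the Levy vector from the current RNG stream only when B
#'   is needed.
#' @export
hho_dive_step <- function(m_i, f_i, base, m_rab, E, r_e, objective,
                          lower, upper, levy_beta = 1.5, levy_scale = 0.01) {
  A <- hho_dive_candidate(base, m_rab, E, r_e, lower, upper)
  fA <- objective(A)
  if (fA < f_i)
    return(list(position = A, fitness = fA, n_evals = 1L))
  dim <- length(m_i)
  B <- clip_box(A + stats::runif(dim) * levy_flight(dim, levy_beta, levy_scale),
                lower, upper)
  fB <- objective(B)
  if (fB < f_i)
    return(list(position = B, fitness = fB, n_evals = 2L))
  list(position = m_i, fitness = f_i, n_evals = 2L)
}

#' Levy flight step (Mantegna's algorithm)
#'
#' Heavy-tailed step used by the rapid dives:
#' `step = scale * u / |v|^(1/beta)` with `u ~ N(0, sigma_u^2)`,
#' `v ~ N(0, 1)` and `sigma_u` given by Mantegna's closed form.
#'
#' @param dim Number of components.
#' @param beta Stability index in (1, 2] (default 1.5).
#' @param scale Step scale (default 0.01).
#' @return Numeric vector of length `dim`. Uses the current RNG stream.
#' @export
levy_flight <- function(dim, beta = 1.5, scale = 0.01) {
  if (beta <= 1 || beta > 2)
    hawkfs_abort("beta must lie in (1, 2]", "hawkfs_error_bad_config")
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(dim, 0, sigma_u)
  v <- stats::rnorm(dim)
  scale * u / abs(v)^(1 / beta)
}

#' Elite update for the best-ranked individual (alpha)
#'
#' With probability set by a Cauchy gate the alpha individual jumps onto the
#' prey position: when `tan(pi * (gate_rand - 0.5)) < 1 - t/s` it returns
#' `m_rab`; otherwise it perturbs the prey by a shrinking difference step,
#' `m_rab + (4 - 4 * t/s) * step_rand * (m_m - m_n)` with `m_m`, `m_n` two
#' distinct non-alpha members.
#'
#' @param m_rab Prey position.
#' @param t,s Current and total iterations.
#' @param gate_rand Uniform random in (0, 1) feeding the Cauchy gate.
#' @param step_rand Uniform random in [0, 1] scaling the difference step.
#' @param m_m,m_n Positions of two distinct non-alpha members.
#' @param lower,upper Box bounds.
#' @return Candidate position, clipped.
#' @export
ihho_alpha_move <- function(m_rab, t, s, gate_rand, step_rand, m_m, m_n,
                            lower, upper) {
  if (tan(pi * (gate_rand - 0.5)) < 1 - t / s) {
    clip_box(m_rab, lower, upper)
  } else {
    clip_box(m_rab + (4 - 4 * t / s) * step_rand * (m_m - m_n), lower, upper)
  }
}

#' Elite update for the second-ranked individual (beta)
#'
#' Keeps the current position when `rand > 0.5`, otherwise moves to the
#' midpoint of the alpha and beta positions.
#'
#' @param m_alpha,m_beta Positions of the two best-ranked individuals.
#' @param rand Uniform random in [0, 1].
#' @param lower,upper Box bounds.
#' @return Candidate position, clipped.
#' @export
ihho_beta_move <- function(m_alpha, m_beta, rand, lower, upper) {
  pos <- if (rand > 0.5) m_beta else (m_alpha + m_beta) / 2
  clip_box(pos, lower, upper)
}

#' Elite update for the third-ranked individual (gamma)
#'
#' With `rand > 0.5` moves to the midpoint of two distinct randomly chosen
#' members `m_e`, `m_f`; otherwise to the centroid of the three elites.
#'
#' @param m_alpha,m_beta,m_gamma Elite positions.
#' @param m_e,m_f Two distinct randomly chosen member positions.
#' @param rand Uniform random in [0, 1].
#' @param lower,upper Box bounds.
#' @return Candidate position, clipped.
#' @export
ihho_gamma_move <- function(m_alpha, m_beta, m_gamma, m_e, m_f, rand,
                            lower, upper) {
  pos <- if (rand > 0.5) (m_e + m_f) / 2 else (m_alpha + m_beta + m_gamma) / 3
  clip_box(pos, lower, upper)
}

#' Run Harris Hawks optimization over a box domain
#'
#' Minimizes `objective` over `[lower, upper]^dim` with the HHO loop: each
#' iteration redraws the prey energy `E = 2 e0 (1 - t/s)`; hawks explore
#' while `|E| >= 1` and otherwise exploit through soft/hard besieges
#' (replacing their position) or progressive rapid dives with Levy flights
#' (greedy acceptance). With `variant = "ihho"`, after ranking, the three
#' best individuals additionally follow the elite update rules
#' ([ihho_alpha_move()], [ihho_beta_move()], [ihho_gamma_move()]), accepted
#' greedily so the best-so-far trace stays monotone.
#'
#' @param objective Function mapping a position vector to a finite scalar;
#'   lower is better.
#' @param config An [hho_config()].
#' @return An object of class `hho_result`: `best_position`,
#'   `best_fitness`, `trace` (best-so-far per iteration, length
#'   `max_iters`), `n_evals`, `elite_evals` (per-iteration elite-update
#'   evaluation counts, `ihho` only), `variant`, `config`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- hho_config(dim = 3, lower = -5, upper = 5, max_iters = 50, seed = 42)
#' fit <- hho_optimize(sphere, cfg)
#' fit$best_fitness
hho_optimize <- function(objective, config) {
  stopifnot(inherits(config, "hho_config"))
  N <- config$n_hawks; s <- config$max_iters; dim <- config$dim
  l <- config$lower; u <- config$upper
  rng <- local_rng(config$seed)

  n_evals <- 0L
  f <- function(x) {
    n_evals <<- n_evals + 1L
    val <- objective(x)
    if (!is.finite(val))
      hawkfs_abort("objective returned a non-finite value", "hawkfs_error_bad_objective")
    val
  }

  positions <- matrix(rng(stats::runif(N * dim, l, u)), N, dim)
  fitness <- apply(positions, 1L, f)
  best_i <- which.min(fitness)
  rabbit <- positions[best_i, ]
  rabbit_fit <- fitness[best_i]

  trace <- numeric(s)
  elite_evals <- integer(s)

  for (t in seq_len(s) - 1L) {
    e0 <- rng(stats::runif(1, -1, 1))
    E <- prey_energy(e0, t, s)
    m_avg <- colMeans(positions)

    for (i in seq_len(N)) {
      m_i <- positions[i, ]
      if (abs(E) >= 1) {
        q <- rng(stats::runif(1))
        r1 <- rng(stats::runif(1)); r2 <- rng(stats::runif(1))
        m_rand <- positions[rng(sample.int(N, 1L)), ]
        newpos <- hho_exploration(m_i, m_rand, rabbit, m_avg, l, u, q, r1, r2)
        positions[i, ] <- newpos
        fitness[i] <- f(newpos)
      } else {
        r_e <- rng(stats::runif(1))
        if (r_e >= 0.5) {
          newpos <- hho_besiege(m_i, rabbit, E, r_e, l, u)
          positions[i, ] <- newpos
          fitness[i] <- f(newpos)
        } else {
          base <- if (abs(E) >= 0.5) m_i else m_avg
          dv <- rng(hho_dive_step(m_i, fitness[i], base, rabbit, E, r_e,
                                  f, l, u, config$levy_beta))
          positions[i, ] <- dv$position
          fitness[i] <- dv$fitness
        }
      }
      if (fitness[i] < rabbit_fit) {
        rabbit_fit <- fitness[i]; rabbit <- positions[i, ]
      }
    }

    if (config$variant == "ihho") {
      before <- n_evals
      ord <- order(fitness)                       # stable: ties by index
      ai <- ord[1L]; bi <- ord[2L]; gi <- ord[3L]

      others <- setdiff(seq_len(N), ai)
      mn <- rng(sample(others, 2L))
      cand <- ihho_alpha_move(rabbit, t, s, rng(stats::runif(1)),
                              rng(stats::runif(1)),
                              positions[mn[1L], ], positions[mn[2L], ], l, u)
      fc <- f(cand)
      if (fc < fitness[ai]) { positions[ai, ] <- cand; fitness[ai] <- fc }

      cand <- ihho_beta_move(positions[ai, ], positions[bi, ],
                             rng(stats::runif(1)), l, u)
      if (!identical(cand, positions[bi, ])) {
        fc <- f(cand)
        if (fc < fitness[bi]) { positions[bi, ] <- cand; fitness[bi] <- fc }
      }

      ef <- rng(sample.int(N, 2L))
      cand <- ihho_gamma_move(positions[ai, ], positions[bi, ], positions[gi, ],
                              positions[ef[1L], ], positions[ef[2L], ],
                              rng(stats::runif(1)), l, u)
      if (!identical(cand, positions[gi, ])) {
        fc <- f(cand)
        if (fc < fitness[gi]) { positions[gi, ] <- cand; fitness[gi] <- fc }
      }

      elite_evals[t + 1L] <- n_evals - before
      best_i <- which.min(fitness)
      if (fitness[best_i] < rabbit_fit) {
        rabbit_fit <- fitness[best_i]; rabbit <- positions[best_i, ]
      }
    }

    trace[t + 1L] <- rabbit_fit
  }

  structure(list(best_position = rabbit, best_fitness = rabbit_fit,
                 trace = trace, n_evals = n_evals,
                 elite_evals = if (config$variant == "ihho") elite_evals else NULL,
                 variant = config$variant, config = config),
            class = "hho_result")
}

#' @export
print.hho_result <- function(x, ...) {
  cat(sprintf("<hho_result> variant %s: best fitness %.6g after %d iterations (%d evaluations)\n",
              x$variant, x$best_fitness, length(x$trace), x$n_evals))
  invisible(x)
}

#' @export
plot.hho_result <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "s",
       xlab = "iteration", ylab = "best-so-far fitness",
       main = sprintf("%s convergence", toupper(x$variant)), ...)
  invisible(x)
}
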