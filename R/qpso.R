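#' Contraction-expansion coefficient schedule
#'
#' Linear decay of the quantum swarm's contraction-expansion (inertia)
#' coefficient from \code{lambdaMax} at iteration 0 to \code{lambdaMin}
#' at \code{tMax}: \eqn{\lambda(t) = \lambda_{max} - (\lambda_{max} -
#' \lambda_{min}) \, t / t_{max}}. Decaying from 1 to 0.5 over the run
#' is the recommended setting.
#'
#' @param t current iteration (0-based, \code{0 <= t <= tMax}).
#' @param tMax total iterations.
#' @param lambdaMax,lambdaMin schedule bounds.
#' @return The coefficient at iteration \code{t}.
#' @examples
#' lambdaSchedule(15, 30, 1, 0.5)   # 0.75
#' @export
lambdaSchedule <- function(t, tMax, lambdaMax = 1, lambdaMin = 0.5) {
  stopIfNot(t >= 0 && t <= tMax, "'t' must lie in [0, tMax]")
  lambdaMax - (lambdaMax - lambdaMin) / tMax * t
}

#' One quantum-behaved particle position update
#'
#' Samples the next position from the quantum potential well around the
#' local attractor \eqn{p = \phi\,pbest + (1-\phi)\,gbest}:
#' \deqn{x' = p \pm \lambda\,|Mbest - x|\,\ln(1/u)}
#' with \code{+} when \eqn{k \ge 0.5} and \code{-} otherwise, clamped
#' to \code{bounds}. \eqn{u, k, \phi} are uniform(0,1] draws supplied
#' by the caller (deterministic unit; the optimizer draws them).
#'
#' @param x current position (numeric vector).
#' @param pbest particle's personal best position.
#' @param gbest swarm's global best position.
#' @param mbest mean of all personal bests.
#' @param lambda contraction-expansion coefficient.
#' @param u,k,phi uniform draws in (0, 1]; vectors are recycled to the
#'   dimension of \code{x}. \code{u = 0} is rejected (ln divergence).
#' @param bounds optional 2-row matrix (\code{rbind(lower, upper)}).
#' @return The updated position.
#' @examples
#' qpsoUpdate(1, 2, 4, 5, 0.75, exp(-1), 0.7, 0.5)   # 6
#' @export
qpsoUpdate <- function(x, pbest, gbest, mbest, lambda, u, k, phi,
                       bounds = NULL) {
  stopIfNot(all(u > 0 & u <= 1), "'u' must lie in (0, 1]")
  stopIfNot(all(k >= 0 & k <= 1), "'k' must lie in [0, 1]")
  stopIfNot(all(phi >= 0 & phi <= 1), "'phi' must lie in [0, 1]")
  p <- phi * pbest + (1 - phi) * gbest
  step <- lambda * abs(mbest - x) * log(1 / u)
  xNew <- ifelse(k >= 0.5, p + step, p - step)
  if (!is.null(bounds))
    xNew <- pmin(pmax(xNew, bounds[1, ]), bounds[2, ])
  xNew
}

#' Tune (C, gamma) with the improved quantum particle swarm
#'
#' Maximizes a fitness function (by default the stratified k-fold CV
#' accuracy of an RBF-SVM, [cvFitness()]) over \code{(log10 C, log10
#' gamma)} within \code{bounds}. Each iteration evaluates the fitness
#' at every particle, updates personal/global bests and the mean best
#' position \eqn{Mbest = \frac{1}{N}\sum_i pbest_i}, sets
#' \eqn{\lambda} by [lambdaSchedule()] (or a fixed value), and moves
#' every particle by [qpsoUpdate()]. Runs are reproducible bit-for-bit
#' given \code{seed}.
#'
#' @param x,y training data for the default fitness; ignored when
#'   \code{fitness} is supplied.
#' @param bounds 2-row matrix of \code{rbind(lower, upper)} in
#'   \code{(log10 C, log10 gamma)} space; default \code{[-3, 4]^2}
#'   (i.e. 0.001 to 10000).
#' @param nParticles swarm size.
#' @param tMax iterations.
#' @param kFolds folds for the default fitness.
#' @param seed integer seed for all randomness (fold assignment
#'   included).
#' @param lambdaMax,lambdaMin schedule bounds; set both equal for the
#'   fixed-coefficient variant.
#' @param fitness optional function(position) -> scalar to maximize
#'   (positions on the log10 scale).
#' @param patience early-stop after this many iterations without any
#'   gbest improvement (Inf to disable).
#' @return List: \code{cost}, \code{gamma} (back on the natural scale),
#'   \code{position} (log10), \code{fitness}, \code{history}
#'   (data.frame per iteration: \code{iteration, gbest_log10C,
#'   gbest_log10gamma, fitness}), \code{evaluations}.
#' @export
iqpsoOptimize <- function(x = NULL, y = NULL,
                          bounds = rbind(c(-3, -3), c(4, 4)),
                          nParticles = 20, tMax = 30, kFolds = 3,
                          seed = 1L, lambdaMax = 1, lambdaMin = 0.5,
                          fitness = NULL, patience = Inf) {
  stopIfNot(nrow(bounds) == 2 && all(bounds[2, ] >= bounds[1, ]),
            "'bounds' must be rbind(lower, upper)")
  dim <- ncol(bounds)
  if (is.null(fitness)) {
    stopIfNot(!is.null(x) && !is.null(y),
              "supply (x, y) or an explicit fitness function")
    fitness <- function(pos)
      cvFitness(x, y, cost = 10^pos[1], gamma = 10^pos[2],
                kFolds = kFolds, seed = childSeed(seed, 999))
  }
  withLocalSeed(childSeed(seed, 1), {
    ## iteration 1 evaluates the seeded swarm; each further iteration
    ## moves and re-evaluates it, so the budget is nParticles * tMax
    pos <- matrix(stats::runif(nParticles * dim, bounds[1, ], bounds[2, ]),
                  nParticles, dim, byrow = TRUE)
    fit <- apply(pos, 1, fitness)
    nEval <- nParticles
    pbest <- pos; pbestFit <- fit
    gi <- which.max(pbestFit)
    gbest <- pbest[gi, ]; gbestFit <- pbestFit[gi]
    hist <- data.frame(iteration = 1, gbest_log10C = gbest[1],
                       gbest_log10gamma = gbest[min(2, dim)],
                       fitness = gbestFit)
    stall <- 0L
    for (t in seq_len(tMax)[-1]) {
      lambda <- lambdaSchedule(t - 1, tMax - 1, lambdaMax, lambdaMin)
      mbest <- colMeans(pbest)
      for (i in seq_len(nParticles)) {
        u <- stats::runif(dim); k <- stats::runif(dim)
        phi <- stats::runif(dim)
        while (any(u == 0)) u[u == 0] <- stats::runif(sum(u == 0))
        pos[i, ] <- qpsoUpdate(pos[i, ], pbest[i, ], gbest, mbest,
                               lambda, u, k, phi, bounds)
      }
      fit <- apply(pos, 1, fitness)
      nEval <- nEval + nParticles
      improve <- fit > pbestFit
      pbest[improve, ] <- pos[improve, , drop = FALSE]
      pbestFit[improve] <- fit[improve]
      gi <- which.max(pbestFit)
      improved <- pbestFit[gi] > gbestFit
      if (improved) { gbest <- pbest[gi, ]; gbestFit <- pbestFit[gi] }
      stall <- if (improved) 0L else stall + 1L
      hist <- rbind(hist, data.frame(
        iteration = t, gbest_log10C = gbest[1],
        gbest_log10gamma = gbest[min(2, dim)], fitness = gbestFit))
      if (stall >= patience) break
    }
    list(cost = 10^gbest[1],
         gamma = if (dim >= 2) 10^gbest[2] else NA_real_,
         position = gbest, fitness = gbestFit, history = hist,
         evaluations = nEval)
  })
}

#' Exhaustive grid search over (C, gamma)
#'
#' Evaluates the cross-validated accuracy at every point of the
#' Cartesian grid and returns the argmax; ties are broken toward
#' smaller C, then smaller gamma (stronger regularization preferred).
#'
#' @param x,y training data.
#' @param cRange,gammaRange numeric vectors of candidate values (on the
#'   natural scale), e.g. \code{seq(1, 10000, by = 100)}.
#' @param kFolds folds for [cvFitness()].
#' @param seed integer seed (fold assignment).
#' @return List: \code{cost}, \code{gamma}, \code{fitness},
#'   \code{surface} (accuracy matrix, C in rows, gamma in columns),
#'   \code{evaluations}.
#' @export
gridSearchSVM <- function(x, y, cRange, gammaRange, kFolds = 3,
                          seed = 1L) {
  stopIfNot(length(cRange) >= 1 && length(gammaRange) >= 1,
            "grid must be nonempty")
  cRange <- sort(cRange); gammaRange <- sort(gammaRange)
  surface <- matrix(NA_real_, length(cRange), length(gammaRange),
                    dimnames = list(C = as.character(cRange),
                                    gamma = as.character(gammaRange)))
  for (i in seq_along(cRange))
    for (j in seq_along(gammaRange))
      surface[i, j] <- cvFitness(x, y, cost = cRange[i],
                                 gamma = gammaRange[j],
                                 kFolds = kFolds,
                                 seed = childSeed(seed, 999))
  best <- which(surface == max(surface), arr.ind = TRUE)
  # ties: smallest C first, then smallest gamma
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(cost = cRange[best[1]], gamma = gammaRange[best[2]],
       fitness = max(surface), surface = surface,
       evaluations = length(surface))
}
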