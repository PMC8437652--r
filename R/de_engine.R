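# Shared low-level RNG primitive. Both the R reference loop and the C++
# generation kernel draw indices as floor(unif * n), so that the two paths
# consume the random stream identically and can be compared draw-for-draw.
sample_int1 <- function(n) {
  v <- as.integer(runif(1L) * n)
  if (v >= n) v <- n - 1L
  v + 1L
}

draw_distinct <- function(n, exclude, count) {
  out <- integer(0)
  taken <- exclude
  while (length(out) < count) {
    r <- sample_int1(n)
    if (!(r %in% taken)) {
      out <- c(out, r)
      taken <- c(taken, r)
    }
  }
  out
}

#' Differential-evolution configuration
#'
#' Bundles the DE control parameters. The defaults are the settings used by
#' the UCI benchmark protocol: mutation factor `F = 0.6`, crossover
#' probability `CR = 0.5`, diversity threshold 0.005, a cap of 1500
#' generations and termination after 400 consecutive generations without
#' improvement of the best fitness. `NP = NULL` means "10 x problem
#' dimension", resolved when the data are known.
#'
#' @param F mutation (scale) factor, > 0.
#' @param CR crossover probability in `[0, 1]`.
#' @param NP population size (>= 4) or NULL for `10 * D`.
#' @param lambda_threshold diversity switch threshold for the
#'   double-mutation strategy.
#' @param max_generations generation cap.
#' @param stagnation_limit terminate after this many consecutive
#'   generations with an unchanged best fitness (exact equality).
#' @param seed optional integer seed applied at run start.
#' @param strategy one of `"rand_1"`, `"best_1"`, `"current_to_best_1"`,
#'   `"double_mutation"`.
#' @param diversity_rms if TRUE, the population spread `sigma` is the
#'   root-mean-square distance to the centroid instead of the mean distance
#'   (sensitivity switch; the mean-distance reading is the default).
#' @return an object of class `de_config`.
#' @export
de_config <- function(F = 0.6, CR = 0.5, NP = NULL,
                      lambda_threshold = 0.005,
                      max_generations = 1500L,
                      stagnation_limit = 400L,
                      seed = NULL,
                      strategy = c("double_mutation", "rand_1", "best_1",
                                   "current_to_best_1"),
                      diversity_rms = FALSE) {
  strategy <- match.arg(strategy)
  if (!is.numeric(F) || F <= 0) stop("de_config: F must be > 0")
  if (CR < 0 || CR > 1) stop("de_config: CR must lie in [0, 1]")
  if (!is.null(NP) && NP < 4L)
    stop("de_config: NP must be >= 4 (mutation needs three distinct partners)")
  if (max_generations < 1L) stop("de_config: max_generations must be >= 1")
  if (stagnation_limit < 1L) stop("de_config: stagnation_limit must be >= 1")
  if (lambda_threshold < 0 && is.finite(lambda_threshold))
    stop("de_config: lambda_threshold must be nonnegative (or -Inf/Inf)")
  structure(list(F = F, CR = CR, NP = if (is.null(NP)) NULL else as.integer(NP),
                 lambda_threshold = lambda_threshold,
                 max_generations = as.integer(max_generations),
                 stagnation_limit = as.integer(stagnation_limit),
                 seed = seed, strategy = strategy,
                 diversity_rms = isTRUE(diversity_rms)),
            class = "de_config")
}

#' Initialize a DE population uniformly inside the search box
#'
#' Each gene of each individual is drawn uniformly from its bound interval.
#' Genes are drawn individual-by-individual (row-major), which fixes the
#' random-stream layout shared with the C++ kernel.
#'
#' @param bounds D x 2 matrix of per-gene `(min, max)` pairs.
#' @param NP population size.
#' @return object of class `de_population`: `genes` (NP x D matrix),
#'   `fitness` (NA until evaluated), `generation`, `bounds`, `best_index`.
#' @export
init_population <- function(bounds, NP) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stop("init_population: bounds must be D x 2")
  if (!all(is.finite(bounds))) stop("init_population: bounds must be finite")
  if (any(bounds[, 1L] > bounds[, 2L]))
    stop("init_population: inverted bounds (min > max)")
  NP <- as.integer(NP)
  if (NP < 4L) stop("init_population: NP must be >= 4")
  D <- nrow(bounds)
  lo <- bounds[, 1L]; span <- bounds[, 2L] - bounds[, 1L]
  genes <- matrix(0, NP, D)
  for (i in seq_len(NP))
    genes[i, ] <- lo + runif(D) * span
  structure(list(genes = genes, fitness = rep(NA_real_, NP),
                 generation = 0L, bounds = bounds, best_index = NA_integer_),
            class = "de_population")
}

#' @export
print.de_population <- function(x, ...) {
  cat(sprintf("<de_population> NP = %d, D = %d, generation %d\n",
              nrow(x$genes), ncol(x$genes), x$generation))
  invisible(x)
}

pop_best_index <- function(pop) {
  if (anyNA(pop$fitness)) stop("population fitness not evaluated")
  which.min(pop$fitness)
}

#' DE/rand/1 mutation
#'
#' Builds the mutant `v = x_r1 + F * (x_r2 - x_r3)` from three population
#' members drawn mutually distinct and distinct from the target index `i`.
#' The chosen indices are attached as attribute `"idx"` so tests can replay
#' the arithmetic.
#'
#' @param pop a [init_population()] population.
#' @param i target (parent) index.
#' @param F mutation factor.
#' @return length-D mutant vector with attribute `idx = c(r1, r2, r3)`.
#' @export
mutate_rand_1 <- function(pop, i, F) {
  NP <- nrow(pop$genes)
  if (NP < 4L) stop("mutate_rand_1: NP must be >= 4")
  r <- draw_distinct(NP, i, 3L)
  v <- pop$genes[r[1L], ] + F * (pop$genes[r[2L], ] - pop$genes[r[3L], ])
  attr(v, "idx") <- r
  v
}

#' DE/best/1 mutation
#'
#' `v = x_best + F * (x_r1 - x_r2)` with `r1 != r2`, both distinct from the
#' target `i`; `x_best` is the current best-fitness individual.
#'
#' @inheritParams mutate_rand_1
#' @return length-D mutant vector with attribute `idx = c(r1, r2)`.
#' @export
mutate_best_1 <- function(pop, i, F) {
  NP <- nrow(pop$genes)
  if (NP < 4L) stop("mutate_best_1: NP must be >= 4")
  b <- pop_best_index(pop)
  r <- draw_distinct(NP, i, 2L)
  v <- pop$genes[b, ] + F * (pop$genes[r[1L], ] - pop$genes[r[2L], ])
  attr(v, "idx") <- r
  v
}

#' DE/current-to-best/1 mutation
#'
#' `v = x_i + F * (x_best - x_i) + F * (x_r1 - x_r2)`. Provided for
#' completeness; the double-mutation scheme only switches between
#' DE/rand/1 and DE/best/1.
#'
#' @inheritParams mutate_rand_1
#' @return length-D mutant vector with attribute `idx = c(r1, r2)`.
#' @export
mutate_current_to_best_1 <- function(pop, i, F) {
  NP <- nrow(pop$genes)
  if (NP < 4L) stop("mutate_current_to_best_1: NP must be >= 4")
  b <- pop_best_index(pop)
  r <- draw_distinct(NP, i, 2L)
  v <- pop$genes[i, ] + F * (pop$genes[b, ] - pop$genes[i, ]) +
    F * (pop$genes[r[1L], ] - pop$genes[r[2L], ])
  attr(v, "idx") <- r
  v
}

#' Binomial (uniform) crossover
#'
#' Gene j of the trial vector comes from the mutant when `u_j <= CR` or
#' `j == j_rand`, otherwise from the parent. The guaranteed index `j_rand`
#' (uniform over genes) ensures at least one mutant gene even at `CR = 0`.
#'
#' @param parent,mutant numeric vectors of equal length.
#' @param CR crossover probability in `[0, 1]`.
#' @return trial vector; attribute `j_rand` records the guaranteed index.
#' @export
binomial_crossover <- function(parent, mutant, CR) {
  if (length(parent) != length(mutant))
    stop("binomial_crossover: parent and mutant differ in length")
  D <- length(parent)
  j_rand <- sample_int1(D)
  u <- runif(D)
  take <- u <= CR
  take[j_rand] <- TRUE
  trial <- ifelse(take, mutant, parent)
  attr(trial, "j_rand") <- j_rand
  trial
}

#' Greedy one-to-one selection
#'
#' The trial replaces the parent only when its fitness is strictly smaller;
#' ties keep the parent.
#'
#' @param parent,trial lists with fields `genes` and `fitness`.
#' @return whichever of the two survives.
#' @export
de_select <- function(parent, trial) {
  if (is.na(parent$fitness) || is.na(trial$fitness))
    stop("de_select: both fitnesses must be evaluated")
  if (trial$fitness < parent$fitness) trial else parent
}

#' Population-diversity indicator lambda(g)
#'
#' Computes the central individual `mu` (coordinate-wise mean), the spread
#' `sigma` (mean Euclidean distance from individuals to `mu`; RMS variant
#' behind `rms = TRUE`), and the scale-free indicator
#' `lambda = sigma / ||mu||`. Small lambda means the population has
#' collapsed. When `||mu|| = 0` the ratio is undefined and `lambda` is
#' returned as `+Inf` (treated as "diverse" by the double-mutation switch).
#'
#' @param pop a population (or a plain NP x D matrix of genes).
#' @param rms use root-mean-square spread instead of mean distance.
#' @return object of class `de_diversity`: `mu`, `sigma`, `lambda`.
#' @export
diversity_lambda <- function(pop, rms = FALSE) {
  genes <- if (inherits(pop, "de_population")) pop$genes else as.matrix(pop)
  NP <- nrow(genes)
  if (NP < 1L) stop("diversity_lambda: empty population")
  mu <- colMeans(genes)
  df <- sweep(genes, 2L, mu, "-")
  dist <- sqrt(rowSums(df * df))
  # sum()/NP rather than mean(): mean()'s two-pass correction would desync
  # this value from the C++ kernel's accumulator at the last bit
  sigma <- if (isTRUE(rms)) sqrt(sum(dist^2) / NP) else sum(dist) / NP
  nmu <- sqrt(sum(mu^2))
  lam <- if (nmu > 0) sigma / nmu else Inf
  structure(list(mu = mu, sigma = sigma, lambda = lam),
            class = "de_diversity")
}

#' @export
print.de_diversity <- function(x, ...) {
  cat(sprintf("<de_diversity> sigma = %.6g, lambda = %.6g\n",
              x$sigma, x$lambda))
  invisible(x)
}
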