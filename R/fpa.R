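#' Flower pollination algorithm configuration
#'
#' @param population_size number of pollen (candidate solutions), >= 2.
#' @param max_iter iteration budget.
#' @param switch_p probability of taking the global (biotic, Levy-flight)
#'   move rather than the local (abiotic) move; default 0.8.
#' @param levy_lambda Levy tail index lambda in (0, 2); default 0.5
#'   (1.5 is the other common choice; both are supported).
#' @param levy_scale multiplier applied to Levy steps (default 0.1).
#' @param bounds numeric length-2 search interval in Hz, or `NULL` to use the
#'   spectrum's band range.
#' @param rng_seed integer seed for reproducible runs, or `NULL`.
#' @param stagnation stop after this many consecutive iterations without
#'   improvement of the best fitness (default 20).
#' @return an `fpa_config` object.
#' @export
fpa_config <- function(population_size = 25L, max_iter = 100L, switch_p = 0.8,
                       levy_lambda = 0.5, levy_scale = 0.1, bounds = NULL,
                       rng_seed = NULL, stagnation = 20L) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (switch_p < 0 || switch_p > 1) stop("switch_p must be in [0, 1]")
  if (levy_lambda <= 0 || levy_lambda >= 2) stop("levy_lambda must be in (0, 2)")
  if (!is.null(bounds) && (length(bounds) != 2 || bounds[2] <= bounds[1])) {
    stop("bounds must be an ordered pair")
  }
  structure(list(population_size = as.integer(population_size),
                 max_iter = as.integer(max_iter), switch_p = switch_p,
                 levy_lambda = levy_lambda, levy_scale = levy_scale,
                 bounds = bounds, rng_seed = rng_seed,
                 stagnation = as.integer(stagnation)),
            class = "fpa_config")
}

#' Levy-flight step sizes (Mantegna's algorithm)
#'
#' Heavy-tailed random steps with tail index `levy_lambda`: the survival
#' function of |L| decays like `s^(-lambda)`. Steps are generated as
#' `u / |v|^(1/lambda)` with `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and
#' Mantegna's variance choice, then multiplied by `levy_scale`.
#'
#' @param cfg an [fpa_config()] (fields `levy_lambda`, `levy_scale` used).
#' @param count number of steps to draw.
#' @return numeric vector of `count` signed step sizes.
#' @export
levy_step <- function(cfg, count) {
  if (count < 0) stop("count must be >= 0")
  lam <- cfg$levy_lambda
  if (lam <= 0 || lam >= 2) stop("levy_lambda must be in (0, 2)")
  sigma_u <- (gamma(1 + lam) * sin(pi * lam / 2) /
                (gamma((1 + lam) / 2) * lam * 2^((lam - 1) / 2)))^(1 / lam)
  u <- rnorm(count, 0, sigma_u)
  v <- rnorm(count)
  cfg$levy_scale * u / abs(v)^(1 / lam)
}

#' Flower pollination optimization of a 1-D objective
#'
#' Maximizes `objective` over `cfg$bounds` starting from a seed solution.
#' The population is initialized with the seed plus uniform random members.
#' Each iteration, every pollen takes the global (biotic) move
#' `x + L * (g* - x)` with probability `switch_p` (L a Levy step, `g*` the
#' current best) or the local (abiotic) move `x + eps * (x_j - x_k)` with
#' `eps ~ U(0, 1)` and random distinct partners. Candidates are clipped to
#' the bounds and accepted greedily; the best solution is therefore
#' monotonically non-decreasing in fitness (elitism).
#'
#' @param objective function mapping a numeric vector of solutions to their
#'   fitness values (must be vectorized).
#' @param seed_solution starting solution inside the bounds.
#' @param cfg an [fpa_config()] with non-`NULL` `bounds`.
#' @return An object of class `fpa_result`: `best`, `best_fitness`,
#'   `history` (best fitness per iteration), `n_iter`.
#' @export
fpa_optimize <- function(objective, seed_solution, cfg = fpa_config()) {
  if (is.null(cfg$bounds)) stop("cfg$bounds must be set")
  lo <- cfg$bounds[1]; hi <- cfg$bounds[2]
  if (hi <= lo) stop("empty bounds")
  with_seed(cfg$rng_seed, {
    np <- cfg$population_size
    x <- c(seed_solution, runif(np - 1, lo, hi))
    fit <- objective(x)
    bi <- which.max(fit)
    best <- x[bi]; best_fit <- fit[bi]
    history <- numeric(0)
    stag <- 0L
    n_iter <- 0L
    for (t in seq_len(cfg$max_iter)) {
      n_iter <- t
      glob <- runif(np) < cfg$switch_p
      cand <- x
      ng <- sum(glob)
      if (ng > 0) {
        L <- levy_step(cfg, ng)
        cand[glob] <- x[glob] + L * (best - x[glob])
      }
      nl <- np - ng
      if (nl > 0) {
        li <- which(!glob)
        eps <- runif(nl)
        for (m in seq_len(nl)) {
          jk <- sample(seq_len(np)[-li[m]], 2L)  # distinct partners, not self
          cand[li[m]] <- x[li[m]] + eps[m] * (x[jk[1]] - x[jk[2]])
        }
      }
      cand <- pmin(pmax(cand, lo), hi)
      cf <- objective(cand)
      acc <- cf > fit
      x[acc] <- cand[acc]
      fit[acc] <- cf[acc]
      bi <- which.max(fit)
      if (fit[bi] > best_fit) {
        best_fit <- fit[bi]; best <- x[bi]; stag <- 0L
      } else {
        stag <- stag + 1L
      }
      history <- c(history, best_fit)
      if (stag >= cfg$stagnation) break
    }
    structure(list(best = best, best_fitness = best_fit, history = history,
                   n_iter = n_iter),
              class = "fpa_result")
  })
}

#' Critical spectral verge (CSV) of a band spectrum
#'
#' The CSV is the spectral-verge frequency refined by flower pollination
#' optimization: the objective assigns to a candidate frequency the value of
#' its nearest PSD bin's frequency when that bin's PSD strictly exceeds the
#' band's average spectral power, and a large negative penalty otherwise. The
#' plain spectral verge is used as the seed solution, so by elitism the CSV
#' is never worse than the verge. When no bin exceeds the average, the
#' sentinel (`NA`, `valid = FALSE`) propagates.
#'
#' @param spectrum a `band_spectrum` from [compute_psd()].
#' @param cfg an [fpa_config()]; `bounds = NULL` means the band's frequency
#'   range.
#' @return list with `frequency` (Hz at a PSD bin, or `NA`), `valid`, and
#'   `fpa` (the underlying `fpa_result`, or `NULL` for sentinels).
#' @export
compute_csv <- function(spectrum, cfg = fpa_config()) {
  freqs <- spectrum$freqs
  psd <- spectrum$psd
  avg <- spectrum$ps_avg
  passing <- psd > avg
  if (!any(passing)) {
    return(list(frequency = NA_real_, valid = FALSE, fpa = NULL))
  }
  if (length(freqs) == 1) {
    return(list(frequency = freqs, valid = TRUE, fpa = NULL))
  }
  nearest_bin <- function(f) {
    pmax(1L, pmin(length(freqs), as.integer(round((f - freqs[1]) /
                                                    (freqs[2] - freqs[1]))) + 1L))
  }
  objective <- function(f) {
    b <- nearest_bin(f)
    ifelse(passing[b], freqs[b], -1e12)
  }
  if (is.null(cfg$bounds)) cfg$bounds <- range(freqs)
  sv <- spectral_verge(spectrum)
  seed <- if (sv$valid) sv$frequency else mean(cfg$bounds)
  res <- fpa_optimize(objective, seed, cfg)
  list(frequency = freqs[nearest_bin(res$best)], valid = TRUE, fpa = res)
}
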