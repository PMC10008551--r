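# Bayesian dietary mixing in the FRUITS/ReSources tradition: caloric source
# contributions alpha live on the simplex, consumer proxies are predicted by
# concentration-weighted mixing within macronutrient fractions, routed into
# each tissue proxy, offset by diet-to-tissue enrichment, and compared to
# group targets under a Gaussian likelihood. Source signals, concentrations
# and offsets are latent nuisance parameters sampled inside the MCMC.

.fractions <- c("protein", "energy")

#' Define a food source for the mixing model
#'
#' A source carries, per macronutrient fraction (protein / energy), the
#' isotopic signal of that fraction for each proxy signal (d13C, d15N) as
#' mean and sd, plus the caloric concentration of each fraction (fractions
#' of total calories, summing to 1) with an sd on the protein share.
#'
#' @param name source name (e.g. "C3 plants", "marine fish").
#' @param protein named list of signals for the protein fraction, each a
#'   `c(mean, sd)` pair, e.g. `list(d13C = c(-26, 0.5), d15N = c(3, 1))`.
#' @param energy named list of signals for the energy (carbohydrate + lipid)
#'   fraction, e.g. `list(d13C = c(-26.5, 0.5))`.
#' @param concentration `c(protein, energy)` caloric fractions, must sum
#'   to 1.
#' @param concentration_sd sd of the protein caloric fraction.
#' @return a `food_source` list.
#' @export
food_source <- function(name, protein, energy,
                        concentration = c(protein = 0.15, energy = 0.85),
                        concentration_sd = 0.02) {
  stopifnot(is.character(name), length(concentration) == 2)
  if (abs(sum(concentration) - 1) > 1e-6)
    stop(sprintf("concentrations of source '%s' must sum to 1", name))
  chk <- function(sig) {
    for (s in sig) stopifnot(length(s) == 2, s[2] >= 0)
  }
  chk(protein); chk(energy)
  stopifnot(concentration_sd >= 0)
  structure(list(name = name,
                 signals = list(protein = protein, energy = energy),
                 concentration = setNames(as.numeric(concentration),
                                          .fractions),
                 concentration_sd = concentration_sd),
            class = "food_source")
}

#' Define a consumer proxy for the mixing model
#'
#' @param name proxy name, e.g. `"d13C_coll"`.
#' @param signal which source signal it draws on (`"d13C"` or `"d15N"`).
#' @param target_mean,target_sd consumer group mean and sd, per mil.
#' @param offset_mean,offset_sd diet-to-tissue offset, per mil.
#' @param routing named weights over fractions (protein, energy) summing
#'   to 1: which macronutrients the tissue proxy is synthesized from.
#' @return a `mixing_proxy` list.
#' @export
mixing_proxy <- function(name, signal, target_mean, target_sd,
                         offset_mean, offset_sd,
                         routing = c(protein = 1, energy = 0)) {
  stopifnot(signal %in% c("d13C", "d15N"), target_sd > 0, offset_sd >= 0)
  routing <- routing[.fractions]
  routing[is.na(routing)] <- 0
  names(routing) <- .fractions
  if (abs(sum(routing) - 1) > 1e-6)
    stop(sprintf("routing weights of proxy '%s' must sum to 1", name))
  structure(list(name = name, signal = signal,
                 target_mean = target_mean, target_sd = target_sd,
                 offset_mean = offset_mean, offset_sd = offset_sd,
                 routing = routing),
            class = "mixing_proxy")
}

#' Linear inequality prior on source contributions
#'
#' Represents `sum(coef * alpha) >= rhs` (or `<=`). For example
#' `mixing_constraint(c("C3 plants" = 1), 0.3)` demands at least a 30%
#' caloric contribution from C3 plants.
#'
#' @param coef named numeric vector over source names.
#' @param rhs right-hand side.
#' @param op `">="` or `"<="`.
#' @return a `mixing_constraint` list.
#' @export
mixing_constraint <- function(coef, rhs, op = ">=") {
  op <- match.arg(op, c(">=", "<="))
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  structure(list(coef = coef, rhs = rhs, op = op),
            class = "mixing_constraint")
}

#' Assemble and validate a dietary mixing problem
#'
#' Checks structural validity (routing rows sum to 1, every routed fraction
#' is represented with positive caloric concentration in at least one
#' source, every proxy's signal is defined for every source fraction it
#' routes through) and prior feasibility: constraints are screened by
#' uniform sampling on the simplex and rejected if no sampled point
#' satisfies them all.
#'
#' @param sources list of [food_source()] (2 or more for a non-degenerate
#'   problem; a single source is allowed and yields a point posterior).
#' @param proxies list of [mixing_proxy()].
#' @param constraints list of [mixing_constraint()] (may be empty: uniform
#'   simplex prior).
#' @param feasibility_draws simplex points sampled in the feasibility check.
#' @return a `mixing_problem` object.
#' @export
build_problem <- function(sources, proxies, constraints = list(),
                          feasibility_draws = 200000) {
  stopifnot(length(sources) >= 1, length(proxies) >= 1)
  src_names <- vapply(sources, `[[`, character(1), "name")
  if (anyDuplicated(src_names)) stop("duplicate source names")
  K <- length(sources)

  for (px in proxies) {
    for (f in .fractions) {
      if (px$routing[[f]] > 0) {
        tot_conc <- sum(vapply(sources, function(s)
          s$concentration[[f]], numeric(1)))
        if (tot_conc <= 0)
          stop(sprintf(
            "proxy '%s' routes through fraction '%s' but no source has positive caloric concentration there",
            px$name, f))
        for (s in sources)
          if (is.null(s$signals[[f]][[px$signal]]))
            stop(sprintf("source '%s' lacks a %s signal for fraction '%s'",
                         s$name, px$signal, f))
      }
    }
  }

  cm <- .constraint_matrices(constraints, src_names)
  if (nrow(cm$A) > 0) {
    # seeded sampling so validation is deterministic; caller's RNG restored
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(285714L)
    pts <- .runif_simplex(feasibility_draws, K)
    sat <- pts %*% t(cm$A) >= matrix(cm$b, nrow(pts), length(cm$b),
                                     byrow = TRUE)
    ok <- any(rowSums(sat) == length(cm$b))
    if (!ok) {
      worst <- which.min(colSums(sat))
      stop(sprintf(
        "infeasible prior constraints: no point of the simplex satisfied all %d constraints (least often satisfied: #%d)",
        length(cm$b), worst))
    }
  }

  structure(list(sources = sources, proxies = proxies,
                 constraints = constraints,
                 source_names = src_names),
            class = "mixing_problem")
}

# constraints -> A alpha >= b over the source order src_names
.constraint_matrices <- function(constraints, src_names) {
  K <- length(src_names)
  if (!length(constraints))
    return(list(A = matrix(0, 0, K), b = numeric(0)))
  A <- t(vapply(constraints, function(cn) {
    v <- setNames(numeric(K), src_names)
    unknown <- setdiff(names(cn$coef), src_names)
    if (length(unknown))
      stop("constraint references unknown source(s): ",
           paste(unknown, collapse = ", "))
    v[names(cn$coef)] <- cn$coef
    if (cn$op == "<=") -v else v
  }, numeric(K)))
  b <- vapply(constraints, function(cn)
    if (cn$op == "<=") -cn$rhs else cn$rhs, numeric(1))
  list(A = matrix(A, ncol = K), b = b)
}

# uniform draws on the K-simplex (Dirichlet(1,...,1))
.runif_simplex <- function(n, K) {
  g <- matrix(-log(runif(n * K)), n, K)
  g / rowSums(g)
}

# Flatten a mixing_problem into the arrays the compiled sampler consumes.
.problem_arrays <- function(p) {
  K <- length(p$sources); P <- length(p$proxies); Fn <- length(.fractions)
  sig_mean <- array(0, c(K, Fn, P)); sig_sd <- array(0, c(K, Fn, P))
  conc_mean <- matrix(0, K, Fn); conc_sd <- numeric(K)
  for (k in seq_len(K)) {
    s <- p$sources[[k]]
    conc_mean[k, ] <- s$concentration[.fractions]
    conc_sd[k] <- s$concentration_sd
    for (f in seq_len(Fn)) for (i in seq_len(P)) {
      sig <- s$signals[[.fractions[f]]][[p$proxies[[i]]$signal]]
      if (!is.null(sig)) { sig_mean[k, f, i] <- sig[1]; sig_sd[k, f, i] <- sig[2] }
    }
  }
  routing <- t(vapply(p$proxies, function(px) px$routing, numeric(Fn)))
  cm <- .constraint_matrices(p$constraints, p$source_names)
  list(K = K, P = P, Fn = Fn,
       sig_mean = sig_mean, sig_sd = sig_sd,
       conc_mean = conc_mean, conc_sd = conc_sd,
       routing = matrix(routing, ncol = Fn),
       offset_mean = vapply(p$proxies, `[[`, numeric(1), "offset_mean"),
       offset_sd = vapply(p$proxies, `[[`, numeric(1), "offset_sd"),
       target_mean = vapply(p$proxies, `[[`, numeric(1), "target_mean"),
       target_sd = vapply(p$proxies, `[[`, numeric(1), "target_sd"),
       A = cm$A, b = cm$b)
}

#' Deterministic forward model: proxies predicted from contributions
#'
#' For proxy i, `pred_i = offset_i + sum_f routing_{i,f} *
#' (sum_k alpha_k c_{k,f} s_{k,f,i}) / (sum_k alpha_k c_{k,f})`, where
#' `c` is the caloric concentration of fraction f in source k and `s` that
#' fraction's signal for the proxy. Evaluated at the mean signals,
#' concentrations and offsets unless latent values are supplied.
#'
#' @param alpha contribution vector on the simplex (named or in source
#'   order).
#' @param problem a [build_problem()] result.
#' @return named numeric vector of predicted proxy means, per mil.
#' @export
forward_model <- function(alpha, problem) {
  arr <- .problem_arrays(problem)
  alpha <- .check_alpha(alpha, problem)
  pred <- numeric(arr$P)
  for (i in seq_len(arr$P)) {
    acc <- 0
    for (f in seq_len(arr$Fn)) {
      w <- arr$routing[i, f]
      if (w == 0) next
      denom <- sum(alpha * arr$conc_mean[, f])
      if (denom <= 0)
        stop("zero total caloric concentration in a routed fraction")
      acc <- acc + w * sum(alpha * arr$conc_mean[, f] *
                             arr$sig_mean[, f, i]) / denom
    }
    pred[i] <- arr$offset_mean[i] + acc
  }
  setNames(pred, vapply(problem$proxies, `[[`, character(1), "name"))
}

.check_alpha <- function(alpha, problem) {
  K <- length(problem$sources)
  if (!is.null(names(alpha))) alpha <- alpha[problem$source_names]
  stopifnot(length(alpha) == K, all(alpha >= -1e-9))
  if (abs(sum(alpha) - 1) > 1e-6) stop("alpha must sum to 1")
  as.numeric(alpha)
}

#' Sample the posterior of caloric source contributions
#'
#' Random-walk Metropolis on the softmax-transformed simplex with a
#' uniform-simplex base prior, inequality priors enforced by rejection at
#' proposal time, and source signals, caloric concentrations and
#' diet-to-tissue offsets treated as latent nuisance values refreshed each
#' iteration by an independence Metropolis step with the prior as proposal.
#' Step size adapts toward a 30% acceptance rate during burn-in only.
#' Convergence is monitored with split-chain potential scale reduction and
#' a warning (with diagnostics attached) is raised if any contribution has
#' R-hat above 1.05.
#'
#' @param problem a [build_problem()] result.
#' @param chains number of chains.
#' @param iter iterations per chain (including burn-in).
#' @param burn_in iterations discarded per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed (mandatory: runs are reproducible).
#' @param step initial random-walk step size on the softmax scale.
#' @return a `diet_posterior` object with `draws` (matrix, one column per
#'   source), `diagnostics` (`rhat`, `ess`, `accept_rate`), and `settings`.
#' @export
sample_posterior <- function(problem, chains = 4, iter = 4000,
                             burn_in = floor(iter / 2), thin = 2,
                             seed, step = 0.5) {
  if (missing(seed)) stop("a seed is mandatory for reproducible sampling")
  stopifnot(chains >= 1, iter > burn_in, burn_in >= 0, thin >= 1)
  arr <- .problem_arrays(problem)
  K <- arr$K
  if (K == 1) {
    n_keep <- chains * floor((iter - burn_in) / thin)
    draws <- matrix(1, n_keep, 1,
                    dimnames = list(NULL, problem$source_names))
    return(structure(list(draws = draws,
                          diagnostics = list(rhat = setNames(1, problem$source_names),
                                             ess = setNames(n_keep, problem$source_names),
                                             accept_rate = NA_real_),
                          settings = list(chains = chains, iter = iter,
                                          burn_in = burn_in, thin = thin,
                                          seed = seed),
                          problem = problem),
                     class = "diet_posterior"))
  }
  set.seed(seed)
  chain_draws <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    init <- .feasible_start(arr, K)
    res <- mix_mcmc_chain(arr$sig_mean, arr$sig_sd, arr$conc_mean,
                          arr$conc_sd, arr$routing, arr$offset_mean,
                          arr$offset_sd, arr$target_mean, arr$target_sd,
                          arr$A, arr$b, init,
                          as.integer(iter), as.integer(burn_in),
                          as.integer(thin), step)
    chain_draws[[ch]] <- res$draws
    acc[ch] <- res$accept_rate
  }
  draws <- do.call(rbind, chain_draws)
  colnames(draws) <- problem$source_names
  diag <- .mcmc_diagnostics(chain_draws, problem$source_names)
  diag$accept_rate <- mean(acc)
  post <- structure(list(draws = draws, diagnostics = diag,
                         settings = list(chains = chains, iter = iter,
                                         burn_in = burn_in, thin = thin,
                                         seed = seed, step = step),
                         problem = problem),
                    class = "diet_posterior")
  if (any(diag$rhat > 1.05, na.rm = TRUE)) {
    warning(sprintf(
      "posterior may not have converged: max R-hat %.3f (threshold 1.05); inspect $diagnostics",
      max(diag$rhat, na.rm = TRUE)))
    attr(post, "converged") <- FALSE
  } else attr(post, "converged") <- TRUE
  post
}

# random feasible simplex point for chain initialization
.feasible_start <- function(arr, K) {
  for (i in 1:20000) {
    a <- as.numeric(.runif_simplex(1, K))
    if (nrow(arr$A) == 0 || all(arr$A %*% a >= arr$b - 1e-12)) return(a)
  }
  stop("could not find a feasible starting point; constraints too tight")
}

# split-chain potential scale reduction + crude autocorrelation ESS
.mcmc_diagnostics <- function(chain_draws, src_names) {
  K <- ncol(chain_draws[[1]])
  halves <- list()
  for (d in chain_draws) {
    n <- nrow(d); h <- floor(n / 2)
    halves <- c(halves, list(d[1:h, , drop = FALSE],
                             d[(h + 1):(2 * h), , drop = FALSE]))
  }
  rhat <- numeric(K); ess <- numeric(K)
  all_draws <- do.call(rbind, chain_draws)
  for (k in seq_len(K)) {
    m <- length(halves); n <- nrow(halves[[1]])
    means <- vapply(halves, function(h) mean(h[, k]), numeric(1))
    vars <- vapply(halves, function(h) var(h[, k]), numeric(1))
    W <- mean(vars); B <- n * var(means)
    if (W < 1e-12) { rhat[k] <- 1 } else {
      rhat[k] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
    x <- all_draws[, k] - mean(all_draws[, k])
    if (sd(x) < 1e-12) { ess[k] <- length(x); next }
    ac <- stats::acf(x, lag.max = min(200, length(x) - 1),
                     plot = FALSE)$acf[-1]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1] - 1 else length(ac)
    ess[k] <- length(x) / (1 + 2 * sum(ac[seq_len(cut)]))
  }
  list(rhat = setNames(rhat, src_names), ess = setNames(ess, src_names))
}

#' Summarize a dietary posterior
#'
#' Per-source posterior mean, median, and equal-tailed 68% and 95% credible
#' intervals (empirical quantiles of the draws), plus the derived caloric
#' split between protein and non-protein (energy) macronutrients obtained
#' by weighting each draw by the sources' mean caloric concentrations.
#'
#' @param post a `diet_posterior`.
#' @return list with `sources` (data.frame) and `macronutrients`
#'   (data.frame with the protein vs energy caloric split).
#' @export
summarize_posterior <- function(post) {
  stopifnot(inherits(post, "diet_posterior"))
  d <- post$draws
  qs <- function(x) quantile(x, c(0.025, 0.16, 0.5, 0.84, 0.975),
                             names = FALSE, type = 7)
  tab <- t(apply(d, 2, function(x) c(mean(x), qs(x))))
  sources <- data.frame(source = colnames(d), mean = tab[, 1],
                        ci95_low = tab[, 2], ci68_low = tab[, 3],
                        median = tab[, 4], ci68_high = tab[, 5],
                        ci95_high = tab[, 6], row.names = NULL)
  cp <- vapply(post$problem$sources, function(s)
    s$concentration[["protein"]], numeric(1))
  prot <- as.numeric(d %*% cp)
  mtab <- rbind(protein = c(mean(prot), qs(prot)),
                energy = c(mean(1 - prot), qs(1 - prot)))
  macronutrients <- data.frame(fraction = rownames(mtab),
                               mean = mtab[, 1], ci95_low = mtab[, 2],
                               ci68_low = mtab[, 3], median = mtab[, 4],
                               ci68_high = mtab[, 5], ci95_high = mtab[, 6],
                               row.names = NULL)
  list(sources = sources, macronutrients = macronutrients)
}

#' @export
print.diet_posterior <- function(x, ...) {
  cat(sprintf("Dietary posterior: %d draws x %d sources (max R-hat %.3f)\n",
              nrow(x$draws), ncol(x$draws),
              max(x$diagnostics$rhat, na.rm = TRUE)))
  print(summarize_posterior(x)$sources, digits = 3)
  invisible(x)
}

#' Default seven-source medieval Mediterranean food web
#'
#' A configurable starting point covering the food groups typically used
#' for medieval southern-European dietary reconstruction: C3 plants, C4
#' cereals (millet/sorghum), cattle, ovicaprid, pig, poultry, and marine
#' fish. Signal means/sds are standard literature values for protein and
#' energy macronutrient fractions; they are defaults, not data, and every
#' number can be overridden.
#'
#' @return named list of [food_source()] objects.
#' @export
default_sources <- function() {
  list(
    food_source("C3 plants",
                protein = list(d13C = c(-26.0, 0.5), d15N = c(3.0, 1.0)),
                energy = list(d13C = c(-26.5, 0.5)),
                concentration = c(protein = 0.12, energy = 0.88),
                concentration_sd = 0.02),
    food_source("C4 cereals",
                protein = list(d13C = c(-11.5, 0.5), d15N = c(4.0, 1.0)),
                energy = list(d13C = c(-12.0, 0.5)),
                concentration = c(protein = 0.11, energy = 0.89),
                concentration_sd = 0.02),
    food_source("cattle",
                protein = list(d13C = c(-20.5, 0.5), d15N = c(6.5, 1.0)),
                energy = list(d13C = c(-27.0, 1.0)),
                concentration = c(protein = 0.5, energy = 0.5),
                concentration_sd = 0.05),
    food_source("ovicaprid",
                protein = list(d13C = c(-20.5, 0.5), d15N = c(6.0, 1.0)),
                energy = list(d13C = c(-27.0, 1.0)),
                concentration = c(protein = 0.5, energy = 0.5),
                concentration_sd = 0.05),
    food_source("pig",
                protein = list(d13C = c(-20.8, 0.5), d15N = c(7.0, 1.0)),
                energy = list(d13C = c(-26.5, 1.0)),
                concentration = c(protein = 0.45, energy = 0.55),
                concentration_sd = 0.05),
    food_source("poultry",
                protein = list(d13C = c(-20.5, 0.5), d15N = c(8.0, 1.0)),
                energy = list(d13C = c(-25.0, 1.0)),
                concentration = c(protein = 0.55, energy = 0.45),
                concentration_sd = 0.05),
    food_source("marine fish",
                protein = list(d13C = c(-12.0, 1.0), d15N = c(12.0, 1.5)),
                energy = list(d13C = c(-14.0, 1.0)),
                concentration = c(protein = 0.75, energy = 0.25),
                concentration_sd = 0.05)
  )
}

#' Default proxy set for bone collagen and bioapatite targets
#'
#' Collagen carbon is routed 75% through dietary protein and 25% through
#' energy macronutrients; collagen nitrogen 100% through protein; bioapatite
#' carbonate carbon 100% through the energy (whole-diet caloric) pool.
#' Diet-to-tissue offsets default to +4.8 +/- 0.5 (collagen d13C),
#' +5.5 +/- 0.5 (d15N) and +10.1 +/- 1.0 (carbonate d13C) per mil.
#'
#' @param d13C_coll,d15N,d13C_carb `c(mean, sd)` consumer group targets,
#'   per mil; pass `NULL` to drop a proxy.
#' @return list of [mixing_proxy()] objects.
#' @export
default_proxies <- function(d13C_coll = c(-19.0, 0.7),
                            d15N = c(10.0, 1.0),
                            d13C_carb = c(-12.3, 1.2)) {
  out <- list()
  if (!is.null(d13C_coll))
    out <- c(out, list(mixing_proxy("d13C_coll", "d13C",
                                    d13C_coll[1], d13C_coll[2],
                                    offset_mean = 4.8, offset_sd = 0.5,
                                    routing = c(protein = 0.75, energy = 0.25))))
  if (!is.null(d15N))
    out <- c(out, list(mixing_proxy("d15N", "d15N", d15N[1], d15N[2],
                                    offset_mean = 5.5, offset_sd = 0.5,
                                    routing = c(protein = 1, energy = 0))))
  if (!is.null(d13C_carb))
    out <- c(out, list(mixing_proxy("d13C_carb", "d13C",
                                    d13C_carb[1], d13C_carb[2],
                                    offset_mean = 10.1, offset_sd = 1.0,
                                    routing = c(protein = 0, energy = 1))))
  out
}
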