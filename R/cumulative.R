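# pmf of a sum of independent Bernoulli(p_t) indicators, by convolution
pois_binom_pmf <- function(p) {
  f <- 1
  for (pt in p) f <- c(f * (1 - pt), 0) + c(0, f * pt)
  f
}

# P(count >= k) for k = 0..M from a count pmf (length M + 1)
tail_from_pmf <- function(pmf) rev(cumsum(rev(pmf)))

new_cumulative_result <- function(center, M, p_at_least, engine,
                                  clipped_mass = NA_real_, se = NULL) {
  structure(list(center = center, M = M, k = 0:M,
                 p_at_least = as.numeric(p_at_least),
                 engine = engine, clipped_mass = clipped_mass, se = se),
            class = "cumulative_result")
}

#' @export
print.cumulative_result <- function(x, ...) {
  cat(sprintf("<cumulative_result> centre %s, M = %d (engine: %s)\n",
              x$center, x$M, x$engine))
  df <- data.frame(k = x$k, p_at_least = round(x$p_at_least, 4))
  print(utils::head(df, 12), row.names = FALSE)
  if (x$M + 1 > 12) cat(sprintf("... %d more rows\n", x$M - 11))
  if (!is.na(x$clipped_mass) && x$clipped_mass > 0)
    cat(sprintf("clipped Bahadur mass: %.3g\n", x$clipped_mass))
  invisible(x)
}

#' Look up P(at least k) with boundary conventions
#'
#' `k <= 0` returns 1; `k > M` returns 0.
#'
#' @param result a `cumulative_result`.
#' @param k integer (vectorised).
#' @return probabilities.
#' @export
at_least_value <- function(result, k) {
  vapply(k, function(ki) {
    if (ki <= 0) return(1)
    if (ki > result$M) return(0)
    result$p_at_least[ki + 1L]
  }, 0)
}

#' Exact probability of obtaining at least k of M surplus organs
#'
#' Dynamic programme over (joint strip state, number of organs the target
#' centre has accepted so far), evolved one organ at a time exactly as in
#' [nth_probability()]. Exact up to floating-point rounding.
#'
#' @param config a `nation_config`.
#' @param center target centre id.
#' @param M number of surplus organs in the period.
#' @param cap joint-state-space cap (see [evolve()]); beyond it, use the
#'   Monte Carlo engine.
#' @return a `cumulative_result` with `p_at_least[k + 1] = P(at least k)`,
#'   `k = 0..M`.
#' @export
at_least_exact <- function(config, center, M, cap = .state_cap) {
  validate_nation_config(config)
  idx <- config_index(config)
  if (!center %in% names(idx$rates))
    stop(sprintf("unknown center '%s'", center), call. = FALSE)
  M <- as.integer(M)
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  pd <- donor_distribution(config)
  donors <- names(pd)[pd > 0]

  key_env <- new.env(parent = emptyenv())
  states <- list(initial_state(config))
  key_env[[state_key(states[[1]])]] <- 1L
  W <- matrix(0, 1, M + 1L)  # rows: states, cols: counts 0..M
  W[1, 1] <- 1

  for (t in seq_len(M)) {
    newW <- matrix(0, nrow(W), M + 1L)
    for (si in seq_len(nrow(W))) {
      row <- W[si, ]
      if (all(row == 0)) next
      st <- states[[si]]
      for (d in donors) {
        wd <- pd[[d]]
        out <- cascade_outcomes(st, config, idx, d)
        for (oi in seq_along(out$probs)) {
          po <- out$probs[oi] * wd
          if (po == 0) next
          k <- state_key(out$succ[[oi]])
          ti <- key_env[[k]]
          if (is.null(ti)) {
            ti <- length(states) + 1L
            if (ti > cap)
              stop(sprintf(paste0("joint strip state space exceeds %d states; ",
                                  "use the Monte Carlo engine"), cap), call. = FALSE)
            states[[ti]] <- out$succ[[oi]]
            key_env[[k]] <- ti
            W <- rbind(W, 0)
            newW <- rbind(newW, 0)
          }
          contrib <- row * po
          if (identical(out$acceptor[oi], center))
            contrib <- c(0, contrib[seq_len(M)])  # count shifts by one
          newW[ti, ] <- newW[ti, ] + contrib
        }
      }
    }
    W <- newW
  }
  pmf <- colSums(W)
  new_cumulative_result(center, M, tail_from_pmf(pmf), "exact")
}

#' Acceptance-sequence law of a centre
#'
#' The joint law summary of the acceptance indicators `X_t` ("the centre
#' obtains organ t"), t = 1..M: marginals `p_t` from the exact chain, pairwise
#' joint probabilities `P(X_s = 1, X_t = 1)` from a conditioned forward pass
#' of the same chain, and the derived pairwise correlations. This is the input
#' of the Bahadur and independence engines.
#'
#' With `engine = "montecarlo"` the law is estimated from simulated seasons
#' and standard errors are attached; use it when the joint state space
#' overflows the exact cap.
#'
#' @param config a `nation_config`.
#' @param center target centre id.
#' @param M number of surplus organs.
#' @param engine `"exact"` (default) or `"montecarlo"`.
#' @param n_reps,seed Monte Carlo engine only.
#' @param cap joint-state-space cap for the exact engine.
#' @return object of class `acceptance_law`: list with `p` (length M),
#'   `joint` (M x M, diagonal `p`), `R` (M x M correlation matrix, unit
#'   diagonal; entries 0 by convention where an indicator is degenerate),
#'   plus `se` for the Monte Carlo engine.
#' @export
law_from_chain <- function(config, center, M, engine = c("exact", "montecarlo"),
                           n_reps = 2e5, seed = 1L, cap = .state_cap) {
  engine <- match.arg(engine)
  M <- as.integer(M)
  if (engine == "montecarlo")
    return(mc_acceptance_law(config, center, M, n_reps, seed))
  idx <- config_index(config)
  if (!center %in% names(idx$rates))
    stop(sprintf("unknown center '%s'", center), call. = FALSE)

  # step a (sub-)measure over joint states one organ forward, splitting off
  # the mass on which `center` accepts this organ
  step_measure <- function(measure) {
    acc_env <- new.env(parent = emptyenv())
    sts <- list(); prs <- numeric(0); prs_acc <- numeric(0)
    add <- function(st, w, accepted) {
      k <- state_key(st)
      pos <- acc_env[[k]]
      if (is.null(pos)) {
        pos <- length(sts) + 1L
        if (pos > cap)
          stop(sprintf("joint strip state space exceeds %d states; use the Monte Carlo engine", cap),
               call. = FALSE)
        sts[[pos]] <<- st; prs[pos] <<- 0; prs_acc[pos] <<- 0
        acc_env[[k]] <- pos
      }
      prs[pos] <<- prs[pos] + w
      if (accepted) prs_acc[pos] <<- prs_acc[pos] + w
    }
    pd <- donor_distribution(config)
    donors <- names(pd)[pd > 0]
    for (si in seq_along(measure$states)) {
      w <- measure$probs[[si]]
      if (w == 0) next
      st <- measure$states[[si]]
      for (d in donors) {
        out <- cascade_outcomes(st, config, idx, d)
        for (oi in seq_along(out$probs)) {
          po <- out$probs[oi] * pd[[d]] * w
          if (po == 0) next
          add(out$succ[[oi]], po, identical(out$acceptor[oi], center))
        }
      }
    }
    list(all = list(states = sts, probs = prs),
         accepted = list(states = sts, probs = prs_acc),
         accept_mass = sum(prs_acc))
  }

  chain <- list(states = list(initial_state(config)), probs = 1)
  chains <- vector("list", M)  # measure entering organ t
  p <- numeric(M)
  acc_measures <- vector("list", M)
  for (t in seq_len(M)) {
    chains[[t]] <- chain
    stp <- step_measure(chain)
    p[t] <- stp$accept_mass
    acc_measures[[t]] <- stp$accepted
    chain <- stp$all
  }
  joint <- diag(p, M)
  if (M >= 2) {
    for (s in seq_len(M - 1L)) {
      mu <- acc_measures[[s]]
      for (t in (s + 1L):M) {
        stp <- step_measure(mu)
        joint[s, t] <- joint[t, s] <- stp$accept_mass
        mu <- stp$all
      }
    }
  }
  R <- diag(1, M)
  if (M >= 2) {
    v <- p * (1 - p)
    for (s in seq_len(M - 1L)) for (t in (s + 1L):M) {
      if (v[s] > 0 && v[t] > 0) {
        R[s, t] <- R[t, s] <- (joint[s, t] - p[s] * p[t]) / sqrt(v[s] * v[t])
      } else {
        R[s, t] <- R[t, s] <- 0  # degenerate indicator: correlation 0 by convention
      }
    }
  }
  structure(list(p = p, joint = joint, R = R, center = center, M = M,
                 engine = "exact", se = NULL),
            class = "acceptance_law")
}

#' Construct an acceptance law directly
#'
#' For analyses where marginals (and optionally pairwise correlations) are
#' supplied rather than derived from a configuration.
#'
#' @param p marginal acceptance probabilities, one per organ.
#' @param R pairwise correlation matrix (unit diagonal, symmetric); default
#'   identity (independence).
#' @return an `acceptance_law`.
#' @export
acceptance_law <- function(p, R = diag(1, length(p))) {
  p <- as.numeric(p)
  M <- length(p)
  if (any(p < 0 | p > 1)) stop("marginals must lie in [0, 1]", call. = FALSE)
  R <- as.matrix(R)
  if (!identical(dim(R), c(M, M)) || !isTRUE(all.equal(R, t(R), tolerance = 0)))
    stop("R must be a symmetric M x M matrix", call. = FALSE)
  if (any(abs(R) > 1) || any(diag(R) != 1))
    stop("R must have unit diagonal and entries in [-1, 1]", call. = FALSE)
  structure(list(p = p, joint = NULL, R = R, center = NA_character_, M = M,
                 engine = "direct", se = NULL),
            class = "acceptance_law")
}

#' At-least-k probability under independence (Poisson-binomial)
#'
#' Treats the per-organ acceptance indicators as independent with the law's
#' marginals and returns the Poisson-binomial upper tail, computed by a
#' convolution dynamic programme. This evaluates the literal independence
#' product-sum form of the cumulative model.
#'
#' @param law an `acceptance_law`.
#' @param k integer, or `NULL` for the full curve.
#' @return a probability (vectorised over `k`), or a `cumulative_result` when
#'   `k` is `NULL`.
#' @export
at_least_independent <- function(law, k = NULL) {
  tail <- tail_from_pmf(pois_binom_pmf(law$p))
  res <- new_cumulative_result(law$center, law$M, tail, "independent")
  if (is.null(k)) return(res)
  at_least_value(res, k)
}

#' At-least-k probability under the second-order Bahadur expansion
#'
#' The joint density of correlated acceptance indicators is expanded around
#' the independence product: `f(x) = prod_t p_t^{x_t} (1-p_t)^{1-x_t} *
#' (1 + sum_{s<t} r_st z_s z_t)` with `z_t` the standardised indicators,
#' truncated at pairwise terms. The count distribution is obtained by summing
#' the corrected density over outcomes with each total (a pairwise
#' conditioning over the Poisson-binomial of the remaining indicators, not a
#' `2^M` enumeration). Truncation can make masses negative: they are clipped
#' to 0, the distribution is renormalised, and the clipped mass is reported.
#'
#' @param law an `acceptance_law` with marginals and correlations.
#' @param k integer, or `NULL` for the full curve.
#' @return as [at_least_independent()]; the `cumulative_result` carries
#'   `clipped_mass`.
#' @export
at_least_bahadur <- function(law, k = NULL) {
  p <- law$p
  M <- law$M
  R <- law$R
  if (!isTRUE(all.equal(R, t(R), tolerance = 0)))
    stop("correlation matrix must be symmetric", call. = FALSE)
  f <- pois_binom_pmf(p)
  corr <- numeric(M + 1L)
  v <- p * (1 - p)
  if (M >= 2) {
    for (s in seq_len(M - 1L)) for (t in (s + 1L):M) {
      r <- R[s, t]
      if (r == 0 || v[s] == 0 || v[t] == 0) next
      z1s <- sqrt((1 - p[s]) / p[s]); z0s <- -sqrt(p[s] / (1 - p[s]))
      z1t <- sqrt((1 - p[t]) / p[t]); z0t <- -sqrt(p[t] / (1 - p[t]))
      rest <- pois_binom_pmf(p[-c(s, t)])  # counts 0..M-2
      for (a in 0:1) for (b in 0:1) {
        w <- (if (a) p[s] else 1 - p[s]) * (if (b) p[t] else 1 - p[t]) *
          (if (a) z1s else z0s) * (if (b) z1t else z0t)
        sel <- (a + b) + seq_along(rest)  # count index m+1
        corr[sel] <- corr[sel] + r * w * rest
      }
    }
  }
  g <- f + corr
  clipped <- -sum(g[g < 0])
  if (clipped > 0) {
    g[g < 0] <- 0
    g <- g / sum(g)
  }
  res <- new_cumulative_result(law$center, M, tail_from_pmf(g), "bahadur",
                               clipped_mass = clipped)
  if (is.null(k)) return(res)
  at_least_value(res, k)
}

#' At-least-k probabilities for a centre, all engines
#'
#' Front door for the cumulative model. `exact` runs the joint-state dynamic
#' programme; `bahadur` and `independent` first derive the acceptance law
#' from the exact chain, then apply the respective approximation;
#' `montecarlo` estimates the curve from simulated seasons.
#'
#' @param config a `nation_config`.
#' @param center target centre id.
#' @param M number of surplus organs.
#' @param engine one of `"exact"`, `"bahadur"`, `"independent"`,
#'   `"montecarlo"`.
#' @param n_reps,seed Monte Carlo engine only.
#' @param cap joint-state-space cap for the exact engines.
#' @return a `cumulative_result`.
#' @export
at_least <- function(config, center, M,
                     engine = c("exact", "bahadur", "independent", "montecarlo"),
                     n_reps = 2e5, seed = 1L, cap = .state_cap) {
  engine <- match.arg(engine)
  switch(engine,
    exact = at_least_exact(config, center, M, cap = cap),
    bahadur = at_least_bahadur(law_from_chain(config, center, M, cap = cap)),
    independent = at_least_independent(law_from_chain(config, center, M, cap = cap)),
    montecarlo = {
      est <- estimate(config, M, n_reps, seed)
      new_cumulative_result(center, M, est$atleast_freq[center, ], "montecarlo",
                            se = est$atleast_se[center, ])
    })
}
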