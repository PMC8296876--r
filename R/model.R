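#' Fit the surplus-allocation probability model
#'
#' The package's front door: given a national configuration and a number of
#' surplus organs `M`, computes both probability models for every transplant
#' centre -- the per-organ probabilities `P_c^t` of obtaining the t-th organ
#' (with the loss probability) and the cumulative probabilities of obtaining
#' at least k of the M organs -- with the engine of choice.
#'
#' @param config a `nation_config`, e.g. [italy_fixture()] or
#'   [load_config()].
#' @param n_organs number of surplus organs `M` in the period.
#' @param engine `"exact"` (chain / dynamic programme, default),
#'   `"bahadur"`, `"independent"` (approximations for the cumulative model;
#'   per-organ probabilities stay exact), or `"montecarlo"`.
#' @param n_reps,seed Monte Carlo engine only.
#' @param cap joint-state-space cap for the exact engines.
#' @return object of class `strip_model` with components `nth` (per-organ
#'   probability matrix plus loss vector), `atleast` (centres x (M + 1)
#'   matrix of at-least-k probabilities), `use_probability`, `config`,
#'   `engine`.
#' @export
#' @examples
#' fit <- strip_model(italy_fixture(), n_organs = 10)
#' fit
#' coef(fit)[1, ]          # organ-1 probabilities per centre
#' predict(fit, center = "NITp", at_least = 2)
strip_model <- function(config, n_organs,
                        engine = c("exact", "bahadur", "independent", "montecarlo"),
                        n_reps = 2e5, seed = 1L, cap = .state_cap) {
  engine <- match.arg(engine)
  validate_nation_config(config)
  M <- as.integer(n_organs)
  if (M < 1) stop("n_organs must be >= 1", call. = FALSE)
  centers <- names(config$centers)

  if (engine == "montecarlo") {
    est <- estimate(config, M, n_reps, seed)
    nth <- list(prob = est$organ_freq[, centers, drop = FALSE],
                lost = est$organ_freq[, "LOST"],
                se = est$organ_se[, centers, drop = FALSE])
    atl <- est$atleast_freq
    atl_extra <- list(se = est$atleast_se)
  } else {
    nr <- nth_probability(config, M, cap = cap)
    nth <- list(prob = nr$prob, lost = nr$lost, T = nr$T, Pcj = nr$Pcj)
    atl <- matrix(NA_real_, length(centers), M + 1L,
                  dimnames = list(centers, as.character(0:M)))
    clipped <- stats::setNames(rep(NA_real_, length(centers)), centers)
    for (c in centers) {
      res <- switch(engine,
        exact = at_least_exact(config, c, M, cap = cap),
        bahadur = at_least_bahadur(law_from_chain(config, c, M, cap = cap)),
        independent = at_least_independent(law_from_chain(config, c, M, cap = cap)))
      atl[c, ] <- res$p_at_least
      clipped[c] <- res$clipped_mass
    }
    atl_extra <- list(clipped_mass = clipped)
  }
  structure(c(list(config = config, M = M, engine = engine,
                   centers = centers, nth = nth, atleast = atl,
                   use_probability = overall_use_probability(config),
                   n_reps = if (engine == "montecarlo") n_reps else NULL,
                   seed = if (engine == "montecarlo") seed else NULL),
              atl_extra),
            class = "strip_model")
}

#' @export
print.strip_model <- function(x, ...) {
  cat(sprintf("Surplus-allocation model: %d organs, %d centres (engine: %s)\n",
              x$M, length(x$centers), x$engine))
  cat(sprintf("Overall probability that a surplus organ is used: %.4f\n",
              x$use_probability))
  cat("\nP(centre obtains organ t):\n")
  df <- as.data.frame(round(x$nth$prob, 4))
  df$LOST <- round(x$nth$lost, 4)
  rownames(df) <- paste0("t=", seq_len(x$M))
  print(utils::head(df, 8))
  if (x$M > 8) cat(sprintf("   ... %d more organs\n", x$M - 8))
  invisible(x)
}

#' @export
summary.strip_model <- function(object, ...) {
  plateau <- object$nth$prob[object$M, ]
  expected <- colSums(object$nth$prob)
  out <- list(M = object$M, engine = object$engine,
              use_probability = object$use_probability,
              plateau = plateau, expected_organs = expected,
              expected_lost = sum(object$nth$lost),
              atleast = object$atleast)
  class(out) <- "summary.strip_model"
  out
}

#' @export
print.summary.strip_model <- function(x, ...) {
  cat(sprintf("Surplus-allocation model summary (M = %d, engine: %s)\n",
              x$M, x$engine))
  cat(sprintf("P(organ used) = %.4f; expected organs lost over the period: %.2f\n\n",
              x$use_probability, x$expected_lost))
  df <- data.frame(`P at organ M` = round(x$plateau, 4),
                   `expected organs` = round(x$expected_organs, 2),
                   `P at least 1` = round(x$atleast[, "1"], 4),
                   check.names = FALSE)
  print(df)
  invisible(x)
}

#' @export
coef.strip_model <- function(object, ...) object$nth$prob

#' Query fitted allocation probabilities
#'
#' @param object a `strip_model`.
#' @param center centre id (default: all).
#' @param organ organ index t, to return `P(centre obtains organ t)`.
#' @param at_least k, to return `P(centre obtains at least k organs)`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
predict.strip_model <- function(object, center = NULL, organ = NULL,
                                at_least = NULL, ...) {
  centers <- center %||% object$centers
  if (!is.null(organ)) {
    if (organ < 1 || organ > object$M) stop("organ index out of range", call. = FALSE)
    return(object$nth$prob[organ, centers])
  }
  if (!is.null(at_least)) {
    k <- as.integer(at_least)
    out <- vapply(centers, function(c) {
      if (k <= 0) 1 else if (k > object$M) 0 else object$atleast[c, k + 1L]
    }, 0)
    return(out)
  }
  stop("specify either `organ` or `at_least`", call. = FALSE)
}

#' Plot fitted allocation probability curves
#'
#' Two base-graphics panels: the per-organ probability `P_c^t` against the
#' organ index (first model) and the at-least-k curves (second model), one
#' line per centre.
#'
#' @param x a `strip_model`.
#' @param which `"nth"`, `"atleast"` or `"both"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.strip_model <- function(x, which = c("both", "nth", "atleast"), ...) {
  which <- match.arg(which)
  nc <- length(x$centers)
  cols <- grDevices::hcl.colors(nc, "Dark 3")
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  }
  if (which %in% c("both", "nth")) {
    graphics::matplot(seq_len(x$M), x$nth$prob, type = "l", lty = 1,
                      col = cols, xlab = "organ index t",
                      ylab = "P(centre obtains organ t)", ylim = c(0, 1), ...)
    graphics::legend("topright", legend = x$centers, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  if (which %in% c("both", "atleast")) {
    graphics::matplot(0:x$M, t(x$atleast), type = "l", lty = 1,
                      col = cols, xlab = "k",
                      ylab = "P(at least k organs)", ylim = c(0, 1), ...)
    graphics::legend("topright", legend = x$centers, col = cols, lty = 1,
                     cex = 0.7, bty = "n")
  }
  invisible(x)
}

#' Simulate allocation seasons from a fitted model
#'
#' @param object a `strip_model`.
#' @param nsim number of seasons.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `season_trace` objects (length `nsim`).
#' @export
simulate.strip_model <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_season(object$config, object$M, seed = seed + i - 1L))
}
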