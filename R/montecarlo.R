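# Precompute the cascade structure of every reachable (joint state, donor)
# pair: query order, per-position acceptance rates, successor state indices.
# Used by the vectorised season simulator.
build_mc_tables <- function(config, cap = .state_cap) {
  idx <- config_index(config)
  pd <- donor_distribution(config)
  donors <- names(pd)[pd > 0]
  nd <- length(donors)
  centers <- names(idx$rates)

  key_env <- new.env(parent = emptyenv())
  states <- list(initial_state(config))
  key_env[[state_key(states[[1]])]] <- 1L
  register <- function(st) {
    k <- state_key(st)
    pos <- key_env[[k]]
    if (is.null(pos)) {
      pos <- length(states) + 1L
      if (pos > cap)
        stop(sprintf("joint strip state space exceeds %d states", cap), call. = FALSE)
      states[[pos]] <<- st
      key_env[[k]] <- pos
    }
    pos
  }

  orders <- list()   # [[state]][[donor]] -> centre index vector
  succs <- list()    # [[state]][[donor]] -> successor state index per accept pos
  si <- 1L
  while (si <= length(states)) {
    st <- states[[si]]
    orders[[si]] <- vector("list", nd)
    succs[[si]] <- vector("list", nd)
    for (di in seq_len(nd)) {
      out <- cascade_outcomes(st, config, idx, donors[di])
      L <- length(out$acceptor) - 1L
      orders[[si]][[di]] <- match(out$acceptor[seq_len(L)], centers)
      succs[[si]][[di]] <- vapply(seq_len(L), function(i) register(out$succ[[i]]), 0L)
    }
    si <- si + 1L
  }

  maxL <- max(1L, vapply(orders, function(o) max(vapply(o, length, 0L)), 0L))
  nrow_tab <- length(states) * nd
  rateTab <- matrix(NA_real_, nrow_tab, maxL)
  succTab <- matrix(NA_integer_, nrow_tab, maxL + 1L)
  centerTab <- matrix(NA_integer_, nrow_tab, maxL)
  for (si in seq_along(states)) for (di in seq_len(nd)) {
    row <- (si - 1L) * nd + di
    ord <- orders[[si]][[di]]
    L <- length(ord)
    if (L > 0) {
      rateTab[row, seq_len(L)] <- idx$rates[ord]
      centerTab[row, seq_len(L)] <- ord
      succTab[row, seq_len(L)] <- succs[[si]][[di]]
    }
    succTab[row, maxL + 1L] <- si  # loss: state unchanged
  }
  list(states = states, donors = donors, pd = unname(pd[donors]), nd = nd,
       centers = centers, maxL = maxL,
       rateTab = rateTab, succTab = succTab, centerTab = centerTab)
}

#' Simulate one allocation season
#'
#' Draws `M` surplus organs: each donor region i.i.d. from the
#' production-weighted donor distribution, each queried centre accepting
#' independently with its acceptance rate. The strip state is carried across
#' organs within the season. Reproducible from `(config, M, seed)`.
#'
#' @param config a `nation_config`.
#' @param M number of organs in the season.
#' @param seed integer seed.
#' @return object of class `season_trace`: list with `events` (one row per
#'   offer: `organ_index`, `donor_region`, `center`, `position`, `decision`,
#'   `outcome`), `organs` (one row per organ: `organ_index`, `donor_region`,
#'   `accepted_by`), and `final_state`.
#' @export
simulate_season <- function(config, M, seed) {
  validate_nation_config(config)
  idx <- config_index(config)
  pd <- donor_distribution(config)
  donors <- names(pd)[pd > 0]
  set.seed(seed)
  state <- initial_state(config)
  events <- list()
  organs <- list()
  for (t in seq_len(M)) {
    d <- donors[sample.int(length(donors), 1L, prob = pd[donors])]
    order <- offer_order(state, config, d)
    # decisions drawn lazily in query order
    decisions <- stats::setNames(rep(FALSE, length(order)), order)
    acceptor <- NA_character_
    for (c in order) {
      decisions[[c]] <- stats::runif(1) < idx$rates[[c]]
      if (decisions[[c]]) { acceptor <- c; break }
    }
    res <- allocate_one(state, config, d, decisions)
    state <- res$state
    ev <- res$offer_sequence
    if (nrow(ev) > 0) {
      ev$organ_index <- t
      ev$donor_region <- d
      ev$outcome <- res$accepted_by
      events[[t]] <- ev[, c("organ_index", "donor_region", "center",
                            "position", "decision", "outcome")]
    }
    organs[[t]] <- data.frame(organ_index = t, donor_region = d,
                              accepted_by = res$accepted_by,
                              stringsAsFactors = FALSE)
  }
  structure(list(events = do.call(rbind, events),
                 organs = do.call(rbind, organs),
                 final_state = state, M = M, seed = seed),
            class = "season_trace")
}

#' @export
print.season_trace <- function(x, ...) {
  cat(sprintf("<season_trace> %d organs (seed %s)\n", x$M, format(x$seed)))
  print(x$organs, row.names = FALSE)
  invisible(x)
}

#' Monte Carlo estimates over many seasons
#'
#' Simulates `n_reps` independent seasons of `M` organs (vectorised across
#' replicates from one seeded stream; deterministic given
#' `(config, M, n_reps, seed)`) and aggregates per-organ acceptance
#' frequencies and per-centre at-least-k frequencies with binomial standard
#' errors. Per-organ frequencies plus the loss frequency sum to exactly 1.
#'
#' @param config a `nation_config`.
#' @param M organs per season.
#' @param n_reps number of seasons.
#' @param seed integer seed.
#' @return object of class `empirical_estimates`: `organ_freq` and `organ_se`
#'   (M x (centres + "LOST") matrices), `atleast_freq` and `atleast_se`
#'   (centres x (M + 1) matrices, columns k = 0..M), `state_freq` (final
#'   joint-state occupancy), `n_reps`, `seed`.
#' @export
estimate <- function(config, M, n_reps, seed) {
  validate_nation_config(config)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  M <- as.integer(M); n_reps <- as.integer(n_reps)
  tab <- build_mc_tables(config)
  nc <- length(tab$centers)
  set.seed(seed)

  S <- rep(1L, n_reps)                       # joint-state index per replicate
  counts <- matrix(0L, n_reps, nc)           # per-centre season totals
  organ_freq <- matrix(0, M, nc + 1L,
                       dimnames = list(NULL, c(tab$centers, "LOST")))
  for (t in seq_len(M)) {
    d <- sample.int(tab$nd, n_reps, replace = TRUE, prob = tab$pd)
    key <- (S - 1L) * tab$nd + d
    accpos <- integer(n_reps)
    for (pos in seq_len(tab$maxL)) {
      rate <- tab$rateTab[key, pos]
      u <- stats::runif(n_reps)
      hit <- accpos == 0L & !is.na(rate) & u < rate
      accpos[hit] <- pos
    }
    lost <- accpos == 0L
    ctr <- integer(n_reps)
    if (any(!lost))
      ctr[!lost] <- tab$centerTab[cbind(key[!lost], accpos[!lost])]
    S <- tab$succTab[cbind(key, ifelse(lost, tab$maxL + 1L, accpos))]
    tallies <- tabulate(ctr[!lost], nbins = nc)
    organ_freq[t, seq_len(nc)] <- tallies
    organ_freq[t, nc + 1L] <- sum(lost)
    if (any(!lost)) {
      inc <- cbind(which(!lost), ctr[!lost])
      counts[inc] <- counts[inc] + 1L
    }
  }
  organ_freq <- organ_freq / n_reps
  organ_se <- sqrt(organ_freq * (1 - organ_freq) / n_reps)

  atleast_freq <- matrix(0, nc, M + 1L,
                         dimnames = list(tab$centers, as.character(0:M)))
  for (ci in seq_len(nc)) {
    n_m <- tabulate(counts[, ci] + 1L, nbins = M + 1L)
    atleast_freq[ci, ] <- tail_from_pmf(n_m) / n_reps
  }
  atleast_se <- sqrt(atleast_freq * (1 - atleast_freq) / n_reps)

  st_tab <- tabulate(S, nbins = length(tab$states))
  state_freq <- stats::setNames(st_tab / n_reps,
                                vapply(tab$states, state_key, ""))
  structure(list(organ_freq = organ_freq, organ_se = organ_se,
                 atleast_freq = atleast_freq, atleast_se = atleast_se,
                 state_freq = state_freq,
                 M = M, n_reps = n_reps, seed = seed),
            class = "empirical_estimates")
}

#' @export
print.empirical_estimates <- function(x, ...) {
  cat(sprintf("<empirical_estimates> %d seasons of %d organs (seed %s)\n",
              x$n_reps, x$M, format(x$seed)))
  cat("per-organ acceptance frequencies:\n")
  print(round(utils::head(x$organ_freq, 6), 4))
  invisible(x)
}

# Monte Carlo estimate of an acceptance-sequence law (marginals, pairwise
# joints, correlations) for one centre, with standard errors on the marginals.
mc_acceptance_law <- function(config, center, M, n_reps, seed) {
  idx <- config_index(config)
  if (!center %in% names(idx$rates))
    stop(sprintf("unknown center '%s'", center), call. = FALSE)
  tab <- build_mc_tables(config)
  ci <- match(center, tab$centers)
  M <- as.integer(M); n_reps <- as.integer(n_reps)
  set.seed(seed)
  S <- rep(1L, n_reps)
  X <- matrix(0L, n_reps, M)
  for (t in seq_len(M)) {
    d <- sample.int(tab$nd, n_reps, replace = TRUE, prob = tab$pd)
    key <- (S - 1L) * tab$nd + d
    accpos <- integer(n_reps)
    for (pos in seq_len(tab$maxL)) {
      rate <- tab$rateTab[key, pos]
      u <- stats::runif(n_reps)
      hit <- accpos == 0L & !is.na(rate) & u < rate
      accpos[hit] <- pos
    }
    lost <- accpos == 0L
    ctr <- integer(n_reps)
    if (any(!lost))
      ctr[!lost] <- tab$centerTab[cbind(key[!lost], accpos[!lost])]
    X[, t] <- as.integer(ctr == ci)
    S <- tab$succTab[cbind(key, ifelse(lost, tab$maxL + 1L, accpos))]
  }
  p <- colMeans(X)
  joint <- crossprod(X) / n_reps
  R <- diag(1, M)
  v <- p * (1 - p)
  if (M >= 2) {
    for (s in seq_len(M - 1L)) for (t in (s + 1L):M) {
      R[s, t] <- R[t, s] <- if (v[s] > 0 && v[t] > 0)
        (joint[s, t] - p[s] * p[t]) / sqrt(v[s] * v[t]) else 0
    }
  }
  structure(list(p = p, joint = joint, R = R, center = center, M = M,
                 engine = "montecarlo",
                 se = sqrt(p * (1 - p) / n_reps)),
            class = "acceptance_law")
}
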