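state_key <- function(state) {
  paste(vapply(state, paste, "", collapse = "|"), collapse = " :: ")
}

#' Initial chain distribution
#'
#' A chain distribution is a probability distribution over joint strip states,
#' evolved organ by organ. Initially all mass sits on the configured
#' arrangement.
#'
#' @param config a `nation_config`.
#' @return object of class `chain_distribution`: list with `states` (list of
#'   joint states) and `probs` (numeric, summing to 1).
#' @export
chain_init <- function(config) {
  s0 <- initial_state(config)
  structure(list(states = list(s0), probs = 1), class = "chain_distribution")
}

# Enumerate the cascade outcomes for (state, donor): data.frame of acceptor
# (NA = lost), probability, and the successor joint state (list column).
cascade_outcomes <- function(state, config, idx, donor_region) {
  order <- offer_order(state, config, donor_region)
  L <- length(order)
  probs <- numeric(L + 1L)
  succ <- vector("list", L + 1L)
  prefix <- 1
  for (i in seq_len(L)) {
    p <- idx$rates[[order[i]]]
    probs[i] <- prefix * p
    ma <- idx$center_ma[[order[i]]]
    in_ma <- order[seq_len(i)][vapply(order[seq_len(i)],
                                      function(c) idx$center_ma[[c]] == ma, NA)]
    st <- state
    st[[ma]] <- rotate_strip(state[[ma]], setdiff(in_ma, order[i]), order[i])
    succ[[i]] <- st
    prefix <- prefix * (1 - p)
  }
  probs[L + 1L] <- prefix
  succ[[L + 1L]] <- state
  list(acceptor = c(order, NA_character_), probs = probs, succ = succ)
}

# default cap on the exact joint-state space
.state_cap <- 1e5

#' Evolve a chain distribution by one organ
#'
#' Marginalises over donor regions (via [donor_distribution()]) and over every
#' accept/refuse outcome of the offer cascade, accumulating probability onto
#' the successor joint states.
#'
#' @param config a `nation_config`.
#' @param chain a `chain_distribution`.
#' @param cap maximum number of joint states tracked before erroring (the
#'   Monte Carlo engine handles larger configurations).
#' @return the successor `chain_distribution`.
#' @export
evolve <- function(config, chain, cap = .state_cap) {
  step_chain(config, chain, collect = FALSE, cap = cap)$chain
}

# One exact step. With collect = TRUE also returns the per-centre acceptance
# probabilities for the organ allocated during this step, the strip-position
# distribution T[c, j], and the position-conditional acceptance A[c, j]/T[c, j].
step_chain <- function(config, chain, collect = TRUE, cap = .state_cap) {
  idx <- config_index(config)
  pd <- donor_distribution(config)
  donors <- names(pd)[pd > 0]
  centers <- names(idx$rates)

  acc_env <- new.env(parent = emptyenv())  # key -> position in new lists
  new_states <- list()
  new_probs <- numeric(0)
  add_mass <- function(st, w) {
    k <- state_key(st)
    pos <- acc_env[[k]]
    if (is.null(pos)) {
      pos <- length(new_states) + 1L
      if (pos > cap)
        stop(sprintf(paste0("joint strip state space exceeds %d states; ",
                            "use the Monte Carlo engine"), cap), call. = FALSE)
      new_states[[pos]] <<- st
      new_probs[pos] <<- 0
      acc_env[[k]] <- pos
    }
    new_probs[pos] <<- new_probs[pos] + w
  }

  if (collect) {
    strip_len <- vapply(idx$strips, length, 0L)
    A <- lapply(centers, function(c) numeric(strip_len[[idx$center_ma[[c]]]]))
    Tmat <- lapply(centers, function(c) numeric(strip_len[[idx$center_ma[[c]]]]))
    names(A) <- names(Tmat) <- centers
    p_lost <- 0
  }

  for (si in seq_along(chain$states)) {
    st <- chain$states[[si]]
    w <- chain$probs[[si]]
    if (w == 0) next
    if (collect) {
      for (c in centers) {
        j <- match(c, st[[idx$center_ma[[c]]]])
        if (!is.na(j)) Tmat[[c]][j] <- Tmat[[c]][j] + w
      }
    }
    for (d in donors) {
      wd <- w * pd[[d]]
      out <- cascade_outcomes(st, config, idx, d)
      for (oi in seq_along(out$probs)) {
        po <- out$probs[oi]
        if (po == 0) next
        add_mass(out$succ[[oi]], wd * po)
        if (collect) {
          c <- out$acceptor[oi]
          if (is.na(c)) {
            p_lost <- p_lost + wd * po
          } else {
            j <- match(c, st[[idx$center_ma[[c]]]])
            A[[c]][j] <- A[[c]][j] + wd * po
          }
        }
      }
    }
  }

  new_chain <- structure(list(states = new_states, probs = new_probs),
                         class = "chain_distribution")
  if (!collect) return(list(chain = new_chain))
  prob <- vapply(A, sum, 0)
  Pcj <- lapply(centers, function(c) {
    out <- ifelse(Tmat[[c]] > 0, A[[c]] / Tmat[[c]], 0)
    as.numeric(out)
  })
  names(Pcj) <- centers
  list(chain = new_chain,
       result = list(prob = prob, lost = p_lost, T = Tmat, Pcj = Pcj))
}

#' Per-organ acceptance probabilities (first probability model)
#'
#' For each organ index `t = 1..M` and each transplant centre, the exact
#' probability that the centre obtains (is offered and accepts) the t-th
#' surplus organ of the period, together with the loss probability, the
#' strip-position distribution `T[c, t, j]` and the position-conditional
#' acceptance probabilities `Pcj[c, t, j]`, so that
#' `prob[t, c] = sum_j T[c, t, j] * Pcj[c, t, j]`.
#'
#' Computed by exact evolution of the Markov chain over joint strip states:
#' each step marginalises over donor regions and cascade outcomes, and the
#' resulting state distribution feeds the next organ.
#'
#' @param config a `nation_config`.
#' @param M number of surplus organs in the period (>= 1).
#' @param cap joint-state-space cap, see [evolve()].
#' @return object of class `nth_organ_result`: list with `prob` (M x centres
#'   matrix), `lost` (length-M vector; `rowSums(prob) + lost == 1`), `T` and
#'   `Pcj` (per centre, M x strip-length matrices), and `engine = "exact"`.
#' @export
nth_probability <- function(config, M, cap = .state_cap) {
  if (!is.numeric(M) || length(M) != 1L || M < 1)
    stop("M must be a single integer >= 1", call. = FALSE)
  M <- as.integer(M)
  validate_nation_config(config)
  idx <- config_index(config)
  centers <- names(idx$rates)
  chain <- chain_init(config)
  prob <- matrix(NA_real_, M, length(centers), dimnames = list(NULL, centers))
  lost <- numeric(M)
  strip_len <- vapply(idx$strips, length, 0L)
  Tarr <- lapply(centers, function(c) matrix(NA_real_, M, strip_len[[idx$center_ma[[c]]]]))
  Pcj <- lapply(centers, function(c) matrix(NA_real_, M, strip_len[[idx$center_ma[[c]]]]))
  names(Tarr) <- names(Pcj) <- centers
  for (t in seq_len(M)) {
    stp <- step_chain(config, chain, collect = TRUE, cap = cap)
    prob[t, ] <- stp$result$prob[centers]
    lost[t] <- stp$result$lost
    for (c in centers) {
      Tarr[[c]][t, ] <- stp$result$T[[c]]
      Pcj[[c]][t, ] <- stp$result$Pcj[[c]]
    }
    chain <- stp$chain
  }
  structure(list(prob = prob, lost = lost, T = Tarr, Pcj = Pcj,
                 M = M, centers = centers, engine = "exact",
                 final_chain = chain),
            class = "nth_organ_result")
}

#' @export
print.nth_organ_result <- function(x, ...) {
  cat(sprintf("<nth_organ_result> %d organs, %d centres (engine: %s)\n",
              x$M, length(x$centers), x$engine))
  df <- as.data.frame(round(x$prob, 4))
  df$lost <- round(x$lost, 4)
  print(utils::head(df, 10))
  if (x$M > 10) cat(sprintf("... %d more organs\n", x$M - 10))
  invisible(x)
}

#' Position-conditional acceptance probability
#'
#' Probability that `center`, sitting at position `j` of its strip in the
#' given joint state, obtains an organ produced in `donor_region`: its own
#' acceptance rate, times zero if the donor region belongs to the centre
#' (the producer is excluded), times the product of refusal probabilities of
#' every centre queried before it in the full offer cascade.
#'
#' `variant = "marginal"` instead evaluates the literal within-strip form:
#' the acceptance rate times the marginal probability that the organ is not
#' produced in the centre's own regions (`1 - S_c / sum(S)`), times refusals
#' of the centres occupying earlier slots of the same strip only. It ignores
#' `donor_region` and does not condition on the donor, so summing it over
#' centres does not complement the loss probability; it is kept for
#' comparison with the engine's exact conditioning.
#'
#' @param config a `nation_config`.
#' @param state joint state.
#' @param center centre id.
#' @param j 1-based slot position; `center` must occupy it.
#' @param donor_region region name (exact variant only).
#' @param variant `"exact"` (default) or `"marginal"`.
#' @return a probability.
#' @export
position_conditional_probability <- function(config, state, center, j,
                                             donor_region = NULL,
                                             variant = c("exact", "marginal")) {
  variant <- match.arg(variant)
  idx <- config_index(config)
  if (!center %in% names(idx$rates))
    stop(sprintf("unknown center '%s'", center), call. = FALSE)
  arr <- state[[idx$center_ma[[center]]]]
  slots <- which(arr == center)
  if (length(slots) == 0L)
    stop(sprintf("center '%s' is absent from its macroarea strip", center), call. = FALSE)
  if (!j %in% slots)
    stop(sprintf("center '%s' does not occupy position %d", center, j), call. = FALSE)
  p_c <- idx$rates[[center]]
  if (variant == "marginal") {
    S_c <- sum(idx$production[config$centers[[center]]$member_regions])
    not_produced <- 1 - S_c / sum(idx$production)
    preds <- setdiff(unique(arr[seq_len(j - 1L)]), center)
    return(p_c * not_produced * prod(1 - idx$rates[preds]))
  }
  if (is.null(donor_region))
    stop("donor_region is required for the exact variant", call. = FALSE)
  order <- offer_order(state, config, donor_region)
  pos <- match(center, order)
  if (is.na(pos)) return(0)  # producer exclusion
  prod(1 - idx$rates[order[seq_len(pos - 1L)]]) * p_c
}

#' Overall probability that a surplus organ is used
#'
#' One minus the loss probability of the exact chain. Because, for a fixed
#' donor, an organ is lost exactly when every eligible centre refuses --
#' irrespective of strip order -- this probability is the same for every
#' organ index.
#'
#' @param config a `nation_config`.
#' @return a probability.
#' @seealso [use_probability_decomposition()] for the independent
#'   macroarea-level decomposition.
#' @export
overall_use_probability <- function(config) {
  1 - nth_probability(config, 1)$lost[1]
}

#' Macroarea decomposition of the use probability
#'
#' Independent closed form derived from the offer cascade: summing over
#' macroareas and donor types (no-centre regions vs each centre's member
#' regions), the probability that at least one eligible centre -- in the
#' donor macroarea minus the producer, or failing that in the other
#' macroarea -- accepts. Used as a cross-check of [overall_use_probability()].
#'
#' @param config a `nation_config`.
#' @return a probability.
#' @export
use_probability_decomposition <- function(config) {
  if (config$options$head_only_fallback)
    stop("decomposition assumes the full fallback cascade", call. = FALSE)
  idx <- config_index(config)
  tot <- sum(idx$production)
  if (tot <= 0) stop("total production is zero", call. = FALSE)
  p_any <- function(centers) 1 - prod(1 - idx$rates[centers])  # P(some c in set accepts)
  total <- 0
  for (ma in idx$ma_ids) {
    other <- setdiff(idx$ma_ids, ma)
    C_ma <- names(idx$center_ma)[idx$center_ma == ma]
    C_ot <- names(idx$center_ma)[idx$center_ma == other]
    regs <- config$macroareas[[ma]]$regions
    # donors in regions without a centre
    P_O <- sum(regs$production[is.na(regs$center)]) / tot
    total <- total + P_O * (1 - (1 - p_any(C_ma)) * (1 - p_any(C_ot)))
    # donors in each centre's member regions: that centre is excluded
    for (c in C_ma) {
      P_c <- sum(idx$production[config$centers[[c]]$member_regions]) / tot
      elig <- setdiff(C_ma, c)
      total <- total + P_c * (1 - (1 - p_any(elig)) * (1 - p_any(C_ot)))
    }
  }
  total
}
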