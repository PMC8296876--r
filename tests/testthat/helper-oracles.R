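# Small hand-built configurations --------------------------------------------

# one centre per macroarea, rates p (MA1) and q (MA2); production sits in a
# no-centre region of MA1
two_center_config <- function(p, q) {
  nation_config(
    macroareas = list(
      list(id = "MA1", strip = "A",
           regions = data.frame(name = c("RA", "RX"), center = c("A", NA),
                                production = c(0L, 1L))),
      list(id = "MA2", strip = "B",
           regions = data.frame(name = "RB", center = "B", production = 0L))
    ),
    centers = list(
      list(id = "A", acceptance_rate = p, member_regions = "RA"),
      list(id = "B", acceptance_rate = q, member_regions = "RB")
    )
  )
}

# a single centre in the nation; production in a no-centre region of the
# other macroarea, so every organ is offered to that centre
single_center_config <- function(p) {
  nation_config(
    macroareas = list(
      list(id = "MA1", strip = "A",
           regions = data.frame(name = "RA", center = "A", production = 0L)),
      list(id = "MA2", strip = character(0),
           regions = data.frame(name = "RX", center = NA_character_,
                                production = 1L))
    ),
    centers = list(list(id = "A", acceptance_rate = p, member_regions = "RA"))
  )
}

# two centres in one macroarea (round-robin when rates are 1); production in a
# no-centre region of the same macroarea
two_slot_config <- function(p = 1, q = 1) {
  nation_config(
    macroareas = list(
      list(id = "MA1", strip = c("A", "B"),
           regions = data.frame(name = c("RA", "RB", "RX"),
                                center = c("A", "B", NA),
                                production = c(0L, 0L, 1L))),
      list(id = "MA2", strip = character(0),
           regions = data.frame(name = "RY", center = NA_character_,
                                production = 0L))
    ),
    centers = list(
      list(id = "A", acceptance_rate = p, member_regions = "RA"),
      list(id = "B", acceptance_rate = q, member_regions = "RB")
    )
  )
}

# Brute-force path-enumeration oracle -----------------------------------------
# Enumerates every (donor, cascade outcome) sequence over all M organs with its
# probability -- no state merging, no dynamic programming. Returns per-organ
# acceptance probabilities, per-organ loss, and (optionally) the distribution
# of the number of organs a target centre accepts.
oracle_enumerate <- function(config, M, target = NULL) {
  idx <- stripalloc:::config_index(config)
  pd <- donor_distribution(config)
  donors <- names(pd)[pd > 0]
  centers <- names(idx$rates)
  prob <- matrix(0, M, length(centers), dimnames = list(NULL, centers))
  lost <- numeric(M)
  count_pmf <- numeric(M + 1L)
  recurse <- function(state, t, w, cnt) {
    if (t > M) {
      count_pmf[cnt + 1L] <<- count_pmf[cnt + 1L] + w
      return(invisible())
    }
    for (d in donors) {
      wd <- w * pd[[d]]
      ord <- offer_order(state, config, d)
      pref <- 1
      for (i in seq_along(ord)) {
        c <- ord[i]
        pacc <- wd * pref * idx$rates[[c]]
        if (pacc > 0) {
          prob[t, c] <<- prob[t, c] + pacc
          ma <- idx$center_ma[[c]]
          in_ma <- ord[seq_len(i)][vapply(ord[seq_len(i)],
                                          function(x) idx$center_ma[[x]] == ma, NA)]
          st2 <- state
          st2[[ma]] <- rotate_strip(state[[ma]], setdiff(in_ma, c), c)
          recurse(st2, t + 1L, pacc,
                  cnt + as.integer(identical(c, target)))
        }
        pref <- pref * (1 - idx$rates[[c]])
      }
      wl <- wd * pref
      if (wl > 0) {
        lost[t] <<- lost[t] + wl
        recurse(state, t + 1L, wl, cnt)
      }
    }
  }
  recurse(initial_state(config), 1L, 1, 0L)
  atleast <- rev(cumsum(rev(count_pmf)))
  list(prob = prob, lost = lost, count_pmf = count_pmf, atleast = atleast)
}

# Second-order Bahadur density by full 2^M enumeration ------------------------
oracle_bahadur_atleast <- function(p, R) {
  M <- length(p)
  v <- p * (1 - p)
  count_mass <- numeric(M + 1L)
  grid <- as.matrix(expand.grid(rep(list(0:1), M)))
  for (row in seq_len(nrow(grid))) {
    x <- grid[row, ]
    f <- prod(p^x * (1 - p)^(1 - x))
    z <- (x - p) / sqrt(v)
    corr <- 0
    if (M >= 2) {
      for (s in 1:(M - 1)) for (t in (s + 1):M) corr <- corr + R[s, t] * z[s] * z[t]
    }
    m <- sum(x)
    count_mass[m + 1L] <- count_mass[m + 1L] + f * (1 + corr)
  }
  clipped <- -sum(count_mass[count_mass < 0])
  if (clipped > 0) {
    count_mass[count_mass < 0] <- 0
    count_mass <- count_mass / sum(count_mass)
  }
  rev(cumsum(rev(count_mass)))
}
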