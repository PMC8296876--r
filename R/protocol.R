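#' Initial joint strip state
#'
#' The joint state carries, for each macroarea, the current arrangement of
#' its strip slots (a permutation of the configured strip multiset). The
#' initial state is the configured order.
#'
#' @param config a `nation_config`.
#' @return named list of character vectors, one arrangement per macroarea id.
#' @export
initial_state <- function(config) {
  lapply(config$macroareas, `[[`, "strip")
}

# centres in query order for one arrangement: a multi-slot centre is queried
# once, at its earliest slot
strip_query_order <- function(arrangement) unique(arrangement)

#' Offer order for one surplus organ
#'
#' The ordered list of centres queried for an organ produced in
#' `donor_region`: the donor macroarea's strip (the donor's own centre
#' excluded -- a region that produces an excess organ cannot also be required
#' to use it), then the other macroarea's strip. A centre occupying several
#' slots is queried once, at its earliest slot.
#'
#' @param state joint state as returned by [initial_state()].
#' @param config a `nation_config`.
#' @param donor_region region name.
#' @return character vector of centre ids, possibly empty.
#' @export
offer_order <- function(state, config, donor_region) {
  idx <- config_index(config)
  if (!donor_region %in% idx$regions)
    stop(sprintf("unknown donor region '%s'", donor_region), call. = FALSE)
  ma_d <- idx$region_ma[[donor_region]]
  ma_o <- setdiff(idx$ma_ids, ma_d)
  own <- idx$region_center[[donor_region]]
  home <- strip_query_order(state[[ma_d]])
  if (!is.na(own)) home <- setdiff(home, own)
  away <- strip_query_order(state[[ma_o]])
  if (config$options$head_only_fallback && length(away) > 1L) away <- away[1L]
  c(home, away)
}

#' Rotate a strip after an allocation
#'
#' After an acceptance, the accepting centre's triggering slot and the
#' triggering slots of every centre that refused before it are moved to the
#' end of the strip, keeping their original relative order (so the acceptor,
#' queried last, ends last). All other slots keep their relative order. If no
#' centre accepted, the strip is unchanged.
#'
#' @param arrangement character vector: current slot arrangement of one strip.
#' @param refusers centres (of this strip) that refused before the acceptor,
#'   in query order.
#' @param acceptor centre id that accepted, or `NULL`/`NA` if none.
#' @return the new arrangement.
#' @export
rotate_strip <- function(arrangement, refusers = character(0), acceptor = NULL) {
  if (is.null(acceptor) || length(acceptor) == 0L || is.na(acceptor))
    return(arrangement)
  if (!acceptor %in% arrangement)
    stop(sprintf("acceptor '%s' is not a slot of this strip", acceptor), call. = FALSE)
  movers <- unique(c(refusers, acceptor))
  if (!all(movers %in% arrangement))
    stop("refuser not a slot of this strip", call. = FALSE)
  slot_idx <- match(movers, arrangement)  # earliest (triggering) slot of each mover
  sorted <- sort(slot_idx)
  c(arrangement[-sorted], arrangement[sorted])
}

#' Allocate one surplus organ under fixed decisions
#'
#' Walks the offer cascade for one organ: each centre in [offer_order()] is
#' queried in turn until the first acceptance. Only the strip of the macroarea
#' in which the acceptance occurred is rotated; if every centre refuses the
#' organ is LOST and both strips stay as they were.
#'
#' @param state joint state.
#' @param config a `nation_config`.
#' @param donor_region region name of the organ's origin.
#' @param decisions named vector (logical, or `"accept"`/`"refuse"`) giving
#'   each centre's decision if queried.
#' @return list with `accepted_by` (centre id or `"LOST"`), `offer_sequence`
#'   (data.frame: `center`, `position`, `decision`), and `state` (the updated
#'   joint state).
#' @export
allocate_one <- function(state, config, donor_region, decisions) {
  order <- offer_order(state, config, donor_region)
  if (is.character(decisions)) decisions <- decisions == "accept"
  idx <- config_index(config)
  seq_centers <- character(0)
  acceptor <- NA_character_
  for (ct in order) {
    if (!ct %in% names(decisions) || is.na(decisions[[ct]]))
      stop(sprintf("missing decision for queried center '%s'", ct), call. = FALSE)
    seq_centers <- c(seq_centers, ct)
    if (isTRUE(decisions[[ct]])) { acceptor <- ct; break }
  }
  new_state <- state
  if (!is.na(acceptor)) {
    ma <- idx$center_ma[[acceptor]]
    in_ma <- seq_centers[vapply(seq_centers, function(c) idx$center_ma[[c]] == ma, NA)]
    refusers <- setdiff(in_ma, acceptor)
    new_state[[ma]] <- rotate_strip(state[[ma]], refusers, acceptor)
  }
  decision_lbl <- ifelse(seq_centers == acceptor & !is.na(acceptor), "accept", "refuse")
  list(
    accepted_by = if (is.na(acceptor)) "LOST" else acceptor,
    offer_sequence = data.frame(center = seq_centers,
                                position = seq_along(seq_centers),
                                decision = decision_lbl,
                                stringsAsFactors = FALSE),
    state = new_state
  )
}
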