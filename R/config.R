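#' Construct a national allocation configuration
#'
#' A `nation_config` describes the whole topology the surplus protocol runs
#' on: exactly two macroareas, each with an ordered "strip" of transplant
#' centres and a set of regions (with or without a centre), per-centre
#' acceptance rates, and per-region surplus-organ production counts.
#'
#' @param macroareas list of two macroarea descriptions, each a list with
#'   `id` (character scalar), `strip` (character vector of centre ids, slots;
#'   repeats allowed, empty iff the macroarea has no centre) and `regions`
#'   (data.frame with columns `name`, `center` -- a centre id or `NA` for
#'   regions without a transplant centre -- and `production`, a non-negative
#'   integer count of surplus organs provided in the period).
#' @param centers list of centre descriptions, each a list with `id`,
#'   `acceptance_rate` in \[0, 1\] (the per-offer Bernoulli acceptance
#'   probability, i.e. the ratio of accepted organs to organs offered over a
#'   period) and `member_regions` (character vector; more than one region
#'   models a macroregion such as NITp).
#' @param head_only_fallback logical; if `TRUE`, only the head of the other
#'   macroarea's strip is queried after a full refusal in the donor macroarea
#'   (the literal reading of the protocol's worked example). Default `FALSE`:
#'   the cascade continues down the whole fallback strip.
#'
#' @return A validated object of class `nation_config`.
#' @export
#' @examples
#' cfg <- nation_config(
#'   macroareas = list(
#'     list(id = "A", strip = c("C1"),
#'          regions = data.frame(name = c("r1", "r2"), center = c("C1", NA),
#'                               production = c(0L, 5L))),
#'     list(id = "B", strip = c("C2"),
#'          regions = data.frame(name = "r3", center = "C2", production = 3L))
#'   ),
#'   centers = list(
#'     list(id = "C1", acceptance_rate = 0.26, member_regions = "r1"),
#'     list(id = "C2", acceptance_rate = 0.26, member_regions = "r3")
#'   )
#' )
#' donor_distribution(cfg)
nation_config <- function(macroareas, centers, head_only_fallback = FALSE) {
  cfg <- structure(
    list(
      macroareas = macroareas,
      centers = centers,
      options = list(head_only_fallback = isTRUE(head_only_fallback))
    ),
    class = "nation_config"
  )
  cfg <- canonicalize_config(cfg)
  validate_nation_config(cfg)
  cfg
}

# Normalize to the canonical in-memory form: named lists, character vectors,
# integer production, ordered columns.
canonicalize_config <- function(cfg) {
  mas <- lapply(cfg$macroareas, function(ma) {
    regs <- as.data.frame(ma$regions, stringsAsFactors = FALSE)
    regs$name <- as.character(regs$name)
    regs$center <- as.character(regs$center)
    regs$center[!is.na(regs$center) & regs$center == ""] <- NA_character_
    regs$production <- as.integer(regs$production)
    regs <- regs[, c("name", "center", "production")]
    rownames(regs) <- NULL
    list(id = as.character(ma$id)[1],
         strip = as.character(ma$strip %||% character(0)),
         regions = regs)
  })
  names(mas) <- vapply(mas, `[[`, "", "id")
  ctrs <- lapply(cfg$centers, function(ct) {
    list(id = as.character(ct$id)[1],
         acceptance_rate = as.numeric(ct$acceptance_rate)[1],
         member_regions = sort(as.character(ct$member_regions)))
  })
  names(ctrs) <- vapply(ctrs, `[[`, "", "id")
  cfg$macroareas <- mas
  cfg$centers <- ctrs
  cfg$options <- list(head_only_fallback = isTRUE(cfg$options$head_only_fallback))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_error <- function(rule, ...) {
  stop(sprintf("invalid nation config [%s]: %s", rule, sprintf(...)), call. = FALSE)
}

#' Validate a nation configuration
#'
#' Checks every structural invariant: exactly two macroareas, globally unique
#' region names, acceptance rates in \[0, 1\], non-negative integer production,
#' strip entries that are centres of their own macroarea (strip non-empty iff
#' the macroarea has at least one centre), and consistency between each
#' centre's `member_regions` and the regions that declare it.
#'
#' @param config a `nation_config` (or a plain list in the same shape).
#' @return the config, invisibly, if valid; otherwise an error naming the
#'   violated rule.
#' @export
validate_nation_config <- function(config) {
  mas <- config$macroareas
  if (length(mas) != 2L)
    config_error("two-macroareas", "exactly two macroareas are required, got %d", length(mas))
  ma_ids <- names(mas)
  if (anyDuplicated(ma_ids))
    config_error("macroarea-ids", "duplicated macroarea id")

  all_regions <- unlist(lapply(mas, function(ma) ma$regions$name), use.names = FALSE)
  if (length(all_regions) == 0L)
    config_error("regions", "no regions defined")
  if (anyDuplicated(all_regions))
    config_error("region-names", "region names must be globally unique: %s",
                 paste(unique(all_regions[duplicated(all_regions)]), collapse = ", "))

  ctrs <- config$centers
  if (anyDuplicated(names(ctrs)))
    config_error("center-ids", "duplicated center id")
  for (ct in ctrs) {
    if (is.na(ct$acceptance_rate) || ct$acceptance_rate < 0 || ct$acceptance_rate > 1)
      config_error("acceptance-rate", "center '%s' has acceptance_rate %s outside [0, 1]",
                   ct$id, format(ct$acceptance_rate))
    if (length(ct$member_regions) == 0L)
      config_error("member-regions", "center '%s' has no member regions", ct$id)
  }

  # each region's declared centre must exist; derive membership and compare
  declared <- list()
  region_ma <- character(0)
  for (ma in mas) {
    regs <- ma$regions
    if (any(is.na(regs$production) | regs$production < 0L))
      config_error("production", "macroarea '%s' has a negative or missing production count", ma$id)
    for (i in seq_len(nrow(regs))) {
      region_ma[regs$name[i]] <- ma$id
      ctr <- regs$center[i]
      if (!is.na(ctr)) {
        if (!ctr %in% names(ctrs))
          config_error("unknown-center", "region '%s' names unknown center '%s'", regs$name[i], ctr)
        declared[[ctr]] <- c(declared[[ctr]], regs$name[i])
      }
    }
    ma_centers <- unique(stats::na.omit(regs$center))
    if (length(ma$strip) == 0L && length(ma_centers) > 0L)
      config_error("strip-empty", "macroarea '%s' has centers but an empty strip", ma$id)
    if (length(ma$strip) > 0L && length(ma_centers) == 0L)
      config_error("strip-nonempty", "macroarea '%s' has a strip but no centers", ma$id)
    if (!all(ma$strip %in% ma_centers))
      config_error("strip-membership", "macroarea '%s' strip entry not a center of this macroarea: %s",
                   ma$id, paste(setdiff(ma$strip, ma_centers), collapse = ", "))
    if (!all(ma_centers %in% ma$strip))
      config_error("strip-coverage", "macroarea '%s' center missing from strip: %s",
                   ma$id, paste(setdiff(ma_centers, ma$strip), collapse = ", "))
  }
  for (ct in ctrs) {
    decl <- sort(declared[[ct$id]] %||% character(0))
    if (!identical(decl, ct$member_regions))
      config_error("member-regions", "center '%s': member_regions (%s) do not match regions declaring it (%s)",
                   ct$id, paste(ct$member_regions, collapse = ", "),
                   paste(decl, collapse = ", "))
    mas_of_members <- unique(region_ma[ct$member_regions])
    if (length(mas_of_members) != 1L)
      config_error("member-regions-macroarea", "center '%s' spans several macroareas", ct$id)
  }
  invisible(config)
}

# Fast lookup tables derived from a config; recomputed on demand (configs are
# small) and used throughout the engines.
config_index <- function(config) {
  mas <- config$macroareas
  region_ma <- character(0)
  region_center <- character(0)
  production <- integer(0)
  for (ma in mas) {
    regs <- ma$regions
    region_ma[regs$name] <- ma$id
    region_center[regs$name] <- regs$center
    production[regs$name] <- regs$production
  }
  rates <- vapply(config$centers, `[[`, 0, "acceptance_rate")
  center_ma <- vapply(names(config$centers), function(id) {
    region_ma[[config$centers[[id]]$member_regions[1]]]
  }, "")
  list(
    ma_ids = names(mas),
    strips = lapply(mas, `[[`, "strip"),
    region_ma = region_ma,
    region_center = region_center,
    production = production,
    rates = rates,
    center_ma = center_ma,
    regions = names(region_ma)
  )
}

#' Donor distribution over regions
#'
#' The probability that a surplus organ is provided by each region: production
#' counts normalised over the national total. Zero-production regions get
#' probability zero.
#'
#' @param config a `nation_config`.
#' @return named numeric vector over all regions, summing to 1.
#' @export
donor_distribution <- function(config) {
  idx <- config_index(config)
  tot <- sum(idx$production)
  if (tot <= 0)
    stop("donor distribution undefined: total surplus production is zero", call. = FALSE)
  idx$production / tot
}

#' @export
print.nation_config <- function(x, ...) {
  cat("<nation_config>\n")
  for (ma in x$macroareas) {
    cat(sprintf("  macroarea %s: strip [%s]\n", ma$id,
                paste(ma$strip, collapse = " > ")))
    nc <- sum(is.na(ma$regions$center))
    cat(sprintf("    %d regions (%d without a centre), production %d\n",
                nrow(ma$regions), nc, sum(ma$regions$production)))
  }
  rates <- vapply(x$centers, `[[`, 0, "acceptance_rate")
  cat(sprintf("  centres: %s\n",
              paste(sprintf("%s (%.0f%%)", names(rates), 100 * rates), collapse = ", ")))
  invisible(x)
}

#' Read a nation configuration from file
#'
#' Accepts YAML (default) or JSON (by `.json` extension). The schema has
#' top-level keys `macroareas` (each: `id`, `strip`, `regions` with `name`,
#' `center`, `production`) and `centers` (each: `id`, `acceptance_rate`,
#' `member_regions`), plus an optional `options` map.
#'
#' @param path file path.
#' @return a validated `nation_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$macroareas))
    stop("malformed config: missing key 'macroareas'", call. = FALSE)
  if (is.null(raw$centers))
    stop("malformed config: missing key 'centers'", call. = FALSE)
  mas <- lapply(raw$macroareas, function(ma) {
    if (is.null(ma$id)) stop("malformed config: macroarea without 'id'", call. = FALSE)
    if (is.null(ma$regions))
      stop(sprintf("malformed config: macroarea '%s' missing key 'regions'", ma$id), call. = FALSE)
    regs <- do.call(rbind, lapply(ma$regions, function(r) {
      if (is.null(r$name))
        stop("malformed config: region without 'name'", call. = FALSE)
      data.frame(name = r$name,
                 center = if (is.null(r$center)) NA_character_ else r$center,
                 production = if (is.null(r$production)) 0L else as.integer(r$production),
                 stringsAsFactors = FALSE)
    }))
    list(id = ma$id, strip = unlist(ma$strip) %||% character(0), regions = regs)
  })
  ctrs <- lapply(raw$centers, function(ct) {
    if (is.null(ct$id)) stop("malformed config: center without 'id'", call. = FALSE)
    if (is.null(ct$acceptance_rate))
      stop(sprintf("malformed config: center '%s' missing key 'acceptance_rate'", ct$id),
           call. = FALSE)
    list(id = ct$id, acceptance_rate = ct$acceptance_rate,
         member_regions = unlist(ct$member_regions))
  })
  nation_config(mas, ctrs,
                head_only_fallback = isTRUE(raw$options$head_only_fallback))
}

#' Write a nation configuration to file
#'
#' YAML by default, JSON when `path` ends in `.json`. `load_config()` of the
#' written file reproduces the config exactly.
#'
#' @param config a `nation_config`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_nation_config(config)
  out <- list(
    macroareas = lapply(unname(config$macroareas), function(ma) {
      list(id = ma$id,
           strip = as.list(ma$strip),
           regions = lapply(seq_len(nrow(ma$regions)), function(i) {
             r <- ma$regions[i, ]
             reg <- list(name = r$name, production = r$production)
             if (!is.na(r$center)) reg$center <- r$center
             reg
           }))
    }),
    centers = lapply(unname(config$centers), function(ct) {
      list(id = ct$id, acceptance_rate = ct$acceptance_rate,
           member_regions = as.list(ct$member_regions))
    }),
    options = list(head_only_fallback = config$options$head_only_fallback)
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
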