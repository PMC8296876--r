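#' Default production preset
#'
#' Named per-region surplus-production weights used by [italy_fixture()]:
#' national donor counts by region (121 Piemonte, 142 Emilia Romagna,
#' 167 Toscana, 130 Veneto, 226 Lombardia, 50 Sicilia, 117 Lazio), a proxy
#' for period-specific surplus counts. Regions not listed produce 0.
#'
#' @return named integer vector.
#' @export
italy_production_preset <- function() {
  c("Piemonte" = 121L, "Emilia Romagna" = 142L, "Toscana" = 167L,
    "Veneto" = 130L, "Lombardia" = 226L, "Sicilia" = 50L, "Lazio" = 117L)
}

#' Italian two-macroarea lung fixture
#'
#' The national topology of the surplus-lung protocol: macroarea Center-North
#' with strip Piemonte > Emilia Romagna > Toscana > NITp (NITp a macroregion
#' centre grouping Lombardia, Veneto, Friuli Venezia Giulia, Trentino-Alto
#' Adige, Liguria and Marche) and macroarea Center-South with strip
#' Lazio > Sicilia; the remaining regions have no lung transplant centre.
#' All centres share one acceptance rate (default 26%, the historical mean).
#'
#' @param acceptance_rate uniform per-centre acceptance probability in
#'   \[0, 1\].
#' @param production named vector of per-region surplus counts; defaults to
#'   [italy_production_preset()]. Unnamed regions produce 0.
#' @param head_only_fallback see [nation_config()].
#' @return a `nation_config`.
#' @export
#' @examples
#' cfg <- italy_fixture()
#' donor_distribution(cfg)["Toscana"]  # 167 / 953
italy_fixture <- function(acceptance_rate = 0.26,
                          production = italy_production_preset(),
                          head_only_fallback = FALSE) {
  if (acceptance_rate < 0 || acceptance_rate > 1)
    stop("acceptance_rate must lie in [0, 1]", call. = FALSE)
  if (length(production) == 0 || all(production <= 0))
    stop("production weights must be non-negative and not all zero", call. = FALSE)
  prod_of <- function(r) {
    p <- production[r]
    as.integer(ifelse(is.na(p), 0L, p))
  }
  north_regions <- data.frame(
    name = c("Piemonte", "Emilia Romagna", "Toscana",
             "Lombardia", "Veneto", "Friuli Venezia Giulia",
             "Trentino-Alto Adige", "Liguria", "Marche",
             "Valle d'Aosta", "Sardegna"),
    center = c("Piemonte", "Emilia Romagna", "Toscana",
               rep("NITp", 6), NA, NA),
    stringsAsFactors = FALSE
  )
  south_regions <- data.frame(
    name = c("Lazio", "Sicilia", "Abruzzo-Molise", "Umbria",
             "Campania", "Puglia", "Basilicata", "Calabria"),
    center = c("Lazio", "Sicilia", rep(NA, 6)),
    stringsAsFactors = FALSE
  )
  north_regions$production <- prod_of(north_regions$name)
  south_regions$production <- prod_of(south_regions$name)
  unknown <- setdiff(names(production),
                     c(north_regions$name, south_regions$name))
  if (length(unknown) > 0)
    stop(sprintf("unknown region in production weights: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  mk_center <- function(id, members) {
    list(id = id, acceptance_rate = acceptance_rate, member_regions = members)
  }
  nation_config(
    macroareas = list(
      list(id = "Center-North",
           strip = c("Piemonte", "Emilia Romagna", "Toscana", "NITp"),
           regions = north_regions),
      list(id = "Center-South",
           strip = c("Lazio", "Sicilia"),
           regions = south_regions)
    ),
    centers = list(
      mk_center("Piemonte", "Piemonte"),
      mk_center("Emilia Romagna", "Emilia Romagna"),
      mk_center("Toscana", "Toscana"),
      mk_center("NITp", c("Lombardia", "Veneto", "Friuli Venezia Giulia",
                          "Trentino-Alto Adige", "Liguria", "Marche")),
      mk_center("Lazio", "Lazio"),
      mk_center("Sicilia", "Sicilia")
    ),
    head_only_fallback = head_only_fallback
  )
}

#' Random valid nation configuration
#'
#' Property-test generator: two macroareas with a random number of centres,
#' random strip slot multiplicities, random acceptance rates and production
#' counts. Always passes [validate_nation_config()]. Reproducible from `seed`.
#'
#' @param seed integer seed.
#' @param n_centers length-2 range for centres per macroarea.
#' @param max_slots maximum slots a centre may occupy in its strip.
#' @param n_extra_regions length-2 range of no-centre regions per macroarea.
#' @param n_producers number of regions with non-zero production (default:
#'   random, at least 1).
#' @param rate_range range of acceptance rates.
#' @param production_max maximum per-region production count.
#' @return a `nation_config`.
#' @export
random_config <- function(seed, n_centers = c(1, 4), max_slots = 2,
                          n_extra_regions = c(0, 2), n_producers = NULL,
                          rate_range = c(0.05, 0.95), production_max = 50) {
  set.seed(seed)
  ridx <- 0L
  mas <- list()
  all_regions <- character(0)
  centers <- list()
  for (mi in 1:2) {
    nc <- sample(n_centers[1]:n_centers[2], 1)
    ne <- sample(n_extra_regions[1]:n_extra_regions[2], 1)
    reg_names <- character(0)
    ctr_col <- character(0)
    strip <- character(0)
    for (ci in seq_len(nc)) {
      cid <- sprintf("C%d_%d", mi, ci)
      n_members <- sample(1:2, 1)
      members <- sprintf("R%d", ridx + seq_len(n_members)); ridx <- ridx + n_members
      reg_names <- c(reg_names, members)
      ctr_col <- c(ctr_col, rep(cid, n_members))
      centers[[cid]] <- list(
        id = cid,
        acceptance_rate = stats::runif(1, rate_range[1], rate_range[2]),
        member_regions = members)
      strip <- c(strip, rep(cid, sample(1:max_slots, 1)))
    }
    if (ne > 0) {
      extra <- sprintf("R%d", ridx + seq_len(ne)); ridx <- ridx + ne
      reg_names <- c(reg_names, extra)
      ctr_col <- c(ctr_col, rep(NA_character_, ne))
    }
    if (length(strip) > 1) strip <- sample(strip)
    mas[[mi]] <- list(id = sprintf("MA%d", mi), strip = strip,
                      regions = data.frame(name = reg_names, center = ctr_col,
                                           production = 0L,
                                           stringsAsFactors = FALSE))
    all_regions <- c(all_regions, reg_names)
  }
  if (is.null(n_producers))
    n_producers <- sample(seq_along(all_regions), 1)
  n_producers <- min(n_producers, length(all_regions))
  producers <- sample(all_regions, n_producers)
  for (mi in 1:2) {
    sel <- mas[[mi]]$regions$name %in% producers
    mas[[mi]]$regions$production[sel] <-
      sample.int(production_max, sum(sel), replace = TRUE)
  }
  nation_config(mas, unname(centers))
}
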