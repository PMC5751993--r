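#' Filter photo events to independent detections
#'
#' Within each (station, species) stream, the first photo opens a 1-hour
#' window (anchored at the opening event, not a rolling gap): every photo
#' strictly within `window_h` hours of the opening event merges into a single
#' independent event carrying the largest group count observed in the window;
#' the first photo at or beyond `window_h` hours opens the next window. A
#' rolling-gap variant (`rule = "gap"`, window re-anchors on every photo) is
#' available for sensitivity checks.
#'
#' @param photos photo-event table (needs `station_id`, `species`,
#'   `timestamp`, `count`).
#' @param window_h independence window in hours (default 1).
#' @param rule `"anchored"` (default) or `"gap"`.
#' @return the filtered photo table (one row per independent event, window
#'   opening timestamps, maximal counts), sorted by station, species, time.
#' @export
independence_filter <- function(photos, window_h = 1,
                                rule = c("anchored", "gap")) {
  rule <- match.arg(rule)
  stopifnot(window_h > 0)
  if (nrow(photos) == 0) return(photos)
  photos <- photos[order(photos$station_id, photos$species,
                         photos$timestamp), , drop = FALSE]
  key <- paste(photos$station_id, photos$species, sep = "\r")
  keep <- logical(nrow(photos))
  count <- photos$count
  win <- window_h * 3600
  for (g in split(seq_len(nrow(photos)), key)) {
    t <- as.numeric(photos$timestamp[g])
    open <- 1L
    keep[g[1]] <- TRUE
    for (i in seq_along(g)[-1]) {
      anchor <- if (rule == "anchored") t[open] else t[i - 1L]
      if (t[i] - anchor < win) {
        count[g[open]] <- max(count[g[open]], count[g[i]])
      } else {
        open <- i
        keep[g[i]] <- TRUE
      }
    }
  }
  photos$count <- count
  out <- photos[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Species class roster
#'
#' Which photographed species count as ungulates and which enter the biomass
#' index at all (terrestrial, >= 1 kg; the sympatric puma is excluded because
#' it is not prey). The roster is configuration data, not a constant: the
#' default ships as an editable CSV (`extdata/species_classes.csv`), and any
#' data frame with the same columns can be passed to [biomass_index()].
#'
#' @param path CSV with columns `species`, `ungulate`, `include`.
#' @return data frame with `species`, `ungulate` (logical), `include`
#'   (logical).
#' @export
species_classes <- function(path = system.file("extdata",
                                               "species_classes.csv",
                                               package = "camtrapDens")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$ungulate <- as.logical(df$ungulate)
  df$include <- as.logical(df$include)
  df
}

#' Per-station prey biomass index
#'
#' `BI = sum_i n_i * w_i / t` in kg/day: over the species detected at a
#' station, the total number of individuals in independent photo events
#' (`n_i`), times the species' mean adult mass (`w_i`, kg), divided by the
#' days the station was active (`t`). Events should already have passed
#' [independence_filter()].
#'
#' @param events independent photo-event table.
#' @param masses species mass table (`species`, `mass_kg`).
#' @param stations station table (defines `t` and site membership; stations
#'   without events get `BI = 0`).
#' @param class which species enter the sum: `"all"` (every included species),
#'   `"ungulates"`, or `"nonungulates"`.
#' @param roster species class roster as from [species_classes()]; species
#'   absent from the roster are treated as included non-ungulates.
#' @return data frame with `station_id`, `site`, `t_days`, `bi` (kg/day).
#' @export
biomass_index <- function(events, masses, stations,
                          class = c("all", "ungulates", "nonungulates"),
                          roster = species_classes()) {
  class <- match.arg(class)
  t_days <- stations$active_to - stations$active_from + 1L
  ev <- events
  if (nrow(ev)) {
    ri <- match(ev$species, roster$species)
    include <- ifelse(is.na(ri), TRUE, roster$include[ri])
    ung <- ifelse(is.na(ri), FALSE, roster$ungulate[ri])
    sel <- include & switch(class, all = TRUE, ungulates = ung,
                            nonungulates = !ung)
    ev <- ev[sel, , drop = FALSE]
  }
  if (nrow(ev)) {
    mi <- match(ev$species, masses$species)
    if (anyNA(mi))
      stop_ct("no mass recorded for species: %s",
              toString(unique(ev$species[is.na(mi)])))
    kg <- ev$count * masses$mass_kg[mi]
    tot <- tapply(kg, ev$station_id, sum)
  } else tot <- numeric(0)
  bi <- as.numeric(tot[stations$station_id])
  bi[is.na(bi)] <- 0
  data.frame(station_id = stations$station_id, site = stations$site,
             t_days = t_days, bi = bi / t_days, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis rank test across sites
#'
#' Rank-based H statistic with tie correction and the chi-square p-value
#' (wraps the standard test). Degenerate input with all values identical
#' yields `H = 0`, `p = 1`.
#'
#' @param values numeric observations (e.g. per-station biomass indices).
#' @param groups group labels (e.g. sites) of the same length.
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2 || length(values) < 2)
    stop_ct("need >= 2 groups and >= 2 observations")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pearson correlation with a Bayesian-bootstrap interval
#'
#' Point estimate is the sample Pearson correlation; uncertainty comes from
#' the Bayesian bootstrap: each posterior draw reweights the observations with
#' flat-Dirichlet weights and recomputes the weighted Pearson correlation. The
#' interval is the 95% highest density interval of the draws.
#'
#' @param x,y numeric vectors of equal length (>= 3, finite, non-degenerate).
#' @param draws number of posterior resamples (default 1000).
#' @param seed optional seed for the Dirichlet draws.
#' @param mass interval mass (default 0.95).
#' @return list with `r`, `hdi` (`c(lower, upper)`), and the posterior
#'   `draws`.
#' @export
bayes_boot_correlation <- function(x, y, draws = 1000, seed = NULL,
                                   mass = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_ct("x and y must be finite")
  if (var(x) == 0 || var(y) == 0)
    stop_ct("zero variance in x or y; correlation undefined")
  n <- length(x)
  r <- cor(x, y)
  post <- with_seed(seed, {
    vapply(seq_len(draws), function(d) {
      w <- rexp(n)
      w <- w / sum(w)
      mx <- sum(w * x); my <- sum(w * y)
      sxy <- sum(w * (x - mx) * (y - my))
      sx <- sum(w * (x - mx)^2); sy <- sum(w * (y - my)^2)
      if (sx <= 0 || sy <= 0) return(NA_real_)
      sxy / sqrt(sx * sy)
    }, 0)
  })
  post <- post[is.finite(post)]
  list(r = r, hdi = hdi(post, mass), draws = post)
}

#' Site-level biomass summary
#'
#' Mean and SD of the station biomass index per site, for each species class,
#' plus the Kruskal-Wallis comparison across sites.
#'
#' @param survey a [ct_survey()] with photos and masses.
#' @param window_h independence window (hours).
#' @param roster species class roster.
#' @return list with `stations` (per-station BI for the three classes),
#'   `sites` (per-site mean +/- SD per class), `tests` (Kruskal-Wallis per
#'   class).
#' @export
biomass_summary <- function(survey, window_h = NULL,
                            roster = species_classes()) {
  stopifnot(inherits(survey, "ct_survey"))
  if (is.null(survey$photos) || is.null(survey$masses))
    stop_ct("survey bundle needs photos and masses for the biomass index")
  window_h <- window_h %||% survey$config$independence_hours
  ev <- independence_filter(survey$photos, window_h)
  classes <- c("all", "ungulates", "nonungulates")
  per <- lapply(classes, function(cl)
    biomass_index(ev, survey$masses, survey$stations, cl, roster))
  names(per) <- classes
  stations <- per$all
  names(stations)[names(stations) == "bi"] <- "bi_all"
  stations$bi_ungulates <- per$ungulates$bi
  stations$bi_nonungulates <- per$nonungulates$bi
  sites <- do.call(rbind, lapply(classes, function(cl) {
    agg <- aggregate(per[[cl]]$bi, list(site = per[[cl]]$site),
                     function(v) c(mean = mean(v), sd = sd(v), n = length(v)))
    data.frame(class = cl, site = agg$site, mean = agg$x[, "mean"],
               sd = agg$x[, "sd"], n = agg$x[, "n"],
               stringsAsFactors = FALSE)
  }))
  tests <- lapply(per, function(df) kruskal_wallis(df$bi, df$site))
  list(stations = stations, sites = sites, tests = tests)
}
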