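#' Threshold a continuous layer into a binary resistance surface
#'
#' Converts a continuous predictor raster (habitat index, percent cover,
#' abundance kernel, ...) into a binary habitat/nonhabitat resistance
#' surface. For variables with a positive association with the species
#' (e.g. habitat index, sagebrush cover) cells at or above the threshold
#' are habitat (resistance 1) and cells below receive
#' `nonhabitat_resistance`; for negative associations (canopy cover,
#' tillage, disturbance, terrain, drought) the rule is mirrored: cells at
#' or below the threshold are habitat. The NoData mask is preserved.
#'
#' @param raster an [lg_raster].
#' @param threshold threshold value; a warning is issued if it lies outside
#'   the observed value range.
#' @param direction `"positive"` or `"negative"` association.
#' @param nonhabitat_resistance resistance assigned to nonhabitat; must be
#'   greater than 1.
#' @param variable tag naming the source variable (metadata).
#' @return a `resistance_surface` (an [lg_raster] with threshold metadata).
#' @export
threshold_surface <- function(raster, threshold,
                              direction = c("positive", "negative"),
                              nonhabitat_resistance, variable = "var") {
  stopifnot(inherits(raster, "lg_raster"))
  direction <- match.arg(direction)
  if (!is.numeric(nonhabitat_resistance) || nonhabitat_resistance <= 1)
    stop("nonhabitat_resistance must be > 1", call. = FALSE)
  v <- raster$values
  rng <- range(v, na.rm = TRUE)
  if (threshold < rng[1] || threshold > rng[2])
    warning(sprintf("threshold %g outside observed range [%g, %g]",
                    threshold, rng[1], rng[2]), call. = FALSE)
  habitat <- if (direction == "positive") v >= threshold else v <= threshold
  out <- ifelse(habitat, 1, nonhabitat_resistance)
  out[is.na(v)] <- NA_real_
  res <- raster; res$values <- out
  structure(c(unclass(res),
              list(variable = variable, threshold = threshold,
                   direction = direction,
                   nonhabitat_resistance = nonhabitat_resistance)),
            class = c("resistance_surface", "lg_raster"))
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat(sprintf(
    "<resistance_surface> %s: threshold %g (%s), nonhabitat r=%g\n",
    x$variable, x$threshold, x$direction, x$nonhabitat_resistance))
  NextMethod()
}

#' Uniform all-habitat surface on a mask
#'
#' The undifferentiated landscape in which every non-masked cell has
#' resistance 1; effective resistances on this surface are the
#' geographic-null "distances" used as the null predictor throughout.
#'
#' @param raster an [lg_raster] supplying the grid and mask.
#' @return a `resistance_surface` of all ones.
#' @export
uniform_surface <- function(raster) {
  v <- ifelse(is.na(raster$values), NA_real_, 1)
  res <- raster; res$values <- v
  structure(c(unclass(res),
              list(variable = "null", threshold = NA_real_,
                   direction = "positive", nonhabitat_resistance = Inf)),
            class = c("resistance_surface", "lg_raster"))
}

#' Empirical percentile threshold of a raster
#'
#' The value v such that the top `top_percent` of the non-masked cell mass
#' lies at or above v (an empirical quantile with linear interpolation
#' between order statistics). Used for strongly zero-skewed layers such as
#' abundance kernels, where absolute thresholds are not meaningful.
#'
#' @param raster an [lg_raster].
#' @param top_percent percentage of cells to classify as the "top"
#'   (0 < top_percent < 100).
#' @return the threshold value.
#' @export
percentile_threshold <- function(raster, top_percent) {
  stopifnot(inherits(raster, "lg_raster"))
  if (top_percent <= 0 || top_percent >= 100)
    stop("top_percent must be in (0, 100)", call. = FALSE)
  v <- raster$values[!is.na(raster$values)]
  if (length(v) == 0L) stop("all cells masked", call. = FALSE)
  unname(stats::quantile(v, probs = 1 - top_percent / 100, type = 7))
}

#' Additive combination of resistance surfaces
#'
#' Sums several binary resistance surfaces into one combined landscape
#' surface: the cell value is `1 + sum(value_s - 1)`, so a cell that is
#' habitat on every input keeps resistance 1 and a cell that is resistant
#' for more than one variable accumulates the excess resistances
#' additively.
#'
#' @param surfaces list of `resistance_surface` objects on identical grids
#'   and masks.
#' @return a `resistance_surface` tagged `"landsum"`.
#' @export
combine_surfaces <- function(surfaces) {
  if (length(surfaces) == 0L) stop("no surfaces", call. = FALSE)
  base <- surfaces[[1]]
  acc <- base$values - 1
  for (s in surfaces[-1]) {
    if (!same_grid(base, s) ||
        !identical(is.na(base$values), is.na(s$values)))
      stop("surfaces are not on identical grids/masks", call. = FALSE)
    acc <- acc + (s$values - 1)
  }
  out <- base
  out$values <- 1 + acc
  out$variable <- "landsum"
  out$threshold <- NA_real_
  out$nonhabitat_resistance <- max(out$values, na.rm = TRUE)
  out
}

#' Build the six candidate surfaces for one variable
#'
#' Three thresholds crossed with the two selected nonhabitat resistance
#' values give the standard six candidate surfaces per variable
#' (3 thresholds x 2 resistances).
#'
#' @param raster continuous predictor raster.
#' @param thresholds numeric vector of three threshold values (absolute),
#'   or percentages when `threshold_mode = "percentile"` (interpreted as
#'   top-percent).
#' @param direction association direction.
#' @param resistances the two nonhabitat resistance values.
#' @param variable variable tag.
#' @param threshold_mode `"absolute"` or `"percentile"`.
#' @return named list of `resistance_surface` objects
#'   (`<var>_t<threshold>_r<resistance>`).
#' @export
candidate_surfaces <- function(raster, thresholds, direction, resistances,
                               variable = "var",
                               threshold_mode = c("absolute",
                                                  "percentile")) {
  threshold_mode <- match.arg(threshold_mode)
  out <- list()
  for (th in thresholds) {
    thv <- if (threshold_mode == "percentile")
      percentile_threshold(raster, th) else th
    for (r in resistances) {
      s <- threshold_surface(raster, thv, direction, r, variable)
      out[[sprintf("%s_t%g_r%g", variable, th, r)]] <- s
    }
  }
  out
}

#' Select nonhabitat resistance values by the decorrelation rule
#'
#' Resistance surfaces representing competing hypotheses are hard to
#' distinguish when their pairwise resistances are highly correlated with
#' each other or with distance. This search picks, per variable, the first
#' (low) nonhabitat resistance as the smallest candidate in `low_set` whose
#' three threshold-specific pairwise-resistance matrices have mean Pearson
#' correlation with the geographic-null matrix at or below `corr_limit` in
#' at least one zone, and the second (high) value as the smallest candidate
#' in `high_set` whose matrices' mean correlation with the chosen low-value
#' matrices is at or below `corr_limit` in any zone. If no candidate
#' satisfies the rule the largest is returned with a warning.
#'
#' @param rasters_by_zone named list (zone -> continuous predictor
#'   [lg_raster]).
#' @param nodes_by_zone named list (zone -> node sets, see
#'   [effective_resistance_pairwise]).
#' @param thresholds,direction,threshold_mode threshold specification for
#'   the variable.
#' @param low_set,high_set candidate nonhabitat resistances (defaults
#'   c(5, 10, 20) and c(50, 100, 200)).
#' @param corr_limit correlation limit (default 0.7).
#' @param neighborhood graph stencil passed to [build_graph].
#' @return list with `r_low`, `r_high` and the full correlation `audit`
#'   table (zone, candidate, threshold, correlation, stage).
#' @export
select_resistance_values <- function(rasters_by_zone, nodes_by_zone,
                                     thresholds, direction,
                                     threshold_mode = "absolute",
                                     low_set = c(5, 10, 20),
                                     high_set = c(50, 100, 200),
                                     corr_limit = 0.7, neighborhood = 8) {
  zones <- names(rasters_by_zone)
  stopifnot(length(zones) >= 1L, identical(zones, names(nodes_by_zone)))
  low_set <- sort(low_set); high_set <- sort(high_set)

  resist_mats <- function(zone, r) {
    ras <- rasters_by_zone[[zone]]
    lapply(thresholds, function(th) {
      thv <- if (threshold_mode == "percentile")
        percentile_threshold(ras, th) else th
      s <- threshold_surface(ras, thv, direction, r)
      g <- build_graph(s, neighborhood = neighborhood)
      effective_resistance_pairwise(g, nodes_by_zone[[zone]])
    })
  }
  null_mats <- lapply(zones, function(z) {
    g <- build_graph(uniform_surface(rasters_by_zone[[z]]),
                     neighborhood = neighborhood)
    effective_resistance_pairwise(g, nodes_by_zone[[z]])
  })
  names(null_mats) <- zones

  cor_offdiag <- function(a, b) {
    ut <- upper.tri(a)
    ok <- is.finite(a[ut]) & is.finite(b[ut])
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(a[ut][ok], b[ut][ok]))
  }

  audit <- list()
  pick <- function(set, ref_mats_fn, stage) {
    chosen <- NA_real_
    low_mats <- NULL
    for (r in set) {
      mats_z <- lapply(zones, function(z) resist_mats(z, r))
      names(mats_z) <- zones
      mean_by_zone <- numeric(length(zones))
      for (zi in seq_along(zones)) {
        refs <- ref_mats_fn(zones[zi])
        cors <- numeric(length(thresholds))
        for (ti in seq_along(thresholds)) {
          ref <- if (is.list(refs) && !inherits(refs, "pairwise_matrix"))
            refs[[ti]] else refs
          cors[ti] <- cor_offdiag(mats_z[[zi]][[ti]], ref)
          audit[[length(audit) + 1L]] <<- data.frame(
            stage = stage, zone = zones[zi], candidate = r,
            threshold = thresholds[ti], correlation = cors[ti])
        }
        mean_by_zone[zi] <- mean(cors, na.rm = TRUE)
      }
      if (is.na(chosen) && any(mean_by_zone <= corr_limit, na.rm = TRUE)) {
        chosen <- r
        low_mats <- mats_z
      }
    }
    if (is.na(chosen)) {
      warning(sprintf(
        "no %s-set candidate reached mean correlation <= %g; using %g",
        stage, corr_limit, max(set)), call. = FALSE)
      chosen <- max(set)
      low_mats <- lapply(zones, function(z) resist_mats(z, chosen))
      names(low_mats) <- zones
    }
    list(r = chosen, mats = low_mats)
  }

  low <- pick(low_set, function(z) null_mats[[z]], "low")
  high <- pick(high_set, function(z) low$mats[[z]], "high")
  list(r_low = low$r, r_high = high$r,
       audit = do.call(rbind, audit))
}
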