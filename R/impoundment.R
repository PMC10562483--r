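# Barrier-level impoundment accounting and continental extrapolation:
# backwater length h/s, remaining vs altered habitat, per-type corrections
# for missing heights and inventory underreporting, catchment medians,
# and restoration prioritisation.

#' Impoundment (backwater) length of a barrier
#'
#' The backwater pond upstream of a barrier is approximated by barrier height
#' divided by local channel slope: h (m) / s (m/km) gives km. Records with
#' zero slope or missing height cannot be scored; they return `NA` and are
#' meant to be counted in an exclusion report, never an infinity.
#'
#' @param height_m barrier height in meters (NA = unknown).
#' @param slope_permil channel slope in per-mille (m per km).
#' @return Impoundment length in km, vectorised; NA where not computable.
#' @export
impoundment_length <- function(height_m, slope_permil) {
  if (any(slope_permil < 0, na.rm = TRUE))
    stop("negative slope", call. = FALSE)
  if (any(height_m <= 0, na.rm = TRUE))
    stop("non-positive barrier height", call. = FALSE)
  out <- height_m / slope_permil
  out[!is.na(slope_permil) & slope_permil == 0] <- NA_real_
  out
}

#' Remaining and altered habitat within an impoundment
#'
#' The impounded reach of length L retains a fraction wRHp of usable habitat:
#' remaining = L * wRHp, altered = L - remaining. wRHp above 1 yields negative
#' alteration (a net habitat gain, possible for limnophilic communities); the
#' sign is preserved, not clipped.
#'
#' @param L_km impoundment length (km).
#' @param wrhp_fraction wRHp as a fraction in `[0, 2]`.
#' @return data.frame with `remaining_km` and `altered_km`.
#' @export
remaining_length <- function(L_km, wrhp_fraction) {
  if (any(wrhp_fraction < 0 | wrhp_fraction > 2, na.rm = TRUE))
    stop("wRHp fraction outside [0, 2]", call. = FALSE)
  rem <- L_km * wrhp_fraction
  data.frame(remaining_km = rem, altered_km = L_km - rem)
}

#' Per-type correction table
#'
#' @param type barrier type(s).
#' @param p proportion of recorded barriers of the type that carry height
#'   information, in (0, 1].
#' @param err underreporting error: fraction of real barriers of the type
#'   absent from the inventory, in [0, 1).
#' @return data.frame of class `type_correction`.
#' @export
type_correction <- function(type, p, err) {
  type <- as_barrier_type(type)
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]", call. = FALSE)
  if (any(err < 0 | err >= 1)) stop("err must be in [0, 1)", call. = FALSE)
  structure(data.frame(type = type, p = p, err = err,
                       stringsAsFactors = FALSE),
            class = c("type_correction", "data.frame"))
}

#' Scale a calculated total up for missing heights and underreporting
#'
#' Calculated sums only cover barriers that are recorded (a fraction 1 - err
#' of the real population) and carry a height (a fraction p of the recorded
#' ones). Under missingness independent of barrier size the real total is
#' estimated by \deqn{X_{est} = X_{calc} / ((1 - err) \, p).}
#'
#' @param x calculated quantity (km or a count).
#' @param p,err correction fractions (see [type_correction()]).
#' @return Estimated quantity, vectorised.
#' @export
estimate_corrected <- function(x, p, err) {
  if (any(p <= 0)) stop("uncorrectable type: p = 0", call. = FALSE)
  x / ((1 - err) * p)
}

#' Score a barrier inventory
#'
#' Computes per-barrier impoundment length, looks up wRHp from the barrier's
#' macrohabitat type, and derives remaining / altered habitat. Barriers with
#' zero slope or missing height are excluded and tallied.
#'
#' @param barriers inventory data.frame: `barrier_id`, `type`, `height_m`
#'   (NA = missing), `slope_permil`, `catchment_id`, `fcmacht_id`, optionally
#'   `upstream_km`.
#' @param wrhp_lookup either a data.frame (`macrohabitat_type`,
#'   `barrier_type`, `wRHp_percent`) such as [wrhp_grid()] output, or a named
#'   numeric vector of per-barrier-type wRHp percents applied irrespective of
#'   macrohabitat.
#' @return List: `scored` (data.frame with `L_km`, `wrhp_fraction`,
#'   `remaining_km`, `altered_km` for scoreable rows) and `exclusions`
#'   (counts by reason).
#' @export
score_barriers <- function(barriers, wrhp_lookup) {
  need <- c("barrier_id", "type", "height_m", "slope_permil")
  stopifnot(all(need %in% names(barriers)))
  barriers$type <- as_barrier_type(barriers$type)
  no_height <- is.na(barriers$height_m)
  zero_slope <- !no_height & barriers$slope_permil == 0
  keep <- !no_height & !zero_slope
  sc <- barriers[keep, , drop = FALSE]
  sc$L_km <- impoundment_length(sc$height_m, sc$slope_permil)
  if (is.data.frame(wrhp_lookup)) {
    key <- paste(sc$fcmacht_id, sc$type)
    lk <- stats::setNames(wrhp_lookup$wRHp_percent,
                          paste(wrhp_lookup$macrohabitat_type,
                                wrhp_lookup$barrier_type))
    pct <- lk[key]
  } else {
    pct <- wrhp_lookup[sc$type]
  }
  if (anyNA(pct))
    stop("no wRHp value for some (macrohabitat, barrier type) pairs",
         call. = FALSE)
  sc$wrhp_fraction <- as.numeric(pct) / 100
  rl <- remaining_length(sc$L_km, sc$wrhp_fraction)
  sc$remaining_km <- rl$remaining_km
  sc$altered_km <- rl$altered_km
  list(scored = sc,
       exclusions = c(missing_height = sum(no_height),
                      zero_slope = sum(zero_slope)))
}

#' Corrected alteration totals for one barrier type
#'
#' Sums calculated impoundment and remaining habitat over the scoreable
#' records of one type, then scales each up by 1 / ((1 - err) p). The
#' projected number of barriers of the type is the height-bearing record
#' count scaled the same way.
#'
#' @param calc_impoundment_km,calc_remaining_km calculated (observed) sums.
#' @param n_height number of records with height information.
#' @param correction one-row [type_correction()] (or a list with `p`, `err`).
#' @return One-row data.frame: calculated and estimated impoundment /
#'   remaining / alteration km and `projected_count`.
#' @export
correct_type_totals <- function(calc_impoundment_km, calc_remaining_km,
                                n_height, correction) {
  p <- correction$p; err <- correction$err
  est_imp <- estimate_corrected(calc_impoundment_km, p, err)
  est_rem <- estimate_corrected(calc_remaining_km, p, err)
  data.frame(
    n_height = n_height,
    calc_impoundment_km = calc_impoundment_km,
    calc_remaining_km = calc_remaining_km,
    calc_alteration_km = calc_impoundment_km - calc_remaining_km,
    p = p, err = err,
    est_impoundment_km = est_imp,
    est_remaining_km = est_rem,
    est_alteration_km = est_imp - est_rem,
    projected_count = estimate_corrected(n_height, p, err))
}

#' Continental alteration summary
#'
#' Scores an inventory, aggregates per barrier type, applies the per-type
#' corrections, and appends a column-sum total row. By default only dams,
#' weirs and sluices (the impoundment-forming types) are corrected and
#' reported; other types can be included via `types`.
#'
#' @inheritParams score_barriers
#' @param corrections [type_correction()] table covering `types`.
#' @param types barrier types to report.
#' @return List: `summary` (one row per type + "total"), `exclusions`.
#' @export
alteration_summary <- function(barriers, wrhp_lookup, corrections,
                               types = c("dam", "weir", "sluice")) {
  scored <- score_barriers(barriers[barriers$type %in% types, , drop = FALSE],
                           wrhp_lookup)
  sc <- scored$scored
  rows <- lapply(types, function(ty) {
    s <- sc[sc$type == ty, , drop = FALSE]
    corr <- corrections[corrections$type == ty, , drop = FALSE]
    if (!nrow(corr)) stop("no correction for type ", ty, call. = FALSE)
    cbind(type = ty,
          correct_type_totals(sum(s$L_km), sum(s$remaining_km), nrow(s), corr),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  total <- out[1, , drop = FALSE]
  total$type <- "total"
  total[num] <- lapply(out[num], sum)
  total$p <- NA_real_; total$err <- NA_real_
  out <- rbind(out, total)
  rownames(out) <- NULL
  list(summary = out, exclusions = scored$exclusions)
}

#' Catchment-level median wRHp
#'
#' Summarises per-barrier wRHp by catchment with the standard median (mean of
#' the middle two for even counts) and classifies the result.
#'
#' @param scored data.frame with `catchment_id` and `wrhp_fraction` (or
#'   `wRHp_percent`).
#' @return data.frame: `catchment_id`, `median_wRHp_percent`, `severity`.
#' @export
catchment_median_wrhp <- function(scored) {
  pct <- if ("wRHp_percent" %in% names(scored)) scored$wRHp_percent
         else 100 * scored$wrhp_fraction
  ok <- !is.na(pct) & !is.na(scored$catchment_id)
  dropped <- sum(!ok)
  if (dropped) message(dropped, " barrier(s) without wRHp or catchment omitted")
  med <- tapply(pct[ok], scored$catchment_id[ok], stats::median)
  data.frame(catchment_id = names(med),
             median_wRHp_percent = as.numeric(med),
             severity = classify_alteration(as.numeric(med)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Restoration priority ranking
#'
#' Plots each barrier in the plane (altered habitat proportion 1 - wRHp,
#' upstream river length blocked rescaled to `[0, 1]` by the set maximum) and
#' scores it by Euclidean distance from the origin: barriers that both alter
#' much habitat and block much river rank first. Ties break by barrier id.
#'
#' @param barriers data.frame with `barrier_id`, `wrhp_fraction`, and
#'   `upstream_km` (length blocked upstream).
#' @return The input ordered by descending `priority_score`, with
#'   `altered_proportion`, `normalized_length`, `priority_score`, `rank`.
#' @export
restoration_priority <- function(barriers) {
  stopifnot(nrow(barriers) > 0,
            all(c("barrier_id", "wrhp_fraction", "upstream_km")
                %in% names(barriers)))
  mx <- max(barriers$upstream_km)
  nl <- if (mx > 0) barriers$upstream_km / mx else rep(0, nrow(barriers))
  ap <- 1 - barriers$wrhp_fraction
  score <- sqrt(ap^2 + nl^2)
  out <- barriers
  out$altered_proportion <- ap
  out$normalized_length <- nl
  out$priority_score <- score
  out <- out[order(-score, out$barrier_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
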