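# CHAMP score algebra: altered habitat suitability (AHS = HP x HA),
# ponding sensitivity (PSI), remaining-habitat proportion (RHp),
# macrohabitat sensitivity, weighted RHp, and the categorical bins.

#' Altered habitat suitability score
#'
#' AHS = HP x HA for one guild-criterion-barrier combination. A value of 1
#' means the habitat area supported by that criterion is unchanged; 0 means it
#' is lost (or the criterion never mattered); values above 1 mean a gain.
#'
#' @param hp habitat-preference score(s) in \{0, 0.5, 1\}.
#' @param ha habitat-alteration score(s) in \{0, 0.5, 1, 1.5, 2\}.
#' @return hp * ha, vectorised.
#' @examples
#' compute_ahs(1, 0)    # critical criterion wiped out -> 0
#' compute_ahs(0.5, 2)  # moderate criterion doubled -> 1
#' @export
compute_ahs <- function(hp, ha) {
  if (!all(hp %in% HP_SCORES))
    stop("HP score(s) outside {0, 0.5, 1}", call. = FALSE)
  if (!all(ha %in% HA_SCORES))
    stop("HA score(s) outside {0, 0.5, 1, 1.5, 2}", call. = FALSE)
  hp * ha
}

#' Ponding sensitivity index
#'
#' PSI of a guild is the sum of its HP scores over all criteria: the number of
#' (importance-weighted) habitat attributes that impoundment could touch.
#' Specialised riverine guilds score high, generalists low.
#'
#' @param hp `hp_matrix`.
#' @param guild guild id(s); default all rows.
#' @return Named numeric vector of PSI values in `[0, ncol(hp)]`.
#' @export
compute_psi <- function(hp, guild = rownames(hp)) {
  miss <- setdiff(guild, rownames(hp))
  if (length(miss))
    stop("unknown guild id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  rowSums(hp[guild, , drop = FALSE])
}

#' Remaining riverine habitat proportion (RHp)
#'
#' For guild i and barrier type b,
#' \deqn{RHp_{i,b} = \sum_j (HP_{i,j} \times HA_{b,j}) / \sum_j HP_{i,j},}
#' i.e. the composite altered habitat suitability normalised by the guild's
#' unaltered suitability (its PSI). RHp is a fraction in `[0, 2]`: 1 = no
#' change, 0 = total habitat loss, >1 = net gain.
#'
#' @param hp `hp_matrix`.
#' @param ha `ha_matrix` sharing the same criterion columns.
#' @param guild single guild id.
#' @param type single barrier type.
#' @return A single fraction.
#' @seealso [rhp_table()] for the full guild-by-type grid.
#' @export
compute_rhp <- function(hp, ha, guild, type) {
  rhp_table(hp, ha, guilds = guild, types = type)[guild, type]
}

#' RHp for every guild and barrier type
#'
#' @inheritParams compute_rhp
#' @param guilds,types subsets of rows to compute (defaults: all).
#' @return Matrix (class `rhp_table`) of fractions, guilds x barrier types.
#' @export
rhp_table <- function(hp, ha, guilds = rownames(hp), types = rownames(ha)) {
  if (!identical(colnames(hp), colnames(ha))) {
    if (!setequal(colnames(hp), colnames(ha)))
      stop("HP and HA criterion columns differ", call. = FALSE)
    ha <- ha[, colnames(hp), drop = FALSE]
  }
  miss <- setdiff(types, rownames(ha))
  if (length(miss))
    stop("unknown barrier type(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  psi <- compute_psi(hp, guilds)
  zero <- names(psi)[psi == 0]
  if (length(zero))
    stop("guild has no habitat preferences (PSI = 0): ",
         paste(zero, collapse = ", "), call. = FALSE)
  num <- hp[guilds, , drop = FALSE] %*% t(ha[types, , drop = FALSE])
  out <- sweep(num, 1, psi, "/")
  structure(out, class = c("rhp_table", "matrix", "array"))
}

#' Macrohabitat (expected guild proportion) profile
#'
#' @param proportions named numeric vector over guild ids, nonnegative,
#'   summing to 1 (tolerance 1e-9).
#' @param type_id optional macrohabitat type label.
#' @return Object of class `champ_profile`.
#' @export
champ_profile <- function(proportions, type_id = NULL) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)))
  if (any(proportions < 0)) stop("negative guild proportion", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("guild proportions must sum to 1 (got ", sum(proportions), ")",
         call. = FALSE)
  structure(proportions, type_id = type_id, class = "champ_profile")
}

#' Fish-community sensitivity of a macrohabitat to impoundment
#'
#' The guild PSI values weighted by their expected proportions in the
#' macrohabitat, as a percentage of the maximum attainable suitability
#' (= the criterion count, 21 for the default criterion set):
#' \deqn{sensitivity = 100 \sum_i PSI_i GP_i / n_{crit}.}
#' Classes: lowest (<45), moderate ([45, 55]), highest (>55).
#'
#' @param hp `hp_matrix`.
#' @param profile `champ_profile` (or named proportion vector) over guilds
#'   present in `hp`.
#' @param criterion_count denominator; defaults to `ncol(hp)`.
#' @param bounds two ordered class boundaries in percent.
#' @return List with `sensitivity` (percent) and `class`.
#' @export
compute_sensitivity <- function(hp, profile, criterion_count = ncol(hp),
                                bounds = c(45, 55)) {
  if (!inherits(profile, "champ_profile")) profile <- champ_profile(profile)
  g <- names(profile)
  psi <- compute_psi(hp, g)
  pct <- 100 * sum(psi * as.numeric(profile)) / criterion_count
  list(sensitivity = pct, class = classify_sensitivity(pct, bounds))
}

#' @rdname compute_sensitivity
#' @param percent sensitivity value(s) in percent.
#' @export
classify_sensitivity <- function(percent, bounds = c(45, 55)) {
  stopifnot(length(bounds) == 2, diff(bounds) >= 0)
  cls <- ifelse(percent < bounds[1], "lowest",
                ifelse(percent <= bounds[2], "moderate", "highest"))
  factor(cls, levels = c("lowest", "moderate", "highest"))
}

#' Weighted remaining riverine habitat proportion (wRHp)
#'
#' Guild-level RHp values weighted by the expected guild proportions of a
#' macrohabitat: \deqn{wRHp_b = \sum_i GP_i RHp_{i,b},} reported in percent
#' (0-200). 100% = no barrier impact; 0% = complete loss of suitable habitat.
#'
#' @param rhp `rhp_table` (guild x barrier-type fractions).
#' @param profile `champ_profile` over guilds present in `rhp`.
#' @param type barrier type(s); default all columns.
#' @return data.frame with `barrier_type`, `wRHp_percent`, `severity`.
#' @export
compute_wrhp <- function(rhp, profile, type = colnames(rhp)) {
  if (!inherits(profile, "champ_profile")) profile <- champ_profile(profile)
  miss <- setdiff(names(profile), rownames(rhp))
  if (length(miss))
    stop("guild(s) in profile missing from RHp table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss_t <- setdiff(type, colnames(rhp))
  if (length(miss_t))
    stop("unknown barrier type(s): ", paste(miss_t, collapse = ", "),
         call. = FALSE)
  w <- as.numeric(profile) %*% rhp[names(profile), type, drop = FALSE]
  pct <- 100 * as.numeric(w)
  data.frame(barrier_type = type, wRHp_percent = pct,
             severity = classify_alteration(pct), stringsAsFactors = FALSE)
}

#' Habitat-alteration severity class of a wRHp value
#'
#' Bins: severe (<=25), major (25-50], substantial (50-75], moderate (75-90],
#' low (>90). Values above 100% (net habitat gain for limnophilic/generalist
#' communities) fall in "low".
#'
#' @param percent wRHp value(s) in percent, within `[0, 200]`.
#' @return Factor with levels severe < major < substantial < moderate < low.
#' @export
classify_alteration <- function(percent) {
  if (any(percent < 0 | percent > 200, na.rm = TRUE))
    stop("wRHp percent outside [0, 200]", call. = FALSE)
  cut(percent, breaks = c(-Inf, 25, 50, 75, 90, Inf),
      labels = c("severe", "major", "substantial", "moderate", "low"),
      right = TRUE)
}

#' wRHp for every macrohabitat type and barrier type
#'
#' Convenience grid used for reporting: one row per (macrohabitat, barrier
#' type) pair.
#'
#' @param rhp `rhp_table`.
#' @param profiles named list of `champ_profile`s (names = macrohabitat ids).
#' @return Tidy data.frame: `macrohabitat_type`, `barrier_type`,
#'   `wRHp_percent`, `severity`.
#' @export
wrhp_grid <- function(rhp, profiles) {
  stopifnot(length(profiles) > 0, !is.null(names(profiles)))
  out <- do.call(rbind, lapply(names(profiles), function(id) {
    d <- compute_wrhp(rhp, profiles[[id]])
    cbind(macrohabitat_type = id, d, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
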