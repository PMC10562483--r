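# Domain vocabulary: habitat-use guilds, free-flowing habitat criteria,
# barrier types, and the HP / HA score matrices.

HP_SCORES <- c(0, 0.5, 1)
HA_SCORES <- c(0, 0.5, 1, 1.5, 2)

#' Habitat-use guilds
#'
#' The default set of 11 habitat-use guilds (HUGs), ordered from rheophilic /
#' intolerant to generalist / tolerant. Each guild groups fish species that
#' share dominant habitat needs during adult, rearing and growth life stages:
#' tolerance to environmental change, flow preference, position in the water
#' column, and substrate association.
#'
#' @return A data.frame with columns `id`, `name` and `traits`
#'   (semicolon-separated tags).
#' @examples
#' champ_guilds()$id
#' @export
champ_guilds <- function() {
  df <- data.frame(
    id = c("RH_INT", "RB_SG", "RW_SG", "RB_DP", "WC_INT", "LB_MT",
           "LW_MT", "LL_MT", "LP_MT", "B_MT", "GEN"),
    name = c(
      "intolerant highly rheophilic",
      "rheophilic benthic, sandy-gravel substrate",
      "rheophilic water column, sandy-gravel substrate",
      "intolerant rheophilic benthic, detritus/pelal substrate",
      "intolerant water column",
      "limnophilic benthic, moderate tolerance",
      "limnophilic water column, moderate tolerance",
      "limnophilic lithophilic, moderate tolerance",
      "limnophilic phytophilic, moderate tolerance",
      "benthic, moderate tolerance",
      "tolerant generalist"
    ),
    traits = c(
      "intolerant;rheophilic;water-column",
      "tolerant-moderate;rheophilic;benthic;sand-gravel",
      "tolerant-moderate;rheophilic;water-column;sand-gravel",
      "intolerant;rheophilic;benthic;detritus-pelal",
      "intolerant;water-column",
      "tolerant-moderate;limnophilic;benthic",
      "tolerant-moderate;limnophilic;water-column",
      "tolerant-moderate;limnophilic;lithophilic",
      "tolerant-moderate;limnophilic;phytophilic",
      "tolerant-moderate;benthic",
      "tolerant;generalist"
    ),
    stringsAsFactors = FALSE
  )
  df
}

#' Free-flowing riverine habitat criteria
#'
#' The default set of 21 habitat criteria likely to be modified by barrier
#' impoundment, grouped into ten categories (flow velocity, depth, substrate,
#' in-stream cover, physico-chemical conditions, vegetation, bank structure,
#' floodplain accessibility, habitat continuity, flow stability). The count is
#' configurable downstream: all score algebra uses the actual column set of the
#' matrices supplied.
#'
#' @return A data.frame with columns `id` and `category`.
#' @export
champ_criteria <- function() {
  data.frame(
    id = c("vel_high", "vel_low",
           "depth_deep", "depth_shallow",
           "sub_interstitial", "sub_sand", "sub_mud", "sub_gravel",
           "cov_wood", "cov_boulder",
           "pc_oxygen", "pc_temperature", "pc_nutrient",
           "veg_rheo_moss", "veg_macrophyte", "veg_canopy", "veg_overhang",
           "bank_undercut",
           "floodplain_access",
           "habitat_continuity",
           "flow_stability"),
    category = c("flow velocity", "flow velocity",
                 "depth", "depth",
                 "substrate", "substrate", "substrate", "substrate",
                 "in-stream cover", "in-stream cover",
                 "physico-chemical", "physico-chemical", "physico-chemical",
                 "vegetation", "vegetation", "vegetation", "vegetation",
                 "bank structure",
                 "floodplain accessibility",
                 "habitat continuity",
                 "flow stability"),
    stringsAsFactors = FALSE
  )
}

#' Barrier types
#'
#' The closed set of six in-river barrier types considered by the model.
#'
#' @return Character vector of the six type labels.
#' @export
barrier_types <- function() {
  c("dam", "weir", "sluice", "culvert", "ford", "ramp")
}

#' Coerce and check a barrier-type label
#'
#' @param x character vector of labels.
#' @return `x`, lowercased, after validation.
#' @export
as_barrier_type <- function(x) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x), barrier_types())
  if (length(bad))
    stop("unknown barrier type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  x
}

new_score_matrix <- function(values, class, allowed) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("score matrix needs row and column names", call. = FALSE)
  structure(m, class = c(class, "matrix", "array"), allowed = allowed)
}

#' Construct an HP (habitat preference) matrix
#'
#' Rows are guilds, columns habitat criteria; cells score the importance of a
#' criterion for a guild: 0 (not important), 0.5 (moderately important),
#' 1 (very important).
#'
#' @param values numeric matrix or data.frame with guild row names and
#'   criterion column names.
#' @param validate reject out-of-set cells immediately (default TRUE).
#' @return An object of class `hp_matrix`.
#' @export
hp_matrix <- function(values, validate = TRUE) {
  m <- new_score_matrix(values, "hp_matrix", HP_SCORES)
  if (validate) stop_on_violations(check_cells(m, HP_SCORES, "HP"))
  m
}

#' Construct an HA (habitat alteration) matrix
#'
#' Rows are barrier types, columns habitat criteria; cells score the relative
#' change of a criterion under impoundment by that barrier type: 0 (major
#' reduction), 0.5 (small reduction), 1 (no change), 1.5 (small increase),
#' 2 (major increase).
#'
#' @inheritParams hp_matrix
#' @return An object of class `ha_matrix`.
#' @export
ha_matrix <- function(values, validate = TRUE) {
  m <- new_score_matrix(values, "ha_matrix", HA_SCORES)
  rownames(m) <- as_barrier_type(rownames(m))
  if (validate) stop_on_violations(check_cells(m, HA_SCORES, "HA"))
  m
}

check_cells <- function(m, allowed, label) {
  bad <- which(matrix(!(m %in% allowed), nrow(m)), arr.ind = TRUE)
  if (!nrow(bad)) return(empty_violations())
  data.frame(
    check = "cell_value",
    row = rownames(m)[bad[, 1]],
    column = colnames(m)[bad[, 2]],
    detail = sprintf("%s cell %g not in {%s}", label,
                     m[bad], paste(allowed, collapse = ",")),
    stringsAsFactors = FALSE
  )
}

empty_violations <- function() {
  data.frame(check = character(), row = character(), column = character(),
             detail = character(), stringsAsFactors = FALSE)
}

stop_on_violations <- function(v) {
  if (nrow(v))
    stop("invalid score matrix:\n  ",
         paste(v$detail, collapse = "\n  "), call. = FALSE)
  invisible(v)
}

#' Validate a matched HP / HA matrix pair
#'
#' Collects every structural violation: out-of-set cells, missing or extra
#' guild rows, barrier-type rows, and criterion columns, and criterion
#' mismatches between the two matrices. An empty report means the pair is
#' valid for downstream scoring.
#'
#' @param hp `hp_matrix`.
#' @param ha `ha_matrix`.
#' @param guilds expected guild ids (default: the 11-guild set).
#' @param criteria expected criterion ids (default: the 21-criterion set);
#'   `NULL` skips the criterion-set check and only requires HP and HA to agree.
#' @param types expected barrier types.
#' @return A data.frame report (class `champ_validation`), zero rows iff valid.
#' @export
validate_matrices <- function(hp, ha,
                              guilds = champ_guilds()$id,
                              criteria = champ_criteria()$id,
                              types = barrier_types()) {
  v <- rbind(check_cells(hp, HP_SCORES, "HP"),
             check_cells(ha, HA_SCORES, "HA"))
  set_check <- function(found, expected, what) {
    miss <- setdiff(expected, found)
    extra <- setdiff(found, expected)
    rbind(
      if (length(miss))
        data.frame(check = paste0("missing_", what), row = miss, column = NA,
                   detail = sprintf("missing %s: %s", what, miss),
                   stringsAsFactors = FALSE),
      if (length(extra))
        data.frame(check = paste0("extra_", what), row = extra, column = NA,
                   detail = sprintf("unexpected %s: %s", what, extra),
                   stringsAsFactors = FALSE)
    )
  }
  v <- rbind(v, set_check(rownames(hp), guilds, "guild"))
  v <- rbind(v, set_check(rownames(ha), types, "barrier_type"))
  if (!is.null(criteria)) {
    v <- rbind(v, set_check(colnames(hp), criteria, "hp_criterion"))
    v <- rbind(v, set_check(colnames(ha), criteria, "ha_criterion"))
  }
  if (!identical(sort(colnames(hp)), sort(colnames(ha))))
    v <- rbind(v, data.frame(
      check = "criterion_mismatch", row = NA, column = NA,
      detail = "HP and HA criterion columns differ", stringsAsFactors = FALSE))
  class(v) <- c("champ_validation", "data.frame")
  v
}

#' @export
print.champ_validation <- function(x, ...) {
  if (!nrow(x)) cat("valid: no violations\n")
  else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Read an HP or HA matrix from CSV
#'
#' First column holds the guild id (HP) or barrier type (HA); the header row
#' holds criterion ids; cells are numeric scores.
#'
#' @param path CSV file path.
#' @return `hp_matrix` / `ha_matrix`.
#' @export
read_hp <- function(path) hp_matrix(read_score_csv(path))

#' @rdname read_hp
#' @export
read_ha <- function(path) ha_matrix(read_score_csv(path))

read_score_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (ncol(df) < 2) stop("cannot parse ", path, ": need id column + scores",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("cannot parse ", path, ": non-numeric cells",
                           call. = FALSE)
  rownames(m) <- ids
  m
}

#' Read a species-to-guild map from CSV
#'
#' Two columns: `species`, `guild_id`. Species names must be unique and every
#' guild id must belong to the supplied guild set.
#'
#' @param path CSV file path.
#' @param guilds allowed guild ids.
#' @return Named character vector: species -> guild id.
#' @export
read_species_map <- function(path, guilds = champ_guilds()$id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "guild_id") %in% names(df)))
    stop("species map needs columns species, guild_id", call. = FALSE)
  species_map(stats::setNames(df$guild_id, df$species), guilds)
}

#' @rdname read_species_map
#' @param map named character vector (names = species, values = guild ids).
#' @export
species_map <- function(map, guilds = champ_guilds()$id) {
  if (anyDuplicated(names(map)))
    stop("duplicate species in map", call. = FALSE)
  bad <- setdiff(unique(map), guilds)
  if (length(bad))
    stop("guild id(s) not in guild set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  map
}

#' Aggregate a species catch into guild proportions
#'
#' Abundances of mapped species are summed per guild and normalised to
#' proportions. Unmapped species are excluded from the denominator and
#' reported via a warning and the `unmapped` attribute.
#'
#' @param catch named numeric vector: species -> abundance (>= 0).
#' @param map species-to-guild map (see [species_map()]).
#' @param guilds guild ids defining the output order; guilds absent from the
#'   catch get proportion 0.
#' @return Named numeric vector of guild proportions summing to 1, with
#'   attribute `unmapped` listing excluded species.
#' @export
assign_guilds <- function(catch, map, guilds = sort(unique(unname(map)))) {
  stopifnot(is.numeric(catch), !is.null(names(catch)))
  if (any(catch < 0)) stop("negative abundance", call. = FALSE)
  mapped <- names(catch) %in% names(map)
  unmapped <- names(catch)[!mapped & catch > 0]
  if (length(unmapped))
    warning("unmapped species excluded: ", paste(unmapped, collapse = ", "),
            call. = FALSE)
  total <- sum(catch[mapped])
  if (total <= 0)
    stop("no mappable catch: all abundance in unmapped species", call. = FALSE)
  g <- map[names(catch)[mapped]]
  sums <- tapply(catch[mapped], factor(g, levels = guilds), sum, default = 0)
  out <- as.numeric(sums) / total
  names(out) <- guilds
  structure(out, unmapped = unmapped)
}
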