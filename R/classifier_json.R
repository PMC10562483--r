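# Plain-text serialisation of the fitted type classifier: the tree is
# flattened to a node list (variable, threshold or level set, children,
# leaf label) so a saved model reloads exactly, without binary state.

#' Serialise a type classifier to JSON
#'
#' Writes the tree as a list of nodes keyed by the usual binary heap
#' numbering (children of node i are 2i and 2i+1). Numeric splits are stored
#' as a threshold with the convention that values <= threshold go left
#' (thresholds are midpoints between observed values, so the convention
#' cannot disagree with the fitted tree on any observed value); categorical
#' splits store the set of levels routed left. Prediction from the reloaded
#' structure is handled by [predict_type_json()].
#'
#' @param classifier `champ_classifier`.
#' @param path output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to file.
#' @export
classifier_to_json <- function(classifier, path = NULL) {
  stopifnot(inherits(classifier, "champ_classifier"))
  fit <- classifier$tree
  if (is.null(fit)) {   # degenerate single-class model: one leaf
    obj <- list(attributes = classifier$attributes,
                levels = classifier$levels, kappa = classifier$kappa,
                nodes = list("1" = list(leaf = TRUE,
                                        label = classifier$constant)))
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (is.null(path)) return(as.character(js))
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  frame <- fit$frame
  ylev <- attr(fit, "ylevels")
  nodes <- list()
  split_row <- 1L
  splits <- fit$splits
  csplit <- fit$csplit
  for (i in seq_len(nrow(frame))) {
    node_id <- as.integer(rownames(frame)[i])
    if (frame$var[i] == "<leaf>") {
      nodes[[as.character(node_id)]] <-
        list(leaf = TRUE, label = ylev[frame$yval[i]])
    } else {
      s <- splits[split_row, , drop = TRUE]
      var <- as.character(frame$var[i])
      if (s[["ncat"]] > 1) {            # categorical split
        lev <- classifier$levels[[var]]
        dirs <- csplit[s[["index"]], seq_along(lev)]
        node <- list(leaf = FALSE, var = var,
                     left_levels = lev[dirs == 1],
                     left = 2L * node_id, right = 2L * node_id + 1L)
      } else {
        # numeric: rpart ncat = -1 routes x < cut to the first child,
        # ncat = +1 the reverse; record which child takes the <= side
        node <- list(leaf = FALSE, var = var,
                     threshold = unname(s[["index"]]),
                     le_goes = if (s[["ncat"]] > 0) "right" else "left",
                     left = 2L * node_id, right = 2L * node_id + 1L)
      }
      nodes[[as.character(node_id)]] <- node
      split_row <- split_row + 1L + frame$ncompete[i] + frame$nsurrogate[i]
    }
  }
  obj <- list(attributes = classifier$attributes,
              levels = classifier$levels,
              kappa = classifier$kappa,
              nodes = nodes)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Reload a serialised classifier
#'
#' @param path JSON file written by [classifier_to_json()] (or a JSON string).
#' @return List of class `champ_classifier_json` usable with
#'   [predict_type_json()].
#' @export
classifier_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(obj, class = "champ_classifier_json")
}

#' Predict from a JSON-serialised tree
#'
#' Walks the node list: numeric attributes route by threshold (ties at the
#' stored threshold follow the recorded side), categorical attributes by
#' membership in the left-level set. Unseen levels are rejected.
#'
#' @param model `champ_classifier_json`.
#' @param newdata data.frame with the model's attribute columns.
#' @return Character vector of type labels.
#' @export
predict_type_json <- function(model, newdata) {
  stopifnot(inherits(model, "champ_classifier_json"))
  attrs <- unlist(model$attributes)
  miss <- setdiff(attrs, names(newdata))
  if (length(miss))
    stop("missing attribute(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (v in names(model$levels)) {
    bad <- setdiff(unique(as.character(newdata[[v]])),
                   unlist(model$levels[[v]]))
    if (length(bad))
      stop("unseen level(s) in ", v, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  vapply(seq_len(nrow(newdata)), function(i) {
    id <- "1"
    repeat {
      node <- model$nodes[[id]]
      if (is.null(node)) stop("malformed tree: node ", id, call. = FALSE)
      if (isTRUE(node$leaf)) return(node$label)
      x <- newdata[[node$var]][i]
      go_left <- if (!is.null(node$threshold)) {
        le <- as.numeric(x) <= node$threshold
        if (identical(node$le_goes, "right")) !le else le
      } else {
        as.character(x) %in% unlist(node$left_levels)
      }
      id <- as.character(if (go_left) node$left else node$right)
    }
  }, character(1))
}
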