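# Macrohabitat typing: reciprocal-rank expected guild proportions (target
# fish community), Gower / city-block dissimilarities, medoid clustering,
# ANOSIM validation, and a decision-tree attribute -> type classifier.

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Expected guild proportions by reciprocal ranks (target fish community)
#'
#' Draws `n` reference sites of one macrohabitat type at random (without
#' replacement, from the sites sorted by id so the frame is order-invariant),
#' sums the observed guild proportions across the draw, ranks guilds by the
#' sums in descending order, and converts ranks to expected proportions:
#' reciprocal rank 1/r, normalised to sum 1. Tied sums receive their average
#' rank; guilds with zero summed proportion are excluded from ranking and get
#' expected proportion 0.
#'
#' @param sites data.frame of survey sites of a single type with a `site_id`
#'   column and one column per guild proportion.
#' @param guild_cols names of the guild-proportion columns.
#' @param n number of sites to draw (default 10).
#' @param seed RNG seed for the draw.
#' @param type_id optional label attached to the returned profile.
#' @return A [champ_profile()] over `guild_cols`.
#' @export
tfc_expected_proportions <- function(sites, guild_cols, n = 10, seed = NULL,
                                     type_id = NULL) {
  stopifnot(is.data.frame(sites), "site_id" %in% names(sites),
            all(guild_cols %in% names(sites)))
  if (nrow(sites) < n)
    stop("need at least ", n, " sites, got ", nrow(sites), call. = FALSE)
  sites <- sites[order(sites$site_id), , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(sites), n))
  sums <- colSums(sites[idx, guild_cols, drop = FALSE])
  reciprocal_rank_proportions(sums, type_id = type_id)
}

# Core reciprocal-rank step, exposed for oracle tests.
reciprocal_rank_proportions <- function(sums, type_id = NULL) {
  out <- numeric(length(sums))
  names(out) <- names(sums)
  pos <- sums > 0
  if (!any(pos)) stop("all guild sums are zero", call. = FALSE)
  r <- rank(-sums[pos], ties.method = "average")
  rec <- 1 / r
  out[pos] <- rec / sum(rec)
  champ_profile(out, type_id = type_id)
}

#' Site dissimilarity matrix
#'
#' Gower dissimilarity (mixed numeric / categorical attribute data; numeric
#' variables range-normalised, categorical mismatch 0/1, averaged over
#' variables) or city-block (Manhattan) distance for numeric data such as
#' guild proportions. Zero-range numeric variables carry no information under
#' Gower and are dropped with a warning.
#'
#' @param data data.frame (Gower: factors + numerics; cityblock: numeric).
#' @param vars columns to use; default all.
#' @param metric `"gower"` or `"cityblock"`.
#' @return A `dist` object with attribute `metric`.
#' @export
site_dissimilarity <- function(data, vars = names(data),
                               metric = c("gower", "cityblock")) {
  metric <- match.arg(metric)
  d <- data[, vars, drop = FALSE]
  if (metric == "gower") {
    d[] <- lapply(d, function(x) if (is.character(x)) factor(x) else x)
    num <- vapply(d, is.numeric, logical(1))
    rng <- vapply(d[num], function(x) diff(range(x)), numeric(1))
    if (any(rng == 0)) {
      warning("zero-range numeric variable(s) excluded from Gower: ",
              paste(names(rng)[rng == 0], collapse = ", "), call. = FALSE)
      d <- d[, !(names(d) %in% names(rng)[rng == 0]), drop = FALSE]
    }
    out <- cluster::daisy(d, metric = "gower")
    out <- stats::as.dist(as.matrix(out))   # plain dist, drop daisy extras
  } else {
    m <- as.matrix(d)
    if (!is.numeric(m)) stop("cityblock metric needs numeric data", call. = FALSE)
    out <- stats::dist(m, method = "manhattan")
  }
  attr(out, "metric") <- metric
  out
}

#' Partitioning around medoids
#'
#' Thin wrapper over [cluster::pam()] (BUILD + SWAP local search on a
#' precomputed dissimilarity). Deterministic for a given dissimilarity
#' matrix; no random initialisation is involved.
#'
#' @param d `dist` object or symmetric dissimilarity matrix.
#' @param k number of clusters, `2 <= k < n`.
#' @return List with `labels` (integer vector), `medoids` (indices),
#'   `objective` (total within-cluster dissimilarity to medoids), and the
#'   underlying `pam` fit.
#' @export
pam_cluster <- function(d, k) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k < 2 || k >= n)
    stop("k must satisfy 2 <= k < n (n = ", n, ")", call. = FALSE)
  fit <- cluster::pam(d, k = k, diss = TRUE)
  m <- as.matrix(d)
  med <- as.integer(fit$id.med)
  obj <- sum(m[cbind(seq_len(n), med[fit$clustering])])
  list(labels = as.integer(fit$clustering), medoids = med,
       objective = obj, fit = fit)
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs PAM for each k in `k_range` and tabulates the average silhouette
#' width; the returned `k` is the argmax, but the full table is kept so a
#' scree inspection can override it.
#'
#' @param d dissimilarity (`dist` or matrix).
#' @param k_range candidate cluster counts.
#' @return List with `k` and `table` (data.frame k, avg_silhouette).
#' @export
choose_k <- function(d, k_range = 2:8) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) stop("empty valid k_range", call. = FALSE)
  avg <- vapply(k_range, function(k) {
    lab <- pam_cluster(d, k)$labels
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  tab <- data.frame(k = k_range, avg_silhouette = avg)
  list(k = k_range[which.max(avg)], table = tab)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones. All n(n-1)/2 dissimilarities are ranked
#' (average ranks for ties) and
#' \deqn{R = (\bar r_{between} - \bar r_{within}) / (M/2), \quad M = n(n-1)/2.}
#' R lies in `[-1, 1]`; ~0 under no structure, 1 when every between-group
#' dissimilarity is larger than every within-group one. The p-value is the
#' fraction of label permutations (the observed labelling included) with a
#' permuted R at least the observed R. When the number of distinct label
#' arrangements is no larger than `permutations`, all of them are enumerated
#' and the p-value is exact; otherwise `permutations` random permutations are
#' drawn.
#'
#' @param d dissimilarity (`dist` or matrix).
#' @param labels group labels, >= 2 groups with >= 2 members each.
#' @param permutations maximum number of permutations (default 999).
#' @param seed RNG seed for the sampled-permutation case.
#' @return List with `R`, `p_value`, `permutations` used, and `exact`.
#' @export
champ_anosim <- function(d, labels, permutations = 999, seed = NULL) {
  m <- as.matrix(stats::as.dist(d))
  n <- nrow(m)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  lower <- lower.tri(m)
  r <- rank(m[lower])          # average ranks for ties
  M <- n * (n - 1) / 2
  stat <- function(lab) {
    within <- outer(lab, lab, "==")[lower]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  obs <- stat(labels)

  n_distinct <- count_label_arrangements(tab)
  if (!is.na(n_distinct) && n_distinct <= permutations) {
    perms <- enumerate_label_arrangements(labels)
    rs <- vapply(perms, stat, numeric(1))
    p <- mean(rs >= obs - 1e-12)
    list(R = obs, p_value = p, permutations = length(perms), exact = TRUE)
  } else {
    rs <- with_seed(seed, vapply(seq_len(permutations),
                                 function(i) stat(sample(labels)), numeric(1)))
    p <- (sum(rs >= obs - 1e-12) + 1) / (permutations + 1)
    list(R = obs, p_value = p, permutations = permutations, exact = FALSE)
  }
}

# Multinomial coefficient n! / prod(n_g!); NA if it overflows.
count_label_arrangements <- function(tab) {
  v <- exp(lgamma(sum(tab) + 1) - sum(lgamma(tab + 1)))
  if (!is.finite(v) || v > .Machine$integer.max) NA_real_ else round(v)
}

# All distinct assignments of the multiset of labels to positions.
enumerate_label_arrangements <- function(labels) {
  out <- list()
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      recurse(remaining[-i], c(acc, u))
    }
  }
  recurse(sort(labels), character())
  out
}

#' Cohen's kappa for a confusion matrix
#'
#' Chance-corrected agreement between predicted and observed class labels.
#'
#' @param confusion square contingency table (observed x predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m))
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Fit the attribute -> macrohabitat-type decision tree
#'
#' Greedy recursive binary partitioning (CART via [rpart::rpart()], Gini
#' impurity) on the physical attributes, followed by cost-complexity pruning
#' at `cp`. Training performance is summarised with Cohen's kappa.
#'
#' @param sites data.frame with the attribute columns and a `type` column
#'   (the macrohabitat label).
#' @param attributes attribute column names (default: Strahler order,
#'   catchment area, geology, climate zone — slope and altitude are carried as
#'   descriptive variables but excluded from modelling).
#' @param cp complexity parameter for pruning (default 0.01).
#' @param minsplit minimum node size to attempt a split.
#' @return Object of class `champ_classifier`: `tree` (rpart fit), `kappa`,
#'   `attributes`, `levels` seen for categorical attributes.
#' @export
fit_type_classifier <- function(sites,
                                attributes = c("strahler", "catchment_km2",
                                               "geology", "climate_zone"),
                                cp = 0.01, minsplit = 5) {
  stopifnot("type" %in% names(sites), all(attributes %in% names(sites)))
  df <- sites[, c("type", attributes), drop = FALSE]
  df$type <- factor(df$type)
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  if (nlevels(df$type) < 2) {
    warning("single-class input: degenerate one-leaf tree", call. = FALSE)
    lev <- lapply(df[attributes], function(x) if (is.factor(x)) levels(x))
    return(structure(list(tree = NULL, constant = levels(df$type),
                          kappa = NA_real_, attributes = attributes,
                          levels = lev[!vapply(lev, is.null, logical(1))]),
                     class = "champ_classifier"))
  }
  fit <- rpart::rpart(type ~ ., data = df, method = "class",
                      control = rpart::rpart.control(cp = cp,
                                                     minsplit = minsplit,
                                                     xval = 0))
  fit <- rpart::prune(fit, cp = cp)
  pred <- stats::predict(fit, df, type = "class")
  kap <- cohen_kappa(table(df$type, factor(pred, levels = levels(df$type))))
  lev <- lapply(df[attributes], function(x) if (is.factor(x)) levels(x))
  structure(list(tree = fit, kappa = kap, attributes = attributes,
                 levels = lev[!vapply(lev, is.null, logical(1))]),
            class = "champ_classifier")
}

#' Predict macrohabitat types for new attribute data
#'
#' Deterministic: each row follows the tree's splits to a leaf and takes the
#' leaf's majority type. Unseen categorical levels are rejected rather than
#' silently routed.
#'
#' @param classifier `champ_classifier` from [fit_type_classifier()].
#' @param newdata data.frame with the classifier's attribute columns.
#' @return Character vector of type labels.
#' @export
predict_type <- function(classifier, newdata) {
  stopifnot(inherits(classifier, "champ_classifier"))
  miss <- setdiff(classifier$attributes, names(newdata))
  if (length(miss))
    stop("missing attribute(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (v in names(classifier$levels)) {
    vals <- as.character(newdata[[v]])
    bad <- setdiff(unique(vals[!is.na(vals)]), classifier$levels[[v]])
    if (length(bad))
      stop("unseen level(s) in ", v, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    newdata[[v]] <- factor(vals, levels = classifier$levels[[v]])
  }
  if (is.null(classifier$tree))
    return(rep(classifier$constant, nrow(newdata)))
  as.character(stats::predict(classifier$tree, newdata, type = "class"))
}

#' Fill missing geology from an upstream neighbour
#'
#' River segments without geology take the value of the nearest upstream
#' segment that has one, when a segment -> downstream-segment topology is
#' supplied; without topology the gaps are flagged and left missing.
#'
#' @param sites data.frame with `site_id` and `geology` (NA = missing).
#' @param upstream_of optional named character vector mapping a site id to its
#'   nearest upstream site id.
#' @return `sites` with geology filled where possible; attribute `unfilled`
#'   lists ids still missing.
#' @export
fill_geology <- function(sites, upstream_of = NULL) {
  miss <- which(is.na(sites$geology))
  if (length(miss) && !is.null(upstream_of)) {
    for (i in miss) {
      id <- sites$site_id[i]
      seen <- character()
      while (!is.na(id) && id %in% names(upstream_of) && !(id %in% seen)) {
        seen <- c(seen, id)
        id <- upstream_of[[id]]
        g <- sites$geology[match(id, sites$site_id)]
        if (length(g) && !is.na(g)) { sites$geology[i] <- g; break }
      }
    }
  }
  unfilled <- sites$site_id[is.na(sites$geology)]
  if (length(unfilled))
    warning("geology still missing for: ", paste(unfilled, collapse = ", "),
            call. = FALSE)
  structure(sites, unfilled = unfilled)
}

#' Two-step macrohabitat typology
#'
#' Step one clusters the physical attributes (Gower dissimilarity, PAM);
#' step two appends the physical-cluster label (one-hot by default) to the
#' guild proportions, builds a city-block dissimilarity, and clusters again
#' into the final macrohabitat types.
#'
#' @param sites survey data.frame (see [read_surveys()] for the schema).
#' @param guild_cols guild-proportion column names.
#' @param physical_vars attribute columns for step one (slope and altitude are
#'   excluded by default).
#' @param k_physical,k_types cluster counts; `NULL` selects by silhouette over
#'   `k_range`.
#' @param k_range candidate k values when selecting automatically.
#' @param cluster_encoding `"onehot"` (0/1 indicator columns) or `"label"`
#'   (cluster index as one numeric column).
#' @return List: `physical` (step-one pam_cluster), `types` (step-two labels),
#'   `d_mixed` (step-two dissimilarity), `k` used at each step, and the
#'   silhouette tables when k was selected.
#' @export
two_step_typology <- function(sites, guild_cols,
                              physical_vars = c("strahler", "catchment_km2",
                                                "geology", "climate_zone"),
                              k_physical = NULL, k_types = NULL,
                              k_range = 2:10,
                              cluster_encoding = c("onehot", "label")) {
  cluster_encoding <- match.arg(cluster_encoding)
  d_phys <- site_dissimilarity(sites, physical_vars, "gower")
  sil_phys <- sil_types <- NULL
  if (is.null(k_physical)) {
    sel <- choose_k(d_phys, k_range); k_physical <- sel$k; sil_phys <- sel$table
  }
  phys <- pam_cluster(d_phys, k_physical)
  gp <- as.matrix(sites[, guild_cols, drop = FALSE])
  enc <- if (cluster_encoding == "onehot") {
    oh <- outer(phys$labels, sort(unique(phys$labels)), "==") * 1
    colnames(oh) <- paste0("pc", sort(unique(phys$labels)))
    oh
  } else {
    matrix(phys$labels, ncol = 1, dimnames = list(NULL, "pc"))
  }
  d_mixed <- site_dissimilarity(as.data.frame(cbind(gp, enc)),
                                metric = "cityblock")
  if (is.null(k_types)) {
    sel <- choose_k(d_mixed, k_range); k_types <- sel$k; sil_types <- sel$table
  }
  typ <- pam_cluster(d_mixed, k_types)
  list(physical = phys, types = typ$labels, type_medoids = typ$medoids,
       d_mixed = d_mixed, k = c(physical = k_physical, types = k_types),
       silhouette_physical = sil_phys, silhouette_types = sil_types)
}
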