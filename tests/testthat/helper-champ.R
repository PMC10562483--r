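# Shared fixture builders: everything is constructed in code.

fixture_path <- function(name) {
  system.file("extdata", name, package = "champ", mustWork = TRUE)
}

# tiny matched HP/HA pair with hand-checkable algebra
tiny_hp <- function() {
  hp_matrix(matrix(c(1, 0.5, 0,
                     0, 0.5, 1),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("c1", "c2", "c3"))))
}

tiny_ha <- function() {
  ha_matrix(matrix(c(0.5, 1.5, 2,
                     1,   1,   1,
                     0,   0,   0),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("dam", "ford", "weir"),
                                   c("c1", "c2", "c3"))))
}

# random valid HP/HA pair on shared criteria
random_matrices <- function(n_guilds, n_crit) {
  repeat {
    hp <- matrix(sample(c(0, 0.5, 1), n_guilds * n_crit, replace = TRUE),
                 n_guilds,
                 dimnames = list(paste0("g", seq_len(n_guilds)),
                                 paste0("c", seq_len(n_crit))))
    if (all(rowSums(hp) > 0)) break
  }
  ha <- matrix(sample(c(0, 0.5, 1, 1.5, 2), 6 * n_crit, replace = TRUE),
               6, dimnames = list(barrier_types(),
                                  paste0("c", seq_len(n_crit))))
  list(hp = hp_matrix(hp), ha = ha_matrix(ha))
}

# independent elementwise-loop oracle for RHp
rhp_loop_oracle <- function(hp, ha, guild, type) {
  num <- 0; den <- 0
  for (j in colnames(hp)) {
    num <- num + hp[guild, j] * ha[type, j]
    den <- den + hp[guild, j]
  }
  num / den
}

# exhaustive PAM objective: best total dissimilarity over all medoid sets
pam_exhaustive <- function(d, k) {
  m <- as.matrix(d)
  n <- nrow(m)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(m[, med, drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# exhaustive ANOSIM oracle: R and exact p over all distinct labelings
anosim_oracle <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  lower <- lower.tri(m)
  r <- rank(m[lower])
  M <- n * (n - 1) / 2
  stat <- function(lab) {
    w <- outer(lab, lab, "==")[lower]
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  perms <- apply(gtools_permutations(labels), 1, stat)
  obs <- stat(labels)
  list(R = obs, p = mean(perms >= obs - 1e-12))
}

# all distinct permutations of a label multiset (rows of a matrix)
gtools_permutations <- function(labels) {
  uniq <- unique(labels)
  rec <- function(rem) {
    if (!length(rem)) return(matrix(character(), 1, 0))
    out <- NULL
    for (u in intersect(uniq, rem)) {
      i <- match(u, rem)
      sub <- rec(rem[-i])
      out <- rbind(out, cbind(u, sub, deparse.level = 0))
    }
    out
  }
  rec(sort(labels))
}

# two clean separable blobs in 2-D for clustering checks
two_blobs <- function(n_per = 10, seed = 7) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_per, 0, 0.1), rnorm(n_per, 0, 0.1)),
             cbind(rnorm(n_per, 5, 0.1), rnorm(n_per, 5, 0.1)))
  list(x = x, labels = rep(1:2, each = n_per))
}
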