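# Independent oracles and scene factories shared across test files.
# These deliberately re-derive energies by direct enumeration rather than
# calling the solver under test.

random_scene <- function(n, span = 300) {
  gcff_scene(data.frame(id = paste0("p", seq_len(n)),
                        x = stats::runif(n, 0, span),
                        y = stats::runif(n, 0, span),
                        theta = stats::runif(n, -pi, pi)))
}

# two persons facing each other whose TS centres sit 2r apart on the x axis
pair_scene <- function(r, D) {
  gcff_scene(data.frame(id = c("a", "b"),
                        x = c(-r - D, r + D), y = c(0, 0),
                        theta = c(0, pi)))
}

# exhaustive enumeration over candidate subsets with per-person
# cheapest-centre assignment (uncapacitated facility location by brute force)
brute_force_subset_energy <- function(scene, candidates, params) {
  n <- nrow(scene)
  m <- nrow(candidates)
  M <- matrix(0, n, m)
  for (c in seq_len(m)) {
    for (i in seq_len(n)) {
      M[i, c] <- unary_cost(scene$x[i], scene$y[i], scene$theta[i],
                            candidates[c, ], params) +
        person_visibility_penalty(i, scene, candidates[c, ], params)
    }
  }
  best <- Inf
  for (mask in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) != 0)
    used <- unique(apply(M[, sel, drop = FALSE], 1, which.min))
    cost <- sum(apply(M[, sel, drop = FALSE], 1, min)) +
      params$mdl_weight * length(used)
    best <- min(best, cost)
  }
  best
}

# all set partitions of 1..n (restricted-growth recursion)
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# energy of a given partition with centres at member TS means
partition_energy <- function(scene, partition, params) {
  mu <- ts_centres(scene, params = params)
  centres <- t(vapply(partition,
                      function(ix) colMeans(mu[ix, , drop = FALSE]),
                      numeric(2L)))
  colnames(centres) <- c("u", "v")
  lab <- integer(nrow(scene))
  for (b in seq_along(partition)) lab[partition[[b]]] <- b
  a <- structure(list(labels = stats::setNames(as.integer(lab), scene$id),
                      centres = centres, energy = NA_real_),
                 class = "gcff_assignment")
  scene_cost(scene, a, params)
}

best_partition_energy <- function(scene, params) {
  min(vapply(all_partitions(nrow(scene)),
             function(p) partition_energy(scene, p, params), numeric(1L)))
}

groups_equal <- function(a, b) {
  a <- gcff:::as_gcff_groups(a)
  b <- gcff:::as_gcff_groups(b)
  isTRUE(all.equal(a$groups, b$groups)) &&
    identical(a$singletons, b$singletons)
}
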